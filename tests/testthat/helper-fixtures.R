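# Shared fixtures: a coarse phantom for fast structural tests and a
# homogeneous water block for dose-engine physics checks.

small_geometry <- function() default_geometry(c(32L, 32L, 32L), c(4, 4, 4))

small_snapshot <- function(seed = NULL) generate_phantom(small_geometry(), seed)

# homogeneous water block (SPR = 1 everywhere, external everywhere)
water_snapshot <- function(n = 48L, spacing = 3) {
  snap <- generate_phantom(default_geometry(rep(n, 3), rep(spacing, 3)))
  snap$spr_grid[] <- 1
  snap$masks$external[] <- TRUE
  snap
}

grid_center <- function(snapshot) {
  snapshot$origin + (dim(snapshot$spr_grid) - 1) * snapshot$spacing / 2
}

# a small hand-made plan (no optimization): a 3 x 3 lateral bundle of spots
# per beam at two energy layers around the primary target
tiny_plan <- function(snapshot, mu = 1) {
  ctr <- grid_center(snapshot)
  beams <- list(beam_spec(c(1, 0, 0)), beam_spec(c(-1, 0, 0)))
  lat <- expand.grid(y = ctr[2] + c(-8, 0, 8), z = ctr[3] + c(-8, 0, 8))
  spots <- NULL
  for (b in 1:2) {
    w <- water_equivalent_depth(snapshot, beams[[b]], c(ctr[2], ctr[3]))
    pri_cols <- which(snapshot$masks$CTV_pri[,
      which.min(abs(ctr[2] - (snapshot$origin[2] +
        (seq_len(dim(snapshot$spr_grid)[2]) - 1) * snapshot$spacing[2]))),
      which.min(abs(ctr[3] - (snapshot$origin[3] +
        (seq_len(dim(snapshot$spr_grid)[3]) - 1) * snapshot$spacing[3])))])
    wtg <- range(w$wed_mm[pri_cols])
    for (R in seq(wtg[1], wtg[2], length.out = 3)) {
      spots <- rbind(spots, data.frame(beam = b, y = lat$y, z = lat$z,
                                       R = R, mu = mu))
    }
  }
  plan_spec(beams, spots)
}
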