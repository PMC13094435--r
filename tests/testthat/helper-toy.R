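# A 2-spot toy optimization problem with a strictly convex objective,
# shared by the planner unit tests and the acceptance checks.

# a 2-spot toy problem on a water block: one beam, two laterally separated
# spots, and a quadratic (two-sided) target dose term at 1 Gy -- strictly
# convex, so the minimizer is unique and interior to [0, 2]^2
toy_problem <- function() {
  snap <- water_snapshot(n = 32L, spacing = 4)
  ctr <- grid_center(snap)
  geom <- list(beams = list(beam_spec(c(1, 0, 0))),
               spots = data.frame(beam = 1L, y = ctr[2] + c(-6, 6),
                                  z = ctr[3], R = 60, mu = 1))
  # a small slab target straddling both spots
  tgt <- array(FALSE, dim(snap$spr_grid))
  ix <- round((ctr - snap$origin) / snap$spacing) + 1
  tgt[(ix[1] - 1):(ix[1] + 1), (ix[2] - 2):(ix[2] + 2),
      (ix[3] - 1):(ix[3] + 1)] <- TRUE
  snap$masks$CTV_pri <- tgt
  vox_idx <- which(tgt)
  voxsets <- list(vox = vox_idx, sets = list(CTV_pri = seq_along(vox_idx)))
  objective <- rbind(
    data.frame(structure = "CTV_pri", type = "min_dose", dose = 1,
               weight = 1),
    data.frame(structure = "CTV_pri", type = "max_dose", dose = 1,
               weight = 1)
  )
  A <- scenario_influence(snap, geom$beams, geom$spots,
                          list(dx = 0, dy = 0, dz = 0, range_pct = 0),
                          vox_idx)
  list(snap = snap, geom = geom, voxsets = voxsets, objective = objective,
       A = as.matrix(A))
}

toy_f <- function(A, mu, ref = 1) {
  d <- as.numeric(A %*% mu)
  mean((d - ref)^2) / 70^2
}

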