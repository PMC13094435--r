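# Simplified analytic pencil-beam dose engine for scanned protons.
#
# Physics model: each spot deposits MU x B(WED; R) x G(lateral distance),
# where B is a single-peaked analytic Bragg curve evaluated at the
# water-equivalent depth along the (axis-parallel) ray and G a
# depth-independent lateral Gaussian. Range errors multiply the
# stopping-power grid by (1 + r/100); setup errors rigidly translate the
# patient relative to the beam (resample SPR into the beam frame, compute
# dose there, resample the dose back). The engine is deterministic and
# exactly linear in the spot MU vector.

#' Default engine parameters
#'
#' @param sigma_lateral lateral Gaussian sigma in mm.
#' @param peak_sigma Bragg-peak width parameter in mm.
#' @param plateau entrance-plateau level relative to the peak Gaussian.
#' @param col_eps relative lateral-weight threshold below which a grid
#'   column is skipped for one energy layer (exact linearity in MU is
#'   preserved because the threshold is relative).
#' @export
engine_params <- function(sigma_lateral = 7, peak_sigma = 5, plateau = 0.35,
                          col_eps = 1e-4) {
  list(sigma_lateral = sigma_lateral, peak_sigma = peak_sigma,
       plateau = plateau, col_eps = col_eps)
}

#' Analytic Bragg depth-dose curve
#'
#' B(w; R) = exp(-(w - R)^2 / (2 s^2)) + p * Phi((R - w) / s): a Gaussian
#' peak at the nominal range on top of a smoothly terminated entrance
#' plateau. Single-peaked, smooth, with the distal 80% falloff within a few
#' mm of R.
#'
#' @param wed water-equivalent depth(s) in mm.
#' @param range_mm nominal range R in mm (> 0).
#' @param params engine parameters, see [engine_params()].
#' @return dose per unit MU (arbitrary units), same shape as `wed`.
#' @export
bragg_curve <- function(wed, range_mm, params = engine_params()) {
  stopifnot(range_mm > 0)
  .bragg_u(wed - range_mm, params)
}

# shared depth-dose kernel as a function of u = wed - R; the engine and
# bragg_curve() evaluate the identical expression
.bragg_u <- function(u, params) {
  s <- params$peak_sigma
  exp(-u^2 / (2 * s^2)) + params$plateau * .plateau_phi(-u / s)
}

#' Beam specification
#'
#' Only axis-parallel beams along +/- x are supported (two lateral opposed
#' fields by default); the direction must be a signed unit vector along x.
#'
#' @param direction length-3 unit vector, (+-1, 0, 0).
#' @param spot_spacing lateral spot grid spacing in mm.
#' @param layer_spacing energy-layer spacing expressed in nominal-range mm.
#' @export
beam_spec <- function(direction, spot_spacing = 10, layer_spacing = 8) {
  if (!isTRUE(all.equal(sum(direction^2), 1)) ||
      any(direction[2:3] != 0) || abs(direction[1]) != 1) {
    stop("direction must be a unit vector along +x or -x")
  }
  if (spot_spacing <= 0 || layer_spacing <= 0) stop("spacings must be > 0")
  structure(list(direction = direction, spot_spacing = spot_spacing,
                 layer_spacing = layer_spacing), class = "beam_spec")
}

#' Construct a plan specification
#'
#' @param beams list of [beam_spec()].
#' @param spots data.frame with columns `beam` (index into `beams`), `y`,
#'   `z` (lateral position, mm, grid coordinates), `R` (nominal range in
#'   water, mm) and `mu` (monitor-unit weight, >= 0).
#' @param prescriptions named numeric, Gy(RBE): `CTV_pri`, `CTV_pro`.
#' @param n_fractions fractions over which the plan is delivered.
#' @param robustness_setting length-2 numeric `c(RR_pct, SR_mm)` used at
#'   optimization.
#' @param params engine parameters.
#' @export
plan_spec <- function(beams, spots,
                      prescriptions = c(CTV_pri = 70, CTV_pro = 54.25),
                      n_fractions = 35L, robustness_setting = c(3, 3),
                      params = engine_params()) {
  stopifnot(length(beams) >= 1, nrow(spots) >= 1,
            all(prescriptions > 0), all(spots$mu >= 0), all(spots$R > 0))
  structure(list(beams = beams, spots = spots, prescriptions = prescriptions,
                 n_fractions = as.integer(n_fractions),
                 robustness_setting = robustness_setting,
                 rbe_factor = 1.1, params = params),
            class = "plan_spec")
}

#' Water-equivalent depth profile along a ray
#'
#' Cumulative WED (integral of SPR along the beam direction) sampled at the
#' voxel centers of the grid column nearest to the requested lateral
#' position.
#'
#' @param snapshot a `phantom_snapshot`.
#' @param beam a [beam_spec()].
#' @param lateral_position length-2 (y, z) position in mm (grid coords).
#' @return data.frame with `depth_mm` (geometric depth along the beam from
#'   the entry face) and `wed_mm`.
#' @export
water_equivalent_depth <- function(snapshot, beam, lateral_position) {
  d <- dim(snapshot$spr_grid)
  crd <- .axis_coords(d, snapshot$spacing, snapshot$origin)
  j <- which.min(abs(crd[[2]] - lateral_position[1]))
  k <- which.min(abs(crd[[3]] - lateral_position[2]))
  if (abs(crd[[2]][j] - lateral_position[1]) > snapshot$spacing[2] / 2 ||
      abs(crd[[3]][k] - lateral_position[2]) > snapshot$spacing[3] / 2) {
    return(data.frame(depth_mm = numeric(0), wed_mm = numeric(0)))
  }
  spr <- snapshot$spr_grid[, j, k]
  dxm <- snapshot$spacing[1]
  if (beam$direction[1] < 0) spr <- rev(spr)
  wed <- (cumsum(spr) - spr / 2) * dxm
  data.frame(depth_mm = (seq_len(d[1]) - 0.5) * dxm, wed_mm = wed)
}

# Core: dose field in the patient frame for a set of spots.
# Spots within one beam and nominal range share the depth-dose field, so
# the computation is grouped by energy layer: dose_layer(x, y, z) =
# L(y, z) * B(WED(x, y, z); R) with L the MU-weighted sum of spot
# Gaussians. Lateral spot coordinates live in the (unshifted) grid frame;
# under a setup shift the whole patient is resampled into the beam frame
# and the dose resampled back.
.dose_field <- function(snapshot, beams, spots, range_scale = 0,
                        setup_shift = c(0, 0, 0), params = engine_params(),
                        columns = NULL) {
  cache <- .layer_cache(snapshot, beams, spots, params, columns)
  .dose_from_cache(snapshot, cache, range_scale, setup_shift, params)
}

# Precompute, per (beam, energy layer): the MU-weighted lateral fluence on
# its active grid columns. These maps do not depend on the error scenario,
# so an evaluation over many scenarios builds the cache once.
.layer_cache <- function(snapshot, beams, spots, params, columns = NULL) {
  d <- dim(snapshot$spr_grid)
  crd <- .axis_coords(d, snapshot$spacing, snapshot$origin)
  s2 <- 2 * params$sigma_lateral^2
  layers <- list()
  for (b in seq_along(beams)) {
    bspots <- spots[spots$beam == b, , drop = FALSE]
    if (!nrow(bspots)) next
    for (R in unique(bspots$R)) {
      lsp <- bspots[bspots$R == R, , drop = FALSE]
      L <- matrix(0, d[2], d[3])
      for (si in seq_len(nrow(lsp))) {
        if (lsp$mu[si] == 0) next
        gy <- exp(-(crd[[2]] - lsp$y[si])^2 / s2)
        gz <- exp(-(crd[[3]] - lsp$z[si])^2 / s2)
        L <- L + lsp$mu[si] * outer(gy, gz)
      }
      mx <- max(L)
      if (mx == 0) next
      cols <- which(L > params$col_eps * mx)
      if (!is.null(columns)) cols <- cols[cols %in% columns]
      if (!length(cols)) next
      layers[[length(layers) + 1L]] <-
        list(beam = b, direction = beams[[b]]$direction[1], R = R,
             cols = cols, L = L[cols])
    }
  }
  layers
}

# dose for one error scenario from a prebuilt layer cache; `wed_base`
# optionally carries the per-beam-direction WED fields of the already
# shifted (but unscaled) SPR grid, so the two +/- range scenarios of one
# setup shift share the ray tracing
.dose_from_cache <- function(snapshot, cache, range_scale = 0,
                             setup_shift = c(0, 0, 0),
                             params = engine_params(), wed_base = NULL) {
  stopifnot(abs(range_scale) <= 10, all(is.finite(setup_shift)))
  d <- dim(snapshot$spr_grid)
  sp <- snapshot$spacing
  nyz <- d[2] * d[3]
  shifted <- any(setup_shift != 0)
  if (is.null(wed_base)) {
    wed_base <- .shifted_wed(snapshot, setup_shift,
                             unique(vapply(cache, `[[`, numeric(1),
                                           "direction")))
  }
  scale <- 1 + range_scale / 100
  dose <- matrix(0, d[1], nyz)
  for (ly in cache) {
    w <- wed_base[[as.character(ly$direction)]]
    B <- .bragg_u(w[, ly$cols, drop = FALSE] * scale - ly$R, params)
    dose[, ly$cols] <- dose[, ly$cols] + B * rep(ly$L, each = d[1])
  }
  dim(dose) <- d
  if (shifted) dose <- shift_grid(dose, -setup_shift, sp, "linear", fill = 0)
  dose
}

# WED fields of the setup-shifted SPR grid, one per beam direction,
# as [nx, nyz] matrices keyed by direction
.shifted_wed <- function(snapshot, setup_shift, directions) {
  d <- dim(snapshot$spr_grid)
  air <- min(snapshot$spr_grid)
  spr <- snapshot$spr_grid
  if (any(setup_shift != 0)) {
    spr <- shift_grid(spr, setup_shift, snapshot$spacing, "linear",
                      fill = air)
  }
  out <- list()
  for (dir in directions) {
    w <- wed_field(spr, snapshot$spacing[1], direction = dir)
    dim(w) <- c(d[1], prod(d[-1]))
    out[[as.character(dir)]] <- w
  }
  out
}

#' Dose of a single spot
#'
#' @param snapshot a `phantom_snapshot`.
#' @param beam a [beam_spec()].
#' @param spot one-row data.frame (or list) with `y`, `z`, `R`, `mu`.
#' @param range_scale signed range error in percent (|r| <= 10).
#' @param setup_shift length-3 setup shift in mm.
#' @param params engine parameters.
#' @return 3-D dose array co-registered with the snapshot grid.
#' @export
spot_dose <- function(snapshot, beam, spot, range_scale = 0,
                      setup_shift = c(0, 0, 0), params = engine_params()) {
  spots <- data.frame(beam = 1L, y = spot$y, z = spot$z, R = spot$R,
                      mu = spot$mu)
  .dose_field(snapshot, list(beam), spots, range_scale, setup_shift, params)
}

#' Dose of a full plan under one error scenario
#'
#' Sum of all spot doses; exactly linear in the MU vector.
#'
#' @inheritParams spot_dose
#' @param plan a [plan_spec()].
#' @param columns optional integer vector of (y, z) column indices (linear
#'   into the ny x nz plane) to which the computation is restricted;
#'   voxels in other columns are returned as zero. Used internally to
#'   speed up target-region scenario evaluation.
#' @export
plan_dose <- function(snapshot, plan, range_scale = 0,
                      setup_shift = c(0, 0, 0), columns = NULL) {
  .dose_field(snapshot, plan$beams, plan$spots, range_scale, setup_shift,
              plan$params, columns = columns)
}

#' MU-weighted mean proton range of a plan
#'
#' R_mean = sum(MU_i R_i) / sum(MU_i), the normalization length used to
#' express the absolute range-uncertainty component in relative form.
#'
#' @param plan a [plan_spec()].
#' @return R_mean in mm.
#' @export
mu_weighted_mean_range <- function(plan) {
  mu <- plan$spots$mu
  if (sum(mu) <= 0) stop("all spot MU are zero")
  sum(mu * plan$spots$R) / sum(mu)
}
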