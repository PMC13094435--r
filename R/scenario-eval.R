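# Scenario sets, voxel-wise min/max dose envelopes, DVH metrics,
# patient-specific range uncertainty and target-coverage pass/fail flags.

#' Optimization scenario set (14 scenarios)
#'
#' Seven isocenter shifts (no shift, +/- the setup magnitude along each
#' axis) crossed with two range shifts (+/- the range magnitude). Exact
#' duplicates arising from degenerate magnitudes (SR = 0 or RR = 0) are
#' removed.
#'
#' @param sr_mm setup robustness magnitude in mm (>= 0).
#' @param rr_pct range robustness magnitude in percent (>= 0).
#' @return a `scenario_set` data.frame with `dx`, `dy`, `dz` (mm) and
#'   `range_pct`, plus a `provenance` attribute.
#' @export
optimization_scenarios <- function(sr_mm, rr_pct) {
  if (sr_mm < 0 || rr_pct < 0) stop("robustness magnitudes must be >= 0")
  shifts <- rbind(c(0, 0, 0),
                  sr_mm * diag(3), -sr_mm * diag(3))
  .scenario_set(shifts, rr_pct, "optimization")
}

#' Evaluation scenario set (28 scenarios)
#'
#' Fourteen setup directions -- the six axis-aligned and the eight body
#' diagonals, each scaled to the full setup magnitude -- crossed with +/-
#' the range magnitude. Duplicates from degenerate magnitudes are removed.
#'
#' @param setup_mm setup shift magnitude in mm (>= 0).
#' @param range_pct range shift magnitude in percent (>= 0).
#' @param diagonal "magnitude" (default: diagonal shift vectors normalized
#'   so |shift| = setup_mm) or "component" (setup_mm per component).
#' @export
evaluation_scenarios <- function(setup_mm, range_pct,
                                 diagonal = c("magnitude", "component")) {
  if (setup_mm < 0 || range_pct < 0) stop("magnitudes must be >= 0")
  diagonal <- match.arg(diagonal)
  axes <- rbind(diag(3), -diag(3))
  diag_dirs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  if (diagonal == "magnitude") diag_dirs <- diag_dirs / sqrt(3)
  shifts <- setup_mm * rbind(axes, unname(diag_dirs))
  .scenario_set(shifts, range_pct, "rct_evaluation")
}

.scenario_set <- function(shifts, range_pct, provenance) {
  df <- data.frame(
    dx = rep(shifts[, 1], times = 2),
    dy = rep(shifts[, 2], times = 2),
    dz = rep(shifts[, 3], times = 2),
    range_pct = rep(c(range_pct, -range_pct), each = nrow(shifts))
  )
  df <- unique(df)
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("scenario_set", "data.frame")
  df
}

#' Range-uncertainty model
#'
#' @param relative_1sd relative 1-SD component in percent (default 1.2).
#' @param absolute_1sd absolute 1-SD component in mm (default 0.5).
#' @param sd_multiplier scaling to the working confidence level
#'   (default 1.5 SD).
#' @export
range_uncertainty_model <- function(relative_1sd = 1.2, absolute_1sd = 0.5,
                                    sd_multiplier = 1.5) {
  stopifnot(relative_1sd >= 0, absolute_1sd >= 0, sd_multiplier >= 0)
  list(relative_1sd = relative_1sd, absolute_1sd = absolute_1sd,
       sd_multiplier = sd_multiplier)
}

#' Patient-specific range uncertainty
#'
#' The absolute 1-SD component is normalized to the plan's MU-weighted mean
#' proton range, added to the relative component and scaled to the working
#' SD level: multiplier x (relative + 100 x absolute / R_mean), in percent.
#' Strictly decreasing in R_mean with asymptote multiplier x relative.
#'
#' @param r_mean_mm MU-weighted mean range in mm (> 0).
#' @param model a [range_uncertainty_model()].
#' @return range uncertainty in percent at the working SD level.
#' @export
patient_range_uncertainty <- function(r_mean_mm,
                                      model = range_uncertainty_model()) {
  if (r_mean_mm <= 0) stop("R_mean must be > 0")
  model$sd_multiplier * (model$relative_1sd +
                           100 * model$absolute_1sd / r_mean_mm)
}

#' Voxel-wise minimum and maximum dose envelopes
#'
#' @param scenario_doses list of co-registered 3-D dose arrays.
#' @return list with `vwmin` and `vwmax` arrays.
#' @export
voxelwise_envelopes <- function(scenario_doses) {
  stopifnot(length(scenario_doses) >= 1)
  d <- dim(scenario_doses[[1]])
  for (x in scenario_doses) {
    if (!identical(dim(x), d)) stop("dose grids are not co-registered")
  }
  vwmin <- scenario_doses[[1]]
  vwmax <- scenario_doses[[1]]
  for (x in scenario_doses[-1]) {
    vwmin <- pmin(vwmin, x)
    vwmax <- pmax(vwmax, x)
  }
  list(vwmin = vwmin, vwmax = vwmax)
}

#' DVH quantile metric D_v%
#'
#' The minimum dose received by the hottest v% of the structure volume.
#' Convention (frozen): sort structure doses descending and linearly
#' interpolate at position 1 + (n - 1) v / 100, i.e. the type-7 quantile of
#' the dose distribution at probability 1 - v/100.
#'
#' @param dose 3-D dose array.
#' @param mask logical array, non-empty.
#' @param v_pct volume percentage in (0, 100).
#' @return dose in Gy(RBE).
#' @export
dvh_metric <- function(dose, mask, v_pct) {
  if (!any(mask)) stop("empty structure mask")
  if (v_pct <= 0 || v_pct >= 100) stop("v_pct must be in (0, 100)")
  d <- sort(dose[mask], decreasing = TRUE)
  n <- length(d)
  h <- 1 + (n - 1) * v_pct / 100
  i <- floor(h)
  if (i >= n) return(d[n])
  d[i] + (h - i) * (d[i + 1] - d[i])
}

#' Target-coverage pass/fail flags
#'
#' Coverage passes when, in the voxel-wise minimum distribution, D98% of
#' the CTV receives at least 94% of its prescription; hot spots pass when
#' the CTV_pri D2% of the voxel-wise maximum stays at or below 110% of the
#' primary prescription. Boundary comparisons are inclusive.
#'
#' @param metrics named list/vector with `pri_D98_vwmin`, `pro_D98_vwmin`,
#'   `pri_D2_vwmax` in Gy(RBE).
#' @param prescriptions named numeric with `CTV_pri`, `CTV_pro`.
#' @return named logical vector `pri_D98_pass`, `pro_D98_pass`,
#'   `pri_D2_pass`.
#' @export
coverage_flags <- function(metrics, prescriptions) {
  if (is.na(prescriptions["CTV_pri"]) || is.na(prescriptions["CTV_pro"])) {
    stop("missing prescription")
  }
  c(pri_D98_pass = unname(metrics[["pri_D98_vwmin"]] >=
                            0.94 * prescriptions[["CTV_pri"]]),
    pro_D98_pass = unname(metrics[["pro_D98_vwmin"]] >=
                            0.94 * prescriptions[["CTV_pro"]]),
    pri_D2_pass = unname(metrics[["pri_D2_vwmax"]] <=
                           1.10 * prescriptions[["CTV_pri"]]))
}

# columns (linear indices into the ny x nz plane) within ~15 mm of the
# prophylactic target projection: generous enough to cover evaluation
# shifts and anatomical drift of the CTV masks, computed by 2-D dilation
# of the beam's-eye-view projection
.target_region_columns <- function(snapshot) {
  n_iter <- ceiling(15 / min(snapshot$spacing[2:3]))
  proj <- apply(snapshot$masks$CTV_pro, c(2, 3), any)
  d <- dim(proj)
  for (i in seq_len(n_iter)) {
    p <- proj
    p[-1, ] <- p[-1, ] | proj[-d[1], ]
    p[-d[1], ] <- p[-d[1], ] | proj[-1, ]
    p[, -1] <- p[, -1] | proj[, -d[2]]
    p[, -d[2]] <- p[, -d[2]] | proj[, -1]
    proj <- p
  }
  which(proj)
}

#' Evaluation configuration
#'
#' @param setup_mm setup shift magnitude for the 28-scenario evaluation.
#' @param range_mode "fixed" (use `range_pct`) or "patient" (derive the
#'   magnitude from the plan's R_mean via [patient_range_uncertainty()]).
#' @param range_pct fixed range magnitude in percent (used when
#'   `range_mode = "fixed"`).
#' @param uncertainty_model a [range_uncertainty_model()] (used when
#'   `range_mode = "patient"`).
#' @export
eval_config <- function(setup_mm = 3, range_mode = c("fixed", "patient"),
                        range_pct = 3,
                        uncertainty_model = range_uncertainty_model()) {
  range_mode <- match.arg(range_mode)
  list(setup_mm = setup_mm, range_mode = range_mode, range_pct = range_pct,
       uncertainty_model = uncertainty_model)
}

#' Robust evaluation of a plan on one anatomy snapshot
#'
#' Builds the 28-scenario evaluation set (range magnitude fixed or
#' patient-specific), computes all scenario doses plus the nominal dose
#' (zero shift, zero range error; not part of the 28), the voxel-wise
#' min/max envelopes, the D98/D2 DVH metrics and the coverage flags.
#'
#' @param plan a [plan_spec()].
#' @param snapshot a `phantom_snapshot`.
#' @param config an [eval_config()].
#' @return a `robust_eval` list: `nominal`, `vwmin`, `vwmax` dose arrays,
#'   `metrics`, `flags`, `range_pct_used`, `n_scenarios`, `timepoint_week`.
#' @export
evaluate_plan_on_snapshot <- function(plan, snapshot, config = eval_config()) {
  range_pct <- if (config$range_mode == "patient") {
    patient_range_uncertainty(mu_weighted_mean_range(plan),
                              config$uncertainty_model)
  } else {
    config$range_pct
  }
  scen <- evaluation_scenarios(config$setup_mm, range_pct)
  if (nrow(scen) == 0) stop("evaluation scenario set is empty")
  # the scenario doses only enter through CTV DVH metrics, so their
  # computation is restricted to grid columns around the targets (a
  # generous dilation that covers anatomy drift and setup shifts); the
  # nominal dose, which feeds OAR mean doses downstream, stays full-grid.
  # The per-layer lateral maps are scenario-independent and the +/- range
  # scenarios of one setup shift share the ray tracing, so both are reused.
  cols <- .target_region_columns(snapshot)
  cache <- .layer_cache(snapshot, plan$beams, plan$spots, plan$params, cols)
  dirs <- unique(vapply(cache, `[[`, numeric(1), "direction"))
  shift_key <- paste(scen$dx, scen$dy, scen$dz)
  doses <- vector("list", nrow(scen))
  for (key in unique(shift_key)) {
    rows <- which(shift_key == key)
    v <- c(scen$dx[rows[1]], scen$dy[rows[1]], scen$dz[rows[1]])
    wed <- .shifted_wed(snapshot, v, dirs)
    for (i in rows) {
      doses[[i]] <- .dose_from_cache(snapshot, cache, scen$range_pct[i], v,
                                     plan$params, wed_base = wed)
    }
  }
  env <- voxelwise_envelopes(doses)
  nominal <- plan_dose(snapshot, plan)
  metrics <- list(
    pri_D98_vwmin = dvh_metric(env$vwmin, snapshot$masks$CTV_pri, 98),
    pro_D98_vwmin = dvh_metric(env$vwmin, snapshot$masks$CTV_pro, 98),
    pri_D2_vwmax = dvh_metric(env$vwmax, snapshot$masks$CTV_pri, 2)
  )
  structure(
    list(nominal = nominal, vwmin = env$vwmin, vwmax = env$vwmax,
         metrics = metrics,
         flags = coverage_flags(metrics, plan$prescriptions),
         range_pct_used = range_pct, n_scenarios = nrow(scen),
         timepoint_week = snapshot$timepoint_week),
    class = "robust_eval"
  )
}
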