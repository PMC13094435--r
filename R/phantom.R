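# Synthetic head-and-neck phantom cohorts: a cylindrical neck with
# ellipsoidal targets and organs-at-risk on a regular voxel grid, weekly
# anatomy snapshots with progressive radial shrinkage (weight-loss-like
# neck slimming) and per-snapshot rigid positioning offsets, and
# fraction/repeat-CT calendars.

#' Default neck-phantom geometry
#'
#' Cylindrical external contour with voxelized ellipsoidal structures:
#' primary and prophylactic clinical target volumes (CTV_pri, CTV_pro),
#' both parotid and submandibular glands, the three pharyngeal constrictor
#' muscles, oral cavity and cricopharyngeal muscle. Coordinates are mm,
#' axes (x lateral, y anterior-posterior, z cranio-caudal); structure
#' centers are offsets from the grid center.
#'
#' @param grid_dim integer length-3 grid size in voxels (>= 32 per axis).
#' @param spacing voxel spacing in mm per axis.
#' @return a geometry parameter list consumed by [generate_phantom()].
#' @export
default_geometry <- function(grid_dim = c(48L, 48L, 48L), spacing = c(3, 3, 3)) {
  list(
    grid_dim = as.integer(grid_dim),
    spacing = as.numeric(spacing),
    origin = c(0, 0, 0),
    external_radius = 55,
    air_spr = 0.001,
    tissue_spr = 1.0,
    center_jitter_sd = 1.5,   # mm, per-patient anatomical variation
    radius_jitter_sd = 0.04,  # relative
    structures = list(
      CTV_pri         = list(center = c(0, 8, 0),     radii = c(15, 15, 18)),
      CTV_pro         = list(center = c(0, 8, 0),     radii = c(23, 23, 26)),
      parotid_L       = list(center = c(-38, -5, 8),  radii = c(9, 11, 13)),
      parotid_R       = list(center = c(38, -5, 8),   radii = c(9, 11, 13)),
      submandibular_L = list(center = c(-22, 14, -18), radii = c(7, 7, 8)),
      submandibular_R = list(center = c(22, 14, -18),  radii = c(7, 7, 8)),
      PCM_superior    = list(center = c(0, 30, 20),   radii = c(12, 5, 9)),
      PCM_medius      = list(center = c(0, 30, 0),    radii = c(12, 5, 9)),
      PCM_inferior    = list(center = c(0, 30, -20),  radii = c(12, 5, 9)),
      oral_cavity     = list(center = c(0, -20, 10),  radii = c(16, 12, 12)),
      cricopharyngeal = list(center = c(0, 24, -32),  radii = c(8, 6, 5))
    )
  )
}

#' Names of the organ-at-risk structures in a phantom
#' @export
oar_structures <- function() {
  c("parotid_L", "parotid_R", "submandibular_L", "submandibular_R",
    "PCM_superior", "PCM_medius", "PCM_inferior", "oral_cavity",
    "cricopharyngeal")
}

#' Generate a week-0 phantom snapshot
#'
#' Builds the voxelized stopping-power grid and binary structure masks for
#' one synthetic patient at planning time. With a seed, structure centers
#' and radii are jittered (patient-to-patient anatomical variation);
#' without one the nominal geometry is returned. Organs-at-risk are cropped
#' to be disjoint from CTV_pri and all structures are cropped to the
#' external contour; a structure extending outside the external contour
#' before cropping, or an empty structure, is a configuration error.
#'
#' @param geometry geometry list from [default_geometry()].
#' @param seed optional integer; applies per-patient jitter when given.
#' @return a `phantom_snapshot`: list with `spr_grid`, `masks` (named list
#'   of logical arrays incl. `external`), `spacing`, `origin`,
#'   `timepoint_week` (0).
#' @export
generate_phantom <- function(geometry = default_geometry(), seed = NULL) {
  g <- geometry
  if (any(g$grid_dim < 32L)) {
    stop("configuration error: grid must be at least 32 voxels per axis")
  }
  structures <- g$structures
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    shared <- stats::rnorm(3, 0, g$center_jitter_sd)  # CTVs move together
    for (nm in names(structures)) {
      jc <- if (nm %in% c("CTV_pri", "CTV_pro")) shared
            else stats::rnorm(3, 0, g$center_jitter_sd)
      jr <- exp(stats::rnorm(3, 0, g$radius_jitter_sd))
      structures[[nm]]$center <- structures[[nm]]$center + jc
      structures[[nm]]$radii <- structures[[nm]]$radii * jr
    }
    # keep the prophylactic volume a strict superset of the primary
    structures$CTV_pro$radii <- pmax(structures$CTV_pro$radii,
                                     structures$CTV_pri$radii + 2)
  }
  if (any(vapply(structures, function(s) any(s$radii <= 0), logical(1)))) {
    stop("configuration error: non-positive structure radius")
  }
  crd <- .axis_coords(g$grid_dim, g$spacing, g$origin)
  center <- g$origin + (g$grid_dim - 1) * g$spacing / 2
  dx2 <- outer((crd[[1]] - center[1])^2, (crd[[2]] - center[2])^2, "+")
  external <- array(FALSE, g$grid_dim)
  inside <- dx2 <= g$external_radius^2
  for (k in seq_len(g$grid_dim[3])) external[, , k] <- inside

  masks <- list()
  for (nm in names(structures)) {
    s <- structures[[nm]]
    m <- .ellipsoid_mask(crd, center + s$center, s$radii)
    if (!any(m)) stop("configuration error: structure ", nm, " is empty")
    if (any(m & !external)) {
      stop("configuration error: structure ", nm,
           " extends outside the external contour")
    }
    masks[[nm]] <- m
  }
  for (nm in oar_structures()) {
    masks[[nm]] <- masks[[nm]] & !masks$CTV_pri
    if (!any(masks[[nm]])) {
      stop("configuration error: structure ", nm, " is empty after cropping")
    }
  }
  masks$CTV_pro <- masks$CTV_pro | masks$CTV_pri
  masks$external <- external

  spr <- array(g$air_spr, g$grid_dim)
  spr[external] <- g$tissue_spr

  structure(
    list(spr_grid = spr, masks = masks, spacing = g$spacing,
         origin = g$origin, timepoint_week = 0L, geometry = g),
    class = "phantom_snapshot"
  )
}

.ellipsoid_mask <- function(crd, center, radii) {
  u2 <- lapply(1:3, function(a) ((crd[[a]] - center[a]) / radii[a])^2)
  q <- outer(u2[[1]], u2[[2]], "+")
  m <- array(FALSE, lengths(crd))
  for (k in seq_along(u2[[3]])) m[, , k] <- q + u2[[3]][k] <= 1
  m
}

#' @export
print.phantom_snapshot <- function(x, ...) {
  cat("phantom_snapshot: ", paste(dim(x$spr_grid), collapse = "x"),
      " voxels @ ", paste(x$spacing, collapse = "x"), " mm, week ",
      x$timepoint_week, "\n", sep = "")
  vols <- vapply(x$masks, mask_volume, numeric(1), spacing = x$spacing)
  print(round(vols / 1000, 1))  # cm^3
  invisible(x)
}

#' Evolve phantom anatomy to a later week
#'
#' Applies the weekly anatomy-change model: a global radial scaling about
#' the patient (z) axis that shrinks the external contour (and everything
#' inside it, parotids moving medially) such that volumes compound as
#' (1 - rate)^week, plus an optional rigid positioning offset representing
#' inter-fraction setup variation at the repeat-CT. Masks are resampled
#' nearest-neighbour, the stopping-power grid with linear interpolation,
#' and SPR outside the new external contour is reset to air. With rate 0
#' and zero offset the snapshot is returned unchanged except for the
#' timepoint.
#'
#' @param snapshot a week-0 `phantom_snapshot`.
#' @param week integer >= 1 target week.
#' @param drift list with `rate` (volume fraction lost per week, in
#'   [0, 0.1]) and optional `setup_offset_mm` (length-3, default zero).
#' @return a `phantom_snapshot` at the requested week.
#' @export
evolve_anatomy <- function(snapshot, week, drift) {
  stopifnot(inherits(snapshot, "phantom_snapshot"), week >= 1)
  rate <- drift$rate
  if (is.null(rate) || rate < 0 || rate > 0.1) {
    stop("drift rate must be in [0, 0.1] per week")
  }
  offset <- drift$setup_offset_mm %||% c(0, 0, 0)
  s_r <- (1 - rate)^(week / 2)  # radial factor: volume scales (1-rate)^week

  out <- snapshot
  out$timepoint_week <- as.integer(week)
  if (s_r == 1 && all(offset == 0)) return(out)

  g <- snapshot$geometry %||% list()
  air <- g$air_spr %||% min(snapshot$spr_grid)
  center <- snapshot$origin + (dim(snapshot$spr_grid) - 1) * snapshot$spacing / 2

  out$spr_grid <- .radial_scale(snapshot$spr_grid, s_r, center,
                                snapshot$spacing, snapshot$origin,
                                linear = TRUE, fill = air)
  out$masks <- lapply(snapshot$masks, function(m) {
    .radial_scale(m, s_r, center, snapshot$spacing, snapshot$origin,
                  linear = FALSE, fill = FALSE)
  })
  if (any(offset != 0)) {
    out$spr_grid <- shift_grid(out$spr_grid, offset, snapshot$spacing,
                               "linear", fill = air)
    out$masks <- lapply(out$masks, function(m) {
      shift_grid(m, offset, snapshot$spacing, "nearest", fill = FALSE) > 0.5
    })
  }
  out$spr_grid[!out$masks$external] <- air
  empty <- names(out$masks)[!vapply(out$masks, any, logical(1))]
  if (length(empty)) {
    stop("degenerate anatomy: structure(s) collapsed to zero voxels: ",
         paste(empty, collapse = ", "))
  }
  out
}

# scale content radially about the z axis by factor s (inverse mapping),
# separable 1-D resampling in x then y
.radial_scale <- function(arr, s, center, spacing, origin, linear, fill) {
  if (!is.logical(arr[1])) storage.mode(arr) <- "double"
  for (ax in 1:2) {
    n <- dim(arr)[ax]
    x <- origin[ax] + (seq_len(n) - 1) * spacing[ax]
    src <- center[ax] + (x - center[ax]) / s        # sample position (mm)
    idx <- (src - origin[ax]) / spacing[ax] + 1     # fractional index
    arr <- .resample_axis(arr, ax, idx, linear, fill)
  }
  if (!linear) arr > 0.5 else arr
}

.resample_axis <- function(arr, axis, idx, linear, fill) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr * 1, perm)
  dp <- dim(a)
  dim(a) <- c(dp[1], prod(dp[-1]))
  if (linear) {
    i0 <- floor(idx)
    t <- idx - i0
    out <- (1 - t) * .gather_rows(a, i0, fill * 1) +
      t * .gather_rows(a, i0 + 1, fill * 1)
  } else {
    out <- .gather_rows(a, round(idx), fill * 1)
  }
  dim(out) <- dp
  aperm(out, order(perm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a fraction and repeat-CT calendar
#'
#' Conventional fractionation delivers 5 fractions per week (weekdays 1-5);
#' accelerated delivers 6 per week. Day 1 is the Monday of week 1. Repeat
#' CTs are acquired once per week starting week 1, on the mid-week day
#' (day 3 of each week).
#'
#' @param n_fractions integer >= 1 (35 for a standard course).
#' @param n_rcts number of weekly repeat CTs, one of 5, 6, 7.
#' @param pattern "conventional" or "accelerated".
#' @return a `fraction_schedule`: list with `fraction_days`, `rct_days`.
#' @export
build_schedule <- function(n_fractions, n_rcts,
                           pattern = c("conventional", "accelerated")) {
  pattern <- match.arg(pattern)
  stopifnot(n_fractions >= 1)
  if (!n_rcts %in% c(5L, 6L, 7L)) stop("n_rcts must be 5, 6 or 7")
  per_week <- if (pattern == "conventional") 5L else 6L
  i <- seq_len(n_fractions)
  week <- ceiling(i / per_week)
  dayofweek <- i - (week - 1L) * per_week
  structure(
    list(fraction_days = (week - 1L) * 7L + dayofweek,
         rct_days = (seq_len(n_rcts) - 1L) * 7L + 3L,
         pattern = pattern),
    class = "fraction_schedule"
  )
}

#' Cohort specification
#'
#' @param n_patients number of synthetic patients.
#' @param n_rcts_distribution named integer vector: how many patients get
#'   5, 6 or 7 weekly repeat CTs; must sum to `n_patients`.
#' @param anatomy_drift list with `mean`, `sd`, `max`: per-patient weekly
#'   volume-loss rate drawn from a normal truncated to [0, max]; and
#'   `setup_sd_mm` (length 3): SD of the rigid per-rCT positioning offset.
#' @param n_fractions fractions in the course (default 35).
#' @param geometry phantom geometry, see [default_geometry()].
#' @param seed global integer seed; per-patient substreams are derived from
#'   it so that changing the cohort size does not perturb earlier patients.
#' @export
cohort_spec <- function(n_patients,
                        n_rcts_distribution = c(`5` = 3L, `6` = 21L, `7` = 2L),
                        anatomy_drift = list(mean = 0.015, sd = 0.01,
                                             max = 0.05,
                                             setup_sd_mm = c(1, 3, 3)),
                        n_fractions = 35L,
                        geometry = default_geometry(),
                        seed = 1L) {
  if (any(n_rcts_distribution < 0)) stop("distribution counts must be >= 0")
  if (sum(n_rcts_distribution) != n_patients) {
    stop("n_rcts_distribution counts must sum to n_patients")
  }
  if (anatomy_drift$mean < 0 || anatomy_drift$max > 0.1) {
    stop("shrinkage rate must lie in [0, 0.1] per week")
  }
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  structure(
    list(n_patients = as.integer(n_patients),
         n_rcts_distribution = n_rcts_distribution,
         anatomy_drift = anatomy_drift,
         n_fractions = as.integer(n_fractions),
         geometry = geometry, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# deterministic per-patient substream seed (kept below 2^31)
.patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 48271 * i) %% 2147483629)
}

.rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  u <- stats::runif(1, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# clinical covariates drawn with the study population frequencies
.sample_factors <- function() {
  list(
    baseline_xerostomia = sample(c("none_a_bit", "moderate_severe"), 1,
                                 prob = c(24, 2)),
    baseline_dysphagia = sample(c("grade_0_1", "grade_2_3"), 1,
                                prob = c(17, 9)),
    weight_loss = sample(c("none", "upto_10pct", "over_10pct"), 1,
                         prob = c(12, 10, 4)),
    modality = sample(c("chemoradiation", "conventional", "accelerated"), 1,
                      prob = c(13, 9, 4))
  )
}

#' Generate a synthetic patient cohort
#'
#' For each patient: a jittered week-0 planning snapshot, a per-patient
#' weekly shrinkage rate from a truncated normal, one evolved snapshot per
#' weekly repeat CT (with a random rigid positioning offset each), clinical
#' covariates sampled with the study-population frequencies, and a
#' fraction/rCT calendar matching the patient's treatment modality.
#'
#' @param spec a [cohort_spec()].
#' @return list of patients; each has `id`, `drift_rate`, `factors`,
#'   `snapshots` (week 0 first, then one per rCT), `schedule`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_rcts_each <- rep(as.integer(names(spec$n_rcts_distribution)),
                     times = spec$n_rcts_distribution)
  lapply(seq_len(spec$n_patients), function(i) {
    pseed <- .patient_seed(spec$seed, i)
    baseline <- generate_phantom(spec$geometry, seed = pseed)
    set.seed(pseed + 1L)
    drift_rate <- .rtruncnorm1(spec$anatomy_drift$mean, spec$anatomy_drift$sd,
                               0, spec$anatomy_drift$max)
    factors <- .sample_factors()
    n_rcts <- n_rcts_each[i]
    sd_mm <- spec$anatomy_drift$setup_sd_mm %||% c(0, 0, 0)
    offsets <- matrix(stats::rnorm(3 * n_rcts, 0, rep(sd_mm, n_rcts)),
                      nrow = 3)
    snapshots <- vector("list", n_rcts + 1L)
    snapshots[[1L]] <- baseline
    for (k in seq_len(n_rcts)) {
      snapshots[[k + 1L]] <- evolve_anatomy(
        baseline, week = k,
        drift = list(rate = drift_rate, setup_offset_mm = offsets[, k])
      )
    }
    pattern <- if (factors$modality == "accelerated") "accelerated"
               else "conventional"
    list(id = i, seed = pseed, drift_rate = drift_rate, factors = factors,
         snapshots = snapshots,
         schedule = build_schedule(spec$n_fractions, n_rcts, pattern))
  })
}
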