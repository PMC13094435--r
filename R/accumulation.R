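# Treatment-course dose accumulation: each fraction's dose is represented
# by the plan recalculated on the repeat CT acquired closest in time, and
# the nominal, voxel-wise-minimum and voxel-wise-maximum distributions are
# summed with weight 1/n_fractions over the course. Synthetic snapshots
# share one grid, so voxel-wise summation is exact (no registration).

#' Map treatment fractions to the nearest repeat CT
#'
#' Each fraction day is assigned the rCT with the smallest absolute day
#' difference; ties break toward the earlier rCT.
#'
#' @param schedule a `fraction_schedule` from [build_schedule()].
#' @return integer vector: for each fraction, the index of its rCT.
#' @export
map_fractions_to_rcts <- function(schedule) {
  fd <- schedule$fraction_days
  rd <- schedule$rct_days
  stopifnot(length(fd) >= 1, length(rd) >= 1)
  vapply(fd, function(day) {
    dist <- abs(rd - day)
    which.min(dist)  # which.min returns the first (earlier) minimum on ties
  }, integer(1))
}

#' Accumulate dose over the treatment course
#'
#' Evaluates the plan once per distinct mapped rCT snapshot (cached) and
#' sums the nominal, voxel-wise-minimum and voxel-wise-maximum
#' distributions with per-fraction weight 1/n_fractions. Accumulated DVH
#' metrics and per-OAR mean doses are computed on the planning-CT
#' structures (all snapshots share the grid).
#'
#' @param plan a [plan_spec()].
#' @param snapshots list of `phantom_snapshot`s: planning CT first, then
#'   one per rCT (as produced by [generate_cohort()]).
#' @param schedule the patient's `fraction_schedule`.
#' @param config an [eval_config()] for the per-rCT robust evaluations.
#' @param evals optional pre-computed list of `robust_eval` objects, one
#'   per rCT snapshot (avoids recomputation when the weekly evaluations
#'   are also needed individually).
#' @return a `course_accumulation`: `acc_nominal`, `acc_vwmin`, `acc_vwmax`
#'   arrays, `fraction_map`, `metrics` (accumulated D98/D2), `oar_mean`
#'   (per-OAR mean of the accumulated nominal dose), `flags`.
#' @export
accumulate_course <- function(plan, snapshots, schedule,
                              config = eval_config(setup_mm = 1,
                                                   range_mode = "patient"),
                              evals = NULL) {
  fmap <- map_fractions_to_rcts(schedule)
  n_rcts <- length(schedule$rct_days)
  if (length(snapshots) != n_rcts + 1L) {
    stop("expected one planning snapshot plus one snapshot per rCT")
  }
  if (max(fmap) > n_rcts) stop("fraction mapped to a missing rCT")
  n_frac <- length(schedule$fraction_days)
  weights <- tabulate(fmap, nbins = n_rcts) / n_frac

  if (is.null(evals)) evals <- vector("list", n_rcts)
  acc <- NULL
  for (r in seq_len(n_rcts)) {
    if (weights[r] == 0 && is.null(evals[[r]])) next
    if (is.null(evals[[r]])) {
      evals[[r]] <- evaluate_plan_on_snapshot(plan, snapshots[[r + 1L]],
                                              config)
    }
    e <- evals[[r]]
    contrib <- list(nominal = e$nominal * weights[r],
                    vwmin = e$vwmin * weights[r],
                    vwmax = e$vwmax * weights[r])
    if (is.null(acc)) {
      acc <- contrib
    } else {
      acc$nominal <- acc$nominal + contrib$nominal
      acc$vwmin <- acc$vwmin + contrib$vwmin
      acc$vwmax <- acc$vwmax + contrib$vwmax
    }
  }
  planning <- snapshots[[1L]]
  metrics <- list(
    pri_D98_vwmin = dvh_metric(acc$vwmin, planning$masks$CTV_pri, 98),
    pro_D98_vwmin = dvh_metric(acc$vwmin, planning$masks$CTV_pro, 98),
    pri_D2_vwmax = dvh_metric(acc$vwmax, planning$masks$CTV_pri, 2)
  )
  oar_mean <- vapply(oar_structures(), function(nm) {
    mean(acc$nominal[planning$masks[[nm]]])
  }, numeric(1))
  composite <- Reduce(`|`, planning$masks[oar_structures()])
  oar_mean <- c(oar_mean, composite_OAR = mean(acc$nominal[composite]))
  structure(
    list(acc_nominal = acc$nominal, acc_vwmin = acc$vwmin,
         acc_vwmax = acc$vwmax, fraction_map = fmap, weights = weights,
         metrics = metrics, oar_mean = oar_mean,
         flags = coverage_flags(metrics, plan$prescriptions),
         evals = evals),
    class = "course_accumulation"
  )
}

#' Course-level coverage verdicts
#'
#' Applies the same D98/D2 thresholds as the weekly evaluation to the
#' accumulated voxel-wise minimum/maximum maps.
#'
#' @param acc a `course_accumulation`.
#' @param prescriptions named prescriptions.
#' @return named logical vector as in [coverage_flags()].
#' @export
patient_course_verdicts <- function(acc, prescriptions) {
  coverage_flags(acc$metrics, prescriptions)
}
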