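# End-to-end orchestration: cohort -> plan suite -> weekly robust
# evaluations -> course accumulation -> failure-rate statistics, NTCP and
# trade-off slopes.

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()].
#' @param settings list of robustness settings `c(RR_pct, SR_mm)`; must
#'   include the reference.
#' @param reference reference setting (default `c(3, 3)`).
#' @param rct_eval [eval_config()] for the weekly rCT evaluations
#'   (default: 1 mm setup, patient-specific 1.5-SD range uncertainty).
#' @param acceptance_eval [eval_config()] for plan acceptance on the
#'   planning CT (default 3 mm / 3%); only used when `acceptance_check`.
#' @param acceptance_check also evaluate every plan on the planning CT.
#' @param confidence,alpha,delta Wilson confidence level, test level, and
#'   TOST equivalence margin (proportion scale).
#' @param ntcp_models named list of [ntcp_model()]s (default: the shipped
#'   synthetic example models).
#' @param planner_args list passed through to [build_plan_suite()]
#'   (objective, mimic/control parameters, spot geometry arguments).
#' @param outdir optional output directory for CSV artifacts.
#' @export
pipeline_config <- function(cohort,
                            settings = list(c(3, 3), c(2, 3), c(1, 3),
                                            c(3, 2), c(3, 1)),
                            reference = c(3, 3),
                            rct_eval = eval_config(setup_mm = 1,
                                                   range_mode = "patient"),
                            acceptance_eval = eval_config(setup_mm = 3,
                                                          range_pct = 3),
                            acceptance_check = FALSE,
                            confidence = 0.95, alpha = 0.05, delta = 0.10,
                            ntcp_models = NULL,
                            planner_args = list(),
                            outdir = NULL) {
  is_ref <- vapply(settings, function(s) all(s == reference), logical(1))
  if (!any(is_ref)) stop("settings must include the reference setting")
  if (any(vapply(settings, function(s) any(s < 0), logical(1)))) {
    stop("robustness magnitudes must be >= 0")
  }
  structure(
    list(cohort = cohort, settings = settings, reference = reference,
         rct_eval = rct_eval, acceptance_eval = acceptance_eval,
         acceptance_check = acceptance_check, confidence = confidence,
         alpha = alpha, delta = delta, ntcp_models = ntcp_models,
         planner_args = planner_args, outdir = outdir),
    class = "pipeline_config"
  )
}

#' Run the full robustness-versus-adaptation analysis
#'
#' Deterministic under the cohort seed. For every patient: builds the
#' reference and margin-reduced plan suite on the planning snapshot,
#' robustly evaluates every plan on every weekly rCT (producing one
#' pass/fail flags row per patient x setting x rCT), accumulates the
#' nominal / voxel-wise min / voxel-wise max dose over the course, and
#' converts accumulated mean OAR doses into NTCP. Then aggregates failure
#' rates with Wilson intervals, pairwise z-tests vs the reference with
#' Holm correction, TOST equivalence conclusions, and OLS trade-off
#' slopes.
#'
#' @param config a [pipeline_config()].
#' @param verbose print one progress line per patient/setting.
#' @return list with `flags`, `failure_table`, `comparisons`, `course`,
#'   `slopes`, `summary_text`, `seed`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  models <- config$ntcp_models %||% synthetic_ntcp_models()
  cohort <- generate_cohort(config$cohort)
  labels <- vapply(config$settings, setting_label, character(1))

  flags <- NULL
  course <- NULL
  for (p in cohort) {
    plans <- do.call(build_plan_suite,
                     c(list(snapshot = p$snapshots[[1]],
                            settings = config$settings,
                            reference = config$reference),
                       config$planner_args))
    n_rcts <- length(p$snapshots) - 1L
    for (li in seq_along(labels)) {
      lbl <- labels[li]
      plan <- plans[[lbl]]
      evals <- vector("list", n_rcts)
      for (r in seq_len(n_rcts)) {
        evals[[r]] <- evaluate_plan_on_snapshot(plan, p$snapshots[[r + 1L]],
                                                config$rct_eval)
        e <- evals[[r]]
        flags <- rbind(flags, data.frame(
          patient = p$id, setting = lbl,
          rr_pct = config$settings[[li]][1], sr_mm = config$settings[[li]][2],
          week = e$timepoint_week, range_pct_used = e$range_pct_used,
          pri_D98_vwmin = e$metrics$pri_D98_vwmin,
          pro_D98_vwmin = e$metrics$pro_D98_vwmin,
          pri_D2_vwmax = e$metrics$pri_D2_vwmax,
          pri_D98_pass = unname(e$flags["pri_D98_pass"]),
          pro_D98_pass = unname(e$flags["pro_D98_pass"]),
          pri_D2_pass = unname(e$flags["pri_D2_pass"])
        ))
      }
      acc <- accumulate_course(plan, p$snapshots, p$schedule,
                               config$rct_eval, evals = evals)
      if (config$acceptance_check) {
        pa <- evaluate_plan_on_snapshot(plan, p$snapshots[[1]],
                                        config$acceptance_eval)
        acc_pass <- all(pa$flags)
      } else {
        acc_pass <- NA
      }
      ntcps <- vapply(models, function(m) {
        ntcp(m, as.list(acc$oar_mean), p$factors)
      }, numeric(1))
      row <- data.frame(
        patient = p$id, setting = lbl,
        rr_pct = config$settings[[li]][1], sr_mm = config$settings[[li]][2],
        acc_pri_D98 = acc$metrics$pri_D98_vwmin,
        acc_pro_D98 = acc$metrics$pro_D98_vwmin,
        acc_pri_D2 = acc$metrics$pri_D2_vwmax,
        acc_pri_D98_pass = unname(acc$flags["pri_D98_pass"]),
        acc_pro_D98_pass = unname(acc$flags["pro_D98_pass"]),
        acc_pri_D2_pass = unname(acc$flags["pri_D2_pass"]),
        plan_acceptance_pass = acc_pass,
        total_ntcp = total_ntcp(ntcps)
      )
      for (nm in names(acc$oar_mean)) row[[paste0("mean_", nm)]] <-
        unname(acc$oar_mean[nm])
      for (nm in names(ntcps)) row[[paste0("ntcp_", nm)]] <-
        unname(ntcps[nm])
      course <- rbind(course, row)
      if (verbose) {
        message(sprintf("patient %d setting %s: %d/%d weekly D98 passes",
                        p$id, lbl, sum(flags$pri_D98_pass[
                          flags$patient == p$id & flags$setting == lbl]),
                        n_rcts))
      }
    }
  }

  ft <- failure_rates(flags)
  ci <- t(vapply(seq_len(nrow(ft)), function(i) {
    wilson_ci(ft$n_failures[i], ft$n_evaluations[i], config$confidence)
  }, numeric(2)))
  ft$ci_lower <- ci[, 1]
  ft$ci_upper <- ci[, 2]

  comparisons <- .pairwise_comparisons(ft, labels,
                                       setting_label(config$reference),
                                       config$alpha, config$delta)
  report <- report_tradeoffs(course, ft, config$settings, config$reference)

  out <- list(flags = flags, failure_table = ft, comparisons = comparisons,
              course = course, slopes = report$slopes,
              summary_text = report$summary_text, seed = config$cohort$seed)
  if (!is.null(config$outdir)) .write_artifacts(out, config$outdir)
  out
}

# z-tests vs reference with per-criterion Holm families, plus TOST
.pairwise_comparisons <- function(ft, labels, ref_label, alpha, delta) {
  out <- NULL
  for (cn in c("pri_D98", "pro_D98", "pri_D2")) {
    ref <- ft[ft$setting == ref_label & ft$criterion == cn, ]
    rows <- NULL
    for (lbl in setdiff(labels, ref_label)) {
      cmp <- ft[ft$setting == lbl & ft$criterion == cn, ]
      zt <- tryCatch(two_proportion_ztest(cmp$n_failures, cmp$n_evaluations,
                                          ref$n_failures,
                                          ref$n_evaluations),
                     error = function(e) list(z = NA_real_, p = NA_real_))
      ts <- tryCatch(tost_equivalence(cmp$n_failures, cmp$n_evaluations,
                                      ref$n_failures, ref$n_evaluations,
                                      delta, alpha),
                     error = function(e) list(equivalent = NA))
      rows <- rbind(rows, data.frame(
        criterion = cn, setting = lbl, reference = ref_label,
        z = zt$z, p_raw = zt$p, equivalent = ts$equivalent
      ))
    }
    if (!is.null(rows)) {
      ok <- !is.na(rows$p_raw)
      rows$p_holm <- NA_real_
      if (any(ok)) rows$p_holm[ok] <- holm_bonferroni(rows$p_raw[ok])
      rows$significant <- !is.na(rows$p_holm) & rows$p_holm < alpha
      out <- rbind(out, rows)
    }
  }
  out
}

#' Trade-off slopes and summary
#'
#' OLS slopes of CTV failure rate (percentage points), mean composite OAR
#' dose (Gy(RBE)), and NTCP (percentage points) versus the range
#' robustness setting (setup fixed at the reference) and versus the setup
#' robustness setting (range fixed at the reference).
#'
#' @param course course-level data.frame from [run_pipeline()].
#' @param failure_table failure-rate table from [failure_rates()] (with or
#'   without CI columns).
#' @param settings,reference as in [pipeline_config()].
#' @return list with `slopes` data.frame (`series`, `quantity`, `slope`,
#'   `slope_se`, `unit`) and `summary_text`.
#' @export
report_tradeoffs <- function(course, failure_table, settings,
                             reference = c(3, 3)) {
  rr <- vapply(settings, `[`, numeric(1), 1)
  sr <- vapply(settings, `[`, numeric(1), 2)
  labels <- vapply(settings, setting_label, character(1))
  series <- list(RR = which(sr == reference[2]), SR = which(rr == reference[1]))
  xs_of <- list(RR = rr, SR = sr)

  slopes <- NULL
  for (ax in names(series)) {
    idx <- series[[ax]]
    if (length(idx) < 2) {
      warning("fewer than two settings along the ", ax, " axis; ",
              "slope omitted")
      next
    }
    x <- xs_of[[ax]][idx]
    unit_x <- if (ax == "RR") "% RR" else "mm SR"
    for (cn in c("pri_D98", "pro_D98")) {
      y <- vapply(idx, function(i) {
        100 * failure_table$rate[failure_table$setting == labels[i] &
                                   failure_table$criterion == cn]
      }, numeric(1))
      ts <- trend_slope(x, y)
      slopes <- rbind(slopes, data.frame(
        series = ax, quantity = paste0("failure_", cn), slope = ts$slope,
        slope_se = ts$slope_se, unit = paste0("%-points per ", unit_x)))
    }
    quantities <- c("mean_composite_OAR", grep("^ntcp_|^total_ntcp",
                                               names(course), value = TRUE))
    for (q in quantities) {
      col <- if (q == "mean_composite_OAR") "mean_composite_OAR" else q
      if (!col %in% names(course)) next
      y <- vapply(idx, function(i) {
        mean(course[[col]][course$setting == labels[i]])
      }, numeric(1))
      scale <- if (grepl("ntcp", q)) 100 else 1
      ts <- trend_slope(x, scale * y)
      unit_y <- if (grepl("ntcp", q)) "%-points" else "Gy(RBE)"
      slopes <- rbind(slopes, data.frame(
        series = ax, quantity = q, slope = ts$slope, slope_se = ts$slope_se,
        unit = paste0(unit_y, " per ", unit_x)))
    }
  }
  txt <- .tradeoff_text(slopes)
  list(slopes = slopes, summary_text = txt)
}

.tradeoff_text <- function(slopes) {
  if (is.null(slopes) || !nrow(slopes)) {
    return("No trade-off slopes available (fewer than two settings per axis).")
  }
  pick <- function(series, quantity) {
    r <- slopes[slopes$series == series & slopes$quantity == quantity, ]
    if (nrow(r)) r$slope else NA_real_
  }
  sprintf(paste0(
    "Per 1%% reduction in range robustness (setup fixed): CTV_pri failure ",
    "rate %+.2f %%-points, mean composite OAR dose %+.3f Gy(RBE), total ",
    "NTCP %+.2f %%-points. Per 1 mm reduction in setup robustness (range ",
    "fixed): failure rate %+.2f %%-points, composite OAR dose %+.3f ",
    "Gy(RBE), total NTCP %+.2f %%-points."),
    -pick("RR", "failure_pri_D98"), -pick("RR", "mean_composite_OAR"),
    -pick("RR", "total_ntcp"), -pick("SR", "failure_pri_D98"),
    -pick("SR", "mean_composite_OAR"), -pick("SR", "total_ntcp"))
}

.write_artifacts <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$flags, file.path(outdir, "flags.csv"),
                   row.names = FALSE)
  utils::write.csv(out$failure_table, file.path(outdir, "failure_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(out$comparisons, file.path(outdir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(out$course, file.path(outdir, "course.csv"),
                   row.names = FALSE)
  utils::write.csv(out$slopes, file.path(outdir, "slopes.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("seed: %d", out$seed),
               sprintf("generated: %s", format(Sys.time())),
               out$summary_text),
             file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
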