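# Scenario sets, range-uncertainty model, envelopes, DVH metrics and
# coverage flags.

test_that("scenario sets have the prescribed structure", {
  opt <- optimization_scenarios(3, 3)
  expect_equal(nrow(opt), 14)
  mags <- sqrt(opt$dx^2 + opt$dy^2 + opt$dz^2)
  expect_true(all(abs(mags) < 1e-12 | abs(mags - 3) < 1e-12))
  expect_equal(sum(mags < 1e-12), 2)  # the two null-shift scenarios
  expect_setequal(unique(opt$range_pct), c(3, -3))

  ev <- evaluation_scenarios(3, 3)
  expect_equal(nrow(ev), 28)
  expect_true(all(abs(sqrt(ev$dx^2 + ev$dy^2 + ev$dz^2) - 3) < 1e-12))

  ev1 <- evaluation_scenarios(1, 2.9)
  expect_equal(nrow(ev1), 28)
  expect_true(all(abs(sqrt(ev1$dx^2 + ev1$dy^2 + ev1$dz^2) - 1) < 1e-12))
  expect_setequal(unique(ev1$range_pct), c(2.9, -2.9))

  opt2 <- optimization_scenarios(2, 1)
  m2 <- sqrt(opt2$dx^2 + opt2$dy^2 + opt2$dz^2)
  expect_true(all(abs(m2) < 1e-12 | abs(m2 - 2) < 1e-12))
  expect_setequal(unique(opt2$range_pct), c(1, -1))
})

test_that("degenerate magnitudes collapse after de-duplication", {
  expect_equal(nrow(optimization_scenarios(0, 3)), 2)
  expect_equal(nrow(evaluation_scenarios(0, 3)), 2)
  expect_equal(nrow(optimization_scenarios(3, 0)), 7)
  expect_error(optimization_scenarios(-1, 3))
  expect_error(evaluation_scenarios(3, -1))
})

test_that("the component diagonal convention is available", {
  ev <- evaluation_scenarios(3, 3, diagonal = "component")
  diag_rows <- abs(ev$dx) > 1e-12 & abs(ev$dy) > 1e-12
  expect_true(all(abs(abs(ev$dx[diag_rows]) - 3) < 1e-12))
  expect_equal(nrow(ev), 28)
})

test_that("patient-specific range uncertainty follows the 1.5-SD formula", {
  expect_equal(patient_range_uncertainty(75), 2.8)
  # analytic inversion of the formula at the clinical span endpoints
  r_at <- function(target) 1.5 * 100 * 0.5 / (target - 1.5 * 1.2)
  expect_equal(patient_range_uncertainty(r_at(3.2)), 3.2)
  expect_equal(patient_range_uncertainty(r_at(2.7)), 2.7)
  expect_equal(r_at(3.2), 53.571429, tolerance = 1e-6)
  expect_equal(r_at(2.7), 83.333333, tolerance = 1e-6)
  # strictly decreasing with asymptote 1.5 x 1.2 = 1.8
  rs <- seq(20, 500, by = 5)
  vals <- vapply(rs, patient_range_uncertainty, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(patient_range_uncertainty(1e9), 1.8, tolerance = 1e-6)
  expect_true(all(vals > 1.8))
  expect_error(patient_range_uncertainty(0))
})

test_that("voxel-wise envelopes match a brute-force elementwise loop", {
  g1 <- array(c(1, 2), c(2, 1, 1))
  g2 <- array(c(2, 1), c(2, 1, 1))
  env <- voxelwise_envelopes(list(g1, g2))
  expect_equal(as.vector(env$vwmin), c(1, 1))
  expect_equal(as.vector(env$vwmax), c(2, 2))

  one <- voxelwise_envelopes(list(g1))
  expect_identical(one$vwmin, g1)
  expect_identical(one$vwmax, g1)

  set.seed(7)
  grids <- lapply(1:28, function(i) array(runif(4 * 5 * 3), c(4, 5, 3)))
  env <- voxelwise_envelopes(grids)
  brute_min <- array(Inf, c(4, 5, 3))
  brute_max <- array(-Inf, c(4, 5, 3))
  for (g in grids) {
    for (i in seq_along(g)) {
      brute_min[i] <- min(brute_min[i], g[i])
      brute_max[i] <- max(brute_max[i], g[i])
    }
  }
  expect_equal(env$vwmin, brute_min)
  expect_equal(env$vwmax, brute_max)
  for (g in grids) {
    expect_true(all(env$vwmin <= g) && all(g <= env$vwmax))
  }
  expect_error(voxelwise_envelopes(list(g1, array(0, c(3, 1, 1)))),
               "co-registered")
})

test_that("D_v% follows the frozen sort-and-interpolate convention", {
  m <- array(TRUE, c(100, 1, 1))
  expect_equal(dvh_metric(array(70, c(100, 1, 1)), m, 98), 70)
  expect_equal(dvh_metric(array(70, c(100, 1, 1)), m, 2), 70)
  expect_equal(dvh_metric(array(1:100, c(100, 1, 1)), m, 98), 2.98)
  # against the equivalent type-7 quantile oracle on random fields
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:400, 1)
    d <- array(rexp(n, 1 / 50), c(n, 1, 1))
    v <- runif(1, 1, 99)
    expect_equal(dvh_metric(d, array(TRUE, c(n, 1, 1)), v),
                 unname(stats::quantile(as.vector(d), 1 - v / 100,
                                        type = 7)),
                 tolerance = 1e-12)
  }
  # quantile ordering
  set.seed(43)
  d <- array(rnorm(500, 60, 10), c(500, 1, 1))
  m <- array(TRUE, c(500, 1, 1))
  expect_true(dvh_metric(d, m, 98) <= dvh_metric(d, m, 50))
  expect_true(dvh_metric(d, m, 50) <= dvh_metric(d, m, 2))
  expect_error(dvh_metric(d, array(FALSE, c(500, 1, 1)), 98), "empty")
  expect_error(dvh_metric(d, m, 0))
  expect_error(dvh_metric(d, m, 100))
})

test_that("coverage flags use inclusive boundaries at the stated thresholds", {
  rx <- c(CTV_pri = 70, CTV_pro = 54.25)
  mk <- function(pri98, pro98, pri2) {
    coverage_flags(list(pri_D98_vwmin = pri98, pro_D98_vwmin = pro98,
                        pri_D2_vwmax = pri2), rx)
  }
  expect_true(mk(0.94 * 70, 60, 70)[["pri_D98_pass"]])    # boundary passes
  expect_false(mk(0.94 * 70 - 1e-9, 60, 70)[["pri_D98_pass"]])
  expect_false(mk(70, 60, 77.01)[["pri_D2_pass"]])        # 1.10 x 70 = 77
  expect_true(mk(70, 60, 77)[["pri_D2_pass"]])
  expect_false(mk(70, 50.99, 70)[["pro_D98_pass"]])       # 0.94 x 54.25 = 50.995
  expect_true(mk(70, 51.00, 70)[["pro_D98_pass"]])
  expect_error(coverage_flags(list(pri_D98_vwmin = 70, pro_D98_vwmin = 51,
                                   pri_D2_vwmax = 70), c(CTV_pri = 70)),
               "prescription")
})

test_that("plan evaluation is deterministic and its envelopes bound the scenario doses", {
  snap <- small_snapshot(seed = 4)
  plan <- tiny_plan(snap, mu = 10)
  cfg <- eval_config(setup_mm = 2, range_pct = 2)
  e1 <- evaluate_plan_on_snapshot(plan, snap, cfg)
  e2 <- evaluate_plan_on_snapshot(plan, snap, cfg)
  expect_identical(e1, e2)
  expect_equal(e1$n_scenarios, 28)
  expect_true(all(e1$vwmin <= e1$vwmax))
  # spot-check the envelope bound against three recomputed scenario doses
  scen <- evaluation_scenarios(2, 2)
  pri <- snap$masks$CTV_pri
  for (i in c(1, 9, 20)) {
    ds <- plan_dose(snap, plan, scen$range_pct[i],
                    c(scen$dx[i], scen$dy[i], scen$dz[i]))
    expect_true(all(e1$vwmin[pri] <= ds[pri] + 1e-9))
    expect_true(all(ds[pri] <= e1$vwmax[pri] + 1e-9))
  }
  # vwmin D98 is at most the D98 of any single scenario
  expect_lte(e1$metrics$pri_D98_vwmin,
             dvh_metric(plan_dose(snap, plan, scen$range_pct[1],
                                  c(scen$dx[1], scen$dy[1], scen$dz[1])),
                        pri, 98) + 1e-9)
})

test_that("patient-specific evaluation derives its range magnitude from the plan", {
  snap <- small_snapshot(seed = 4)
  plan <- tiny_plan(snap, mu = 10)
  cfg <- eval_config(setup_mm = 1, range_mode = "patient")
  e <- evaluate_plan_on_snapshot(plan, snap, cfg)
  expect_equal(e$range_pct_used,
               patient_range_uncertainty(mu_weighted_mean_range(plan)))
  expect_gt(e$range_pct_used, 1.8)
})
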