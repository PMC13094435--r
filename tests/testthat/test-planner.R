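# Minimax spot-weight optimization and dose-mimicking re-optimization,
# checked on deliberately small problems with independent oracles.

test_that("the two-spot minimax solution matches an exhaustive grid search", {
  tp <- toy_problem()
  opt <- cmro_optimize(list(tp$A), tp$A, tp$objective, tp$voxsets)
  # coarse-to-fine exhaustive search over MU in [0, 2]^2 down to 1e-3
  grid_best <- function(lo, hi, by) {
    g <- as.matrix(expand.grid(mu1 = seq(lo[1], hi[1], by = by),
                               mu2 = seq(lo[2], hi[2], by = by)))
    vals <- colMeans((tp$A %*% t(g) - 1)^2) / 70^2
    g[which.min(vals), ]
  }
  b1 <- grid_best(c(0, 0), c(2, 2), 0.01)
  b2 <- grid_best(pmax(b1 - 0.02, 0), b1 + 0.02, 0.001)
  expect_true(all(b2 > 0.01 & b2 < 1.99))  # interior optimum
  expect_lt(max(abs(opt$mu - b2)), 1e-2)
  expect_lt(abs(toy_f(tp$A, opt$mu) - toy_f(tp$A, b2)), 1e-8)
})

test_that("a single-scenario minimax reduces to plain optimization", {
  tp <- toy_problem()
  opt <- cmro_optimize(list(tp$A), tp$A, tp$objective, tp$voxsets)
  # independent plain minimization of the same objective
  plain <- stats::optim(rep(1, 2), function(mu) toy_f(tp$A, pmax(mu, 0)),
                        method = "L-BFGS-B", lower = 0,
                        control = list(maxit = 500, factr = 10))
  expect_lt(abs(toy_f(tp$A, opt$mu) - plain$value), 1e-8)
  expect_lt(max(abs(opt$mu - plain$par)), 1e-2)
})

test_that("the worst-case objective trace is non-increasing and MU stays non-negative", {
  tp <- toy_problem()
  scen <- optimization_scenarios(4, 3)
  As <- lapply(seq_len(nrow(scen)), function(i) {
    scenario_influence(tp$snap, tp$geom$beams, tp$geom$spots, scen[i, ],
                       tp$voxsets$vox)
  })
  opt <- cmro_optimize(As, tp$A, tp$objective, tp$voxsets)
  expect_true(all(diff(opt$trace) <= 1e-9 * max(opt$trace[1], 1)))
  expect_true(all(opt$mu >= 0))
  # minimax dominance: every scenario objective is at most the reported max
  fs <- vapply(As, function(A) toy_f(as.matrix(A), opt$mu), numeric(1))
  expect_equal(max(fs), tail(opt$trace, 1), tolerance = 1e-9)
  expect_true(all(fs <= max(fs) + 1e-12))
})

test_that("doubling all objective weights leaves the argmin unchanged", {
  tp <- toy_problem()
  opt1 <- cmro_optimize(list(tp$A), tp$A, tp$objective, tp$voxsets)
  obj2 <- tp$objective
  obj2$weight <- obj2$weight * 2
  opt2 <- cmro_optimize(list(tp$A), tp$A, obj2, tp$voxsets)
  expect_lt(max(abs(opt1$mu - opt2$mu)), 1e-3)
})

test_that("an objective without a target underdose term is rejected", {
  tp <- toy_problem()
  bad <- data.frame(structure = "CTV_pri", type = "mean_dose", dose = 0,
                    weight = 1)
  expect_error(cmro_optimize(list(tp$A), tp$A, bad, tp$voxsets),
               "underdose")
})

test_that("self-mimicking on a fully converged toy problem recovers the plan", {
  tp <- toy_problem()
  rx <- c(CTV_pri = 1, CTV_pro = 1)   # toy doses live at the 1 Gy scale
  ref <- cmro_optimize(list(tp$A), tp$A, tp$objective, tp$voxsets,
                       prescriptions = rx,
                       control = list(maxit = c(200, 800), tol = 1e-14))
  ref_dose <- as.numeric(tp$A %*% ref$mu)
  mim <- mimic_optimize(tp$A, ref_dose, list(tp$A), tp$objective,
                        tp$voxsets, ref$mu, prescriptions = rx,
                        control = list(maxit = c(200, 800), tol = 1e-14))
  # with the same scenario set, the mimicked nominal dose reproduces the
  # reference to well under 1% of its level
  d_mim <- as.numeric(tp$A %*% mim$mu)
  expect_lt(max(abs(d_mim - ref_dose)), 0.01)
})

test_that("the plan suite preserves target dose, orders robustness and never worsens OARs", {
  snap <- generate_phantom(seed = 1)   # the shipped default phantom
  plans <- build_plan_suite(snap, settings = list(c(3, 3), c(3, 1)))
  ref <- plans[["3%/3mm"]]
  adj <- plans[["3%/1mm"]]
  expect_identical(ref$spots[, c("beam", "y", "z", "R")],
                   adj$spots[, c("beam", "y", "z", "R")])
  d_ref <- plan_dose(snap, ref)
  d_adj <- plan_dose(snap, adj)
  pri <- snap$masks$CTV_pri
  # the mimicked plan preserves nominal target coverage within 0.5 Gy
  expect_lt(abs(dvh_metric(d_adj, pri, 98) - dvh_metric(d_ref, pri, 98)),
            0.5)
  expect_lt(abs(dvh_metric(d_adj, snap$masks$CTV_pro, 98) -
                  dvh_metric(d_ref, snap$masks$CTV_pro, 98)), 1)
  # the reference plan passes plan acceptance on the planning anatomy
  cfg <- eval_config(setup_mm = 3, range_pct = 3)
  ev_ref <- evaluate_plan_on_snapshot(ref, snap, cfg)
  expect_true(all(ev_ref$flags))
  # robustness ordering under the full 3 mm / 3% evaluation set
  ev_adj <- evaluate_plan_on_snapshot(adj, snap, cfg)
  expect_gte(ev_ref$metrics$pri_D98_vwmin,
             ev_adj$metrics$pri_D98_vwmin - 0.05)
  # margin reduction does not increase the OAR burden
  oar <- Reduce(`|`, snap$masks[oar_structures()])
  expect_lte(mean(d_adj[oar]), mean(d_ref[oar]) + 0.05)
})

test_that("the plan suite requires the reference setting", {
  snap <- small_snapshot(seed = 1)
  expect_error(build_plan_suite(snap, settings = list(c(2, 3))),
               "reference")
  expect_error(build_plan_suite(snap, settings = list()), "empty")
})
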