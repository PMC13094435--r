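# Failure-rate statistics: Wilson intervals, z-tests, Holm, TOST, OLS.

test_that("Wilson intervals match the closed form and its boundary behaviour", {
  expect_equal(wilson_ci(0, 155)[["lower"]], 0)
  expect_equal(wilson_ci(155, 155)[["upper"]], 1)
  ci <- wilson_ci(22, 155)
  expect_equal(unname(round(ci, 4)), c(0.0956, 0.2056))
  # agrees with the score interval in prop.test (no continuity correction)
  for (case in list(c(22, 155), c(1, 10), c(7, 8), c(50, 200))) {
    pt <- suppressWarnings(stats::prop.test(case[1], case[2],
                                            correct = FALSE))
    expect_equal(unname(wilson_ci(case[1], case[2])),
                 as.numeric(pt$conf.int), tolerance = 1e-10)
  }
  ci <- wilson_ci(3, 11, 0.9)
  expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] < 3 / 11 && 3 / 11 < ci[2])
  expect_error(wilson_ci(-1, 10))
  expect_error(wilson_ci(11, 10))
  expect_error(wilson_ci(5, 10, 1.2))
})

test_that("Wilson intervals invert the score equation (root-finding oracle)", {
  z <- qnorm(0.975)
  score_root <- function(x, n, side) {
    # the score equation has a spurious root at p = phat when phat is 0
    # or 1, so the bracket endpoints avoid the boundary in those cases
    phat <- x / n
    f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
    if (side == "lower") {
      if (x == 0) return(0)
      hi <- if (x == n) 1 - 1e-12 else phat
      uniroot(f, c(1e-14, hi), tol = 1e-14)$root
    } else {
      if (x == n) return(1)
      lo <- if (x == 0) 1e-12 else phat
      uniroot(f, c(lo, 1 - 1e-14), tol = 1e-14)$root
    }
  }
  set.seed(1)
  for (rep in 1:40) {
    n <- sample(1:200, 1)
    x <- sample(0:n, 1)
    ci <- wilson_ci(x, n)
    expect_equal(ci[["lower"]], score_root(x, n, "lower"), tolerance = 1e-10)
    expect_equal(ci[["upper"]], score_root(x, n, "upper"), tolerance = 1e-10)
  }
})

test_that("the pooled two-proportion z-test matches its closed form", {
  zt <- two_proportion_ztest(22, 155, 44, 155)
  expect_equal(abs(zt$z), 3.052366, tolerance = 1e-6)
  expect_equal(zt$p, 0.002270449, tolerance = 1e-6)
  # identical proportions
  z0 <- two_proportion_ztest(10, 100, 10, 100)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  # antisymmetry under group swap
  a <- two_proportion_ztest(30, 120, 10, 80)
  b <- two_proportion_ztest(10, 80, 30, 120)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # matches the chi-square test without continuity correction
  pt <- stats::prop.test(c(22, 44), c(155, 155), correct = FALSE)
  expect_equal(zt$p, pt$p.value, tolerance = 1e-12)
  expect_equal(zt$z^2, unname(pt$statistic), tolerance = 1e-12)
  expect_error(two_proportion_ztest(0, 10, 0, 10), "degenerate")
  expect_error(two_proportion_ztest(10, 10, 10, 10), "degenerate")
})

test_that("Holm adjustment reproduces the hand-executed step-down", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03, 0.005)),
               c(0.03, 0.06, 0.06, 0.02))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.02)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  # permutation invariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(holm_bonferroni(p[perm]), adj[perm])
  expect_error(holm_bonferroni(c(0.1, 1.2)))
  expect_error(holm_bonferroni(c(0.1, -0.1)))
})

test_that("TOST concludes equivalence exactly when both one-sided tests reject", {
  big <- tost_equivalence(150, 1000, 150, 1000, delta = 0.10)
  expect_true(big$equivalent)
  # observed difference exactly at the margin: one-sided p = 0.5
  bound <- tost_equivalence(30, 200, 10, 200, delta = 0.10)
  expect_equal(bound$p_upper, 0.5)
  expect_false(bound$equivalent)
  expect_error(tost_equivalence(0, 50, 0, 50, 0.1), "degenerate")
  expect_error(tost_equivalence(5, 50, 6, 50, -0.1))
})

test_that("TOST agrees with the 90% Wald-interval inclusion duality", {
  for (x1 in c(5, 15, 30, 45)) {
    for (x2 in c(5, 15, 30, 45)) {
      n1 <- 155
      n2 <- 155
      t <- tost_equivalence(x1, n1, x2, n2, delta = 0.10, alpha = 0.05)
      p1 <- x1 / n1
      p2 <- x2 / n2
      se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
      z90 <- qnorm(0.95)
      inside <- (p1 - p2 - z90 * se > -0.10) && (p1 - p2 + z90 * se < 0.10)
      expect_identical(t$equivalent, inside,
                       label = paste("x1 =", x1, "x2 =", x2))
    }
  }
})

test_that("failure tables count per setting and criterion", {
  flags <- data.frame(
    setting = rep(c("3%/3mm", "3%/1mm"), each = 5),
    pri_D98_pass = c(TRUE, TRUE, FALSE, TRUE, TRUE,
                     FALSE, FALSE, TRUE, FALSE, TRUE),
    pro_D98_pass = TRUE,
    pri_D2_pass = TRUE
  )
  ft <- failure_rates(flags)
  expect_equal(nrow(ft), 6)
  r <- ft[ft$setting == "3%/1mm" & ft$criterion == "pri_D98", ]
  expect_equal(r$n_failures, 3)
  expect_equal(r$rate, 0.6)
  expect_equal(ft$rate[ft$criterion == "pro_D98"], c(0, 0))
  all_pass <- flags
  all_pass$pri_D98_pass <- TRUE
  ft2 <- failure_rates(all_pass)
  expect_true(all(ft2$rate == 0))
  expect_true(all(vapply(seq_len(nrow(ft2)), function(i) {
    wilson_ci(ft2$n_failures[i], ft2$n_evaluations[i])[["lower"]] == 0
  }, logical(1))))
  expect_error(failure_rates(data.frame(setting = "a")), "columns")
})

test_that("OLS trend slopes are exact on the printed failure-rate series", {
  rr <- trend_slope(c(3, 2, 1), c(14, 17, 21))
  expect_equal(rr$slope, -3.5)
  sr <- trend_slope(c(3, 2, 1), c(14, 20, 28))
  expect_equal(sr$slope, -7.0)
  lin <- trend_slope(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4) + 1)
  expect_equal(lin$slope, 2)
  expect_equal(lin$intercept, 1)
  expect_equal(lin$slope_se, 0)
  expect_error(trend_slope(c(2, 2, 2), c(1, 2, 3)), "distinct")
})
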