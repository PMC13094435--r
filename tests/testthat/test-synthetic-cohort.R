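# Phantom generation, anatomy evolution, schedules and cohort structure.

test_that("generated phantom satisfies the structural invariants", {
  snap <- small_snapshot(seed = 1)
  ext <- snap$masks$external
  expect_true(all(snap$spr_grid >= 0))
  expect_true(all(snap$spr_grid[!ext] < 0.01))       # air outside
  for (nm in names(snap$masks)) {
    expect_true(all(!snap$masks[[nm]] | ext), info = nm)  # mask within body
    expect_gt(sum(snap$masks[[nm]]), 0)
  }
  expect_true(all(!snap$masks$CTV_pri | snap$masks$CTV_pro))  # pri inside pro
  for (nm in oar_structures()) {
    expect_equal(sum(snap$masks[[nm]] & snap$masks$CTV_pri), 0, info = nm)
  }
})

test_that("phantom generation is deterministic under a fixed seed and jittered across seeds", {
  a <- small_snapshot(seed = 7)
  b <- small_snapshot(seed = 7)
  c <- small_snapshot(seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$masks$CTV_pri, c$masks$CTV_pri))
})

test_that("degenerate geometry is rejected", {
  g <- small_geometry()
  g$structures$CTV_pri$radii <- c(0, 0, 0)
  expect_error(generate_phantom(g), "configuration error")
  g2 <- small_geometry()
  g2$structures$parotid_L$center <- c(-70, 0, 0)  # outside the external
  expect_error(generate_phantom(g2), "configuration error")
  g3 <- small_geometry()
  g3$grid_dim <- c(16L, 16L, 16L)
  expect_error(generate_phantom(g3), "at least 32")
})

test_that("zero drift is the identity apart from the timepoint", {
  snap <- small_snapshot(seed = 2)
  out <- evolve_anatomy(snap, week = 3, drift = list(rate = 0))
  expect_identical(out$masks, snap$masks)
  expect_identical(out$spr_grid, snap$spr_grid)
  expect_identical(out$timepoint_week, 3L)
})

test_that("weekly shrinkage compounds on the external volume", {
  snap <- small_snapshot(seed = 2)
  out <- evolve_anatomy(snap, week = 5, drift = list(rate = 0.02))
  v0 <- sum(snap$masks$external)
  v5 <- sum(out$masks$external)
  # one voxel layer on the cylinder surface, as fraction of its volume
  layer_frac <- 2 * snap$spacing[1] / snap$geometry$external_radius
  expect_lt(abs(v5 / v0 - 0.98^5), layer_frac)
  # parotids shrink too (discretization is coarse for small structures at
  # this voxel size, so only the direction is asserted)
  vp <- sum(out$masks$parotid_L) / sum(snap$masks$parotid_L)
  expect_lt(vp, 1)
  expect_gt(vp, 0.6)
})

test_that("volumes are non-increasing in week under positive drift", {
  snap <- small_snapshot(seed = 3)
  vols <- sapply(1:6, function(wk) {
    out <- evolve_anatomy(snap, wk, drift = list(rate = 0.02))
    c(sum(out$masks$external), sum(out$masks$parotid_R))
  })
  expect_true(all(diff(vols[1, ]) <= 0))
  expect_true(all(diff(vols[2, ]) <= 0))
})

test_that("anatomy collapsing to nothing is flagged", {
  snap <- small_snapshot(seed = 2)
  expect_error(evolve_anatomy(snap, week = 60, drift = list(rate = 0.1)),
               "degenerate anatomy")
  expect_error(evolve_anatomy(snap, week = 1, drift = list(rate = 0.5)),
               "rate")
})

test_that("fraction schedules match the fractionation patterns", {
  s <- build_schedule(35, 6, "conventional")
  expect_length(s$fraction_days, 35)
  expect_length(s$rct_days, 6)
  expect_true(all(diff(s$fraction_days) > 0))
  expect_true(all(diff(s$rct_days) > 0))
  # conventional: 5 per week over 7 calendar weeks
  expect_equal(ceiling(max(s$fraction_days) / 7), 7)
  a <- build_schedule(35, 6, "accelerated")
  expect_equal(ceiling(max(a$fraction_days) / 7), 6)
  one <- build_schedule(1, 5, "conventional")
  expect_length(one$fraction_days, 1)
  expect_length(one$rct_days, 5)
  expect_error(build_schedule(35, 6, "hypo"))
  expect_error(build_schedule(35, 4, "conventional"), "5, 6 or 7")
})

test_that("cohort generation follows the rCT distribution and is reproducible", {
  spec <- cohort_spec(4, n_rcts_distribution = c(`5` = 1, `6` = 2, `7` = 1),
                      geometry = small_geometry(), seed = 5)
  cohort <- generate_cohort(spec)
  expect_length(cohort, 4)
  n_rcts <- vapply(cohort, function(p) length(p$snapshots) - 1L, integer(1))
  expect_equal(n_rcts, c(5L, 6L, 6L, 7L))
  expect_equal(sum(n_rcts), 24L)
  # weeks are labelled 0, 1, 2, ...
  wk <- vapply(cohort[[1]]$snapshots, `[[`, integer(1), "timepoint_week")
  expect_equal(wk, 0:5)
  # reproducibility, including when the cohort grows (substreams)
  cohort2 <- generate_cohort(spec)
  expect_identical(cohort, cohort2)
  spec3 <- cohort_spec(3, n_rcts_distribution = c(`5` = 1, `6` = 2, `7` = 0),
                       geometry = small_geometry(), seed = 5)
  cohort3 <- generate_cohort(spec3)
  expect_identical(cohort3[[1]], cohort[[1]])
})

test_that("inconsistent cohort specifications are rejected", {
  expect_error(cohort_spec(25), "sum to n_patients")
  expect_error(cohort_spec(2, n_rcts_distribution = c(`5` = 2),
                           anatomy_drift = list(mean = 0.2, sd = 0, max = 0.2)),
               "shrinkage")
})

test_that("a cohort writes volumes plus a JSON manifest", {
  spec <- cohort_spec(1, n_rcts_distribution = c(`5` = 1),
                      geometry = small_geometry(), seed = 3)
  cohort <- generate_cohort(spec)
  dir <- file.path(tempdir(), "adaptrt_cohort")
  manifest_path <- write_cohort(cohort, dir)
  expect_true(file.exists(manifest_path))
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  expect_length(man, 1)
  expect_length(man[[1]]$snapshot_prefixes, 6)  # planning CT + 5 rCTs
  expect_length(man[[1]]$fraction_days, 35)
  back <- read_snapshot(man[[1]]$snapshot_prefixes[[2]])
  expect_equal(which(back$masks$CTV_pri),
               which(cohort[[1]]$snapshots[[2]]$masks$CTV_pri))
})

test_that("snapshots survive a NIfTI round trip", {
  snap <- small_snapshot(seed = 9)
  prefix <- file.path(tempdir(), "rt_snap")
  write_snapshot(snap, prefix)
  back <- read_snapshot(prefix)
  expect_equal(back$spr_grid, unclass(snap$spr_grid), tolerance = 1e-6,
               ignore_attr = TRUE)
  for (nm in names(snap$masks)) {
    expect_equal(which(back$masks[[nm]]), which(snap$masks[[nm]]), info = nm)
  }
  expect_equal(back$spacing, snap$spacing)
  expect_equal(back$timepoint_week, snap$timepoint_week)
})
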