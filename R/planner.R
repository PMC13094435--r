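# Composite minimax robust optimization (worst-case over the optimization
# scenario set) of spot monitor-unit weights, and dose-mimicking
# re-optimization used to derive margin-reduced adjusted plans from the
# reference plan. Dose is linear in MU, so per-scenario influence matrices
# (objective voxels x spots) make each scenario objective piecewise
# quadratic; the worst case is minimized with L-BFGS-B under
# non-negativity bounds on a log-sum-exp smoothed maximum with a
# decreasing temperature schedule, tracking the true worst case so the
# reported trace of accepted iterates is non-increasing.

#' Default composite optimization objective
#'
#' Quadratic one-sided underdose penalties at 100% of prescription for both
#' CTVs, an overdose penalty at 107% of the primary prescription, a
#' conformity shell ("ring") around CTV_pro with overdose and mean-dose
#' penalties driving the lateral/distal falloff, and mean-dose penalties on
#' all organs-at-risk.
#'
#' @param prescriptions named numeric with `CTV_pri`, `CTV_pro` in Gy(RBE).
#' @return data.frame of terms (`structure`, `type`, `dose`, `weight`).
#' @export
default_objective <- function(prescriptions = c(CTV_pri = 70,
                                                CTV_pro = 54.25)) {
  p1 <- prescriptions[["CTV_pri"]]
  p2 <- prescriptions[["CTV_pro"]]
  # coverage weights dominate the sparing terms by orders of magnitude:
  # the voxel-wise envelope criteria require every scenario's shifted
  # edge shell to be covered, which a softer balance trades away
  rbind(
    data.frame(structure = "CTV_pri", type = "min_dose", dose = 1.007 * p1,
               weight = 5000),
    data.frame(structure = "CTV_pri", type = "max_dose", dose = 1.05 * p1,
               weight = 1500),
    data.frame(structure = "CTV_pro", type = "min_dose", dose = 1.03 * p2,
               weight = 8000),
    data.frame(structure = "ring", type = "max_dose", dose = 0.9 * p1,
               weight = 2),
    data.frame(structure = "ring", type = "mean_dose", dose = 0,
               weight = 0.8),
    data.frame(structure = oar_structures(), type = "mean_dose", dose = 0,
               weight = 0.3)
  )
}

# dilate a logical array by n_iter one-voxel steps (6-neighbourhood)
.dilate <- function(mask, n_iter) {
  d <- dim(mask)
  for (i in seq_len(n_iter)) {
    m <- mask
    m[-1, , ] <- m[-1, , ] | mask[-d[1], , ]
    m[-d[1], , ] <- m[-d[1], , ] | mask[-1, , ]
    m[, -1, ] <- m[, -1, ] | mask[, -d[2], ]
    m[, -d[2], ] <- m[, -d[2], ] | mask[, -1, ]
    m[, , -1] <- m[, , -1] | mask[, , -d[3]]
    m[, , -d[3]] <- m[, , -d[3]] | mask[, , -1]
    mask <- m
  }
  mask
}

.subsample_idx <- function(idx, cap) {
  if (length(idx) <= cap) return(idx)
  idx[unique(round(seq(1, length(idx), length.out = cap)))]
}

#' Objective voxel sets for optimization
#'
#' Collects (sub-sampled) voxel index sets for the targets, each OAR and a
#' conformity ring around CTV_pro, plus the combined unique voxel vector on
#' which influence matrices are computed.
#'
#' @param snapshot a `phantom_snapshot`.
#' @param ring_margin_mm thickness of the dilated shell around CTV_pro.
#' @param caps named list of per-set voxel caps (deterministic striding).
#' @return list with `vox` (linear indices into the grid) and `sets`
#'   (per-structure positions into `vox`).
#' @export
objective_voxels <- function(snapshot, ring_margin_mm = 18,
                             caps = list(ctv = 1200, ring = 1500, oar = 250)) {
  m <- snapshot$masks
  n_iter <- ceiling(ring_margin_mm / snapshot$spacing[1])
  ring <- .dilate(m$CTV_pro, n_iter) & m$external & !m$CTV_pro
  sets_idx <- list(
    CTV_pri = .subsample_idx(which(m$CTV_pri), caps$ctv),
    CTV_pro = .subsample_idx(which(m$CTV_pro), caps$ctv),
    ring = .subsample_idx(which(ring), caps$ring)
  )
  for (nm in oar_structures()) {
    # OAR sparing terms act outside the elective target: where an OAR
    # overlaps CTV_pro, target coverage takes precedence (the overlap
    # would otherwise fight the coverage terms); reported OAR mean doses
    # downstream always use the full anatomical mask
    oar <- m[[nm]] & !m$CTV_pro
    if (!any(oar)) oar <- m[[nm]]
    sets_idx[[nm]] <- .subsample_idx(which(oar), caps$oar)
  }
  vox <- sort(unique(unlist(sets_idx, use.names = FALSE)))
  sets <- lapply(sets_idx, function(ix) match(ix, vox))
  list(vox = vox, sets = sets)
}

# resolve objective terms against the voxel sets
.compile_terms <- function(objective, voxsets) {
  has_target <- any(objective$type == "min_dose" &
                      objective$structure %in% c("CTV_pri", "CTV_pro"))
  if (!has_target) stop("objective must contain a target underdose term")
  lapply(seq_len(nrow(objective)), function(i) {
    st <- objective$structure[i]
    if (is.null(voxsets$sets[[st]])) stop("unknown structure in objective: ", st)
    list(idx = voxsets$sets[[st]], type = objective$type[i],
         ref = objective$dose[i], weight = objective$weight[i])
  })
}

# composite objective value (and d-space residual) for one dose vector;
# normalized by the primary prescription squared for scale balance
.composite_objective <- function(d, cterms, norm = 70, grad = FALSE) {
  f <- 0
  r <- if (grad) numeric(length(d)) else NULL
  n2 <- norm^2
  for (t in cterms) {
    dt <- d[t$idx]
    n <- length(dt)
    if (t$type == "min_dose") {
      u <- pmax(t$ref - dt, 0)
      f <- f + t$weight * sum(u^2) / (n * n2)
      if (grad) r[t$idx] <- r[t$idx] - 2 * t$weight * u / (n * n2)
    } else if (t$type == "max_dose") {
      o <- pmax(dt - t$ref, 0)
      f <- f + t$weight * sum(o^2) / (n * n2)
      if (grad) r[t$idx] <- r[t$idx] + 2 * t$weight * o / (n * n2)
    } else if (t$type == "mean_dose") {
      md <- mean(dt)
      f <- f + t$weight * (md / norm)^2
      if (grad) r[t$idx] <- r[t$idx] + 2 * t$weight * md / (n * n2)
    } else {
      stop("unknown objective term type: ", t$type)
    }
  }
  list(f = f, r = r)
}

# trilinear gather stencil: for objective voxels (linear indices `vox` into
# a grid of dim d) sampled at a constant offset v_mm, return 8 neighbour
# linear indices, their (y,z)-column indices, and interpolation weights
.interp_stencil <- function(vox, d, spacing, v_mm) {
  ijk <- arrayInd(vox, d)
  fr <- sweep(ijk, 2, v_mm / spacing, "+")  # fractional sample index
  i0 <- floor(fr)
  t <- fr - i0
  n <- nrow(ijk)
  nb <- matrix(1L, n, 8)
  cb <- matrix(1L, n, 8)
  wt <- matrix(0, n, 8)
  c8 <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (q in 1:8) {
    ii <- i0 + rep(c8[q, ], each = n)
    ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] & ii[, 2] >= 1 & ii[, 2] <= d[2] &
      ii[, 3] >= 1 & ii[, 3] <= d[3]
    w <- (ifelse(c8[q, 1] == 1, t[, 1], 1 - t[, 1])) *
      (ifelse(c8[q, 2] == 1, t[, 2], 1 - t[, 2])) *
      (ifelse(c8[q, 3] == 1, t[, 3], 1 - t[, 3]))
    iic <- ii
    iic[!ok, ] <- 1L
    nb[, q] <- iic[, 1] + d[1] * (iic[, 2] - 1L + d[2] * (iic[, 3] - 1L))
    cb[, q] <- iic[, 2] + d[2] * (iic[, 3] - 1L)
    wt[, q] <- w * ok
  }
  list(nb = nb, cb = cb, wt = wt)
}

#' Influence matrix of all spots for one error scenario
#'
#' Dose at the objective voxels per unit MU of each spot, with the setup
#' shift realized by sampling the beam-frame dose at the shifted voxel
#' positions (trilinear) and the range shift by scaling the SPR grid.
#'
#' @param snapshot a `phantom_snapshot`.
#' @param beams list of [beam_spec()].
#' @param spots spot data.frame (`beam`, `y`, `z`, `R`); MU ignored.
#' @param scenario list/row with `dx`, `dy`, `dz` (mm), `range_pct`.
#' @param vox integer vector of linear voxel indices.
#' @param params engine parameters.
#' @param sparse return a sparse `dgCMatrix` with entries below
#'   `drop_tol` times the largest entry removed (the optimizer only sees
#'   the influence through quadratic penalties, where the relative
#'   truncation is negligible); set `FALSE` for the exact dense matrix.
#' @param drop_tol relative truncation threshold for `sparse = TRUE`.
#' @return matrix `length(vox)` x `nrow(spots)`.
#' @export
scenario_influence <- function(snapshot, beams, spots, scenario, vox,
                               params = engine_params(), sparse = TRUE,
                               drop_tol = 1e-4) {
  d <- dim(snapshot$spr_grid)
  sp <- snapshot$spacing
  air <- min(snapshot$spr_grid)
  v <- c(scenario$dx, scenario$dy, scenario$dz)
  spr <- snapshot$spr_grid * (1 + scenario$range_pct / 100)
  if (any(v != 0)) spr <- shift_grid(spr, v, sp, "linear", fill = air)
  st <- .interp_stencil(vox, d, sp, v)
  crd <- .axis_coords(d, sp, snapshot$origin)
  ucol <- sort(unique(as.vector(st$cb)))
  # (y, z) coordinates of the referenced columns
  cy <- crd[[2]][(ucol - 1L) %% d[2] + 1L]
  cz <- crd[[3]][(ucol - 1L) %/% d[2] + 1L]
  cb_pos <- matrix(match(st$cb, ucol), nrow(st$cb), 8)
  # linear index into the column-subset B matrix for every stencil corner
  bidx <- ((cb_pos - 1L) * d[1]) + ((st$nb - 1L) %% d[1]) + 1L
  nvox <- length(vox)
  irow <- rep(seq_len(nvox), 8)
  infl <- matrix(0, nvox, nrow(spots))
  s2 <- 2 * params$sigma_lateral^2
  nyz <- d[2] * d[3]
  for (b in seq_along(beams)) {
    sel <- which(spots$beam == b)
    if (!length(sel)) next
    # lateral Gaussian of every distinct spot position at the referenced
    # columns (shared across energy layers)
    lat <- unique(spots[sel, c("y", "z")])
    G <- exp(-(outer(cy, lat$y, "-")^2 + outer(cz, lat$z, "-")^2) / s2)
    lat_id <- match(interaction(spots$y[sel], spots$z[sel], drop = TRUE),
                    interaction(lat$y, lat$z, drop = TRUE))
    w <- wed_field(spr, sp[1], direction = beams[[b]]$direction[1])
    dim(w) <- c(d[1], nyz)
    wsub <- w[, ucol, drop = FALSE]
    for (R in unique(spots$R[sel])) {
      in_layer <- spots$R[sel] == R
      B <- .bragg_u(wsub - R, params)
      # voxel x column sparse stencil carrying weight x depth-dose;
      # duplicate (voxel, column) entries are summed by sparseMatrix
      Tm <- Matrix::sparseMatrix(
        i = irow, j = as.vector(cb_pos),
        x = as.vector(st$wt * matrix(B[bidx], nvox, 8)),
        dims = c(nvox, length(ucol))
      )
      infl[, sel[in_layer]] <- as.matrix(Tm %*% G[, lat_id[in_layer],
                                                  drop = FALSE])
    }
  }
  if (sparse) {
    infl[infl < drop_tol * max(infl)] <- 0
    infl <- Matrix::drop0(Matrix::Matrix(infl, sparse = TRUE))
  }
  infl
}

# Minimax solver: L-BFGS-B (non-negativity via box bounds) on the
# log-sum-exp smoothed maximum, with a decreasing temperature schedule.
# `evalfun(mu, tau)` must return list(F_true, F_smooth, grad_smooth,
# active). The true worst-case objective is tracked across all evaluated
# iterates; the returned trace is the sequence of accepted (improving)
# worst-case values, which is non-increasing by construction, and the
# returned MU is the best iterate encountered.
.minimax_solve <- function(evalfun, mu0, maxit = c(50, 150), tol = 1e-8) {
  env <- new.env()
  env$best_F <- Inf
  env$best_mu <- pmax(mu0, 0)
  env$trace <- numeric(0)
  env$active <- integer(0)
  env$cache_mu <- NULL
  env$cache <- NULL

  first <- evalfun(pmax(mu0, 0), 1)
  tau_sched <- pmax(first$F_true, 1e-12) * c(0.1, 0.005)

  wrap <- function(tau) {
    fn <- function(mu) {
      if (is.null(env$cache_mu) || !identical(mu, env$cache_mu)) {
        env$cache <- evalfun(mu, tau)
        env$cache_mu <- mu
        if (env$cache$F_true < env$best_F) {
          env$best_F <- env$cache$F_true
          env$best_mu <- mu
          env$trace <- c(env$trace, env$cache$F_true)
          env$active <- c(env$active, env$cache$active)
        }
      }
      env$cache$F_smooth
    }
    gr <- function(mu) {
      fn(mu)
      env$cache$grad_smooth
    }
    list(fn = fn, gr = gr)
  }

  mu <- pmax(mu0, 0)
  conv <- 1L
  for (stage in seq_along(tau_sched)) {
    env$cache_mu <- NULL
    w <- wrap(tau_sched[stage])
    res <- stats::optim(mu, w$fn, w$gr, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = maxit[stage],
                                       factr = tol / .Machine$double.eps,
                                       pgtol = 0))
    mu <- res$par
    conv <- res$convergence
  }
  # guard against sub-epsilon bound violations from the optimizer
  list(mu = pmax(env$best_mu, 0), trace = env$trace,
       active_scenario = env$active, converged = conv == 0L)
}

# softmax weights and log-sum-exp of a vector of scenario objectives
.lse <- function(fs, tau) {
  mx <- max(fs)
  w <- exp((fs - mx) / tau)
  sw <- sum(w)
  list(value = mx + tau * log(sw), weights = w / sw,
       active = which.max(fs))
}

#' Composite minimax robust optimization of spot weights
#'
#' Minimizes F(MU) = max over scenarios of the composite objective of the
#' scenario dose, subject to MU >= 0, by projected subgradient descent
#' (the gradient of the currently worst scenario) with a backtracking line
#' search; only improving steps are accepted, so the worst-case objective
#' trace is non-increasing. With a single scenario this reduces to plain
#' (non-robust) optimization.
#'
#' @param influences list of per-scenario influence matrices (voxels x
#'   spots), as from [scenario_influence()].
#' @param nominal_influence influence matrix of the nominal (error-free)
#'   scenario; used to scale the uniform initial MU so that the median
#'   CTV_pri dose equals its prescription.
#' @param objective objective term data.frame, see [default_objective()].
#' @param voxsets from [objective_voxels()].
#' @param prescriptions named numeric prescriptions.
#' @param control list: `maxit`, `tol`.
#' @return an `opt_result`: `mu`, `trace` (worst-case objective at accepted
#'   iterations, non-increasing), `active_scenario`, `converged`.
#' @export
cmro_optimize <- function(influences, nominal_influence, objective, voxsets,
                          prescriptions = c(CTV_pri = 70, CTV_pro = 54.25),
                          control = list()) {
  stopifnot(length(influences) >= 1)
  cterms <- .compile_terms(objective, voxsets)
  p1 <- prescriptions[["CTV_pri"]]
  nspots <- ncol(influences[[1]])
  d1 <- nominal_influence[voxsets$sets$CTV_pri, , drop = FALSE] %*%
    rep(1, nspots)
  med <- stats::median(as.numeric(d1))
  if (!is.finite(med) || med <= 0) stop("non-finite or zero initial dose")
  mu0 <- rep(p1 / med, nspots)

  evalfun <- function(mu, tau) {
    fs <- numeric(length(influences))
    doses <- vector("list", length(influences))
    for (s in seq_along(influences)) {
      doses[[s]] <- as.numeric(influences[[s]] %*% mu)
      fs[s] <- .composite_objective(doses[[s]], cterms, p1)$f
    }
    if (any(!is.finite(fs))) stop("non-finite objective")
    l <- .lse(fs, tau)
    grad <- 0
    for (s in seq_along(influences)) {
      if (l$weights[s] < 1e-10) next
      r <- .composite_objective(doses[[s]], cterms, p1, grad = TRUE)$r
      grad <- grad + l$weights[s] * as.numeric(Matrix::crossprod(influences[[s]], r))
    }
    list(F_true = max(fs), F_smooth = l$value, grad_smooth = grad,
         active = l$active)
  }
  res <- .minimax_solve(evalfun, mu0,
                        maxit = control$maxit %||% c(60, 280),
                        tol = control$tol %||% 1e-8)
  structure(res, class = "opt_result")
}

#' Dose-mimicking re-optimization at reduced robustness settings
#'
#' Produces an adjusted plan that preserves the reference plan's target
#' dose while re-optimizing everything else under a (smaller) scenario
#' set: minimizes a quadratic match to the reference nominal dose on the
#' target voxels, plus the sparing terms of the planning objective
#' (conformity ring and OAR mean doses) on the nominal dose, plus
#' `lambda` times the worst-case target-underdose penalty over the new
#' scenario set. Initialized at the reference MU, so with the reference
#' scenario set the reference plan is (close to) a fixed point.
#'
#' @param nominal_influence nominal influence matrix on the objective
#'   voxels.
#' @param reference_dose reference nominal dose at the objective voxels
#'   (same order), e.g. `nominal_influence %*% mu_ref`.
#' @param ctv_influences list of per-scenario influence matrices for the
#'   worst-case underdose term. By default rows are taken to cover the
#'   same objective voxels as `nominal_influence`; pass `und_sets` when
#'   the matrices are restricted to a target-voxel subset (faster).
#' @param objective planning objective; its non-target terms form the
#'   sparing part of the mimic objective.
#' @param voxsets from [objective_voxels()].
#' @param mu_ref reference plan MU vector (initialization).
#' @param prescriptions named prescriptions.
#' @param mimic_params list: `w_match` (target match weight, default
#'   1000); `coverage_scale` (default 0.4): the worst-case underdose term
#'   reuses the planning objective's coverage references and weights
#'   scaled by this factor, so the reduced scenario set frees exactly the
#'   margin band it no longer protects; `w_overshoot` (default 500):
#'   one-sided overdose-vs-reference penalty outside the targets that
#'   pins the near-degenerate beam-balance direction; `lambda` (default
#'   1): overall multiplier on the worst-case coverage term.
#' @param und_sets optional list with `CTV_pri`, `CTV_pro` row positions
#'   into the `ctv_influences` matrices (defaults to `voxsets$sets`).
#' @param control list: `maxit`, `tol`.
#' @return an `opt_result`.
#' @export
mimic_optimize <- function(nominal_influence, reference_dose, ctv_influences,
                           objective, voxsets, mu_ref,
                           prescriptions = c(CTV_pri = 70, CTV_pro = 54.25),
                           mimic_params = list(), und_sets = NULL,
                           control = list()) {
  if (nrow(nominal_influence) != length(reference_dose)) {
    stop("reference dose is not co-registered with the influence matrix")
  }
  w_match <- mimic_params$w_match %||% 1000
  lambda <- mimic_params$lambda %||% 1
  cov_scale <- mimic_params$coverage_scale %||% 0.25
  p1 <- prescriptions[["CTV_pri"]]
  spare <- objective[!(objective$structure %in% c("CTV_pri", "CTV_pro")), ,
                     drop = FALSE]
  cspare <- if (nrow(spare)) .compile_terms2(spare, voxsets) else list()
  # CTV_pro includes CTV_pri; fall back for single-target toy objectives
  tgt <- voxsets$sets$CTV_pro %||% voxsets$sets$CTV_pri
  und_sets <- und_sets %||% voxsets$sets
  # the worst-case coverage term reuses the planning objective's own
  # underdose references and weights (scaled by coverage_scale), so that
  # with the reference scenario set the reference plan is a near-fixed
  # point, while a reduced set frees exactly the margin band it no
  # longer protects
  cov <- objective[objective$type == "min_dose" &
                     objective$structure %in% c("CTV_pri", "CTV_pro"), ,
                   drop = FALSE]
  if (!nrow(cov)) stop("objective must contain a target underdose term")
  # references here are the plain prescriptions (not the planning
  # objective's headroom-inflated ones): the adjusted plan must keep its
  # reduced-scenario coverage at the clinical level, while the headroom
  # band is available for sparing
  und_terms <- lapply(seq_len(nrow(cov)), function(i) {
    list(idx = und_sets[[cov$structure[i]]], type = "min_dose",
         ref = prescriptions[[cov$structure[i]]],
         weight = cov_scale * cov$weight[i])
  })
  dref_t <- reference_dose[tgt]
  out <- setdiff(seq_len(nrow(nominal_influence)), tgt)
  dref_o <- reference_dose[out]
  w_over <- mimic_params$w_overshoot %||% 500
  n2 <- p1^2

  evalfun <- function(mu, tau) {
    d0 <- as.numeric(nominal_influence %*% mu)
    mres <- d0[tgt] - dref_t
    f <- w_match * sum(mres^2) / (length(tgt) * n2)
    # one-sided overdose-vs-reference penalty outside the targets: pins
    # down the near-degenerate beam-balance direction (swapping dose
    # between the two entrance channels) while leaving the sparing terms
    # free to push dose below the reference in the released margin band
    ores <- pmax(d0[out] - dref_o, 0)
    if (length(out)) f <- f + w_over * sum(ores^2) / (length(out) * n2)
    so <- .composite_objective(d0, cspare, p1, grad = TRUE)
    f <- f + so$f
    us <- numeric(length(ctv_influences))
    ds <- vector("list", length(ctv_influences))
    for (s in seq_along(ctv_influences)) {
      ds[[s]] <- as.numeric(ctv_influences[[s]] %*% mu)
      us[s] <- .composite_objective(ds[[s]], und_terms, p1)$f
    }
    if (!is.finite(f) || any(!is.finite(us))) stop("non-finite objective")
    r0 <- so$r
    r0[tgt] <- r0[tgt] + 2 * w_match * mres / (length(tgt) * n2)
    if (length(out)) r0[out] <- r0[out] + 2 * w_over * ores / (length(out) * n2)
    grad <- as.numeric(Matrix::crossprod(nominal_influence, r0))
    F_true <- f
    F_smooth <- f
    active <- 0L
    if (length(us)) {
      l <- .lse(us, tau)
      F_true <- f + lambda * max(us)
      F_smooth <- f + lambda * l$value
      active <- l$active
      for (s in seq_along(ctv_influences)) {
        if (l$weights[s] < 1e-10) next
        rw <- .composite_objective(ds[[s]], und_terms, p1, grad = TRUE)$r
        grad <- grad + lambda * l$weights[s] *
          as.numeric(Matrix::crossprod(ctv_influences[[s]], rw))
      }
    }
    list(F_true = F_true, F_smooth = F_smooth, grad_smooth = grad,
         active = active)
  }
  res <- .minimax_solve(evalfun, mu_ref,
                        maxit = control$maxit %||% c(60, 280),
                        tol = control$tol %||% 1e-8)
  structure(res, class = "opt_result")
}

# like .compile_terms but without requiring a target term (sparing-only)
.compile_terms2 <- function(objective, voxsets) {
  lapply(seq_len(nrow(objective)), function(i) {
    st <- objective$structure[i]
    if (is.null(voxsets$sets[[st]])) stop("unknown structure in objective: ", st)
    list(idx = voxsets$sets[[st]], type = objective$type[i],
         ref = objective$dose[i], weight = objective$weight[i])
  })
}

#' Label for a robustness setting
#' @param setting length-2 numeric `c(RR_pct, SR_mm)`.
#' @export
setting_label <- function(setting) {
  paste0(setting[1], "%/", setting[2], "mm")
}

#' Build the scanned-spot geometry for a snapshot
#'
#' Two lateral opposed beams along +/- x. Lateral spot positions form a
#' regular grid covering the CTV_pro projection plus a lateral margin;
#' energy layers span the water-equivalent depth range of CTV_pro plus a
#' range margin, separately per beam.
#'
#' @param snapshot a `phantom_snapshot` (week 0).
#' @param params engine parameters.
#' @param spot_spacing,layer_spacing grid spacings in mm.
#' @param lateral_margin_mm,range_margin_mm coverage margins.
#' @return list with `beams` and a `spots` data.frame (`mu = 1`).
#' @export
build_spot_geometry <- function(snapshot, params = engine_params(),
                                spot_spacing = 12, layer_spacing = 10,
                                lateral_margin_mm = 9, range_margin_mm = 7) {
  d <- dim(snapshot$spr_grid)
  crd <- .axis_coords(d, snapshot$spacing, snapshot$origin)
  beams <- list(beam_spec(c(1, 0, 0), spot_spacing, layer_spacing),
                beam_spec(c(-1, 0, 0), spot_spacing, layer_spacing))
  pro <- snapshot$masks$CTV_pro
  proj <- apply(pro, c(2, 3), any)
  pc <- which(proj, arr.ind = TRUE)
  py <- crd[[2]][pc[, 1]]
  pz <- crd[[3]][pc[, 2]]
  yr <- range(py) + c(-1, 1) * lateral_margin_mm
  zr <- range(pz) + c(-1, 1) * lateral_margin_mm
  ygrid <- seq(yr[1], yr[2], by = spot_spacing)
  zgrid <- seq(zr[1], zr[2], by = spot_spacing)
  cand <- expand.grid(y = ygrid, z = zgrid)
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    min((py - cand$y[i])^2 + (pz - cand$z[i])^2) <= lateral_margin_mm^2
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]

  spots <- NULL
  for (b in seq_along(beams)) {
    w <- wed_field(snapshot$spr_grid, snapshot$spacing[1],
                   direction = beams[[b]]$direction[1])
    wtg <- range(w[pro])
    layers <- seq(max(wtg[1] - range_margin_mm, layer_spacing / 2),
                  wtg[2] + range_margin_mm, by = layer_spacing)
    sb <- data.frame(beam = b,
                     y = rep(cand$y, times = length(layers)),
                     z = rep(cand$z, times = length(layers)),
                     R = rep(layers, each = nrow(cand)))
    spots <- rbind(spots, sb)
  }
  spots$mu <- 1
  rownames(spots) <- NULL
  list(beams = beams, spots = spots)
}

#' Build the reference and margin-reduced plan suite for one patient
#'
#' The reference setting (3% / 3 mm by convention, and required to be in
#' `settings`) is planned with [cmro_optimize()] over its 14-scenario
#' optimization set; every other setting is derived by [mimic_optimize()]
#' against the reference nominal dose with its own (reduced) 14-scenario
#' set. All plans share beams and spot geometry and differ only in MU.
#'
#' @param snapshot planning (week 0) `phantom_snapshot`.
#' @param objective planning objective data.frame.
#' @param settings list of length-2 numerics `c(RR_pct, SR_mm)`; must
#'   contain the reference setting.
#' @param reference length-2 reference setting (default `c(3, 3)`).
#' @param prescriptions named prescriptions.
#' @param params engine parameters.
#' @param geometry_args list passed to [build_spot_geometry()].
#' @param mimic_params,control see [mimic_optimize()] / [cmro_optimize()].
#' @return named list (labels from [setting_label()]) of [plan_spec()]
#'   objects; each carries its `opt_result` as attribute `"opt"`.
#' @export
build_plan_suite <- function(snapshot, objective = default_objective(),
                             settings = list(c(3, 3), c(2, 3), c(1, 3),
                                             c(3, 2), c(3, 1)),
                             reference = c(3, 3),
                             prescriptions = c(CTV_pri = 70, CTV_pro = 54.25),
                             params = engine_params(),
                             geometry_args = list(),
                             mimic_params = list(), control = list()) {
  if (!length(settings)) stop("settings list is empty")
  is_ref <- vapply(settings, function(s) all(s == reference), logical(1))
  if (!any(is_ref)) stop("settings must include the reference setting")
  geom <- do.call(build_spot_geometry,
                  c(list(snapshot = snapshot, params = params), geometry_args))
  voxsets <- objective_voxels(snapshot)
  nom_scen <- list(dx = 0, dy = 0, dz = 0, range_pct = 0)
  A0 <- scenario_influence(snapshot, geom$beams, geom$spots, nom_scen,
                           voxsets$vox, params)

  ref_scen <- optimization_scenarios(reference[2], reference[1])
  A_ref <- lapply(seq_len(nrow(ref_scen)), function(i) {
    scenario_influence(snapshot, geom$beams, geom$spots, ref_scen[i, ],
                       voxsets$vox, params)
  })
  ref_opt <- cmro_optimize(A_ref, A0, objective, voxsets, prescriptions,
                           control)
  ref_dose <- as.numeric(A0 %*% ref_opt$mu)
  rm(A_ref)

  # target-voxel subset for the mimic stage's worst-case coverage term
  ctv_pos <- sort(unique(c(voxsets$sets$CTV_pri, voxsets$sets$CTV_pro)))
  und_sets <- list(CTV_pri = match(voxsets$sets$CTV_pri, ctv_pos),
                   CTV_pro = match(voxsets$sets$CTV_pro, ctv_pos))
  ctv_vox <- voxsets$vox[ctv_pos]

  plans <- list()
  for (s in settings) {
    lbl <- setting_label(s)
    if (all(s == reference)) {
      opt <- ref_opt
    } else {
      scen <- optimization_scenarios(s[2], s[1])
      A_s <- lapply(seq_len(nrow(scen)), function(i) {
        scenario_influence(snapshot, geom$beams, geom$spots, scen[i, ],
                           ctv_vox, params)
      })
      opt <- mimic_optimize(A0, ref_dose, A_s, objective, voxsets,
                            ref_opt$mu, prescriptions, mimic_params,
                            und_sets = und_sets, control = control)
      rm(A_s)
    }
    sp <- geom$spots
    sp$mu <- opt$mu
    plan <- plan_spec(geom$beams, sp, prescriptions,
                      robustness_setting = s, params = params)
    attr(plan, "opt") <- opt
    plans[[lbl]] <- plan
  }
  plans
}
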