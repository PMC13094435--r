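# Logistic normal-tissue complication probability (NTCP) models driven by
# mean organ-at-risk doses and clinical factors, the total-NTCP summary,
# and the model-based patient-selection rule on photon-minus-proton NTCP
# differences. Model coefficients are configuration inputs: the package
# ships a clearly-labelled synthetic example coefficient file (see
# `system.file("extdata", "ntcp_models_synthetic.json", package =
# "adaptrt")`), never clinical constants.

#' Construct an NTCP model
#'
#' NTCP = 1 / (1 + exp(-S)) with S = intercept + sum of dose terms
#' (optionally sqrt-transformed mean structure dose) + clinical-factor
#' coefficients.
#'
#' @param endpoint endpoint name (e.g. "xerostomia_mod_severe").
#' @param grade complication grade class: "grade2" or "grade3_4".
#' @param intercept logistic intercept beta0.
#' @param dose_terms list of lists with `structure`, `coefficient` (per Gy
#'   or per sqrt(Gy)), `transform` ("identity" or "sqrt").
#' @param factor_terms named list: for each clinical factor, a named
#'   numeric map from level to coefficient.
#' @param provenance free-text citation / provenance note.
#' @export
ntcp_model <- function(endpoint, grade = c("grade2", "grade3_4"),
                       intercept, dose_terms = list(),
                       factor_terms = list(), provenance = "") {
  grade <- match.arg(grade)
  for (t in dose_terms) {
    if (is.null(t$structure) || is.null(t$coefficient)) {
      stop("dose terms need `structure` and `coefficient`")
    }
    if (!(t$transform %||% "identity") %in% c("identity", "sqrt")) {
      stop("transform must be 'identity' or 'sqrt'")
    }
    if (!is.finite(t$coefficient)) stop("coefficients must be finite")
  }
  if (!is.finite(intercept)) stop("coefficients must be finite")
  structure(list(endpoint = endpoint, grade = grade, intercept = intercept,
                 dose_terms = dose_terms, factor_terms = factor_terms,
                 provenance = provenance),
            class = "ntcp_model")
}

#' Evaluate an NTCP model
#'
#' @param model an [ntcp_model()].
#' @param mean_doses named numeric: mean dose in Gy(RBE) per structure.
#' @param factors named list of clinical-factor levels (see
#'   [generate_cohort()]); only factors named by the model are read.
#' @return probability in (0, 1), strictly increasing in any dose covariate
#'   with positive coefficient.
#' @export
ntcp <- function(model, mean_doses, factors = list()) {
  s <- model$intercept
  for (t in model$dose_terms) {
    d <- mean_doses[[t$structure]]
    if (is.null(d) || is.na(d)) {
      stop("missing mean dose for covariate structure: ", t$structure)
    }
    x <- if ((t$transform %||% "identity") == "sqrt") sqrt(d) else d
    s <- s + t$coefficient * x
  }
  for (fn in names(model$factor_terms)) {
    lev <- factors[[fn]]
    if (is.null(lev)) stop("missing clinical factor: ", fn)
    ft <- model$factor_terms[[fn]]
    if (!lev %in% names(ft)) {
      stop("unknown level '", lev, "' for factor ", fn)
    }
    s <- s + ft[[lev]]
  }
  stats::plogis(s)
}

#' Total NTCP across endpoints
#'
#' Defined as the sum of the endpoint probabilities (reported in
#' percentage points it may exceed 100); the sum is the convention
#' consistent with additivity of per-endpoint trend slopes.
#'
#' @param endpoint_ntcps numeric vector of endpoint NTCP values in [0, 1].
#' @export
total_ntcp <- function(endpoint_ntcps) {
  stopifnot(all(endpoint_ntcps >= 0), all(endpoint_ntcps <= 1))
  sum(endpoint_ntcps)
}

#' Model-based selection rule on NTCP differences
#'
#' A patient qualifies for proton therapy when the photon-minus-proton
#' NTCP difference reaches 10 percentage points for a single grade-2
#' complication, 15 points for the cumulative occurrence of two grade-2
#' complications, or 5 points for a single grade 3-4 complication
#' (thresholds inclusive).
#'
#' @param ntcp_photon,ntcp_proton named numeric vectors (same endpoints),
#'   probabilities in [0, 1].
#' @param grades named character vector: "grade2" or "grade3_4" per
#'   endpoint.
#' @return list with `eligible`, `delta_pct` (per endpoint, in percentage
#'   points) and `rule` (the first rule that fired, or NA).
#' @export
model_based_selection <- function(ntcp_photon, ntcp_proton, grades) {
  ep <- names(ntcp_photon)
  if (is.null(ep) || !setequal(ep, names(ntcp_proton))) {
    stop("photon and proton NTCP must be named identically")
  }
  if (any(!ep %in% names(grades))) {
    stop("missing grade annotation for endpoint(s): ",
         paste(setdiff(ep, names(grades)), collapse = ", "))
  }
  delta <- (ntcp_photon - ntcp_proton[ep]) * 100
  g2 <- delta[grades[ep] == "grade2"]
  g34 <- delta[grades[ep] == "grade3_4"]
  rule <- NA_character_
  if (length(g2) && max(g2) >= 10) {
    rule <- "single_grade2_10pp"
  } else if (length(g2) >= 2 &&
             sum(sort(g2, decreasing = TRUE)[1:2]) >= 15) {
    rule <- "two_grade2_15pp"
  } else if (length(g34) && max(g34) >= 5) {
    rule <- "single_grade3_4_5pp"
  }
  list(eligible = !is.na(rule), delta_pct = delta, rule = rule)
}

#' Read NTCP models from a JSON coefficient file
#'
#' @param path JSON file with a list of model objects (fields as in
#'   [ntcp_model()]).
#' @return named list of `ntcp_model` objects.
#' @export
read_ntcp_models <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  models <- lapply(raw, function(m) {
    ntcp_model(endpoint = m$endpoint, grade = m$grade,
               intercept = m$intercept,
               dose_terms = m$dose_terms %||% list(),
               factor_terms = lapply(m$factor_terms %||% list(), unlist),
               provenance = m$provenance %||% "")
  })
  names(models) <- vapply(models, `[[`, character(1), "endpoint")
  models
}

#' Synthetic example NTCP models shipped with the package
#'
#' Convenience loader for the synthetic coefficient file. The coefficients
#' are illustrative placeholders with plausible signs and magnitudes, not
#' validated clinical models.
#' @export
synthetic_ntcp_models <- function() {
  read_ntcp_models(system.file("extdata", "ntcp_models_synthetic.json",
                               package = "adaptrt", mustWork = TRUE))
}
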