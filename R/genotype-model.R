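#' The published reference genotype model
#'
#' The fixed combined three-metric logistic model for the probability of a
#' diffuse glioma being IDH-mutant:
#' \deqn{p = 1/[1 + e^{-(8.941\,SDC - 0.124\,DDVD + 0.034\,ADC - 1.229)}]}
#' with SDC in au/s, DDVD in au/pixel and ADC in 1e-4 mm^2/s. This object
#' is immutable and never overwritten by refitting; use [fitLogistic()] to
#' estimate the same model form on a new cohort.
#'
#' @return a [LogisticCoefficients-class] labelled
#'   `"paper-2025-reference"`.
#' @export
referenceModel <- function() {
  new("LogisticCoefficients",
      betaSDC = 8.941, betaDDVD = -0.124, betaADC = 0.034,
      intercept = -1.229,
      units = "SDC au/s; DDVD au/pixel; ADC 1e-4 mm2/s",
      label = "paper-2025-reference")
}

#' Construct a logistic coefficient set
#'
#' @param betaSDC,betaDDVD,betaADC,intercept the four coefficients, on the
#'   unit contract SDC au/s, DDVD au/pixel, ADC 1e-4 mm^2/s.
#' @param label model name.
#' @return a [LogisticCoefficients-class].
#' @export
logisticCoefficients <- function(betaSDC, betaDDVD, betaADC, intercept,
                                 label = "custom") {
  new("LogisticCoefficients",
      betaSDC = as.numeric(betaSDC), betaDDVD = as.numeric(betaDDVD),
      betaADC = as.numeric(betaADC), intercept = as.numeric(intercept),
      units = "SDC au/s; DDVD au/pixel; ADC 1e-4 mm2/s", label = label)
}

tripletMatrix <- function(x) {
  if (is(x, "MetricTriplet")) {
    x <- adcToModelUnits(x)
    return(cbind(sdc = x@sdc, ddvd = x@ddvd, adc = x@adc))
  }
  if (is.data.frame(x)) {
    need <- c("sdc_au_per_s", "ddvd_au_per_pixel", "adc_e4_mm2_per_s")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("unit-tagged metric columns missing: ",
           paste(miss, collapse = ", "),
           " (ADC must be supplied in 1e-4 mm2/s under its unit-named ",
           "column; raw mm2/s is refused, never silently rescaled)",
           call. = FALSE)
    return(cbind(sdc = x$sdc_au_per_s, ddvd = x$ddvd_au_per_pixel,
                 adc = x$adc_e4_mm2_per_s))
  }
  stop("expected a MetricTriplet or a cohort data.frame", call. = FALSE)
}

#' Probability of IDH-mutant genotype
#'
#' Evaluates the combined logistic model on one [MetricTriplet-class] or a
#' whole cohort table. Units are enforced through the triplet's unit tag
#' (ADC in mm^2/s is converted once to 1e-4 mm^2/s; a tag mismatch is an
#' error, never a silent double rescale).
#'
#' @param x a [MetricTriplet-class] or cohort data.frame (see
#'   [readCohort()]).
#' @param coeffs a [LogisticCoefficients-class]; default the published
#'   reference model.
#' @return numeric probability/probabilities, strictly inside (0, 1) for
#'   finite inputs.
#' @export
predictProbability <- function(x, coeffs = referenceModel()) {
  stopifnot(is(coeffs, "LogisticCoefficients"))
  M <- tripletMatrix(x)
  eta <- coeffs@betaSDC * M[, "sdc"] + coeffs@betaDDVD * M[, "ddvd"] +
    coeffs@betaADC * M[, "adc"] + coeffs@intercept
  unname(stats::plogis(eta))
}

#' Fit the three-metric logistic genotype model to a cohort
#'
#' Maximum-likelihood fit (binomial IRLS, log-likelihood tolerance 1e-8,
#' at most 100 iterations) of
#' `label ~ SDC + DDVD + ADC`, unregularized. Complete or
#' quasi-complete separation is detected (fitted probabilities numerically
#' 0/1 or exploding standard errors) and reported as an error rather than
#' returning divergent coefficients.
#'
#' @param cohort cohort data.frame.
#' @param label label column: `"idh_gene"` (0/1) or `"idh_ihc"`
#'   (0/0.5/1; requires `excludePartial = TRUE`).
#' @param excludePartial drop immunohistochemistry partially-positive
#'   (0.5) cases before fitting; they are excluded, never merged into a
#'   class.
#' @return list: `coeffs` ([LogisticCoefficients-class]), `se` (named
#'   standard errors), `converged`, `nIter`, `auc` (in-sample AUC of the
#'   fitted probabilities), `n`.
#' @export
fitLogistic <- function(cohort, label = "idh_gene",
                        excludePartial = (label == "idh_ihc")) {
  lab <- cohort[[label]]
  if (is.null(lab)) stop("no label column '", label, "'", call. = FALSE)
  keep <- !is.na(lab)
  if (excludePartial) keep <- keep & lab != 0.5
  df <- cohort[keep, , drop = FALSE]
  y <- as.numeric(df[[label]] == max(df[[label]]))
  if (length(unique(y)) < 2L)
    stop("single class after exclusions: cannot fit", call. = FALSE)
  M <- tripletMatrix(df)
  if (anyNA(M)) stop("missing metric values in cohort", call. = FALSE)
  dat <- data.frame(y = y, sdc = M[, "sdc"], ddvd = M[, "ddvd"],
                    adc = M[, "adc"])
  fit <- stats::glm(y ~ sdc + ddvd + adc, family = stats::binomial(),
                    data = dat,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged)
    stop("IRLS did not converge within 100 iterations", call. = FALSE)
  mu <- stats::fitted(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (all(mu > 1 - 1e-8 | mu < 1e-8) || any(!is.finite(se)) ||
      max(abs(stats::coef(fit))) > 1e4)
    stop("complete separation detected: coefficients diverge; ",
         "the unregularized ML fit is not identified on these data",
         call. = FALSE)
  cf <- stats::coef(fit)
  list(
    coeffs = logisticCoefficients(cf[["sdc"]], cf[["ddvd"]], cf[["adc"]],
                                  cf[["(Intercept)"]], label = "refit"),
    se = c(sdc = se[["sdc"]], ddvd = se[["ddvd"]], adc = se[["adc"]],
           intercept = se[["(Intercept)"]]),
    converged = fit$converged, nIter = fit$iter,
    auc = auc(rocCurve(mu, y)), n = nrow(dat)
  )
}

#' Classify a cohort with a genotype model
#'
#' Deterministic per-subject probability and predicted class at a stated
#' probability threshold. A probability exactly at the threshold is
#' classified positive (documented tie rule).
#'
#' @param cohort cohort data.frame (may be empty).
#' @param coeffs a [LogisticCoefficients-class].
#' @param threshold probability threshold, default 0.5.
#' @return data.frame: `subject_id`, `probability`, `predictedClass`
#'   (1 = IDH-mutant-positive).
#' @export
classifyCohort <- function(cohort, coeffs = referenceModel(),
                           threshold = 0.5) {
  if (nrow(cohort) == 0L)
    return(data.frame(subject_id = character(), probability = numeric(),
                      predictedClass = integer()))
  p <- predictProbability(cohort, coeffs)
  data.frame(subject_id = if ("subject_id" %in% names(cohort))
               cohort$subject_id else seq_len(nrow(cohort)),
             probability = p,
             predictedClass = as.integer(p >= threshold))
}

#' Serialize / deserialize logistic coefficients as JSON
#'
#' @param coeffs a [LogisticCoefficients-class].
#' @param path JSON path.
#' @return `writeCoefficients`: `path` invisibly; `readCoefficients`: a
#'   [LogisticCoefficients-class].
#' @export
writeCoefficients <- function(coeffs, path) {
  jsonlite::write_json(
    list(beta_sdc = coeffs@betaSDC, beta_ddvd = coeffs@betaDDVD,
         beta_adc = coeffs@betaADC, intercept = coeffs@intercept,
         units = coeffs@units, label = coeffs@label),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCoefficients
#' @export
readCoefficients <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  logisticCoefficients(j$beta_sdc, j$beta_ddvd, j$beta_adc, j$intercept,
                       label = j$label %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
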