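rankSumU <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided test for a location difference between two independent
#' groups. For combined n <= 20 the p-value is computed by exact
#' enumeration of all group assignments (valid with ties); otherwise by the
#' tie-corrected normal approximation with continuity correction, matching
#' common commercial-software behavior. U is oriented so that U = 0 when
#' every value in `x` ranks below every value in `y`; ties contribute one
#' half.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exactMax largest combined sample size for exact enumeration.
#' @param correct apply the continuity correction in the normal
#'   approximation (default TRUE; FALSE makes the k = 2 Kruskal-Wallis
#'   chi-square p identical to the Mann-Whitney normal p).
#' @return list: `U`, `p`, `method`, `n1`, `n2`.
#' @export
mannWhitney <- function(x, y, exactMax = 20L, correct = TRUE) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  U <- rankSumU(x, y)
  mu <- n1 * n2 / 2
  if (N <= exactMax) {
    r <- rank(c(x, y))
    idx <- utils::combn(N, n1)
    Uall <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    r <- rank(c(x, y))
    tab <- table(r)
    tiecorr <- sum(tab^3 - tab) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tiecorr))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - if (correct) 0.5 else 0) / sigma
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "tie-corrected normal approximation"
  }
  list(U = U, p = p, method = method, n1 = n1, n2 = n2)
}

#' Kruskal-Wallis rank test across k groups
#'
#' Tie-corrected H with a chi-square p on k-1 degrees of freedom. All
#' values identical across groups gives H = 0, p = 1 (not an error).
#'
#' @param values numeric vector, or a list of per-group numeric vectors.
#' @param groups grouping factor (ignored when `values` is a list).
#' @return list: `H`, `df`, `p`.
#' @export
kruskalWallis <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(g) - 1L, p = 1))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y paired numeric vectors, n >= 3, each with nonzero variance.
#' @param level confidence level (default 0.95).
#' @return list: `r`, `ciLow`, `ciHigh`, `p` (two-sided, t with n-2 df),
#'   `n`.
#' @export
pearsonCorrelation <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, conf.level = level)
  list(r = unname(ct$estimate), ciLow = ct$conf.int[1],
       ciHigh = ct$conf.int[2], p = ct$p.value, n = length(x))
}

#' Inter-reader intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the two-way ANOVA decomposition (subjects x readers), with the F-based
#' confidence interval using Satterthwaite degrees of freedom — the
#' standard form for inter-reader reliability of a continuous measurement.
#'
#' @param reader1,reader2 paired measurements, n >= 3 subjects.
#' @param level confidence level.
#' @return list: `icc`, `ciLow`, `ciHigh`, `n`.
#' @export
iccInterReader <- function(reader1, reader2, level = 0.95) {
  if (length(reader1) != length(reader2))
    stop("reader vectors must have equal length", call. = FALSE)
  n <- length(reader1)
  if (n < 3L) stop("need n >= 3 subjects", call. = FALSE)
  k <- 2
  Y <- cbind(reader1, reader2)
  rowM <- rowMeans(Y); colM <- colMeans(Y); gm <- mean(Y)
  MSR <- k * sum((rowM - gm)^2) / (n - 1)          # between subjects
  MSC <- n * sum((colM - gm)^2) / (k - 1)          # between readers
  SSE <- sum((Y - outer(rowM, rep(1, k)) -
              outer(rep(1, n), colM) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, ciLow = lo, ciHigh = hi, n = n)
}

#' Cohort-level descriptive and inferential summary
#'
#' Per-metric group statistics (mean +/- SD, median/IQR), a Mann-Whitney
#' test between the two label classes per metric, the grade-wise
#' Kruskal-Wallis test on SDC (ungraded NEC cases excluded), the
#' between-metric Pearson correlation matrix with Fisher-z CIs, and the
#' SDC vs Ki-67 correlation.
#'
#' @param cohort cohort data.frame (see [readCohort()]).
#' @param label binary label column, default `"idh_gene"`.
#' @return nested list of results.
#' @export
cohortSummary <- function(cohort, label = "idh_gene") {
  metrics <- c("sdc_au_per_s", "ddvd_au_per_pixel", "adc_e4_mm2_per_s")
  lab <- cohort[[label]]
  if (is.null(lab)) stop("no label column '", label, "'", call. = FALSE)
  groupStats <- lapply(metrics, function(m) {
    vapply(split(cohort[[m]], lab), function(v)
      c(n = length(v), mean = mean(v), sd = stats::sd(v),
        median = stats::median(v),
        q1 = unname(stats::quantile(v, 0.25)),
        q3 = unname(stats::quantile(v, 0.75))), numeric(6))
  })
  names(groupStats) <- metrics
  tests <- lapply(metrics, function(m)
    mannWhitney(cohort[[m]][lab == sort(unique(lab))[1]],
                cohort[[m]][lab == sort(unique(lab))[2]]))
  names(tests) <- metrics
  gradeTest <- NULL
  if ("grade" %in% names(cohort)) {
    gr <- cohort[!is.na(cohort$grade), ]
    if (length(unique(gr$grade)) >= 2)
      gradeTest <- c(kruskalWallis(gr$sdc_au_per_s, gr$grade),
                     list(medians = tapply(gr$sdc_au_per_s, gr$grade,
                                           stats::median)))
  }
  corrs <- list(
    sdc_ddvd = pearsonCorrelation(cohort$sdc_au_per_s,
                                  cohort$ddvd_au_per_pixel),
    sdc_adc = pearsonCorrelation(cohort$sdc_au_per_s,
                                 cohort$adc_e4_mm2_per_s),
    ddvd_adc = pearsonCorrelation(cohort$ddvd_au_per_pixel,
                                  cohort$adc_e4_mm2_per_s)
  )
  if ("ki67_pct" %in% names(cohort))
    corrs$sdc_ki67 <- pearsonCorrelation(cohort$sdc_au_per_s,
                                         cohort$ki67_pct)
  list(groupStats = groupStats, tests = tests, gradeTest = gradeTest,
       correlations = corrs)
}
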