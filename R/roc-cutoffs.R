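asBinaryLabel <- function(labels) {
  u <- sort(unique(labels))
  if (length(u) < 2L)
    stop("single-class input: both classes must be present", call. = FALSE)
  if (length(u) > 2L)
    stop("labels must be binary, got levels: ",
         paste(u, collapse = ", "), call. = FALSE)
  labels == u[2L]
}

#' Empirical ROC curve and AUC
#'
#' Empirical ROC over all distinct observed thresholds with trapezoidal
#' AUC. Tied values are handled by the Mann-Whitney convention (a tied
#' positive-negative pair contributes one half), so the AUC equals
#' U/(n1*n2) identically. The positive-class orientation is an explicit
#' flag — higher SDC indicating IDH-mutant is `direction = ">"` — and is
#' never auto-flipped.
#'
#' @param values numeric classifier scores.
#' @param labels binary labels; the larger level is the positive class.
#' @param direction `">"` (higher score = positive, default) or `"<"`.
#' @return a [ROCResult-class].
#' @export
rocCurve <- function(values, labels, direction = c(">", "<")) {
  direction <- match.arg(direction)
  pos <- asBinaryLabel(labels)
  stopifnot(length(values) == length(pos), all(is.finite(values)))
  sc <- if (direction == ">") values else -values
  nP <- sum(pos); nN <- sum(!pos)
  thr <- sort(unique(sc), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(sc[pos] >= t), 0) / nP
  fpr <- vapply(thr, function(t) sum(sc[!pos] >= t), 0) / nN
  curve <- data.frame(threshold = c(Inf, thr, -Inf),
                      fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  aucv <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                 utils::tail(curve$tpr, -1)) / 2)
  if (direction == "<") curve$threshold <- -curve$threshold
  new("ROCResult", auc = aucv, curve = curve, direction = direction,
      nPositive = as.integer(nP), nNegative = as.integer(nN))
}

#' Binomial proportion confidence interval (hybrid Wilson/Brown)
#'
#' Wilson score interval, with Brown's modification for near-boundary
#' counts: when the number of successes (for the lower bound) or failures
#' (for the upper bound) is 1 or 2, the Wilson bound is replaced by the
#' one-sided Poisson chi-square bound \eqn{\chi^2_{2k,\alpha}/(2n)} — the
#' hybrid used by common biostatistics software, which is what the
#' sensitivity/specificity CIs of published cutoff tables typically come
#' from. `method = "wilson"` gives the unmodified Wilson score interval.
#' Bounds are exact 0 and 100 at empty/full counts.
#'
#' @param successes,n counts, 0 <= successes <= n, n >= 1.
#' @param level confidence level (default 0.95).
#' @param method `"hybrid"` (default) or `"wilson"`.
#' @return numeric `c(lo, hi)` in percent.
#' @export
wilsonCI <- function(successes, n, level = 0.95,
                     method = c("hybrid", "wilson")) {
  method <- match.arg(method)
  stopifnot(n >= 1, successes >= 0, successes <= n)
  alpha <- 1 - level
  z <- stats::qnorm(1 - alpha / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  lo <- (centre - half) / den
  hi <- (centre + half) / den
  if (method == "hybrid") {
    if (successes %in% 1:2)
      lo <- stats::qchisq(alpha, 2 * successes) / (2 * n)
    if ((n - successes) %in% 1:2)
      hi <- 1 - stats::qchisq(alpha, 2 * (n - successes)) / (2 * n)
  }
  if (successes == 0) lo <- 0
  if (successes == n) hi <- 1
  c(lo = lo * 100, hi = hi * 100)
}

#' Positive likelihood ratio
#'
#' LR+ = sensitivity / (1 - specificity), computed on exact count
#' fractions (never on rounded percentages: 11/15 vs 34/35 gives 25.67
#' where rounded percentages would give 25.64). Specificity 1 gives `Inf`.
#'
#' @param sens,spec sensitivity and specificity as fractions in \[0, 1\].
#' @return LR+ (may be `Inf`).
#' @export
likelihoodRatio <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  if (spec == 1) return(Inf)
  sens / (1 - spec)
}

#' Cutoff table: sensitivity, specificity, CIs and likelihood ratios
#'
#' One row per threshold of the rule "predict positive if value >
#' threshold" (strict inequality, the convention of published SDC cutoff
#' tables). With `thresholds = NULL` the candidates are the midpoints
#' between consecutive distinct observed values, so any printed
#' four-decimal cutoff is representable. Sensitivity and specificity are
#' exact count fractions reported in percent with hybrid Wilson/Brown 95%
#' CIs; LR+ comes from the exact fractions, `Inf` when specificity is
#' 100%.
#'
#' @param values numeric scores (e.g. per-lesion SDC, au/s).
#' @param labels binary labels; larger level = positive class.
#' @param thresholds numeric thresholds, or `NULL` for all midpoints.
#' @param level CI confidence level.
#' @param ciMethod passed to [wilsonCI()].
#' @return data.frame: `threshold`, `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `sensLow`, `sensHigh`, `specificity`, `specLow`,
#'   `specHigh` (percent), `likelihoodRatio`.
#' @export
cutoffTable <- function(values, labels, thresholds = NULL, level = 0.95,
                        ciMethod = c("hybrid", "wilson")) {
  ciMethod <- match.arg(ciMethod)
  pos <- asBinaryLabel(labels)
  if (is.null(thresholds)) {
    v <- sort(unique(values))
    thresholds <- if (length(v) > 1L)
      (utils::head(v, -1) + utils::tail(v, -1)) / 2 else v
  }
  nP <- sum(pos); nN <- sum(!pos)
  rows <- lapply(thresholds, function(t) {
    tp <- sum(values[pos] > t); tn <- sum(values[!pos] <= t)
    sensCI <- wilsonCI(tp, nP, level, ciMethod)
    specCI <- wilsonCI(tn, nN, level, ciMethod)
    data.frame(threshold = t, tp = tp, fn = nP - tp, tn = tn,
               fp = nN - tn,
               sensitivity = 100 * tp / nP,
               sensLow = sensCI[["lo"]], sensHigh = sensCI[["hi"]],
               specificity = 100 * tn / nN,
               specLow = specCI[["lo"]], specHigh = specCI[["hi"]],
               likelihoodRatio = likelihoodRatio(tp / nP, tn / nN))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Youden-optimal row of a cutoff table
#'
#' @param table result of [cutoffTable()].
#' @return the row maximizing sensitivity + specificity (first on ties).
#' @export
youdenRow <- function(table) {
  table[which.max(table$sensitivity + table$specificity), , drop = FALSE]
}

#' DeLong confidence interval for an AUC
#'
#' Asymptotic normal CI from the DeLong variance estimate (midrank
#' placements).
#'
#' @param values,labels as in [rocCurve()].
#' @param level confidence level.
#' @return list: `auc`, `ciLow`, `ciHigh`, `se`.
#' @export
delongCI <- function(values, labels, level = 0.95) {
  pos <- asBinaryLabel(labels)
  X <- values[pos]; Y <- values[!pos]
  m <- length(X); n <- length(Y)
  plc <- function(a, b) vapply(a, function(ai)
    (sum(ai > b) + 0.5 * sum(ai == b)) / length(b), 0)
  V10 <- plc(X, Y)                     # placement of each positive
  V01 <- 1 - plc(Y, X)                 # placement of each negative
  theta <- mean(V10)
  se <- sqrt(stats::var(V10) / m + stats::var(V01) / n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = theta, ciLow = max(0, theta - z * se),
       ciHigh = min(1, theta + z * se), se = se)
}
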