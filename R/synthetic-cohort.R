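#' One group of a synthetic cohort
#'
#' @param name group label (e.g. `"IDH-wildtype"`).
#' @param n group size, >= 1.
#' @param mean,sd length-3 numeric vectors, metric order
#'   (SDC au/s, DDVD au/pixel, ADC 1e-4 mm^2/s); SDs >= 0 (0 gives a
#'   degenerate constant draw).
#' @param ki67Mean,ki67SD Ki-67 labeling index location/spread (percent).
#' @param idhGene 0 (wildtype) or 1 (mutant) gene-testing label.
#' @param ihcProbs length-3 probabilities for immunohistochemistry status
#'   (negative, partially positive, positive).
#' @param gradeCounts named integer counts over grades `"2"`, `"3"`, `"4"`,
#'   `"NA"` (NEC, excluded from grade analyses); must sum to `n`.
#' @return a `cohortGroup` list.
#' @export
cohortGroup <- function(name, n, mean, sd, ki67Mean = 20, ki67SD = 10,
                        idhGene = 0,
                        ihcProbs = c(1, 0, 0),
                        gradeCounts = c("2" = 0, "3" = 0, "4" = 0,
                                        "NA" = n)) {
  stopifnot(n >= 1, length(mean) == 3L, length(sd) == 3L, all(sd >= 0),
            ki67SD >= 0, idhGene %in% c(0, 1),
            length(ihcProbs) == 3L, all(ihcProbs >= 0),
            sum(gradeCounts) == n)
  structure(list(name = name, n = as.integer(n), mean = mean, sd = sd,
                 ki67Mean = ki67Mean, ki67SD = ki67SD, idhGene = idhGene,
                 ihcProbs = ihcProbs / sum(ihcProbs),
                 gradeCounts = gradeCounts),
            class = "cohortGroup")
}

#' Cohort simulation specification
#'
#' Metric triplets are drawn per group from a multivariate normal on the
#' metric scale (SDC in au/s, DDVD in au/pixel, ADC in 1e-4 mm^2/s) with a
#' shared between-metric correlation matrix; SDC and ADC are truncated at
#' zero. Ki-67 LI is a linear function of SDC plus noise, scaled so its
#' within-group correlation with SDC equals `ki67Cor`, then clamped to
#' \[0, 100\] percent.
#'
#' @param groups list of [cohortGroup()] entries.
#' @param metricCor 3x3 between-metric correlation matrix (SDC, DDVD, ADC
#'   order); must be symmetric positive-definite unless `projectPD`.
#' @param ki67Cor target within-group Pearson correlation of Ki-67 with SDC.
#' @param seed integer RNG seed.
#' @param projectPD if `TRUE`, a non-positive-definite `metricCor` is
#'   projected to the nearest positive-definite correlation matrix instead
#'   of being rejected.
#' @return a `cohortSpec` list.
#' @export
cohortSpec <- function(groups,
                       metricCor = defaultMetricCor(),
                       ki67Cor = -0.382, seed = 1L, projectPD = FALSE) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, TRUE, "cohortGroup")))
  R <- as.matrix(metricCor)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    if (!projectPD)
      stop("non-positive-definite correlation matrix (min eigenvalue ",
           signif(min(ev), 3), "); set projectPD = TRUE to project",
           call. = FALSE)
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  }
  stopifnot(abs(ki67Cor) < 1)
  structure(list(groups = groups, metricCor = R, ki67Cor = ki67Cor,
                 seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Default between-metric correlation matrix
#'
#' SDC-ADC +0.705 and SDC-DDVD -0.212 are the cohort Pearson correlations
#' the analysis reproduces; DDVD-ADC is unreported and defaults to 0.
#'
#' @return 3x3 correlation matrix (SDC, DDVD, ADC order).
#' @export
defaultMetricCor <- function() {
  R <- diag(3)
  dimnames(R) <- rep(list(c("sdc", "ddvd", "adc")), 2)
  R["sdc", "ddvd"] <- R["ddvd", "sdc"] <- -0.212
  R["sdc", "adc"]  <- R["adc", "sdc"]  <- 0.705
  R
}

#' Default IDH-genotype cohort specification
#'
#' Two groups sized and calibrated to the published SDC statistics:
#' 33 IDH-wildtype cases at 0.339 +/- 0.055 au/s and 30 IDH-mutant cases at
#' 0.437 +/- 0.097 au/s. DDVD and ADC group statistics are not published;
#' defaults place the wildtype group at higher DDVD (microvascular
#' proliferation) and lower ADC (denser tissue) than the mutant group, with
#' magnitudes typical for glioma imaging. Ki-67 locations follow the
#' published medians (32.5% wildtype, 10% mutant).
#'
#' @param seed integer RNG seed.
#' @return a [cohortSpec()].
#' @export
defaultCohortSpec <- function(seed = 1L) {
  cohortSpec(
    groups = list(
      cohortGroup("IDH-wildtype", n = 33,
                  mean = c(0.339, 35, 10), sd = c(0.055, 12, 2),
                  ki67Mean = 32.5, ki67SD = 15, idhGene = 0,
                  ihcProbs = c(0.94, 0.06, 0),
                  gradeCounts = c("2" = 0, "3" = 0, "4" = 28, "NA" = 5)),
      cohortGroup("IDH-mutant", n = 30,
                  mean = c(0.437, 25, 13), sd = c(0.097, 10, 2.5),
                  ki67Mean = 12, ki67SD = 8, idhGene = 1,
                  ihcProbs = c(0.13, 0.37, 0.50),
                  gradeCounts = c("2" = 19, "3" = 6, "4" = 5, "NA" = 0))
    ),
    seed = seed
  )
}

#' Default grade-wise cohort specification
#'
#' Three histological grades sized and centred on the published SDC medians
#' (0.472, 0.441, 0.364 au/s at n = 19, 6, 33); under the normal model the
#' median equals the mean. Spreads are not published; they are calibrated
#' once to 0.065, 0.065 and 0.050 au/s — grade-specific groups are more
#' homogeneous than the pooled IDH groups (SDs 0.055 and 0.097), and at
#' these spreads the generator reproduces the hallmark grade-wise
#' Kruskal-Wallis significance (p < 1e-4) in over 90% of replicates.
#'
#' @param seed integer RNG seed.
#' @return a [cohortSpec()].
#' @export
gradeCohortSpec <- function(seed = 1L) {
  cohortSpec(
    groups = list(
      cohortGroup("grade-2", n = 19, mean = c(0.472, 25, 13.5),
                  sd = c(0.065, 10, 2.5), ki67Mean = 8, ki67SD = 5,
                  idhGene = 1, ihcProbs = c(0.1, 0.4, 0.5),
                  gradeCounts = c("2" = 19, "3" = 0, "4" = 0, "NA" = 0)),
      cohortGroup("grade-3", n = 6, mean = c(0.441, 28, 12.5),
                  sd = c(0.065, 10, 2.5), ki67Mean = 15, ki67SD = 8,
                  idhGene = 1, ihcProbs = c(0.2, 0.4, 0.4),
                  gradeCounts = c("2" = 0, "3" = 6, "4" = 0, "NA" = 0)),
      cohortGroup("grade-4", n = 33, mean = c(0.364, 34, 10.5),
                  sd = c(0.050, 12, 2), ki67Mean = 32.5, ki67SD = 15,
                  idhGene = 0, ihcProbs = c(0.85, 0.12, 0.03),
                  gradeCounts = c("2" = 0, "3" = 0, "4" = 33, "NA" = 0))
    ),
    seed = seed
  )
}

#' Simulate a cohort of glioma subject records
#'
#' Deterministic for a fixed `spec$seed`. Returns the canonical cohort
#' table (see [readCohort()] for the column contract).
#'
#' @param spec a [cohortSpec()].
#' @return data.frame, one row per subject.
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  rho <- spec$ki67Cor
  rows <- lapply(spec$groups, function(g) {
    D <- diag(g$sd, 3)
    Sigma <- D %*% spec$metricCor %*% D
    X <- MASS::mvrnorm(g$n, mu = g$mean, Sigma = Sigma)
    X <- matrix(X, ncol = 3)
    X[, 1] <- pmax(X[, 1], 0)          # SDC truncated at 0
    X[, 3] <- pmax(X[, 3], 0)          # ADC truncated at 0
    zsdc <- if (g$sd[1] > 0) (X[, 1] - g$mean[1]) / g$sd[1] else
      rep(0, g$n)
    ki67 <- g$ki67Mean + g$ki67SD *
      (rho * zsdc + sqrt(1 - rho^2) * stats::rnorm(g$n))
    ihc <- sample(c(0, 0.5, 1), g$n, replace = TRUE, prob = g$ihcProbs)
    grade <- rep(c(2, 3, 4, NA), times = g$gradeCounts)
    data.frame(
      subject_id = paste0(gsub("[^A-Za-z0-9]+", "_", g$name), "_",
                          seq_len(g$n)),
      group = g$name,
      sdc_au_per_s = X[, 1],
      ddvd_au_per_pixel = X[, 2],
      adc_e4_mm2_per_s = X[, 3],
      idh_gene = g$idhGene,
      idh_ihc = ihc,
      grade = grade,
      ki67_pct = pmin(pmax(ki67, 0), 100),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
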