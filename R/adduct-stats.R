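## Rank-based (Wilcoxon-scores) robust comparison of lesion burdens between
## genotypes. For the two-group design the R-estimate of the shift that
## minimizes Jaeckel's dispersion with Wilcoxon scores is the Hodges-Lehmann
## estimator: the median of all pairwise differences.

## Window estimator of the Wilcoxon-scores scale parameter
## tau = 1 / (sqrt(12) * int f^2): density of absolute pairwise residual
## differences at zero, with degrees-of-freedom and Huber-type finite-sample
## corrections.
wilcoxonTau <- function(resid, p, delta = if (length(resid) / max(p, 1) > 5)
                          0.8 else 0.95, huberParam = 2) {
  n <- length(resid)
  pairs <- utils::combn(n, 2L)
  d <- sort(abs(resid[pairs[1L, ]] - resid[pairs[2L, ]]))
  d <- d[(p + 1L):length(d)]
  tdelta <- stats::quantile(d, delta, names = FALSE) / sqrt(n)
  w <- sum(d <= tdelta)
  cn <- 2 / (n * (n - 1))
  tau <- sqrt(n / (n - p - 1)) * (2 * tdelta) / (sqrt(12) * w * cn)
  stan <- (resid - stats::median(resid)) /
    max(stats::mad(resid), .Machine$double.eps)
  hub <- max(mean(abs(stan) < huberParam), 1e-6)
  tau * (1 + ((p + 1) / n) * (1 - hub) / hub)
}

## Length-of-CI estimator of tau_S = 1 / (2 f(median)); SE(median) =
## tauStar / sqrt(n).
tauStar <- function(resid, p = 0L, conf = 0.95) {
  n <- length(resid)
  zc <- stats::qnorm((1 + conf) / 2)
  ic1 <- max(floor(n / 2 - sqrt(n) * zc / 2 - 0.5), 0)
  z <- sort(resid)
  sqrt(n / (n - p - 1)) * sqrt(n) * (z[n - ic1] - z[ic1 + 1L]) / (2 * zc)
}

#' Sample median with a rank-based standard error
#'
#' The standard error is `tauStar / sqrt(n)` where `tauStar` estimates
#' `1 / (2 f(median))` from the length of a distribution-free confidence
#' interval for the median, consistent with the rank-based fit of
#' [rankFit()].
#'
#' @param x numeric vector, n >= 3.
#' @return List with `median` and `se`.
#' @examples
#' medianWithSE(c(1, 2, 3))
#' @export
medianWithSE <- function(x) {
  if (length(x) < 3L) stop("need at least 3 observations")
  m <- stats::median(x)
  list(median = m, se = tauStar(x - m) / sqrt(length(x)))
}

#' Rank-based two-group comparison of lesion burdens
#'
#' Estimates the genotype shift in lesion burden by the Hodges-Lehmann
#' estimator (median of all pairwise ko - wt differences; the minimizer of
#' Jaeckel's dispersion with Wilcoxon scores for a two-group design), its
#' standard error from the Wilcoxon-scores scale estimate
#' `tau * sqrt(1/n1 + 1/n2)`, and the Wald-type test statistic
#' `TS = (shift / SE)^2` referred to an F(1, n - 2) distribution.
#' Mid-ranks are used throughout, so ties (e.g. censored values at the MDQ
#' midpoint) are permitted.
#'
#' @param lesions numeric vector of lesion burdens (per 1e8 nucleotides).
#' @param genotype factor/character of the same length with exactly two
#'   levels; the shift is `koLevel` minus the other level.
#' @param koLevel level whose median is compared against the reference
#'   (default `"ko"`).
#' @return List: per-group medians with standard errors ([medianWithSE()]),
#'   `shift`, `se_shift`, `TS`, `df = c(1, n - 2)`, `p_value`, `n`.
#' @examples
#' rankFit(c(1, 2, 3, 11, 12, 13), rep(c("wt", "ko"), each = 3))$shift  # 10
#' @export
rankFit <- function(lesions, genotype, koLevel = "ko") {
  genotype <- as.character(genotype)
  lv <- unique(genotype)
  if (length(lv) != 2L) stop("exactly two genotype levels required")
  if (!koLevel %in% lv) stop("koLevel absent from genotype")
  ref <- setdiff(lv, koLevel)
  yk <- lesions[genotype == koLevel]
  yr <- lesions[genotype == ref]
  if (length(yk) < 3L || length(yr) < 3L)
    stop("need n >= 3 per group")
  shift <- stats::median(outer(yk, yr, "-"))
  n <- length(lesions)
  resid <- lesions - ifelse(genotype == koLevel, shift, 0)
  if (stats::sd(yk) == 0 && stats::sd(yr) == 0) {
    warning("zero variance in both groups; TS = 0 reported")
    ts <- 0
    seShift <- NA_real_
    pval <- 1
  } else {
    tau <- wilcoxonTau(resid, p = 1L)
    seShift <- tau * sqrt(1 / length(yk) + 1 / length(yr))
    ts <- (shift / seShift)^2
    pval <- stats::pf(ts, 1, n - 2, lower.tail = FALSE)
  }
  list(median_ref = medianWithSE(yr), median_ko = medianWithSE(yk),
       ref_level = ref, ko_level = koLevel,
       shift = shift, se_shift = seShift, TS = ts, df = c(1, n - 2),
       p_value = pval, n = n)
}

#' Genotype comparison of adduct burdens per tissue and timepoint
#'
#' Runs [rankFit()] for every tissue x timepoint stratum of a lesion table,
#' comparing the two genotypes among MAM-treated animals.
#'
#' @param lesions lesion table (`animal_id`, `tissue`, `timepoint_h`,
#'   `lesions_per_1e8`, `censored`).
#' @param sheet sample sheet mapping `animal_id` to `genotype` and
#'   `treatment`.
#' @param trtLevel treatment arm analyzed (default `"MAM"`).
#' @param koLevel knockout genotype level (default `"ko"`).
#' @return data.frame, one row per tissue x timepoint: group medians and
#'   standard errors, shift, TS, df2 and p-value. Strata with fewer than 3
#'   animals per group are dropped with a warning.
#' @export
adductStats <- function(lesions, sheet, trtLevel = "MAM", koLevel = "ko") {
  ann <- sheet[match(lesions$animal_id, sheet$animal_id),
               c("genotype", "treatment")]
  les <- cbind(lesions, ann)
  les <- les[les$treatment == trtLevel & !is.na(les$genotype), , drop = FALSE]
  out <- list()
  for (ts in unique(les$tissue)) {
    for (tp in sort(unique(les$timepoint_h))) {
      s <- les[les$tissue == ts & les$timepoint_h == tp, , drop = FALSE]
      if (min(table(s$genotype)) < 3L || length(unique(s$genotype)) != 2L) {
        warning(sprintf("stratum %s / %s h: too few animals; dropped", ts, tp))
        next
      }
      f <- rankFit(s$lesions_per_1e8, s$genotype, koLevel = koLevel)
      out[[length(out) + 1L]] <- data.frame(
        tissue = ts, timepoint_h = tp,
        median_wt = f$median_ref$median, se_wt = f$median_ref$se,
        median_ko = f$median_ko$median, se_ko = f$median_ko$se,
        shift = f$shift, TS = f$TS, df2 = f$df[2], p_value = f$p_value)
    }
  }
  do.call(rbind, out)
}
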