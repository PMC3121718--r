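## Factorial linear modelling per probeset with the two-laboratory
## replication-consistency filter, BH-FDR adjustment, and fold-change-gated
## differential expression calls.

## +1/2, -1/2 coding: main-effect coefficients are then directly the
## (balanced-design) group contrasts and the interaction coefficient is the
## difference of differences.
.halfCode <- function(x, positive) {
  lv <- unique(as.character(x))
  if (!positive %in% lv)
    stop(sprintf("level '%s' absent from the design", positive))
  ifelse(as.character(x) == positive, 0.5, -0.5)
}

.designLevels <- function(sheet, trtLevel, koLevel) {
  list(trt = trtLevel, ko = koLevel,
       siteB = sort(unique(as.character(sheet$site)))[2])
}

.designMatrices <- function(sheet, trtLevel = "MAM", koLevel = "ko") {
  lv <- .designLevels(sheet, trtLevel, koLevel)
  t <- .halfCode(sheet$treatment, lv$trt)
  g <- .halfCode(sheet$genotype, lv$ko)
  l <- .halfCode(sheet$site, lv$siteB)
  full <- cbind(intercept = 1, treatment = t, genotype = g, lab = l,
                `treatment:genotype` = t * g, `lab:treatment` = l * t,
                `lab:genotype` = l * g, `lab:treatment:genotype` = l * t * g)
  reduced <- full[, c("intercept", "treatment", "genotype",
                      "treatment:genotype", "lab"), drop = FALSE]
  list(full = full, reduced = reduced)
}

## OLS for a matrix of responses sharing one design: Y is n x G.
.olsMulti <- function(X, Y) {
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p)
    stop("rank-deficient design (missing cell); probesets are unestimable")
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(XtXinv), sigma2))
  tt <- B / se
  pval <- 2 * stats::pt(-abs(tt), df)
  dimnames(B) <- dimnames(se) <- dimnames(tt) <- dimnames(pval) <-
    list(colnames(X), colnames(Y))
  list(coefficients = B, se = se, t = tt, p = pval, df = df,
       sigma2 = sigma2, XtXinv = XtXinv, rss = sigma2 * df)
}

## estimate/se/p for a linear combination c'beta of a .olsMulti fit
.contrastMulti <- function(fit, cvec) {
  est <- drop(crossprod(cvec, fit$coefficients))
  se <- sqrt(drop(crossprod(cvec, fit$XtXinv %*% cvec)) * fit$sigma2)
  tt <- est / se
  list(estimate = est, se = se,
       p = 2 * stats::pt(-abs(tt), fit$df))
}

#' Fit the full two-laboratory factorial model to one probeset
#'
#' Ordinary least squares fit of
#' `y ~ treatment + genotype + treatment:genotype + lab + lab:treatment +
#' lab:genotype + lab:treatment:genotype` with sum-to-zero (+1/2 / -1/2)
#' factor coding, at a single timepoint. With this coding each main-effect
#' coefficient is the corresponding group contrast (e.g. MAM minus vehicle
#' log2 means averaged over the other factors) and each interaction
#' coefficient is a difference of differences.
#'
#' @param y numeric response (log2 expression) across the arrays in `sheet`.
#' @param sheet data.frame with columns `treatment`, `genotype`, `site` (one
#'   row per array, a single timepoint).
#' @param trtLevel,koLevel factor levels coded +1/2 (active treatment,
#'   knockout genotype).
#' @return Object of class `"factorialFit"`: coefficients, standard errors,
#'   per-term two-sided p-values, residual df, and the inputs (kept so
#'   [consistencyFilter()] can refit the reduced model).
#' @export
fitFullModel <- function(y, sheet, trtLevel = "MAM", koLevel = "ko") {
  stopifnot(length(y) == nrow(sheet))
  dm <- .designMatrices(sheet, trtLevel, koLevel)
  if (nrow(dm$full) <= ncol(dm$full))
    stop("not enough arrays for a positive residual df")
  fit <- .olsMulti(dm$full, cbind(y = y))
  structure(list(coefficients = drop(fit$coefficients),
                 se = drop(fit$se), p = drop(fit$p), df = fit$df,
                 y = y, sheet = sheet, trtLevel = trtLevel,
                 koLevel = koLevel),
            class = "factorialFit")
}

#' Apply the laboratory replication-consistency filter
#'
#' If all three laboratory-interaction terms of the full model
#' (lab:treatment, lab:genotype, lab:treatment:genotype) have p > `alphaLab`,
#' the model is reduced by dropping those interactions (the main laboratory
#' term is retained), refitted, and the effects of interest are taken from the
#' reduced fit (`status = "reduced"`). If any laboratory interaction is
#' significant (p <= `alphaLab`), the effects of interest differ between
#' laboratories and the probeset is excluded (`status = "excluded"`).
#' `labTest = "joint"` replaces the three per-term tests by a single joint
#' F test of the three interaction terms.
#'
#' @param fit a `"factorialFit"` from [fitFullModel()].
#' @param alphaLab significance threshold for the laboratory interactions
#'   (default 0.15).
#' @param labTest `"each"` (default) or `"joint"`.
#' @return List with `status` (`"reduced"` or `"excluded"`), `labP` (the
#'   three interaction p-values), `jointP` (joint F p-value) and, when
#'   reduced, `fit`: coefficients/se/p of the reduced model.
#' @export
consistencyFilter <- function(fit, alphaLab = 0.15,
                              labTest = c("each", "joint")) {
  labTest <- match.arg(labTest)
  stopifnot(inherits(fit, "factorialFit"))
  labTerms <- c("lab:treatment", "lab:genotype", "lab:treatment:genotype")
  labP <- fit$p[labTerms]
  dm <- .designMatrices(fit$sheet, fit$trtLevel, fit$koLevel)
  fullFit <- .olsMulti(dm$full, cbind(y = fit$y))
  redFit <- .olsMulti(dm$reduced, cbind(y = fit$y))
  extraDf <- ncol(dm$full) - ncol(dm$reduced)
  fstat <- ((redFit$rss - fullFit$rss) / extraDf) /
    (fullFit$rss / fullFit$df)
  jointP <- stats::pf(fstat, extraDf, fullFit$df, lower.tail = FALSE)
  pass <- if (labTest == "each") all(labP > alphaLab) else jointP > alphaLab
  if (!pass)
    return(list(status = "excluded", labP = labP, jointP = jointP))
  list(status = "reduced", labP = labP, jointP = jointP,
       fit = list(coefficients = drop(redFit$coefficients),
                  se = drop(redFit$se), p = drop(redFit$p),
                  df = redFit$df))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values: `q_i = min_{j: p_(j) >= p_(i)} m * p_(j) / j`, capped at
#'   1; order-preserving.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.9))
#' @export
benjaminiHochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fit all probesets of a normalized experiment, per timepoint
#'
#' For each timepoint: fits the full two-laboratory factorial model to every
#' probeset, applies the replication-consistency filter (see
#' [consistencyFilter()]), refits the reduced model for the consistent
#' probesets, and adjusts the effect p-values by Benjamini-Hochberg within
#' each (timepoint, effect) family over the non-excluded probesets.
#'
#' Reported effects: `treatment` (MAM - vehicle, averaged over genotypes),
#' `genotype` (ko - wt), `interaction` (difference of the treatment effect
#' between the genotypes), and `treatment_ko` (MAM - vehicle within the
#' knockout, the contrast `treatment + interaction/2`). Fold changes are
#' signed linear-scale versions of the log2 estimates,
#' `sign(est) * 2^|est|`.
#'
#' @param normSE probeset-level log2 [SummarizedExperiment::SummarizedExperiment]
#'   from [rmaNormalize()].
#' @param alphaLab consistency-filter threshold (default 0.15).
#' @param labTest `"each"` or `"joint"`, see [consistencyFilter()].
#' @param trtLevel,koLevel factor levels coded +1/2.
#' @return A [S4Vectors::DataFrame] with one row per probeset x timepoint x
#'   effect: `probeset_id`, `gene_id`, `timepoint_h`, `status`, `effect`,
#'   `estimate`, `se`, `p_value`, `q_value`, `fold_change`, and the three
#'   laboratory-interaction p-values. Excluded probesets carry `NA`
#'   q-values and propagate no effect estimates.
#' @export
runDiffExpr <- function(normSE, alphaLab = 0.15,
                        labTest = c("each", "joint"),
                        trtLevel = "MAM", koLevel = "ko") {
  labTest <- match.arg(labTest)
  Y <- assay(normSE, "exprs")
  sheet <- as.data.frame(colData(normSE))
  gene <- as.character(rowData(normSE)$gene_id)
  names(gene) <- rownames(Y)
  out <- list()
  for (tp in sort(unique(sheet$timepoint_h))) {
    cols <- which(sheet$timepoint_h == tp)
    sh <- sheet[cols, , drop = FALSE]
    dm <- .designMatrices(sh, trtLevel, koLevel)
    Ytp <- t(Y[, cols, drop = FALSE])
    fullFit <- .olsMulti(dm$full, Ytp)
    redFit <- .olsMulti(dm$reduced, Ytp)
    labP <- t(fullFit$p[c("lab:treatment", "lab:genotype",
                          "lab:treatment:genotype"), , drop = FALSE])
    if (labTest == "each") {
      pass <- rowSums(labP > alphaLab) == 3L
    } else {
      extraDf <- ncol(dm$full) - ncol(dm$reduced)
      fstat <- ((redFit$rss - fullFit$rss) / extraDf) /
        (fullFit$rss / fullFit$df)
      pass <- stats::pf(fstat, extraDf, fullFit$df, lower.tail = FALSE) >
        alphaLab
    }
    status <- ifelse(pass, "reduced", "excluded")
    trtKo <- .contrastMulti(redFit, c(intercept = 0, treatment = 1,
                                      genotype = 0,
                                      `treatment:genotype` = 0.5, lab = 0))
    effTab <- list(
      treatment = list(est = redFit$coefficients["treatment", ],
                       se = redFit$se["treatment", ],
                       p = redFit$p["treatment", ]),
      genotype = list(est = redFit$coefficients["genotype", ],
                      se = redFit$se["genotype", ],
                      p = redFit$p["genotype", ]),
      interaction = list(est = redFit$coefficients["treatment:genotype", ],
                         se = redFit$se["treatment:genotype", ],
                         p = redFit$p["treatment:genotype", ]),
      treatment_ko = list(est = trtKo$estimate, se = trtKo$se, p = trtKo$p)
    )
    for (eff in names(effTab)) {
      e <- effTab[[eff]]
      est <- ifelse(pass, e$est, NA_real_)
      pv <- ifelse(pass, e$p, NA_real_)
      qv <- rep(NA_real_, length(pv))
      if (any(pass)) qv[pass] <- benjaminiHochberg(pv[pass])
      out[[length(out) + 1L]] <- DataFrame(
        probeset_id = rownames(Y), gene_id = gene[rownames(Y)],
        timepoint_h = tp, status = status, effect = eff,
        estimate = est, se = ifelse(pass, e$se, NA_real_), p_value = pv,
        q_value = qv,
        fold_change = sign(est) * 2^abs(est),
        p_lab_treatment = labP[, "lab:treatment"],
        p_lab_genotype = labP[, "lab:genotype"],
        p_lab_3way = labP[, "lab:treatment:genotype"]
      )
    }
  }
  res <- do.call(rbind, out)
  metadata(res) <- list(alphaLab = alphaLab, labTest = labTest)
  res
}

#' Call differential expression with the FDR and fold-change gates
#'
#' A probeset is significant for an effect at a timepoint iff its BH q-value
#' is below `fdr` and its absolute linear fold change exceeds `minFc`; both
#' gates are required and excluded probesets are never significant. Probesets
#' are mapped to genes keeping, per gene, the probeset with the smallest
#' q-value anywhere.
#'
#' @param results the [S4Vectors::DataFrame] from [runDiffExpr()].
#' @param effect one of `"treatment"`, `"genotype"`, `"interaction"`,
#'   `"treatment_ko"`.
#' @param fdr FDR threshold (default 0.05).
#' @param minFc absolute fold-change threshold, linear scale (default 1.3).
#' @param label analysis label stored in the result.
#' @return A [DEGeneSet-class]: per-timepoint significant probesets, their
#'   union, and the de-duplicated gene list.
#' @export
callDE <- function(results, effect = c("treatment", "genotype",
                                       "interaction", "treatment_ko"),
                   fdr = 0.05, minFc = 1.3, label = effect) {
  effect <- match.arg(effect)
  label <- label[1L]
  r <- results[results$effect == effect, , drop = FALSE]
  keep <- r$status == "reduced"
  if (!any(keep))
    warning("no non-excluded probesets; returning an empty DEGeneSet")
  sig <- keep & !is.na(r$q_value) & r$q_value < fdr &
    abs(r$fold_change) > minFc
  tps <- sort(unique(r$timepoint_h))
  perTp <- lapply(tps, function(tp)
    sort(unique(r$probeset_id[sig & r$timepoint_h == tp])))
  names(perTp) <- as.character(tps)
  unionPs <- sort(unique(unlist(perTp, use.names = FALSE)))
  sigRows <- as.data.frame(r[sig, c("probeset_id", "gene_id", "q_value")])
  geneMap <- sigRows[order(sigRows$q_value), , drop = FALSE]
  geneMap <- geneMap[!duplicated(geneMap$gene_id), , drop = FALSE]
  names(geneMap) <- c("probeset_id", "gene_id", "q_value")
  rownames(geneMap) <- NULL
  new("DEGeneSet", label = label, perTimepoint = perTp,
      unionProbesets = unionPs, genes = sort(unique(geneMap$gene_id)),
      geneMap = geneMap)
}

#' Combine two analyses into one de-duplicated gene list
#'
#' Set union at the gene level, e.g. merging the knockout MAM response with
#' the genotype-difference analysis into a single non-duplicated list.
#'
#' @param setA,setB [DEGeneSet-class] objects or character gene vectors.
#' @return Sorted character vector of unique genes; its length is at most
#'   `|A| + |B|`.
#' @examples
#' combineAnalyses(c("g1", "g2"), c("g2", "g3"))
#' @export
combineAnalyses <- function(setA, setB) {
  ga <- if (is(setA, "DEGeneSet")) setA@genes else as.character(setA)
  gb <- if (is(setB, "DEGeneSet")) setB@genes else as.character(setB)
  sort(unique(c(ga, gb)))
}
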