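## Anchoring expression to DNA lesion burden: Spearman correlation between
## normalized probeset intensity and O6-mG lesions among MAM-treated animals,
## per timepoint, thresholded at 0.70.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; ties receive average ranks. A constant
#' vector has no defined rank correlation and yields `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\], or `NA`.
#' @examples
#' spearmanRho(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Anchor candidate probesets to lesion burden
#'
#' For every candidate probeset and timepoint, computes the Spearman rank
#' correlation between its normalized log2 intensity and the brain
#' O6-mG lesion burden across the MAM-treated animals of that timepoint
#' (both genotypes pooled). A probeset is "anchored" when its correlation
#' exceeds `threshold` at one or more timepoints. Censored lesion values enter
#' at the MDQ midpoint, which is rank-safe because all censored values tie.
#' Timepoints with fewer than 3 matched animals are skipped with a warning.
#'
#' @param normSE probeset-level log2 experiment from [rmaNormalize()]; its
#'   `colData` must carry `treatment`, `timepoint_h` and `animal_id`.
#' @param lesions lesion table (data.frame: `animal_id`, `tissue`,
#'   `timepoint_h`, `lesions_per_1e8`, `censored`).
#' @param candidates character vector of candidate probeset ids, or a
#'   [DEGeneSet-class] (its union set is used). Anchoring is assessed within
#'   this candidate set only, so the anchored set is always a subset of it.
#' @param threshold correlation threshold (default 0.70).
#' @param absolute apply the threshold to `|rho|` instead of signed rho
#'   (default `FALSE`: anchoring means rho > threshold).
#' @param tissue lesion tissue paired with the expression data (default
#'   `"brain"`).
#' @param trtLevel treatment level defining the MAM arm.
#' @return A [S4Vectors::DataFrame], one row per candidate: per-timepoint
#'   `rho_<t>` columns, `max_rho`, `anchored`, `n_animals` (minimum used),
#'   plus the anchored ids in `metadata(.)$anchoredProbesets`.
#' @export
anchorGenes <- function(normSE, lesions, candidates, threshold = 0.70,
                        absolute = FALSE, tissue = "brain",
                        trtLevel = "MAM") {
  if (is(candidates, "DEGeneSet")) candidates <- candidates@unionProbesets
  candidates <- as.character(candidates)
  if (!length(candidates)) {
    res <- DataFrame(probeset_id = character(), max_rho = numeric(),
                     anchored = logical(), n_animals = integer())
    metadata(res)$anchoredProbesets <- character()
    return(res)
  }
  missingPs <- setdiff(candidates, rownames(normSE))
  if (length(missingPs))
    stop("candidates absent from the expression matrix: ",
         paste(utils::head(missingPs, 3), collapse = ", "))
  Y <- assay(normSE, "exprs")[candidates, , drop = FALSE]
  sheet <- as.data.frame(colData(normSE))
  les <- lesions[lesions$tissue == tissue, , drop = FALSE]
  lesByAnimal <- stats::setNames(les$lesions_per_1e8, les$animal_id)
  tps <- sort(unique(sheet$timepoint_h))
  rhoMat <- matrix(NA_real_, nrow = length(candidates), ncol = length(tps),
                   dimnames = list(candidates, paste0("rho_", tps)))
  nUsed <- integer(length(tps))
  for (i in seq_along(tps)) {
    cols <- which(sheet$timepoint_h == tps[i] & sheet$treatment == trtLevel &
                    sheet$animal_id %in% names(lesByAnimal))
    nUsed[i] <- length(cols)
    if (length(cols) < 3L) {
      warning(sprintf("timepoint %s h: only %d matched MAM animals; skipped",
                      tps[i], length(cols)))
      next
    }
    lv <- lesByAnimal[sheet$animal_id[cols]]
    if (stats::sd(lv) == 0) {
      warning(sprintf(
        "timepoint %s h: constant lesion values; correlations undefined",
        tps[i]))
      next
    }
    lr <- rank(lv, ties.method = "average")
    for (j in seq_along(candidates)) {
      yv <- Y[j, cols]
      if (stats::sd(yv) == 0) next  # constant expression: undefined, not anchored
      rhoMat[j, i] <- stats::cor(rank(yv, ties.method = "average"), lr)
    }
  }
  score <- if (absolute) abs(rhoMat) else rhoMat
  maxRho <- apply(score, 1L, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  anchored <- !is.na(maxRho) & maxRho > threshold
  res <- DataFrame(probeset_id = candidates, rhoMat, max_rho = maxRho,
                   anchored = anchored,
                   n_animals = if (any(nUsed > 0)) min(nUsed[nUsed > 0])
                               else 0L)
  metadata(res)$anchoredProbesets <- candidates[anchored]
  metadata(res)$threshold <- threshold
  metadata(res)$absolute <- absolute
  res
}
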