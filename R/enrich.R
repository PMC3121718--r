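## Gene-set overrepresentation for DE and anchored gene lists: hypergeometric
## (Fisher one-sided) and EASE (jackknifed Fisher) tails with BH adjustment.

#' Read a GMT gene-set collection
#'
#' Standard GMT layout: term, description, then tab-separated gene ids.
#'
#' @param path GMT file.
#' @return Named list of character gene vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

#' Write a named list of gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @export
writeGMT <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
}

#' Hypergeometric and EASE overrepresentation of a gene list
#'
#' For each term set (intersected with the universe): with `N` universe
#' genes, `K` term genes, `n` list genes, and `k` overlapping genes, the
#' Fisher p-value is the upper hypergeometric tail `P(X >= k)` and the EASE
#' p-value is the same tail with the overlap jackknifed to `k - 1` (floored
#' at 0), the conservative variant popularized by DAVID. Both are reported,
#' with BH adjustment of the EASE p-values across terms.
#'
#' @param geneList character vector, must be a subset of `universe`.
#' @param termSets named list of character vectors (e.g. from [readGMT()]).
#' @param universe character vector of all eligible genes (typically every
#'   gene represented on the array after filtering).
#' @return data.frame: `term_id`, `N`, `K`, `n`, `k`, `fisher_p`, `ease_p`,
#'   `bh_q`, `genes` (comma-separated overlap).
#' @examples
#' hypergeomEnrich(c("a", "b"), list(T1 = c("a", "b", "c")), letters[1:10])
#' @export
hypergeomEnrich <- function(geneList, termSets, universe) {
  universe <- unique(as.character(universe))
  geneList <- unique(as.character(geneList))
  if (!length(universe)) stop("empty universe")
  if (!length(geneList)) stop("empty gene list")
  if (!all(geneList %in% universe))
    stop("gene list must be a subset of the universe")
  n <- length(geneList)
  N <- length(universe)
  rows <- lapply(names(termSets), function(tid) {
    term <- intersect(unique(termSets[[tid]]), universe)
    K <- length(term)
    hit <- intersect(geneList, term)
    k <- length(hit)
    fisherP <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    easeP <- stats::phyper(max(k - 1, 0) - 1, K, N - K, n,
                           lower.tail = FALSE)
    data.frame(term_id = tid, N = N, K = K, n = n, k = k,
               fisher_p = fisherP, ease_p = easeP,
               genes = paste(sort(hit), collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$bh_q <- benjaminiHochberg(out$ease_p)
  out[, c("term_id", "N", "K", "n", "k", "fisher_p", "ease_p", "bh_q",
          "genes")]
}

#' Rank enrichment results
#'
#' Orders terms by ascending EASE p-value, breaking ties by larger overlap
#' and then term id, and returns the top `topM`.
#'
#' @param results data.frame from [hypergeomEnrich()].
#' @param topM number of terms to return (all if larger than the result).
#' @return Reordered data.frame of at most `topM` rows.
#' @export
rankTerms <- function(results, topM = 4L) {
  if (!nrow(results)) stop("empty enrichment results")
  o <- order(results$ease_p, -results$k, results$term_id)
  utils::head(results[o, , drop = FALSE], topM)
}
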