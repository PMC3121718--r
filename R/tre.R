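## Promoter transcriptional-regulatory-element (TRE) analysis: degenerate
## IUPAC / PWM motif scanning, the binary gene x motif interaction matrix
## with the >5% prevalence filter, and per-motif enrichment of a candidate
## list against a reference set.

.checkDNA <- function(s) {
  ltr <- strsplit(toupper(s), "")[[1]]
  bad <- setdiff(unique(ltr), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("non-DNA characters in sequence: ", paste(bad, collapse = ", "))
  ltr
}

.revcompChars <- function(ltr) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[ltr]))
}

## exact degenerate scan of a character vector; an N in the sequence never
## matches a non-N consensus position
.scanConsensus <- function(ltr, consensus) {
  m <- nchar(consensus)
  L <- length(ltr)
  if (L < m) return(integer(0))
  mot <- strsplit(consensus, "")[[1]]
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) {
    allowed <- IUPAC_MAP[[mot[j]]]
    if (mot[j] == "N") allowed <- c(allowed, "N")
    ok <- ok & ltr[j:(L - m + j)] %in% allowed
  }
  which(ok) - 1L  # 0-based
}

.scanPWM <- function(ltr, pwm, threshold, background = rep(0.25, 4)) {
  m <- ncol(pwm)
  L <- length(ltr)
  if (L < m) return(integer(0))
  lo <- log2(pmax(pwm, 1e-12) / background)
  rownames(lo) <- rownames(pwm)
  score <- rep(0, L - m + 1L)
  valid <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) {
    win <- ltr[j:(L - m + j)]
    isN <- win == "N"
    valid <- valid & !isN
    sc <- lo[cbind(match(win, rownames(lo)), j)]
    sc[isN] <- -Inf
    score <- score + sc
  }
  which(valid & score >= threshold) - 1L
}

#' Scan a promoter sequence for a motif
#'
#' Consensus mode counts exact degenerate matches of the IUPAC consensus
#' (case-insensitive; e.g. the lowercase `a` in the HNF-4 site
#' `AGGTCAaAGGTCA` is an A). PWM mode reports windows whose log-odds score
#' against a uniform base background reaches the motif's threshold. With
#' `strand = "both"` the reverse complement is scanned too and all positions
#' are reported in forward-strand coordinates (0-based, half-open windows).
#' An `N` in the sequence never matches a non-N motif position. Overlapping
#' matches are all counted.
#'
#' @param seq DNA string over A, C, G, T, N (character or
#'   [Biostrings::DNAString]).
#' @param motif a [Motif-class].
#' @param strand override of the motif's strand policy.
#' @return List with `count` and 0-based forward-strand start `positions`.
#' @examples
#' hnf4 <- consensusMotif("HNF-4", "AGGTCAaAGGTCA")
#' scanPromoter("AGGTCAAAGGTCA", hnf4, strand = "forward")
#' @export
scanPromoter <- function(seq, motif, strand = motif@strand) {
  stopifnot(is(motif, "Motif"))
  validObject(motif)
  strand <- match.arg(strand, c("both", "forward"))
  ltr <- .checkDNA(as.character(seq))
  scan1 <- function(chars) {
    if (motif@kind == "consensus") .scanConsensus(chars, motif@consensus)
    else .scanPWM(chars, motif@pwm, motif@threshold)
  }
  pos <- scan1(ltr)
  if (strand == "both" && length(ltr)) {
    m <- if (motif@kind == "consensus") nchar(motif@consensus)
         else ncol(motif@pwm)
    rcPos <- scan1(.revcompChars(ltr))
    pos <- sort(unique(c(pos, length(ltr) - rcPos - m)))
  }
  list(count = length(pos), positions = as.integer(pos))
}

#' Build the binary gene x motif promoter interaction matrix
#'
#' An entry is 1 iff the gene's promoter has at least one match of the motif.
#' Motifs present in no more than `prevalenceMin` of all promoters are
#' dropped (and recorded); genes without a promoter sequence are skipped with
#' a warning.
#'
#' @param promoters named [Biostrings::DNAStringSet] (or named character
#'   vector), keyed by gene.
#' @param motifs list of [Motif-class] objects.
#' @param genes genes to include (default: all promoters).
#' @param prevalenceMin drop motifs with prevalence <= this fraction of all
#'   scanned promoters (default 0.05).
#' @return A [TREInteractionMatrix-class].
#' @export
buildInteractionMatrix <- function(promoters, motifs,
                                   genes = names(promoters),
                                   prevalenceMin = 0.05) {
  if (is.null(names(promoters))) stop("promoters must be named by gene")
  seqs <- as.character(promoters)
  missing <- setdiff(genes, names(seqs))
  if (length(missing))
    warning("no promoter sequence for: ", paste(missing, collapse = ", "),
            "; skipped")
  genes <- intersect(genes, names(seqs))
  motNames <- vapply(motifs, function(m) m@name, character(1))
  hits <- matrix(0L, nrow = length(genes), ncol = length(motifs),
                 dimnames = list(genes, motNames))
  for (j in seq_along(motifs)) {
    for (i in seq_along(genes)) {
      if (scanPromoter(seqs[[genes[i]]], motifs[[j]])$count > 0)
        hits[i, j] <- 1L
    }
  }
  prevalence <- colMeans(hits)
  dropped <- motNames[prevalence <= prevalenceMin]
  if (length(dropped))
    message("dropped below prevalence threshold: ",
            paste(dropped, collapse = ", "))
  widths <- unique(nchar(seqs[genes]))
  new("TREInteractionMatrix",
      hits = hits[, setdiff(motNames, dropped), drop = FALSE],
      prevalence = prevalence, dropped = dropped,
      promoterLength = if (length(widths) == 1L) as.integer(widths)
                       else NA_integer_,
      skipped = missing)
}

#' Test motifs for enrichment in a candidate gene list
#'
#' For every retained motif, compares its promoter hit frequency in the
#' candidate list against a reference set by a one-sided Fisher
#' (hypergeometric) test: with the candidates drawn from the reference
#' universe, the p-value is `P(X >= k)` for `k` candidate hits given the
#' reference hit total. Motifs with `p < alpha` are called significantly
#' enriched and the table is ordered by ascending p.
#'
#' @param tre a [TREInteractionMatrix-class] covering candidates and
#'   reference genes.
#' @param candidates character vector of candidate genes.
#' @param reference character vector of reference genes; with
#'   `mode = "subset"` (default) the candidates must be contained in it,
#'   with `mode = "disjoint"` the two sets are pooled into the universe.
#' @param alpha significance threshold (default 0.05).
#' @param mode `"subset"` or `"disjoint"`.
#' @return data.frame per motif: hit counts and frequencies in both sets,
#'   `p_value`, `significant`; ordered by ascending p-value. A motif absent
#'   from both sets has p = 1.
#' @export
treEnrichment <- function(tre, candidates, reference, alpha = 0.05,
                          mode = c("subset", "disjoint")) {
  mode <- match.arg(mode)
  stopifnot(is(tre, "TREInteractionMatrix"))
  hits <- tre@hits
  candidates <- intersect(candidates, rownames(hits))
  reference <- intersect(reference, rownames(hits))
  if (mode == "subset") {
    if (!all(candidates %in% reference))
      stop("candidates must be a subset of the reference in 'subset' mode")
    universe <- reference
  } else {
    if (length(intersect(candidates, reference)))
      stop("candidates and reference must be disjoint in 'disjoint' mode")
    universe <- union(candidates, reference)
  }
  N <- length(universe)
  n <- length(candidates)
  rows <- lapply(colnames(hits), function(mn) {
    K <- sum(hits[universe, mn])
    k <- sum(hits[candidates, mn])
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(motif = mn, n_candidates = n, k_candidates = k,
               freq_candidates = k / n, N_universe = N, K_universe = K,
               freq_universe = K / N, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out[order(out$p_value, out$motif), , drop = FALSE]
}

#' Read a simple motif table
#'
#' Tab-separated file with columns `name` and `consensus` (IUPAC), and an
#' optional `strand` column (`both`/`forward`).
#'
#' @param path TSV file.
#' @return List of [Motif-class] objects.
#' @export
readMotifs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "consensus") %in% names(tab)))
    stop("motif file needs 'name' and 'consensus' columns")
  lapply(seq_len(nrow(tab)), function(i)
    consensusMotif(tab$name[i], tab$consensus[i],
                   strand = if ("strand" %in% names(tab)) tab$strand[i]
                            else "both"))
}
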