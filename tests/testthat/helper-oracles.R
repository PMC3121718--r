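## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths (and, where the implementation wraps a
## base routine, avoid that routine too).

## mid-ranks by counting, not via rank()
refRanks <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

## Spearman rho as Pearson correlation of mid-ranks, from sum formulas
refSpearman <- function(x, y) {
  rx <- refRanks(x); ry <- refRanks(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

## BH step-up from the definition: q_i = min_{j: p_(j) >= p_(i)} m p_(j) / j
refBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

## upper hypergeometric tail P(X >= k) by direct summation of choose() terms
refHyperTail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## all permutations of 1..n (n small), one per row
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

## probeset-level experiment built directly (bypasses probe simulation)
makeProbesetSE <- function(values, sheet) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    rowData = S4Vectors::DataFrame(
      probeset_id = rownames(values),
      gene_id = sub("_at$", "", rownames(values)),
      row.names = rownames(values)),
    colData = S4Vectors::DataFrame(sheet, row.names = sheet$sample_id))
  S4Vectors::metadata(se)$scale <- "log2"
  se
}

## balanced one-timepoint sample sheet: 2 sites x 2 genotypes x 2 treatments
oneTimepointSheet <- function(arraysPerCell = 3L, timepoint = 6) {
  sheet <- expand.grid(rep = seq_len(arraysPerCell),
                       site = c("siteA", "siteB"),
                       genotype = c("wt", "ko"),
                       treatment = c("vehicle", "MAM"),
                       stringsAsFactors = FALSE)
  sheet$rep <- NULL
  sheet$timepoint_h <- timepoint
  sheet$tissue <- "brain"
  sheet$animal_id <- sprintf("animal%03d", seq_len(nrow(sheet)))
  sheet$sample_id <- sprintf("S%03d", seq_len(nrow(sheet)))
  sheet
}
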