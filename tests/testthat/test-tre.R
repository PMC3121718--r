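hnf4 <- consensusMotif("HNF-4", "AGGTCAaAGGTCA")

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

test_that("IUPAC scanning finds degenerate matches on both strands", {
  ## the HNF-4 consensus matches itself once, at position 0
  hit <- scanPromoter("AGGTCAAAGGTCA", hnf4, strand = "forward")
  expect_equal(hit$count, 1)
  expect_equal(hit$positions, 0L)
  ## lower case input is accepted
  expect_equal(scanPromoter("aggtcaaaggtca", hnf4, strand = "forward")$count,
               1)
  ## empty sequence: no hits
  expect_equal(scanPromoter("", hnf4)$count, 0)
  ## reverse-complemented instance: found in both-strand mode only
  rc <- revcomp("AGGTCAAAGGTCA")
  expect_equal(scanPromoter(rc, hnf4, strand = "forward")$count, 0)
  both <- scanPromoter(rc, hnf4, strand = "both")
  expect_equal(both$count, 1)
  expect_equal(both$positions, 0L)  # forward coordinates
  ## embedded instance keeps forward coordinates from both strands
  seqf <- paste0("TT", "AGGTCAAAGGTCA", "CCC")
  expect_equal(scanPromoter(seqf, hnf4)$positions, 2L)
  expect_equal(scanPromoter(revcomp(seqf), hnf4)$positions, 3L)
  ## degenerate positions: R matches A and G
  mR <- consensusMotif("m", "ARG", strand = "forward")
  expect_equal(scanPromoter("AAGCAGG", mR)$positions, c(0L, 4L))
  ## N in the sequence never matches a non-N motif position
  expect_equal(scanPromoter("ANGTCAAAGGTCA", hnf4, "forward")$count, 0)
  mN <- consensusMotif("n", "ANA", strand = "forward")
  expect_equal(scanPromoter("ACA", mN)$count, 1)
  expect_equal(scanPromoter("ANA", mN)$count, 1)  # motif N matches N
  expect_error(scanPromoter("ACGU", hnf4), "non-DNA")
})

test_that("both-strand scans are invariant to reverse complementation", {
  set.seed(71)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    m <- consensusMotif("m", "RGGNCA")
    expect_equal(scanPromoter(s, m)$count,
                 scanPromoter(revcomp(s), m)$count)
  }
})

test_that("PWM scanning thresholds the log-odds score", {
  pwm <- matrix(0.01 / 3, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["A", 1] <- pwm["C", 2] <- pwm["G", 3] <- pwm["T", 4] <- 0.99
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  perfect <- sum(log2(0.99 / 0.25))
  m <- pwmMotif("pwm1", pwm, threshold = perfect - 1e-6, strand = "forward")
  expect_equal(scanPromoter("TTACGTTT", m)$positions, 2L)
  ## one mismatch drops the score far below the threshold
  expect_equal(scanPromoter("TTACGATT", m)$count, 0)
  ## looser threshold admits it again
  m2 <- pwmMotif("pwm1", pwm, threshold = perfect - 10, strand = "forward")
  expect_equal(scanPromoter("TTACGATT", m2)$count, 1)
  ## invalid PWMs are rejected
  bad <- pwm; bad[1, 1] <- 0.5
  expect_error(pwmMotif("bad", bad, 1), "sum to 1")
})

test_that("interaction matrix applies the >5% prevalence filter", {
  set.seed(72)
  genes <- sprintf("G%03d", 1:100)
  prom <- simulatePromoters(genes, width = 300, seed = 72)
  ## plant a rare motif in exactly one promoter and a common one in all
  rare <- "TTTTACGTACGTAAAA"
  common <- consensusMotif("common", "N")  # matches everywhere
  s <- as.character(prom)
  substr(s[5], 10, 9 + nchar(rare)) <- rare
  prom <- Biostrings::DNAStringSet(s); names(prom) <- genes
  motifs <- list(consensusMotif("rare", rare, strand = "forward"), common)
  expect_message(
    im <- buildInteractionMatrix(prom, motifs, prevalenceMin = 0.05),
    "rare")
  expect_equal(im@dropped, "rare")
  expect_equal(colnames(interactionMatrix(im)), "common")
  expect_equal(unname(im@prevalence["common"]), 1.0)
  expect_equal(im@promoterLength, 300L)
  ## binary entries only
  expect_true(all(interactionMatrix(im) %in% 0:1))
  ## genes without a promoter are skipped with a warning
  expect_warning(
    im2 <- buildInteractionMatrix(prom, motifs,
                                  genes = c(genes[1:10], "missing")),
    "missing")
  expect_equal(im2@skipped, "missing")
})

test_that("a motif planted in 60% of candidates shows ~0.6 prevalence", {
  genes <- sprintf("A%03d", 1:60)
  prom <- simulatePromoters(genes, width = 2000, motif = hnf4,
                            plantFrac = 0.6, seed = 73)
  im <- suppressMessages(
    buildInteractionMatrix(prom, list(hnf4), prevalenceMin = 0.05))
  prev <- mean(interactionMatrix(im)[, "HNF-4"])
  ## planted 0.6 plus rare chance hits
  expect_gt(prev, 0.55)
  expect_lt(prev, 0.75)
})

test_that("candidate-vs-reference enrichment matches the exact Fisher tail", {
  ## 12 candidates with 9 hits inside a 200-gene reference with 50 hits
  genes <- sprintf("G%03d", 1:200)
  hits <- matrix(0L, 200, 1, dimnames = list(genes, "m1"))
  hits[1:9, 1] <- 1L       # candidate hits
  hits[13:53, 1] <- 1L     # remaining reference hits (total K = 50)
  im <- new("TREInteractionMatrix", hits = hits,
            prevalence = c(m1 = mean(hits)), dropped = character(),
            promoterLength = 2000L, skipped = character())
  out <- treEnrichment(im, candidates = genes[1:12], reference = genes)
  expect_equal(out$p_value, refHyperTail(200, 50, 12, 9))
  expect_equal(out$k_candidates, 9)
  expect_equal(out$K_universe, 50)

  ## equal frequencies: not significant
  hits2 <- hits
  hits2[, 1] <- rep(c(1L, 0L), 100)
  im2 <- new("TREInteractionMatrix", hits = hits2,
             prevalence = c(m1 = 0.5), dropped = character(),
             promoterLength = 2000L, skipped = character())
  out2 <- treEnrichment(im2, genes[1:40], genes)
  expect_gt(out2$p_value, 0.2)
  expect_false(out2$significant)

  ## motif absent from both sets: p = 1
  hits3 <- hits; hits3[, 1] <- 0L
  im3 <- new("TREInteractionMatrix", hits = hits3,
             prevalence = c(m1 = 0), dropped = character(),
             promoterLength = 2000L, skipped = character())
  expect_equal(treEnrichment(im3, genes[1:12], genes)$p_value, 1)
})

test_that("planted 0.6 vs 0.1 enrichment is detected across seeds", {
  hit <- vapply(1:20, function(s) {
    set.seed(700 + s)
    cand <- rbinom(60, 1, 0.6)
    ref <- rbinom(940, 1, 0.1)
    genes <- sprintf("G%04d", 1:1000)
    hits <- matrix(c(cand, ref), ncol = 1,
                   dimnames = list(genes, "m1"))
    im <- new("TREInteractionMatrix", hits = hits,
              prevalence = c(m1 = mean(hits)), dropped = character(),
              promoterLength = 2000L, skipped = character())
    treEnrichment(im, genes[1:60], genes)$significant
  }, logical(1))
  expect_true(all(hit))
})

test_that("null candidate labels give calibrated enrichment p-values", {
  set.seed(74)
  genes <- sprintf("G%04d", 1:300)
  hits <- matrix(rbinom(300, 1, 0.3), ncol = 1,
                 dimnames = list(genes, "m1"))
  im <- new("TREInteractionMatrix", hits = hits,
            prevalence = c(m1 = mean(hits)), dropped = character(),
            promoterLength = 2000L, skipped = character())
  pv <- replicate(400,
    treEnrichment(im, sample(genes, 30), genes)$p_value)
  for (alpha in c(0.05, 0.1, 0.25)) {
    slack <- 3 * sqrt(alpha * (1 - alpha) / 400)
    expect_lte(mean(pv <= alpha), alpha + slack)
  }
})

test_that("motif tables round-trip through the simple TSV format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tconsensus\tstrand",
               "HNF-4\tAGGTCAaAGGTCA\tboth",
               "GATA\tWGATAR\tforward"), path)
  motifs <- readMotifs(path)
  expect_length(motifs, 2)
  expect_equal(motifs[[1]]@consensus, "AGGTCAAAGGTCA")
  expect_equal(motifs[[2]]@strand, "forward")
  expect_error(consensusMotif("bad", "AXGT"), "non-IUPAC")
})
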