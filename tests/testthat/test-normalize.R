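test_that("background correction is positive, monotone and accurate", {
  set.seed(11)
  o <- rexp(5000, 1 / 1000) + rnorm(5000, 100, 20)
  corrected <- backgroundCorrect(o)
  expect_true(all(corrected > 0))
  expect_identical(order(corrected), order(o))
  ## recovered signal mean within 10% of the true exponential mean
  expect_lt(abs(mean(corrected) - 1000) / 1000, 0.1)

  ## closed form agrees with a quadrature oracle of the posterior mean at the
  ## same estimated parameters
  probe <- c(150, 400, 1200, 3000)
  fresh <- c(o, probe)  # probe points appended so they share the estimates
  p <- txanchor:::estimateBgParameters(fresh)
  postMeanQuad <- function(obs) {
    ## integrand is a normal kernel of width sigma around obs - mu; keep the
    ## quadrature on its support
    lo <- max(0, obs - p$mu - 15 * p$sigma)
    hi <- obs - p$mu + 15 * p$sigma
    num <- integrate(function(s) s * p$alpha * exp(-p$alpha * s) *
                       dnorm(obs - s, p$mu, p$sigma), lo, hi,
                     rel.tol = 1e-10)$value
    den <- integrate(function(s) p$alpha * exp(-p$alpha * s) *
                       dnorm(obs - s, p$mu, p$sigma), lo, hi,
                     rel.tol = 1e-10)$value
    num / den
  }
  closedForm <- backgroundCorrect(fresh)[length(o) + seq_along(probe)]
  expect_equal(closedForm, vapply(probe, postMeanQuad, numeric(1)),
               tolerance = 1e-6)

  ## degenerate constant column passes through unchanged
  expect_equal(backgroundCorrect(rep(5, 10)), rep(5, 10))
  expect_error(backgroundCorrect(c(1, -2, 3)), "positive")
})

test_that("quantile normalization maps columns onto the mean distribution", {
  x <- cbind(a = c(2, 4, 6), b = c(1, 3, 5))
  qn <- quantileNormalize(x)
  expect_equal(unname(qn[, "a"]), c(1.5, 3.5, 5.5))
  expect_equal(unname(qn[, "b"]), c(1.5, 3.5, 5.5))

  ## identical columns unchanged
  y <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(quantileNormalize(y), y)

  ## definitional invariant: one common multiset of values per column
  set.seed(2)
  z <- matrix(rnorm(60), ncol = 4)
  qz <- quantileNormalize(z)
  ref <- sort(qz[, 1])
  for (j in 2:4) expect_equal(sort(qz[, j]), ref)

  ## idempotence
  expect_equal(quantileNormalize(qz), qz)

  ## ties: tied values get the mean of the tied reference ranks
  w <- cbind(c(1, 1, 5), c(2, 4, 6))
  qw <- quantileNormalize(w)
  expect_equal(qw[1, 1], qw[2, 1])
  ## reference = rowMeans(sorted cols) = (1.5, 2.5, 5.5); tied ranks 1 and 2
  expect_equal(unname(qw[1:2, 1]), c(2, 2))

  expect_warning(qn1 <- quantileNormalize(matrix(1:3)), "2 columns")
  expect_equal(qn1, matrix(1:3))
})

test_that("quantile normalization matches an established implementation", {
  skip_if_not_installed("limma")
  set.seed(3)
  z <- matrix(rexp(200), ncol = 5)
  expect_equal(unname(quantileNormalize(z)),
               unname(limma::normalizeQuantiles(z, ties = TRUE)),
               tolerance = 1e-12)
})

test_that("median polish summarization behaves like Tukey's decomposition", {
  expect_equal(unname(medianPolishSummarize(rbind(c(1, 2), c(3, 4)))),
               c(2, 3))
  ## single probe: identity
  expect_equal(unname(medianPolishSummarize(matrix(c(5.1, 6.2, 7.3), 1))),
               c(5.1, 6.2, 7.3))
  ## column equivariance, exact on the worked example
  expect_equal(unname(medianPolishSummarize(rbind(c(1, 3.5), c(3, 5.5)))),
               c(2, 4.5))
  ## ... and approximate on a random block: the additive decomposition is not
  ## unique, so sweeps started from shifted data may settle a few hundredths
  ## away
  set.seed(4)
  blk <- matrix(rnorm(5 * 4, 8), 5, 4)
  base <- medianPolishSummarize(blk, eps = 1e-9, maxIter = 200L)
  blk2 <- blk
  blk2[, 2] <- blk2[, 2] + 1.5
  shifted <- medianPolishSummarize(blk2, eps = 1e-9, maxIter = 200L)
  expect_equal(shifted[2], base[2] + 1.5, tolerance = 0.05)
  expect_equal(shifted[-2], base[-2], tolerance = 0.05)
  ## residual row and column medians vanish at convergence
  mp <- medpolish(blk, eps = 1e-9, maxiter = 200, trace.iter = FALSE)
  expect_true(all(abs(apply(mp$residuals, 1, median)) <= 1e-9))
  expect_true(all(abs(apply(mp$residuals, 2, median)) <= 1e-9))
  expect_error(medianPolishSummarize(matrix(numeric(0), 0, 0)), "empty")
})

test_that("blockwise median polish agrees with the per-block reference", {
  set.seed(5)
  nP <- 40L; nPr <- 11L; nS <- 8L
  X <- matrix(rnorm(nP * nPr * nS, 8, 1), nP * nPr, nS)
  fast <- txanchor:::.medianPolishBlocks(X, nPr)
  ref <- t(sapply(split(seq_len(nrow(X)), rep(seq_len(nP), each = nPr)),
                  function(i) medianPolishSummarize(X[i, ])))
  expect_equal(unname(fast), unname(ref), tolerance = 0.02)
})

test_that("preprocessing is permutation-equivariant in samples", {
  st <- simulateStudy(studyDesign(nProbesets = 15L, timepointsH = c(6, 24)),
                      seed = 6L)
  se <- probeExperiment(st)
  norm <- rmaNormalize(se, background = FALSE)
  perm <- sample(ncol(se))
  normPerm <- rmaNormalize(se[, perm], background = FALSE)
  expect_equal(SummarizedExperiment::assay(normPerm, "exprs"),
               SummarizedExperiment::assay(norm, "exprs")[, perm])
})

test_that("rmaNormalize output is log2 probeset level with gene annotation", {
  st <- simulateStudy(studyDesign(nProbesets = 12L, timepointsH = c(6, 24)),
                      seed = 7L)
  norm <- rmaNormalize(probeExperiment(st), background = TRUE)
  expect_equal(nrow(norm), 12)
  expect_equal(S4Vectors::metadata(norm)$scale, "log2")
  expect_false(anyNA(SummarizedExperiment::assay(norm, "exprs")))
  expect_equal(as.character(SummarizedExperiment::rowData(norm)$gene_id),
               sprintf("G%04d", 1:12))
})
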