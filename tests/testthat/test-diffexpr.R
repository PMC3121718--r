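test_that("noiseless treatment effect is recovered exactly", {
  sheet <- oneTimepointSheet()
  y <- 8 + 1.0 * (sheet$treatment == "MAM")
  fit <- fitFullModel(y, sheet)
  expect_equal(unname(fit$coefficients["treatment"]), 1.0)
  expect_lt(fit$p["treatment"], 1e-10)
})

test_that("coefficients and p-values agree with lm on a random instance", {
  set.seed(21)
  sheet <- oneTimepointSheet()
  y <- rnorm(nrow(sheet), 8)
  fit <- fitFullModel(y, sheet)
  t <- ifelse(sheet$treatment == "MAM", 0.5, -0.5)
  g <- ifelse(sheet$genotype == "ko", 0.5, -0.5)
  l <- ifelse(sheet$site == "siteB", 0.5, -0.5)
  ref <- lm(y ~ t * g * l)
  cf <- summary(ref)$coefficients
  expect_equal(unname(fit$coefficients),
               unname(cf[c("(Intercept)", "t", "g", "l", "t:g", "t:l",
                           "g:l", "t:g:l"), "Estimate"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$p),
               unname(cf[c("(Intercept)", "t", "g", "l", "t:g", "t:l",
                           "g:l", "t:g:l"), "Pr(>|t|)"]),
               tolerance = 1e-8)
})

test_that("null p-values are uniform (KS over 600 probesets)", {
  set.seed(22)
  sheet <- oneTimepointSheet()
  pv <- replicate(600, {
    fit <- fitFullModel(rnorm(nrow(sheet), 8, 0.3), sheet)
    fit$p[c("treatment", "genotype", "treatment:genotype")]
  })
  for (i in 1:3)
    expect_gt(ks.test(pv[i, ], "punif")$p.value, 0.01)
})

test_that("consistency filter reduces or excludes per the laboratory rule", {
  sheet <- oneTimepointSheet()
  set.seed(23)
  ## no laboratory interaction planted: given all lab p > 0.15, reduced
  repeat {
    fit <- fitFullModel(rnorm(nrow(sheet), 8, 0.3), sheet)
    if (all(fit$p[c("lab:treatment", "lab:genotype",
                    "lab:treatment:genotype")] > 0.15)) break
  }
  out <- consistencyFilter(fit)
  expect_equal(out$status, "reduced")
  expect_named(out$fit$coefficients,
               c("intercept", "treatment", "genotype", "treatment:genotype",
                 "lab"))

  ## planted lab x treatment interaction of 2 log2 units: excluded nearly
  ## always
  lt <- (sheet$site == "siteB") * (sheet$treatment == "MAM")
  status <- replicate(100, {
    y <- 8 + 2.0 * lt + rnorm(nrow(sheet), 0, 0.25)
    consistencyFilter(fitFullModel(y, sheet))$status
  })
  expect_gte(mean(status == "excluded"), 0.95)

  ## boundary: alphaLab = 0 can exclude nothing
  fit2 <- fitFullModel(8 + 2 * lt + rnorm(nrow(sheet), 0, 0.25), sheet)
  expect_equal(consistencyFilter(fit2, alphaLab = 0)$status, "reduced")

  ## joint-F variant agrees on a clear-cut case
  expect_equal(consistencyFilter(fit2, labTest = "joint")$status, "excluded")
})

test_that("reduced-model treatment estimate matches the cell-means contrast", {
  set.seed(24)
  sheet <- oneTimepointSheet()
  y <- rnorm(nrow(sheet), 8)
  fit <- fitFullModel(y, sheet)
  out <- consistencyFilter(fit, alphaLab = 0)  # force reduction
  cellMeans <- tapply(y, list(sheet$treatment, sheet$genotype, sheet$site),
                      mean)
  ## balanced design: treatment contrast = mean of MAM cells - vehicle cells
  expect_equal(unname(out$fit$coefficients["treatment"]),
               mean(cellMeans["MAM", , ]) - mean(cellMeans["vehicle", , ]),
               tolerance = 1e-10)
})

test_that("Benjamini-Hochberg step-up matches its definition", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(benjaminiHochberg(rep(1, 4)), rep(1, 4))
  expect_equal(benjaminiHochberg(0.37), 0.37)  # m = 1
  set.seed(25)
  p <- runif(50)
  expect_equal(benjaminiHochberg(p), refBH(p))
  ## order invariance
  o <- sample(50)
  expect_equal(benjaminiHochberg(p[o]), benjaminiHochberg(p)[o])
  ## order preserving, and q >= p
  q <- benjaminiHochberg(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "0, 1")
  expect_error(benjaminiHochberg(c(0.5, -0.1)), "0, 1")
})

test_that("DE calls require both the q-value and fold-change gates", {
  tab <- S4Vectors::DataFrame(
    probeset_id = sprintf("PS%02d_at", 1:4),
    gene_id = sprintf("G%02d", 1:4),
    timepoint_h = 6,
    status = c("reduced", "reduced", "reduced", "excluded"),
    effect = "treatment",
    estimate = c(log2(1.25), -log2(1.5), log2(2), log2(5)),
    se = 0.1,
    p_value = c(0.001, 0.001, 0.001, 0.001),
    q_value = c(0.04, 0.04, 0.2, NA),
    fold_change = c(1.25, -1.5, 2, 5),
    p_lab_treatment = 0.5, p_lab_genotype = 0.5, p_lab_3way = 0.5)
  de <- callDE(tab, "treatment")
  ## q ok but |fc| 1.25 < 1.3: out; q ok and fc -1.5: in (sign-blind);
  ## q 0.2: out; excluded: never significant
  expect_equal(de@unionProbesets, "PS02_at")
  expect_equal(de@genes, "G02")

  ## fully excluded family: empty set with warning
  tabX <- tab
  tabX$status <- "excluded"
  expect_warning(deX <- callDE(tabX, "treatment"), "empty")
  expect_equal(length(deX@unionProbesets), 0)
})

test_that("probesets are excluded for every effect at a timepoint", {
  set.seed(26)
  sheet <- oneTimepointSheet()
  Y <- matrix(rnorm(50 * nrow(sheet), 8, 0.3), nrow = 50,
              dimnames = list(sprintf("PS%04d_at", 1:50), sheet$sample_id))
  res <- runDiffExpr(makeProbesetSE(Y, sheet))
  st <- tapply(res$status, list(res$probeset_id, res$effect),
               function(s) unique(s))
  expect_true(all(apply(st, 1, function(r) length(unique(r)) == 1)))
  ## q-values only on non-excluded rows
  expect_true(all(is.na(res$q_value[res$status == "excluded"])))
  expect_true(all(!is.na(res$q_value[res$status == "reduced"])))
  ## fold change consistency: sign and magnitude tied to the estimate
  r <- res[res$status == "reduced", ]
  expect_equal(sign(r$fold_change), sign(r$estimate))
  expect_equal(abs(r$fold_change), 2^abs(r$estimate))
})

test_that("gene-level union combines analyses without duplication", {
  expect_equal(combineAnalyses(paste0("g", 1:3), paste0("h", 1:4)),
               sort(c(paste0("g", 1:3), paste0("h", 1:4))))
  expect_length(combineAnalyses(paste0("g", 1:5), paste0("g", 1:5)), 5)
  ## 362 and 153 with 72 shared -> 443
  a <- sprintf("gene%04d", 1:362)
  b <- sprintf("gene%04d", c(1:72, 1000 + 1:81))
  expect_length(combineAnalyses(a, b), 443)
})
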