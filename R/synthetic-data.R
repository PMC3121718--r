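#' Simulate an O6-methylguanine lesion time-course
#'
#' Single-pulse first-order kinetics: the expected burden at `tH` hours after
#' dosing is `initialBurden[tissue] * exp(-repairRatePerH[genotype] * tH)`,
#' multiplied by lognormal measurement noise with coefficient of variation
#' `measurementCv` (mean-preserving). Values below the upper bound of the
#' assay's minimal detectable quantity (MDQ) are reported left-censored at the
#' MDQ midpoint with the `censored` flag set.
#'
#' @param kinetics a [LesionKinetics-class] object.
#' @param genotype `"wt"` or `"ko"`.
#' @param tissue `"brain"` or `"liver"`.
#' @param tH hours post dosing (vectorized, must be >= 0).
#' @return data.frame with columns `lesions_per_1e8` and `censored`.
#' @examples
#' k <- lesionKinetics(measurementCv = 0)
#' lesionTimecourse(k, "ko", "liver", c(0, 24, 168))
#' @export
lesionTimecourse <- function(kinetics, genotype, tissue, tH) {
  stopifnot(is(kinetics, "LesionKinetics"))
  validObject(kinetics)
  genotype <- match.arg(genotype, names(kinetics@repairRatePerH))
  tissue <- match.arg(tissue, names(kinetics@initialBurden))
  if (any(tH < 0)) stop("tH must be non-negative")
  mu <- kinetics@initialBurden[[tissue]] *
    exp(-kinetics@repairRatePerH[[genotype]] * tH)
  cv <- kinetics@measurementCv
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    obs <- mu * exp(stats::rnorm(length(tH), -sdlog^2 / 2, sdlog))
  } else {
    obs <- mu
  }
  mdqMid <- mean(kinetics@mdqRange)
  cen <- obs < kinetics@mdqRange[2]
  obs[cen] <- mdqMid
  data.frame(lesions_per_1e8 = obs, censored = cen)
}

## Deterministic disjoint assignment of planted categories to probesets.
assignCategories <- function(nProbesets, effects) {
  counts <- c(
    treatment = round(effects@fracTreatmentDE * nProbesets),
    genotype = round(effects@fracGenotypeDE * nProbesets),
    interaction = round(effects@fracInteractionDE * nProbesets),
    lab_inconsistent = round(effects@fracLabInconsistent * nProbesets),
    anchored = round(effects@fracAnchored * nProbesets)
  )
  if (sum(counts) > nProbesets)
    stop("planted fractions imply more probesets than available")
  pool <- sample.int(nProbesets)
  cat <- rep("null", nProbesets)
  at <- 0L
  for (nm in names(counts)) {
    k <- counts[[nm]]
    if (k > 0) cat[pool[(at + 1L):(at + k)]] <- nm
    at <- at + k
  }
  cat
}

#' Generate a truth-labelled synthetic factorial study
#'
#' Draws probe-level brain expression intensities and matched per-animal
#' lesion time-courses (brain and liver) under the factorial design in
#' `design`. Baseline log2 probeset levels are uniform on (6, 10); each probe
#' carries a fixed affinity (sd 0.5 log2 units) so that median-polish
#' summarization has probe-level structure to work with. Planted effects
#' (see [effectSpec()]) are additive on the log2 scale and recorded in the
#' truth table; lesion-anchored probesets couple their MAM-arm expression to
#' the animal's brain lesion burden through a Gaussian copula on the
#' within-timepoint lesion ranks, so that the latent correlation (and hence,
#' approximately, the Spearman correlation) equals `anchorStrength`. One
#' animal corresponds to one array and one lesion measurement per tissue.
#'
#' @param design a [StudyDesign-class].
#' @param effects an [EffectSpec-class].
#' @param kinetics a [LesionKinetics-class].
#' @param seed integer seed; defaults to `effects@seed`. Identical inputs and
#'   seed give identical output.
#' @return A [SimulatedStudy-class].
#' @examples
#' study <- simulateStudy(studyDesign(nProbesets = 50L))
#' study
#' @export
simulateStudy <- function(design = studyDesign(), effects = effectSpec(),
                          kinetics = lesionKinetics(), seed = effects@seed) {
  stopifnot(is(design, "StudyDesign"), is(effects, "EffectSpec"),
            is(kinetics, "LesionKinetics"))
  validObject(design); validObject(effects); validObject(kinetics)
  set.seed(seed)

  sheet <- expand.grid(
    replicate = seq_len(design@arraysPerCell),
    site = design@sites, genotype = design@genotypes,
    treatment = design@treatments, timepoint_h = design@timepointsH,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  sheet$replicate <- NULL
  n <- nrow(sheet)
  sheet$tissue <- "brain"
  sheet$animal_id <- sprintf("animal%03d", seq_len(n))
  sheet$sample_id <- sprintf("S%03d", seq_len(n))
  rownames(sheet) <- sheet$sample_id

  ## per-animal lesions, brain and liver; vehicle animals carry background
  ## burden 0 and are reported censored at the MDQ
  lesions <- do.call(rbind, lapply(design@tissues, function(ts) {
    out <- data.frame(animal_id = sheet$animal_id, tissue = ts,
                      timepoint_h = sheet$timepoint_h,
                      lesions_per_1e8 = NA_real_, censored = NA)
    for (g in design@genotypes) {
      idx <- which(sheet$genotype == g & sheet$treatment == design@treatments[2])
      if (length(idx)) {
        tc <- lesionTimecourse(kinetics, g, ts, sheet$timepoint_h[idx])
        out$lesions_per_1e8[idx] <- tc$lesions_per_1e8
        out$censored[idx] <- tc$censored
      }
    }
    veh <- which(sheet$treatment == design@treatments[1])
    out$lesions_per_1e8[veh] <- mean(kinetics@mdqRange)
    out$censored[veh] <- TRUE
    out
  }))
  rownames(lesions) <- NULL

  nP <- design@nProbesets
  nPr <- design@probesPerProbeset
  probesetIds <- sprintf("PS%04d_at", seq_len(nP))
  geneIds <- sprintf("G%04d", seq_len(nP))
  probeIds <- paste0(rep(probesetIds, each = nPr),
                     sprintf(":p%02d", rep(seq_len(nPr), nP)))

  category <- assignCategories(nP, effects)
  sgn <- sample(c(-1, 1), nP, replace = TRUE)
  eff <- effects@log2EffectSize
  truth <- data.frame(probeset_id = probesetIds, gene_id = geneIds,
                      category = category, sign = sgn,
                      effect_size = ifelse(category %in%
                        c("treatment", "genotype", "interaction",
                          "lab_inconsistent"), eff,
                        ifelse(category == "anchored",
                               effects@anchorStrength, 0)))
  truth <- truth[truth$category != "null", , drop = FALSE]
  rownames(truth) <- NULL

  mu <- stats::runif(nP, 6, 10)
  affinity <- stats::rnorm(nP * nPr, 0, 0.5)

  isMAM <- sheet$treatment == design@treatments[2]
  isKO <- sheet$genotype == design@genotypes[2]
  isSiteB <- sheet$site == design@sites[2]

  ## probeset x array log2 signal
  sig <- matrix(rep(mu, n), nrow = nP)
  trtRows <- category == "treatment"
  genRows <- category == "genotype"
  intRows <- category == "interaction"
  labRows <- category == "lab_inconsistent"
  ancRows <- which(category == "anchored")
  if (any(trtRows))
    sig[trtRows, isMAM] <- sig[trtRows, isMAM] + sgn[trtRows] * eff
  if (any(genRows))
    sig[genRows, isKO] <- sig[genRows, isKO] + sgn[genRows] * eff
  if (any(intRows))
    sig[intRows, isMAM & isKO] <- sig[intRows, isMAM & isKO] +
      sgn[intRows] * eff
  if (any(labRows))
    sig[labRows, isMAM & isSiteB] <- sig[labRows, isMAM & isSiteB] +
      sgn[labRows] * eff
  sig[, isSiteB] <- sig[, isSiteB] + effects@siteShiftLog2

  ## anchored probesets: Gaussian copula on within-timepoint lesion ranks of
  ## the MAM animals; amplitude 1 log2 unit so the coupling dominates probe
  ## noise after summarization
  if (length(ancRows)) {
    rho <- effects@anchorStrength
    brain <- lesions[lesions$tissue == "brain", ]
    brainByAnimal <- stats::setNames(brain$lesions_per_1e8, brain$animal_id)
    for (tp in design@timepointsH) {
      cols <- which(isMAM & sheet$timepoint_h == tp)
      if (!length(cols)) next
      les <- brainByAnimal[sheet$animal_id[cols]]
      z <- stats::qnorm((rank(les, ties.method = "average") - 0.5) /
                          length(les))
      epsm <- matrix(stats::rnorm(length(ancRows) * length(cols)),
                     nrow = length(ancRows))
      sig[ancRows, cols] <- sig[ancRows, cols] +
        1.0 * (rho * matrix(z, nrow = length(ancRows), ncol = length(cols),
                            byrow = TRUE) + sqrt(1 - rho^2) * epsm)
    }
  }

  probeLog2 <- sig[rep(seq_len(nP), each = nPr), , drop = FALSE] +
    matrix(affinity, nrow = nP * nPr, ncol = n) +
    matrix(stats::rnorm(nP * nPr * n, 0, effects@noiseSdLog2),
           nrow = nP * nPr)
  raw <- 2^probeLog2
  dimnames(raw) <- list(probeIds, sheet$sample_id)

  se <- SummarizedExperiment(
    assays = list(exprs = raw),
    rowData = DataFrame(probe_id = probeIds,
                        probeset_id = rep(probesetIds, each = nPr),
                        gene_id = rep(geneIds, each = nPr)),
    colData = DataFrame(sheet[, c("sample_id", "site", "genotype",
                                  "treatment", "timepoint_h", "tissue",
                                  "animal_id")])
  )
  metadata(se)$scale <- "raw"

  new("SimulatedStudy", se = se, lesions = lesions, truth = truth,
      design = design, effects = effects, kinetics = kinetics)
}

#' Simulate gene-set collections over a gene universe
#'
#' Convenience generator of GMT-style term sets for exercising the
#' overrepresentation stage on synthetic data.
#'
#' @param genes character vector, the gene universe.
#' @param nSets number of sets.
#' @param sizeRange integer(2), min and max set size.
#' @param seed integer seed.
#' @return Named list of character vectors.
#' @export
simulateGeneSets <- function(genes, nSets = 50L, sizeRange = c(10L, 50L),
                             seed = 1L) {
  set.seed(seed)
  stats::setNames(lapply(seq_len(nSets), function(i) {
    k <- sample(seq(sizeRange[1], min(sizeRange[2], length(genes))), 1L)
    sort(sample(genes, k))
  }), sprintf("SET%03d", seq_len(nSets)))
}

#' Simulate promoter sequences with an optionally planted motif
#'
#' Uniform-composition random promoters; in a `plantFrac` fraction of genes a
#' single instance of `motif` (IUPAC codes resolved uniformly at random) is
#' written at a random position on the forward strand.
#'
#' @param genes character vector of gene ids (FASTA names).
#' @param width promoter length in bp (default 2000, upstream of the TSS by
#'   convention).
#' @param motif a [Motif-class] in consensus mode, or `NULL`.
#' @param plantFrac fraction of genes receiving one planted instance.
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet] named by gene.
#' @export
simulatePromoters <- function(genes, width = 2000L, motif = NULL,
                              plantFrac = 0, seed = 1L) {
  set.seed(seed)
  n <- length(genes)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), character(1))
  if (!is.null(motif) && plantFrac > 0) {
    stopifnot(is(motif, "Motif"), motif@kind == "consensus")
    ltr <- strsplit(motif@consensus, "")[[1]]
    planted <- sample.int(n, round(plantFrac * n))
    for (i in planted) {
      inst <- paste(vapply(ltr, function(l)
        sample(IUPAC_MAP[[l]], 1L), character(1)), collapse = "")
      at <- sample.int(width - nchar(inst) + 1L, 1L)
      substr(seqs[i], at, at + nchar(inst) - 1L) <- inst
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- genes
  out
}
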