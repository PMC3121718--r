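#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Factorial study design
#'
#' Describes the layout of a two-laboratory factorial toxicogenomics study:
#' each combination of site, genotype, treatment and timepoint is hybridized
#' on `arraysPerCell` arrays, one array per animal. The default reproduces a
#' 2 site x 2 genotype (wt, Mgmt-null) x 2 treatment (MAM, vehicle) x
#' 4 timepoint (6, 24, 48, 168 h) design with 3 arrays per cell, i.e. 96
#' arrays. Expression is simulated for brain; lesion burdens are simulated for
#' brain and liver.
#'
#' @slot sites character(2), laboratory labels.
#' @slot genotypes character(2), reference level first.
#' @slot treatments character(2), vehicle first, active treatment second.
#' @slot timepointsH strictly increasing numeric vector of hours post dosing.
#' @slot arraysPerCell integer, arrays (= animals) per design cell.
#' @slot tissues character, tissues with lesion measurements.
#' @slot probesPerProbeset integer, probes summarized into one probeset.
#' @slot nProbesets integer, number of probesets on the simulated array.
#' @export
setClass("StudyDesign", representation(
  sites = "character",
  genotypes = "character",
  treatments = "character",
  timepointsH = "numeric",
  arraysPerCell = "integer",
  tissues = "character",
  probesPerProbeset = "integer",
  nProbesets = "integer"
))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@sites) != 2L) msg <- c(msg, "exactly 2 sites required")
  if (length(object@genotypes) != 2L) msg <- c(msg, "exactly 2 genotypes required")
  if (length(object@treatments) != 2L) msg <- c(msg, "exactly 2 treatments required")
  if (length(object@timepointsH) < 1L || is.unsorted(object@timepointsH, strictly = TRUE))
    msg <- c(msg, "timepointsH must be strictly increasing")
  if (any(object@timepointsH < 0)) msg <- c(msg, "timepointsH must be non-negative")
  if (object@arraysPerCell < 1L) msg <- c(msg, "arraysPerCell must be >= 1")
  if (object@probesPerProbeset < 1L) msg <- c(msg, "probesPerProbeset must be >= 1")
  if (object@nProbesets < 1L) msg <- c(msg, "nProbesets must be >= 1")
  if (anyDuplicated(object@sites) || anyDuplicated(object@genotypes) ||
      anyDuplicated(object@treatments) || anyDuplicated(object@timepointsH))
    msg <- c(msg, "factor levels must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname StudyDesign-class
#' @param sites,genotypes,treatments,timepointsH,arraysPerCell,tissues
#'   design factors; see slots.
#' @param probesPerProbeset,nProbesets array geometry of the simulated chip.
#' @return A [StudyDesign-class] object.
#' @examples
#' d <- studyDesign()
#' nArrays(d)  # 96
#' @export
studyDesign <- function(sites = c("siteA", "siteB"),
                        genotypes = c("wt", "ko"),
                        treatments = c("vehicle", "MAM"),
                        timepointsH = c(6, 24, 48, 168),
                        arraysPerCell = 3L,
                        tissues = c("brain", "liver"),
                        probesPerProbeset = 11L,
                        nProbesets = 1000L) {
  new("StudyDesign", sites = sites, genotypes = genotypes,
      treatments = treatments, timepointsH = as.numeric(timepointsH),
      arraysPerCell = as.integer(arraysPerCell), tissues = tissues,
      probesPerProbeset = as.integer(probesPerProbeset),
      nProbesets = as.integer(nProbesets))
}

#' Planted effect specification for the synthetic study
#'
#' Controls which probesets carry planted signal and how strong it is. The
#' planted categories (treatment, genotype, interaction, laboratory-
#' inconsistent, lesion-anchored) are disjoint by construction; the remaining
#' probesets are null. Effects are additive on the log2 scale.
#'
#' @slot fracTreatmentDE,fracGenotypeDE,fracInteractionDE proportions of
#'   probesets with a planted treatment / genotype / treatment x genotype
#'   effect of size `log2EffectSize` (random sign).
#' @slot fracLabInconsistent proportion with a planted site x treatment
#'   interaction of magnitude `log2EffectSize` (the replication-consistency
#'   filter should exclude these).
#' @slot fracAnchored proportion whose MAM-arm expression is coupled to the
#'   animal's lesion burden through a Gaussian copula on lesion ranks, so the
#'   latent correlation equals `anchorStrength`.
#' @slot log2EffectSize planted effect size, log2 units.
#' @slot anchorStrength copula correlation between 0 and 1.
#' @slot noiseSdLog2 iid per-probe Gaussian noise sd, log2 units.
#' @slot siteShiftLog2 constant per-site offset (batch effect removable by the
#'   laboratory term).
#' @slot seed integer default seed for [simulateStudy()].
#' @export
setClass("EffectSpec", representation(
  fracTreatmentDE = "numeric",
  fracGenotypeDE = "numeric",
  fracInteractionDE = "numeric",
  fracLabInconsistent = "numeric",
  fracAnchored = "numeric",
  log2EffectSize = "numeric",
  anchorStrength = "numeric",
  noiseSdLog2 = "numeric",
  siteShiftLog2 = "numeric",
  seed = "integer"
))

setValidity("EffectSpec", function(object) {
  msg <- character()
  fr <- c(object@fracTreatmentDE, object@fracGenotypeDE,
          object@fracInteractionDE, object@fracLabInconsistent,
          object@fracAnchored)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all proportions must lie in [0, 1]")
  if (sum(fr) > 1) msg <- c(msg, "planted proportions must sum to <= 1 (categories are disjoint)")
  if (object@noiseSdLog2 <= 0) msg <- c(msg, "noiseSdLog2 must be > 0")
  if (object@anchorStrength < 0 || object@anchorStrength > 1)
    msg <- c(msg, "anchorStrength must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname EffectSpec-class
#' @param fracTreatmentDE,fracGenotypeDE,fracInteractionDE,fracLabInconsistent,fracAnchored
#'   proportions of probesets per planted category.
#' @param log2EffectSize,anchorStrength,noiseSdLog2,siteShiftLog2,seed see slots.
#' @return An [EffectSpec-class] object.
#' @export
effectSpec <- function(fracTreatmentDE = 0.05,
                       fracGenotypeDE = 0.05,
                       fracInteractionDE = 0.05,
                       fracLabInconsistent = 0.05,
                       fracAnchored = 0.05,
                       log2EffectSize = 1.0,
                       anchorStrength = 0.9,
                       noiseSdLog2 = 0.25,
                       siteShiftLog2 = 0.3,
                       seed = 1L) {
  new("EffectSpec",
      fracTreatmentDE = fracTreatmentDE, fracGenotypeDE = fracGenotypeDE,
      fracInteractionDE = fracInteractionDE,
      fracLabInconsistent = fracLabInconsistent, fracAnchored = fracAnchored,
      log2EffectSize = log2EffectSize, anchorStrength = anchorStrength,
      noiseSdLog2 = noiseSdLog2, siteShiftLog2 = siteShiftLog2,
      seed = as.integer(seed))
}

#' Lesion kinetics for the O6-methylguanine time-course
#'
#' Single-pulse, first-order-repair surrogate for the adduct time-course: the
#' expected burden after a single dose is
#' `initialBurden * exp(-repairRate * t)`, with a genotype-specific repair
#' rate (MGMT-proficient wt repairs, the knockout does not) and multiplicative
#' lognormal measurement noise. The assay has a minimal detectable quantity
#' (MDQ) of 1-2.6 lesions per 1e8 normal nucleotides; observations below the
#' upper bound are reported left-censored at the MDQ midpoint.
#'
#' @slot initialBurden named numeric (brain, liver), lesions per 1e8
#'   nucleotides at t = 0; the liver/brain ratio defaults to ~1e3.
#' @slot repairRatePerH named numeric (wt, ko), first-order repair rates / h.
#' @slot mdqRange numeric(2), assay MDQ range (lesions per 1e8 nucleotides).
#' @slot measurementCv coefficient of variation of the lognormal measurement
#'   noise (0 disables noise).
#' @export
setClass("LesionKinetics", representation(
  initialBurden = "numeric",
  repairRatePerH = "numeric",
  mdqRange = "numeric",
  measurementCv = "numeric"
))

setValidity("LesionKinetics", function(object) {
  msg <- character()
  if (!all(c("brain", "liver") %in% names(object@initialBurden)))
    msg <- c(msg, "initialBurden needs named entries 'brain' and 'liver'")
  if (any(object@initialBurden < 0)) msg <- c(msg, "initialBurden must be >= 0")
  if (!all(c("wt", "ko") %in% names(object@repairRatePerH)))
    msg <- c(msg, "repairRatePerH needs named entries 'wt' and 'ko'")
  if (any(object@repairRatePerH < 0)) msg <- c(msg, "repair rates must be >= 0")
  if (all(c("wt", "ko") %in% names(object@repairRatePerH)) &&
      object@repairRatePerH["ko"] > object@repairRatePerH["wt"])
    msg <- c(msg, "ko repair rate must not exceed wt repair rate")
  if (length(object@mdqRange) != 2L || any(object@mdqRange <= 0) ||
      object@mdqRange[1] >= object@mdqRange[2])
    msg <- c(msg, "mdqRange must be an increasing positive pair")
  if (object@measurementCv < 0) msg <- c(msg, "measurementCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname LesionKinetics-class
#' @param initialBurden,repairRatePerH,mdqRange,measurementCv see slots.
#' @return A [LesionKinetics-class] object.
#' @export
lesionKinetics <- function(initialBurden = c(brain = 300, liver = 3e5),
                           repairRatePerH = c(wt = log(2) / 24, ko = 0),
                           mdqRange = c(1, 2.6),
                           measurementCv = 0.2) {
  new("LesionKinetics", initialBurden = initialBurden,
      repairRatePerH = repairRatePerH, mdqRange = as.numeric(mdqRange),
      measurementCv = measurementCv)
}

#' Simulated anchored-expression study
#'
#' Container returned by [simulateStudy()]: a probe-level
#' [SummarizedExperiment::SummarizedExperiment] (assay `"exprs"`, raw scale;
#' `colData` is the sample sheet, `rowData` the probe/probeset/gene
#' annotation), the matched per-animal lesion table, and truth labels for
#' every planted probeset.
#'
#' @slot se probe-level [SummarizedExperiment::SummarizedExperiment].
#' @slot lesions data.frame: animal_id, tissue, timepoint_h, lesions_per_1e8,
#'   censored.
#' @slot truth data.frame: probeset_id, category, sign, effect_size.
#' @slot design,effects,kinetics the generating parameter objects.
#' @export
setClass("SimulatedStudy", representation(
  se = "SummarizedExperiment",
  lesions = "data.frame",
  truth = "data.frame",
  design = "StudyDesign",
  effects = "EffectSpec",
  kinetics = "LesionKinetics"
))

#' A differential-expression gene set
#'
#' Significant probesets per timepoint, their union ("significant at at least
#' one timepoint"), and the de-duplicated gene-level list (one probeset per
#' gene, keeping the smallest q-value).
#'
#' @slot label analysis label, e.g. `"ko MAM-vs-vehicle"`.
#' @slot perTimepoint named list (timepoint -> character probeset ids).
#' @slot unionProbesets character, union across timepoints.
#' @slot genes character, de-duplicated mapped gene ids.
#' @slot geneMap data.frame: probeset_id, gene_id, q_value used for mapping.
#' @export
setClass("DEGeneSet", representation(
  label = "character",
  perTimepoint = "list",
  unionProbesets = "character",
  genes = "character",
  geneMap = "data.frame"
))

setValidity("DEGeneSet", function(object) {
  u <- sort(unique(unlist(object@perTimepoint, use.names = FALSE)))
  if (!identical(sort(object@unionProbesets), u))
    return("unionProbesets must equal the union of the per-timepoint sets")
  TRUE
})

#' A promoter motif (TRE) definition
#'
#' Either an IUPAC degenerate consensus or a position-weight matrix with a
#' log-odds threshold. `N` in a scanned sequence never matches a non-N
#' consensus position.
#'
#' @slot name motif label.
#' @slot kind `"consensus"` or `"pwm"`.
#' @slot consensus IUPAC string (consensus mode).
#' @slot pwm 4 x width probability matrix, rows A, C, G, T (pwm mode).
#' @slot threshold log-odds score threshold (pwm mode).
#' @slot strand `"both"` or `"forward"`.
#' @export
setClass("Motif", representation(
  name = "character",
  kind = "character",
  consensus = "character",
  pwm = "matrix",
  threshold = "numeric",
  strand = "character"
))

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

setValidity("Motif", function(object) {
  msg <- character()
  if (!object@kind %in% c("consensus", "pwm"))
    msg <- c(msg, "kind must be 'consensus' or 'pwm'")
  if (!object@strand %in% c("both", "forward"))
    msg <- c(msg, "strand must be 'both' or 'forward'")
  if (object@kind == "consensus") {
    ltr <- strsplit(toupper(object@consensus), "")[[1]]
    if (length(ltr) == 0L) msg <- c(msg, "empty consensus")
    if (!all(ltr %in% names(IUPAC_MAP)))
      msg <- c(msg, "consensus contains non-IUPAC characters")
  } else {
    if (nrow(object@pwm) != 4L || is.null(rownames(object@pwm)) ||
        !identical(rownames(object@pwm), c("A", "C", "G", "T")))
      msg <- c(msg, "pwm must have rows A, C, G, T")
    else if (any(abs(colSums(object@pwm) - 1) > 1e-6))
      msg <- c(msg, "pwm columns must sum to 1 (+- 1e-6)")
    if (!is.finite(object@threshold)) msg <- c(msg, "threshold must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Motif-class
#' @param name motif label.
#' @param consensus IUPAC consensus string; lower case accepted.
#' @param strand `"both"` (default) or `"forward"`.
#' @return A [Motif-class] object.
#' @examples
#' hnf4 <- consensusMotif("HNF-4", "AGGTCAaAGGTCA")
#' @export
consensusMotif <- function(name, consensus, strand = "both") {
  new("Motif", name = name, kind = "consensus",
      consensus = toupper(consensus),
      pwm = matrix(numeric(0), nrow = 0, ncol = 0), threshold = NA_real_,
      strand = strand)
}

#' @rdname Motif-class
#' @param pwm 4 x width probability matrix with rows A, C, G, T.
#' @param threshold log-odds score threshold for calling a hit.
#' @export
pwmMotif <- function(name, pwm, threshold, strand = "both") {
  new("Motif", name = name, kind = "pwm", consensus = NA_character_,
      pwm = pwm, threshold = threshold, strand = strand)
}

#' Gene x motif promoter interaction matrix
#'
#' Binary matrix recording, for every gene's promoter, which motifs have at
#' least one match. Motifs present in no more than `prevalenceMin` of all
#' promoters are dropped (recorded in `dropped`).
#'
#' @slot hits binary integer matrix, genes x retained motifs.
#' @slot prevalence named numeric, per-motif fraction of promoters hit
#'   (all motifs, including dropped ones).
#' @slot dropped character, motifs removed by the prevalence filter.
#' @slot promoterLength integer, promoter length (bp) recorded for the output
#'   header; NA when promoters have mixed lengths.
#' @slot skipped character, candidate genes without a promoter sequence.
#' @export
setClass("TREInteractionMatrix", representation(
  hits = "matrix",
  prevalence = "numeric",
  dropped = "character",
  promoterLength = "integer",
  skipped = "character"
))

setValidity("TREInteractionMatrix", function(object) {
  if (length(object@hits) && !all(object@hits %in% c(0L, 1L)))
    return("hits must be binary")
  TRUE
})
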