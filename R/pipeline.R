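## End-to-end orchestration: simulate -> normalize -> per-timepoint factorial
## DE -> union -> lesion anchoring -> gene-set enrichment -> promoter TRE
## analysis -> adduct statistics, from one serializable config.

#' Default pipeline configuration
#'
#' Plain named list (YAML round-trippable) holding every stage parameter with
#' its standard default: FDR 0.05, fold-change gate 1.3, laboratory-
#' consistency alpha 0.15, anchoring threshold 0.70, TRE prevalence minimum
#' 0.05 and TRE alpha 0.05; plus the generator settings and per-stage
#' toggles.
#'
#' @param ... overrides of any default entry (unknown names are an error).
#' @return Named list with class `"txanchorConfig"`.
#' @examples
#' cfg <- pipelineConfig(n_probesets = 200, seed = 7)
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    ## generator
    n_probesets = 500L, probes_per_probeset = 11L, arrays_per_cell = 3L,
    timepoints_h = c(6, 24, 48, 168),
    frac_treatment_de = 0.05, frac_genotype_de = 0.05,
    frac_interaction_de = 0.05, frac_lab_inconsistent = 0.05,
    frac_anchored = 0.05, log2_effect_size = 1.0, anchor_strength = 0.9,
    noise_sd_log2 = 0.25, site_shift_log2 = 0.3,
    ## stage parameters
    background = FALSE, fdr = 0.05, min_fc = 1.3, alpha_lab = 0.15,
    anchor_threshold = 0.70, anchor_absolute = FALSE,
    prevalence_min = 0.05, alpha_tre = 0.05, enrich_top = 4L,
    promoter_length = 2000L, tre_plant_frac = 0.6,
    ## optional external inputs (NULL -> simulate/skip)
    gmt = NULL, promoters = NULL, motifs = NULL,
    stages = list(enrich = TRUE, tre = TRUE, adduct_stats = TRUE)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "txanchorConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return `readPipelineConfig`: the configuration list (defaults filled in
#'   for entries not present in the file).
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' @rdname readPipelineConfig
#' @param config a configuration from [pipelineConfig()].
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
}

#' Anchored percentage of a differential-expression set
#'
#' The summary statistic `100 * nAnchored / nDE` reported by the pipeline:
#' the share of a differentially expressed gene set whose members are also
#' anchored to lesion burden.
#'
#' @param nAnchored,nDE set sizes; `nAnchored` must not exceed `nDE` (the
#'   anchored set is a subset of its candidates).
#' @return Percentage (0-100).
#' @examples
#' anchoredPercent(60, 153)  # ~40
#' @export
anchoredPercent <- function(nAnchored, nDE) {
  if (nDE <= 0) stop("nDE must be positive")
  if (nAnchored < 0 || nAnchored > nDE)
    stop("nAnchored must lie in [0, nDE]")
  100 * nAnchored / nDE
}

#' Validate pipeline input files
#'
#' Schema checks for the tabular inputs; each file gets a pass/fail row with
#' the first offending line where applicable.
#'
#' @param paths named list/vector with any of `expression`, `sample_sheet`,
#'   `lesions`, `annotation`.
#' @return data.frame: `file`, `ok`, `message`.
#' @export
validateInputs <- function(paths) {
  checkOne <- function(kind, path) {
    if (!file.exists(path)) return(sprintf("file not found: %s", path))
    res <- tryCatch({
      switch(kind,
        expression = {
          m <- readExpressionMatrix(path)
          if (any(!is.finite(m))) stop("non-finite intensities")
          if (any(m <= 0))
            stop("non-positive intensity at data line ",
                 which(rowSums(m <= 0) > 0)[1])
          if (anyDuplicated(rownames(m))) stop("duplicate probe ids")
          "ok"
        },
        sample_sheet = { readSampleSheet(path); "ok" },
        lesions = { readLesionTable(path); "ok" },
        annotation = {
          ann <- utils::read.delim(path, stringsAsFactors = FALSE)
          need <- c("probe_id", "probeset_id", "gene_id")
          miss <- setdiff(need, names(ann))
          if (length(miss))
            stop("missing column(s): ", paste(miss, collapse = ", "))
          "ok"
        },
        stop("unknown input kind: ", kind))
    }, error = function(e) conditionMessage(e))
    res
  }
  msgs <- vapply(names(paths), function(k) checkOne(k, paths[[k]]),
                 character(1))
  data.frame(file = unname(unlist(paths)), kind = names(paths),
             ok = msgs == "ok", message = ifelse(msgs == "ok", "", msgs),
             row.names = NULL)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full anchored-expression analysis pipeline
#'
#' Executes, in dependency order: synthetic study generation (or loading of
#' supplied inputs), RMA-style normalization, per-timepoint factorial
#' differential expression for the knockout MAM response
#' (`treatment_ko` contrast) and the genotype-difference
#' (`interaction`) analysis, the gene-level union of the two, lesion
#' anchoring of each candidate set, gene-set overrepresentation of the union,
#' promoter TRE analysis of the anchored genes, and the rank-based genotype
#' comparison of adduct burdens. All tabular outputs are written to `outDir`
#' with a JSON manifest of MD5 checksums; rerunning with the same config
#' reproduces the checksums.
#'
#' @param config configuration from [pipelineConfig()].
#' @param outDir output directory.
#' @param study optional pre-built [SimulatedStudy-class] (otherwise
#'   simulated from the config).
#' @return List: `summary` (DE counts per analysis and timepoint, union
#'   sizes, anchored counts and percentages, top enriched terms, significant
#'   TREs, adduct test table), `manifest` (file -> md5), `outDir`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, study = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(study)) {
    design <- studyDesign(nProbesets = as.integer(config$n_probesets),
                          probesPerProbeset =
                            as.integer(config$probes_per_probeset),
                          arraysPerCell = as.integer(config$arrays_per_cell),
                          timepointsH = config$timepoints_h)
    effects <- effectSpec(
      fracTreatmentDE = config$frac_treatment_de,
      fracGenotypeDE = config$frac_genotype_de,
      fracInteractionDE = config$frac_interaction_de,
      fracLabInconsistent = config$frac_lab_inconsistent,
      fracAnchored = config$frac_anchored,
      log2EffectSize = config$log2_effect_size,
      anchorStrength = config$anchor_strength,
      noiseSdLog2 = config$noise_sd_log2,
      siteShiftLog2 = config$site_shift_log2,
      seed = as.integer(config$seed))
    study <- simulateStudy(design, effects, lesionKinetics())
  }
  writeStudy(study, outDir)
  message(sprintf("simulate: %d probes x %d arrays", nrow(study@se),
                  ncol(study@se)))

  norm <- rmaNormalize(study@se, background = isTRUE(config$background))
  writeExpressionMatrix(assay(norm, "exprs"),
                        file.path(outDir, "normalized.tsv"),
                        idColumn = "probeset_id")

  results <- runDiffExpr(norm, alphaLab = config$alpha_lab)
  .writeTsv(as.data.frame(results), file.path(outDir, "diffexpr.tsv"))
  deKo <- callDE(results, "treatment_ko", fdr = config$fdr,
                 minFc = config$min_fc, label = "ko MAM-vs-vehicle")
  deGeno <- callDE(results, "interaction", fdr = config$fdr,
                   minFc = config$min_fc, label = "genotype-difference")
  unionGenes <- combineAnalyses(deKo, deGeno)
  writeLines(unionGenes, file.path(outDir, "union_genes.txt"))

  anchorOne <- function(deSet, stem) {
    if (!length(deSet@unionProbesets)) {
      return(list(result = NULL, anchored = character()))
    }
    a <- suppressWarnings(anchorGenes(
      norm, lesionTable(study), deSet,
      threshold = config$anchor_threshold,
      absolute = isTRUE(config$anchor_absolute)))
    .writeTsv(as.data.frame(a), file.path(outDir, paste0(stem, ".tsv")))
    anchored <- metadata(a)$anchoredProbesets
    writeLines(anchored, file.path(outDir, paste0(stem, "_genes.txt")))
    list(result = a, anchored = anchored)
  }
  ancKo <- anchorOne(deKo, "anchor_ko")
  ancGeno <- anchorOne(deGeno, "anchor_genotype")

  universe <- sort(unique(as.character(rowData(norm)$gene_id)))
  psToGene <- stats::setNames(as.character(rowData(norm)$gene_id),
                              rownames(norm))

  enrichTop <- NULL
  if (isTRUE(config$stages$enrich) && length(unionGenes)) {
    sets <- if (!is.null(config$gmt)) readGMT(config$gmt)
            else simulateGeneSets(universe, seed = config$seed + 2L)
    enr <- hypergeomEnrich(unionGenes, sets, universe)
    .writeTsv(enr, file.path(outDir, "enrichment.tsv"))
    enrichTop <- rankTerms(enr, config$enrich_top)
  }

  treTab <- NULL
  ancGenes <- sort(unique(psToGene[ancGeno$anchored]))
  if (isTRUE(config$stages$tre)) {
    motifs <- if (!is.null(config$motifs)) readMotifs(config$motifs)
              else list(consensusMotif("HNF-4", "AGGTCAaAGGTCA"),
                        consensusMotif("GATA-2", "NNGATANN"))
    if (!is.null(config$promoters)) {
      prom <- Biostrings::readDNAStringSet(config$promoters)
    } else {
      ## synthetic promoters: plant the first motif in a fraction of the
      ## anchored genes' promoters so the enrichment stage has signal
      prom <- simulatePromoters(universe,
                                width = as.integer(config$promoter_length),
                                seed = config$seed + 1L)
      if (length(ancGenes)) {
        planted <- simulatePromoters(
          ancGenes, width = as.integer(config$promoter_length),
          motif = motifs[[1]], plantFrac = config$tre_plant_frac,
          seed = config$seed + 3L)
        prom[names(planted)] <- planted
      }
    }
    ## reference scan of every promoter (no prevalence filter) for the
    ## enrichment null; the reported interaction matrix covers the candidate
    ## list, where the >5%-of-promoters rule applies
    imAll <- suppressMessages(buildInteractionMatrix(
      prom, motifs, prevalenceMin = -1))
    if (length(ancGenes)) {
      imCand <- suppressMessages(buildInteractionMatrix(
        prom, motifs, genes = intersect(ancGenes, names(prom)),
        prevalenceMin = config$prevalence_min))
      writeExpressionMatrix(imCand@hits, file.path(outDir, "tre_matrix.tsv"),
                            idColumn = "gene_id")
      keep <- intersect(colnames(imCand@hits), colnames(imAll@hits))
      if (length(keep)) {
        imTest <- imAll
        imTest@hits <- imAll@hits[, keep, drop = FALSE]
        treTab <- treEnrichment(imTest,
                                intersect(ancGenes, rownames(imAll@hits)),
                                rownames(imAll@hits),
                                alpha = config$alpha_tre)
        .writeTsv(treTab, file.path(outDir, "tre_enrichment.tsv"))
      }
    }
  }

  adduct <- NULL
  if (isTRUE(config$stages$adduct_stats)) {
    adduct <- suppressWarnings(
      adductStats(lesionTable(study), sampleSheet(study)))
    if (!is.null(adduct))
      .writeTsv(adduct, file.path(outDir, "adduct_stats.tsv"))
  }

  deCounts <- function(deSet) {
    c(vapply(deSet@perTimepoint, length, integer(1)),
      union = length(deSet@unionProbesets),
      genes = length(deSet@genes))
  }
  summary <- list(
    n_arrays = ncol(study@se),
    de_ko_mam_vs_vehicle = deCounts(deKo),
    de_genotype_difference = deCounts(deGeno),
    union_genes = length(unionGenes),
    anchored_ko = length(ancKo$anchored),
    anchored_genotype = length(ancGeno$anchored),
    anchored_percent_ko =
      if (length(deKo@unionProbesets))
        anchoredPercent(length(ancKo$anchored),
                        length(deKo@unionProbesets)) else NA_real_,
    anchored_percent_genotype =
      if (length(deGeno@unionProbesets))
        anchoredPercent(length(ancGeno$anchored),
                        length(deGeno@unionProbesets)) else NA_real_,
    enrich_top = enrichTop,
    tre_significant =
      if (!is.null(treTab)) treTab$motif[treTab$significant] else character(),
    adduct = adduct
  )
  jsonlite::write_json(
    list(parameters = unclass(config)[!vapply(config, is.null, logical(1))],
         de_counts = list(ko_mam_vs_vehicle = deCounts(deKo),
                          genotype_difference = deCounts(deGeno)),
         union_genes = length(unionGenes),
         anchored = list(ko = length(ancKo$anchored),
                         genotype = length(ancGeno$anchored))),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(outDir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  list(summary = summary, manifest = manifest, outDir = outDir)
}
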