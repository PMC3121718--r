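## Plain-text readers and writers for the pipeline's tabular interfaces:
## expression TSV (probes x samples), sample sheet CSV, lesion CSV,
## annotation TSV, truth-label CSV.

#' Read / write an expression matrix TSV
#'
#' Rows are probes (or probesets), columns samples; the first column holds
#' the row ids.
#'
#' @param path file path.
#' @return `readExpressionMatrix`: numeric matrix with row and column names.
#' @export
readExpressionMatrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readExpressionMatrix
#' @param x numeric matrix with unique row and column names.
#' @param idColumn name of the row-id column written first.
#' @export
writeExpressionMatrix <- function(x, path, idColumn = "probe_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  names(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample sheet CSV
#'
#' Requires columns `sample_id`, `site`, `genotype`, `treatment`,
#' `timepoint_h`, `tissue`, `animal_id`.
#'
#' @param path CSV file.
#' @return data.frame keyed by `sample_id`.
#' @export
readSampleSheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "site", "genotype", "treatment", "timepoint_h",
            "tissue", "animal_id")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  rownames(sheet) <- sheet$sample_id
  sheet
}

#' Read a lesion table CSV
#'
#' Requires columns `animal_id`, `tissue`, `timepoint_h`, `lesions_per_1e8`,
#' `censored`; burdens must be non-negative.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readLesionTable <- function(path) {
  les <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "tissue", "timepoint_h", "lesions_per_1e8",
            "censored")
  miss <- setdiff(need, names(les))
  if (length(miss))
    stop("lesion table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(les$lesions_per_1e8 < 0)
  if (length(bad))
    stop("negative lesion burden at row ", bad[1])
  les$censored <- as.logical(les$censored)
  les
}

#' Assemble a probe-level experiment from its tabular parts
#'
#' @param exprs probes x samples numeric matrix (raw intensities).
#' @param sheet sample sheet ([readSampleSheet()] layout); must cover every
#'   expression column.
#' @param annotation data.frame `probe_id`, `probeset_id`, `gene_id` covering
#'   every expression row.
#' @return Probe-level [SummarizedExperiment::SummarizedExperiment].
#' @export
buildProbeExperiment <- function(exprs, sheet, annotation) {
  if (!all(colnames(exprs) %in% sheet$sample_id))
    stop("sample sheet does not cover every expression column")
  if (!all(rownames(exprs) %in% annotation$probe_id))
    stop("annotation does not cover every expression row")
  sheet <- sheet[match(colnames(exprs), sheet$sample_id), , drop = FALSE]
  annotation <- annotation[match(rownames(exprs), annotation$probe_id), ,
                           drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(exprs = exprs),
    rowData = DataFrame(annotation),
    colData = DataFrame(sheet, row.names = sheet$sample_id))
  metadata(se)$scale <- "raw"
  se
}

#' Write all tables of a simulated study
#'
#' Emits `expression.tsv` (probe-level raw intensities), `sample_sheet.csv`,
#' `lesions.csv`, `truth.csv` and `annotation.tsv` into `dir`.
#'
#' @param study a [SimulatedStudy-class].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.csv"),
    lesions = file.path(dir, "lesions.csv"),
    truth = file.path(dir, "truth.csv"),
    annotation = file.path(dir, "annotation.tsv"))
  writeExpressionMatrix(assay(study@se, "exprs"), paths["expression"])
  utils::write.csv(sampleSheet(study), paths["sample_sheet"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(lesionTable(study), paths["lesions"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(truthLabels(study), paths["truth"], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(as.data.frame(rowData(study@se)), paths["annotation"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
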