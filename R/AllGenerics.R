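#' Accessors for SimulatedStudy and TREInteractionMatrix
#'
#' `sampleSheet` returns the per-array factor table (site, genotype,
#' treatment, timepoint_h, tissue, animal_id); `lesionTable` the per-animal
#' lesion burdens; `truthLabels` the planted-signal labels;
#' `probeExperiment` the probe-level SummarizedExperiment; `nArrays` the
#' total array count of a design; `interactionMatrix` the binary gene x motif
#' hit matrix.
#'
#' @param x a [SimulatedStudy-class], [StudyDesign-class] or
#'   [TREInteractionMatrix-class] object as appropriate.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname accessors
#' @export
setGeneric("lesionTable", function(x) standardGeneric("lesionTable"))

#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname accessors
#' @export
setGeneric("probeExperiment", function(x) standardGeneric("probeExperiment"))

#' @rdname accessors
#' @export
setGeneric("nArrays", function(x) standardGeneric("nArrays"))

#' @rdname accessors
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' @rdname accessors
setMethod("sampleSheet", "SimulatedStudy", function(x)
  as.data.frame(colData(x@se)))

#' @rdname accessors
setMethod("lesionTable", "SimulatedStudy", function(x) x@lesions)

#' @rdname accessors
setMethod("truthLabels", "SimulatedStudy", function(x) x@truth)

#' @rdname accessors
setMethod("probeExperiment", "SimulatedStudy", function(x) x@se)

#' @rdname accessors
setMethod("nArrays", "StudyDesign", function(x)
  length(x@sites) * length(x@genotypes) * length(x@treatments) *
    length(x@timepointsH) * x@arraysPerCell)

#' @rdname accessors
setMethod("interactionMatrix", "TREInteractionMatrix", function(x) x@hits)

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", nArrays(object), "arrays\n")
  cat("  sites:      ", paste(object@sites, collapse = ", "), "\n")
  cat("  genotypes:  ", paste(object@genotypes, collapse = ", "), "\n")
  cat("  treatments: ", paste(object@treatments, collapse = ", "), "\n")
  cat("  timepoints: ", paste(object@timepointsH, collapse = ", "), "h\n")
  cat("  arrays/cell:", object@arraysPerCell, "\n")
  cat("  probesets:  ", object@nProbesets, "x", object@probesPerProbeset,
      "probes\n")
})

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy:", nrow(object@se), "probes x", ncol(object@se),
      "arrays\n")
  tab <- table(object@truth$category)
  if (length(tab)) {
    cat("  planted:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  } else cat("  planted: none (null study)\n")
  cat("  lesions:", nrow(object@lesions), "measurements (",
      sum(object@lesions$censored), "censored at MDQ )\n")
})

setMethod("show", "DEGeneSet", function(object) {
  cat("DEGeneSet '", object@label, "': ", length(object@unionProbesets),
      " probesets / ", length(object@genes),
      " genes at >=1 timepoint\n", sep = "")
  for (tp in names(object@perTimepoint))
    cat("  ", tp, "h: ", length(object@perTimepoint[[tp]]),
        " probesets\n", sep = "")
})

setMethod("show", "Motif", function(object) {
  if (object@kind == "consensus")
    cat("Motif", object@name, ": consensus", object@consensus,
        "| strand:", object@strand, "\n")
  else
    cat("Motif", object@name, ": PWM width", ncol(object@pwm),
        ", log-odds threshold", object@threshold,
        "| strand:", object@strand, "\n")
})

setMethod("show", "TREInteractionMatrix", function(object) {
  cat("TREInteractionMatrix:", nrow(object@hits), "genes x",
      ncol(object@hits), "motifs (", length(object@dropped),
      "dropped below prevalence threshold )\n")
})
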