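#' @rdname ExpressionMatrix-class
#' @param object an object.
#' @export
setGeneric("platformOf", function(object) standardGeneric("platformOf"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("platformOf", "ExpressionMatrix", function(object) object@platform)

#' @rdname ActivityMatrix-class
#' @param object an \linkS4class{ActivityMatrix}.
#' @export
setGeneric("activityRaw", function(object) standardGeneric("activityRaw"))

#' @rdname ActivityMatrix-class
#' @export
setMethod("activityRaw", "ActivityMatrix", function(object) assay(object, "raw"))

#' @rdname ActivityMatrix-class
#' @export
setGeneric("activityNorm", function(object) standardGeneric("activityNorm"))

#' @rdname ActivityMatrix-class
#' @export
setMethod("activityNorm", "ActivityMatrix",
          function(object) assay(object, "normalized"))

#' @rdname FeatureSet-class
#' @param object an object.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname FeatureSet-class
#' @export
setMethod("geneIds", "FeatureSet", function(object) object@genes)

#' @rdname FeatureSet-class
#' @export
setGeneric("featureLevel", function(object) standardGeneric("featureLevel"))

#' @rdname FeatureSet-class
#' @export
setMethod("featureLevel", "FeatureSet", function(object) object@level)

#' @rdname FeatureSet-class
#' @export
setGeneric("parentPathway", function(object) standardGeneric("parentPathway"))

#' @rdname FeatureSet-class
#' @export
setMethod("parentPathway", "FeatureSet", function(object) object@parent)

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet '%s' (%s%s): %d genes\n", object@id, object@level,
              if (nzchar(object@parent)) paste0(", parent ", object@parent) else "",
              length(object@genes)))
  gshow <- utils::head(object@genes, 6L)
  cat("  ", paste(gshow, collapse = " "),
      if (length(object@genes) > 6L) "..." else "", "\n")
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult (%s-effect, %d studies)\n", object@model,
              object@df + 1L))
  cat(sprintf("  pooled HR %.3f [%.3f, %.3f], p = %.3g\n",
              exp(object@logHR), object@ci[1], object@ci[2], object@p))
  cat(sprintf("  Q = %.3f (df %d), I2 = %.1f%%, tau2 = %.4f\n",
              object@Q, object@df, object@I2, object@tau2))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d cohorts x %d samples, %d genes\n",
    "  planted set of %d genes, log HR %.2f per SD of activity\n",
    "  baseline hazard %.3f, censor rate %.2f, classical fraction %.2f\n",
    "  IC50 rho %.2f (%d cell lines, %d drugs), noise SD %.2f, seed %d\n"),
    object@n_cohorts, object@samples_per_cohort, object@n_genes,
    object@planted_set_size, object@planted_log_hr, object@baseline_hazard,
    object@censor_rate, object@classical_fraction, object@ic50_rho,
    object@n_cell_lines, length(object@drugs), object@noise_sd, object@seed))
})

setMethod("show", "SyntheticCohortBundle", function(object) {
  cat(sprintf("SyntheticCohortBundle: %d cohorts (%s)\n",
              length(object@expression),
              paste(names(object@expression), collapse = ", ")))
  cat(sprintf("  planted subpathway '%s'; %d feature sets; %d cell lines; %d drugs\n",
              object@plantedId, length(object@featureSets),
              ncol(object@cellLineExpression),
              length(unique(object@drugTable$drug))))
})
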