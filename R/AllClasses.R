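#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors metadata DataFrame SimpleList
NULL

.PLATFORMS <- c("microarray", "rnaseq")
.LEVELS <- c("gene", "subpathway", "pathway")

#' ExpressionMatrix: genes x samples expression with a platform tag
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' \code{"exprs"} (genes in rows, samples in columns) plus the profiling
#' platform (\code{"microarray"} for log-scale intensities, \code{"rnaseq"}
#' for counts). Downstream activity scoring is rank-based per sample, so any
#' within-sample monotone scale is acceptable; values must be finite and ids
#' unique.
#'
#' @slot platform character, one of \code{"microarray"}, \code{"rnaseq"}.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(platform = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@platform) != 1L || !object@platform %in% .PLATFORMS)
    msg <- c(msg, sprintf("platform must be one of: %s",
                          paste(.PLATFORMS, collapse = ", ")))
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- assay(object, "exprs")
    if (anyNA(m) || any(!is.finite(m)))
      msg <- c(msg, "expression values must be finite (pre-impute missing values)")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param platform \code{"microarray"} or \code{"rnaseq"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' ExpressionMatrix(m, platform = "microarray")
#' @export
ExpressionMatrix <- function(values, platform = "microarray") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  new("ExpressionMatrix",
      SummarizedExperiment(assays = list(exprs = values)),
      platform = platform)
}

#' FeatureSet: a named gene set at gene, subpathway or pathway level
#'
#' Subpathways carry ids of the form \code{"<pathway>_<j>"} and record their
#' parent pathway; pathway-level sets carry the pathway id itself; gene-level
#' features are singletons named by the gene.
#'
#' @slot id feature identifier.
#' @slot level one of \code{"gene"}, \code{"subpathway"}, \code{"pathway"}.
#' @slot genes character vector of member gene ids (nonempty, unique).
#' @slot parent parent pathway id, or \code{""}.
#' @export
setClass("FeatureSet",
  representation(id = "character", level = "character",
                 genes = "character", parent = "character"))

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id)) msg <- c(msg, "id must be a nonempty string")
  if (length(object@level) != 1L || !object@level %in% .LEVELS)
    msg <- c(msg, sprintf("level must be one of: %s", paste(.LEVELS, collapse = ", ")))
  if (length(object@genes) == 0L) msg <- c(msg, "genes must be nonempty")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate genes in set")
  if (length(msg)) msg else TRUE
})

#' @param id,level,genes,parent see slots.
#' @rdname FeatureSet-class
#' @export
FeatureSet <- function(id, level, genes, parent = "") {
  new("FeatureSet", id = as.character(id), level = level,
      genes = as.character(genes), parent = as.character(parent))
}

#' ActivityMatrix: per-sample feature activities
#'
#' Extends \linkS4class{SummarizedExperiment} with two assays:
#' \code{"raw"} (the in-set minus out-of-set rank-weight contrast, or the
#' expression value itself for gene-level features) and \code{"normalized"}
#' (per-feature z-scores across samples, population SD). \code{rowData}
#' records the per-feature normalization mean and SD, the feature level and
#' parent, the number of set genes absent from the expression universe, and a
#' flag for constant raw rows (normalized to all zeros).
#'
#' @export
setClass("ActivityMatrix", contains = "SummarizedExperiment")

setValidity("ActivityMatrix", function(object) {
  msg <- character()
  need <- c("raw", "normalized")
  if (!all(need %in% names(assays(object))))
    msg <- c(msg, "assays 'raw' and 'normalized' are required")
  rd <- rowData(object)
  for (col in c("level", "mean", "sd", "constant", "dropped"))
    if (!col %in% names(rd)) msg <- c(msg, sprintf("rowData column '%s' missing", col))
  if (length(msg)) msg else TRUE
})

#' MetaResult: a pooled hazard-ratio estimate with heterogeneity diagnostics
#'
#' @slot logHR pooled log hazard ratio.
#' @slot se standard error of the pooled log HR.
#' @slot ci numeric length-2, 95\% CI on the HR scale.
#' @slot Q Cochran's Q about the fixed-effect pooled value.
#' @slot df degrees of freedom (number of studies minus one).
#' @slot I2 heterogeneity percentage, \code{max(0, (Q - df)/Q) * 100}.
#' @slot tau2 DerSimonian-Laird between-study variance (floored at 0).
#' @slot model \code{"fixed"} or \code{"random"}.
#' @slot weights named per-study weights (sum to 1).
#' @slot p two-sided Wald p-value for the pooled log HR.
#' @export
setClass("MetaResult",
  representation(logHR = "numeric", se = "numeric", ci = "numeric",
                 Q = "numeric", df = "numeric", I2 = "numeric",
                 tau2 = "numeric", model = "character", weights = "numeric",
                 p = "numeric"))

setValidity("MetaResult", function(object) {
  msg <- character()
  if (!object@model %in% c("fixed", "random")) msg <- c(msg, "model must be 'fixed' or 'random'")
  if (length(object@ci) != 2L) msg <- c(msg, "ci must have length 2")
  if (object@I2 < 0 || object@I2 > 100) msg <- c(msg, "I2 must lie in [0, 100]")
  if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic multi-cohort generator
#'
#' Defaults emulate an eleven-cohort pancreatic-cancer study design: seven
#' training and four test cohorts of 500 patients each, a ten-gene planted
#' subpathway acting as a protective covariate (log HR -0.5 per SD of its
#' normalized activity), ~30\% independent censoring, a "classical" molecular
#' subtype covering ~45\% of samples, and cell-line IC50 values with rank
#' correlation -0.5 against planted activity within the classical subset.
#'
#' @slot n_cohorts total number of patient cohorts.
#' @slot samples_per_cohort samples in each cohort.
#' @slot n_genes size of the shared gene universe.
#' @slot planted_set_size number of genes in the planted subpathway.
#' @slot planted_log_hr log hazard ratio per 1 SD of normalized planted
#'   activity; negative is protective.
#' @slot baseline_hazard events per time unit (months) for a sample at mean
#'   activity.
#' @slot censor_rate target fraction of censored samples, in [0, 1].
#' @slot classical_fraction fraction of samples/cell lines labeled
#'   \code{"classical"}, in [0, 1].
#' @slot ic50_rho target Spearman correlation of log IC50 with planted
#'   activity within classical cell lines, in [-1, 1].
#' @slot noise_sd SD of the i.i.d. per-gene log-expression noise (> 0).
#' @slot seed integer RNG seed; identical config + seed gives bit-identical
#'   bundles.
#' @slot factor_loading shift (in log-expression units) of planted genes per
#'   SD of the latent per-sample factor.
#' @slot cohort_shift_sd SD of cohort-specific per-gene mean shifts
#'   (inter-study heterogeneity in expression; 0 disables).
#' @slot n_decoy_sets number of random decoy subpathways of the planted size.
#' @slot rnaseq_cohorts indices of cohorts simulated as RNA-seq (counts);
#'   the rest are microarray-flavored log intensities.
#' @slot n_cell_lines number of cell lines in the drug-sensitivity table.
#' @slot drugs drug names for the IC50 table (>= 2).
#' @export
setClass("SimulationConfig",
  representation(n_cohorts = "integer", samples_per_cohort = "integer",
                 n_genes = "integer", planted_set_size = "integer",
                 planted_log_hr = "numeric", baseline_hazard = "numeric",
                 censor_rate = "numeric", classical_fraction = "numeric",
                 ic50_rho = "numeric", noise_sd = "numeric", seed = "integer",
                 factor_loading = "numeric", cohort_shift_sd = "numeric",
                 n_decoy_sets = "integer", rnaseq_cohorts = "integer",
                 n_cell_lines = "integer", drugs = "character"))

setValidity("SimulationConfig", function(object) {
  bad <- function(field) sprintf("invalid configuration field '%s'", field)
  msg <- character()
  if (object@n_cohorts < 1L) msg <- c(msg, bad("n_cohorts"))
  if (object@samples_per_cohort < 4L) msg <- c(msg, bad("samples_per_cohort"))
  if (object@n_genes < 2L) msg <- c(msg, bad("n_genes"))
  if (object@planted_set_size < 1L || object@planted_set_size >= object@n_genes)
    msg <- c(msg, bad("planted_set_size"))
  if (object@baseline_hazard <= 0) msg <- c(msg, bad("baseline_hazard"))
  if (object@censor_rate < 0 || object@censor_rate >= 1) msg <- c(msg, bad("censor_rate"))
  if (object@classical_fraction < 0 || object@classical_fraction > 1)
    msg <- c(msg, bad("classical_fraction"))
  if (object@ic50_rho < -1 || object@ic50_rho > 1) msg <- c(msg, bad("ic50_rho"))
  if (object@noise_sd <= 0) msg <- c(msg, bad("noise_sd"))
  if (object@cohort_shift_sd < 0) msg <- c(msg, bad("cohort_shift_sd"))
  if (object@n_decoy_sets < 0L) msg <- c(msg, bad("n_decoy_sets"))
  if (length(object@rnaseq_cohorts) &&
      (any(object@rnaseq_cohorts < 1L) || any(object@rnaseq_cohorts > object@n_cohorts)))
    msg <- c(msg, bad("rnaseq_cohorts"))
  if (object@n_cell_lines < 8L) msg <- c(msg, bad("n_cell_lines"))
  if (length(object@drugs) < 2L) msg <- c(msg, bad("drugs"))
  if (length(msg)) msg else TRUE
})

#' SyntheticCohortBundle: generated multi-cohort inputs
#'
#' @slot expression named list of \linkS4class{ExpressionMatrix}, one per cohort.
#' @slot survival named list of survival data.frames
#'   (\code{sample_id, time, event, subtype, age, sex}).
#' @slot featureSets list of \linkS4class{FeatureSet} (planted set first).
#' @slot plantedId id of the planted subpathway.
#' @slot cellLineExpression \linkS4class{ExpressionMatrix} for cell lines.
#' @slot drugTable long data.frame \code{cell_line, drug, ic50, subtype}.
#' @slot responseTable data.frame \code{sample_id, cohort, response} with
#'   RECIST-style labels CR/PR/SD/PD.
#' @slot latentFactors named list of per-sample latent factor vectors
#'   (ground truth, for diagnostics).
#' @slot config the \linkS4class{SimulationConfig} used.
#' @export
setClass("SyntheticCohortBundle",
  representation(expression = "list", survival = "list",
                 featureSets = "list", plantedId = "character",
                 cellLineExpression = "ExpressionMatrix",
                 drugTable = "data.frame", responseTable = "data.frame",
                 latentFactors = "list", config = "SimulationConfig"))

setValidity("SyntheticCohortBundle", function(object) {
  msg <- character()
  if (length(object@expression) != length(object@survival))
    msg <- c(msg, "expression and survival cohort lists differ in length")
  genes <- unique(unlist(lapply(object@featureSets, function(fs) fs@genes)))
  for (nm in names(object@expression)) {
    if (!all(genes %in% rownames(object@expression[[nm]])))
      msg <- c(msg, sprintf("cohort %s is missing feature-set genes", nm))
    sv <- object@survival[[nm]]
    if (!all(sv$event %in% c(0, 1))) msg <- c(msg, sprintf("cohort %s: event must be 0/1", nm))
    if (any(sv$time <= 0)) msg <- c(msg, sprintf("cohort %s: times must be positive", nm))
  }
  if (any(object@drugTable$ic50 <= 0)) msg <- c(msg, "IC50 values must be positive")
  if (length(msg)) msg else TRUE
})
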