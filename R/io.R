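#' @importFrom utils read.table write.table head combn
#' @importFrom yaml write_yaml read_yaml
NULL

#' Read and write expression TSV
#'
#' First column is the gene id (header \code{gene_id}), remaining columns
#' are sample ids.
#'
#' @param path file path.
#' @param platform platform tag for the returned object.
#' @return \code{readExpressionTSV}: an \linkS4class{ExpressionMatrix}.
#' @export
readExpressionTSV <- function(path, platform = "microarray") {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  ExpressionMatrix(m, platform = platform)
}

#' @param expr an \linkS4class{ExpressionMatrix}.
#' @rdname readExpressionTSV
#' @export
writeExpressionTSV <- function(expr, path) {
  m <- assay(expr, "exprs")
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write survival tables
#'
#' Columns: \code{sample_id, time, event}, then any covariate columns
#' (typically \code{subtype, age, sex}).
#'
#' @param path file path.
#' @return \code{readSurvivalTSV}: a data.frame.
#' @export
readSurvivalTSV <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @param surv survival data.frame.
#' @rdname readSurvivalTSV
#' @export
writeSurvivalTSV <- function(surv, path) {
  write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: set id, description (the parent pathway id, or the
#' level for gene-level sets), then tab-separated member genes.
#'
#' @param path file path.
#' @param level feature level to assign to all read sets.
#' @return \code{readGMT}: a named list of \linkS4class{FeatureSet}.
#' @export
readGMT <- function(path, level = "subpathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    FeatureSet(parts[1L], level, parts[-(1:2)],
               parent = if (parts[2L] %in% .LEVELS) "" else parts[2L])
  })
  names(sets) <- vapply(sets, function(f) f@id, character(1))
  sets
}

#' @param sets list of \linkS4class{FeatureSet}.
#' @rdname readGMT
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(sets, function(f) {
    desc <- if (nzchar(f@parent)) f@parent else f@level
    paste(c(f@id, desc, f@genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a study-estimate table for meta-analysis
#'
#' Columns: \code{study, loghr, se} and optionally \code{subgroup}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readStudyEstimates <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a synthetic bundle to a directory
#'
#' Writes per-cohort expression and survival TSVs, the feature sets as GMT,
#' the drug-sensitivity and response tables as TSV, the cell-line
#' expression, and a YAML manifest listing cohorts, platform tags, the
#' planted set id and the generator configuration.
#'
#' @param bundle a \linkS4class{SyntheticCohortBundle}.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
writeCohortBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohorts <- names(bundle@expression)
  for (nm in cohorts) {
    writeExpressionTSV(bundle@expression[[nm]],
                       file.path(dir, paste0(nm, "_expr.tsv")))
    writeSurvivalTSV(bundle@survival[[nm]],
                     file.path(dir, paste0(nm, "_surv.tsv")))
  }
  writeGMT(bundle@featureSets, file.path(dir, "feature_sets.gmt"))
  writeExpressionTSV(bundle@cellLineExpression,
                     file.path(dir, "cell_lines_expr.tsv"))
  write.table(bundle@drugTable, file.path(dir, "drugs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle@responseTable, file.path(dir, "response.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- bundle@config
  manifest <- list(
    cohorts = lapply(cohorts, function(nm) list(
      id = nm, platform = platformOf(bundle@expression[[nm]]),
      expression = paste0(nm, "_expr.tsv"),
      survival = paste0(nm, "_surv.tsv"))),
    feature_sets = "feature_sets.gmt",
    planted_id = bundle@plantedId,
    cell_lines = "cell_lines_expr.tsv",
    drugs = "drugs.tsv", response = "response.tsv",
    config = lapply(setNames(slotNames(cfg), slotNames(cfg)),
                    function(s) slot(cfg, s)))
  path <- file.path(dir, "manifest.yaml")
  write_yaml(manifest, path)
  invisible(path)
}

#' Read a bundle directory written by \code{writeCohortBundle}
#'
#' @param dir bundle directory containing \code{manifest.yaml}.
#' @return List with \code{expression} (ExpressionMatrix per cohort),
#'   \code{survival}, \code{featureSets}, \code{drugTable},
#'   \code{responseTable}, \code{cellLineExpression}, \code{plantedId},
#'   \code{manifest}.
#' @export
readCohortBundle <- function(dir) {
  mpath <- file.path(dir, "manifest.yaml")
  if (!file.exists(mpath)) stop("manifest not found: ", mpath)
  manifest <- read_yaml(mpath)
  expression <- list(); survival <- list()
  for (co in manifest$cohorts) {
    fe <- file.path(dir, co$expression)
    if (!file.exists(fe)) stop("missing cohort file: ", fe)
    expression[[co$id]] <- readExpressionTSV(fe, platform = co$platform)
    survival[[co$id]] <- readSurvivalTSV(file.path(dir, co$survival))
  }
  list(expression = expression, survival = survival,
       featureSets = readGMT(file.path(dir, manifest$feature_sets)),
       cellLineExpression = readExpressionTSV(
         file.path(dir, manifest$cell_lines)),
       drugTable = read.table(file.path(dir, manifest$drugs), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE),
       responseTable = read.table(file.path(dir, manifest$response),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE),
       plantedId = manifest$planted_id, manifest = manifest)
}
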