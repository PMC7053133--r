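#' Enumerate training-cohort combinations
#'
#' All distinct subsets of the given sizes, in deterministic order (by size,
#' then lexicographically over sorted cohort ids). Seven cohorts with sizes
#' \{5, 6, 7\} give the 21 + 7 + 1 = 29 combinations used for integrated
#' scoring.
#'
#' @param cohort_ids character vector of cohort ids.
#' @param sizes integer vector of subset sizes (each <= number of cohorts).
#' @return Named list of character vectors; names like \code{"size5_01"}.
#' @export
enumerateCombinations <- function(cohort_ids, sizes = c(5L, 6L, 7L)) {
  cohort_ids <- sort(unique(as.character(cohort_ids)))
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L) || any(sizes > length(cohort_ids)))
    stop("combination size exceeds the number of cohorts")
  out <- list()
  for (s in sizes) {
    combs <- utils::combn(cohort_ids, s, simplify = FALSE)
    names(combs) <- sprintf("size%d_%02d", s, seq_along(combs))
    out <- c(out, combs)
  }
  out
}

#' Integrated prognostic score
#'
#' The mean of \eqn{-\log_{10} p} over the per-cohort Cox p-values of one
#' feature within one training-set combination. P-values below 1e-300 are
#' clipped to 1e-300 before the log.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return The ipScore (>= 0).
#' @examples
#' ipScore(c(0.1, 0.01, 0.001))  # 2
#' @export
ipScore <- function(pvalues) {
  if (length(pvalues) == 0L) stop("at least one p-value is required")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  mean(-log10(pmax(pvalues, 1e-300)))
}

#' Rank features by ipScore and keep the top k
#'
#' Descending ipScore; ties are broken by lexicographic feature id so the
#' ranking is deterministic. If fewer than \code{k} features are scored, all
#' are returned with a warning.
#'
#' @param scores named numeric vector of ipScores (names = feature ids).
#' @param k number of features to keep (default 30).
#' @return Character vector of feature ids, best first.
#' @export
rankTopK <- function(scores, k = 30L) {
  if (is.null(names(scores))) stop("scores must be named by feature id")
  ord <- order(-scores, names(scores))
  ids <- names(scores)[ord]
  if (length(ids) < k) {
    warning(sprintf("only %d features scored; returning all", length(ids)))
    return(ids)
  }
  ids[seq_len(k)]
}

#' Serial cumulative signature sets from a ranked top-30 list
#'
#' The 28 prefix sets of sizes 3 through 30 (1st-3rd, 1st-4th, ...,
#' 1st-30th). A shorter ranked list yields the prefix sets up to its length,
#' with a warning.
#'
#' @param ranked character vector of feature ids, best first.
#' @return Named list of character vectors (\code{"set03"} ... \code{"set30"}).
#' @export
serialSets <- function(ranked) {
  if (length(ranked) < 30L)
    warning(sprintf("ranked list has %d (< 30) features; returning sets up to that size",
                    length(ranked)))
  top <- utils::head(ranked, 30L)
  if (length(top) < 3L) stop("ranked list must contain at least 3 features")
  sizes <- 3:length(top)
  out <- lapply(sizes, function(s) top[seq_len(s)])
  names(out) <- sprintf("set%02d", sizes)
  out
}

#' Assess a signature set on one cohort
#'
#' Samples are clustered into two groups by K-means (K = 2, Euclidean) on
#' the set's activity rows, features standardized; initialization is
#' deterministic at the per-feature 25th/75th percentile points. The groups
#' are then compared by a log-rank test. A singleton set reduces to
#' \code{\link{splitTwoGroups}} on that feature.
#'
#' @param feature_ids character vector of feature ids in \code{activity}.
#' @param activity an \linkS4class{ActivityMatrix} (normalized assay used).
#' @param surv survival data.frame aligned with the activity columns (or
#'   carrying \code{sample_id}).
#' @return List with \code{p}, \code{chisq}, and the group \code{labels}.
#' @export
assessSetOnCohort <- function(feature_ids, activity, surv) {
  A <- activityNorm(activity)
  missing <- setdiff(feature_ids, rownames(A))
  if (length(missing))
    stop(sprintf("features not in activity matrix: %s",
                 paste(missing, collapse = ", ")))
  if (!is.null(surv$sample_id)) {
    A <- A[, as.character(surv$sample_id), drop = FALSE]
  }
  X <- t(A[feature_ids, , drop = FALSE])
  # standardize features (columns); drop degenerate ones
  keep <- apply(X, 2L, stats::var) > 0
  if (!any(keep)) stop("all selected features are constant across samples")
  X <- scale(X[, keep, drop = FALSE])
  if (ncol(X) == 1L) {
    labels <- splitTwoGroups(drop(X))
  } else {
    centers <- rbind(apply(X, 2L, quantile, 0.25),
                     apply(X, 2L, quantile, 0.75))
    if (all(centers[1, ] == centers[2, ]))
      stop("degenerate activity: identical quantile centers")
    km <- kmeans(X, centers = centers, iter.max = 100, algorithm = "Lloyd")
    means <- tapply(rowMeans(X), km$cluster, mean)
    high <- as.integer(names(means)[which.max(means)])
    labels <- ifelse(km$cluster == high, "high", "low")
    names(labels) <- rownames(X)
  }
  lr <- logrankTest(labels, surv)
  list(p = lr$p, chisq = lr$chisq, labels = labels)
}

#' Frequency-based signature selection over top-30 lists
#'
#' Counts, for every feature, the number of combinations whose top-30 list
#' contains it, and selects features whose count meets the cutoff (default
#' >= 20 of the 29 combinations). \code{exclude_self = TRUE} instead counts
#' appearances in the other lists only (count over n-1 lists for features
#' present in at least one list).
#'
#' @param top_lists list of character vectors (one top-30 list per
#'   combination).
#' @param cutoff selection cutoff on the count (default 20).
#' @param exclude_self logical; count each feature's appearances excluding
#'   the list under consideration.
#' @return data.frame \code{feature, count, selected}, sorted by descending
#'   count then feature id.
#' @export
frequencySelect <- function(top_lists, cutoff = 20L, exclude_self = FALSE) {
  if (length(top_lists) < 1L) stop("at least one top list is required")
  feats <- sort(unique(unlist(top_lists)))
  count <- vapply(feats, function(f)
    sum(vapply(top_lists, function(l) f %in% l, logical(1))), integer(1))
  if (exclude_self) count <- pmax(count - 1L, 0L)
  out <- data.frame(feature = feats, count = as.integer(count),
                    selected = count >= cutoff, stringsAsFactors = FALSE)
  out[order(-out$count, out$feature), , drop = FALSE]
}

#' Hypergeometric relevance enrichment
#'
#' Upper-tail hypergeometric probability \eqn{P(X \ge \mathrm{overlap})} of
#' the observed overlap between a candidate gene list and a reference gene
#' catalogue within a common gene universe.
#'
#' @param candidate_genes,reference_genes character vectors (subsets of
#'   \code{universe}).
#' @param universe character vector of all considered genes (nonempty).
#' @return List with \code{p}, \code{overlap}, and the three set sizes.
#' @export
relevanceEnrichment <- function(candidate_genes, reference_genes, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  cand <- unique(intersect(candidate_genes, universe))
  ref <- unique(intersect(reference_genes, universe))
  ov <- length(intersect(cand, ref))
  p <- if (ov == 0L) 1 else
    phyper(ov - 1L, length(ref), length(universe) - length(ref),
           length(cand), lower.tail = FALSE)
  list(p = p, overlap = ov, n_candidate = length(cand),
       n_reference = length(ref), n_universe = length(universe))
}

#' Shared genes between two feature sets
#'
#' Utility for reporting gene overlap between pathway/subpathway signatures.
#'
#' @param a,b \linkS4class{FeatureSet} objects or character gene vectors.
#' @return List with \code{genes} (the intersection), \code{n}, and the
#'   fraction of \code{b}'s genes covered by \code{a}.
#' @export
sharedGenes <- function(a, b) {
  ga <- if (is(a, "FeatureSet")) geneIds(a) else as.character(a)
  gb <- if (is(b, "FeatureSet")) geneIds(b) else as.character(b)
  common <- intersect(ga, gb)
  list(genes = common, n = length(common),
       fraction_of_b = length(common) / length(unique(gb)))
}
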