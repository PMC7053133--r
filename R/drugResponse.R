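#' Spearman correlation of signature activity with IC50
#'
#' Rank correlation (average-rank ties) between per-cell-line activity and
#' drug IC50. IC50 is log-transformed before correlating; the rank
#' correlation is invariant to this, but the logged values standardize
#' exported tables. A constant input vector leaves the correlation
#' undefined: \code{NA} is returned with a flag.
#'
#' @param activity numeric vector of signature activities.
#' @param ic50 positive numeric vector of IC50 values, same length (>= 4).
#' @return List with \code{rho}, \code{n}, \code{flag}.
#' @export
spearmanActivityIC50 <- function(activity, ic50) {
  if (length(activity) != length(ic50)) stop("length mismatch")
  keep <- is.finite(activity) & is.finite(ic50)
  x <- activity[keep]; y <- ic50[keep]
  if (length(x) < 4L) stop("at least 4 paired observations are required")
  if (any(y <= 0)) stop("IC50 values must be positive")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(rho = NA_real_, n = length(x), flag = "constant_input"))
  list(rho = cor(x, log(y), method = "spearman"), n = length(x), flag = "")
}

#' Subtype permutation test of an activity-IC50 correlation
#'
#' The observed Spearman correlation is computed on the designated subtype
#' subset (e.g. classical cell lines). B random subsets of the same size are
#' then drawn without replacement from all samples, and N counts the null
#' correlations strictly less than the observed one; \eqn{p = N/B}. This is
#' a left-tail test, appropriate when the observed correlation is negative
#' (greater activity, greater drug sensitivity); for a positive observed
#' correlation use \code{tail = "two.sided"} or interpret \eqn{1 - p}.
#' Random subsets may coincide with the true subtype subset; they are
#' retained.
#'
#' @param activity,ic50 per-sample vectors over all samples.
#' @param subtype_mask logical vector marking the subtype subset (at least
#'   2 and fewer than all samples; sizes below 4 give a degenerate rank
#'   correlation and are warned about but allowed, so small subsets can be
#'   checked against exhaustive enumeration).
#' @param B number of permutations (default 10000).
#' @param seed integer RNG seed (the draw is deterministic given the seed).
#' @param tail \code{"left"} (the N/B rule) or \code{"two.sided"}.
#' @return List: \code{rho} (observed), \code{B}, \code{N}, \code{p},
#'   \code{n_subset}, \code{seed}, \code{tail}.
#' @export
subtypePermutationTest <- function(activity, ic50, subtype_mask, B = 10000L,
                                   seed = 1L, tail = c("left", "two.sided")) {
  tail <- match.arg(tail)
  n <- length(activity)
  if (length(ic50) != n || length(subtype_mask) != n) stop("length mismatch")
  m <- sum(subtype_mask)
  if (m < 2L || m >= n) stop("subtype subset must have >= 2 samples and be a proper subset")
  if (m < 4L) warning("subtype subset smaller than 4: correlation is degenerate")
  ly <- log(ic50)
  obs <- cor(activity[subtype_mask], ly[subtype_mask], method = "spearman")
  null <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, m)
      cor(activity[idx], ly[idx], method = "spearman")
    }, numeric(1))
  })
  N <- sum(null < obs)
  p <- if (tail == "left") N / B else min(1, 2 * min(N, sum(null > obs)) / B)
  list(rho = obs, B = as.integer(B), N = as.integer(N), p = p,
       n_subset = m, seed = seed, tail = tail)
}

#' Wilcoxon rank-sum test between pooled response groups
#'
#' Compares signature activity between two pooled groups of RECIST-style
#' response labels (e.g. \{CR, PR, SD\} vs \{PD\}). Two-sided; the exact
#' null distribution is used when both groups have at most 10 samples and
#' there are no ties, otherwise the normal approximation with tie
#' correction.
#'
#' @param activity numeric per-sample vector.
#' @param response_labels character vector of labels (CR/PR/SD/PD or
#'   similar), same length.
#' @param grouping list of two character vectors naming the labels pooled
#'   into each group.
#' @return List with \code{W}, \code{p}, \code{n1}, \code{n2},
#'   \code{exact} (logical).
#' @export
responseGroupTest <- function(activity, response_labels,
                              grouping = list(c("CR", "PR", "SD"), "PD")) {
  if (length(activity) != length(response_labels)) stop("length mismatch")
  g1 <- activity[response_labels %in% grouping[[1]]]
  g2 <- activity[response_labels %in% grouping[[2]]]
  if (length(g1) == 0L || length(g2) == 0L) stop("both pooled groups must be nonempty")
  ties <- anyDuplicated(c(g1, g2)) > 0L
  exact <- length(g1) <= 10L && length(g2) <= 10L && !ties
  wt <- suppressWarnings(
    wilcox.test(g1, g2, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(W = unname(wt$statistic), p = wt$p.value,
       n1 = length(g1), n2 = length(g2), exact = exact)
}
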