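#' Exponential rank weights for one sample
#'
#' Genes are ranked in descending order of expression (rank 1 = highest;
#' ties share the average of the tied integer ranks) and weighted by
#' \deqn{w_{g,s} = r_{g,s} \cdot e^{sign \cdot r_{g,s} / |N|}}
#' where \eqn{|N|} is the number of genes in the sample. The default
#' \code{sign = +1} reproduces the weight formula as printed in the method's
#' description; \code{sign = -1} gives weights that decay with rank, matching
#' the verbal description of "exponential decreasing weights". Downstream
#' in-set/out-of-set contrasts are well defined under either convention.
#'
#' @param sample_expression numeric vector of expression values for one
#'   sample (length >= 2, finite), named by gene.
#' @param sign +1 or -1, exponent sign.
#' @return List with \code{weights} and \code{ranks}, both named by gene.
#' @examples
#' rankWeights(c(g1 = 5, g2 = 1))$weights  # 1*exp(0.5), 2*exp(1)
#' @export
rankWeights <- function(sample_expression, sign = 1) {
  x <- sample_expression
  if (length(x) < 2L) stop("at least 2 genes are required for ranking")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite expression values")
  if (!sign %in% c(1, -1)) stop("sign must be +1 or -1")
  r <- rank(-x, ties.method = "average")
  n <- length(x)
  w <- r * exp(sign * r / n)
  list(weights = w, ranks = r)
}

#' Raw activity of a feature set in one sample
#'
#' The mean rank weight of the set's genes minus the mean rank weight of all
#' other genes. Set genes absent from the weight vector's gene universe are
#' dropped (their count is reported via attribute \code{"dropped"}).
#'
#' @param weights a weight vector as returned by \code{\link{rankWeights}}
#'   (the list, or its named \code{weights} component).
#' @param feature a \linkS4class{FeatureSet} or character vector of gene ids.
#' @return The activity score, with attribute \code{"dropped"}.
#' @export
featureActivity <- function(weights, feature) {
  w <- if (is.list(weights)) weights$weights else weights
  genes <- if (is(feature, "FeatureSet")) geneIds(feature) else as.character(feature)
  present <- genes[genes %in% names(w)]
  if (length(present) == 0L) stop("no feature genes present in the expression universe")
  inset <- names(w) %in% present
  if (all(inset)) stop("feature covers the whole gene universe: empty complement")
  out <- mean(w[inset]) - mean(w[!inset])
  attr(out, "dropped") <- length(genes) - length(present)
  out
}

#' Z-normalize a feature's raw activities across samples
#'
#' Uses the across-sample mean and population SD (denominator \eqn{n}).
#' A constant row has no defined SD and is returned as all zeros with
#' attribute \code{"constant" = TRUE}.
#'
#' @param raw_scores numeric vector of raw activities across >= 2 samples.
#' @return Normalized vector with attribute \code{"constant"}.
#' @examples
#' normalizeActivity(c(1, 3))  # -1, 1
#' @export
normalizeActivity <- function(raw_scores) {
  if (length(raw_scores) < 2L) stop("normalization needs at least 2 samples")
  m <- mean(raw_scores)
  s <- sqrt(mean((raw_scores - m)^2))  # population SD
  if (s == 0) {
    out <- rep(0, length(raw_scores))
    names(out) <- names(raw_scores)
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (raw_scores - m) / s
  attr(out, "constant") <- FALSE
  out
}

#' Score feature activities across all samples of an expression matrix
#'
#' Applies \code{\link{rankWeights}} per sample and
#' \code{\link{featureActivity}} per (feature, sample) for subpathway- and
#' pathway-level sets, then \code{\link{normalizeActivity}} per feature.
#' Gene-level features use the gene's expression value itself as raw
#' activity, normalized identically.
#'
#' @param expr an \linkS4class{ExpressionMatrix} (or plain genes x samples
#'   matrix).
#' @param features list of \linkS4class{FeatureSet} objects.
#' @param sign exponent sign passed to \code{\link{rankWeights}}.
#' @return An \linkS4class{ActivityMatrix}.
#' @export
scoreMatrix <- function(expr, features, sign = 1) {
  m <- if (is(expr, "SummarizedExperiment")) assay(expr, "exprs") else as.matrix(expr)
  if (nrow(m) < 2L) stop("expression matrix needs at least 2 genes")
  if (ncol(m) < 2L) stop("activity normalization needs at least 2 samples")
  if (is.null(names(features)))
    names(features) <- vapply(features, function(f) f@id, character(1))
  ns <- ncol(m)

  # weight matrix: genes x samples
  W <- apply(m, 2L, function(col) rankWeights(col, sign = sign)$weights)
  rownames(W) <- rownames(m)
  colmean <- colMeans(W)
  ng <- nrow(W)

  raw <- matrix(NA_real_, nrow = length(features), ncol = ns,
                dimnames = list(names(features), colnames(m)))
  dropped <- integer(length(features))
  for (i in seq_along(features)) {
    fs <- features[[i]]
    genes <- geneIds(fs)
    present <- genes[genes %in% rownames(m)]
    dropped[i] <- length(genes) - length(present)
    if (length(present) == 0L)
      stop(sprintf("feature '%s' has no genes in the expression matrix", fs@id))
    if (featureLevel(fs) == "gene") {
      raw[i, ] <- m[present[1L], ]
    } else {
      ni <- length(present)
      if (ni == ng)
        stop(sprintf("feature '%s' covers the whole gene universe", fs@id))
      insum <- if (ni == 1L) W[present, ] else colSums(W[present, , drop = FALSE])
      # mean(out) = (total - insum) / (ng - ni); total = colmean * ng
      raw[i, ] <- insum / ni - (colmean * ng - insum) / (ng - ni)
    }
  }

  normed <- raw
  constant <- logical(length(features))
  for (i in seq_len(nrow(raw))) {
    z <- normalizeActivity(raw[i, ])
    constant[i] <- attr(z, "constant")
    normed[i, ] <- z
  }
  mu <- rowMeans(raw)
  sdev <- sqrt(rowMeans((raw - mu)^2))

  rd <- DataFrame(
    level = vapply(features, featureLevel, character(1)),
    parent = vapply(features, parentPathway, character(1)),
    n_genes = vapply(features, function(f) length(geneIds(f)), integer(1)),
    mean = mu, sd = sdev, constant = constant, dropped = dropped,
    row.names = names(features))
  new("ActivityMatrix",
      SummarizedExperiment(assays = list(raw = raw, normalized = normed),
                           rowData = rd))
}
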