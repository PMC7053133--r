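.checkEstimates <- function(estimates, min_n = 2L) {
  est <- as.data.frame(estimates)
  need <- c("study", "loghr", "se")
  if (!all(need %in% names(est)))
    stop("estimates need columns: study, loghr, se")
  if (anyDuplicated(est$study)) stop("duplicate study ids")
  if (any(!is.finite(est$loghr)) || any(!is.finite(est$se)) || any(est$se <= 0))
    stop("log HRs must be finite and SEs positive")
  if (nrow(est) < min_n)
    stop(sprintf("at least %d studies are required", min_n))
  est
}

.metaResult <- function(est, tau2, model, Q, df, I2) {
  w <- 1 / (est$se^2 + tau2)
  pooled <- sum(w * est$loghr) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- pooled / se
  new("MetaResult", logHR = pooled, se = se,
      ci = exp(pooled + c(-1.96, 1.96) * se),
      Q = Q, df = df, I2 = I2, tau2 = tau2, model = model,
      weights = setNames(w / sum(w), est$study),
      p = 2 * pnorm(-abs(z)))
}

#' Fixed-effect (inverse-variance) pooling of log hazard ratios
#'
#' Weights are \eqn{1/SE^2}; the pooled log HR is the weighted mean with
#' \eqn{SE = 1/\sqrt{\sum w}}. HRs are pooled on the log scale and
#' exponentiated for the reported CI.
#'
#' @param estimates data.frame with columns \code{study}, \code{loghr},
#'   \code{se} (and optionally \code{subgroup}); >= 2 rows.
#' @return A \linkS4class{MetaResult} with the heterogeneity statistics of
#'   the input set.
#' @export
poolFixed <- function(estimates) {
  est <- .checkEstimates(estimates)
  h <- heterogeneity(est)
  .metaResult(est, tau2 = 0, model = "fixed", Q = h$Q, df = h$df, I2 = h$I2)
}

#' Cochran's Q, I-squared and the DerSimonian-Laird tau-squared
#'
#' Q is computed about the fixed-effect pooled value;
#' \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100}; \eqn{\tau^2} is the
#' DerSimonian-Laird moment estimator floored at 0.
#'
#' @param estimates as in \code{\link{poolFixed}}.
#' @return List with \code{Q}, \code{df}, \code{I2} (percent), \code{tau2}.
#' @export
heterogeneity <- function(estimates) {
  est <- .checkEstimates(estimates)
  w <- 1 / est$se^2
  pooled <- sum(w * est$loghr) / sum(w)
  Q <- sum(w * (est$loghr - pooled)^2)
  df <- nrow(est) - 1L
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(Q = Q, df = df, I2 = I2, tau2 = tau2)
}

#' Pool with automatic fixed/random model choice
#'
#' Computes heterogeneity first; if \eqn{I^2 < 50\%} the fixed-effect model
#' is used, otherwise DerSimonian-Laird random effects (weights
#' \eqn{1/(SE^2 + \tau^2)}). The model actually used is recorded in the
#' result.
#'
#' @inheritParams poolFixed
#' @param i2_threshold I-squared percentage above which random effects are
#'   used (default 50).
#' @return A \linkS4class{MetaResult}.
#' @export
poolAuto <- function(estimates, i2_threshold = 50) {
  est <- .checkEstimates(estimates)
  h <- heterogeneity(est)
  if (h$I2 < i2_threshold)
    .metaResult(est, tau2 = 0, model = "fixed", Q = h$Q, df = h$df, I2 = h$I2)
  else
    .metaResult(est, tau2 = h$tau2, model = "random", Q = h$Q, df = h$df,
                I2 = h$I2)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools (with automatic model choice) after removing each study in turn,
#' to locate studies driving heterogeneity or the pooled estimate.
#'
#' @inheritParams poolAuto
#' @return data.frame with one row per omitted study: \code{omitted, loghr,
#'   hr, ci_lower, ci_upper, I2, model}.
#' @export
sensitivityLeaveOneOut <- function(estimates, i2_threshold = 50) {
  est <- .checkEstimates(estimates, min_n = 3L)
  rows <- lapply(seq_len(nrow(est)), function(i) {
    r <- poolAuto(est[-i, , drop = FALSE], i2_threshold)
    data.frame(omitted = est$study[i], loghr = r@logHR, hr = exp(r@logHR),
               ci_lower = r@ci[1], ci_upper = r@ci[2], I2 = r@I2,
               model = r@model, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subgroup meta-analysis
#'
#' Pools within each subgroup (e.g. microarray vs RNA-seq cohorts) and
#' overall, each with automatic model choice. A subgroup with a single study
#' is reported as-is and flagged.
#'
#' @inheritParams poolAuto
#' @param grouping character vector of subgroup labels aligned with the
#'   estimate rows; defaults to the \code{subgroup} column.
#' @return data.frame with rows per subgroup plus \code{"overall"}:
#'   \code{subgroup, n_studies, loghr, hr, ci_lower, ci_upper, I2, model,
#'   p, flag}.
#' @export
subgroupPool <- function(estimates, grouping = NULL, i2_threshold = 50) {
  est <- .checkEstimates(estimates)
  grouping <- grouping %||% est$subgroup
  if (is.null(grouping)) stop("no subgroup labels provided")
  grouping <- as.character(grouping)
  one <- function(sub, label) {
    if (nrow(sub) == 1L)
      return(data.frame(subgroup = label, n_studies = 1L,
                        loghr = sub$loghr, hr = exp(sub$loghr),
                        ci_lower = exp(sub$loghr - 1.96 * sub$se),
                        ci_upper = exp(sub$loghr + 1.96 * sub$se),
                        I2 = NA_real_, model = "single",
                        p = 2 * pnorm(-abs(sub$loghr / sub$se)),
                        flag = "single_study", stringsAsFactors = FALSE))
    r <- poolAuto(sub, i2_threshold)
    data.frame(subgroup = label, n_studies = nrow(sub), loghr = r@logHR,
               hr = exp(r@logHR), ci_lower = r@ci[1], ci_upper = r@ci[2],
               I2 = r@I2, model = r@model, p = r@p, flag = "",
               stringsAsFactors = FALSE)
  }
  parts <- lapply(sort(unique(grouping)), function(g)
    one(est[grouping == g, , drop = FALSE], g))
  do.call(rbind, c(parts, list(one(est, "overall"))))
}

#' Funnel-plot data export
#'
#' Tabular funnel data: per-study effect and SE, plus 95\% pseudo-confidence
#' bounds \eqn{pooled \pm 1.96 \cdot SE} over an SE grid from 0 to the
#' largest observed SE.
#'
#' @inheritParams poolFixed
#' @param pooled pooled log HR to center the funnel on; default the
#'   fixed-effect pooled value.
#' @param grid_points number of SE grid points (default 50).
#' @return List of two data.frames: \code{studies} (study, loghr, se) and
#'   \code{bounds} (se, lower, upper).
#' @export
funnelData <- function(estimates, pooled = NULL, grid_points = 50L) {
  est <- .checkEstimates(estimates)
  if (is.null(pooled)) pooled <- poolFixed(est)@logHR
  grid <- seq(0, max(est$se), length.out = grid_points)
  list(studies = data.frame(study = est$study, loghr = est$loghr,
                            se = est$se, stringsAsFactors = FALSE),
       bounds = data.frame(se = grid, lower = pooled - 1.96 * grid,
                           upper = pooled + 1.96 * grid),
       pooled = pooled)
}
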