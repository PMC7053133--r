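#' @importFrom survival coxph Surv survdiff
NULL

.coxFlagged <- function(n, events, reason, terms = "x") {
  data.frame(term = terms, coef = NA_real_, hr = NA_real_, se = NA_real_,
             ci_lower = NA_real_, ci_upper = NA_real_, p = 1,
             n = n, events = events, flag = reason,
             stringsAsFactors = FALSE)
}

.coxResult <- function(fit, n, events) {
  s <- summary(fit)$coefficients
  co <- s[, "coef"]
  se <- s[, "se(coef)"]
  data.frame(term = rownames(s), coef = co, hr = exp(co), se = se,
             ci_lower = exp(co - 1.96 * se), ci_upper = exp(co + 1.96 * se),
             p = s[, "Pr(>|z|)"], n = n, events = events, flag = "",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Univariate Cox proportional-hazards screen
#'
#' Fits a single-covariate Cox model (Breslow tie handling) and reports the
#' coefficient (log HR), hazard ratio, 95\% Wald CI and two-sided Wald
#' p-value. Degenerate inputs (no events, constant covariate,
#' non-convergence) do not error: they return a flagged row with \code{p = 1}
#' and a warning, so genome-wide screening never crashes on one feature.
#'
#' @param x numeric per-sample covariate, aligned with \code{surv} rows
#'   (or named by sample id matching \code{surv$sample_id}).
#' @param surv data.frame with columns \code{time} (> 0) and \code{event}
#'   (0/1), optionally \code{sample_id}.
#' @return One-row data.frame: \code{term, coef, hr, se, ci_lower, ci_upper,
#'   p, n, events, flag}.
#' @export
coxUnivariate <- function(x, surv) {
  if (!is.null(names(x)) && !is.null(surv$sample_id))
    x <- x[as.character(surv$sample_id)]
  keep <- complete.cases(x, surv$time, surv$event)
  x <- x[keep]; time <- surv$time[keep]; event <- surv$event[keep]
  n <- length(x); events <- sum(event)
  if (events < 1L) {
    warning("no events: flagged Cox result")
    return(.coxFlagged(n, events, "no_events"))
  }
  if (stats::var(x) == 0) {
    warning("constant covariate: flagged Cox result")
    return(.coxFlagged(n, events, "constant_covariate"))
  }
  fit <- tryCatch(
    coxph(Surv(time, event) ~ x, ties = "breslow",
          control = survival::coxph.control(eps = 1e-8, iter.max = 50)),
    error = function(e) NULL, warning = function(w) {
      f <- suppressWarnings(
        coxph(Surv(time, event) ~ x, ties = "breslow",
              control = survival::coxph.control(eps = 1e-8, iter.max = 50)))
      if (any(!is.finite(sqrt(diag(f$var))))) NULL else f
    })
  if (is.null(fit) || any(!is.finite(coef(fit)))) {
    warning("Cox fit did not converge: flagged result")
    return(.coxFlagged(n, events, "nonconvergence"))
  }
  out <- .coxResult(fit, n, events)
  out$term <- "x"
  out
}

#' Multivariate Cox proportional-hazards fit
#'
#' Joint fit of several covariates; categorical columns are expanded to
#' indicator contrasts against the first level in sorted order. Degenerate
#' fits (including collinear covariates, detected as non-finite or absent
#' coefficient estimates) return flagged rows with \code{p = 1}.
#'
#' @param X data.frame of covariates (numeric and/or character/factor),
#'   rows aligned with \code{surv}.
#' @param surv survival data.frame as in \code{\link{coxUnivariate}}.
#' @return data.frame with one row per fitted term.
#' @export
coxMultivariate <- function(X, surv) {
  X <- as.data.frame(X)
  keep <- complete.cases(X) & is.finite(surv$time) & !is.na(surv$event)
  X <- X[keep, , drop = FALSE]
  time <- surv$time[keep]; event <- surv$event[keep]
  n <- nrow(X); events <- sum(event)
  for (j in seq_along(X)) {
    if (is.character(X[[j]]))
      X[[j]] <- factor(X[[j]], levels = sort(unique(X[[j]])))
  }
  if (events < 1L) {
    warning("no events: flagged Cox result")
    return(.coxFlagged(n, events, "no_events", terms = names(X)))
  }
  d <- X
  d$.time <- time
  d$.event <- event
  fit <- tryCatch(suppressWarnings(
    coxph(Surv(.time, .event) ~ ., data = d, ties = "breslow",
          control = survival::coxph.control(eps = 1e-8, iter.max = 50))),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(coef(fit)) || any(!is.finite(coef(fit))) ||
      any(!is.finite(sqrt(diag(fit$var))))) {
    warning("multivariate Cox fit degenerate (collinearity or non-convergence): flagged")
    return(.coxFlagged(n, events, "nonconvergence", terms = names(X)))
  }
  .coxResult(fit, n, events)
}

#' Split samples into high/low activity groups by 1-D K-means (K = 2)
#'
#' Deterministic Lloyd K-means initialized at the 25th and 75th percentiles
#' (at most 100 iterations). The cluster with the greater mean activity is
#' labeled \code{"high"}.
#'
#' @param activity numeric per-sample vector (>= 4 samples, non-constant).
#' @return character vector of \code{"high"}/\code{"low"} labels, named as
#'   the input.
#' @export
splitTwoGroups <- function(activity) {
  if (length(activity) < 4L) stop("need at least 4 samples to split")
  if (stats::var(activity) == 0) stop("constant activity cannot be split")
  q <- unname(quantile(activity, c(0.25, 0.75)))
  if (q[1] == q[2]) q <- range(activity)
  km <- kmeans(activity, centers = matrix(q, ncol = 1), iter.max = 100,
               algorithm = "Lloyd")
  high <- which.max(km$centers[, 1])
  out <- ifelse(km$cluster == high, "high", "low")
  names(out) <- names(activity)
  out
}

#' Two-group log-rank test
#'
#' @param labels two-level grouping vector aligned with \code{surv} rows.
#' @param surv survival data.frame with \code{time} and \code{event}.
#' @return List with \code{chisq} (1 df) and \code{p}.
#' @export
logrankTest <- function(labels, surv) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) stop("exactly two nonempty groups are required")
  if (sum(surv$event) < 1L) stop("log-rank test needs at least one event")
  sd <- survdiff(Surv(surv$time, surv$event) ~ labels)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}
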