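.bundleParts <- function(bundle) {
  if (is(bundle, "SyntheticCohortBundle"))
    list(expression = bundle@expression, survival = bundle@survival,
         featureSets = bundle@featureSets,
         cellLineExpression = bundle@cellLineExpression,
         drugTable = bundle@drugTable, responseTable = bundle@responseTable,
         plantedId = bundle@plantedId)
  else bundle
}

#' Per-cohort univariate Cox p-values for every feature
#'
#' @param activity an \linkS4class{ActivityMatrix} for one cohort.
#' @param surv the cohort's survival data.frame.
#' @return data.frame \code{feature, coef, hr, se, p, flag}.
#' @export
screenCohort <- function(activity, surv) {
  A <- activityNorm(activity)
  rows <- lapply(rownames(A), function(f) {
    r <- suppressWarnings(coxUnivariate(setNames(A[f, ], colnames(A)), surv))
    data.frame(feature = f, coef = r$coef, hr = r$hr, se = r$se, p = r$p,
               flag = r$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the integrated signature-discovery pipeline
#'
#' Executes the full discovery procedure on a multi-cohort bundle: activity
#' scoring of every cohort, per-training-cohort univariate Cox screening of
#' every feature, integrated prognostic scores (mean \eqn{-\log_{10} p})
#' over all training-set combinations of the given sizes, per-combination
#' top-k ranking (per feature level), serial cumulative sets assessed on the
#' test cohorts by K = 2 clustering + log-rank, and frequency-based
#' candidate selection.
#'
#' @param bundle a \linkS4class{SyntheticCohortBundle} or the list returned
#'   by \code{\link{readCohortBundle}}.
#' @param train_cohorts,test_cohorts cohort ids; defaults: the first 7
#'   cohorts train, the rest test.
#' @param sizes combination sizes (default \code{c(5, 6, 7)}).
#' @param top_k per-combination list length (default 30).
#' @param cutoff frequency-selection cutoff (default 20).
#' @param sign weight exponent sign for \code{\link{scoreMatrix}}.
#' @param exclude_self frequency variant counting only the other
#'   combinations' lists.
#' @param assess_serial logical; assess the serial cumulative sets on the
#'   test cohorts (the most expensive stage).
#' @return List with \code{activity} (per cohort), \code{cox} (long
#'   data.frame of per-cohort screens), \code{pmatrix} (features x training
#'   cohorts), \code{combinations}, \code{ipscores} (features x
#'   combinations), \code{top_lists} (per level), \code{frequency}
#'   (data.frame with \code{level} column), \code{selected} (character ids),
#'   \code{serial_assessment} (long data.frame or NULL).
#' @export
runDiscovery <- function(bundle, train_cohorts = NULL, test_cohorts = NULL,
                         sizes = c(5L, 6L, 7L), top_k = 30L, cutoff = 20L,
                         sign = 1, exclude_self = FALSE,
                         assess_serial = TRUE) {
  parts <- .bundleParts(bundle)
  cohorts <- names(parts$expression)
  if (is.null(train_cohorts))
    train_cohorts <- cohorts[seq_len(min(7L, length(cohorts)))]
  if (is.null(test_cohorts))
    test_cohorts <- setdiff(cohorts, train_cohorts)
  missing <- setdiff(c(train_cohorts, test_cohorts), cohorts)
  if (length(missing))
    stop("unknown cohorts: ", paste(missing, collapse = ", "))

  features <- parts$featureSets
  activity <- lapply(parts$expression, scoreMatrix, features = features,
                     sign = sign)

  cox <- do.call(rbind, lapply(train_cohorts, function(co) {
    sc <- screenCohort(activity[[co]], parts$survival[[co]])
    sc$cohort <- co
    sc
  }))
  fids <- rownames(activityNorm(activity[[train_cohorts[1L]]]))
  pmatrix <- matrix(NA_real_, length(fids), length(train_cohorts),
                    dimnames = list(fids, train_cohorts))
  for (co in train_cohorts) {
    sub <- cox[cox$cohort == co, ]
    pmatrix[sub$feature, co] <- sub$p
  }

  combos <- enumerateCombinations(train_cohorts, sizes)
  ipscores <- vapply(combos, function(cs)
    apply(pmatrix[, cs, drop = FALSE], 1L, ipScore), numeric(length(fids)))
  rownames(ipscores) <- fids

  levels_of <- vapply(features[fids], featureLevel, character(1))
  top_lists <- list(); freq_parts <- list()
  for (lv in unique(levels_of)) {
    lf <- fids[levels_of == lv]
    tls <- lapply(colnames(ipscores), function(cb)
      rankTopK(setNames(ipscores[lf, cb], lf), k = top_k))
    names(tls) <- colnames(ipscores)
    top_lists[[lv]] <- tls
    fr <- frequencySelect(tls, cutoff = cutoff, exclude_self = exclude_self)
    fr$level <- lv
    freq_parts[[lv]] <- fr
  }
  frequency <- do.call(rbind, freq_parts)
  rownames(frequency) <- NULL
  selected <- frequency$feature[frequency$selected]

  serial_assessment <- NULL
  if (assess_serial && length(test_cohorts)) {
    rows <- list()
    for (lv in names(top_lists)) {
      for (cb in names(top_lists[[lv]])) {
        sets <- suppressWarnings(serialSets(top_lists[[lv]][[cb]]))
        for (sn in names(sets)) {
          for (co in test_cohorts) {
            res <- assessSetOnCohort(sets[[sn]], activity[[co]],
                                     parts$survival[[co]])
            rows[[length(rows) + 1L]] <- data.frame(
              level = lv, combination = cb, set = sn,
              set_size = length(sets[[sn]]), cohort = co, p = res$p,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    serial_assessment <- do.call(rbind, rows)
  }

  list(activity = activity, cox = cox, pmatrix = pmatrix,
       combinations = combos, ipscores = ipscores, top_lists = top_lists,
       frequency = frequency, selected = selected,
       serial_assessment = serial_assessment,
       train_cohorts = train_cohorts, test_cohorts = test_cohorts)
}

#' Validate a signature: meta-analysis and drug-response association
#'
#' Fits a univariate Cox model of the signature's normalized activity in
#' every cohort, pools the per-cohort log hazard ratios with automatic
#' fixed/random model choice, and adds platform-subgroup pooling,
#' leave-one-out sensitivity, and funnel data. If the bundle carries
#' cell-line and response tables, the signature's cell-line activity is
#' correlated with each drug's IC50 within the classical subtype (with the
#' subset permutation test) and compared between pooled response groups by
#' Wilcoxon rank-sum.
#'
#' @param bundle as in \code{\link{runDiscovery}}.
#' @param signature feature id to validate (default: the bundle's planted
#'   set).
#' @param cohorts cohort ids to include (default all).
#' @param activity optional list of precomputed
#'   \linkS4class{ActivityMatrix} per cohort (e.g. from
#'   \code{\link{runDiscovery}}) to avoid re-scoring.
#' @param sign weight exponent sign for scoring.
#' @param B,perm_seed permutation count and seed for the drug test.
#' @param i2_threshold I-squared switch to random effects (default 50).
#' @return List with \code{estimates}, \code{meta}
#'   (\linkS4class{MetaResult}), \code{subgroups}, \code{sensitivity},
#'   \code{funnel}, \code{drug} (per-drug data.frame), \code{response}.
#' @export
runValidation <- function(bundle, signature = NULL, cohorts = NULL,
                          activity = NULL, sign = 1, B = 10000L,
                          perm_seed = 1L, i2_threshold = 50) {
  parts <- .bundleParts(bundle)
  signature <- signature %||% parts$plantedId
  cohorts <- cohorts %||% names(parts$expression)
  feat <- parts$featureSets[[signature]]
  if (is.null(feat)) stop("unknown signature: ", signature)

  estimates <- do.call(rbind, lapply(cohorts, function(co) {
    A <- if (!is.null(activity) && co %in% names(activity))
      activity[[co]] else scoreMatrix(parts$expression[[co]], list(feat),
                                      sign = sign)
    a <- setNames(activityNorm(A)[signature, ],
                  colnames(activityNorm(A)))
    r <- suppressWarnings(coxUnivariate(a, parts$survival[[co]]))
    data.frame(study = co, loghr = r$coef, se = r$se, p = r$p,
               subgroup = platformOf(parts$expression[[co]]),
               stringsAsFactors = FALSE)
  }))

  meta <- poolAuto(estimates, i2_threshold)
  subgroups <- subgroupPool(estimates, i2_threshold = i2_threshold)
  sensitivity <- if (nrow(estimates) >= 3L)
    sensitivityLeaveOneOut(estimates, i2_threshold) else NULL
  funnel <- funnelData(estimates)

  drug <- NULL
  if (!is.null(parts$drugTable) && nrow(parts$drugTable)) {
    Acl <- scoreMatrix(parts$cellLineExpression, list(feat), sign = sign)
    acl <- setNames(activityNorm(Acl)[signature, ],
                    colnames(activityNorm(Acl)))
    drug <- do.call(rbind, lapply(unique(parts$drugTable$drug), function(dg) {
      sub <- parts$drugTable[parts$drugTable$drug == dg, ]
      a <- acl[sub$cell_line]
      mask <- sub$subtype == "classical"
      sp <- spearmanActivityIC50(a[mask], sub$ic50[mask])
      pt <- subtypePermutationTest(a, sub$ic50, mask, B = B,
                                   seed = perm_seed)
      data.frame(drug = dg, rho = sp$rho, n_classical = sp$n,
                 perm_N = pt$N, perm_B = pt$B, perm_p = pt$p,
                 stringsAsFactors = FALSE)
    }))
  }

  response <- NULL
  if (!is.null(parts$responseTable) && nrow(parts$responseTable)) {
    co <- parts$responseTable$cohort[1L]
    A <- if (!is.null(activity) && co %in% names(activity))
      activity[[co]] else scoreMatrix(parts$expression[[co]], list(feat),
                                      sign = sign)
    a <- setNames(activityNorm(A)[signature, ], colnames(activityNorm(A)))
    rt <- parts$responseTable
    response <- responseGroupTest(a[rt$sample_id], rt$response)
  }

  list(signature = signature, estimates = estimates, meta = meta,
       subgroups = subgroups, sensitivity = sensitivity, funnel = funnel,
       drug = drug, response = response)
}
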