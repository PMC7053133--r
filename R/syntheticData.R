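#' Construct a simulation configuration
#'
#' Defaults define the package's reference study design: 11 cohorts (7
#' training + 4 test by convention of \code{\link{runDiscovery}}) of 500
#' samples over a 1000-gene universe, with a 10-gene planted subpathway
#' whose normalized activity enters an exponential proportional-hazards
#' model at log HR -0.5 per SD (protective), ~30\% independent censoring,
#' the last two cohorts RNA-seq-flavored, and 60 cell lines whose log IC50
#' has target Spearman correlation -0.5 with planted activity within the
#' classical subtype.
#'
#' @param n_cohorts,samples_per_cohort,n_genes,planted_set_size,planted_log_hr
#'   see \linkS4class{SimulationConfig}.
#' @param baseline_hazard,censor_rate,classical_fraction,ic50_rho,noise_sd,seed
#'   see \linkS4class{SimulationConfig}.
#' @param factor_loading,cohort_shift_sd,n_decoy_sets,rnaseq_cohorts see
#'   \linkS4class{SimulationConfig}.
#' @param n_cell_lines,drugs see \linkS4class{SimulationConfig}.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(n_cohorts = 11L, samples_per_cohort = 500L,
                             n_genes = 1000L, planted_set_size = 10L,
                             planted_log_hr = -0.5, baseline_hazard = 0.05,
                             censor_rate = 0.3, classical_fraction = 0.45,
                             ic50_rho = -0.5, noise_sd = 1, seed = 1L,
                             factor_loading = 2, cohort_shift_sd = 0.2,
                             n_decoy_sets = 200L,
                             rnaseq_cohorts = NULL,
                             n_cell_lines = 60L,
                             drugs = c("irinotecan", "gemcitabine",
                                       "cisplatin", "fluorouracil")) {
  if (is.null(rnaseq_cohorts))
    rnaseq_cohorts <- if (n_cohorts >= 3L) c(n_cohorts - 1L, n_cohorts) else integer()
  new("SimulationConfig",
      n_cohorts = as.integer(n_cohorts),
      samples_per_cohort = as.integer(samples_per_cohort),
      n_genes = as.integer(n_genes),
      planted_set_size = as.integer(planted_set_size),
      planted_log_hr = as.numeric(planted_log_hr),
      baseline_hazard = as.numeric(baseline_hazard),
      censor_rate = as.numeric(censor_rate),
      classical_fraction = as.numeric(classical_fraction),
      ic50_rho = as.numeric(ic50_rho), noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed), factor_loading = as.numeric(factor_loading),
      cohort_shift_sd = as.numeric(cohort_shift_sd),
      n_decoy_sets = as.integer(n_decoy_sets),
      rnaseq_cohorts = as.integer(rnaseq_cohorts),
      n_cell_lines = as.integer(n_cell_lines),
      drugs = as.character(drugs))
}

# Tune an independent exponential censoring rate so that the expected
# censored fraction over the realized hazards equals the target.
.censorRate <- function(hazards, target) {
  if (target <= 0) return(0)
  f <- function(cr) mean(cr / (cr + hazards)) - target
  uniroot(f, lower = 1e-12, upper = max(hazards) * 1e6, tol = 1e-12)$root
}

# Simulate one log2-scale expression matrix; planted genes share the latent
# per-sample factor f through an additive shift of factor_loading * f.
.simExpression <- function(cfg, mu, shift, planted_idx, f, sample_ids,
                           platform) {
  G <- cfg@n_genes; n <- length(f)
  E <- matrix(rnorm(G * n, sd = cfg@noise_sd), G, n) + mu + shift
  E[planted_idx, ] <- E[planted_idx, ] +
    matrix(cfg@factor_loading * f, nrow = length(planted_idx), ncol = n,
           byrow = TRUE)
  dimnames(E) <- list(names(mu), sample_ids)
  if (platform == "rnaseq") E <- round(pmax(2^E, 0))
  ExpressionMatrix(E, platform = platform)
}

#' Generate a synthetic multi-cohort bundle
#'
#' Draws i.i.d. per-gene log-scale expression for each cohort; the planted
#' subpathway's member genes share a latent per-sample factor so the set's
#' normalized rank-weight activity varies across samples. Survival times
#' come from an exponential proportional-hazards model whose linear
#' predictor is \code{planted_log_hr} times the planted set's normalized
#' activity (computed from the cohort's own expression with
#' \code{\link{scoreMatrix}}), with independent exponential censoring tuned
#' to \code{censor_rate}. A \code{classical_fraction} of samples and cell
#' lines carry the \code{"classical"} subtype label; cell-line IC50 values
#' are drawn (Gaussian copula) so their rank correlation with planted
#' activity within classical lines approximates \code{ic50_rho}; response
#' labels (CR/PR/SD/PD) threshold a noisy monotone function of activity in
#' the first cohort. Identical config and seed give bit-identical bundles;
#' the caller's RNG state is untouched.
#'
#' Note on orientation: with the default as-printed weight exponent
#' (\code{sign = +1}), rank weights grow with rank, so the planted set's
#' activity is anti-correlated with its member genes' expression (and hence
#' with the latent factor). All downstream contracts use the activity
#' itself, so the orientation is internally consistent.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{SyntheticCohortBundle}.
#' @export
generateCohorts <- function(config) {
  validObject(config)
  cfg <- config
  withSeed(cfg@seed, {
    genes <- sprintf("g%04d", seq_len(cfg@n_genes))
    mu <- setNames(rnorm(cfg@n_genes, 6, 1.5), genes)

    planted_idx <- sort(sample.int(cfg@n_genes, cfg@planted_set_size))
    planted <- FeatureSet("path:00982_1", "subpathway",
                          genes[planted_idx], parent = "path:00982")
    decoys <- lapply(seq_len(cfg@n_decoy_sets), function(j)
      FeatureSet(sprintf("path:%05d_1", 10000L + j), "subpathway",
                 genes[sort(sample.int(cfg@n_genes, cfg@planted_set_size))],
                 parent = sprintf("path:%05d", 10000L + j)))
    featureSets <- c(list(planted), decoys)
    names(featureSets) <- vapply(featureSets, function(f) f@id, character(1))

    cohort_ids <- sprintf("cohort%02d", seq_len(cfg@n_cohorts))
    expression <- list(); survival <- list(); latent <- list()
    for (ci in seq_len(cfg@n_cohorts)) {
      n <- cfg@samples_per_cohort
      sample_ids <- sprintf("%s_s%03d", cohort_ids[ci], seq_len(n))
      platform <- if (ci %in% cfg@rnaseq_cohorts) "rnaseq" else "microarray"
      shift <- if (cfg@cohort_shift_sd > 0)
        rnorm(cfg@n_genes, 0, cfg@cohort_shift_sd) else 0
      f <- rnorm(n)
      ex <- .simExpression(cfg, mu, shift, planted_idx, f, sample_ids,
                           platform)
      a <- drop(activityNorm(scoreMatrix(ex, list(planted)))[1L, ])
      hz <- cfg@baseline_hazard * exp(cfg@planted_log_hr * a)
      T <- rexp(n, hz)
      if (cfg@censor_rate > 0) {
        cr <- .censorRate(hz, cfg@censor_rate)
        C <- rexp(n, cr)
        time <- pmin(T, C); event <- as.integer(T <= C)
      } else {
        time <- T; event <- rep(1L, n)
      }
      subtype <- ifelse(runif(n) < cfg@classical_fraction, "classical", "other")
      survival[[cohort_ids[ci]]] <- data.frame(
        sample_id = sample_ids, time = time, event = event,
        subtype = subtype, age = round(rnorm(n, 65, 8)),
        sex = sample(c("F", "M"), n, replace = TRUE),
        stringsAsFactors = FALSE)
      expression[[cohort_ids[ci]]] <- ex
      latent[[cohort_ids[ci]]] <- setNames(f, sample_ids)
    }

    # cell lines: same expression scheme, no cohort shift, microarray scale
    ncl <- cfg@n_cell_lines
    cl_ids <- sprintf("cell%03d", seq_len(ncl))
    f_cl <- rnorm(ncl)
    cl_expr <- .simExpression(cfg, mu, 0, planted_idx, f_cl, cl_ids,
                              "microarray")
    a_cl <- drop(activityNorm(scoreMatrix(cl_expr, list(planted)))[1L, ])
    cl_classical <- runif(ncl) < cfg@classical_fraction
    # guarantee a workable classical subset
    if (sum(cl_classical) < 4L) cl_classical[seq_len(4L)] <- TRUE
    if (all(cl_classical)) cl_classical[ncl] <- FALSE
    rho_pearson <- 2 * sin(pi * cfg@ic50_rho / 6)  # Gaussian-copula inverse
    drug_rows <- lapply(cfg@drugs, function(dg) {
      y <- rnorm(ncl)
      z <- as.numeric(scale(a_cl[cl_classical]))
      y[cl_classical] <- rho_pearson * z +
        sqrt(1 - rho_pearson^2) * rnorm(sum(cl_classical))
      data.frame(cell_line = cl_ids, drug = dg, ic50 = exp(0.8 * y + 1),
                 subtype = ifelse(cl_classical, "classical", "other"),
                 stringsAsFactors = FALSE)
    })
    drugTable <- do.call(rbind, drug_rows)

    # ordinal chemotherapy response from cohort 1's planted activity
    a1 <- drop(activityNorm(
      scoreMatrix(expression[[1L]], list(planted)))[1L, ])
    score <- a1 + rnorm(length(a1))
    cuts <- quantile(score, c(0.25, 0.5, 0.75))
    response <- cut(score, c(-Inf, cuts, Inf),
                    labels = c("PD", "SD", "PR", "CR"))
    responseTable <- data.frame(sample_id = names(a1),
                                cohort = cohort_ids[1L],
                                response = as.character(response),
                                stringsAsFactors = FALSE)
    latent[["cell_lines"]] <- setNames(f_cl, cl_ids)

    new("SyntheticCohortBundle",
        expression = expression, survival = survival,
        featureSets = featureSets, plantedId = planted@id,
        cellLineExpression = cl_expr, drugTable = drugTable,
        responseTable = responseTable, latentFactors = latent,
        config = cfg)
  })
}
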