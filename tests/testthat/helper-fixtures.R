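suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# Small bundle for fast tests: 2 cohorts x 120 samples, 120 genes.
makeTinyBundle <- function(seed = 1L, ...) {
  args <- list(n_cohorts = 2L, samples_per_cohort = 120L, n_genes = 120L,
               n_decoy_sets = 10L, n_cell_lines = 40L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  generateCohorts(do.call(simulationConfig, args))
}

# One-cohort config for replicate loops.
makeOneCohort <- function(seed, n = 300L, ...) {
  makeTinyBundle(seed = seed, n_cohorts = 1L, samples_per_cohort = as.integer(n),
                 n_genes = 150L, n_decoy_sets = 0L, ...)
}

# Planted normalized activity of a bundle cohort.
plantedActivity <- function(bundle, cohort = 1L) {
  A <- scoreMatrix(bundle@expression[[cohort]],
                   bundle@featureSets[bundle@plantedId])
  drop(activityNorm(A)[1L, ])
}

# Brute-force subpathway oracle: maximal subsets with pairwise shortest-path
# distance <= k, enumerated over all nonempty node subsets (<= 12 nodes).
bruteForceSubpathways <- function(graph, k) {
  d <- igraph::distances(graph)
  nodes <- rownames(d)
  n <- length(nodes)
  stopifnot(n <= 12L)
  ok <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    dd <- d[members, members, drop = FALSE]
    if (all(is.finite(dd)) && all(dd <= k)) ok[[length(ok) + 1L]] <- members
  }
  maximal <- Filter(function(s) {
    !any(vapply(ok, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, ok)
  unique(lapply(maximal, sort))
}

# Canonical form for comparing set collections.
setKey <- function(sets) sort(vapply(sets, function(s)
  paste(sort(s), collapse = "|"), character(1)))

# Random connected undirected graph on n nodes (spanning tree + extra edges).
randomConnectedGraph <- function(n, extra = 2L, id = "path:test") {
  nodes <- letters[seq_len(n)]
  # spanning tree: connect node i+1 to a uniform earlier node
  from <- vapply(2:n, function(i) nodes[sample.int(i - 1L, 1L)], character(1))
  edges <- cbind(from, nodes[2:n])
  for (e in seq_len(extra)) {
    pair <- sample(nodes, 2L)
    edges <- rbind(edges, pair)
  }
  pathwayGraph(id, edges, nodes = nodes)
}
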