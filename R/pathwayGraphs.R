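#' @importFrom igraph graph_from_data_frame distances max_cliques simplify
#'   vcount V graph_from_adjacency_matrix
NULL

#' Build an undirected pathway graph
#'
#' Nodes are genes, edges are unordered gene pairs. Self-loops and duplicate
#' edges are dropped; isolated nodes may be supplied via \code{nodes}.
#'
#' @param id pathway identifier, e.g. \code{"path:00982"}.
#' @param edges two-column matrix or data.frame of gene pairs (may have 0 rows).
#' @param nodes optional character vector of node ids (must cover all edge
#'   endpoints; extra entries become isolated nodes).
#' @return An \code{igraph} object with a \code{pathway_id} attribute.
#' @export
pathwayGraph <- function(id, edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L && nrow(edges) > 0L)
    stop("edges must have two columns")
  if (nrow(edges) > 0L) {
    edges <- data.frame(from = as.character(edges[[1]]),
                        to = as.character(edges[[2]]))
    endpoints <- unique(c(edges$from, edges$to))
  } else endpoints <- character()
  nodes <- unique(c(nodes %||% character(), endpoints))
  if (length(nodes) == 0L) stop("empty graph: no nodes")
  if (!all(endpoints %in% nodes)) stop("edge endpoints missing from node list")
  g <- igraph::simplify(graph_from_data_frame(
    if (nrow(edges) > 0L) edges else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = data.frame(name = nodes)))
  g$pathway_id <- as.character(id)
  g
}

#' Read a pathway graph from a TSV or SIF edge list
#'
#' TSV: two tab-separated columns (no header) of gene pairs. SIF: three
#' columns \code{source relation target}, relation ignored.
#'
#' @param path file path.
#' @param id pathway id to attach (default: file base name).
#' @param format \code{"tsv"} or \code{"sif"} (default guessed from extension).
#' @return An \code{igraph} object.
#' @export
readEdgeList <- function(path, id = NULL,
                         format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  edges <- if (format == "sif") tab[, c(1L, 3L)] else tab[, 1:2]
  pathwayGraph(id %||% sub("\\.[^.]*$", "", basename(path)), edges)
}

#' Mine subpathways by the pairwise distance rule
#'
#' A subpathway is a maximal set of genes in which every pair lies within
#' shortest-path distance \code{k} of each other in the pathway graph —
#' equivalently, a maximal clique of the graph's k-th power. Disconnected
#' pairs have infinite distance and are never co-members. Subpathway ids are
#' \code{"<pathway>_<j>"} with 1-based indices assigned in a deterministic
#' order: descending set size, then lexicographically smallest member.
#'
#' @param graph an \code{igraph} pathway graph (see \code{\link{pathwayGraph}}).
#' @param k distance cutoff, a positive integer; default 3.
#' @return List of \linkS4class{FeatureSet} objects at subpathway level.
#' @examples
#' g <- pathwayGraph("path:00001",
#'                   cbind(c("a", "b", "c", "d"), c("b", "c", "d", "e")))
#' mineSubpathways(g, k = 3)
#' @export
mineSubpathways <- function(graph, k = 3L) {
  if (!inherits(graph, "igraph")) stop("graph must be an igraph object")
  if (vcount(graph) == 0L) stop("empty graph")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  d <- distances(graph)
  adj <- (d <= k) & is.finite(d)
  diag(adj) <- FALSE
  power <- graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- max_cliques(power)
  sets <- lapply(cl, function(v) sort(names(V(power))[as.integer(v)]))
  ord <- order(-lengths(sets), vapply(sets, `[`, character(1), 1L))
  sets <- sets[ord]
  pid <- graph$pathway_id %||% "path"
  lapply(seq_along(sets), function(j)
    FeatureSet(id = sprintf("%s_%d", pid, j), level = "subpathway",
               genes = sets[[j]], parent = pid))
}
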