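# Interactome graph construction and centrality: degree, betweenness,
# top-k% bottleneck classification, and set-to-set shortest distances.

#' Build the interactome graph
#'
#' Constructs a simple undirected graph from (already quality-filtered)
#' interaction records. Duplicate edges and self-loops are collapsed.
#'
#' @param records an `interaction_table` (or any data frame with
#'   `protein_a`, `protein_b` columns).
#' @return an igraph object.
#' @export
build_network <- function(records) {
  if (nrow(records) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(
    records[, c("protein_a", "protein_b")], directed = FALSE)
  igraph::simplify(g)
}

#' Betweenness centrality of every node
#'
#' Unnormalized betweenness: for node v, the sum over unordered node pairs
#' \{s, t\} (s, t != v) of the fraction of shortest s-t paths that pass
#' through v. Pairs in different components contribute zero.
#'
#' @param net an igraph object.
#' @return named numeric vector over nodes.
#' @export
betweenness_all <- function(net) {
  igraph::betweenness(net, directed = FALSE, normalized = FALSE)
}

#' Classify bottleneck proteins
#'
#' Bottlenecks are the nodes whose betweenness ranks in the top
#' `fraction` of all nodes (default top 20%). Ties at the cutoff are broken
#' by lexicographic protein id; exactly `ceiling(fraction * N)` nodes are
#' returned.
#'
#' @param btw named numeric betweenness vector.
#' @param fraction cutoff fraction in (0, 1].
#' @return character vector of bottleneck protein ids.
#' @export
classify_bottlenecks <- function(btw, fraction = 0.20) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (length(btw) == 0L) return(character(0))
  ord <- order(-btw, names(btw))
  names(btw)[ord[seq_len(ceiling(fraction * length(btw)))]]
}

#' Average shortest distance between two protein sets
#'
#' Mean shortest-path length over all (u, v) pairs of `from_set` x `to_set`,
#' with u = v counting as 0. Pairs with no connecting path are excluded from
#' the mean; proteins absent from the network are dropped from the sets.
#' Returns `NA` (the drug is excluded from distance analyses) when no finite
#' pair remains.
#'
#' @param net an igraph object.
#' @param from_set,to_set character vectors of protein ids.
#' @return numeric mean distance, or `NA_real_` if undefined.
#' @export
avg_set_distance <- function(net, from_set, to_set) {
  nn <- igraph::V(net)$name
  from <- intersect(unique(from_set), nn)
  to <- intersect(unique(to_set), nn)
  if (length(from) == 0L || length(to) == 0L) return(NA_real_)
  d <- igraph::distances(net, v = from, to = to)
  fin <- d[is.finite(d)]
  if (length(fin) == 0L) return(NA_real_)
  mean(fin)
}

#' Centrality table for a network
#'
#' Per-protein degree, betweenness, and bottleneck membership at the given
#' cutoff fraction.
#'
#' @param net an igraph object.
#' @param bottleneck_fraction top-betweenness fraction defining bottlenecks.
#' @return data frame with columns `protein`, `degree`, `betweenness`,
#'   `is_bottleneck`.
#' @export
centrality_table <- function(net, bottleneck_fraction = 0.20) {
  btw <- betweenness_all(net)
  bn <- classify_bottlenecks(btw, bottleneck_fraction)
  data.frame(protein = igraph::V(net)$name,
             degree = as.integer(igraph::degree(net)),
             betweenness = as.numeric(btw),
             is_bottleneck = igraph::V(net)$name %in% bn,
             stringsAsFactors = FALSE)
}
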