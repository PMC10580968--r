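# Co-occurrence network construction, topology metrics and hub/keystone
# classification.
#
# Edges are kept when |r| > 0.6 and p < 0.05 (the sign is recorded;
# `positive_only = TRUE` restores the literal positive-correlation rule).
# Hubs are nodes in the top 30% of both degree and betweenness; keystones
# have top-30% degree and closeness but bottom-30% betweenness: highly
# connected, centrally placed taxa that shortest paths do not depend on,
# whose removal is disproportionately damaging to community structure.

#' Build a correlation network from r and p matrices
#'
#' @param r symmetric SparCC correlation matrix.
#' @param p symmetric p-value matrix.
#' @param r_min correlation magnitude threshold (strict, default 0.6).
#' @param p_max p-value threshold (strict, default 0.05).
#' @param positive_only if TRUE, keep only r > r_min (ignore strong
#'   negative correlations).
#' @param relab optional named vector of mean relative abundances attached
#'   to nodes.
#' @return an igraph graph of class `correlation_network` with edge
#'   attributes `r`, `p`, `sign`; isolated nodes are dropped and recorded
#'   in the graph attribute `isolated_nodes`.
#' @export
build_network <- function(r, p, r_min = 0.6, p_max = 0.05,
                          positive_only = FALSE, relab = NULL) {
  stopifnot(all(dim(r) == dim(p)))
  ids <- colnames(r) %||% paste0("OTU", seq_len(ncol(r)))
  keep <- if (positive_only) r > r_min else abs(r) > r_min
  keep <- keep & (p < p_max)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      r = r[idx], p = p[idx],
                      sign = ifelse(r[idx] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  deg <- igraph::degree(g)
  isolated <- names(deg)[deg == 0]
  g <- igraph::delete_vertices(g, isolated)
  if (!is.null(relab)) {
    igraph::V(g)$relab <- unname(relab[igraph::V(g)$name])
  }
  g <- igraph::set_graph_attr(g, "isolated_nodes", isolated)
  class(g) <- c("correlation_network", class(g))
  g
}

#' Per-node topology metrics
#'
#' Degree, shortest-path betweenness (normalised), harmonic closeness
#' (well-defined on disconnected graphs), local clustering coefficient
#' (0 for nodes with degree < 2) and connected-component id, all computed
#' on the filtered graph.
#'
#' @param net an igraph graph.
#' @return a data.frame with one row per node.
#' @export
node_metrics <- function(net) {
  cl <- igraph::transitivity(net, type = "local", isolates = "zero")
  comp <- igraph::components(net)
  ids <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  data.frame(
    otu_id = ids,
    degree = unname(igraph::degree(net)),
    betweenness = unname(igraph::betweenness(net, normalized = TRUE)),
    closeness = unname(igraph::harmonic_centrality(net, normalized = TRUE)),
    clustering = cl,
    component = unname(comp$membership),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Whole-network summary statistics
#'
#' Mean degree is 2E/N; the diameter is the longest shortest path within
#' the largest connected component (the full-graph value is undefined for
#' disconnected graphs); the clustering coefficient is the mean local
#' clustering with degree < 2 nodes contributing 0.
#'
#' @param net an igraph graph.
#' @return a list: `n_nodes`, `n_edges`, `mean_degree` (3 decimals),
#'   `diameter`, `clustering_coefficient`.
#' @export
network_summary <- function(net) {
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  list(
    n_nodes = n,
    n_edges = e,
    mean_degree = round(2 * e / n, 3),
    diameter = igraph::diameter(giant, weights = NA),
    clustering_coefficient = mean(
      igraph::transitivity(net, type = "local", isolates = "zero"))
  )
}

#' Classify network nodes as hubs, keystones or other
#'
#' Percentile cuts use the nearest-rank method over the network's nodes
#' and are inclusive at the boundary. Hub: degree >= P70 and betweenness
#' >= P70. Keystone: degree >= P70, closeness >= P70 and betweenness <=
#' P30. When heavy betweenness ties make the top-30% and bottom-30% sets
#' overlap, the hub label takes precedence so the two roles stay
#' mutually exclusive.
#'
#' @param metrics a [node_metrics()] data.frame.
#' @param fraction percentile band (default 0.30).
#' @return the data.frame with added columns `role` and per-metric
#'   percentile thresholds in attributes.
#' @export
classify_roles <- function(metrics, fraction = 0.30) {
  p70_deg <- nearest_rank_quantile(metrics$degree, 1 - fraction)
  p70_bet <- nearest_rank_quantile(metrics$betweenness, 1 - fraction)
  p70_clo <- nearest_rank_quantile(metrics$closeness, 1 - fraction)
  p30_bet <- nearest_rank_quantile(metrics$betweenness, fraction)
  hub <- metrics$degree >= p70_deg & metrics$betweenness >= p70_bet
  keystone <- metrics$degree >= p70_deg & metrics$closeness >= p70_clo &
    metrics$betweenness <= p30_bet & !hub
  metrics$role <- ifelse(hub, "hub", ifelse(keystone, "keystone", "other"))
  attr(metrics, "thresholds") <- c(degree_p70 = p70_deg,
                                   betweenness_p70 = p70_bet,
                                   closeness_p70 = p70_clo,
                                   betweenness_p30 = p30_bet)
  metrics
}

#' Overlay functional annotations on a network
#'
#' Annotates each node with pathway membership booleans and reports, per
#' pathway, the fraction of network nodes annotated with it.
#'
#' @param net an igraph graph whose vertex names are OTU ids.
#' @param fn a function table (see [read_function_table()]).
#' @return a list: `net` (annotated graph) and `fractions` (named numeric,
#'   one entry per pathway present in `fn`).
#' @export
overlay_functions <- function(net, fn) {
  ids <- igraph::V(net)$name
  pathways <- unique(fn$pathway)
  if (!length(pathways)) {
    warning("empty function table; all fractions are 0")
    return(list(net = net, fractions = numeric(0)))
  }
  fractions <- numeric(0)
  for (pw in pathways) {
    annotated <- fn$otu_id[fn$pathway == pw & fn$present]
    flag <- ids %in% annotated
    net <- igraph::set_vertex_attr(net, pw, value = flag)
    fractions[pw] <- mean(flag)
  }
  list(net = net, fractions = fractions)
}

#' Write a network edge list as TSV
#' @param net an igraph graph with `r`, `p`, `sign` edge attributes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("source", "target")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a node metrics/roles table as TSV
#' @param metrics a [node_metrics()] or [classify_roles()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
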