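# Mapper topological networks of samples and SAFE enrichment scoring.
#
# Samples are projected to a 2-D lens by classical metric MDS of the
# Bray-Curtis distance matrix. A rectangular cover of overlapping bins is
# laid over the lens; inside each cover cell the samples are grouped by
# density clustering (single-linkage components of the eps-neighbourhood
# graph, eps taken from a percentile of the global distance distribution,
# discarding clusters below a minimum size). Clusters become nodes; nodes
# sharing samples are linked. The SAFE score of a variable on a node is a
# normalised permutation -log10 p for the concentration of that variable
# in the node's 1-hop network neighbourhood.

#' Mapper/SAFE configuration
#'
#' @param resolution bins per lens dimension (default 40).
#' @param overlap fraction of each bin shared with its neighbour, in
#'   `[0, 1)` (default 0.75).
#' @param min_samples minimum cluster size for a node (default 2).
#' @param eps_percentile percentile of the global pairwise-distance
#'   distribution used as the clustering radius (default 98).
#' @param n_perm permutations for SAFE scoring (default 1000).
#' @param seed integer seed.
#' @return a list of class `tda_config`.
#' @export
tda_config <- function(resolution = 40, overlap = 0.75, min_samples = 2,
                       eps_percentile = 98, n_perm = 1000, seed = 1) {
  stopifnot(resolution >= 2, overlap >= 0, overlap < 1,
            eps_percentile > 0, eps_percentile <= 100, min_samples >= 1)
  structure(list(resolution = resolution, overlap = overlap,
                 min_samples = min_samples,
                 eps_percentile = eps_percentile, n_perm = n_perm,
                 seed = seed), class = "tda_config")
}

#' Classical MDS lens
#'
#' Double-centred spectral embedding of a distance matrix into k
#' dimensions. Deterministic up to axis sign; the sign of each axis is
#' fixed so that its largest-magnitude coordinate is positive.
#'
#' @param dist a distance matrix (e.g. `1 - community_similarity(...)`).
#' @param k number of lens dimensions (default 2).
#' @return an n x k coordinate matrix (zero-padded if the embedding has
#'   lower rank).
#' @export
mds_lens <- function(dist, k = 2) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (all(d == 0)) {
    out <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
    return(out)
  }
  sol <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k,
                                          eig = TRUE))
  coords <- sol$points
  if (ncol(coords) < k) {
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  # axes with (numerically) zero eigenvalue carry no structure, only
  # floating-point noise; zero them so degenerate directions cannot split
  # identical samples across cover bins
  ev <- pmax(sol$eig, 0)
  negligible <- ev[seq_len(k)] <= max(ev) * 1e-8
  coords[, which(negligible)] <- 0
  for (j in seq_len(k)) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(d)
  coords
}

# single-linkage components of the eps-neighbourhood graph within a cell;
# returns a list of integer index vectors of size >= min_samples
eps_clusters <- function(idx, dmat, eps, min_samples) {
  if (length(idx) < min_samples) return(list())
  sub <- dmat[idx, idx, drop = FALSE]
  adj <- sub <= eps
  n <- length(idx)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  out <- split(idx, comp)
  out[lengths(out) >= min_samples]
}

#' Build a Mapper network of samples
#'
#' @param lens n x 2 lens coordinates (see [mds_lens()]).
#' @param dist n x n distance matrix over the same samples.
#' @param cfg a [tda_config()].
#' @return a list of class `tda_network`: `graph` (igraph; vertex
#'   attribute `members` holds sample ids), `members` (list), `samples`
#'   (all sample ids), `membership` (node x sample logical matrix),
#'   `cfg`. Empty covers yield an empty network with a warning.
#' @export
mapper_network <- function(lens, dist, cfg = tda_config()) {
  d <- as.matrix(dist)
  stopifnot(nrow(lens) == nrow(d))
  samples <- rownames(d) %||% paste0("S", seq_len(nrow(d)))
  eps <- stats::quantile(d[upper.tri(d)], cfg$eps_percentile / 100,
                         names = FALSE, type = 7)
  R <- cfg$resolution
  clusters <- list()
  intervals <- function(v) {
    lo <- min(v); hi <- max(v)
    stride <- (hi - lo) / R
    if (stride == 0) stride <- 1e-12
    len <- stride / (1 - cfg$overlap)
    starts <- lo + (seq_len(R) - 1) * stride
    cbind(starts, starts + len)
  }
  ix <- intervals(lens[, 1])
  iy <- intervals(lens[, 2])
  for (i in seq_len(R)) {
    in_x <- lens[, 1] >= ix[i, 1] & lens[, 1] <= ix[i, 2]
    if (!any(in_x)) next
    for (j in seq_len(R)) {
      cell <- which(in_x & lens[, 2] >= iy[j, 1] & lens[, 2] <= iy[j, 2])
      clusters <- c(clusters, eps_clusters(cell, d, eps, cfg$min_samples))
    }
  }
  # drop duplicate nodes (identical member sets from overlapping cells)
  if (length(clusters)) {
    keys <- vapply(clusters, function(x) paste(sort(x), collapse = ","),
                   character(1))
    clusters <- clusters[!duplicated(keys)]
  }
  if (!length(clusters)) {
    warning("no cover cell reached min_samples; empty Mapper network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g, members = list(), samples = samples,
                          membership = matrix(FALSE, 0, length(samples),
                                              dimnames = list(NULL, samples)),
                          cfg = cfg), class = "tda_network"))
  }
  k <- length(clusters)
  membership <- matrix(FALSE, k, length(samples),
                       dimnames = list(paste0("node", seq_len(k)), samples))
  for (q in seq_len(k)) membership[q, clusters[[q]]] <- TRUE
  shared <- membership %*% t(membership) # counts of shared samples
  adj <- shared > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$members <- lapply(clusters, function(x) samples[x])
  structure(list(graph = g,
                 members = lapply(clusters, function(x) samples[x]),
                 samples = samples, membership = membership, cfg = cfg),
            class = "tda_network")
}

#' @export
print.tda_network <- function(x, ...) {
  cat(sprintf("Mapper network: %d nodes, %d edges over %d samples\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$samples)))
  invisible(x)
}

#' SAFE enrichment scores on a Mapper network
#'
#' For each node, the observed statistic is the sum of node-mean variable
#' values over the node's 1-hop neighbourhood (itself plus adjacent
#' nodes). The null redistributes the sample-to-value assignment
#' `n_perm` times; the empirical enrichment p is
#' (exceedances + 1)/(n_perm + 1), and
#' SAFE = -log10(p) / -log10(1/(n_perm + 1)), in (0, 1], reaching 1 only
#' at the minimum attainable p. Enrichment flags use BH-adjusted p < 0.05
#' across nodes.
#'
#' @param net a [mapper_network()] result.
#' @param variables data.frame or named numeric vector of per-sample
#'   values (numeric or one-hot categorical), rows/names matching the
#'   network's samples.
#' @param cfg a [tda_config()]; `n_perm` and `seed` are used.
#' @return a list with matrices `safe` (nodes x variables), `p`, `p_adj`,
#'   `enriched` (logical).
#' @export
safe_scores <- function(net, variables, cfg = net$cfg) {
  if (is.null(dim(variables))) {
    variables <- data.frame(variable = variables)
  }
  V <- as.matrix(variables)
  if (nrow(V) != length(net$samples)) {
    stop("variables must have one row per sample")
  }
  if (!is.null(rownames(V))) V <- V[net$samples, , drop = FALSE]
  k <- nrow(net$membership)
  if (k == 0) stop("empty Mapper network")
  sizes <- rowSums(net$membership)
  Mavg <- sweep(net$membership * 1, 1, sizes, "/") # node-mean operator
  A1 <- as.matrix(igraph::as_adjacency_matrix(net$graph)) + diag(k)
  NB <- A1 %*% Mavg # neighbourhood-sum operator on sample values
  obs <- NB %*% V
  set.seed(cfg$seed)
  n <- ncol(net$membership)
  exceed <- matrix(0L, k, ncol(V))
  for (b in seq_len(cfg$n_perm)) {
    perm <- NB %*% V[sample.int(n), , drop = FALSE]
    exceed <- exceed + (perm >= obs)
  }
  p <- (exceed + 1) / (cfg$n_perm + 1)
  safe <- -log10(p) / -log10(1 / (cfg$n_perm + 1))
  p_adj <- apply(p, 2, stats::p.adjust, method = "BH")
  if (k == 1) p_adj <- matrix(p_adj, 1, ncol(V))
  enriched <- p_adj < 0.05
  dn <- list(rownames(net$membership), colnames(V))
  dimnames(p) <- dimnames(safe) <- dimnames(p_adj) <- dimnames(enriched) <- dn
  list(safe = safe, p = p, p_adj = p_adj, enriched = enriched)
}

#' Most-enriched variable per node
#'
#' For each node, the enriched variable with the maximum SAFE score; ties
#' are broken lexicographically by variable name. Nodes with no enriched
#' variable are labelled `"none"`.
#'
#' @param net a [mapper_network()] result.
#' @param safe_result output of [safe_scores()] on several variables.
#' @return a data.frame with columns `node`, `dominant`, `safe`.
#' @export
dominant_variable_map <- function(net, safe_result) {
  s <- safe_result$safe
  e <- safe_result$enriched
  vars <- colnames(s)
  ord <- order(vars)
  dominant <- character(nrow(s))
  score <- rep(NA_real_, nrow(s))
  for (i in seq_len(nrow(s))) {
    cand <- which(e[i, ])
    if (!length(cand)) {
      dominant[i] <- "none"
      next
    }
    cand <- cand[order(-s[i, cand], vars[cand])] # lexicographic tie-break
    dominant[i] <- vars[cand[1]]
    score[i] <- s[i, cand[1]]
  }
  data.frame(node = rownames(s), dominant = dominant, safe = score,
             row.names = NULL, stringsAsFactors = FALSE)
}
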