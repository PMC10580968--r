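# Brute-force graph-metric oracle: explicit BFS shortest-path enumeration,
# independent of igraph. Only for small graphs (<= ~15 nodes).

# adj: symmetric logical/0-1 adjacency matrix without self loops
bf_shortest_paths <- function(adj) {
  n <- nrow(adj)
  dmat <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n) # number of distinct shortest paths
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    sig <- rep(0, n)
    dist[s] <- 0
    sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (is.infinite(dist[v])) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[v] == dist[u] + 1) sig[v] <- sig[v] + sig[u]
        }
      }
      frontier <- unique(nxt)
    }
    dmat[s, ] <- dist
    sigma[s, ] <- sig
  }
  list(d = dmat, sigma = sigma)
}

bf_graph_metrics <- function(adj) {
  n <- nrow(adj)
  sp <- bf_shortest_paths(adj)
  d <- sp$d
  sigma <- sp$sigma
  degree <- rowSums(adj > 0)
  # betweenness: sum over unordered pairs (s,t), s,t != v, of the fraction
  # of s-t shortest paths through v
  bet <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v) next
        if (!is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    bet[v] <- acc
  }
  bet_norm <- if (n > 2) bet / ((n - 1) * (n - 2) / 2) else bet
  closeness <- vapply(seq_len(n), function(v) {
    dd <- d[v, -v]
    sum(1 / dd[is.finite(dd)]) / (n - 1)
  }, numeric(1))
  clustering <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    mean(adj[cbind(pairs[1, ], pairs[2, ])] > 0)
  }, numeric(1))
  # components by BFS on finite distances; diameter of the largest
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    comp[is.finite(d[s, ])] <- cur
  }
  giant <- which(comp == which.max(tabulate(comp)))
  dg <- d[giant, giant, drop = FALSE]
  diameter <- if (length(giant) > 1) max(dg[is.finite(dg)]) else 0
  list(degree = degree, betweenness = bet_norm, closeness = closeness,
       clustering = clustering, component = comp, diameter = diameter)
}

random_adjacency <- function(n, p = 0.25) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}
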