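test_that("prevalence filter applies a strict 0.1% rule", {
  m <- matrix(c(5L, 2L, 1L, 9992L,
                5L, 2L, 0L, 9993L), 2, byrow = TRUE,
              dimnames = list(c("a", "b"),
                              c("kept", "exactly", "below", "big")))
  # relative abundances: kept 5e-4? scale so thresholds are exact
  m2 <- matrix(c(20L, 10L, 5L, 9965L,
                 20L, 10L, 5L, 9965L), 2, byrow = TRUE,
               dimnames = list(c("a", "b"),
                               c("kept", "exactly", "below", "big")))
  f <- prevalence_filter(otu_table(m2), 0.001)
  expect_true("kept" %in% colnames(f))      # 0.2% > 0.1%
  expect_false("exactly" %in% colnames(f))  # exactly 0.1% is excluded
  expect_false("below" %in% colnames(f))    # 0.05%
})

test_that("basis variances solve the sparsity linear system exactly", {
  # hand-set symmetric t for 3 taxa; equations:
  #   t12 + t13 = 2*w1 + w2 + w3, etc.  => A w = rowSums(t), A = I + J
  t_mat <- matrix(c(0, 0.6, 0.8,
                    0.6, 0, 1.0,
                    0.8, 1.0, 0), 3, byrow = TRUE)
  A <- matrix(1, 3, 3) + diag(3)
  expected <- solve(A, rowSums(t_mat))
  expect_equal(unname(sparcc_basis_variances(t_mat)), expected,
               tolerance = 1e-12)
  # 4-taxon system with pair (1,2) excluded: partner sets shrink to
  # S1 = {3,4}, S2 = {3,4}, S3 = S4 = {1,2,3,4}\{self}
  t4 <- matrix(c(0, .6, .8, .5,
                 .6, 0, 1.0, .7,
                 .8, 1.0, 0, .9,
                 .5, .7, .9, 0), 4, byrow = TRUE)
  B <- matrix(1, 4, 4) - diag(4)
  B[1, 2] <- B[2, 1] <- 0
  A2 <- B + diag(rowSums(B))
  rhs <- rowSums(t4 * B)
  expected2 <- solve(A2, rhs)
  got2 <- sparcc_basis_variances(t4, matrix(c(1L, 2L), 1))
  expect_equal(unname(got2), pmax(expected2, 1e-12), tolerance = 1e-12)
})

test_that("SparCC recovers a planted correlated pair and its sign", {
  tab <- sparcc_base_table(seed = 61)
  rho <- matrix(c(1, .9, .9, 1), 2)
  pos <- plant_correlated_block(tab, c(10, 11), rho, seed = 62)
  r <- sparcc_correlations(pos, n_dirichlet = 10, seed = 63)
  expect_gte(r["OTU0010", "OTU0011"], 0.6)
  neg <- plant_correlated_block(tab, c(10, 11),
                                matrix(c(1, -.9, -.9, 1), 2), seed = 62)
  rn <- sparcc_correlations(neg, n_dirichlet = 10, seed = 63)
  expect_lte(rn["OTU0010", "OTU0011"], -0.6)
})

test_that("SparCC is invariant to taxon order and per-sample scaling", {
  # independent log-normal abundance variation: the regime SparCC assumes
  base <- sparcc_base_table(n_taxa = 20, n_samples = 80, depth = 5000,
                            seed = 64)
  tab <- plant_correlated_block(base, 1:20, diag(20), seed = 640)
  r0 <- sparcc_correlations(tab, n_dirichlet = 10, seed = 65)
  set.seed(1)
  perm <- sample(20)
  r1 <- sparcc_correlations(otu_table(unclass(tab)[, perm]),
                            n_dirichlet = 10, seed = 65)
  expect_lt(max(abs(r1[colnames(r0), colnames(r0)] - r0)),
            0.1) # Dirichlet resampling noise only
  # compositional invariance: tripling a sample's counts barely moves r
  m <- unclass(tab)[, seq_len(20)]
  m[1:10, ] <- m[1:10, ] * 3L
  r2 <- sparcc_correlations(otu_table(m), n_dirichlet = 10, seed = 65)
  expect_lt(max(abs(r2 - r0)), 0.15)
  expect_error(sparcc_correlations(otu_table(m[, 1:3])), "at least 4")
  mz <- cbind(m[, 1:5], zero = 0L)
  expect_error(sparcc_correlations(otu_table(mz)), "all-zero")
})

test_that("permutation p-values hit the floor for real pairs and stay in (0,1]", {
  tab <- sparcc_base_table(n_taxa = 15, n_samples = 100, depth = 5000,
                           seed = 66)
  pl <- plant_correlated_block(tab, c(3, 4), matrix(c(1, .9, .9, 1), 2),
                               seed = 67)
  r <- sparcc_correlations(pl, n_dirichlet = 10, seed = 68)
  p <- sparcc_pvalues(pl, r, n_perm = 24, seed = 69, n_dirichlet = 3)
  expect_equal(p["OTU0003", "OTU0004"], 1 / 25) # minimum attainable
  expect_true(all(p > 0 & p <= 1))
  expect_equal(p, t(p))
})

test_that("edge filtering keeps |r| > 0.6 with p < 0.05, recording sign", {
  ids <- paste0("O", 1:4)
  r <- diag(4)
  dimnames(r) <- list(ids, ids)
  p <- matrix(1, 4, 4, dimnames = dimnames(r))
  r["O1", "O2"] <- r["O2", "O1"] <- 0.61; p["O1", "O2"] <- p["O2", "O1"] <- 0.01
  r["O1", "O3"] <- r["O3", "O1"] <- 0.61; p["O1", "O3"] <- p["O3", "O1"] <- 0.06
  r["O2", "O4"] <- r["O4", "O2"] <- -0.70; p["O2", "O4"] <- p["O4", "O2"] <- 0.01
  net <- build_network(r, p)
  el <- igraph::as_data_frame(net)
  expect_equal(nrow(el), 2)
  expect_setequal(el$sign, c("+", "-"))
  expect_false("O3" %in% igraph::V(net)$name) # isolated after filtering
  expect_true("O3" %in% igraph::graph_attr(net, "isolated_nodes"))
  # literal positive-only reading drops the strong negative edge
  net_pos <- build_network(r, p, positive_only = TRUE)
  expect_equal(igraph::ecount(net_pos), 1)
})

test_that("network summaries match hand enumeration and the mean-degree identity", {
  tri <- igraph::make_ring(3)
  s <- network_summary(tri)
  expect_equal(s$mean_degree, 2)
  expect_equal(s$diameter, 1)
  expect_equal(s$clustering_coefficient, 1)
  path4 <- igraph::make_graph(~ a - b - c - d)
  s4 <- network_summary(path4)
  expect_equal(s4$diameter, 3)
  expect_equal(s4$mean_degree, 1.5)
  expect_equal(s4$clustering_coefficient, 0)
  set.seed(70)
  g <- igraph::sample_gnm(110, 174)
  expect_equal(network_summary(g)$mean_degree, 3.164)
})

test_that("topology metrics agree with the brute-force shortest-path oracle", {
  set.seed(71)
  for (k in 1:20) {
    n <- sample(4:15, 1)
    adj <- random_adjacency(n, p = runif(1, 0.15, 0.5))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    got <- node_metrics(g)
    orc <- bf_graph_metrics(adj)
    expect_equal(got$degree, unname(orc$degree))
    expect_equal(got$betweenness, orc$betweenness, tolerance = 1e-10)
    expect_equal(got$closeness, orc$closeness, tolerance = 1e-10)
    expect_equal(got$clustering, orc$clustering, tolerance = 1e-10)
    expect_equal(network_summary(g)$diameter, orc$diameter)
    # component labels agree up to relabelling
    expect_equal(length(unique(got$component)),
                 length(unique(orc$component)))
  }
})

test_that("role classification: star hub, clique-periphery keystone, exclusivity", {
  star <- igraph::make_star(6, mode = "undirected")
  roles <- classify_roles(node_metrics(star))
  centre <- which.max(roles$degree)
  expect_equal(roles$role[centre], "hub")
  expect_false(any(roles$role == "keystone" & roles$role == "hub"))
  # K6 clique with a 6-node tail hanging off node 1: clique periphery has
  # high degree and closeness but zero betweenness -> keystone
  g <- igraph::make_full_graph(6)
  g <- igraph::add_vertices(g, 6)
  g <- igraph::add_edges(g, c(1, 7, 7, 8, 8, 9, 9, 10, 10, 11, 11, 12))
  mets <- classify_roles(node_metrics(g))
  # brute-force percentile oracle on the same metrics
  orc <- bf_graph_metrics(as.matrix(igraph::as_adjacency_matrix(g)))
  thr <- function(x, q) sort(x)[ceiling(q * length(x))]
  o_hub <- orc$degree >= thr(orc$degree, 0.7) &
    orc$betweenness >= thr(orc$betweenness, 0.7)
  o_key <- orc$degree >= thr(orc$degree, 0.7) &
    orc$closeness >= thr(orc$closeness, 0.7) &
    orc$betweenness <= thr(orc$betweenness, 0.3) & !o_hub
  expect_equal(mets$role == "hub", o_hub)
  expect_equal(mets$role == "keystone", o_key)
  expect_true(any(mets$role == "keystone"))
  expect_setequal(which(mets$role == "keystone"), 2:6)
  # monotone rescaling of the metrics never changes the labels
  resc <- mets
  resc$degree <- log1p(mets$degree)
  resc$betweenness <- mets$betweenness^3
  resc$closeness <- 2 * mets$closeness + 1
  expect_equal(classify_roles(resc[, c("otu_id", "degree", "betweenness",
                                       "closeness")])$role, mets$role)
  # exclusivity on random graphs
  set.seed(72)
  for (k in 1:20) {
    adj <- random_adjacency(sample(5:15, 1), runif(1, 0.2, 0.6))
    gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    rr <- classify_roles(node_metrics(gg))
    expect_equal(sum(rr$role == "hub" & rr$role == "keystone"), 0)
  }
})

test_that("function overlay reports per-pathway node fractions", {
  g <- igraph::make_ring(10)
  igraph::V(g)$name <- paste0("O", 1:10)
  fn <- data.frame(otu_id = paste0("O", 1:6), pathway = "ASR",
                   present = TRUE)
  ov <- overlay_functions(g, fn)
  expect_equal(unname(ov$fractions["ASR"]), 0.6)
  expect_equal(sum(igraph::V(ov$net)$ASR), 6)
  fn_all <- data.frame(otu_id = paste0("O", 1:10), pathway = "DSR",
                       present = TRUE)
  expect_equal(unname(overlay_functions(g, fn_all)$fractions["DSR"]), 1)
  expect_warning(ov0 <- overlay_functions(g, fn[0, ]), "empty")
  expect_length(ov0$fractions, 0)
})
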