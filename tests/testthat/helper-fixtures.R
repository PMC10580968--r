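# Shared fixtures: all synthetic, generated in code at test time.

# tiny deterministic OTU table (3 samples x 4 OTUs)
tiny_table <- function() {
  otu_table(matrix(c(10L, 0L, 5L, 85L,
                     0L, 10L, 5L, 85L,
                     3L, 3L, 3L, 91L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("S1", "S2", "S3"),
                                   c("O1", "O2", "O3", "O4"))))
}

# two well-separated sample clusters: distinct metacommunities, tight
# within-cluster composition (high Nm), returned with the cluster labels
two_cluster_table <- function(n_per = 30, n_taxa = 120, depth = 2000,
                              seed = 1) {
  a <- simulate_neutral_table(neutral_sim_spec(
    n_taxa = n_taxa, n_samples = n_per, depth = depth, Nm = 5000,
    seed = seed))
  b <- simulate_neutral_table(neutral_sim_spec(
    n_taxa = n_taxa, n_samples = n_per, depth = depth, Nm = 5000,
    seed = seed + 500))
  m <- rbind(unclass(a)[, seq_len(n_taxa)], unclass(b)[, seq_len(n_taxa)])
  rownames(m) <- sprintf("S%03d", seq_len(2 * n_per))
  colnames(m) <- sprintf("OTU%04d", seq_len(n_taxa))
  list(table = otu_table(m),
       label = rep(c("A", "B"), each = n_per))
}

# base table for correlation planting: moderate richness, many samples
sparcc_base_table <- function(n_taxa = 50, n_samples = 200, depth = 10000,
                              seed = 1) {
  simulate_neutral_table(neutral_sim_spec(
    n_taxa = n_taxa, n_samples = n_samples, depth = depth, Nm = 2000,
    meta_param = 1.5, seed = seed))
}
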