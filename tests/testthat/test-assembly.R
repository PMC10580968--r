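test_that("haversine distance is a metric with the right scale", {
  expect_equal(haversine_km(c(10, 20), c(10, 20)), 0)
  # quarter great circle: pi * 6371 / 2
  expect_equal(haversine_km(c(0, 0), c(0, 90)), pi * 6371 / 2,
               tolerance = 1e-6)
  expect_equal(haversine_km(c(12, 34), c(-5, 101)),
               haversine_km(c(-5, 101), c(12, 34)))
  set.seed(1)
  for (k in 1:20) {
    pts <- cbind(runif(3, -90, 90), runif(3, -180, 180))
    ab <- haversine_km(pts[1, ], pts[2, ])
    bc <- haversine_km(pts[2, ], pts[3, ])
    ac <- haversine_km(pts[1, ], pts[3, ])
    expect_lte(ac, ab + bc + 1e-9)
  }
  expect_error(haversine_km(c(91, 0), c(0, 0)), "latitude")
})

test_that("Bray-Curtis similarity matches hand computation", {
  tab <- tiny_table()
  s <- community_similarity(tab)
  expect_equal(diag(s), c(S1 = 1, S2 = 1, S3 = 1))
  expect_equal(s, t(s))
  # (10,0,5,85) vs (0,10,5,85): 1 - (10+10)/(100+100) = 0.9
  expect_equal(s["S1", "S2"], 0.9)
  # fully disjoint samples have similarity 0
  d <- otu_table(matrix(c(5L, 0L, 0L, 7L), 2))
  expect_equal(community_similarity(d)[1, 2], 0)
  # the worked 3-OTU pair: (10,0,5) vs (0,10,5) -> 1 - 20/30
  e <- otu_table(matrix(c(10L, 0L, 5L, 0L, 10L, 5L), 2, byrow = TRUE))
  expect_equal(community_similarity(e)[1, 2], 1 - 20 / 30)
})

test_that("distance-decay regression flags degenerate input and negates on dissimilarity", {
  md <- simulate_coastline_metadata(15, seed = 3)
  dk <- pairwise_distance_km(md)
  # identical communities everywhere: zero variance in similarity
  m <- matrix(rep(c(10L, 20L, 30L), each = 15), 15)
  s <- community_similarity(otu_table(m))
  fit <- distance_decay_fit(s, dk)
  expect_true(fit$degenerate)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r, 0)
  # slope on similarity is the negative of the slope on dissimilarity
  tab <- plant_gradient(simulate_neutral_table(neutral_sim_spec(
    n_taxa = 150, n_samples = 15, depth = 1500, Nm = 2000, seed = 4)),
    md, 0.002, seed = 5)
  s2 <- community_similarity(tab)
  f_sim <- distance_decay_fit(s2, dk, n_perm = 49)
  f_dis <- distance_decay_fit(1 - s2, dk, n_perm = 49)
  # (1 - s) has intercept 1 - a and slope -b
  expect_equal(f_dis$slope, -f_sim$slope)
  expect_equal(f_sim$n_pairs, 15 * 14 / 2)
})

test_that("permuting sample labels destroys the planted decay signal", {
  md <- simulate_coastline_metadata(30, seed = 8)
  dk <- pairwise_distance_km(md)
  tab <- plant_gradient(simulate_neutral_table(neutral_sim_spec(
    n_taxa = 200, n_samples = 30, depth = 1500, Nm = 2000, seed = 9)),
    md, 0.002, seed = 10)
  s <- community_similarity(tab)
  obs <- distance_decay_fit(s, dk, n_perm = 49)$slope
  set.seed(11)
  perm_slopes <- replicate(20, {
    idx <- sample(nrow(s))
    distance_decay_fit(s[idx, idx], dk, n_perm = 0)$slope
  })
  expect_lt(mean(abs(perm_slopes)), abs(obs))
})

test_that("neutral occurrence curve: closed form, integration, monotonicity", {
  # Beta(1, 99) tail at d = 1e-4: (1 - d)^99
  expect_equal(ncm_predicted_freq(0.01, 100, 1e-4), (1 - 1e-4)^99,
               tolerance = 1e-9)
  expect_equal(round(ncm_predicted_freq(0.01, 100, 1e-4), 6), 0.990148)
  # matches numeric integration of the beta density on a grid
  grid <- expand.grid(p = c(1e-4, 1e-3, 0.01, 0.1, 0.5),
                      Nm = c(10, 100, 1000, 1e4),
                      d = c(1e-5, 1e-4, 1e-3, 0.01, 0.1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    num <- stats::integrate(function(x) dbeta(x, g$Nm * g$p,
                                              g$Nm * (1 - g$p)),
                            g$d, 1, rel.tol = 1e-12, abs.tol = 1e-12)$value
    expect_equal(ncm_predicted_freq(g$p, g$Nm, g$d), num, tolerance = 1e-8)
  }
  # monotone increasing in p; tends to 1 when p >> d and Nm large
  p_seq <- 10^seq(-5, -0.5, length.out = 40)
  f <- ncm_predicted_freq(p_seq, 500, 1e-4)
  expect_true(all(diff(f) >= -1e-12))
  expect_equal(ncm_predicted_freq(0.1, 1e8, 1e-4), 1, tolerance = 1e-9)
})

test_that("fit_ncm depends only on per-OTU sufficient statistics and not on ordering", {
  tab <- simulate_neutral_table(neutral_sim_spec(
    n_taxa = 150, n_samples = 50, depth = 2000, Nm = 700, seed = 12))
  f0 <- fit_ncm(tab)
  m <- unclass(tab)[, seq_len(150)]
  # shuffling counts within each OTU across samples preserves p_mean, F_obs
  set.seed(13)
  shuf <- apply(m, 2, sample)
  rownames(shuf) <- rownames(m)
  f1 <- suppressMessages(fit_ncm(otu_table(shuf)))
  # row totals wobble slightly under the shuffle, so equality is approximate
  expect_equal(f1$Nm, f0$Nm, tolerance = 0.02)
  expect_equal(f1$R2, f0$R2, tolerance = 0.02)
  # OTU and sample order invariance
  perm <- otu_table(m[rev(seq_len(nrow(m))), sample(ncol(m))])
  f2 <- fit_ncm(perm)
  expect_equal(f2$Nm, f0$Nm, tolerance = 1e-6)
  # envelope invariants
  expect_true(all(f0$otus$CI_lo <= f0$otus$F_pred + 1e-12))
  expect_true(all(f0$otus$F_pred <= f0$otus$CI_hi + 1e-12))
  expect_true(all(f0$otus$F_obs >= 0 & f0$otus$F_obs <= 1))
  expect_lte(f0$R2, 1)
})

test_that("habitat-confined communities fit the neutral curve poorly", {
  # taxa restricted to single habitats: occupancy is capped far below the
  # neutral expectation for their abundance, so R2 collapses
  set.seed(14)
  n_hab <- 5
  per <- 12
  n_taxa <- 200
  hab_of_taxon <- rep_len(seq_len(n_hab), n_taxa)
  m <- matrix(0L, n_hab * per, n_taxa)
  for (j in seq_len(n_taxa)) {
    rows <- ((hab_of_taxon[j] - 1) * per + 1):(hab_of_taxon[j] * per)
    m[rows, j] <- rpois(per, rlnorm(1, 2, 1))
  }
  m <- m[rowSums(m) > 0, colSums(m) > 0]
  f <- suppressMessages(fit_ncm(otu_table(m)))
  expect_lt(f$R2, 0.2)
})
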