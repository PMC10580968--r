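# Synthetic OTU tables with known, planted structure: neutral assembly,
# spatial distance decay, habitat specialists, and correlated taxon blocks.
# Every downstream stage has a parameter-recovery test against these
# generators, so the pipeline is verifiable without any deposited reads.

#' Specification for a neutral-assembly simulation
#'
#' Defines a metacommunity and the Sloan-model sampling regime used by
#' [simulate_neutral_table()]. `Nm` is the product of local community size
#' and immigration rate: large `Nm` means local communities track the
#' metacommunity closely, small `Nm` means strong drift.
#'
#' @param n_taxa number of taxa in the metacommunity.
#' @param n_samples number of local communities (samples).
#' @param depth reads per sample.
#' @param Nm dimensionless migration-times-size parameter (> 0).
#' @param metacommunity shape of the metacommunity abundance distribution.
#' @param meta_param shape parameter: `sdlog` of the log-normal, or the
#'   log-series parameter theta in (0, 1).
#' @param seed integer seed.
#' @return a list of class `neutral_sim_spec`.
#' @export
neutral_sim_spec <- function(n_taxa = 500, n_samples = 200, depth = 10000,
                             Nm = 1000,
                             metacommunity = c("lognormal", "logseries"),
                             meta_param = NULL, seed = 1) {
  metacommunity <- match.arg(metacommunity)
  if (is.null(meta_param)) {
    meta_param <- if (metacommunity == "lognormal") 2 else 0.999
  }
  stopifnot(Nm > 0, depth >= 1, n_taxa >= 2, n_samples >= 1)
  structure(list(n_taxa = n_taxa, n_samples = n_samples, depth = depth,
                 Nm = Nm, metacommunity = metacommunity,
                 meta_param = meta_param, seed = seed),
            class = "neutral_sim_spec")
}

# log-series (logarithmic) abundance sampler by inverse CDF
rlogseries <- function(n, theta) {
  stopifnot(theta > 0, theta < 1)
  u <- runif(n)
  k <- integer(n)
  norm <- -log(1 - theta)
  for (i in seq_len(n)) {
    cum <- 0; j <- 0
    repeat {
      j <- j + 1
      cum <- cum + theta^j / (j * norm)
      if (cum >= u[i] || j > 1e6) break
    }
    k[i] <- j
  }
  k
}

# metacommunity relative abundances implied by a spec (deterministic in seed)
metacommunity_proportions <- function(spec) {
  set.seed(spec$seed)
  p <- switch(spec$metacommunity,
    lognormal = rlnorm(spec$n_taxa, 0, spec$meta_param),
    logseries = as.numeric(rlogseries(spec$n_taxa, spec$meta_param))
  )
  p / sum(p)
}

#' Simulate an OTU table under Sloan neutral assembly
#'
#' For each taxon with metacommunity proportion p, the latent local
#' proportion in each sample is drawn from Beta(Nm*p, Nm*(1-p)) -- the
#' stationary abundance distribution the neutral model encodes -- then
#' latent proportions are renormalised within the sample and reads drawn
#' multinomially at the configured depth. Taxa whose Beta shape underflows
#' to zero fall back to a Bernoulli(p) presence draw.
#'
#' @param spec a [neutral_sim_spec()].
#' @return an [otu_table()] with attribute `metacommunity_p` holding the
#'   true metacommunity proportions.
#' @export
simulate_neutral_table <- function(spec) {
  stopifnot(inherits(spec, "neutral_sim_spec"))
  p <- metacommunity_proportions(spec)
  set.seed(spec$seed + 1L)
  counts <- matrix(0L, spec$n_samples, spec$n_taxa)
  a1 <- spec$Nm * p
  a2 <- spec$Nm * (1 - p)
  under <- a1 == 0 | !is.finite(a1)
  for (i in seq_len(spec$n_samples)) {
    a <- rbeta(spec$n_taxa, a1, a2)
    a[!is.finite(a)] <- 0
    if (any(under)) a[under] <- ifelse(runif(sum(under)) < p[under], p[under], 0)
    if (sum(a) == 0) a <- p
    counts[i, ] <- as.integer(rmultinom(1, spec$depth, a / sum(a)))
  }
  rownames(counts) <- sprintf("S%03d", seq_len(spec$n_samples))
  colnames(counts) <- sprintf("OTU%04d", seq_len(spec$n_taxa))
  out <- otu_table(counts)
  attr(out, "metacommunity_p") <- p
  out
}

#' Simulate sample metadata along a coastline
#'
#' Places samples along a smooth coastal arc spanning roughly `span_km`,
#' grouped into `n_locations` equally sized locations (sampling sites).
#' Climate covariates (MAT, MAP, MDTR) decline or rise linearly with
#' latitude plus noise, emulating the latitudinal climate gradients of
#' mangrove transects.
#'
#' @param n_samples number of samples.
#' @param n_locations number of discrete locations along the arc.
#' @param span_km approximate along-coast extent of the transect.
#' @param seed integer seed.
#' @return a metadata data.frame (see [read_sample_metadata()]).
#' @export
simulate_coastline_metadata <- function(n_samples = 60, n_locations = 5,
                                        span_km = 3000, seed = 1) {
  set.seed(seed)
  # ~111 km per degree latitude; spread locations along the arc, samples
  # jittered tightly around their location centre
  span_deg <- span_km / 111
  centres <- seq(18, 18 + span_deg, length.out = n_locations)
  loc <- sort(rep_len(seq_len(n_locations), n_samples))
  lat <- centres[loc] + rnorm(n_samples, 0, 0.05)
  lon <- 110 + 0.3 * (lat - 18) + rnorm(n_samples, 0, 0.05)
  df <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    latitude = lat,
    longitude = lon,
    location = paste0("L", loc),
    MAT = 28 - 0.45 * (lat - 18) + rnorm(n_samples, 0, 0.3),
    MAP = 2200 - 35 * (lat - 18) + rnorm(n_samples, 0, 40),
    MDTR = 6 + 0.12 * (lat - 18) + rnorm(n_samples, 0, 0.2),
    region = ifelse(loc <= ceiling(n_locations / 2), "China", "SouthAmerica"),
    stringsAsFactors = FALSE
  )
  validate_sample_metadata(df)
}

#' Plant a spatial gradient into an OTU table
#'
#' Re-draws each sample's counts from a mixture of two endpoint
#' metacommunities, with the mixing weight moving exponentially along the
#' 1-D coastline position (great-circle distance from the southernmost
#' sample). Expected pairwise similarity then declines approximately
#' log-linearly with distance; `strength` is the per-km turnover rate
#' (0 leaves the composition spatially unstructured).
#'
#' @param table an [otu_table()].
#' @param metadata sample metadata with coordinates for all samples.
#' @param strength per-km turnover rate (>= 0).
#' @param seed integer seed.
#' @return an [otu_table()] with the same samples, taxa and per-sample
#'   depths.
#' @export
plant_gradient <- function(table, metadata, strength, seed) {
  stopifnot(strength >= 0)
  m <- unclass_counts(table)
  metadata <- validate_sample_metadata(metadata)
  idx <- match(rownames(m), metadata$sample_id)
  if (anyNA(idx)) stop("metadata missing coordinates for some samples")
  md <- metadata[idx, ]
  anchor <- which.min(md$latitude)
  s <- haversine_km(cbind(md$latitude, md$longitude),
                    c(md$latitude[anchor], md$longitude[anchor]))
  set.seed(seed)
  p_a <- colMeans(relative_abundance(m))
  p_b <- p_a[sample.int(length(p_a))] # same SAD, shuffled identities
  u <- 1 - exp(-strength * s)
  depths <- rowSums(m)
  out <- m
  for (i in seq_len(nrow(m))) {
    p_i <- (1 - u[i]) * p_a + u[i] * p_b
    out[i, ] <- as.integer(rmultinom(1, depths[i], p_i / sum(p_i)))
  }
  res <- otu_table(out)
  attr(res, "planted_strength") <- strength
  res
}

#' Plant habitat specialists into an OTU table
#'
#' Restricts `k` designated taxa to a single habitat each: counts outside
#' the habitat are moved to the sample's most abundant non-planted taxon
#' (preserving depth), and within the habitat the taxon receives a heavily
#' right-skewed abundance profile, so its Levins niche breadth is small by
#' construction.
#'
#' @param table an [otu_table()].
#' @param habitat_labels character/factor of habitat per sample (in row
#'   order of `table`).
#' @param k number of taxa to convert into specialists.
#' @param seed integer seed.
#' @return an [otu_table()] with attribute `planted_specialists` (taxa ids)
#'   and `planted_habitats` (their habitats).
#' @export
plant_specialists <- function(table, habitat_labels, k, seed) {
  m <- unclass_counts(table)
  stopifnot(length(habitat_labels) == nrow(m), k >= 1)
  habitats <- unique(as.character(habitat_labels))
  if (length(habitats) < 2) stop("need at least 2 habitats")
  set.seed(seed)
  candidates <- which(colSums(m) > 0)
  if (length(candidates) < k) stop("not enough non-empty taxa to plant")
  planted <- sample(candidates, k)
  assigned <- habitats[rep_len(seq_along(habitats), k)]
  depths <- rowSums(m)
  for (j in seq_len(k)) {
    tj <- planted[j]
    inside <- as.character(habitat_labels) == assigned[j]
    # remove everywhere first
    removed <- m[, tj]
    m[, tj] <- 0L
    # concentrated, skewed profile within the habitat
    target_total <- max(sum(removed), 10L * sum(inside))
    w <- rlnorm(sum(inside), 0, 1.5)
    alloc <- as.integer(round(target_total * w / sum(w)))
    if (all(alloc == 0)) alloc[which.max(w)] <- 1L
    m[inside, tj] <- alloc
    # rebalance every sample back to its original depth using the most
    # abundant non-planted taxon as the filler
    for (i in seq_len(nrow(m))) {
      diff <- depths[i] - sum(m[i, ])
      if (diff == 0) next
      others <- setdiff(order(m[i, ], decreasing = TRUE), planted)
      filler <- others[1]
      m[i, filler] <- max(0L, m[i, filler] + diff)
    }
  }
  res <- otu_table(m)
  attr(res, "planted_specialists") <- colnames(m)[planted]
  attr(res, "planted_habitats") <- assigned
  res
}

#' Plant a correlated taxon block into an OTU table
#'
#' Overwrites the latent proportions of the designated taxa with a
#' log-normal copula: log-abundances are multivariate normal with the
#' target correlation matrix around each taxon's mean relative abundance,
#' then every sample is compositionally closed and re-drawn multinomially
#' at its original depth. The constant-sum closure means planted
#' correlations survive only approximately; recovery tests account for
#' this.
#'
#' @param table an [otu_table()].
#' @param taxa indices or names of the taxa in the block.
#' @param rho_matrix target correlation matrix on log-abundances (positive
#'   definite, unit diagonal).
#' @param seed integer seed.
#' @param sdlog log-scale standard deviation of the planted abundances.
#' @return an [otu_table()], same dimensions and depths.
#' @export
plant_correlated_block <- function(table, taxa, rho_matrix, seed, sdlog = 1) {
  m <- unclass_counts(table)
  if (is.character(taxa)) taxa <- match(taxa, colnames(m))
  if (anyNA(taxa)) stop("unknown taxa in block")
  b <- length(taxa)
  rho_matrix <- as.matrix(rho_matrix)
  stopifnot(nrow(rho_matrix) == b, ncol(rho_matrix) == b)
  if (max(abs(diag(rho_matrix) - 1)) > 1e-10) stop("rho diagonal must be 1")
  if (max(abs(rho_matrix - t(rho_matrix))) > 1e-10) stop("rho must be symmetric")
  ev <- eigen(rho_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("rho matrix must be positive definite")
  L <- chol(rho_matrix)
  set.seed(seed)
  relab <- relative_abundance(m)
  base <- pmax(colMeans(relab)[taxa], 1e-4) # keep the block detectable
  depths <- rowSums(m)
  out <- m
  for (i in seq_len(nrow(m))) {
    z <- as.vector(crossprod(L, rnorm(b)))
    lat <- relab[i, ]
    lat[taxa] <- base * exp(sdlog * z)
    out[i, ] <- as.integer(rmultinom(1, depths[i], lat / sum(lat)))
  }
  res <- otu_table(out)
  attr(res, "planted_block") <- colnames(m)[taxa]
  res
}
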