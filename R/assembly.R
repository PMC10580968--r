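# Stochastic community-assembly signals: distance-decay of similarity and
# the Sloan neutral community model (NCM).
#
# The NCM predicts, for a taxon with metacommunity relative abundance p,
# that its local relative abundance follows Beta(Nm*p, Nm*(1-p)); the
# probability of being observed above a detection limit d is therefore
# F(p) = 1 - I_d(Nm*p, Nm*(1-p)), the regularised incomplete beta tail.
# Nm is estimated by non-linear least squares of observed occurrence
# frequencies on that curve.

#' Great-circle distance in kilometres
#'
#' Haversine distance with Earth radius 6371.0 km. Accepts single points
#' `c(lat, lon)` (decimal degrees) or matrices with columns (lat, lon);
#' arguments are recycled row-wise.
#'
#' @param a,b points as `c(lat, lon)` or 2-column matrices.
#' @return numeric vector of distances in km.
#' @export
haversine_km <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  pts <- cbind(a[, 1], a[, 2], b[rep_len(seq_len(nrow(b)), nrow(a)), , drop = FALSE])
  if (any(abs(pts[, c(1, 3)]) > 90)) stop("latitude out of range")
  if (any(abs(pts[, c(2, 4)]) > 180)) stop("longitude out of range")
  # geosphere wants (lon, lat); radius in the same unit as the result
  geosphere::distHaversine(pts[, c(2, 1), drop = FALSE],
                           pts[, c(4, 3), drop = FALSE], r = 6371.0)
}

#' Pairwise geographic distance matrix for a metadata table
#'
#' @param metadata data.frame with `sample_id`, `latitude`, `longitude`.
#' @return symmetric matrix of km distances, dimnames = sample ids.
#' @export
pairwise_distance_km <- function(metadata) {
  metadata <- validate_sample_metadata(metadata)
  n <- nrow(metadata)
  d <- matrix(0, n, n, dimnames = list(metadata$sample_id, metadata$sample_id))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- haversine_km(
      cbind(metadata$latitude[j], metadata$longitude[j]),
      c(metadata$latitude[i], metadata$longitude[i]))
  }
  d
}

#' Pairwise community similarity
#'
#' Similarity = 1 - dissimilarity; the default (and currently only) metric
#' is abundance-based Bray-Curtis.
#'
#' @param table an [otu_table()], normally rarefied.
#' @param metric dissimilarity metric.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
community_similarity <- function(table, metric = c("bray_curtis")) {
  metric <- match.arg(metric)
  m <- unclass_counts(table)
  if (any(rowSums(m) == 0)) stop("zero-sum sample")
  1 - as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Distance-decay regression of similarity on geographic distance
#'
#' Ordinary least squares of pairwise community similarity on (by default)
#' log10 distance in km, over the upper-triangle sample pairs. Zero
#' distances (replicate sites) are offset to half the minimum non-zero
#' distance before the log transform. Because pairs are not independent,
#' a Mantel permutation p-value (permuting sample labels) is reported
#' alongside the OLS p.
#'
#' @param sim similarity matrix (e.g. [community_similarity()]).
#' @param dist km distance matrix (e.g. [pairwise_distance_km()]).
#' @param transform `"log10_distance"` or `"linear"`.
#' @param n_perm Mantel permutations.
#' @param seed seed for the Mantel permutations.
#' @return an object of class `distance_decay_fit` with elements `slope`,
#'   `intercept`, `r`, `p_ols`, `p_mantel`, `n_pairs`, `degenerate`.
#' @export
distance_decay_fit <- function(sim, dist, transform = c("log10_distance",
                                                        "linear"),
                               n_perm = 999, seed = 1) {
  transform <- match.arg(transform)
  stopifnot(all(dim(sim) == dim(dist)))
  ut <- upper.tri(sim)
  y <- sim[ut]
  d <- dist[ut]
  if (length(unique(round(d, 9))) < 3) stop("fewer than 3 distinct pairs")
  if (transform == "log10_distance") {
    nz <- d[d > 0]
    if (!length(nz)) stop("all pairwise distances are zero")
    d[d == 0] <- min(nz) * 0.5
    x <- log10(d)
  } else {
    x <- d
  }
  degenerate <- stats::var(y) == 0 || stats::var(x) == 0
  if (degenerate) {
    fit <- list(slope = 0, intercept = mean(y), r = 0, p_ols = NA_real_,
                p_mantel = NA_real_, n_pairs = length(y), degenerate = TRUE,
                transform = transform)
    class(fit) <- "distance_decay_fit"
    return(fit)
  }
  mod <- stats::lm(y ~ x)
  co <- summary(mod)$coefficients
  set.seed(seed)
  mant <- vegan::mantel(stats::as.dist(dist), stats::as.dist(1 - sim),
                        permutations = n_perm)
  fit <- list(slope = unname(co[2, 1]), intercept = unname(co[1, 1]),
              r = unname(stats::cor(x, y)), p_ols = unname(co[2, 4]),
              p_mantel = mant$signif, n_pairs = length(y),
              degenerate = FALSE, transform = transform)
  class(fit) <- "distance_decay_fit"
  fit
}

#' @export
print.distance_decay_fit <- function(x, ...) {
  cat(sprintf("Distance-decay fit (%s): slope = %.4g, r = %.3f, n_pairs = %d\n",
              x$transform, x$slope, x$r, x$n_pairs))
  if (!x$degenerate) {
    cat(sprintf("  P(OLS) = %.3g, P(Mantel) = %.3g\n", x$p_ols, x$p_mantel))
  } else {
    cat("  degenerate fit (no variance in similarity or distance)\n")
  }
  invisible(x)
}

#' Neutral-model predicted occurrence frequency
#'
#' F(p) = 1 - I_d(Nm*p, Nm*(1-p)): the probability that a taxon with
#' metacommunity relative abundance p has local relative abundance above
#' the detection limit d under neutral beta sampling.
#'
#' @param p metacommunity relative abundance, in (0, 1); vectorised.
#' @param Nm positive migration-times-size parameter.
#' @param d detection limit, in (0, 1).
#' @return predicted occurrence frequency in `[0, 1]`.
#' @export
ncm_predicted_freq <- function(p, Nm, d) {
  stopifnot(Nm > 0, d > 0, d < 1)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-12)
  stats::pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
}

#' Fit the Sloan neutral community model to an OTU table
#'
#' Per-OTU mean relative abundance (p) and occurrence frequency (fraction
#' of samples with a non-zero count) are fitted to the neutral occurrence
#' curve by bounded non-linear least squares over log10(Nm) in `[0, 9]`
#' with multiple starts. The detection limit defaults to ln(2)/depth: the
#' relative abundance at which a taxon has a 50% chance of being observed
#' at least once in a multinomial read sample, which calibrates the sharp
#' threshold of the model to the smooth detection curve of count data.
#' The 95% envelope is the Wilson score interval of the predicted
#' frequency at n = number of samples.
#'
#' @param table an [otu_table()], rarefied to even depth.
#' @param d detection limit; default `log(2) /` median sample depth.
#' @param bounds bounds on log10(Nm).
#' @param n_starts number of NLS starting points.
#' @return an object of class `ncm_fit`: `Nm`, `m` (= Nm/depth), `d`, `R2`,
#'   `n_samples`, a per-OTU data.frame `otus` (p_mean, F_obs, F_pred,
#'   CI_lo, CI_hi, partition), and `partition_counts`.
#' @export
fit_ncm <- function(table, d = NULL, bounds = c(0, 9), n_starts = 5) {
  m <- unclass_counts(table)
  depths <- rowSums(m)
  depth <- stats::median(depths)
  if (diff(range(depths)) > 0) {
    message("sample depths are uneven; using median depth ", depth,
            " for the detection limit")
  }
  if (is.null(d)) d <- log(2) / depth
  relab <- sweep(m, 1, depths, "/")
  p_mean <- colMeans(relab)
  F_obs <- colMeans(m > 0)
  keep <- p_mean > 0 & p_mean < 1
  if (sum(keep) < 20) stop("need >= 20 detected OTUs to fit the NCM")
  pm <- p_mean[keep]
  fo <- F_obs[keep]
  dat <- data.frame(pm = pm, fo = fo)
  starts <- seq(bounds[1] + 0.5, bounds[2] - 0.5, length.out = n_starts)
  best <- NULL
  diagnostics <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fo ~ stats::pbeta(d, 10^lNm * pm, 10^lNm * (1 - pm),
                          lower.tail = FALSE),
        data = dat, start = list(lNm = s),
        lower = bounds[1], upper = bounds[2],
        control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 200)),
      error = function(e) {
        diagnostics <<- c(diagnostics, conditionMessage(e))
        NULL
      })
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best))) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("NCM non-linear least squares failed from every start:\n  ",
         paste(unique(diagnostics), collapse = "\n  "))
  }
  Nm <- 10^stats::coef(best)[["lNm"]]
  F_pred <- ncm_predicted_freq(pm, Nm, d)
  ss_res <- sum((fo - F_pred)^2)
  R2 <- 1 - ss_res / sum((fo - mean(fo))^2)
  n_samples <- nrow(m)
  ci <- wilson_interval(F_pred, n_samples)
  part <- ifelse(fo > ci[, "upper"], "above",
                 ifelse(fo < ci[, "lower"], "below", "within"))
  otus <- data.frame(otu_id = colnames(m)[keep], p_mean = pm, F_obs = fo,
                     F_pred = F_pred, CI_lo = ci[, "lower"],
                     CI_hi = ci[, "upper"], partition = part,
                     row.names = NULL, stringsAsFactors = FALSE)
  out <- list(Nm = Nm, m = Nm / depth, d = d, R2 = R2,
              n_samples = n_samples, depth = depth, otus = otus,
              partition_counts = table(factor(part, c("above", "within",
                                                      "below"))))
  class(out) <- "ncm_fit"
  out
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan NCM fit: Nm = %.4g (m = %.4g), R2 = %.3f, d = %.3g\n",
              x$Nm, x$m, x$R2, x$d))
  cat(sprintf("  %d OTUs over %d samples; above/within/below 95%% CI: %d/%d/%d\n",
              nrow(x$otus), x$n_samples, x$partition_counts[["above"]],
              x$partition_counts[["within"]], x$partition_counts[["below"]]))
  invisible(x)
}
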