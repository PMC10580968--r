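# Canonical correspondence analysis of community composition against
# environmental/spatial constraints, marginal permutation tests, and
# CCA-based variation partitioning. The ordination engine is vegan; this
# module standardises inputs, extracts the quantities the pipeline reports
# (constrained proportion, eigenvalues, biplot scores, per-factor p) and
# implements partial-CCA variation partitioning on top of it.

#' Canonical correspondence analysis of an OTU table
#'
#' Fits a CCA of the community matrix on the given constraints (centred
#' and scaled). Constant-zero OTU columns are removed; collinear
#' constraints are dropped by the underlying engine and reported.
#'
#' @param table an [otu_table()].
#' @param constraints data.frame of numeric constraint variables (rows in
#'   sample order), e.g. longitude, latitude, MAT, MAP, MDTR.
#' @param scale centre and scale the constraints (default TRUE).
#' @return an object of class `cca_result`: `constrained_proportion`,
#'   `eig_constrained`, `eig_unconstrained`, `total_inertia`,
#'   `site_scores`, `biplot_scores`, `rank`, `aliased`, and the underlying
#'   vegan model as `model`.
#' @export
cca_fit <- function(table, constraints, scale = TRUE) {
  m <- unclass_counts(table)
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  X <- as.data.frame(constraints)
  if (!all(vapply(X, is.numeric, logical(1)))) {
    stop("all constraint columns must be numeric")
  }
  if (nrow(X) != nrow(m)) stop("constraints and table have different samples")
  if (scale) X[] <- lapply(X, function(v) as.numeric(base::scale(v)))
  mod <- vegan::cca(m ~ ., data = X)
  aliased <- tryCatch(rownames(stats::alias(mod)$Complete) %||% character(0),
                      error = function(e) character(0))
  if (length(aliased)) {
    warning("collinear constraint(s) dropped: ", paste(aliased, collapse = ", "))
  }
  eig_c <- mod$CCA$eig
  eig_u <- mod$CA$eig
  total <- mod$tot.chi
  out <- list(
    constrained_proportion = sum(eig_c) / total,
    eig_constrained = eig_c,
    eig_unconstrained = eig_u,
    total_inertia = total,
    site_scores = vegan::scores(mod, display = "sites", choices = 1:min(2, length(eig_c))),
    biplot_scores = vegan::scores(mod, display = "bp", choices = 1:min(2, length(eig_c))),
    rank = mod$CCA$rank,
    aliased = aliased,
    model = mod
  )
  class(out) <- "cca_result"
  out
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("CCA: constrained proportion = %.3f (rank %d, total inertia %.3f)\n",
              x$constrained_proportion, x$rank, x$total_inertia))
  invisible(x)
}

#' Marginal permutation tests for CCA constraints
#'
#' Tests each constraint with the other constraints held fixed (marginal,
#' type-III-like tests): the statistic is the partial constrained inertia
#' and p = (exceedances + 1) / (n_perm + 1), so p is never exactly zero.
#'
#' @param table an [otu_table()].
#' @param constraints data.frame of numeric constraints.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return a data.frame with columns `factor`, `p`.
#' @export
cca_permutation_test <- function(table, constraints, n_perm = 999, seed = 1) {
  fit <- cca_fit(table, constraints)
  set.seed(seed)
  an <- vegan::anova.cca(fit$model, by = "margin", permutations = n_perm)
  rows <- rownames(an)
  keep <- rows != "Residual"
  data.frame(factor = rows[keep], p = an[keep, "Pr(>F)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' CCA-based variation partitioning
#'
#' Partitions the constrained proportion of community inertia among one or
#' two groups of constraints via partial CCAs. For two groups the unique
#' fraction of each group conditions on the other; the shared fraction is
#' the remainder of the joint constrained proportion and may be slightly
#' negative (reported as-is).
#'
#' @param table an [otu_table()].
#' @param groups named list of character vectors of constraint column
#'   names (1 or 2 groups).
#' @param constraints data.frame containing all named columns.
#' @return a list with per-group unique proportions, `shared`, `total`
#'   (joint constrained proportion) and `residual`.
#' @export
vpa <- function(table, groups, constraints) {
  stopifnot(is.list(groups), length(groups) %in% c(1L, 2L))
  X <- as.data.frame(constraints)[, unique(unlist(groups)), drop = FALSE]
  X[] <- lapply(X, function(v) as.numeric(base::scale(v)))
  m <- unclass_counts(table)
  m <- m[, colSums(m) > 0, drop = FALSE]
  prop <- function(formula) {
    mod <- vegan::cca(formula, data = X)
    sum(mod$CCA$eig) / mod$tot.chi
  }
  all_vars <- unlist(groups)
  full <- prop(stats::as.formula(paste(
    "m ~", paste(all_vars, collapse = " + "))))
  if (length(groups) == 1L) {
    return(list(unique = stats::setNames(full, names(groups)[1] %||% "group1"),
                shared = 0, total = full, residual = 1 - full))
  }
  g1 <- groups[[1]]; g2 <- groups[[2]]
  u1 <- prop(stats::as.formula(paste(
    "m ~", paste(g1, collapse = " + "),
    "+ Condition(", paste(g2, collapse = " + "), ")")))
  u2 <- prop(stats::as.formula(paste(
    "m ~", paste(g2, collapse = " + "),
    "+ Condition(", paste(g1, collapse = " + "), ")")))
  shared <- full - u1 - u2
  nm <- names(groups) %||% c("group1", "group2")
  list(unique = stats::setNames(c(u1, u2), nm), shared = shared,
       total = full, residual = 1 - full)
}
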