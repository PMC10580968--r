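# Partitioning OTUs into abundant/rare and generalist/specialist groups.
#
# Abundant taxa exceed 1% relative abundance in at least one sample (strict
# inequality); everything else is rare. Generalists and specialists are the
# top and bottom 10% of the Levins niche-breadth index B, with all taxa
# attaining the minimum B forced into the specialist set regardless of the
# decile cut.

#' Classify OTUs as abundant or rare
#'
#' Abundant: relative abundance strictly greater than `threshold` in at
#' least one sample. Rare: below or equal in all samples. The two classes
#' are exhaustive.
#'
#' @param relab relative-abundance matrix (samples x OTUs, rows sum to 1).
#' @param threshold proportion cut (default 0.01, i.e. 1%).
#' @return a named factor with levels `abundant`, `rare`.
#' @export
classify_abundance <- function(relab, threshold = 0.01) {
  if (!length(relab)) stop("empty table")
  peak <- apply(relab, 2, max)
  cls <- factor(ifelse(peak > threshold, "abundant", "rare"),
                levels = c("abundant", "rare"))
  names(cls) <- colnames(relab)
  cls
}

#' Levins niche-breadth index
#'
#' For OTU j with per-sample shares q_ij = x_ij / sum_i x_ij, the index is
#' B_j = 1 / sum_i q_ij^2 (the inverse Simpson concentration of the OTU's
#' abundance across samples). B ranges from 1 (all abundance in one sample)
#' to the number of samples (perfectly even). OTUs with zero total
#' abundance get `NA`.
#'
#' @param x abundance matrix (samples x OTUs); counts and relative
#'   abundances give identical B on an evenly rarefied table.
#' @return a named numeric vector of B values.
#' @export
levins_niche_breadth <- function(x) {
  x <- unclass_counts(x)
  totals <- colSums(x)
  q <- sweep(x, 2, ifelse(totals > 0, totals, NA), "/")
  B <- 1 / colSums(q^2)
  B[totals == 0] <- NA_real_
  names(B) <- colnames(x)
  B
}

#' Classify OTUs as generalists, specialists or neither
#'
#' Generalists are the top `fraction` of OTUs by niche breadth, specialists
#' the bottom `fraction`; both cuts use the k-th ranked value with
#' k = ceiling(fraction * n) and are inclusive of boundary ties. All OTUs
#' attaining the minimum B are specialists even if they exceed the
#' fraction. If the two cuts overlap (tiny tables or massive ties), the
#' specialist label wins and the overlapping OTUs are removed from the
#' generalist set.
#'
#' @param B named numeric vector of niche-breadth values (NAs are left
#'   unclassified as `neither`).
#' @param fraction decile cut (default 0.10).
#' @return a named factor with levels `generalist`, `specialist`, `neither`.
#' @export
classify_niche <- function(B, fraction = 0.10) {
  ok <- !is.na(B)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 OTUs with defined niche breadth")
  if (n < 10) warning("fewer than 10 OTUs; decile classification is coarse")
  k <- max(1L, as.integer(ceiling(fraction * n)))
  vals <- B[ok]
  gen_thr <- sort(vals, decreasing = TRUE)[k]
  spec_thr <- sort(vals)[k]
  cls <- rep("neither", length(B))
  cls[ok & B >= gen_thr] <- "generalist"
  spec <- ok & (B <= spec_thr | B == min(vals))
  cls[spec] <- "specialist" # specialist wins on overlap
  out <- factor(cls, levels = c("generalist", "specialist", "neither"))
  names(out) <- names(B)
  out
}

#' Full trait partition of an OTU table
#'
#' Computes relative abundances, the abundant/rare split, Levins B and the
#' generalist/specialist split in one pass on the (rarefied) table.
#'
#' @param table an [otu_table()], normally rarefied to even depth.
#' @param abundance_threshold see [classify_abundance()].
#' @param niche_fraction see [classify_niche()].
#' @return a data.frame with columns `otu_id`, `B`, `abundance_class`,
#'   `niche_class`, of class `trait_partition`.
#' @export
trait_partition <- function(table, abundance_threshold = 0.01,
                            niche_fraction = 0.10) {
  relab <- relative_abundance(table)
  B <- levins_niche_breadth(table)
  out <- data.frame(
    otu_id = colnames(relab),
    B = B,
    abundance_class = classify_abundance(relab, abundance_threshold),
    niche_class = classify_niche(B, niche_fraction),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trait_partition", class(out))
  out
}

#' Summarise a trait partition
#'
#' Counts and percentages (1 decimal) per class, the convention used when
#' reporting trait-group sizes for an OTU inventory.
#'
#' @param partition a [trait_partition()] data.frame.
#' @return a data.frame with columns `class`, `n`, `pct`.
#' @export
trait_summary <- function(partition) {
  n <- nrow(partition)
  classes <- c(abundant = sum(partition$abundance_class == "abundant"),
               rare = sum(partition$abundance_class == "rare"),
               generalist = sum(partition$niche_class == "generalist"),
               specialist = sum(partition$niche_class == "specialist"))
  data.frame(class = names(classes), n = as.integer(classes),
             pct = fraction_pct(as.integer(classes), n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a trait partition as TSV
#' @param partition a [trait_partition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_partition <- function(partition, path) {
  utils::write.table(partition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
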