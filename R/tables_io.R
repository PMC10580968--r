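# OTU table data model, readers/writers, rarefaction and abundance transforms.
#
# Internal convention: samples are rows, OTUs are columns. The classic
# tab-separated OTU table on disk is the transpose (OTUs as rows); readers
# accept either orientation and record which one was detected.

#' Construct and validate an OTU count table
#'
#' An `otu_table` is a non-negative integer matrix with samples as rows and
#' OTUs as columns, both uniquely named. It is the substrate of every
#' analysis stage in this package.
#'
#' @param counts numeric matrix of non-negative whole numbers
#'   (samples x OTUs).
#' @param sample_ids,otu_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return an integer matrix of class `otu_table`.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("OTU1", "OTU2")))
#' otu_table(m)
otu_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("negative count")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("fractional counts are not allowed in an OTU table")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(otu_ids)) colnames(counts) <- otu_ids
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids")
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, total %s reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

# strip the class so matrix maths never dispatches back here
unclass_counts <- function(table) {
  m <- unclass(table)
  attr(m, "dropped_samples") <- NULL
  attr(m, "zero_otus") <- NULL
  attr(m, "orientation") <- NULL
  m
}

#' Read an OTU table from disk
#'
#' Supports the classic tab-separated layout (first column OTU id, remaining
#' columns samples) and BIOM JSON. Orientation of a TSV is auto-detected by
#' default: OTU inventories almost always have more taxa than samples, so the
#' larger dimension is taken to be the OTUs. Pass `orientation` explicitly
#' for tables where the heuristic is wrong.
#'
#' @param path file path.
#' @param format `"tsv"` (classic OTU table) or `"biom"` (BIOM JSON; requires
#'   the biomformat package).
#' @param orientation `"auto"`, `"otus_as_rows"` or `"samples_as_rows"`,
#'   describing the on-disk layout of a TSV.
#' @return an [otu_table()] with attribute `orientation` recording the layout
#'   that was read.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom"),
                           orientation = c("auto", "otus_as_rows",
                                           "samples_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b)) # taxa x samples
    tab <- otu_table(t(m))
    attr(tab, "orientation") <- "otus_as_rows"
    return(tab)
  }
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("OTU table contains non-numeric values")
  if (orientation == "auto") {
    orientation <- if (nrow(m) >= ncol(m)) "otus_as_rows" else "samples_as_rows"
  }
  if (orientation == "otus_as_rows") m <- t(m)
  tab <- otu_table(m)
  attr(tab, "orientation") <- orientation
  tab
}

#' Write an OTU table in the classic layout
#'
#' Writes a tab-separated table with OTUs as rows and samples as columns,
#' first column header `#OTU ID`. `read_otu_table()` on the result returns a
#' bit-identical matrix.
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  m <- t(unclass_counts(table)) # OTUs as rows
  df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy an OTU table to a fixed depth
#'
#' Subsamples each sample's reads without replacement (hypergeometric
#' draw) down to `depth`. Samples whose total is below `depth` are dropped;
#' their ids are recorded in the `dropped_samples` attribute. OTUs whose
#' total becomes zero are retained in the matrix and flagged in the
#' `zero_otus` attribute, so that downstream prevalence filters remove them
#' explicitly rather than silently.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed; rarefaction is deterministic given the seed.
#' @return a rarefied [otu_table()]; every retained row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(depth >= 1)
  m <- unclass_counts(table)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) stop("no samples retained: all totals below depth")
  dropped <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  set.seed(seed)
  # vegan advises against rarefying tables whose smallest entry is large;
  # that heuristic misfires on dense synthetic tables, so muffle it
  r <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  out <- otu_table(r)
  attr(out, "dropped_samples") <- dropped
  attr(out, "zero_otus") <- colnames(out)[colSums(out) == 0]
  out
}

#' Per-sample relative abundances
#'
#' @param table an [otu_table()] (or numeric matrix, samples x OTUs).
#' @return a numeric matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- unclass_counts(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("zero-sum sample(s): ", paste(rownames(m)[totals == 0], collapse = ", "))
  }
  sweep(m, 1, totals, "/")
}

#' Read a sample metadata table
#'
#' Tab-separated, one row per sample, with columns `sample_id`, `latitude`,
#' `longitude`, `location`, `MAT` (mean annual temperature, degrees C),
#' `MAP` (mean annual precipitation, mm), `MDTR` (mean daily temperature
#' range, degrees C) and optionally `region`.
#'
#' @param path file path.
#' @return a data.frame, validated.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  validate_sample_metadata(df)
}

#' Validate a sample metadata data.frame
#'
#' @param df data.frame with the columns listed in [read_sample_metadata()].
#' @return `df`, invisibly checked.
#' @export
validate_sample_metadata <- function(df) {
  required <- c("sample_id", "latitude", "longitude", "location",
                "MAT", "MAP", "MDTR")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (any(df$latitude < -90 | df$latitude > 90)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(df$longitude < -180 | df$longitude > 180)) {
    stop("longitude out of range [-180, 180]")
  }
  df
}

#' Read an OTU-to-pathway annotation table
#'
#' Tab-separated with columns `otu_id`, `pathway`, `present` (logical or
#' 0/1). Pathways follow the energy-metabolism guilds used for sediment
#' prokaryotes: CBB and WL carbon fixation, ASR/DSR sulfate reduction, SOX
#' sulfur oxidation, nitrogen fixation and dissimilatory nitrite reduction.
#' The table is consumed as-is (typically from a PICRUSt2-style prediction);
#' this package never computes it.
#'
#' @param path file path.
#' @return a data.frame with logical `present`.
#' @export
read_function_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  required <- c("otu_id", "pathway", "present")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("function table missing column(s): ", paste(missing, collapse = ", "))
  }
  df$present <- if (is.character(df$present)) {
    df$present %in% c("TRUE", "true", "T", "1") # tolerate mixed encodings
  } else {
    as.logical(df$present)
  }
  known <- c("CBB", "WL", "ASR", "DSR", "SOX", "nitrogen_fixation",
             "dissimilatory_nitrite_reduction")
  unknown <- setdiff(unique(df$pathway), known)
  if (length(unknown)) {
    warning("unrecognised pathway label(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(df[c("otu_id", "pathway")])) {
    stop("duplicate (otu_id, pathway) pairs")
  }
  df
}
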