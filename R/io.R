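# Readers and writers for the three tab-separated inputs (counts, taxonomy,
# sample metadata) plus the two global input filters applied before any
# downstream statistics: removal of ORFs overlapping predicted rRNA genes and
# subsetting to prokaryotes (Bacteria + Archaea).
#
# TSV dialect: tab separators, UTF-8, "." decimal, no quoting; this keeps
# read -> write -> read round trips bit-stable.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

.readTsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read an ORF count table
#'
#' Expects a TSV whose first column is `orf_id`, second column `length_bp`,
#' and remaining columns one per sample holding non-negative integer counts.
#'
#' @param path path to the TSV file.
#' @return An [OrfExperiment-class].
#' @export
readCountTable <- function(path) {
  df <- .readTsv(path, colClasses = "character")
  if (ncol(df) < 2 || !identical(colnames(df)[1:2], c("orf_id", "length_bp")))
    stop("count table must start with columns 'orf_id' and 'length_bp'")
  if (anyDuplicated(df$orf_id))
    stop(sprintf("duplicated orf_id in %s: %s", path,
                 paste(unique(df$orf_id[duplicated(df$orf_id)]), collapse = ", ")))
  sample_ids <- colnames(df)[-(1:2)]
  n <- nrow(df)
  if (n == 0L) {
    m <- matrix(integer(), nrow = 0, ncol = length(sample_ids),
                dimnames = list(NULL, sample_ids))
    return(OrfExperiment(m, length_bp = integer()))
  }
  len <- suppressWarnings(as.numeric(df$length_bp))
  if (any(is.na(len)) || any(len < 1) || any(len != round(len)))
    stop(sprintf("missing or invalid length_bp for ORF(s): %s",
                 paste(df$orf_id[is.na(len) | len < 1 | len != round(len)][1:5],
                       collapse = ", ")))
  m <- matrix(0L, nrow = n, ncol = length(sample_ids),
              dimnames = list(df$orf_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 2L]]))
    bad <- is.na(v) | v < 0 | v != round(v)
    if (any(bad))
      stop(sprintf("negative or non-integer count in sample '%s' at ORF '%s' (value '%s')",
                   sample_ids[j], df$orf_id[which(bad)[1]], df[[j + 2L]][which(bad)[1]]))
    m[, j] <- as.integer(v)
  }
  OrfExperiment(m, length_bp = as.integer(len))
}

#' Write an ORF count table
#'
#' Inverse of [readCountTable()]; round trips are byte-stable.
#'
#' @param x An [OrfExperiment-class].
#' @param path output path.
#' @export
writeCountTable <- function(x, path) {
  stopifnot(is(x, "OrfExperiment"))
  df <- data.frame(orf_id = rownames(x),
                   length_bp = rowData(x)$length_bp,
                   as.data.frame(counts(x), check.names = FALSE),
                   check.names = FALSE)
  .writeTsv(df, path)
}

#' Read a taxonomy lineage table
#'
#' Columns: `orf_id`, the six ranks `domain` .. `genus`, and logical
#' `is_rrna_overlap`. Empty rank cells are normalized to the reserved
#' sentinel `"unclassified"`. A record may only be unclassified at a rank if
#' all lower ranks are unclassified too, and `domain` must be one of
#' Bacteria, Archaea, Eukaryota or unclassified.
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per ORF.
#' @export
readTaxonomyTable <- function(path) {
  df <- .readTsv(path)
  validateTaxonomy(df)
}

#' Validate (and normalize) a taxonomy lineage table
#'
#' @param df data.frame with `orf_id`, rank columns and `is_rrna_overlap`.
#' @return the normalized data.frame, invisibly the same shape.
#' @export
validateTaxonomy <- function(df) {
  need <- c("orf_id", .TAX_RANKS, "is_rrna_overlap")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("taxonomy table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$orf_id))
    stop("duplicated orf_id in taxonomy table: ",
         paste(unique(df$orf_id[duplicated(df$orf_id)]), collapse = ", "))
  for (r in .TAX_RANKS) {
    v <- as.character(df[[r]])
    v[is.na(v) | v == ""] <- .UNCLASSIFIED
    df[[r]] <- v
  }
  bad <- !df$domain %in% .VALID_DOMAINS
  if (any(bad))
    stop("invalid domain label(s): ", paste(unique(df$domain[bad]), collapse = ", "))
  # named rank below an unclassified one violates the lineage invariant
  ranks <- as.matrix(df[, .TAX_RANKS])
  uncl <- ranks == .UNCLASSIFIED
  if (nrow(ranks)) {
    for (i in seq_len(length(.TAX_RANKS) - 1L)) {
      viol <- uncl[, i] & !uncl[, i + 1L]
      if (any(viol))
        stop(sprintf("ORF '%s': rank '%s' is unclassified but lower rank '%s' is named",
                     df$orf_id[which(viol)[1]], .TAX_RANKS[i], .TAX_RANKS[i + 1L]))
    }
  }
  df$is_rrna_overlap <- as.logical(df$is_rrna_overlap)
  if (any(is.na(df$is_rrna_overlap)))
    stop("is_rrna_overlap must be TRUE/FALSE")
  df
}

#' Read a sample metadata table
#'
#' One row per sample: `sample_id`, `depth_m`, `month`, `replicate` and the
#' environmental covariates (temperature, salinity, oxygen, Chl a, DOC and
#' inorganic nutrients).
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path) {
  df <- .readTsv(path)
  if (!"sample_id" %in% colnames(df)) stop("metadata needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if ("depth_m" %in% colnames(df) && any(df$depth_m <= 0))
    stop("depth_m must be > 0")
  df
}

#' Attach a taxonomy table to an OrfExperiment
#'
#' @param x An [OrfExperiment-class].
#' @param taxonomy data.frame as returned by [readTaxonomyTable()]; every ORF
#'   of `x` must have a record.
#' @return `x` with taxonomy columns merged into `rowData`.
#' @export
attachTaxonomy <- function(x, taxonomy) {
  taxonomy <- validateTaxonomy(taxonomy)
  idx <- match(rownames(x), taxonomy$orf_id)
  if (anyNA(idx))
    stop("ORF(s) without taxonomy record: ",
         paste(rownames(x)[is.na(idx)][1:5], collapse = ", "))
  for (col in c(.TAX_RANKS, "is_rrna_overlap"))
    rowData(x)[[col]] <- taxonomy[[col]][idx]
  x
}

#' Attach per-sample metadata to an OrfExperiment
#' @param x An [OrfExperiment-class].
#' @param metadata data.frame with a `sample_id` column covering all samples.
#' @return `x` with metadata merged into `colData`.
#' @export
attachSampleMetadata <- function(x, metadata) {
  idx <- match(colnames(x), metadata$sample_id)
  if (anyNA(idx))
    stop("sample(s) without metadata record: ",
         paste(colnames(x)[is.na(idx)], collapse = ", "))
  cd <- metadata[idx, , drop = FALSE]
  rownames(cd) <- cd$sample_id
  colData(x) <- DataFrame(cd)
  x
}

.requireTaxonomy <- function(x, taxonomy) {
  if (is.null(taxonomy)) taxonomy <- taxonomy(x)
  if (is.null(taxonomy))
    stop("no taxonomy attached; supply one or call attachTaxonomy() first")
  idx <- match(rownames(x), taxonomy$orf_id)
  if (anyNA(idx))
    stop("ORF(s) without taxonomy record: ",
         paste(rownames(x)[is.na(idx)][1:5], collapse = ", "))
  taxonomy[idx, , drop = FALSE]
}

.logFunnel <- function(x, stage, n_removed) {
  fun <- metadata(x)$funnel
  if (is.null(fun)) fun <- list()
  fun[[stage]] <- nrow(x)
  metadata(x)$funnel <- fun
  metadata(x)[[paste0("removed_", stage)]] <- n_removed
  x
}

#' Remove ORFs overlapping predicted rRNA genes
#'
#' ORFs flagged `is_rrna_overlap` (the overlap detection itself happens
#' upstream, on the assembly) are dropped; the relative order of survivors is
#' preserved. The number of removed ORFs is recorded in
#' `metadata(x)$removed_rrna_filter`.
#'
#' @param x An [OrfExperiment-class].
#' @param taxonomy optional taxonomy table; defaults to the attached one.
#' @return the filtered `OrfExperiment`.
#' @export
filterRrnaOverlaps <- function(x, taxonomy = NULL) {
  tax <- .requireTaxonomy(x, taxonomy)
  if (is.null(taxonomy(x))) x <- attachTaxonomy(x, tax)
  drop <- tax$is_rrna_overlap
  out <- x[!drop, ]
  if (ncol(out) > 0 && nrow(out) == 0L)
    warning("all ORFs flagged as rRNA overlaps; result is empty")
  .logFunnel(out, "rrna_filter", sum(drop))
}

#' Subset an OrfExperiment to prokaryotes
#'
#' Keeps ORFs whose domain is Bacteria or Archaea.
#'
#' @inheritParams filterRrnaOverlaps
#' @return the filtered `OrfExperiment`.
#' @export
subsetProkaryotes <- function(x, taxonomy = NULL) {
  tax <- .requireTaxonomy(x, taxonomy)
  if (is.null(taxonomy(x))) x <- attachTaxonomy(x, tax)
  keep <- tax$domain %in% c("Bacteria", "Archaea")
  out <- x[keep, ]
  if (ncol(out) > 0 && nrow(out) == 0L)
    warning("no prokaryotic ORFs retained; result is empty")
  .logFunnel(out, "prokaryote_subset", sum(!keep))
}
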