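#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData colData<-
NULL

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")
.UNCLASSIFIED <- "unclassified"
.VALID_DOMAINS <- c("Bacteria", "Archaea", "Eukaryota", .UNCLASSIFIED)

#' ORF-by-sample transcript count container
#'
#' `OrfExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds an ORF x sample matrix of non-negative integer transcript counts
#' (assay `"counts"`), per-ORF lengths in base pairs (`rowData$length_bp`),
#' and optionally a taxonomy lineage (domain to genus plus an rRNA-overlap
#' flag) in `rowData` and per-sample metadata in `colData`.
#'
#' Validity requires unique ORF and sample identifiers, counts >= 0 with no
#' fractional values, and lengths >= 1.
#'
#' @name OrfExperiment-class
#' @aliases OrfExperiment-class
#' @exportClass OrfExperiment
setClass("OrfExperiment", contains = "SummarizedExperiment")

setValidity("OrfExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (any(is.na(m))) msg <- c(msg, "counts contain NA")
    else {
      if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(m != round(m))) msg <- c(msg, "counts must be whole numbers")
    }
  }
  if (is.null(rownames(object)) && nrow(object) > 0)
    msg <- c(msg, "ORF identifiers (rownames) are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicated orf_id: %s",
                          paste(unique(rownames(object)[duplicated(rownames(object))]),
                                collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample_id")
  if (!"length_bp" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'length_bp' is required")
  else {
    len <- rowData(object)$length_bp
    if (any(is.na(len)) || any(len < 1))
      msg <- c(msg, "every ORF needs a length_bp >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OrfExperiment
#'
#' @param counts integer matrix, ORFs in rows (rownames = ORF ids), samples in
#'   columns (colnames = sample ids).
#' @param length_bp integer vector of ORF lengths in base pairs, one per row
#'   of `counts` (recycled from `rowData` if already embedded).
#' @param taxonomy optional data.frame of taxonomy lineages as returned by
#'   [readTaxonomyTable()]; matched to ORFs by its `orf_id` column.
#' @param metadata optional data.frame of per-sample metadata with a
#'   `sample_id` column; matched to the columns of `counts`.
#' @return An [OrfExperiment-class] object.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("orf", 1:3), c("s1", "s2")))
#' oe <- OrfExperiment(m, length_bp = c(300L, 450L, 900L))
#' orfLengths(oe)
#' @export
OrfExperiment <- function(counts, length_bp, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  rd <- DataFrame(length_bp = as.integer(length_bp), row.names = rownames(counts))
  oe <- new("OrfExperiment",
            SummarizedExperiment(assays = list(counts = counts), rowData = rd))
  if (!is.null(taxonomy)) oe <- attachTaxonomy(oe, taxonomy)
  if (!is.null(metadata)) oe <- attachSampleMetadata(oe, metadata)
  oe
}

#' @describeIn OrfExperiment ORF lengths in base pairs.
#' @param x An `OrfExperiment`.
#' @export
orfLengths <- function(x) {
  stopifnot(is(x, "OrfExperiment"))
  stats::setNames(rowData(x)$length_bp, rownames(x))
}

#' @describeIn OrfExperiment taxonomy lineage (one row per ORF) as a
#'   data.frame, or NULL when no taxonomy is attached.
#' @export
taxonomy <- function(x) {
  stopifnot(is(x, "OrfExperiment"))
  if (!all(.TAX_RANKS %in% colnames(rowData(x)))) return(NULL)
  keep <- intersect(c("orf_id", .TAX_RANKS, "is_rrna_overlap"), colnames(rowData(x)))
  df <- as.data.frame(rowData(x)[, keep, drop = FALSE])
  df$orf_id <- rownames(x)
  rownames(df) <- NULL
  df[, c("orf_id", setdiff(keep, "orf_id"))]
}

#' Counts accessor for OrfExperiment
#' @param object An `OrfExperiment`.
#' @return Integer matrix of transcript counts.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "OrfExperiment",
          function(object) assay(object, "counts"))

setMethod("show", "OrfExperiment", function(object) {
  cat(sprintf("OrfExperiment: %d ORFs x %d samples\n", nrow(object), ncol(object)))
  tx <- taxonomy(object)
  cat(sprintf("  taxonomy attached: %s\n", if (is.null(tx)) "no" else "yes"))
  fun <- metadata(object)$funnel
  if (!is.null(fun))
    cat("  funnel:", paste(sprintf("%s=%d", names(fun), unlist(fun)), collapse = ", "), "\n")
  invisible(NULL)
})

.checkNonEmpty <- function(x, what = "operation") {
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop(sprintf("%s requires a non-empty count matrix (got %d ORFs x %d samples)",
                 what, nrow(x), ncol(x)), call. = FALSE)
  invisible(TRUE)
}
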