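# Count transformations. cpm and TPM rescale columns to one million (TPM
# after dividing counts by gene length in kilobases); the Hellinger
# transformation takes the square root of per-sample relative abundances so
# Euclidean-based ordination behaves sensibly on community counts; SRS
# (scaling with ranked subsampling) scales every library to a common total
# C_min and allocates the leftover integer counts by fractional-part rank,
# breaking rank ties by a seeded random choice.

.transformed <- function(values, tag) {
  attr(values, "transform_tag") <- tag
  values
}

.checkColumns <- function(m, what) {
  zero <- colSums(m) == 0
  if (any(zero))
    stop(sprintf("%s undefined for all-zero sample(s): %s", what,
                 paste(colnames(m)[zero], collapse = ", ")))
  invisible(TRUE)
}

#' Counts per million
#'
#' @param x An [OrfExperiment-class] or count matrix (ORFs x samples).
#' @return numeric matrix; every non-empty column sums to 1e6. The transform
#'   name is recorded in `attr(, "transform_tag")`.
#' @export
countsPerMillion <- function(x) {
  m <- .asCountMatrix(x)
  .checkNonEmpty(m, "countsPerMillion")
  .checkColumns(m, "cpm")
  .transformed(sweep(m, 2, colSums(m), "/") * 1e6, "cpm")
}

#' Transcripts per million
#'
#' Length-normalized relative abundance: per-ORF count rates
#' `count / (length_bp / 1000)` rescaled so each sample sums to 1e6.
#'
#' @param x An [OrfExperiment-class], or a count matrix if `length_bp` given.
#' @param length_bp ORF lengths in base pairs (taken from `x` when omitted).
#' @return numeric matrix with `transform_tag = "tpm"`.
#' @export
tpm <- function(x, length_bp = NULL) {
  m <- .asCountMatrix(x)
  if (is.null(length_bp)) {
    if (!is(x, "OrfExperiment")) stop("length_bp required for a bare matrix")
    length_bp <- orfLengths(x)
  }
  .checkNonEmpty(m, "tpm")
  if (any(length_bp <= 0)) stop("ORF length of zero or less is not allowed")
  rate <- m / (length_bp / 1000)
  .checkColumns(rate, "tpm")
  .transformed(sweep(rate, 2, colSums(rate), "/") * 1e6, "tpm")
}

#' Hellinger transformation
#'
#' `sqrt(count / sample_total)` per cell; every sample column then has unit
#' squared norm, which makes Euclidean distances between samples appropriate
#' for downstream PCA/RDA on community counts.
#'
#' @inheritParams countsPerMillion
#' @return numeric matrix with `transform_tag = "hellinger"`.
#' @export
hellingerTransform <- function(x) {
  m <- .asCountMatrix(x)
  .checkNonEmpty(m, "hellingerTransform")
  .checkColumns(m, "hellinger")
  .transformed(sqrt(sweep(m, 2, colSums(m), "/")), "hellinger")
}

#' Low-abundance ORF filter
#'
#' Keeps ORFs reaching at least `min_cpm` counts per million in at least
#' `min_samples` samples (`strict = TRUE` uses a strict `>` on the cpm
#' threshold instead). Raw counts of the survivors are returned; the filter
#' is evaluated once on the supplied matrix and is deliberately not iterated
#' (recomputing cpm on the filtered matrix can demote further ORFs).
#'
#' @param x An [OrfExperiment-class].
#' @param min_cpm cpm threshold (default 5).
#' @param min_samples number of samples that must reach it (default 2).
#' @param strict require cpm strictly above the threshold.
#' @return the filtered [OrfExperiment-class]; the number of removed ORFs is
#'   recorded in `metadata()$removed_abundance_filter`.
#' @export
abundanceFilter <- function(x, min_cpm = 5, min_samples = 2, strict = FALSE) {
  stopifnot(is(x, "OrfExperiment"))
  cp <- countsPerMillion(x)
  hits <- if (strict) cp > min_cpm else cp >= min_cpm
  keep <- rowSums(hits) >= min_samples
  .logFunnel(x[keep, ], "abundance_filter", sum(!keep))
}

#' Scaling with ranked subsampling (SRS) normalization
#'
#' Every sample is scaled to the common total `c_min`: counts are multiplied
#' by `c_min / total`, integer parts are kept, and the remaining counts are
#' assigned one each to the ORFs with the largest fractional parts. Ties in
#' fractional rank at the cutoff are resolved by a seeded uniform random
#' choice among the tied ORFs, so each normalized count differs from its
#' scaled value by less than one and column totals equal `c_min` exactly.
#'
#' @param x An [OrfExperiment-class] or count matrix.
#' @param c_min target library size; `"auto"` uses the smallest column total.
#'   Requesting more than a sample holds is an error (no upsampling).
#' @param seed integer seed controlling tie resolution.
#' @return integer matrix with `transform_tag = "srs"`.
#' @export
srsNormalize <- function(x, c_min = "auto", seed) {
  m <- .asCountMatrix(x)
  .checkNonEmpty(m, "srsNormalize")
  tot <- colSums(m)
  .checkColumns(m, "srs")
  if (identical(c_min, "auto")) c_min <- min(tot)
  c_min <- as.integer(round(c_min))
  if (any(tot < c_min))
    stop(sprintf("c_min (%d) exceeds the total of sample(s): %s", c_min,
                 paste(colnames(m)[tot < c_min], collapse = ", ")))
  out <- withSeed(seed, {
    res <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
    for (j in seq_len(ncol(m))) {
      scaled <- as.numeric(m[, j]) * (c_min / tot[j])
      base <- floor(scaled)
      remaining <- c_min - sum(base)
      if (remaining > 0) {
        frac <- scaled - base
        ord <- order(-frac, stats::runif(length(frac)))
        base[ord[seq_len(remaining)]] <- base[ord[seq_len(remaining)]] + 1
      }
      res[, j] <- as.integer(base)
    }
    res
  })
  .transformed(out, "srs")
}

#' Substitute below-detection covariate values
#'
#' Replaces covariate values flagged below the detection limit (or recorded
#' as `NA` alongside a `<column>_below_detection` flag) with a small positive
#' constant so the variable remains usable in constrained ordination.
#'
#' @param metadata sample metadata data.frame.
#' @param column covariate column name (default `"nh4_uM"`).
#' @param value replacement value (default 0.001).
#' @return the metadata with substituted values.
#' @export
imputeBelowDetection <- function(metadata, column = "nh4_uM", value = 0.001) {
  flag_col <- paste0(sub("_uM$", "", column), "_below_detection")
  flag <- if (flag_col %in% colnames(metadata)) metadata[[flag_col]]
          else is.na(metadata[[column]])
  flag <- flag | is.na(metadata[[column]])
  metadata[[column]][flag] <- value
  metadata
}
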