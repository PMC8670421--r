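# Taxon-resolved transcription statistics: relative transcription per taxon,
# gene-system TPM totals, investment log ratios between gene systems
# (computed per biological replicate, then averaged, mirroring "mean log
# ratio +/- SD (n = replicates)"), and archaeal marker-gene ratios against
# the single-copy reference radA. Log base 2 throughout so a ratio of 1.0
# reads as a 2-fold difference; zero sums are substituted with half the
# smallest positive system total in the table and flagged.

.resolveRank <- function(taxonomy_df, rank, proteobacteria_at_class = FALSE) {
  if (!rank %in% .TAX_RANKS && rank != "taxon")
    stop("unknown rank: ", rank)
  lab <- taxonomy_df[[rank]]
  if (proteobacteria_at_class && rank == "phylum") {
    pro <- !is.na(lab) & lab == "Proteobacteria"
    lab[pro] <- taxonomy_df$class[pro]
  }
  lab
}

#' Relative transcription per taxon
#'
#' Per sample, the percent of total transcripts attributable to each taxon
#' at the requested rank. At phylum rank, Proteobacteria are reported at
#' class level (rank-override rule) when `proteobacteria_at_class = TRUE`.
#'
#' @param x An [OrfExperiment-class] with taxonomy attached.
#' @param rank taxonomic rank (default `"order"`).
#' @param proteobacteria_at_class split Proteobacteria into classes when
#'   summarizing at phylum rank.
#' @return data.frame with `taxon`, `sample_id`, `pct`; percentages sum to
#'   100 per sample.
#' @export
taxonRelativeTranscription <- function(x, rank = "order",
                                       proteobacteria_at_class = (rank == "phylum")) {
  .checkNonEmpty(x, "taxonRelativeTranscription")
  tax <- taxonomy(x)
  if (is.null(tax)) stop("taxonomy must be attached")
  lab <- .resolveRank(tax, rank, proteobacteria_at_class)
  m <- counts(x)
  agg <- rowsum(m, lab)
  pct <- sweep(agg, 2, colSums(m), "/") * 100
  out <- data.frame(taxon = rep(rownames(pct), ncol(pct)),
                    sample_id = rep(colnames(pct), each = nrow(pct)),
                    pct = as.vector(pct))
  rownames(out) <- NULL
  out
}

#' Gene-system TPM totals per taxon and sample
#'
#' Sums member-ORF TPM per (taxon, sample, system). An ORF contributes to
#' every system it is assigned to (e.g. a transporter that is also the amt
#' marker). Marker assignments are reported as `marker:<gene>`. A `total`
#' system row carries each taxon's full TPM across all its ORFs.
#'
#' @param tpm_matrix TPM matrix (ORFs x samples), see [tpm()].
#' @param assignments functional-assignment table (`orf_id`, `system`,
#'   `family`) as produced by the `classify*`/[consensusCazyme()] functions.
#' @param taxonomy_df taxonomy data.frame covering all ORFs of `tpm_matrix`.
#' @param rank rank at which taxa are aggregated (default `"order"`).
#' @return data.frame with `taxon`, `sample_id`, `system`, `tpm_sum`
#'   (complete grid, zero-filled).
#' @export
systemTotals <- function(tpm_matrix, assignments, taxonomy_df, rank = "order") {
  m <- as.matrix(tpm_matrix)
  unknown <- setdiff(assignments$orf_id, rownames(m))
  if (length(unknown))
    stop("assignment references unknown ORF(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  idx <- match(rownames(m), taxonomy_df$orf_id)
  if (anyNA(idx)) stop("taxonomy does not cover all ORFs")
  taxon <- .resolveRank(taxonomy_df[idx, , drop = FALSE], rank)
  sys_label <- ifelse(assignments$system == "marker",
                      paste0("marker:", assignments$family),
                      assignments$system)
  systems <- sort(unique(sys_label))
  taxa <- sort(unique(taxon))
  grid <- expand.grid(taxon = taxa, sample_id = colnames(m),
                      system = c(systems, "total"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$tpm_sum <- 0
  key <- function(t, s, y) paste(t, s, y, sep = "\r")
  rownames(grid) <- key(grid$taxon, grid$sample_id, grid$system)
  for (sy in systems) {
    ids <- assignments$orf_id[sys_label == sy]
    rows <- rownames(m) %in% ids
    if (!any(rows)) next
    agg <- rowsum(m[rows, , drop = FALSE], taxon[rows])
    for (t in rownames(agg))
      grid[key(t, colnames(m), sy), "tpm_sum"] <- agg[t, ]
  }
  aggT <- rowsum(m, taxon)
  for (t in rownames(aggT))
    grid[key(t, colnames(m), "total"), "tpm_sum"] <- aggT[t, ]
  rownames(grid) <- NULL
  grid
}

.strataReplicates <- function(metadata) {
  need <- c("sample_id", "depth_m", "month", "replicate")
  miss <- setdiff(need, colnames(metadata))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  metadata[, need]
}

#' Gene-system investment log ratios
#'
#' For each taxon, depth and month, computes per-replicate
#' `log2(system_A / system_B)` TPM ratios for the requested ratio types and
#' averages them across biological replicates (mean and SD, n = replicates
#' used). A replicate with one zero sum uses the pseudocount (half the
#' smallest positive system total in the table) and is flagged; a replicate
#' with both sums zero is excluded and flagged. Rows labelled
#' `"(community)"` aggregate all taxa.
#'
#' @param totals data.frame from [systemTotals()].
#' @param metadata sample metadata with `sample_id`, `depth_m`, `month`,
#'   `replicate`.
#' @param ratio_types character vector of `"A/B"` system pairs.
#' @param log_base logarithm base (default 2).
#' @param include_community add the all-taxa aggregate rows.
#' @return data.frame with `taxon`, `depth_m`, `month`, `ratio_type`,
#'   `mean_log_ratio`, `sd_log_ratio`, `n_replicates`, `pseudocount_used`.
#' @export
investmentLogRatios <- function(totals, metadata,
                                ratio_types = c("CAZyme/PEP", "CAZyme/TP",
                                                "PEP/TP"),
                                log_base = 2, include_community = TRUE) {
  meta <- .strataReplicates(metadata)
  pos <- totals$tpm_sum[totals$system != "total" & totals$tpm_sum > 0]
  if (!length(pos)) stop("no positive system totals; nothing to compare")
  pseudo <- min(pos) / 2
  if (include_community) {
    comm <- stats::aggregate(tpm_sum ~ sample_id + system, data = totals, FUN = sum)
    comm$taxon <- "(community)"
    totals <- rbind(totals[, c("taxon", "sample_id", "system", "tpm_sum")],
                    comm[, c("taxon", "sample_id", "system", "tpm_sum")])
  }
  totals <- merge(totals, meta, by = "sample_id")
  out <- list()
  for (rt in ratio_types) {
    parts <- strsplit(rt, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("ratio_type must look like 'A/B': ", rt)
    a <- totals[totals$system == parts[1], ]
    b <- totals[totals$system == parts[2], ]
    key <- c("taxon", "sample_id", "depth_m", "month", "replicate")
    ab <- merge(a[, c(key, "tpm_sum")], b[, c(key, "tpm_sum")],
                by = key, suffixes = c("_a", "_b"))
    ab$defined <- !(ab$tpm_sum_a == 0 & ab$tpm_sum_b == 0)
    ab$pseudo <- ab$defined & (ab$tpm_sum_a == 0 | ab$tpm_sum_b == 0)
    ab$lr <- log(pmax(ab$tpm_sum_a, ifelse(ab$tpm_sum_a == 0, pseudo, 0)) /
                   pmax(ab$tpm_sum_b, ifelse(ab$tpm_sum_b == 0, pseudo, 0)),
                 base = log_base)
    groups <- split(ab, list(ab$taxon, ab$depth_m, ab$month), drop = TRUE)
    out[[rt]] <- do.call(rbind, lapply(groups, function(g) {
      ok <- g$defined
      data.frame(taxon = g$taxon[1], depth_m = g$depth_m[1],
                 month = g$month[1], ratio_type = rt,
                 mean_log_ratio = if (any(ok)) mean(g$lr[ok]) else NA_real_,
                 sd_log_ratio = if (sum(ok) > 1) stats::sd(g$lr[ok]) else NA_real_,
                 n_replicates = sum(ok),
                 pseudocount_used = any(g$pseudo))
    }))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$taxon, res$month, res$depth_m, res$ratio_type), ]
}

#' Marker-gene relative transcript abundance per sample
#'
#' Percent of each sample's total transcripts carried by ORFs assigned to
#' each marker gene.
#'
#' @param x An [OrfExperiment-class] (raw counts).
#' @param assignments assignment table containing `system == "marker"` rows.
#' @return data.frame with `sample_id`, `marker`, `pct`.
#' @export
markerRelativeAbundance <- function(x, assignments) {
  .checkNonEmpty(x, "markerRelativeAbundance")
  mk <- assignments[assignments$system == "marker", , drop = FALSE]
  m <- counts(x)
  tot <- colSums(m)
  markers <- sort(unique(mk$family))
  rows <- lapply(markers, function(g) {
    ids <- mk$orf_id[mk$family == g]
    v <- colSums(m[rownames(m) %in% ids, , drop = FALSE])
    data.frame(sample_id = colnames(m), marker = g, pct = 100 * v / tot,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize marker abundances over replicates
#'
#' @param per_sample data.frame from [markerRelativeAbundance()].
#' @param metadata sample metadata with replicate structure.
#' @return data.frame with `depth_m`, `month`, `marker`, `mean_pct`,
#'   `sd_pct`, `n_replicates`.
#' @export
summarizeMarkerAbundance <- function(per_sample, metadata) {
  df <- merge(per_sample, .strataReplicates(metadata), by = "sample_id")
  groups <- split(df, list(df$marker, df$depth_m, df$month), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(depth_m = g$depth_m[1], month = g$month[1], marker = g$marker[1],
               mean_pct = mean(g$pct), sd_pct = stats::sd(g$pct),
               n_replicates = nrow(g))))
  rownames(out) <- NULL
  out[order(out$marker, out$month, out$depth_m), ]
}

#' Marker-gene log ratios against the single-copy reference radA
#'
#' Per replicate, `log2(marker / radA)` of relative transcript abundances
#' for the requested markers, averaged per depth and month (mean +/- SD). A
#' replicate with radA = 0 uses the half-minimum pseudocount and is flagged;
#' radA absent from the table entirely is an error. A pooled estimate per
#' marker (`log2` of summed abundances across all samples) is attached as
#' `attr(, "pooled")`; pooling weights every transcript equally and is the
#' stable fold estimator when individual strata have few marker reads.
#'
#' @param per_sample data.frame from [markerRelativeAbundance()].
#' @param metadata sample metadata with replicate structure.
#' @param markers numerator markers (default amoA and hcd).
#' @param reference reference gene (default `"radA"`).
#' @return data.frame with `depth_m`, `month`, `marker` (as
#'   `"<marker>/radA"` in `ratio_label`), `mean_log_ratio`, `sd_log_ratio`,
#'   `n_replicates`, `pseudocount_used`; pooled folds in `attr(, "pooled")`.
#' @export
markerLogRatios <- function(per_sample, metadata,
                            markers = c("amoA", "hcd"), reference = "radA") {
  if (!reference %in% per_sample$marker)
    stop("reference gene '", reference, "' absent; a single-copy reference is required")
  meta <- .strataReplicates(metadata)
  wide <- stats::reshape(per_sample, idvar = "sample_id", timevar = "marker",
                         direction = "wide")
  colnames(wide) <- sub("^pct\\.", "", colnames(wide))
  wide <- merge(wide, meta, by = "sample_id")
  pos <- per_sample$pct[per_sample$pct > 0]
  pseudo <- if (length(pos)) min(pos) / 2 else NA_real_
  out <- list(); pooled <- list()
  for (g in markers) {
    if (!g %in% colnames(wide)) next
    num <- wide[[g]]; den <- wide[[reference]]
    flag <- den == 0 | num == 0
    lr <- log2(ifelse(num == 0, pseudo, num) / ifelse(den == 0, pseudo, den))
    df <- data.frame(depth_m = wide$depth_m, month = wide$month, lr = lr,
                     flag = flag)
    groups <- split(df, list(df$depth_m, df$month), drop = TRUE)
    out[[g]] <- do.call(rbind, lapply(groups, function(gg)
      data.frame(depth_m = gg$depth_m[1], month = gg$month[1], marker = g,
                 ratio_label = paste0(g, "/", reference),
                 mean_log_ratio = mean(gg$lr), sd_log_ratio = stats::sd(gg$lr),
                 n_replicates = nrow(gg), pseudocount_used = any(gg$flag))))
    pooled[[g]] <- data.frame(marker = g,
                              log2_pooled = log2(sum(num) / sum(den)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$marker, res$month, res$depth_m), ]
  attr(res, "pooled") <- do.call(rbind, c(pooled, list(make.row.names = FALSE)))
  res
}
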