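# Resolution of raw multi-tool functional predictions into at most one label
# per ORF per gene system.
#
# The CAZyme consensus follows a two-rule scheme: (i) ORFs called by a single
# tool are kept only above that tool's quality threshold (alignment percent
# identity >= 50, profile coverage >= 0.5, peptide-pattern hits >= 10 --
# metrics exactly at the threshold are retained, exclusion uses strict "<");
# (ii) ORFs called by two or more tools are ranked per candidate family by
# the number of tools voting for it and then by the sum of per-tool
# normalized quality scores in [0, 1] (identity/100; coverage;
# min(1, hits/hits_cap) x frequency normalized by the ORF's maximum pattern
# frequency). Exact ties break lexicographically by family label. The
# vote-then-quality combination and its tie handling are package choices and
# are configurable; they are monotone in every raw metric.

.CAZ_TOOLS <- c("diamond", "hmmer", "hotpep")

.validateCazymePredictions <- function(predictions) {
  need <- c("orf_id", "tool", "family")
  miss <- setdiff(need, colnames(predictions))
  if (length(miss))
    stop("prediction table missing column(s): ", paste(miss, collapse = ", "))
  bad <- !predictions$tool %in% .CAZ_TOOLS
  if (any(bad))
    stop("unknown tool label(s): ", paste(unique(predictions$tool[bad]), collapse = ", "))
  if (any(is.na(predictions$family) | predictions$family == ""))
    stop("family label must be non-empty")
  for (col in c("percent_identity", "coverage", "hits", "frequency"))
    if (!col %in% colnames(predictions)) predictions[[col]] <- NA_real_
  own <- list(diamond = "percent_identity", hmmer = "coverage",
              hotpep = c("hits", "frequency"))
  for (tool in .CAZ_TOOLS) {
    rows <- predictions$tool == tool
    if (!any(rows)) next
    mine <- own[[tool]]
    if (any(is.na(as.matrix(predictions[rows, mine, drop = FALSE]))))
      stop(sprintf("'%s' records must carry metric(s) %s", tool,
                   paste(mine, collapse = "+")))
    other <- setdiff(unlist(own), mine)
    if (any(!is.na(as.matrix(predictions[rows, other, drop = FALSE]))))
      stop(sprintf("'%s' records carry metrics belonging to another tool", tool))
  }
  predictions
}

# normalized per-record quality score in [0, 1]
.cazQuality <- function(rec, hits_cap, max_freq) {
  switch(rec$tool,
         diamond = rec$percent_identity / 100,
         hmmer = rec$coverage,
         hotpep = min(1, rec$hits / hits_cap) *
           (if (max_freq > 0) rec$frequency / max_freq else 1))
}

#' Consensus CAZyme family classification
#'
#' Resolves a raw multi-tool prediction table to at most one CAZy family per
#' ORF using the single-tool quality filter and the vote-then-quality ranking
#' described above.
#'
#' @param predictions data.frame with columns `orf_id`, `tool` (one of
#'   `"diamond"`, `"hmmer"`, `"hotpep"`), `family`, and the tool's metrics
#'   (`percent_identity`, `coverage`, `hits` + `frequency`); a record
#'   carrying another tool's metrics is an error.
#' @param thresholds single-tool exclusion thresholds (strict `<`).
#' @param hits_cap cap used to normalize the pattern tool's hit count.
#' @return data.frame with columns `orf_id`, `system` (always `"CAZyme"`),
#'   `family`, `provenance` (`"single-tool"`, `"votes"`, `"quality"` or
#'   `"tie-lexicographic"`); zero or one row per ORF.
#' @export
consensusCazyme <- function(predictions,
                            thresholds = c(percent_identity = 50,
                                           coverage = 0.5, hits = 10),
                            hits_cap = 100) {
  predictions <- .validateCazymePredictions(predictions)
  out <- list()
  for (orf in unique(predictions$orf_id)) {
    recs <- predictions[predictions$orf_id == orf, , drop = FALSE]
    tools <- unique(recs$tool)
    if (length(tools) == 1L) {
      # rule (i): single predicting tool, quality-gated
      best <- switch(tools,
        diamond = recs[which.max(recs$percent_identity), , drop = FALSE],
        hmmer = recs[which.max(recs$coverage), , drop = FALSE],
        hotpep = recs[which.max(recs$hits), , drop = FALSE])
      pass <- switch(tools,
        diamond = best$percent_identity >= thresholds[["percent_identity"]],
        hmmer = best$coverage >= thresholds[["coverage"]],
        hotpep = best$hits >= thresholds[["hits"]])
      if (pass)
        out[[orf]] <- data.frame(orf_id = orf, system = "CAZyme",
                                 family = best$family,
                                 provenance = "single-tool")
      next
    }
    # rule (ii): vote count, then summed normalized quality, then family label
    max_freq <- suppressWarnings(max(recs$frequency[recs$tool == "hotpep"],
                                     na.rm = TRUE))
    if (!is.finite(max_freq)) max_freq <- 0
    fams <- sort(unique(recs$family))
    votes <- qual <- stats::setNames(numeric(length(fams)), fams)
    for (fam in fams) {
      sup <- recs[recs$family == fam, , drop = FALSE]
      votes[fam] <- length(unique(sup$tool))
      qual[fam] <- sum(vapply(unique(sup$tool), function(tl) {
        cand <- sup[sup$tool == tl, , drop = FALSE]
        max(vapply(seq_len(nrow(cand)),
                   function(r) .cazQuality(cand[r, ], hits_cap, max_freq),
                   numeric(1)))
      }, numeric(1)))
    }
    ord <- order(-votes, -qual, fams)
    top <- ord[1]
    tied_votes <- which(votes == votes[top])
    if (length(tied_votes) == 1L) {
      prov <- "votes"
    } else {
      tied_quality <- tied_votes[abs(qual[tied_votes] - qual[top]) < 1e-12]
      prov <- if (length(tied_quality) > 1L) "tie-lexicographic" else "quality"
    }
    out[[orf]] <- data.frame(orf_id = orf, system = "CAZyme",
                             family = fams[top], provenance = prov)
  }
  res <- do.call(rbind, c(out, list(NULL)))
  if (is.null(res))
    res <- data.frame(orf_id = character(), system = character(),
                      family = character(), provenance = character())
  rownames(res) <- NULL
  res
}

#' Classify peptidase ORFs via Pfam to MEROPS mapping
#'
#' Each profile hit is mapped to its MEROPS family; for multi-domain ORFs the
#' highest-scoring mapped hit wins (score ties break on the
#' lexicographically smaller family). Hits whose accession is absent from the
#' map are collected in a side report attached as `attr(result, "unmapped")`.
#'
#' @param profile_hits data.frame with columns `orf_id`, `pfam`, `score`.
#' @param merops_map data.frame with columns `pfam`, `merops_family`.
#' @return data.frame with columns `orf_id`, `system` (`"PEP"`), `family`,
#'   `provenance`; the unmapped hits as attribute `"unmapped"`.
#' @export
classifyPeptidases <- function(profile_hits, merops_map = meropsMapDefault()) {
  stopifnot(all(c("orf_id", "pfam", "score") %in% colnames(profile_hits)),
            all(c("pfam", "merops_family") %in% colnames(merops_map)))
  fam <- merops_map$merops_family[match(profile_hits$pfam, merops_map$pfam)]
  unmapped <- profile_hits[is.na(fam), , drop = FALSE]
  mapped <- profile_hits[!is.na(fam), , drop = FALSE]
  mapped$family <- fam[!is.na(fam)]
  mapped <- mapped[order(mapped$orf_id, -mapped$score, mapped$family), ]
  best <- mapped[!duplicated(mapped$orf_id), , drop = FALSE]
  res <- data.frame(orf_id = best$orf_id, system = "PEP", family = best$family,
                    provenance = "pfam-merops")
  rownames(res) <- NULL
  rownames(unmapped) <- NULL
  attr(res, "unmapped") <- unmapped
  res
}

#' Shipped TCDB reassignment overrides
#'
#' The two manual corrections applied to the profile-to-family map: PF00909
#' to the Ammonium Channel Transporter (Amt) family, TC 1.A.11, and PF00654
#' to the Chloride Carrier/Channel (ClC) family, TC 2.A.49.
#'
#' @return data.frame with columns `profile`, `tcdb_family`, `tc_number`.
#' @export
tcdbOverrides <- function() {
  path <- system.file("extdata", "tcdb_overrides.tsv", package = "stratameta")
  if (nzchar(path)) return(.readTsv(path))
  data.frame(profile = c("PF00909", "PF00654"),
             tcdb_family = c("Amt", "ClC"),
             tc_number = c("1.A.11", "2.A.49"),
             stringsAsFactors = FALSE)
}

.TC_PATTERN <- "^[0-9]+\\.[A-Za-z]\\.[0-9]+(\\.[0-9]+)*$"

#' Classify transporter ORFs from TCDB profile hits
#'
#' Applies the profile-level overrides (by default the two shipped
#' corrections, see [tcdbOverrides()]) and then keeps, per ORF, the
#' highest-scoring family.
#'
#' @param hits data.frame with columns `orf_id`, `profile`, `tcdb_family`,
#'   `tc_number`, `score` (optionally `tcdb_subclass`).
#' @param overrides data.frame in the shape of [tcdbOverrides()].
#' @return data.frame with columns `orf_id`, `system` (`"TP"`), `family`,
#'   `tc_number`, `provenance`.
#' @export
classifyTransporters <- function(hits, overrides = tcdbOverrides()) {
  stopifnot(all(c("orf_id", "profile", "tcdb_family", "tc_number", "score")
                %in% colnames(hits)))
  bad <- !grepl(.TC_PATTERN, hits$tc_number)
  if (any(bad))
    stop("malformed TC number(s): ", paste(unique(hits$tc_number[bad]), collapse = ", "))
  idx <- match(hits$profile, overrides$profile)
  overridden <- !is.na(idx)
  hits$tcdb_family[overridden] <- overrides$tcdb_family[idx[overridden]]
  hits$tc_number[overridden] <- overrides$tc_number[idx[overridden]]
  hits <- hits[order(hits$orf_id, -hits$score, hits$tcdb_family), ]
  best <- hits[!duplicated(hits$orf_id), , drop = FALSE]
  res <- data.frame(orf_id = best$orf_id, system = "TP",
                    family = best$tcdb_family, tc_number = best$tc_number,
                    provenance = ifelse(overridden[match(best$orf_id, hits$orf_id)] &
                                          best$profile %in% overrides$profile,
                                        "tcdb-override", "tcdb"))
  rownames(res) <- NULL
  res
}

.MARKERS <- c("radA", "amoA", "hcd", "amt")

#' Gate marker-gene hits on their gathering-score pass flag
#'
#' radA and amoA hits become assignments only when they meet the profile's
#' recommended gathering score; hcd labels come from an upstream phylogenetic
#' placement and are accepted as given.
#'
#' @param marker_hits data.frame with columns `orf_id`, `marker` (one of
#'   radA, amoA, hcd, amt), `gathering_pass` (logical; ignored for hcd).
#' @return data.frame with columns `orf_id`, `system` (`"marker"`), `family`
#'   (the marker name), `provenance`.
#' @export
assignMarkers <- function(marker_hits) {
  stopifnot(all(c("orf_id", "marker") %in% colnames(marker_hits)))
  bad <- !marker_hits$marker %in% .MARKERS
  if (any(bad))
    stop("unknown marker label(s): ",
         paste(unique(marker_hits$marker[bad]), collapse = ", "))
  is_hcd <- marker_hits$marker == "hcd"
  pass <- is_hcd | (!is.na(marker_hits$gathering_pass) & marker_hits$gathering_pass)
  keep <- marker_hits[pass, , drop = FALSE]
  res <- data.frame(orf_id = keep$orf_id, system = "marker",
                    family = keep$marker,
                    provenance = ifelse(keep$marker == "hcd",
                                        "placement (external)", "gathering-score"))
  rownames(res) <- NULL
  res
}
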