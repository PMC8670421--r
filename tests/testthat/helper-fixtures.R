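# Shared fixtures: a tiny hand-built experiment, an independently coded
# brute-force consensus classifier used as the oracle, a double-loop
# abundance-filter oracle, and the exhaustive tool x boundary grid.

makeToyExperiment <- function(n_orf = 6, n_sample = 4, seed = 11) {
  withSeed(seed, {
    m <- matrix(rpois(n_orf * n_sample, 20), n_orf, n_sample,
                dimnames = list(sprintf("orf%02d", seq_len(n_orf)),
                                sprintf("s%d", seq_len(n_sample))))
    OrfExperiment(m, length_bp = sample(300:3000, n_orf))
  })
}

makeToyTaxonomy <- function(orf_ids, domain = "Bacteria", rrna = FALSE) {
  n <- length(orf_ids)
  data.frame(orf_id = orf_ids,
             domain = rep_len(domain, n), phylum = "Proteobacteria",
             class = "Gammaproteobacteria", order = "Alteromonadales",
             family = "unclassified", genus = "unclassified",
             is_rrna_overlap = rep_len(rrna, n))
}

# Brute-force consensus oracle, written independently of the package path:
# explicit per-ORF loops, explicit candidate enumeration, data.frame sort.
oracleConsensus <- function(pred, thr = c(id = 50, cov = 0.5, hits = 10),
                            cap = 100) {
  out <- list()
  for (orf in unique(pred$orf_id)) {
    p <- pred[pred$orf_id == orf, , drop = FALSE]
    tools <- unique(p$tool)
    if (length(tools) == 1L) {
      metric <- switch(tools, diamond = p$percent_identity,
                       hmmer = p$coverage, hotpep = p$hits)
      best <- which.max(metric)
      ok <- switch(tools,
                   diamond = p$percent_identity[best] >= thr[["id"]],
                   hmmer = p$coverage[best] >= thr[["cov"]],
                   hotpep = p$hits[best] >= thr[["hits"]])
      if (ok) out[[orf]] <- data.frame(orf_id = orf, family = p$family[best])
      next
    }
    fmax <- suppressWarnings(max(p$frequency[p$tool == "hotpep"], na.rm = TRUE))
    if (!is.finite(fmax)) fmax <- 0
    fams <- unique(p$family)
    tab <- do.call(rbind, lapply(fams, function(fm) {
      v <- 0; q <- 0
      for (tl in tools) {
        rows <- p[p$tool == tl & p$family == fm, , drop = FALSE]
        if (!nrow(rows)) next
        v <- v + 1
        qs <- switch(tl,
                     diamond = rows$percent_identity / 100,
                     hmmer = rows$coverage,
                     hotpep = pmin(1, rows$hits / cap) *
                       (if (fmax > 0) rows$frequency / fmax else 1))
        q <- q + max(qs)
      }
      data.frame(family = fm, v = v, q = q)
    }))
    tab <- tab[order(-tab$v, -tab$q, tab$family), ]
    out[[orf]] <- data.frame(orf_id = orf, family = tab$family[1])
  }
  res <- do.call(rbind, c(out, list(NULL)))
  if (is.null(res)) res <- data.frame(orf_id = character(), family = character())
  rownames(res) <- NULL
  res
}

# exhaustive grid: every non-empty tool subset x below/at/above-boundary
# metric level per present tool x same-vs-split family pattern (117 ORFs)
makeConsensusGrid <- function() {
  levels <- list(diamond = c(45, 50, 80), hmmer = c(0.3, 0.5, 0.9),
                 hotpep = c(5, 10, 30))
  tools <- names(levels)
  rows <- list(); orf <- 0
  for (mask in 1:7) {
    present <- tools[bitwAnd(mask, c(1L, 2L, 4L)) > 0]
    combos <- expand.grid(lapply(levels[present], seq_along))
    fam_patterns <- if (length(present) == 1) "same" else c("same", "split")
    for (ci in seq_len(nrow(combos))) {
      for (fp in fam_patterns) {
        orf <- orf + 1
        for (ti in seq_along(present)) {
          tl <- present[ti]
          val <- levels[[tl]][combos[ci, ti]]
          fam <- if (fp == "split" && ti == 1) "GH16" else
                 if (fp == "split") "GH13" else "GH16"
          rows[[length(rows) + 1L]] <- data.frame(
            orf_id = sprintf("grid%03d", orf), tool = tl, family = fam,
            percent_identity = if (tl == "diamond") val else NA,
            coverage = if (tl == "hmmer") val else NA,
            hits = if (tl == "hotpep") val else NA,
            frequency = if (tl == "hotpep") 0.5 else NA)
        }
      }
    }
  }
  do.call(rbind, rows)
}

bruteAbundanceFilter <- function(m, min_cpm = 5, min_samples = 2) {
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    n_pass <- 0
    for (j in seq_len(ncol(m))) {
      cpm_ij <- m[i, j] / sum(m[, j]) * 1e6
      if (cpm_ij >= min_cpm) n_pass <- n_pass + 1
    }
    keep[i] <- n_pass >= min_samples
  }
  keep
}

runAnnotation <- function(sim, cfg, seed) {
  hits <- generateFunctionalHits(sim$experiment, cfg, seed = seed)
  cols <- c("orf_id", "system", "family", "provenance")
  rbind(consensusCazyme(hits$cazyme_predictions)[, cols],
        classifyPeptidases(hits$pep_hits, hits$merops_map)[, cols],
        classifyTransporters(hits$tp_hits)[, cols],
        assignMarkers(hits$marker_hits)[, cols])
}
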