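# End-to-end orchestration: one validated configuration drives
# data acquisition (synthetic or TSV inputs), the two input filters, the
# abundance filter, functional annotation, and the selected analyses, with
# every stage output written once as TSV plus a key=value run manifest
# recording the ORF funnel. Runs are deterministic given the configuration:
# every stochastic stage takes its seed from `seeds`.

.PIPELINE_ANALYSES <- c("taxonomy", "diversity", "ordination", "investment",
                        "markers")

#' Build and validate a pipeline configuration
#'
#' @param synthetic A [SyntheticConfig-class] to simulate inputs, or `NULL`
#'   when reading from files.
#' @param counts,taxonomy,metadata input TSV paths (ignored when
#'   `synthetic` is given); validated for existence here.
#' @param seeds named list of integer seeds per stochastic stage:
#'   `simulate`, `hits` (synthetic runs), `srs` (diversity), `ordination`
#'   (permutation tests). A selected stage without a seed is a validation
#'   error.
#' @param analyses which analysis stages to run.
#' @param min_cpm,min_samples abundance-filter thresholds.
#' @param n_permutations permutations for PERMANOVA/RDA tests.
#' @param k_range candidate cluster numbers.
#' @return validated configuration list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           counts = NULL, taxonomy = NULL, metadata = NULL,
                           seeds = list(),
                           analyses = .PIPELINE_ANALYSES,
                           min_cpm = 5, min_samples = 2,
                           n_permutations = 199, k_range = 2:6) {
  analyses <- match.arg(analyses, .PIPELINE_ANALYSES, several.ok = TRUE)
  if (is.null(synthetic)) {
    for (p in c(counts, taxonomy, metadata))
      if (!file.exists(p)) stop("input path does not exist: ", p)
    if (any(c("investment", "markers") %in% analyses))
      stop("investment/marker analyses need annotation inputs; ",
           "use a synthetic configuration or run the classify* functions directly")
  } else {
    validObject(synthetic)
  }
  need <- c(if (!is.null(synthetic)) c("simulate", "hits"),
            if ("diversity" %in% analyses) "srs",
            if ("ordination" %in% analyses) "ordination")
  miss <- setdiff(need, names(seeds))
  if (length(miss))
    stop("missing seed(s) for stochastic stage(s): ", paste(miss, collapse = ", "))
  structure(list(synthetic = synthetic, counts = counts, taxonomy = taxonomy,
                 metadata = metadata, seeds = seeds, analyses = analyses,
                 min_cpm = min_cpm, min_samples = min_samples,
                 n_permutations = n_permutations, k_range = k_range),
            class = "PipelineConfig")
}

.writeStage <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  if (file.exists(path)) stop("refusing to overwrite existing output: ", path)
  .writeTsv(df, path)
}

#' Run the full analysis pipeline
#'
#' Executes read/simulate, rRNA-overlap removal, prokaryote subsetting, the
#' abundance filter, functional annotation and the selected analyses, writes
#' one TSV per stage output into `out_dir` (write-once; existing files are
#' an error) and a `manifest.txt` with the per-stage ORF funnel.
#'
#' @param config A `PipelineConfig` from [pipelineConfig()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest as a named character vector.
#' @export
runPipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(package_version = as.character(utils::packageVersion("stratameta")))
  for (nm in names(config$seeds))
    manifest[paste0("seed_", nm)] <- as.character(config$seeds[[nm]])

  hits <- truth <- NULL
  if (!is.null(config$synthetic)) {
    sim <- generateDataset(config$synthetic, seed = config$seeds$simulate)
    oe <- sim$experiment
    meta <- sim$metadata
    truth <- sim$truth
    hits <- generateFunctionalHits(oe, config$synthetic,
                                   seed = config$seeds$hits)
  } else {
    oe <- readCountTable(config$counts)
    oe <- attachTaxonomy(oe, readTaxonomyTable(config$taxonomy))
    meta <- readSampleMetadata(config$metadata)
    oe <- attachSampleMetadata(oe, meta)
  }
  manifest["n_samples"] <- as.character(ncol(oe))
  manifest["n_orfs_predicted"] <- as.character(nrow(oe))

  oe <- filterRrnaOverlaps(oe)
  manifest["n_orfs_after_rrna_filter"] <- as.character(nrow(oe))
  oe <- subsetProkaryotes(oe)
  manifest["n_orfs_prokaryote"] <- as.character(nrow(oe))
  oe <- abundanceFilter(oe, min_cpm = config$min_cpm,
                        min_samples = config$min_samples)
  manifest["n_orfs_abundance_filtered"] <- as.character(nrow(oe))
  .writeStage(data.frame(orf_id = rownames(oe),
                         length_bp = rowData(oe)$length_bp,
                         as.data.frame(counts(oe), check.names = FALSE),
                         check.names = FALSE),
              out_dir, "counts_filtered")

  assignments <- NULL
  if (!is.null(hits)) {
    keep <- function(df) df[df$orf_id %in% rownames(oe), , drop = FALSE]
    assignments <- rbind(
      consensusCazyme(keep(hits$cazyme_predictions))[, c("orf_id", "system", "family", "provenance")],
      classifyPeptidases(keep(hits$pep_hits), hits$merops_map)[, c("orf_id", "system", "family", "provenance")],
      classifyTransporters(keep(hits$tp_hits))[, c("orf_id", "system", "family", "provenance")],
      assignMarkers(keep(hits$marker_hits))[, c("orf_id", "system", "family", "provenance")])
    .writeStage(assignments, out_dir, "assignments")
    manifest["n_assignments"] <- as.character(nrow(assignments))
  }

  results <- list(experiment = oe, metadata = meta, assignments = assignments,
                  truth = truth)

  if ("taxonomy" %in% config$analyses) {
    rel <- taxonRelativeTranscription(oe, rank = "order")
    .writeStage(rel, out_dir, "taxon_transcription_order")
    relp <- taxonRelativeTranscription(oe, rank = "phylum",
                                       proteobacteria_at_class = TRUE)
    .writeStage(relp, out_dir, "taxon_transcription_phylum")
    results$taxon_transcription <- rel
  }

  if ("diversity" %in% config$analyses) {
    div <- diversityTable(oe, assignments = assignments,
                          subsets = c("all",
                                      if (!is.null(assignments))
                                        intersect(c("CAZyme", "TP", "PEP"),
                                                  assignments$system)),
                          seed = config$seeds$srs)
    .writeStage(div, out_dir, "diversity")
    results$diversity <- div
    cz <- div[div$subset_tag == if (!is.null(assignments) &&
                                    "CAZyme" %in% div$subset_tag) "CAZyme" else "all", ]
    an <- richnessAnova(cz, meta)
    .writeStage(data.frame(f_statistic = an$f_statistic,
                           df_between = an$df_between,
                           df_within = an$df_within, p_value = an$p_value),
                out_dir, "richness_anova")
    results$richness_anova <- an
  }

  if ("ordination" %in% config$analyses) {
    hel <- hellingerTransform(oe)
    pca <- pcaOrdination(hel)
    .writeStage(data.frame(sample_id = rownames(pca$sample_scores),
                           pca$sample_scores[, 1:min(4, ncol(pca$sample_scores))],
                           check.names = FALSE),
                out_dir, "pca_scores")
    cl <- hierarchicalClusters(hel, k_range = config$k_range)
    .writeStage(data.frame(sample_id = names(cl$labels), cluster = cl$labels,
                           chosen_k = cl$chosen_k),
                out_dir, "clusters")
    .writeStage(data.frame(merge1 = cl$hclust$merge[, 1],
                           merge2 = cl$hclust$merge[, 2],
                           height = cl$hclust$height),
                out_dir, "cluster_linkage")
    pm <- permanovaTest(hel, grouping = factor(meta$depth_m[match(colnames(oe), meta$sample_id)]),
                        n_permutations = config$n_permutations,
                        seed = config$seeds$ordination)
    .writeStage(pm, out_dir, "permanova_depth")
    env <- imputeBelowDetection(meta)
    cand <- setdiff(colnames(env)[vapply(env, is.numeric, logical(1))],
                    c("depth_m", "replicate"))
    vars <- selectEnvVariables(env[, cand, drop = FALSE])
    rda <- rdaOrdination(hel, env[match(colnames(oe), env$sample_id), ],
                         vars, n_permutations = config$n_permutations,
                         seed = config$seeds$ordination + 10L)
    .writeStage(rda$tests, out_dir, "rda_tests")
    results <- c(results, list(pca = pca, clusters = cl, permanova = pm,
                               rda = rda, selected_vars = vars))
    manifest["rda_selected_variables"] <- paste(vars, collapse = ",")
  }

  if ("investment" %in% config$analyses) {
    tp <- tpm(oe)
    tot <- systemTotals(tp, assignments, taxonomy_df = taxonomy(oe),
                        rank = "order")
    inv <- investmentLogRatios(tot, meta)
    .writeStage(inv, out_dir, "investment_ratios")
    results$system_totals <- tot
    results$investment <- inv
  }

  if ("markers" %in% config$analyses) {
    mra <- markerRelativeAbundance(oe, assignments)
    .writeStage(mra, out_dir, "marker_abundance_per_sample")
    msum <- summarizeMarkerAbundance(mra, meta)
    .writeStage(msum, out_dir, "marker_abundance")
    mlr <- markerLogRatios(mra, meta)
    .writeStage(mlr, out_dir, "marker_ratios")
    .writeStage(attr(mlr, "pooled"), out_dir, "marker_ratios_pooled")
    results$marker_abundance <- msum
    results$marker_ratios <- mlr
  }

  manifest_path <- file.path(out_dir, "manifest.txt")
  if (file.exists(manifest_path)) stop("refusing to overwrite ", manifest_path)
  writeLines(paste0(names(manifest), "=", manifest), manifest_path)
  results$manifest <- manifest
  invisible(results)
}
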