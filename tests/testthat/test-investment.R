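toyTotals <- function() {
  # two taxa x two samples (one stratum, replicates 1 and 2)
  expand.grid(taxon = c("TaxA", "TaxB"), sample_id = c("s1", "s2"),
              system = c("CAZyme", "PEP", "TP", "total"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

toyMeta <- function() data.frame(sample_id = c("s1", "s2"), depth_m = 5,
                                 month = "July", replicate = 1:2)

test_that("taxon relative transcription closes to 100% and honours the class override", {
  m <- matrix(c(60L, 30L, 10L, 0L, 20L, 20L, 40L, 20L), 4, 2,
              dimnames = list(paste0("o", 1:4), c("s1", "s2")))
  tax <- data.frame(orf_id = paste0("o", 1:4),
                    domain = "Bacteria",
                    phylum = c("Proteobacteria", "Proteobacteria",
                               "Bacteroidetes", "Cyanobacteria"),
                    class = c("Alphaproteobacteria", "Gammaproteobacteria",
                              "Flavobacteriia", "Cyanophyceae"),
                    order = c("Pelagibacterales", "Alteromonadales",
                              "Flavobacteriales", "Synechococcales"),
                    family = "unclassified", genus = "unclassified",
                    is_rrna_overlap = FALSE)
  oe <- OrfExperiment(m, length_bp = rep(900L, 4), taxonomy = tax)
  rel <- taxonRelativeTranscription(oe, rank = "order")
  sums <- tapply(rel$pct, rel$sample_id, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-9)
  expect_equal(rel$pct[rel$taxon == "Pelagibacterales" & rel$sample_id == "s1"], 60)

  relp <- taxonRelativeTranscription(oe, rank = "phylum",
                                     proteobacteria_at_class = TRUE)
  expect_true(all(c("Alphaproteobacteria", "Gammaproteobacteria",
                    "Bacteroidetes") %in% relp$taxon))
  expect_false("Proteobacteria" %in% relp$taxon)

  # degenerate composition: everything in one order
  one <- OrfExperiment(matrix(c(5L, 7L), 2, 1,
                              dimnames = list(c("a", "b"), "s1")),
                       length_bp = c(100L, 100L),
                       taxonomy = makeToyTaxonomy(c("a", "b")))
  r1 <- taxonRelativeTranscription(one)
  expect_equal(r1$pct, 100)
})

test_that("system totals sum member TPM, honour multi-system ORFs, and keep empty systems", {
  tpm_m <- matrix(c(100, 50, 30, 20), 4, 1,
                  dimnames = list(paste0("o", 1:4), "s1"))
  tax <- makeToyTaxonomy(paste0("o", 1:4))
  asg <- data.frame(orf_id = c("o1", "o2", "o3", "o3"),
                    system = c("CAZyme", "CAZyme", "TP", "marker"),
                    family = c("GH16", "GH13", "Amt", "amt"))
  tot <- systemTotals(tpm_m, asg, tax)
  get <- function(sys) tot$tpm_sum[tot$system == sys]
  expect_equal(get("CAZyme"), 150)
  expect_equal(get("TP"), 30)
  expect_equal(get("marker:amt"), 30)  # dual-assigned ORF counts in both
  expect_equal(get("total"), 200)
  expect_error(systemTotals(tpm_m, data.frame(orf_id = "zz", system = "TP",
                                              family = "Amt"), tax),
               "unknown ORF")
})

test_that("investment log ratios: direct arithmetic, replicate summary, pseudocount path", {
  tot <- toyTotals()
  tot$tpm_sum <- 0
  set_val <- function(tot, tx, s, sys, v) {
    tot$tpm_sum[tot$taxon == tx & tot$sample_id == s & tot$system == sys] <- v
    tot
  }
  tot <- set_val(tot, "TaxA", "s1", "CAZyme", 200)
  tot <- set_val(tot, "TaxA", "s1", "PEP", 100)
  tot <- set_val(tot, "TaxA", "s2", "CAZyme", 800)
  tot <- set_val(tot, "TaxA", "s2", "PEP", 100)
  tot <- set_val(tot, "TaxA", "s1", "TP", 100)
  tot <- set_val(tot, "TaxA", "s2", "TP", 100)
  tot <- set_val(tot, "TaxB", "s1", "CAZyme", 50)
  tot <- set_val(tot, "TaxB", "s1", "PEP", 50)
  inv <- investmentLogRatios(tot, toyMeta(), include_community = FALSE)
  a_cp <- inv[inv$taxon == "TaxA" & inv$ratio_type == "CAZyme/PEP", ]
  expect_equal(a_cp$mean_log_ratio, mean(c(1, 3)))   # log2 ratios 1 and 3
  expect_equal(a_cp$sd_log_ratio, sd(c(1, 3)))       # = sqrt(2)
  expect_equal(a_cp$n_replicates, 2)
  expect_false(a_cp$pseudocount_used)

  # TaxB: replicate 2 has both sums zero -> excluded; replicate 1 clean
  b_cp <- inv[inv$taxon == "TaxB" & inv$ratio_type == "CAZyme/PEP", ]
  expect_equal(b_cp$n_replicates, 1)
  expect_equal(b_cp$mean_log_ratio, 0)
  # TaxB CAZyme/TP: TP zero in replicate 1 -> pseudocount fires
  b_ct <- inv[inv$taxon == "TaxB" & inv$ratio_type == "CAZyme/TP", ]
  expect_true(b_ct$pseudocount_used)
})

test_that("log-ratio identities: antisymmetry, transitivity, scale invariance", {
  sim <- generateDataset(syntheticConfig(orfs_per_taxon = 20L), seed = 61)
  f <- abundanceFilter(subsetProkaryotes(filterRrnaOverlaps(sim$experiment)))
  asg <- runAnnotation(sim, syntheticConfig(orfs_per_taxon = 20L), seed = 62)
  tp <- tpm(f)
  tot <- systemTotals(tp, asg[asg$orf_id %in% rownames(f), ], taxonomy(f))
  inv_ab <- investmentLogRatios(tot, sim$metadata,
                                ratio_types = c("CAZyme/PEP", "PEP/CAZyme"))
  ok <- !inv_ab$pseudocount_used & inv_ab$n_replicates > 0
  ab <- inv_ab[inv_ab$ratio_type == "CAZyme/PEP" & ok, ]
  ba <- inv_ab[inv_ab$ratio_type == "PEP/CAZyme" & ok, ]
  key <- c("taxon", "depth_m", "month")
  mm <- merge(ab, ba, by = key)
  expect_equal(mm$mean_log_ratio.x, -mm$mean_log_ratio.y, tolerance = 1e-12)

  inv3 <- investmentLogRatios(tot, sim$metadata)
  w <- reshape(inv3[!inv3$pseudocount_used,
                    c(key, "ratio_type", "mean_log_ratio")],
               idvar = key, timevar = "ratio_type", direction = "wide")
  colnames(w) <- sub("mean_log_ratio.", "", colnames(w), fixed = TRUE)
  cc <- complete.cases(w)
  expect_lt(max(abs(w$`CAZyme/PEP`[cc] + w$`PEP/TP`[cc] - w$`CAZyme/TP`[cc])),
            1e-10)

  tot2 <- tot; tot2$tpm_sum <- tot2$tpm_sum * 17
  inv_scaled <- investmentLogRatios(tot2, sim$metadata)
  expect_equal(inv3$mean_log_ratio, inv_scaled$mean_log_ratio, tolerance = 1e-10)
})

test_that("marker abundances and log ratios: zero case, identity, bounds, radA required", {
  m <- matrix(c(10L, 40L, 50L, 20L, 30L, 50L), 3, 2,
              dimnames = list(c("radA_o", "amoA_o", "other_o"), c("s1", "s2")))
  oe <- OrfExperiment(m, length_bp = rep(1000L, 3),
                      taxonomy = makeToyTaxonomy(rownames(m), domain = "Archaea"))
  asg <- data.frame(orf_id = c("radA_o", "amoA_o"), system = "marker",
                    family = c("radA", "amoA"))
  mra <- markerRelativeAbundance(oe, asg)
  expect_equal(mra$pct[mra$marker == "radA" & mra$sample_id == "s1"], 10)
  expect_equal(mra$pct[mra$marker == "amoA" & mra$sample_id == "s1"], 40)
  expect_true(all(mra$pct >= 0 & mra$pct <= 100))

  mlr <- markerLogRatios(mra, toyMeta(), markers = "amoA")
  expect_equal(mlr$mean_log_ratio, mean(c(log2(40 / 10), log2(30 / 20))))

  # amoA == radA -> ratio 0; zero marker -> 0%
  asg0 <- data.frame(orf_id = c("radA_o", "amoA_o", "missing"),
                     system = "marker", family = c("radA", "amoA", "hcd"))
  mra0 <- markerRelativeAbundance(oe, asg0)
  expect_equal(mra0$pct[mra0$marker == "hcd"], c(0, 0))
  eqm <- mra; eqm$pct[eqm$marker == "amoA"] <- eqm$pct[eqm$marker == "radA"]
  mlr0 <- markerLogRatios(eqm, toyMeta(), markers = "amoA")
  expect_equal(mlr0$mean_log_ratio, 0)

  no_rad <- mra[mra$marker != "radA", ]
  expect_error(markerLogRatios(no_rad, toyMeta()), "radA")
})

test_that("programmed taxon depth trend and marker folds are recovered from counts", {
  cfg <- syntheticConfig(orfs_per_taxon = 20L)
  sim <- generateDataset(cfg, seed = 71)
  oe <- subsetProkaryotes(filterRrnaOverlaps(sim$experiment))
  rel <- taxonRelativeTranscription(oe, rank = "order")
  meta <- sim$metadata
  th <- rel[rel$taxon == "Nitrosopumilales", ]
  th <- merge(th, meta, by = "sample_id")
  expect_gt(mean(th$pct[th$depth_m == 100]), mean(th$pct[th$depth_m == 5]))

  asg <- runAnnotation(sim, cfg, seed = 72)
  mra <- markerRelativeAbundance(oe, asg)
  mlr <- markerLogRatios(mra, meta)
  pooled <- attr(mlr, "pooled")
  expect_equal(pooled$log2_pooled[pooled$marker == "amoA"], 2, tolerance = 0.15)
  expect_equal(pooled$log2_pooled[pooled$marker == "hcd"], log2(3),
               tolerance = 0.15)
})
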