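pred_row <- function(orf, tool, family, id = NA, cov = NA, hits = NA, freq = NA) {
  data.frame(orf_id = orf, tool = tool, family = family,
             percent_identity = id, coverage = cov, hits = hits,
             frequency = freq)
}

test_that("single-tool rule gates on each tool's threshold, boundary inclusive", {
  # below threshold: no assignment
  expect_identical(nrow(consensusCazyme(pred_row("a", "diamond", "GH16", id = 45))), 0L)
  expect_identical(nrow(consensusCazyme(pred_row("a", "hmmer", "GH16", cov = 0.49))), 0L)
  expect_identical(nrow(consensusCazyme(pred_row("a", "hotpep", "GH16", hits = 9, freq = .5))), 0L)
  # exactly at the threshold: retained (exclusion uses strict <)
  expect_equal(consensusCazyme(pred_row("a", "diamond", "GH16", id = 50))$family, "GH16")
  expect_equal(consensusCazyme(pred_row("a", "hmmer", "GH16", cov = 0.5))$family, "GH16")
  expect_equal(consensusCazyme(pred_row("a", "hotpep", "GH16", hits = 10, freq = .5))$family, "GH16")
  # comfortably above
  res <- consensusCazyme(pred_row("a", "hmmer", "GH16", cov = 0.6))
  expect_equal(res$family, "GH16")
  expect_equal(res$provenance, "single-tool")
})

test_that("multi-tool ranking counts votes first, then normalized quality, then label", {
  p <- rbind(pred_row("a", "diamond", "GH16", id = 80),
             pred_row("a", "hotpep", "GH13", hits = 12, freq = 0.3),
             pred_row("a", "hmmer", "GH16", cov = 0.9))
  res <- consensusCazyme(p)
  expect_equal(res$family, "GH16")   # 2 votes beat 1
  expect_equal(res$provenance, "votes")

  # equal votes: higher summed quality wins
  p2 <- rbind(pred_row("b", "diamond", "GH16", id = 70),
              pred_row("b", "hmmer", "GH13", cov = 0.9))
  expect_equal(consensusCazyme(p2)$family, "GH13")
  expect_equal(consensusCazyme(p2)$provenance, "quality")

  # exact quality tie: lexicographically smallest family, logged as a tie
  p3 <- rbind(pred_row("c", "diamond", "GH16", id = 60),
              pred_row("c", "hmmer", "GH13", cov = 0.6))
  res3 <- consensusCazyme(p3)
  expect_equal(res3$family, "GH13")
  expect_equal(res3$provenance, "tie-lexicographic")

  # below-threshold metrics do not disqualify multi-tool ORFs (rule ii only ranks)
  p4 <- rbind(pred_row("d", "diamond", "GH16", id = 45),
              pred_row("d", "hmmer", "GH16", cov = 0.3))
  expect_equal(consensusCazyme(p4)$family, "GH16")
})

test_that("never more than one CAZyme family per ORF", {
  sim <- generateDataset(syntheticConfig(orfs_per_taxon = 20L,
                                         annotation = list(conflict_rate = 0.5)),
                         seed = 3)
  rd <- as.data.frame(SummarizedExperiment::rowData(sim$experiment))
  rd$orf_id <- rownames(sim$experiment)
  pred <- generateCazymePredictions(rd, syntheticConfig(), seed = 4)
  res <- consensusCazyme(pred)
  expect_identical(anyDuplicated(res$orf_id), 0L)
})

test_that("malformed prediction records are hard errors", {
  expect_error(consensusCazyme(pred_row("a", "blastp", "GH16", id = 80)),
               "unknown tool")
  expect_error(consensusCazyme(pred_row("a", "diamond", "GH16", id = 80, cov = 0.5)),
               "another tool")
  expect_error(consensusCazyme(pred_row("a", "hmmer", "GH16")), "metric")
  expect_error(consensusCazyme(pred_row("a", "diamond", "", id = 80)), "non-empty")
})

test_that("consensus matches the brute-force oracle on random fixtures", {
  withSeed(42, {
    for (rep in 1:25) {
      n_orf <- sample(1:6, 1)
      rows <- list()
      for (o in seq_len(n_orf)) {
        tools <- sample(c("diamond", "hmmer", "hotpep"), sample(1:3, 1))
        for (tl in tools) {
          fam <- sample(c("GH13", "GH16", "GT4", "CBM50"), 1)
          rows[[length(rows) + 1L]] <- pred_row(
            paste0("o", o), tl, fam,
            id = if (tl == "diamond") round(runif(1, 30, 99), 1) else NA,
            cov = if (tl == "hmmer") round(runif(1, 0.2, 1), 2) else NA,
            hits = if (tl == "hotpep") sample(1:40, 1) else NA,
            freq = if (tl == "hotpep") round(runif(1, 0, 1), 2) else NA)
        }
      }
      pred <- do.call(rbind, rows)
      got <- consensusCazyme(pred)
      want <- oracleConsensus(pred)
      expect_identical(got[order(got$orf_id), c("orf_id", "family")],
                       want[order(want$orf_id), c("orf_id", "family")])
    }
  })
})

test_that("peptidase mapping takes the best-scoring mapped domain per ORF", {
  map <- data.frame(pfam = c("PF1", "PF2"), merops_family = c("S08", "M01"))
  hits <- data.frame(orf_id = c("a", "b", "b", "c"),
                     pfam = c("PF1", "PF1", "PF2", "PFX"),
                     score = c(55, 40, 90, 70))
  res <- classifyPeptidases(hits, map)
  expect_equal(res$family[res$orf_id == "a"], "S08")
  expect_equal(res$family[res$orf_id == "b"], "M01")  # score 90 beats 40
  expect_false("c" %in% res$orf_id)
  expect_equal(attr(res, "unmapped")$pfam, "PFX")
})

test_that("transporter overrides and TC-number validation behave as shipped", {
  hits <- data.frame(orf_id = c("a", "b", "c"),
                     profile = c("PF00909", "PF00654", "PF00005"),
                     tcdb_family = c("MIT", "Wrong", "ABC"),
                     tc_number = c("1.A.35", "9.Z.9", "3.A.1"),
                     score = c(100, 100, 100))
  res <- classifyTransporters(hits)
  expect_equal(res$family[res$orf_id == "a"], "Amt")
  expect_equal(res$tc_number[res$orf_id == "a"], "1.A.11")
  expect_equal(res$family[res$orf_id == "b"], "ClC")
  expect_equal(res$tc_number[res$orf_id == "b"], "2.A.49")
  expect_equal(res$family[res$orf_id == "c"], "ABC")  # no override: unchanged

  bad <- hits; bad$tc_number[3] <- "not-a-tc"
  expect_error(classifyTransporters(bad), "malformed TC")

  # per-ORF argmax over competing profiles
  multi <- data.frame(orf_id = "d", profile = c("PF00005", "PF07715"),
                      tcdb_family = c("ABC", "OMR"),
                      tc_number = c("3.A.1", "1.B.14"), score = c(50, 120))
  expect_equal(classifyTransporters(multi)$family, "OMR")
})

test_that("marker assignment gates on the gathering score except for placed hcd", {
  hits <- data.frame(orf_id = c("a", "b", "c", "d"),
                     marker = c("amoA", "amoA", "hcd", "radA"),
                     gathering_pass = c(TRUE, FALSE, NA, TRUE))
  res <- assignMarkers(hits)
  expect_setequal(res$orf_id, c("a", "c", "d"))
  expect_equal(res$provenance[res$family == "hcd"], "placement (external)")
  expect_error(assignMarkers(data.frame(orf_id = "x", marker = "nifH",
                                        gathering_pass = TRUE)),
               "unknown marker")
})
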