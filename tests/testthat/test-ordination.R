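hellOf <- function(sim) hellingerTransform(subsetProkaryotes(
  filterRrnaOverlaps(sim$experiment)))

test_that("PCA identities: rank-1 data, reconstruction, explained fractions", {
  u <- c(1, 2, 3, 4); v <- c(2, -1, 0, 1)
  m <- outer(u, rep(1, 3)) + outer(v, c(-1, 0, 1))  # samples vary along one axis
  rownames(m) <- paste0("o", 1:4); colnames(m) <- paste0("s", 1:3)
  res <- pcaOrdination(m)
  expect_equal(res$explained_fraction[1], 1, tolerance = 1e-10)

  withSeed(3, {
    x <- matrix(rnorm(60), 10, 6,
                dimnames = list(paste0("o", 1:10), paste0("s", 1:6)))
    res2 <- pcaOrdination(x)
    centered <- t(x) - matrix(res2$center, 6, 10, byrow = TRUE)
    recon <- res2$sample_scores %*% t(res2$variable_loadings)
    expect_lt(max(abs(recon - centered)), 1e-8)
    expect_equal(res2$explained_fraction,
                 res2$eigenvalues / sum(res2$eigenvalues), tolerance = 1e-10)
    expect_true(all(diff(res2$explained_fraction) <= 1e-12))
  })
  expect_error(pcaOrdination(matrix(1:3, ncol = 1)), "2 samples")
})

test_that("axis-1 PCA scores separate programmed surface and deep strata", {
  sim <- generateDataset(syntheticConfig(orfs_per_taxon = 20L), seed = 31)
  res <- pcaOrdination(hellOf(sim))
  surface <- sim$metadata$depth_m <= 15
  s1 <- res$sample_scores[, 1]
  expect_true(max(s1[surface]) < min(s1[!surface]) ||
                min(s1[surface]) > max(s1[!surface]))
})

test_that("variable selection drops duplicates, keeps orthogonal sets, matches a minimal-removal oracle", {
  withSeed(8, {
    X <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    X$dup <- X$a
    sel <- selectEnvVariables(X)
    expect_true(sum(c("a", "dup") %in% sel) == 1)
    expect_true(all(c("b", "c") %in% sel))

    orth <- as.data.frame(qr.Q(qr(matrix(rnorm(40 * 4), 40, 4))))
    expect_setequal(selectEnvVariables(orth), colnames(orth))

    expect_warning(selectEnvVariables(data.frame(a = rnorm(10), k = rep(1, 10))),
                   "constant")

    # near-collinear triplet: greedy survivors equal the brute-force minimal
    # removal set satisfying both constraints
    z <- rnorm(40)
    Y <- data.frame(v1 = z + rnorm(40, 0, .05), v2 = z + rnorm(40, 0, .05),
                    v3 = z + rnorm(40, 0, .05), w = rnorm(40))
    sel2 <- sort(selectEnvVariables(Y, r_max = 0.9, vif_max = 10))
    ok <- function(vars) {
      M <- scale(as.matrix(Y[, vars, drop = FALSE]))
      R <- abs(cor(M)); diag(R) <- 0
      if (max(R) >= 0.9) return(FALSE)
      if (length(vars) >= 2 && max(diag(solve(cor(M)))) >= 10) return(FALSE)
      TRUE
    }
    best_size <- 0
    for (k in ncol(Y):1) {
      combs <- utils::combn(colnames(Y), k, simplify = FALSE)
      if (any(vapply(combs, ok, logical(1)))) { best_size <- k; break }
    }
    expect_equal(length(sel2), best_size)
    expect_true(ok(sel2))
  })
})

test_that("RDA noiseless limit: a single driving predictor saturates the model", {
  withSeed(12, {
    n <- 12
    xv <- rnorm(n)
    # response linear in xv up to negligible noise (exact collinearity makes
    # the residual rank degenerate)
    Y <- outer(xv, rnorm(30)) + matrix(rnorm(n * 30, 0, 0.01), n, 30)
    rownames(Y) <- paste0("s", 1:n)
    mat <- t(Y); rownames(mat) <- paste0("o", 1:30); colnames(mat) <- paste0("s", 1:n)
    meta <- data.frame(sample_id = colnames(mat), driver = xv)
    res <- rdaOrdination(mat, meta, "driver", n_permutations = 199, seed = 1)
    expect_gt(res$ordination$constrained_fraction, 0.999)
    marg <- res$tests[res$tests$family == "margin", ]
    expect_equal(marg$p_value, 1 / 200)
  })
})

test_that("permutation results are reproducible, bounded below, and Holm is monotone", {
  sim <- generateDataset(syntheticConfig(orfs_per_taxon = 20L), seed = 33)
  hel <- hellOf(sim)
  meta <- imputeBelowDetection(sim$metadata)
  r1 <- rdaOrdination(hel, meta, c("chla_ug_per_l", "totP_uM"),
                      n_permutations = 99, seed = 5)
  r2 <- rdaOrdination(hel, meta, c("chla_ug_per_l", "totP_uM"),
                      n_permutations = 99, seed = 5)
  expect_identical(r1$tests, r2$tests)
  expect_true(all(r1$tests$p_value >= 1 / 100))
  expect_true(all(r1$tests$p_adjusted >= r1$tests$p_value))
  expect_error(rdaOrdination(hel[, 1:3], meta[1:3, ],
                             c("chla_ug_per_l", "totP_uM", "doc_uM")),
               "predictors")
})

test_that("variance partition is additive, vanishes off-diagonal for orthogonal drivers, and matches vegan", {
  withSeed(21, {
    n <- 24
    Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
    meta <- data.frame(sample_id = paste0("s", 1:n),
                       x1 = Q[, 1], x2 = Q[, 2], x3 = Q[, 3])
    Y <- Q[, 1] %*% t(rnorm(40)) + Q[, 2] %*% t(rnorm(40)) +
      matrix(rnorm(n * 40, 0, 0.5), n, 40)
    mat <- t(Y); rownames(mat) <- paste0("o", 1:40); colnames(mat) <- meta$sample_id
    vp <- variancePartition(mat, meta, c("x1", "x2"))
    expect_equal(sum(vp$adj_r2), attr(vp, "total_adj_r2"), tolerance = 1e-6)
    shared <- vp$adj_r2[vp$n_members > 1]
    expect_lt(max(abs(shared)), 0.05)

    # duplicated predictor: everything is shared
    meta$x1b <- meta$x1
    vp2 <- variancePartition(mat, meta, c("x1", "x1b"))
    uniq <- vp2$adj_r2[vp2$n_members == 1]
    expect_lt(max(abs(uniq)), 0.02)
    expect_gt(vp2$adj_r2[vp2$n_members == 2], 0.1)

    # independent route: vegan::varpart two-variable fractions
    ref <- vegan::varpart(t(mat), ~ x1, ~ x2, data = meta)$part$indfract
    expect_equal(sort(vp$adj_r2), sort(ref$Adj.R.square[1:3]), tolerance = 1e-6)

    expect_error(variancePartition(mat, meta, c("x1", "x2", "x3", "x1b", "x2")),
                 "2 to 4")
  })
})

test_that("PERMANOVA separates programmed clusters and stays in [0,1] on noise", {
  withSeed(14, {
    g <- rep(c("A", "B"), each = 6)
    Y <- matrix(rnorm(12 * 20), 12, 20)
    Y[g == "B", ] <- Y[g == "B", ] + 8
    mat <- t(Y); colnames(mat) <- paste0("s", 1:12); rownames(mat) <- paste0("o", 1:20)
    res <- permanovaTest(mat, g, n_permutations = 199, seed = 2)
    expect_equal(res$p_value, 1 / 200)
    expect_gt(res$r2, 0.9)
    expect_identical(res, permanovaTest(mat, g, n_permutations = 199, seed = 2))

    for (i in 1:20) {
      Yr <- matrix(rnorm(12 * 15), 12, 15)
      mr <- t(Yr); colnames(mr) <- paste0("s", 1:12)
      rr <- permanovaTest(mr, g, n_permutations = 49, seed = i)
      expect_gte(rr$r2, 0); expect_lte(rr$r2, 1)
      expect_gte(rr$p_value, 1 / 50)
    }
    expect_error(permanovaTest(mat, c("A", rep("B", 11)), 99, seed = 1),
                 "singleton")
  })
})

test_that("Ward.D2 clustering recovers programmed strata with sane diagnostics", {
  sim <- generateDataset(syntheticConfig(orfs_per_taxon = 20L), seed = 51)
  hel <- hellOf(sim)
  cl <- hierarchicalClusters(hel, k_range = 2:8)
  expect_true(all(diff(cl$hclust$height) >= -1e-9))  # merge heights monotone
  expect_true(cl$chosen_k %in% 2:8)
  truth2 <- ifelse(sim$metadata$depth_m <= 15, 1, 2)
  skip_if_not_installed("mclust")
  ari2 <- mclust::adjustedRandIndex(cutree(cl$hclust, 2)[sim$metadata$sample_id],
                                    truth2)
  expect_gte(ari2, 0.99)

  # four programmed strata: July surface, September surface, mid, deep
  truth4 <- paste(ifelse(sim$metadata$depth_m <= 15, "surf", "deep"),
                  ifelse(sim$metadata$depth_m <= 15, sim$metadata$month, ""),
                  ifelse(sim$metadata$depth_m == 50, "mid", ""))
  ari4 <- mclust::adjustedRandIndex(cutree(cl$hclust, 4)[sim$metadata$sample_id],
                                    truth4)
  expect_gte(ari4, 0.8)

  # constant rows are dropped with a warning, k_range is capped
  hel2 <- rbind(hel, const = rep(0.1, ncol(hel)))
  expect_warning(hierarchicalClusters(hel2, k_range = 2:30), "constant")
  expect_error(hierarchicalClusters(hel[, 1:2]), "3 samples")
})
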