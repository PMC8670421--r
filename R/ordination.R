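# Multivariate community statistics on the Hellinger-transformed matrix:
# transformation-based PCA, environmental-variable selection (pairwise
# Pearson r then variance inflation factors), transformation-based RDA with
# seeded Monte Carlo permutation tests (global, per-axis, marginal
# per-variable; Holm correction within each family), variance partitioning
# into unique and shared adjusted-R^2 fractions, PERMANOVA on Euclidean
# distances, and Ward.D2 hierarchical clustering with elbow and silhouette
# diagnostics. Standard fits are delegated to vegan; the subset-based
# variance partition and the selection heuristic are implemented here.

#' Principal component analysis of a transformed community matrix
#'
#' Samples (columns of the input) are the observations; ORFs are centered
#' before the eigendecomposition.
#'
#' @param x transformed matrix, ORFs x samples (e.g. from
#'   [hellingerTransform()]).
#' @return list of class `OrdinationResult`: `method`, `sample_scores`,
#'   `variable_loadings`, `eigenvalues`, `explained_fraction`, `center`.
#' @export
pcaOrdination <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 2) stop("PCA needs at least 2 samples")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  structure(list(method = "PCA",
                 sample_scores = pc$x,
                 variable_loadings = pc$rotation,
                 eigenvalues = eig,
                 explained_fraction = eig / sum(eig),
                 center = pc$center),
            class = "OrdinationResult")
}

#' @export
print.OrdinationResult <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes\n", x$method,
              nrow(x$sample_scores), length(x$eigenvalues)))
  ex <- utils::head(round(100 * x$explained_fraction, 1), 3)
  cat("  explained (%):", paste(ex, collapse = ", "), "...\n")
  if (!is.null(x$adjusted_r2))
    cat(sprintf("  constrained fraction %.3f, adjusted R2 %.3f\n",
                x$constrained_fraction, x$adjusted_r2))
  invisible(x)
}

#' Select environmental variables by correlation and VIF screening
#'
#' Variables are z-standardized; constant variables are dropped with a
#' warning. Then, while any absolute pairwise Pearson correlation is
#' `>= r_max`, the member of the worst pair with the larger mean absolute
#' correlation to all other variables is removed; finally, while any
#' variance inflation factor is `>= vif_max`, the variable with the largest
#' VIF is removed. Both loops are deterministic (ties resolved by column
#' order).
#'
#' @param metadata data.frame of candidate covariates (numeric columns; any
#'   non-numeric columns are ignored).
#' @param r_max pairwise correlation threshold (default 0.9).
#' @param vif_max variance inflation threshold (default 10).
#' @return character vector of retained variable names; removed variables
#'   with reasons in `attr(, "dropped")`.
#' @export
selectEnvVariables <- function(metadata, r_max = 0.9, vif_max = 10) {
  num <- vapply(metadata, is.numeric, logical(1))
  X <- as.matrix(metadata[, num, drop = FALSE])
  dropped <- data.frame(variable = character(), reason = character())
  sds <- apply(X, 2, stats::sd)
  if (any(is.na(sds) | sds == 0)) {
    bad <- colnames(X)[is.na(sds) | sds == 0]
    warning("dropping constant or NA variable(s): ", paste(bad, collapse = ", "))
    dropped <- rbind(dropped, data.frame(variable = bad, reason = "constant"))
    X <- X[, !colnames(X) %in% bad, drop = FALSE]
  }
  if (ncol(X) < 2) {
    out <- colnames(X); attr(out, "dropped") <- dropped; return(out)
  }
  X <- scale(X)
  repeat {
    R <- abs(stats::cor(X))
    diag(R) <- 0
    if (max(R) < r_max || ncol(X) <= 1) break
    worst <- which(R == max(R), arr.ind = TRUE)[1, ]
    means <- colMeans(abs(stats::cor(X)))  # includes the offender pair
    victim <- colnames(X)[worst][which.max(means[colnames(X)[worst]])]
    dropped <- rbind(dropped, data.frame(variable = victim,
                                         reason = sprintf("pairwise |r| >= %.2f", r_max)))
    X <- X[, colnames(X) != victim, drop = FALSE]
  }
  repeat {
    if (ncol(X) < 2) break
    vif <- diag(solve(stats::cor(X)))
    if (max(vif) < vif_max) break
    victim <- colnames(X)[which.max(vif)]
    dropped <- rbind(dropped, data.frame(variable = victim,
                                         reason = sprintf("VIF >= %.1f", vif_max)))
    X <- X[, colnames(X) != victim, drop = FALSE]
  }
  out <- colnames(X)
  attr(out, "dropped") <- dropped
  out
}

.rdaModel <- function(x, metadata, variables) {
  Y <- t(as.matrix(x))
  X <- as.data.frame(scale(as.matrix(metadata[, variables, drop = FALSE])))
  if (length(variables) > nrow(Y) - 1)
    stop("more predictors than samples - 1")
  list(model = vegan::rda(Y ~ ., data = X), Y = Y, X = X)
}

#' Transformation-based redundancy analysis with permutation inference
#'
#' Constrains the (Hellinger-transformed) community matrix on standardized
#' environmental predictors and runs seeded Monte Carlo permutation tests:
#' a global model test, sequential per-axis tests and marginal (each
#' variable given all others) per-variable tests, Holm-corrected within each
#' family. Adjusted R^2 uses Ezekiel's formula. Replace below-detection
#' covariate values (e.g. ammonium) with [imputeBelowDetection()] first.
#'
#' @param x transformed matrix, ORFs x samples.
#' @param metadata sample metadata aligned to the columns of `x`.
#' @param variables predictor column names (see [selectEnvVariables()]).
#' @param n_permutations permutations per test (default 999).
#' @param seed integer seed; tests are exactly reproducible.
#' @param families which permutation-test families to run (default all
#'   three: global, per-axis, marginal).
#' @return list with `ordination` (an `OrdinationResult` carrying
#'   `constrained_fraction` and `adjusted_r2`) and `tests` (data.frame:
#'   `family` in global/axis/margin, `term`, `pseudo_f`, `p_value`,
#'   `p_adjusted`, `n_permutations`, `seed`).
#' @export
rdaOrdination <- function(x, metadata, variables, n_permutations = 999, seed,
                          families = c("global", "axis", "margin")) {
  families <- match.arg(families, several.ok = TRUE)
  fit <- .rdaModel(x, metadata, variables)
  mod <- fit$model
  eig_all <- c(mod$CCA$eig, mod$CA$eig)
  res <- structure(list(
    method = "RDA",
    sample_scores = vegan::scores(mod, display = "sites",
                                  choices = seq_len(max(1, mod$CCA$rank))),
    variable_loadings = vegan::scores(mod, display = "bp",
                                      choices = seq_len(max(1, mod$CCA$rank))),
    eigenvalues = eig_all,
    explained_fraction = eig_all / sum(eig_all),
    constrained_fraction = sum(mod$CCA$eig) / mod$tot.chi,
    adjusted_r2 = vegan::RsquareAdj(mod)$adj.r.squared),
    class = "OrdinationResult")
  runTest <- function(off, ...) {
    a <- withSeed(seed + off, stats::anova(mod, permutations = n_permutations, ...))
    data.frame(term = rownames(a), pseudo_f = a$F, p_value = a[["Pr(>F)"]],
               row.names = NULL)[!is.na(a$F), , drop = FALSE]
  }
  fams <- list()
  if ("global" %in% families) fams$global <- runTest(0L)
  if ("axis" %in% families) fams$axis <- runTest(1L, by = "axis")
  if ("margin" %in% families) fams$margin <- runTest(2L, by = "margin")
  tests <- do.call(rbind, lapply(names(fams), function(f) {
    d <- fams[[f]]
    d$family <- f
    d$p_adjusted <- .holm(d$p_value)
    d
  }))
  tests$n_permutations <- n_permutations
  tests$seed <- seed
  rownames(tests) <- NULL
  list(ordination = res,
       tests = tests[, c("family", "term", "pseudo_f", "p_value",
                         "p_adjusted", "n_permutations", "seed")])
}

#' Variance partitioning over predictor subsets
#'
#' Decomposes the full-model adjusted R^2 into unique and shared fractions
#' across 2 to 4 predictors by inclusion-exclusion (Moebius inversion) over
#' the adjusted R^2 of every predictor-subset RDA. The fractions are
#' additive to the full-model adjusted R^2 by construction.
#'
#' @inheritParams rdaOrdination
#' @param variables 2 to 4 predictor column names.
#' @return data.frame with one row per Venn region (`members` such as
#'   `"doc_uM"` or `"chla_ug_per_l:doc_uM"`, `n_members`, `adj_r2`), plus
#'   `attr(, "total_adj_r2")`.
#' @export
variancePartition <- function(x, metadata, variables) {
  k <- length(variables)
  if (k < 2 || k > 4)
    stop("variance partitioning supports 2 to 4 variables")
  subsets <- lapply(seq_len(2^k - 1), function(mask)
    variables[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0])
  f <- vapply(subsets, function(vs)
    vegan::RsquareAdj(.rdaModel(x, metadata, vs)$model)$adj.r.squared,
    numeric(1))
  names(f) <- vapply(subsets, function(vs) paste(sort(vs), collapse = ":"), "")
  total <- f[[paste(sort(variables), collapse = ":")]]
  # h(U) = variance explained by atoms wholly inside U = total - f(complement)
  h <- function(members) {
    if (!length(members)) return(0)
    comp <- setdiff(variables, members)
    if (!length(comp)) return(total)
    total - f[[paste(sort(comp), collapse = ":")]]
  }
  rows <- lapply(subsets, function(members) {
    subs_of <- lapply(seq_len(2^length(members)) - 1L, function(mask)
      members[bitwAnd(mask, 2^(seq_along(members) - 1)) > 0])
    a <- sum(vapply(subs_of, function(u)
      (-1)^(length(members) - length(u)) * h(u), numeric(1)))
    data.frame(members = paste(sort(members), collapse = ":"),
               n_members = length(members), adj_r2 = a)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "total_adj_r2") <- total
  out
}

#' Permutational multivariate analysis of variance
#'
#' Pseudo-F partitioning of squared Euclidean distances (on a transformed
#' community matrix, or any `dist`) across a grouping factor, with a seeded
#' permutation p-value and `R2 = SS_between / SS_total`.
#'
#' @param x transformed matrix (ORFs x samples) or a `dist` over samples.
#' @param grouping factor (or coercible) with one level per group; every
#'   group needs >= 2 members.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return data.frame with `term`, `pseudo_f`, `r2`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanovaTest <- function(x, grouping, n_permutations = 999, seed) {
  d <- if (inherits(x, "dist")) x else stats::dist(t(as.matrix(x)))
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2) stop("need at least two groups")
  if (any(table(grouping) < 2))
    stop("singleton group(s): ",
         paste(names(table(grouping))[table(grouping) < 2], collapse = ", "))
  tab <- withSeed(seed,
    vegan::adonis2(d ~ grouping, permutations = n_permutations))
  data.frame(term = "grouping", pseudo_f = tab$F[1], r2 = tab$R2[1],
             p_value = tab[["Pr(>F)"]][1], n_permutations = n_permutations,
             seed = seed, row.names = NULL)
}

#' Ward.D2 hierarchical clustering with cluster-number diagnostics
#'
#' ORF-wise standardization (zero mean, unit variance) of the transformed
#' matrix, Euclidean distances between samples, Ward.D2 linkage, and both an
#' elbow curve (within-cluster sum of squares vs k) and mean silhouette
#' widths over `k_range`. The automatic choice is the silhouette maximum;
#' the elbow curve is reported for graphical inspection only.
#'
#' @param x transformed matrix, ORFs x samples.
#' @param k_range candidate cluster numbers (default 2:8), capped at
#'   n_samples - 1.
#' @param scale_rows standardize ORF rows first (default TRUE); constant
#'   rows are dropped with a warning.
#' @return list of class `ClusteringResult`: `hclust`, `chosen_k`, `labels`,
#'   `elbow` (data.frame k, within_ss), `silhouette` (data.frame k,
#'   mean_width).
#' @export
hierarchicalClusters <- function(x, k_range = 2:8, scale_rows = TRUE) {
  m <- as.matrix(x)
  if (ncol(m) < 3) stop("clustering needs at least 3 samples")
  if (scale_rows) {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " constant ORF row(s) dropped before standardization")
      m <- m[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    m <- (m - rowMeans(m)) / sds
  }
  z <- t(m)
  d <- stats::dist(z)
  hc <- stats::hclust(d, method = "ward.D2")
  k_range <- k_range[k_range >= 2 & k_range <= nrow(z) - 1]
  if (!length(k_range)) stop("k_range leaves no valid k (need 2 <= k <= n-1)")
  elbow <- sil <- numeric(length(k_range))
  labels_by_k <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    lab <- stats::cutree(hc, k = k)
    labels_by_k[[as.character(k)]] <- lab
    elbow[i] <- sum(vapply(split(seq_len(nrow(z)), lab), function(idx) {
      ctr <- colMeans(z[idx, , drop = FALSE])
      sum(sweep(z[idx, , drop = FALSE], 2, ctr)^2)
    }, numeric(1)))
    sil[i] <- mean(cluster::silhouette(lab, d)[, "sil_width"])
  }
  chosen <- k_range[which.max(sil)]
  structure(list(hclust = hc, chosen_k = chosen,
                 labels = labels_by_k[[as.character(chosen)]],
                 labels_by_k = labels_by_k,
                 elbow = data.frame(k = k_range, within_ss = elbow),
                 silhouette = data.frame(k = k_range, mean_width = sil)),
            class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("Ward.D2 clustering of %d samples; silhouette-chosen k = %d\n",
              length(x$labels), x$chosen_k))
  invisible(x)
}
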