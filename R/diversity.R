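# Richness and evenness on SRS-normalized counts. Chao1 is the
# bias-corrected form S + F1(F1-1)/(2(F2+1)) (the classic F1^2/(2 F2) form
# is available but divides by zero without doubletons); Pielou's J is
# Shannon entropy over the natural log of observed richness.

#' Chao1 richness estimate
#'
#' @param abundances integer abundance vector for one sample (SRS output);
#'   fractional abundances are rejected with a pointer to [srsNormalize()].
#' @param bias_corrected use `S + F1(F1-1)/(2(F2+1))` (default) instead of
#'   the classic `S + F1^2/(2 F2)`.
#' @return list with `observed_richness`, `chao1`, `f1`, `f2`.
#' @examples
#' chao1(c(1, 1, 2, 3, 4))$chao1  # 5.5
#' @export
chao1 <- function(abundances, bias_corrected = TRUE) {
  if (any(is.na(abundances)) || any(abundances < 0))
    stop("abundances must be non-negative")
  if (any(abundances != round(abundances)))
    stop("Chao1 needs integer abundances; normalize with srsNormalize() first")
  s_obs <- sum(abundances > 0)
  f1 <- sum(abundances == 1)
  f2 <- sum(abundances == 2)
  est <- if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
         else if (f2 > 0) s_obs + f1^2 / (2 * f2)
         else if (f1 == 0) s_obs else NaN
  list(observed_richness = s_obs, chao1 = est, f1 = f1, f2 = f2)
}

#' Pielou's evenness J
#'
#' `J = -sum(p log p) / log(S)` with natural logs; undefined (NA) for fewer
#' than two observed categories.
#'
#' @param abundances non-negative abundance vector for one sample.
#' @return evenness in `[0, 1]`, or `NA` when observed richness < 2.
#' @export
pielouEvenness <- function(abundances) {
  if (any(is.na(abundances)) || any(abundances < 0))
    stop("abundances must be non-negative")
  p <- abundances[abundances > 0]
  s <- length(p)
  if (s < 2) return(NA_real_)
  p <- p / sum(p)
  -sum(p * log(p)) / log(s)
}

#' Per-sample diversity table over functional subsets
#'
#' Computes observed richness, Chao1 and Pielou's J per sample, for the full
#' ORF set and for each requested functional subset (ORFs carrying a CAZyme,
#' TP or PEP assignment). Richness comparisons assume a common library size
#' within each subset: when `seed` is given, every subset submatrix is
#' SRS-normalized to its own smallest sample total first; otherwise `x` is
#' used as supplied and unequal totals raise a warning.
#'
#' @param x count matrix or OrfExperiment (raw counts when `seed` is given,
#'   otherwise already SRS-normalized, see [srsNormalize()]).
#' @param assignments optional functional-assignment table (columns `orf_id`,
#'   `system`) used to form the subsets.
#' @param subsets subset tags to compute; `"all"` plus any systems present.
#' @param c_min target subset library size for the internal SRS step.
#' @param seed seed for the internal SRS step; `NULL` disables it.
#' @return data.frame with one row per sample x subset.
#' @export
diversityTable <- function(x, assignments = NULL,
                           subsets = c("all", "CAZyme", "TP", "PEP"),
                           c_min = "auto", seed = NULL) {
  m <- .asCountMatrix(x)
  .checkNonEmpty(m, "diversityTable")
  rows <- list()
  for (tag in subsets) {
    ids <- if (tag == "all") rownames(m)
           else {
             if (is.null(assignments))
               stop("assignments required for subset '", tag, "'")
             assignments$orf_id[assignments$system == tag]
           }
    sub <- m[rownames(m) %in% ids, , drop = FALSE]
    if (nrow(sub) == 0 && tag != "all") next
    if (!is.null(seed)) sub <- srsNormalize(sub, c_min = c_min, seed = seed)
    else if (length(unique(colSums(sub))) > 1)
      warning("sample totals differ in subset '", tag,
              "'; richness is not depth-comparable without SRS")
    for (j in seq_len(ncol(sub))) {
      est <- chao1(sub[, j])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = colnames(sub)[j], subset_tag = tag,
        observed_richness = est$observed_richness, chao1 = est$chao1,
        pielou_j = pielouEvenness(sub[, j]), f1 = est$f1, f2 = est$f2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Depth-layer comparison of richness
#'
#' One-way ANOVA of a diversity estimate on depth layer followed by Tukey's
#' HSD pairwise comparisons. Layers represented by a single sample are
#' excluded with a warning. With no between- or within-layer variation at
#' all the F statistic is reported as 0 with p = 1.
#'
#' @param estimates data.frame from [diversityTable()] (already restricted to
#'   one `subset_tag`).
#' @param metadata sample metadata with `sample_id` and `depth_m`.
#' @param response which column of `estimates` to compare (default
#'   `"chao1"`).
#' @return list with `f_statistic`, `df_between`, `df_within`, `p_value`,
#'   `pairwise` (Tukey HSD table as a data.frame) and the fitted `aov`.
#' @export
richnessAnova <- function(estimates, metadata, response = "chao1") {
  df <- merge(estimates, metadata[, c("sample_id", "depth_m")], by = "sample_id")
  df$layer <- factor(df$depth_m)
  sizes <- table(df$layer)
  if (any(sizes < 2)) {
    warning("excluding depth layer(s) with a single sample: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    df <- df[df$layer %in% names(sizes)[sizes >= 2], , drop = FALSE]
    df$layer <- droplevels(df$layer)
  }
  if (nlevels(df$layer) < 2)
    stop("at least two depth layers with >= 2 samples are required")
  df$y <- df[[response]]
  if (stats::var(df$y) == 0) {
    return(list(f_statistic = 0, df_between = nlevels(df$layer) - 1L,
                df_within = nrow(df) - nlevels(df$layer), p_value = 1,
                pairwise = NULL, fit = NULL))
  }
  fit <- stats::aov(y ~ layer, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$layer
  pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                         p_adjusted = tk[, "p adj"], row.names = NULL)
  list(f_statistic = tab["layer", "F value"],
       df_between = tab["layer", "Df"],
       df_within = tab["Residuals", "Df"],
       p_value = tab["layer", "Pr(>F)"],
       pairwise = pairwise, fit = fit)
}
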