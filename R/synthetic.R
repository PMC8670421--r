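# Synthetic stratified-community metatranscriptome generator.
#
# Emulates the sampling design of a two-season, five-depth fjord profile with
# biological duplicates: a roster of prokaryotic orders whose transcriptional
# activity follows logistic depth profiles (surface vs deep specialists), a
# per-taxon allocation of transcription to gene systems (CAZyme, peptidase,
# transporter, marker genes, everything else) whose CAZyme/PEP log ratio
# follows a programmed linear trajectory over depth, replicate-level
# overdispersion through a Dirichlet-multinomial draw, lognormal library
# sizes, depth-shaped environmental covariates, and raw multi-tool
# functional-prediction tables for the annotation stage. Every generated
# dataset carries its own ground truth for parameter-recovery testing.

#' Synthetic community configuration
#'
#' See [syntheticConfig()] for construction and slot defaults.
#'
#' @name SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig", representation(
  taxa = "data.frame",
  orfs_per_taxon = "integer",
  depths_m = "numeric",
  months = "character",
  replicates = "integer",
  library_size_mean = "numeric",
  library_size_sdlog = "numeric",
  concentration = "numeric",
  marker_folds = "numeric",
  orf_length_bp = "integer",
  within_system_decay = "numeric",
  cazyme_active_fraction_surface = "numeric",
  surface_max_depth_m = "numeric",
  euk_share = "numeric",
  rrna_share = "numeric",
  env = "list",
  annotation = "list"
))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  tx <- object@taxa
  need <- c("order", "domain", "phylum", "class", "base_activity",
            "depth_midpoint_m", "depth_slope", "activity_floor",
            "sept_multiplier", "frac_tp", "frac_marker", "frac_other",
            "logratio_intercept", "logratio_slope")
  miss <- setdiff(need, colnames(tx))
  if (length(miss)) msg <- c(msg, paste("taxa table missing:", paste(miss, collapse = ", ")))
  else {
    rest <- tx$frac_tp + tx$frac_marker + tx$frac_other
    if (any(tx$frac_tp < 0 | tx$frac_marker < 0 | tx$frac_other < 0))
      msg <- c(msg, "gene-system fractions must be >= 0")
    if (any(rest >= 1 - 1e-9))
      msg <- c(msg, "frac_tp + frac_marker + frac_other must leave room for CAZyme+PEP")
    if (any(tx$base_activity <= 0)) msg <- c(msg, "base_activity must be > 0")
  }
  if (nrow(tx) < 1) msg <- c(msg, "at least one taxon is required")
  if (length(object@depths_m) < 1 || any(object@depths_m <= 0))
    msg <- c(msg, "depths_m must be positive")
  if (object@replicates < 1) msg <- c(msg, "replicates must be >= 1")
  if (!(object@concentration > 0)) msg <- c(msg, "concentration (dispersion) must be > 0")
  if (object@library_size_sdlog < 0) msg <- c(msg, "library_size_sdlog must be >= 0")
  if (!all(c("amoA", "hcd") %in% names(object@marker_folds)))
    msg <- c(msg, "marker_folds needs named entries 'amoA' and 'hcd'")
  if (object@cazyme_active_fraction_surface <= 0 ||
      object@cazyme_active_fraction_surface > 1)
    msg <- c(msg, "cazyme_active_fraction_surface must be in (0, 1]")
  if (object@euk_share + object@rrna_share >= 1)
    msg <- c(msg, "contaminant shares must sum to < 1")
  if (length(msg)) msg else TRUE
})

#' Default roster of focal prokaryotic orders
#'
#' Nine orders spanning surface specialists (e.g. *Synechococcales*,
#' *Flavobacteriales*, *Cellvibrionales*), depth specialists (the
#' ammonia-oxidizing *Nitrosopumilales*, *Planctomycetales*, *Nitrospinales*,
#' *Alteromonadales*) and a depth-stable clade (*Pelagibacterales*). Columns
#' define, per order: logistic depth-activity parameters (`base_activity`,
#' `depth_midpoint_m`, `depth_slope` per metre -- positive slope means
#' activity rises with depth -- and `activity_floor`, the residual activity
#' fraction outside the taxon's preferred layer), a September activity
#' multiplier, the fixed fractions of the taxon's transcription allocated to
#' transporters, marker genes and unannotated ORFs (the remainder is split
#' between CAZymes and peptidases), and the programmed CAZyme/PEP log2-ratio
#' trajectory `logratio_intercept + logratio_slope * depth_m`.
#'
#' @return data.frame with one row per order.
#' @export
defaultTaxonProfiles <- function() {
  data.frame(
    order = c("Nitrosopumilales", "Pelagibacterales", "Rhodobacterales",
              "Flavobacteriales", "Cellvibrionales", "Alteromonadales",
              "Synechococcales", "Planctomycetales", "Nitrospinales"),
    domain = c("Archaea", rep("Bacteria", 8)),
    phylum = c("Thaumarchaeota", "Proteobacteria", "Proteobacteria",
               "Bacteroidetes", "Proteobacteria", "Proteobacteria",
               "Cyanobacteria", "Planctomycetes", "Nitrospinae"),
    class = c("Nitrososphaeria", "Alphaproteobacteria", "Alphaproteobacteria",
              "Flavobacteriia", "Gammaproteobacteria", "Gammaproteobacteria",
              "Cyanophyceae", "Planctomycetia", "Nitrospinia"),
    base_activity    = c(3.0, 1.2, 1.0, 1.0, 0.8, 0.7, 1.5, 0.5, 0.4),
    depth_midpoint_m = c(30,  50,  35,  30,  30,  60,  20,  60,  60),
    depth_slope      = c(0.15, 0, -0.08, -0.10, -0.10, 0.06, -0.20, 0.10, 0.10),
    activity_floor   = c(0.05, 0.10, 0.10, 0.10, 0.10, 0.15, 0.05, 0.15, 0.15),
    sept_multiplier  = c(1.0, 1.0, 1.5, 2.0, 0.7, 1.0, 0.5, 1.0, 1.0),
    frac_tp     = c(0.50, 0.45, 0.30, 0.20, 0.20, 0.35, 0.35, 0.25, 0.30),
    frac_marker = c(0.08, 0,    0,    0,    0,    0,    0,    0,    0),
    frac_other  = c(0.40, 0.35, 0.40, 0.40, 0.40, 0.35, 0.45, 0.45, 0.45),
    logratio_intercept = c(0.0, -0.4, 0.9, 1.3, 1.6, -0.7, 0.6, 0.4, 0.1),
    logratio_slope = c(0.0, -0.002, -0.022, -0.030, -0.012, -0.010,
                       -0.026, -0.016, -0.011)
  )
}

#' Build a synthetic community configuration
#'
#' Defaults describe the study conditions the generator emulates: nine focal
#' orders, depths 5/15/50/75/100 m sampled in July and September with two
#' biological replicates, mean library size 2e5 reads, Dirichlet-multinomial
#' concentration 5000 (moderate replicate scatter: coefficient of variation
#' of roughly 5% for a mid-abundance order), and marker-gene transcription
#' folds amoA:radA = 4 and hcd:radA = 3 relative to the single-copy reference
#' radA in the archaeal order.
#'
#' @param taxa taxon profile table, see [defaultTaxonProfiles()].
#' @param orfs_per_taxon ORFs simulated per order (8 CAZyme, 8 peptidase,
#'   10 transporter, remainder unannotated; marker-gene orders additionally
#'   carry radA/amoA/hcd ORFs and an amt transporter ORF).
#' @param depths_m,months,replicates sampling design.
#' @param library_size_mean,library_size_sdlog lognormal library-size model.
#' @param concentration Dirichlet concentration governing replicate-level
#'   overdispersion; `Inf` disables it (pure multinomial sampling).
#' @param marker_folds named vector of marker:radA transcription folds.
#' @param orf_length_bp constant ORF length in bp.
#' @param within_system_decay geometric decay of within-system ORF weights.
#' @param cazyme_active_fraction_surface fraction of each order's CAZyme ORFs
#'   transcribed at depths `<= surface_max_depth_m`; values < 1 depress
#'   expressed CAZyme richness in the surface layer.
#' @param surface_max_depth_m boundary of the "surface" layer in metres.
#' @param euk_share,rrna_share library fractions allotted to eukaryotic and
#'   rRNA-overlap contaminant ORFs (exercised by the input filters).
#' @param env list of environmental-generator options: `noise_scale`
#'   (multiplier on covariate noise; 0 gives deterministic profiles),
#'   `duplicate_variable` (add a perfectly collinear copy of temperature),
#'   `detection_limit_nh4` (censoring threshold in uM).
#' @param annotation list of prediction-table options: `tool_prob`,
#'   `conflict_rate`, `two_domain_rate`, `unmapped_rate`.
#' @return A validated [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(taxa = defaultTaxonProfiles(),
                            orfs_per_taxon = 40L,
                            depths_m = c(5, 15, 50, 75, 100),
                            months = c("July", "September"),
                            replicates = 2L,
                            library_size_mean = 2e5,
                            library_size_sdlog = 0.15,
                            concentration = 5000,
                            marker_folds = c(amoA = 4, hcd = 3),
                            orf_length_bp = 1000L,
                            within_system_decay = 0.8,
                            cazyme_active_fraction_surface = 1,
                            surface_max_depth_m = 25,
                            euk_share = 0.03,
                            rrna_share = 0.01,
                            env = list(),
                            annotation = list()) {
  env <- utils::modifyList(
    list(noise_scale = 1, duplicate_variable = FALSE, detection_limit_nh4 = 0.2),
    env)
  annotation <- utils::modifyList(
    list(tool_prob = 0.75, conflict_rate = 0.05, two_domain_rate = 0.2,
         unmapped_rate = 0, hits_cap = 100),
    annotation)
  new("SyntheticConfig",
      taxa = taxa,
      orfs_per_taxon = as.integer(orfs_per_taxon),
      depths_m = depths_m,
      months = months,
      replicates = as.integer(replicates),
      library_size_mean = library_size_mean,
      library_size_sdlog = library_size_sdlog,
      concentration = concentration,
      marker_folds = marker_folds,
      orf_length_bp = as.integer(orf_length_bp),
      within_system_decay = within_system_decay,
      cazyme_active_fraction_surface = cazyme_active_fraction_surface,
      surface_max_depth_m = surface_max_depth_m,
      euk_share = euk_share,
      rrna_share = rrna_share,
      env = env,
      annotation = annotation)
}

.CAZY_POOL <- c("GH13", "GH16", "GH19", "GH23", "GH109", "GT2", "GT4",
                "GT35", "CBM5", "CBM50", "G0")
.PEP_PFAM_POOL <- c("PF00082", "PF01433", "PF00112", "PF00246", "PF01435",
                    "PF05193")
.TP_POOL <- data.frame(
  profile = c("PF00005", "PF07715", "PF01036", "PF03480", "PF00474",
              "PF02447", "PF04295"),
  tcdb_family = c("ABC", "OMR", "MR", "TRAP-T", "SSS", "OprB", "TTT"),
  tc_number = c("3.A.1", "1.B.14", "3.E.1", "2.A.56", "2.A.21", "1.B.19",
                "2.A.80"),
  stringsAsFactors = FALSE
)

#' Default Pfam to MEROPS peptidase-family map
#'
#' A small mapping table in the shape consumed by [classifyPeptidases()].
#' The family content is synthetic (fixture-scale), not a MEROPS export.
#'
#' @return data.frame with columns `pfam`, `merops_family`.
#' @export
meropsMapDefault <- function() {
  data.frame(pfam = .PEP_PFAM_POOL,
             merops_family = c("S08", "M01", "C01", "M14", "M48", "M16"),
             stringsAsFactors = FALSE)
}

# taxon activity at one depth/month (unnormalized)
.taxonActivity <- function(taxa, depth, month, months) {
  a <- taxa$base_activity *
    (taxa$activity_floor + (1 - taxa$activity_floor) *
       stats::plogis(taxa$depth_slope * (depth - taxa$depth_midpoint_m)))
  if (length(months) > 1 && month != months[1]) a <- a * taxa$sept_multiplier
  a
}

# per-taxon system fractions at one depth; CAZ/PEP split follows the
# programmed log2-ratio trajectory
.systemFractions <- function(tx, depth) {
  s <- 1 - tx$frac_tp - tx$frac_marker - tx$frac_other
  r <- 2^(tx$logratio_intercept + tx$logratio_slope * depth)
  c(CAZyme = s * r / (1 + r), PEP = s / (1 + r),
    TP = tx$frac_tp, marker = tx$frac_marker, other = tx$frac_other)
}

.geomWeights <- function(k, decay) {
  if (k == 0L) return(numeric())
  w <- decay^(seq_len(k) - 1)
  w / sum(w)
}

# deterministic per-ORF layout for one configuration
.orfLayout <- function(config) {
  tx <- config@taxa
  n <- config@orfs_per_taxon
  n_caz <- max(2L, round(0.2 * n)); n_pep <- max(2L, round(0.2 * n))
  n_tp <- max(2L, round(0.25 * n))
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    ord <- tx$order[i]
    has_marker <- tx$frac_marker[i] > 0
    n_marker <- if (has_marker) 3L else 0L
    n_other <- max(1L, n - n_caz - n_pep - n_tp - n_marker)
    sys <- c(rep("CAZyme", n_caz), rep("PEP", n_pep), rep("TP", n_tp),
             if (has_marker) rep("marker", 3L), rep("other", n_other))
    fam <- c(.CAZY_POOL[(seq_len(n_caz) - 1L) %% length(.CAZY_POOL) + 1L],
             .PEP_PFAM_POOL[(seq_len(n_pep) - 1L) %% length(.PEP_PFAM_POOL) + 1L],
             .TP_POOL$profile[(seq_len(n_tp) - 1L) %% nrow(.TP_POOL) + 1L],
             if (has_marker) c("radA", "amoA", "hcd"), rep(NA, n_other))
    marker <- rep(NA_character_, length(sys))
    if (has_marker) {
      marker[sys == "marker"] <- c("radA", "amoA", "hcd")
      marker[which(sys == "TP")[1]] <- "amt"      # dual TP + marker amt ORF
      fam[which(sys == "TP")[1]] <- "PF00909"     # Amt profile (override case)
    }
    rows[[i]] <- data.frame(
      orf_id = sprintf("%s_%s_%02d", ord, tolower(substr(sys, 1, 3)),
                       stats::ave(seq_along(sys), sys, FUN = seq_along)),
      taxon = ord, domain = tx$domain[i], phylum = tx$phylum[i],
      class = tx$class[i], order = ord,
      family = .UNCLASSIFIED, genus = .UNCLASSIFIED,
      is_rrna_overlap = FALSE, system = sys, true_family = fam,
      marker_gene = marker, stringsAsFactors = FALSE)
  }
  prok <- do.call(rbind, rows)
  contam <- NULL
  if (config@euk_share > 0 || config@rrna_share > 0) {
    n_euk <- if (config@euk_share > 0) 10L else 0L
    n_rrna <- if (config@rrna_share > 0) 6L else 0L
    contam <- data.frame(
      orf_id = c(sprintf("Eukaryota_orf_%02d", seq_len(n_euk)),
                 sprintf("rrna_overlap_orf_%02d", seq_len(n_rrna))),
      taxon = c(rep("Eukaryota", n_euk), rep("rrna", n_rrna)),
      domain = c(rep("Eukaryota", n_euk), rep("Bacteria", n_rrna)),
      phylum = .UNCLASSIFIED, class = .UNCLASSIFIED, order = .UNCLASSIFIED,
      family = .UNCLASSIFIED, genus = .UNCLASSIFIED,
      is_rrna_overlap = c(rep(FALSE, n_euk), rep(TRUE, n_rrna)),
      system = "other", true_family = NA, marker_gene = NA_character_,
      stringsAsFactors = FALSE)
  }
  rbind(prok, contam)
}

# prokaryote-conditional expected ORF probabilities for one depth/month
.prokProbs <- function(config, layout, depth, month) {
  tx <- config@taxa
  act <- .taxonActivity(tx, depth, month, config@months)
  share <- act / sum(act)
  p <- numeric(nrow(layout))
  surface <- depth <= config@surface_max_depth_m
  for (i in seq_len(nrow(tx))) {
    ord <- tx$order[i]
    fr <- .systemFractions(tx[i, ], depth)
    for (sys in names(fr)) {
      idx <- which(layout$taxon == ord & layout$system == sys)
      if (!length(idx)) next
      if (sys == "marker") {
        mk <- layout$marker_gene[idx]
        folds <- c(radA = 1, config@marker_folds)[mk]
        w <- folds / sum(folds)
      } else if (sys == "CAZyme" && surface &&
                 config@cazyme_active_fraction_surface < 1) {
        k <- length(idx)
        k_on <- max(1L, ceiling(config@cazyme_active_fraction_surface * k))
        w <- c(.geomWeights(k_on, config@within_system_decay),
               rep(0, k - k_on))
      } else {
        w <- .geomWeights(length(idx), config@within_system_decay)
      }
      p[idx] <- share[i] * fr[[sys]] * w
    }
  }
  p / sum(p)
}

.sampleGrid <- function(config) {
  g <- expand.grid(replicate = seq_len(config@replicates),
                   depth_m = config@depths_m, month = config@months,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("month", "depth_m", "replicate")]
  g$sample_id <- sprintf("%s_%03dm_r%d", substr(g$month, 1, 3),
                         as.integer(g$depth_m), g$replicate)
  g
}

# environmental covariates as smooth functions of depth and month plus noise;
# shapes: temperature/oxygen/DOC decreasing, nitrate/phosphate/silicate
# increasing, Chl a with a subsurface maximum in July and a surface maximum
# in September, ammonium censored below the detection limit in July
.envDraw <- function(config) {
  g <- .sampleGrid(config)
  d <- g$depth_m
  july <- g$month == config@months[1]
  mean_of <- list(
    temperature_C = ifelse(july, 8 + 7.5 * stats::plogis(-(d - 32) / 7),
                           8 + 8 * stats::plogis(-(d - 35) / 6)),
    salinity_PSU = ifelse(july, 28 + 8 * stats::plogis((d - 40) / 15),
                          22 + 14 * stats::plogis((d - 35) / 12)),
    oxygen_ml_per_l = 5 - 3.5 * stats::plogis((d - 45) / 15),
    chla_ug_per_l = ifelse(july,
                           0.1 + 0.4 * exp(-(d - 5)^2 / 128) +
                             0.7 * exp(-(d - 15)^2 / 50),
                           0.15 + 2.65 * exp(-((d - 2) / 12)^2)),
    doc_uM = 170 - 110 * stats::plogis((d - 35) / 20),
    nh4_uM = ifelse(july, 0.05, 0.25 + 0.9 * exp(-d / 25)),
    no3no2_uM = 0.5 + 39.5 * stats::plogis((d - 40) / 15),
    po4_uM = 0.1 + 4.4 * stats::plogis((d - 45) / 18),
    sio2_uM = 2 + 28 * stats::plogis((d - 40) / 18),
    totN_uM = rep(35, length(d)),
    totP_uM = 1.5 + 0.5 * stats::plogis((d - 50) / 20)
  )
  noise_sd <- c(temperature_C = 0.15, salinity_PSU = 0.3, oxygen_ml_per_l = 0.1,
                chla_ug_per_l = 0.04, doc_uM = 3, nh4_uM = 0.02, no3no2_uM = 0.8,
                po4_uM = 0.08, sio2_uM = 0.6, totN_uM = 0.8, totP_uM = 0.05)
  ns <- config@env$noise_scale
  out <- g
  for (v in names(mean_of)) {
    val <- mean_of[[v]] + stats::rnorm(length(d), 0, noise_sd[[v]] * ns)
    out[[v]] <- pmax(val, 0.001)
  }
  lim <- config@env$detection_limit_nh4
  out$nh4_below_detection <- out$nh4_uM < lim
  out$nh4_uM[out$nh4_below_detection] <- NA_real_
  if (isTRUE(config@env$duplicate_variable))
    out$temperature_dup_C <- out$temperature_C
  out[, c("sample_id", setdiff(colnames(out), "sample_id"))]
}

#' Generate sample metadata with depth-shaped environmental covariates
#'
#' Covariates follow the canonical stratified water-column shapes
#' (temperature, oxygen and DOC decreasing with depth; nitrate+nitrite,
#' phosphate and silicate increasing; Chl a peaked at a subsurface maximum in
#' July and at the surface in September) plus Gaussian noise. July ammonium
#' falls below the 0.2 uM detection limit and is reported as `NA` with
#' `nh4_below_detection = TRUE` for downstream substitution (see
#' [imputeBelowDetection()]). Several covariates are depth-collinear by
#' construction, which exercises correlation/VIF-based variable selection.
#'
#' @param config A [SyntheticConfig-class].
#' @param seed integer seed.
#' @param depths_m,months optional overrides of the config design.
#' @return data.frame, one row per sample.
#' @export
generateEnvironment <- function(config, seed, depths_m = NULL, months = NULL) {
  if (!is.null(depths_m)) config@depths_m <- depths_m
  if (!is.null(months)) config@months <- months
  validObject(config)
  withSeed(seed, .envDraw(config))
}

#' Generate a stratified-community metatranscriptome dataset
#'
#' Draws, per sample, a library size from a lognormal model and ORF counts
#' from a Dirichlet-multinomial whose expectation is the product of taxon
#' depth-activity, gene-system allocation and within-system ORF weights.
#' Identical `(config, seed)` pairs give identical output.
#'
#' @param config A [SyntheticConfig-class].
#' @param seed integer seed.
#' @return list with elements `experiment` (an [OrfExperiment-class] with
#'   taxonomy and metadata attached, plus generator columns `system`,
#'   `true_family`, `marker_gene` in `rowData`), `taxonomy`, `metadata`
#'   (plain data.frames) and `truth` (a `SyntheticTruth` list: per-stratum
#'   expected taxon shares in percent, programmed gene-system log2 ratios
#'   incl. the community-level aggregate, marker folds, the per-sample
#'   prokaryote-conditional ORF probabilities, and drawn library sizes).
#' @export
generateDataset <- function(config, seed) {
  validObject(config)
  layout <- .orfLayout(config)
  grid <- .sampleGrid(config)
  prok <- !(layout$taxon %in% c("Eukaryota", "rrna"))
  withSeed(seed, {
    env <- .envDraw(config)
    # expected probabilities per stratum (shared by replicates)
    strata <- unique(grid[, c("month", "depth_m")])
    pm <- matrix(0, nrow(layout), nrow(grid),
                 dimnames = list(layout$orf_id, grid$sample_id))
    for (k in seq_len(nrow(strata))) {
      p_prok <- .prokProbs(config, layout[prok, ], strata$depth_m[k],
                           strata$month[k])
      p <- numeric(nrow(layout))
      p[prok] <- p_prok * (1 - config@euk_share - config@rrna_share)
      if (any(!prok)) {
        euk <- layout$taxon == "Eukaryota"; rrna <- layout$taxon == "rrna"
        if (any(euk)) p[euk] <- config@euk_share *
            .geomWeights(sum(euk), config@within_system_decay)
        if (any(rrna)) p[rrna] <- config@rrna_share *
            .geomWeights(sum(rrna), config@within_system_decay)
      }
      cols <- which(grid$month == strata$month[k] &
                      grid$depth_m == strata$depth_m[k])
      pm[, cols] <- p
    }
    mu <- log(config@library_size_mean) - config@library_size_sdlog^2 / 2
    lib <- round(stats::rlnorm(nrow(grid), mu, config@library_size_sdlog))
    cnt <- matrix(0L, nrow(layout), nrow(grid),
                  dimnames = list(layout$orf_id, grid$sample_id))
    for (j in seq_len(nrow(grid))) {
      p <- pm[, j]
      q <- if (is.finite(config@concentration)) {
        gq <- stats::rgamma(length(p), shape = config@concentration * p)
        if (sum(gq) == 0) p else gq / sum(gq)
      } else p
      cnt[, j] <- stats::rmultinom(1, size = lib[j], prob = q)[, 1]
    }
    taxdf <- layout[, c("orf_id", .TAX_RANKS, "is_rrna_overlap")]
    oe <- OrfExperiment(cnt,
                        length_bp = rep(config@orf_length_bp, nrow(layout)),
                        taxonomy = taxdf, metadata = env)
    rowData(oe)$taxon <- layout$taxon
    rowData(oe)$system <- layout$system
    rowData(oe)$true_family <- layout$true_family
    rowData(oe)$marker_gene <- layout$marker_gene
    truth <- .buildTruth(config, layout[prok, ], grid, pm[prok, , drop = FALSE],
                         lib)
    list(experiment = oe, taxonomy = taxdf, metadata = env, truth = truth)
  })
}

.buildTruth <- function(config, layout, grid, pm_prok, lib) {
  tx <- config@taxa
  strata <- unique(grid[, c("month", "depth_m")])
  shares <- list(); ratios <- list()
  for (k in seq_len(nrow(strata))) {
    d <- strata$depth_m[k]; mo <- strata$month[k]
    act <- .taxonActivity(tx, d, mo, config@months)
    sh <- act / sum(act)
    shares[[k]] <- data.frame(taxon = tx$order, depth_m = d, month = mo,
                              expected_pct = 100 * sh)
    fr <- t(vapply(seq_len(nrow(tx)),
                   function(i) .systemFractions(tx[i, ], d), numeric(5)))
    per_tax <- data.frame(
      taxon = rep(tx$order, each = 3), depth_m = d, month = mo,
      ratio_type = rep(c("CAZyme/PEP", "CAZyme/TP", "PEP/TP"), nrow(tx)),
      true_log2 = as.vector(t(cbind(
        log2(fr[, "CAZyme"] / fr[, "PEP"]),
        log2(fr[, "CAZyme"] / fr[, "TP"]),
        log2(fr[, "PEP"] / fr[, "TP"])))))
    comm <- colSums(sh * fr[, c("CAZyme", "PEP", "TP"), drop = FALSE])
    ratios[[k]] <- rbind(per_tax, data.frame(
      taxon = "(community)", depth_m = d, month = mo,
      ratio_type = c("CAZyme/PEP", "CAZyme/TP", "PEP/TP"),
      true_log2 = c(log2(comm["CAZyme"] / comm["PEP"]),
                    log2(comm["CAZyme"] / comm["TP"]),
                    log2(comm["PEP"] / comm["TP"]))))
  }
  # renormalize prokaryote-conditional sample probabilities
  pm_cond <- sweep(pm_prok, 2, colSums(pm_prok), "/")
  structure(list(taxon_share = do.call(rbind, shares),
                 log_ratios = do.call(rbind, ratios),
                 marker_folds = config@marker_folds,
                 sample_probs = pm_cond,
                 library_sizes = stats::setNames(lib, grid$sample_id)),
            class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d taxon-strata shares, %d programmed log ratios, %d samples\n",
              nrow(x$taxon_share), nrow(x$log_ratios), ncol(x$sample_probs)))
  invisible(x)
}

#' Generate raw multi-tool CAZyme prediction records
#'
#' For each CAZyme-bearing ORF, emits one record per predicting tool
#' (alignment/"diamond", profile/"hmmer", peptide-pattern/"hotpep") with
#' tool-appropriate quality metrics drawn above the consensus-filter
#' thresholds by default. Optional fixed boundary records sit exactly at
#' identity 50.0, coverage 0.5 and 10 hits; optional conflict ORFs make two
#' tools disagree on the family.
#'
#' @param annotations data.frame with columns `orf_id`, `system`,
#'   `true_family` (e.g. `rowData` of a generated experiment, or
#'   `as.data.frame(rowData(x))` with an added `orf_id`).
#' @param config A [SyntheticConfig-class] (annotation options are read from
#'   its `annotation` list).
#' @param seed integer seed.
#' @param boundary_cases add the six fixed boundary/below-boundary records.
#' @return data.frame with columns `orf_id`, `tool`, `family`,
#'   `percent_identity`, `coverage`, `hits`, `frequency`.
#' @export
generateCazymePredictions <- function(annotations, config, seed,
                                      boundary_cases = FALSE) {
  ann <- config@annotation
  caz <- annotations[annotations$system == "CAZyme", , drop = FALSE]
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(caz))) {
      present <- stats::runif(3) < ann$tool_prob
      if (!any(present)) present[1] <- TRUE
      tools <- c("diamond", "hmmer", "hotpep")[present]
      fam <- rep(caz$true_family[i], length(tools))
      if (length(tools) >= 2 && stats::runif(1) < ann$conflict_rate) {
        alt <- setdiff(.CAZY_POOL, caz$true_family[i])
        fam[length(fam)] <- alt[sample.int(length(alt), 1)]
      }
      rows[[i]] <- data.frame(
        orf_id = caz$orf_id[i], tool = tools, family = fam,
        percent_identity = ifelse(tools == "diamond",
                                  pmin(99, pmax(52, stats::rnorm(length(tools), 75, 8))), NA),
        coverage = ifelse(tools == "hmmer",
                          pmin(0.99, pmax(0.55, stats::rnorm(length(tools), 0.8, 0.1))), NA),
        hits = ifelse(tools == "hotpep", 10L + stats::rpois(length(tools), 15), NA),
        frequency = ifelse(tools == "hotpep",
                           round(stats::runif(length(tools), 0.05, 0.95), 3), NA),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(rows, list(NULL)))
    if (isTRUE(boundary_cases)) {
      b <- data.frame(
        orf_id = c("boundary_id_at", "boundary_id_below", "boundary_cov_at",
                   "boundary_cov_below", "boundary_hits_at", "boundary_hits_below"),
        tool = c("diamond", "diamond", "hmmer", "hmmer", "hotpep", "hotpep"),
        family = "GH16",
        percent_identity = c(50, 49.9, NA, NA, NA, NA),
        coverage = c(NA, NA, 0.5, 0.49, NA, NA),
        hits = c(NA, NA, NA, NA, 10L, 9L),
        frequency = c(NA, NA, NA, NA, 0.5, 0.5),
        stringsAsFactors = FALSE)
      out <- rbind(out, b)
    }
    if (is.null(out))
      out <- data.frame(orf_id = character(), tool = character(),
                        family = character(), percent_identity = numeric(),
                        coverage = numeric(), hits = integer(),
                        frequency = numeric())
    rownames(out) <- NULL
    out
  })
}

#' Generate the full set of raw functional-prediction tables
#'
#' Produces, from a generated experiment, the four annotation inputs the
#' pipeline consumes: multi-tool CAZyme predictions, peptidase profile hits
#' (Pfam accessions with bit scores; a configurable fraction unmapped),
#' transporter profile hits (including the deliberately mis-assigned Amt
#' profile PF00909 that the shipped override table corrects), and marker-gene
#' hits with gathering-score pass flags (plus failing decoys).
#'
#' @param x An [OrfExperiment-class] from [generateDataset()].
#' @param config A [SyntheticConfig-class].
#' @param seed integer seed.
#' @return list with `cazyme_predictions`, `pep_hits`, `tp_hits`,
#'   `marker_hits` and `merops_map` data.frames.
#' @export
generateFunctionalHits <- function(x, config, seed) {
  rd <- as.data.frame(rowData(x))
  rd$orf_id <- rownames(x)
  ann <- config@annotation
  caz_pred <- generateCazymePredictions(rd, config, seed)
  withSeed(seed + 1L, {
    pep <- rd[rd$system == "PEP", , drop = FALSE]
    pep_rows <- data.frame(orf_id = pep$orf_id, pfam = pep$true_family,
                           score = round(stats::runif(nrow(pep), 40, 120), 1),
                           stringsAsFactors = FALSE)
    two <- stats::runif(nrow(pep)) < ann$two_domain_rate
    if (any(two)) {
      extra <- pep_rows[two, , drop = FALSE]
      extra$pfam <- .PEP_PFAM_POOL[(match(extra$pfam, .PEP_PFAM_POOL) %% length(.PEP_PFAM_POOL)) + 1L]
      extra$score <- round(extra$score * stats::runif(nrow(extra), 0.3, 0.8), 1)
      pep_rows <- rbind(pep_rows, extra)
    }
    if (ann$unmapped_rate > 0) {
      um <- stats::runif(nrow(pep_rows)) < ann$unmapped_rate
      pep_rows$pfam[um] <- "PF99999"
    }
    tp <- rd[rd$system == "TP", , drop = FALSE]
    amt <- !is.na(tp$marker_gene) & tp$marker_gene == "amt"
    pool_idx <- match(tp$true_family, .TP_POOL$profile)
    tp_rows <- data.frame(
      orf_id = tp$orf_id,
      profile = tp$true_family,
      tcdb_family = ifelse(amt, "MIT", .TP_POOL$tcdb_family[pool_idx]),
      tc_number = ifelse(amt, "1.A.35", .TP_POOL$tc_number[pool_idx]),
      score = round(stats::runif(nrow(tp), 50, 200), 1),
      stringsAsFactors = FALSE)
    tp_rows$tcdb_subclass <- sub("^([0-9]+\\.[A-Za-z]).*$", "\\1",
                                 tp_rows$tc_number)
    mk <- rd[!is.na(rd$marker_gene) & rd$marker_gene != "amt", , drop = FALSE]
    decoys <- utils::head(rd[rd$system == "other" & rd$domain == "Archaea", ], 2)
    marker_rows <- rbind(
      data.frame(orf_id = mk$orf_id, marker = mk$marker_gene,
                 gathering_pass = ifelse(mk$marker_gene == "hcd", NA, TRUE),
                 stringsAsFactors = FALSE),
      data.frame(orf_id = tp$orf_id[amt], marker = rep("amt", sum(amt)),
                 gathering_pass = rep(TRUE, sum(amt))),
      if (nrow(decoys))
        data.frame(orf_id = decoys$orf_id, marker = "amoA",
                   gathering_pass = FALSE))
    rownames(marker_rows) <- NULL
    list(cazyme_predictions = caz_pred, pep_hits = pep_rows,
         tp_hits = tp_rows, marker_hits = marker_rows,
         merops_map = meropsMapDefault())
  })
}
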