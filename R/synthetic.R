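#' Configuration for the perturbation-experiment simulator
#'
#' Describes a small bead-array style experiment: two conditions (control
#' vs perturbation) at each of several time points, a handful of replicates,
#' intensity-dependent noise, all-absent background probes, and a planted set
#' of truly differential genes. The defaults emulate a 13k-probe array with 2
#' replicates per condition x time, ~600 genes responding at the late time
#' point of which ~220 already respond early.
#'
#' @param n_probes total number of probes on the array.
#' @param n_replicates replicates per condition x time point.
#' @param time_points character vector of time-point labels, earliest first.
#'   The full planted set responds at the last time point; the early subset
#'   responds at every time point.
#' @param n_planted_48 number of truly differential genes at the last time
#'   point.
#' @param n_planted_24 number differential at the earlier time point(s); a
#'   subset of the late set.
#' @param lfc_range length-2 numeric, range of |log2 effect| magnitudes.
#' @param frac_up fraction of planted genes that are up-regulated.
#' @param baseline_log_mean,baseline_log_sd per-probe baseline intensity on
#'   the log2 scale: baseline ~ Normal(mean, sd).
#' @param additive_sd standard deviation of additive (background) noise on
#'   the raw intensity scale.
#' @param multiplicative_cv coefficient of variation of multiplicative noise.
#' @param frac_all_absent fraction of probes that are pure background,
#'   flagged "absent" in every sample.
#' @param seed integer RNG seed; the same config is bit-reproducible.
#' @return a validated `perturbation_sim_config` list.
#' @export
perturbation_sim_config <- function(n_probes = 13000L, n_replicates = 2L,
                                    time_points = c("24h", "48h"),
                                    n_planted_48 = 600L, n_planted_24 = 220L,
                                    lfc_range = c(1.2, 3.0), frac_up = 0.4,
                                    baseline_log_mean = 7.0, baseline_log_sd = 1.5,
                                    additive_sd = 30.0, multiplicative_cv = 0.12,
                                    frac_all_absent = 0.07, seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_replicates = as.integer(n_replicates),
              time_points = as.character(time_points),
              n_planted_48 = as.integer(n_planted_48),
              n_planted_24 = as.integer(n_planted_24),
              lfc_range = as.numeric(lfc_range), frac_up = frac_up,
              baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
              additive_sd = additive_sd, multiplicative_cv = multiplicative_cv,
              frac_all_absent = frac_all_absent, seed = as.integer(seed))
  if (cfg$n_probes < 1L || cfg$n_replicates < 1L)
    stop("invalid config: n_probes and n_replicates must be positive")
  if (length(cfg$time_points) < 1L) stop("invalid config: need >= 1 time point")
  if (cfg$n_planted_24 > cfg$n_planted_48)
    stop("invalid config: n_planted_24 must not exceed n_planted_48")
  if (cfg$n_planted_48 > cfg$n_probes)
    stop("invalid config: n_planted_48 must not exceed n_probes")
  if (cfg$n_planted_48 < 0L || cfg$n_planted_24 < 0L)
    stop("invalid config: planted counts must be non-negative")
  if (length(cfg$lfc_range) != 2L || any(cfg$lfc_range <= 0) ||
      cfg$lfc_range[1L] > cfg$lfc_range[2L])
    stop("invalid config: lfc_range must be positive and non-decreasing")
  if (cfg$frac_up < 0 || cfg$frac_up > 1)
    stop("invalid config: frac_up must be in [0,1]")
  if (cfg$frac_all_absent < 0 || cfg$frac_all_absent >= 1)
    stop("invalid config: frac_all_absent must be in [0,1)")
  if (cfg$additive_sd < 0 || cfg$multiplicative_cv < 0)
    stop("invalid config: noise parameters must be non-negative")
  structure(cfg, class = "perturbation_sim_config")
}

#' Configuration for the cohort simulator
#'
#' Describes a skin-biopsy style cohort of ~75 samples partitioned into
#' molecular subsets, on a centered log-ratio scale, in which a supplied
#' signature is fully expressed in the two "diffuse" subsets and partially
#' (default 14% of signature genes) in the "inflammatory" subset.
#'
#' @param n_samples cohort size.
#' @param subset_proportions named numeric, fractions per subset label;
#'   must sum to 1. Sample counts are allocated by largest remainder.
#' @param signature_effect shift (log2 units) applied per signature gene in
#'   the enriched subsets, multiplied by the gene's signature direction.
#' @param inflammatory_concordant_frac fraction of covered signature genes
#'   also shifted in the "inflammatory" subset.
#' @param gene_noise_sd residual per-gene, per-sample noise SD.
#' @param platform_coverage fraction of signature genes present on the
#'   cohort platform.
#' @param n_background_genes non-signature genes on the simulated platform.
#' @param seed integer RNG seed.
#' @return a validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_samples = 75L,
                              subset_proportions = c(diffuse1 = 0.12, diffuse2 = 0.12,
                                                     inflammatory = 0.24, limited = 0.28,
                                                     "normal-like" = 0.24),
                              signature_effect = 1.0,
                              inflammatory_concordant_frac = 0.14,
                              gene_noise_sd = 0.6, platform_coverage = 0.85,
                              n_background_genes = 2000L, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              subset_proportions = subset_proportions,
              signature_effect = signature_effect,
              inflammatory_concordant_frac = inflammatory_concordant_frac,
              gene_noise_sd = gene_noise_sd, platform_coverage = platform_coverage,
              n_background_genes = as.integer(n_background_genes),
              seed = as.integer(seed))
  if (cfg$n_samples < 1L) stop("invalid config: n_samples must be positive")
  if (is.null(names(cfg$subset_proportions)) || any(!nzchar(names(cfg$subset_proportions))))
    stop("invalid config: subset_proportions must be named")
  if (abs(sum(cfg$subset_proportions) - 1) > 1e-9)
    stop("invalid config: subset_proportions must sum to 1")
  if (any(cfg$subset_proportions < 0))
    stop("invalid config: subset_proportions must be non-negative")
  if (cfg$inflammatory_concordant_frac < 0 || cfg$inflammatory_concordant_frac > 1)
    stop("invalid config: inflammatory_concordant_frac must be in [0,1]")
  if (cfg$platform_coverage <= 0 || cfg$platform_coverage > 1)
    stop("invalid config: platform_coverage must be in (0,1]")
  if (cfg$gene_noise_sd < 0) stop("invalid config: gene_noise_sd must be >= 0")
  if (cfg$signature_effect < 0) stop("invalid config: signature_effect must be >= 0")
  structure(cfg, class = "cohort_sim_config")
}

# deterministic largest-remainder allocation of n among proportions
largest_remainder <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)  # ties: earlier label wins
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Simulate a two-condition perturbation bead-array experiment
#'
#' Raw intensity model per probe and sample:
#' `x = 2^(baseline + effect) * (1 + e_m) + e_a`, `e_m ~ N(0, cv)`,
#' `e_a ~ N(0, additive_sd)`, clipped at 0 — an additive + multiplicative
#' error model whose variance grows with the squared mean, the situation the
#' generalized-log transform stabilizes. The planted effect is nonzero only
#' in perturbed samples of responding genes at their responding time points.
#' All-absent probes are pure background: `2 * additive_sd + e_a`, detection
#' flag `FALSE` in every sample.
#'
#' @param config a [perturbation_sim_config()].
#' @return list with `dataset` (an [expression_dataset()], scale `"linear"`,
#'   with detection calls and condition/time annotations) and `truth`
#'   (a `synthetic_truth` record: `planted_genes` data.frame with one
#'   `effect_<time>` column per time point, `absent_probes`, and the config).
#' @export
simulate_perturbation <- function(config) {
  stopifnot(inherits(config, "perturbation_sim_config"))
  withr::with_seed(config$seed, {
    ids <- sprintf("G%05d", seq_len(config$n_probes))
    n_absent <- round(config$frac_all_absent * config$n_probes)
    absent <- sort(sample(ids, n_absent))
    eligible <- setdiff(ids, absent)
    planted48 <- sort(sample(eligible, config$n_planted_48))
    planted24 <- sort(sample(planted48, config$n_planted_24))
    mag <- stats::runif(config$n_planted_48, config$lfc_range[1L], config$lfc_range[2L])
    n_up <- round(config$frac_up * config$n_planted_48)
    sgn <- rep(-1, config$n_planted_48)
    if (config$n_planted_48 > 0L)
      sgn[sample.int(config$n_planted_48, n_up)] <- 1
    effect48 <- mag * sgn

    tps <- config$time_points
    last_tp <- tps[length(tps)]
    # effect matrix: probes x time points (early set active at all tps)
    eff <- matrix(0, config$n_probes, length(tps),
                  dimnames = list(ids, tps))
    eff[planted48, last_tp] <- effect48
    for (tp in setdiff(tps, last_tp))
      eff[planted24, tp] <- effect48[match(planted24, planted48)]

    conds <- c("control", "perturbed")
    design <- expand.grid(replicate = seq_len(config$n_replicates),
                          condition = conds, time = tps,
                          stringsAsFactors = FALSE)
    sample_ids <- sprintf("%s_%s_r%d", design$condition, design$time,
                          design$replicate)
    baseline <- stats::rnorm(config$n_probes, config$baseline_log_mean,
                             config$baseline_log_sd)
    vals <- matrix(0, config$n_probes, nrow(design),
                   dimnames = list(ids, sample_ids))
    for (j in seq_len(nrow(design))) {
      mu_log <- baseline +
        if (design$condition[j] == "perturbed") eff[, design$time[j]] else 0
      mu <- 2^mu_log
      vals[, j] <- mu * (1 + stats::rnorm(config$n_probes, 0, config$multiplicative_cv)) +
        stats::rnorm(config$n_probes, 0, config$additive_sd)
    }
    # all-absent probes: pure background noise
    bg <- 2 * config$additive_sd
    if (n_absent > 0)
      vals[absent, ] <- bg + matrix(stats::rnorm(n_absent * nrow(design), 0,
                                                 config$additive_sd),
                                    n_absent, nrow(design))
    vals[vals < 0] <- 0
    detection <- matrix(TRUE, config$n_probes, nrow(design),
                        dimnames = dimnames(vals))
    detection[absent, ] <- FALSE

    ann <- data.frame(sample_id = sample_ids, condition = design$condition,
                      time = design$time, stringsAsFactors = FALSE)
    planted <- data.frame(gene = planted48, stringsAsFactors = FALSE)
    for (tp in tps) planted[[paste0("effect_", tp)]] <- eff[planted48, tp]
    truth <- structure(list(planted_genes = planted, absent_probes = absent,
                            config = config),
                       class = "synthetic_truth")
    list(dataset = expression_dataset(vals, scale = "linear",
                                      annotations = ann, detection = detection),
         truth = truth)
  })
}

#' Simulate an annotated cohort expressing a signature in specific subsets
#'
#' Generates a gene x sample matrix directly on a centered log-ratio scale
#' (as in preprocessed two-color cohort data — no VST or normalization step
#' is needed downstream). `round(platform_coverage * |signature|)` signature
#' genes are placed on the platform alongside background genes. In both
#' "diffuse" subsets every covered signature gene is shifted by
#' `signature_effect * direction`; in the "inflammatory" subset only a
#' planted concordant fraction of them is shifted; other subsets carry noise
#' only.
#'
#' @param signature a non-empty `gene_signature`.
#' @param config a [cohort_sim_config()].
#' @return list with `dataset` (scale `"log-ratio"`, subset annotations) and
#'   `truth` (`cohort_subsets` data.frame, `cohort_shifted_genes` list per
#'   subset, `covered_genes`, and the config).
#' @export
simulate_cohort <- function(signature, config) {
  stopifnot(inherits(signature, "gene_signature"), inherits(config, "cohort_sim_config"))
  if (nrow(signature$entries) == 0L) stop("signature is empty")
  withr::with_seed(config$seed, {
    sig_genes <- signature$entries$gene
    dir_num <- ifelse(signature$entries$direction == "up", 1, -1)
    names(dir_num) <- sig_genes
    n_cov <- round(config$platform_coverage * length(sig_genes))
    n_cov <- max(n_cov, 0L)
    covered <- sort(sample(sig_genes, n_cov))
    bg_genes <- sprintf("BG%05d", seq_len(config$n_background_genes))
    genes <- c(covered, bg_genes)

    labels <- names(config$subset_proportions)
    counts <- largest_remainder(config$n_samples, config$subset_proportions)
    subset <- sample(rep(labels, counts))  # permuted assignment
    sample_ids <- sprintf("S%03d", seq_len(config$n_samples))

    vals <- matrix(stats::rnorm(length(genes) * config$n_samples, 0,
                                config$gene_noise_sd),
                   length(genes), config$n_samples,
                   dimnames = list(genes, sample_ids))
    shift <- config$signature_effect * dir_num[covered]
    diffuse_cols <- subset %in% c("diffuse1", "diffuse2")
    if (any(diffuse_cols) && n_cov > 0)
      vals[covered, diffuse_cols] <- vals[covered, diffuse_cols] + shift
    n_conc <- round(config$inflammatory_concordant_frac * n_cov)
    conc_genes <- sort(sample(covered, n_conc))
    infl_cols <- subset == "inflammatory"
    if (any(infl_cols) && n_conc > 0)
      vals[conc_genes, infl_cols] <- vals[conc_genes, infl_cols] + shift[conc_genes]

    ann <- data.frame(sample_id = sample_ids, subset = subset,
                      stringsAsFactors = FALSE)
    shifted <- list(diffuse1 = covered, diffuse2 = covered,
                    inflammatory = conc_genes)
    truth <- structure(list(cohort_subsets = ann, cohort_shifted_genes = shifted,
                            covered_genes = covered, config = config),
                       class = "synthetic_truth")
    list(dataset = expression_dataset(vals, scale = "log-ratio", annotations = ann),
         truth = truth)
  })
}

#' Build a small synthetic gene-set collection for enrichment testing
#'
#' Constructs GMT-style sets over a gene universe: a few sets seeded with
#' genes from a supplied signature (so enrichment has something to find) and
#' the remainder drawn uniformly from the universe. Purely a convenience for
#' simulations and the pipeline demo; labelled synthetic.
#'
#' @param universe character vector of gene ids.
#' @param signature_genes gene ids to over-represent in the first sets.
#' @param n_sets total number of sets.
#' @param n_enriched how many sets are seeded from the signature.
#' @param set_size genes per set.
#' @param signature_frac fraction of each enriched set drawn from
#'   `signature_genes`.
#' @param seed integer RNG seed.
#' @return a named list of gene-id vectors (same shape as [read_gmt()]).
#' @export
simulate_gene_sets <- function(universe, signature_genes, n_sets = 12L,
                               n_enriched = 3L, set_size = 80L,
                               signature_frac = 0.5, seed = 1L) {
  stopifnot(n_enriched <= n_sets, length(universe) >= set_size)
  withr::with_seed(seed, {
    sets <- vector("list", n_sets)
    names(sets) <- sprintf("SET%02d", seq_len(n_sets))
    sig_pool <- intersect(signature_genes, universe)
    for (i in seq_len(n_sets)) {
      if (i <= n_enriched && length(sig_pool) > 0) {
        k <- min(round(signature_frac * set_size), length(sig_pool))
        core <- sample(sig_pool, k)
        rest <- sample(setdiff(universe, core), set_size - k)
        sets[[i]] <- sort(unique(c(core, rest)))
      } else {
        sets[[i]] <- sort(sample(universe, set_size))
      }
    }
    attr(sets, "descriptions") <- stats::setNames(
      rep("synthetic gene set", n_sets), names(sets))
    sets
  })
}
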