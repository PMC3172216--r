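# shared fixture builders; everything is generated in code, nothing on disk

make_ds <- function(values, scale = "log2-vst", condition = NULL, time = NULL,
                    subset = NULL, detection = NULL) {
  ann <- NULL
  if (!is.null(condition) || !is.null(subset)) {
    ann <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
    if (!is.null(condition)) ann$condition <- condition
    if (!is.null(time)) ann$time <- time
    if (!is.null(subset)) ann$subset <- subset
  }
  expression_dataset(values, scale = scale, annotations = ann,
                     detection = detection)
}

# a 1-gene, 2v2 dataset with control = c(1,3), perturbed = c(5,7)
toy_two_group <- function() {
  m <- rbind(G1 = c(1, 3, 5, 7))
  colnames(m) <- c("c1", "c2", "p1", "p2")
  make_ds(m, condition = c("control", "control", "perturbed", "perturbed"),
          time = "48h")
}

# scaled-down perturbation config for fast tests
small_perturb_cfg <- function(seed = 1, n_probes = 2000L, n_planted_48 = 150L,
                              n_planted_24 = 60L, ...) {
  perturbation_sim_config(n_probes = n_probes, n_planted_48 = n_planted_48,
                          n_planted_24 = n_planted_24, seed = seed, ...)
}

# build a signature object directly from genes/directions/weights
make_signature <- function(genes, weights, name = "sig", time = "48h") {
  n <- length(genes)
  tab <- data.frame(gene = genes, time = rep(time, n), lfc = weights,
                    s_sq = rep(1, n), s_tilde_sq = rep(1, n),
                    df_residual = rep(2L, n), df_total = rep(6, n),
                    mean_expr = rep(8, n), t_mod = sign(weights) * 10,
                    p = rep(1e-6, n), q = rep(1e-6, n),
                    direction = ifelse(weights >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  class(tab) <- c("differential_table", "data.frame")
  derive_signature(tab, fdr = 0.01, fold = 2, name = name)
}

# per-probe replicate SD pooled across replicate groups, for VST checks
pooled_replicate_sd <- function(values, groups) {
  vs <- sapply(groups, function(g) {
    sub <- values[, g, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2) / (length(g) - 1L)
  })
  sqrt(rowMeans(vs))
}
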