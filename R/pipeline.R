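#' Run the whole signature pipeline end to end
#'
#' Simulate (or accept) a perturbation experiment, preprocess it, test each
#' time point for differential expression, derive the late-time-point
#' signature, run gene-set enrichment, compare the early and late
#' signatures, simulate (or accept) a labelled cohort, and project the
#' signature onto it. Every stage's result is written as deterministic
#' plain-text TSV/JSON under `outdir`, so the same seed and configuration
#' reproduce byte-identical files.
#'
#' @param outdir output directory (created if needed).
#' @param seed master integer seed; stage seeds are derived from it.
#' @param perturb_config a [perturbation_sim_config()]; its own seed is
#'   overridden by `seed`.
#' @param cohort_config a [cohort_sim_config()]; its seed is derived from
#'   `seed`.
#' @param fdr,fold signature thresholds (see [derive_signature()]).
#' @param enrichment_p significance cutoff for [enrich()].
#' @param gene_sets named list of gene sets; by default a synthetic
#'   collection is generated with [simulate_gene_sets()].
#' @param target target subset labels for the projection contrast.
#' @return invisibly, a list with all intermediate objects and `files`, the
#'   named vector of written paths.
#' @export
run_pipeline <- function(outdir, seed = 1L,
                         perturb_config = perturbation_sim_config(),
                         cohort_config = cohort_sim_config(),
                         fdr = 0.01, fold = 2, enrichment_p = 0.001,
                         gene_sets = NULL,
                         target = c("diffuse1", "diffuse2")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  files <- character(0)

  perturb_config$seed <- as.integer(seed)
  sim <- simulate_perturbation(perturb_config)
  write_expression_tsv(sim$dataset, fp("perturbation_raw.tsv"),
                       annotations_path = fp("perturbation_samples.tsv"),
                       detection_path = fp("perturbation_detection.tsv"))

  pre <- preprocess_experiment(sim$dataset)
  write_expression_tsv(pre$dataset, fp("perturbation_normalized.tsv"))
  writeLines(pre$removed_ids, fp("removed_probes.txt"))
  .write_json(list(vst_c = pre$vst$c, vst_a = pre$vst$a, vst_b = pre$vst$b,
                   n_removed = length(pre$removed_ids),
                   n_retained = nrow(pre$dataset$values)),
              fp("preprocess_provenance.json"))

  tps <- perturb_config$time_points
  tables <- lapply(tps, function(tp)
    run_differential(pre$dataset, c("perturbed", "control"), tp))
  names(tables) <- tps
  de_all <- do.call(rbind, tables)
  .write_tsv(de_all[, c("gene", "time", "lfc", "t_mod", "p", "q", "direction")],
             fp("differential.tsv"))

  last_tp <- tps[length(tps)]
  first_tp <- tps[1L]
  sig_late <- derive_signature(tables[[last_tp]], fdr = fdr, fold = fold,
                               name = paste0("perturbation_", last_tp))
  sig_early <- derive_signature(tables[[first_tp]], fdr = fdr, fold = fold,
                                name = paste0("perturbation_", first_tp))
  write_signature_tsv(sig_late, fp("signature_late.tsv"))
  write_signature_tsv(sig_early, fp("signature_early.tsv"))

  universe <- rownames(pre$dataset$values)
  if (is.null(gene_sets))
    gene_sets <- simulate_gene_sets(universe, sig_late$entries$gene,
                                    seed = seed + 1L)
  enr <- enrich(sig_late, gene_sets, universe, p_cutoff = enrichment_p)
  .write_tsv(enr, fp("enrichment.tsv"))

  ovl <- if (nrow(sig_early$entries) && nrow(sig_late$entries))
    overlap_signatures(sig_early, sig_late) else NULL
  if (!is.null(ovl))
    .write_json(unclass(ovl), fp("signature_overlap.json"))

  cohort_config$seed <- as.integer(seed + 2L)
  cosim <- simulate_cohort(sig_late, cohort_config)
  write_expression_tsv(cosim$dataset, fp("cohort_matrix.tsv"),
                       annotations_path = fp("cohort_samples.tsv"))
  proj <- project_signature(sig_late, cosim$dataset, target = target)
  .write_tsv(proj$scores, fp("cohort_scores.tsv"))
  .write_tsv(proj$concordance, fp("cohort_concordance.tsv"))
  .write_json(proj$contrast, fp("cohort_contrast.json"))
  write_tree_newick(proj$tree, fp("cohort_dendrogram.nwk"))

  invisible(list(
    perturbation = sim, preprocessed = pre, tables = tables,
    signature = sig_late, signature_early = sig_early,
    enrichment = enr, overlap = ovl, cohort = cosim, projection = proj,
    files = list.files(outdir, full.names = TRUE)))
}

# deterministic TSV writer: 15 significant digits, no quoting, UNIX newlines
.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num))
    df[[j]] <- ifelse(is.na(df[[j]]), "NA", sprintf("%.15g", df[[j]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
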