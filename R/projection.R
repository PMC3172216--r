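#' Build a signature centroid on a cohort platform
#'
#' The centroid is the signature's representative expression-change vector
#' over the signature genes present in the cohort: per gene, the signature
#' log2 fold-change (`weighting = "lfc"`) or just its sign
#' (`weighting = "sign"`). Matching is by uppercased gene symbol; when an
#' optional probe-to-symbol map makes several cohort rows share a symbol,
#' the most variable row (highest IQR across samples) represents it.
#'
#' @param signature a non-empty `gene_signature`.
#' @param cohort an [expression_dataset()].
#' @param weighting `"lfc"` (default) or `"sign"`.
#' @param symbol_map optional named character vector mapping cohort feature
#'   ids to gene symbols; default is identity.
#' @return a `centroid` list: `genes` (cohort row ids, one per matched
#'   symbol), `symbols`, `values` (named by cohort row id), `coverage`.
#' @export
build_centroid <- function(signature, cohort, weighting = c("lfc", "sign"),
                           symbol_map = NULL) {
  weighting <- match.arg(weighting)
  m <- .match_signature(signature, cohort, symbol_map)
  rows <- m$rows
  syms <- m$symbols
  sig <- signature$entries
  w <- sig$weight[match(syms, sig$gene)]
  if (weighting == "sign") w <- ifelse(sig$direction[match(syms, sig$gene)] == "up", 1, -1)
  coverage <- length(rows) / nrow(sig)
  if (coverage < 0.5)
    warning(sprintf("only %.0f%% of signature genes matched on the cohort platform",
                    100 * coverage))
  if (length(unique(w)) < 2L)
    stop("centroid values are all equal; correlation scoring is undefined")
  structure(list(genes = rows, symbols = syms,
                 values = stats::setNames(w, rows), coverage = coverage,
                 weighting = weighting),
            class = "centroid")
}

#' Score cohort samples by correlation with a centroid
#'
#' Each sample's signature-activity score is the Pearson correlation between
#' the centroid vector and that sample's expression over the centroid genes.
#' With `center_genes = TRUE` (default, appropriate for ratio-style cohort
#' data) each gene's row is median-centered across samples first; this does
#' not change within-sample correlations' ordering but anchors scores at 0
#' for a typical sample. Missing values are dropped pairwise per sample; a
#' sample with fewer than 2 usable genes scores `NA` with a warning.
#'
#' @param centroid a `centroid` from [build_centroid()].
#' @param cohort the [expression_dataset()] it was built on.
#' @param center_genes median-center each gene across samples first.
#' @return data.frame `sample_id`, `score`, `n_genes_used`.
#' @export
score_samples <- function(centroid, cohort, center_genes = TRUE) {
  stopifnot(inherits(centroid, "centroid"), inherits(cohort, "expression_dataset"))
  if (!all(centroid$genes %in% rownames(cohort$values)))
    stop("cohort is missing centroid genes")
  x <- cohort$values[centroid$genes, , drop = FALSE]
  if (center_genes)
    x <- x - apply(x, 1L, stats::median, na.rm = TRUE)
  w <- centroid$values
  scores <- rep(NA_real_, ncol(x))
  used <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j])
    used[j] <- sum(ok)
    if (used[j] >= 2L && stats::sd(x[ok, j]) > 0)
      scores[j] <- stats::cor(w[ok], x[ok, j])
  }
  if (anyNA(scores))
    warning(sum(is.na(scores)), " sample(s) scored NA (fewer than 2 usable genes ",
            "or constant expression)")
  data.frame(sample_id = colnames(x), score = scores, n_genes_used = used,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare signature scores between target subsets and the rest
#'
#' Reports mean and SD (n-1 denominator) of the per-sample scores in the
#' target subsets versus all other samples, and a Welch two-sample t-test
#' (unequal variances, Welch-Satterthwaite degrees of freedom, two-sided).
#' When both groups have zero variance the p-value degenerates: reported as
#' the smallest positive double for a nonzero difference, 1 otherwise.
#'
#' @param scores data.frame from [score_samples()].
#' @param subsets named character vector or data.frame (`sample_id`,
#'   `subset`) giving each sample's subset label.
#' @param target subset labels forming the target group
#'   (default the two diffuse-proliferation labels).
#' @return list `target_mean`, `target_sd`, `target_n`, `rest_mean`,
#'   `rest_sd`, `rest_n`, `difference`, `t`, `df`, `p`.
#' @export
compare_subsets <- function(scores, subsets,
                            target = c("diffuse1", "diffuse2")) {
  lab <- .subset_labels(subsets, scores$sample_id)
  s <- scores$score
  ok <- !is.na(s)
  in_t <- lab %in% target & ok
  in_r <- !(lab %in% target) & ok
  if (sum(in_t) < 2L || sum(in_r) < 2L)
    stop("need >= 2 scored samples in both the target group and the rest")
  x <- s[in_t]; y <- s[in_r]
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  diff <- mean(x) - mean(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    df <- n1 + n2 - 2
    p <- if (diff == 0) 1 else .Machine$double.xmin
  } else {
    t <- diff / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- max(2 * stats::pt(-abs(t), df), .Machine$double.xmin)
  }
  list(target_mean = mean(x), target_sd = stats::sd(x), target_n = n1,
       rest_mean = mean(y), rest_sd = stats::sd(y), rest_n = n2,
       difference = diff, t = t, df = df, p = p)
}

# match signature genes to cohort rows by uppercased symbol; collapse
# duplicate symbols to the highest-IQR row
.match_signature <- function(signature, cohort, symbol_map = NULL) {
  stopifnot(inherits(signature, "gene_signature"),
            inherits(cohort, "expression_dataset"))
  if (nrow(signature$entries) == 0L) stop("signature is empty")
  feats <- rownames(cohort$values)
  symbols <- if (is.null(symbol_map)) stats::setNames(feats, feats)
             else stats::setNames(toupper(symbol_map[feats]), feats)
  if (anyNA(symbols)) stop("symbol_map does not cover all cohort features")
  hit <- which(symbols %in% signature$entries$gene)
  if (length(unique(symbols[hit])) < 2L)
    stop("fewer than 2 signature genes matched on the cohort platform")
  rows <- feats[hit]
  if (anyDuplicated(symbols[hit])) {
    iqr <- apply(cohort$values[rows, , drop = FALSE], 1L, stats::IQR, na.rm = TRUE)
    keep <- vapply(split(rows, symbols[hit]),
                   function(r) r[which.max(iqr[r])], "")
    rows <- unname(keep)
  }
  list(rows = rows, symbols = unname(symbols[rows]))
}

# accept either a named vector or a (sample_id, subset) data.frame
.subset_labels <- function(subsets, sample_ids) {
  if (is.data.frame(subsets)) {
    stopifnot(all(c("sample_id", "subset") %in% names(subsets)))
    lab <- subsets$subset[match(sample_ids, subsets$sample_id)]
  } else {
    lab <- unname(subsets[sample_ids])
  }
  if (anyNA(lab))
    stop("missing subset label for sample(s): ",
         paste(sample_ids[is.na(lab)][1:min(3, sum(is.na(lab)))], collapse = ", "))
  lab
}

#' Direction-concordance fractions per cohort subset
#'
#' For each subset, the fraction of matched signature genes whose mean
#' centered expression within the subset deviates in the gene's signature
#' direction. A gene counts as concordant when the sign of its subset mean
#' equals the signature direction *and* the mean clears a null band of
#' `null_band` standard errors of that subset mean (`null_band = 0` is the
#' pure sign test, under which unshifted genes match by chance ~50% — see
#' the vignette for why the default is 2).
#'
#' @param signature a `gene_signature`.
#' @param cohort an [expression_dataset()].
#' @param subsets labels as in [compare_subsets()]; defaults to the cohort's
#'   own `subset` annotation.
#' @param null_band multiples of the per-gene standard error of the subset
#'   mean that the mean must exceed; 0 disables the band.
#' @param center_genes median-center genes across samples first (default).
#' @param symbol_map optional probe-to-symbol map as in [build_centroid()].
#' @return data.frame `subset`, `n_samples`, `n_genes`, `n_concordant`,
#'   `concordant_frac` (NA for empty subsets).
#' @export
concordance_fractions <- function(signature, cohort, subsets = NULL,
                                  null_band = 2, center_genes = TRUE,
                                  symbol_map = NULL) {
  stopifnot(inherits(signature, "gene_signature"),
            inherits(cohort, "expression_dataset"), null_band >= 0)
  if (is.null(subsets)) {
    if (is.null(cohort$annotations) || !"subset" %in% names(cohort$annotations))
      stop("no subset labels supplied and cohort has no `subset` annotation")
    subsets <- cohort$annotations[, c("sample_id", "subset")]
  }
  m <- .match_signature(signature, cohort, symbol_map)
  x <- cohort$values[m$rows, , drop = FALSE]
  if (center_genes)
    x <- x - apply(x, 1L, stats::median, na.rm = TRUE)
  sig <- signature$entries
  dir_num <- ifelse(sig$direction[match(m$symbols, sig$gene)] == "up", 1, -1)
  lab <- .subset_labels(subsets, colnames(x))
  out <- lapply(unique(lab), function(s) {
    cols <- which(lab == s)
    if (length(cols) == 0L)
      return(data.frame(subset = s, n_samples = 0L, n_genes = length(dir_num),
                        n_concordant = NA_integer_, concordant_frac = NA_real_))
    xm <- rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
    conc <- sign(xm) == dir_num
    if (null_band > 0) {
      if (length(cols) >= 2L) {
        se <- apply(x[, cols, drop = FALSE], 1L, stats::sd, na.rm = TRUE) /
          sqrt(length(cols))
      } else {
        se <- apply(x, 1L, stats::sd, na.rm = TRUE)  # single sample: whole-cohort sd
      }
      conc <- conc & abs(xm) > null_band * se
    }
    data.frame(subset = s, n_samples = length(cols), n_genes = length(dir_num),
               n_concordant = sum(conc), concordant_frac = mean(conc))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cluster cohort samples over the signature genes
#'
#' Agglomerative average-linkage clustering of samples with distance
#' `1 - Pearson(sample_i, sample_j)` computed over the matched signature
#' genes (or all genes when no signature is given). A sample with constant
#' expression has undefined correlations and is an error naming the sample.
#'
#' @param cohort an [expression_dataset()].
#' @param signature optional `gene_signature` restricting the gene space.
#' @param symbol_map optional probe-to-symbol map as in [build_centroid()].
#' @return an object of class `c("cluster_tree", "hclust")` with extra
#'   fields `distance = "1-pearson"` and `linkage = "average"`; works with
#'   [stats::cutree()] and [ape::as.phylo()].
#' @export
cluster_samples <- function(cohort, signature = NULL, symbol_map = NULL) {
  stopifnot(inherits(cohort, "expression_dataset"))
  x <- cohort$values
  if (!is.null(signature)) {
    m <- .match_signature(signature, cohort, symbol_map)
    x <- x[m$rows, , drop = FALSE]
  }
  if (ncol(x) < 2L || nrow(x) < 2L) stop("need >= 2 samples and >= 2 genes")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant expression vector; correlation undefined for sample(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(x))
  hc <- stats::hclust(d, method = "average")
  hc$distance <- "1-pearson"
  hc$linkage <- "average"
  class(hc) <- c("cluster_tree", "hclust")
  hc
}

#' Write a sample dendrogram in Newick format
#'
#' @param tree a `cluster_tree` (or any `hclust`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Overlap and direction-concordance of two signatures
#'
#' Venn-style partition of two directional signatures: shared genes split
#' into concordantly up, concordantly down, and discordant; plus the genes
#' private to each signature.
#'
#' @param sig_a,sig_b non-empty `gene_signature` objects.
#' @return an `overlap_report` list: `n_a`, `n_b`, `n_intersect`,
#'   `n_concordant_up`, `n_concordant_down`, `n_discordant`, and gene-id
#'   vectors `concordant_up`, `concordant_down`, `discordant`, `a_only`,
#'   `b_only`.
#' @export
overlap_signatures <- function(sig_a, sig_b) {
  stopifnot(inherits(sig_a, "gene_signature"), inherits(sig_b, "gene_signature"))
  if (nrow(sig_a$entries) == 0L || nrow(sig_b$entries) == 0L)
    stop("both signatures must be non-empty")
  a <- sig_a$entries; b <- sig_b$entries
  shared <- intersect(a$gene, b$gene)
  da <- a$direction[match(shared, a$gene)]
  db <- b$direction[match(shared, b$gene)]
  up <- shared[da == "up" & db == "up"]
  down <- shared[da == "down" & db == "down"]
  disc <- shared[da != db]
  structure(list(name_a = sig_a$name, name_b = sig_b$name,
                 n_a = nrow(a), n_b = nrow(b), n_intersect = length(shared),
                 n_concordant_up = length(up), n_concordant_down = length(down),
                 n_discordant = length(disc),
                 concordant_up = sort(up), concordant_down = sort(down),
                 discordant = sort(disc),
                 a_only = sort(setdiff(a$gene, shared)),
                 b_only = sort(setdiff(b$gene, shared))),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap of '%s' (n=%d) and '%s' (n=%d): %d shared (%d up, %d down, %d discordant)\n",
              x$name_a, x$n_a, x$name_b, x$n_b, x$n_intersect,
              x$n_concordant_up, x$n_concordant_down, x$n_discordant))
  invisible(x)
}

#' Project a signature onto a cohort
#'
#' Convenience wrapper: centroid construction, per-sample scoring, subset
#' comparison, concordance fractions and sample clustering in one call.
#'
#' @inheritParams build_centroid
#' @param target target subset labels for [compare_subsets()].
#' @param center_genes passed to [score_samples()] and
#'   [concordance_fractions()].
#' @param null_band passed to [concordance_fractions()].
#' @return a `projection_result` list: `centroid`, `scores`, `contrast`,
#'   `concordance`, `tree`.
#' @export
project_signature <- function(signature, cohort, weighting = "lfc",
                              target = c("diffuse1", "diffuse2"),
                              center_genes = TRUE, null_band = 2,
                              symbol_map = NULL) {
  centroid <- build_centroid(signature, cohort, weighting = weighting,
                             symbol_map = symbol_map)
  scores <- score_samples(centroid, cohort, center_genes = center_genes)
  subsets <- cohort$annotations[, c("sample_id", "subset")]
  contrast <- compare_subsets(scores, subsets, target = target)
  concord <- concordance_fractions(signature, cohort, subsets,
                                   null_band = null_band,
                                   center_genes = center_genes,
                                   symbol_map = symbol_map)
  tree <- cluster_samples(cohort, signature, symbol_map = symbol_map)
  structure(list(centroid = centroid, scores = scores, contrast = contrast,
                 concordance = concord, tree = tree),
            class = "projection_result")
}
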