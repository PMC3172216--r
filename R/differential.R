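#' Per-gene two-group summary statistics
#'
#' For one contrast at one time point, computes per gene the log2
#' fold-change (first condition minus second), the pooled within-group
#' variance, the residual degrees of freedom `n1 + n2 - 2`, and the mean
#' expression — the sufficient statistics for moderated-t inference.
#'
#' @param dataset a log-scale [expression_dataset()] with `condition` and
#'   `time` annotations.
#' @param contrast length-2 character: conditions compared as
#'   `contrast[1] - contrast[2]` (e.g. `c("perturbed", "control")`).
#' @param time time-point label selecting the samples.
#' @return data.frame with columns `gene`, `lfc`, `s_sq`, `df_residual`,
#'   `mean_expr`, `n1`, `n2`.
#' @examples
#' m <- rbind(g1 = c(1, 3, 5, 7))
#' colnames(m) <- c("c1", "c2", "p1", "p2")
#' ann <- data.frame(sample_id = colnames(m),
#'                   condition = c("control", "control", "perturbed", "perturbed"),
#'                   time = "48h")
#' ds <- expression_dataset(m, "log2-vst", ann)
#' fit_gene_models(ds, c("perturbed", "control"), "48h")  # lfc 4, s_sq 2, df 2
#' @export
fit_gene_models <- function(dataset, contrast, time) {
  stopifnot(inherits(dataset, "expression_dataset"), length(contrast) == 2L)
  if (dataset$scale == "linear")
    stop("fit_gene_models expects log-scale data; run the VST first")
  ann <- dataset$annotations
  if (is.null(ann) || !all(c("condition", "time") %in% names(ann)))
    stop("dataset needs condition and time annotations")
  ids1 <- ann$sample_id[ann$condition == contrast[1L] & ann$time == time]
  ids2 <- ann$sample_id[ann$condition == contrast[2L] & ann$time == time]
  if (length(ids1) < 2L || length(ids2) < 2L)
    stop(sprintf("need >= 2 samples per condition at time %s (got %d vs %d); ",
                 time, length(ids1), length(ids2)),
         "within-group variance is undefined otherwise")
  x1 <- dataset$values[, ids1, drop = FALSE]
  x2 <- dataset$values[, ids2, drop = FALSE]
  n1 <- length(ids1); n2 <- length(ids2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  data.frame(gene = rownames(dataset$values), lfc = m1 - m2,
             s_sq = (ss1 + ss2) / df, df_residual = df,
             mean_expr = (n1 * m1 + n2 * m2) / (n1 + n2),
             n1 = n1, n2 = n2, row.names = NULL, stringsAsFactors = FALSE)
}

# Newton solve of trigamma(x) = y; monotone decreasing, convex target
trigamma_inverse <- function(y) {
  stopifnot(is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Models per-gene sample variances as scaled F draws around a common prior:
#' `s^2 ~ s0^2 * F(df, d0)`. On the log scale this gives closed moment
#' equations: with `e = log(s^2) - digamma(df/2) + log(df/2)`,
#' `E[e] = log(s0^2) - digamma(d0/2) + log(d0/2)` and
#' `Var[e] = trigamma(df/2) + trigamma(d0/2)`. The prior degrees of freedom
#' `d0` are recovered by inverting the trigamma function on the excess of
#' the observed log-variance dispersion over pure chi-square sampling noise;
#' when there is no excess (or `d0 > 1e6`), the prior is flagged infinite
#' and `s0^2` is the bias-corrected geometric mean of the variances.
#'
#' @param s_sq numeric vector of per-gene variances (>= 10 finite positive
#'   values required).
#' @param df_residual residual degrees of freedom (scalar or per-gene).
#' @return an `ebayes_prior` list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_prior <- function(s_sq, df_residual) {
  df <- rep_len(as.numeric(df_residual), length(s_sq))
  ok <- is.finite(s_sq) & s_sq > 0 & is.finite(df) & df > 0
  if (sum(ok) < 10L)
    stop("need >= 10 finite positive variances; use a fixed prior instead")
  z <- log(s_sq[ok]); dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - mean(trigamma(dfo / 2))
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    if (d0 > 1e6) {
      d0 <- Inf
      s0_sq <- exp(emean)
    } else {
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_prior")
}

#' Fixed empirical-Bayes prior
#'
#' Mainly for tests and for the no-shrinkage (`d0 = 0`) and full-shrinkage
#' (`d0 = Inf`) limits.
#'
#' @param d0 prior degrees of freedom, `>= 0` or `Inf`.
#' @param s0_sq prior variance, positive.
#' @return an `ebayes_prior` list.
#' @export
ebayes_prior <- function(d0, s0_sq) {
  stopifnot(d0 >= 0, s0_sq > 0)
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_prior")
}

#' Moderated t-statistics from shrunken variances
#'
#' Shrinks each gene's variance toward the prior,
#' `s_tilde^2 = (d0 * s0^2 + df * s^2) / (d0 + df)`, and computes
#' `t = lfc / sqrt(s_tilde^2 * (1/n1 + 1/n2))` with two-sided p-values on
#' `d0 + df` degrees of freedom (standard normal when `d0` is infinite).
#' `d0 = 0` reproduces the ordinary pooled two-sample t-test. Benjamini-
#' Hochberg q-values are appended.
#'
#' @param fit data.frame from [fit_gene_models()].
#' @param prior an `ebayes_prior`.
#' @param time optional time-point label recorded in the result.
#' @return a `differential_table` data.frame: `gene`, `time`, `lfc`, `s_sq`,
#'   `s_tilde_sq`, `df_residual`, `df_total`, `mean_expr`, `t_mod`, `p`,
#'   `q`, `direction`.
#' @export
moderate_t <- function(fit, prior, time = NA_character_) {
  stopifnot(inherits(prior, "ebayes_prior"))
  d0 <- prior$d0; s0 <- prior$s0_sq
  df <- fit$df_residual
  if (is.infinite(d0)) {
    s_tilde <- rep_len(s0, nrow(fit))
    df_total <- rep_len(Inf, nrow(fit))
  } else {
    s_tilde <- (d0 * s0 + df * fit$s_sq) / (d0 + df)
    df_total <- d0 + df
  }
  se <- sqrt(s_tilde * (1 / fit$n1 + 1 / fit$n2))
  t_mod <- fit$lfc / se
  p <- ifelse(is.finite(df_total),
              2 * stats::pt(-abs(t_mod), df_total),
              2 * stats::pnorm(-abs(t_mod)))
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  out <- data.frame(gene = fit$gene, time = time, lfc = fit$lfc,
                    s_sq = fit$s_sq, s_tilde_sq = s_tilde,
                    df_residual = df, df_total = df_total,
                    mean_expr = fit$mean_expr, t_mod = t_mod, p = p,
                    q = bh_adjust(p),
                    direction = ifelse(fit$lfc >= 0, "up", "down"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1, returned in the
#' input order. Controls the false discovery rate under independence or
#' positive dependence.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.001, 0.008, 0.039, 0.041))  # 0.004 0.016 0.041 0.041
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Threshold a differential table into a directional gene signature
#'
#' Selects genes with adjusted p below `fdr` (or raw p when
#' `use_raw_p = TRUE`) and `|lfc| >= log2(fold)`; each selected gene carries
#' its direction and its log2 fold-change as weight.
#'
#' @param table a `differential_table` from [moderate_t()].
#' @param fdr significance cutoff in `(0, 1)`.
#' @param fold fold-change cutoff `>= 1` on the linear scale
#'   (`fold = 2` means `|lfc| >= 1`).
#' @param name signature name.
#' @param use_raw_p filter on the unadjusted p-value instead of the BH q.
#' @return a `gene_signature`: list with `entries` (data.frame `gene`,
#'   `direction`, `weight`), `name`, `time`, `thresholds`, `n_up`, `n_down`.
#' @export
derive_signature <- function(table, fdr = 0.01, fold = 2, name = "signature",
                             use_raw_p = FALSE) {
  stopifnot(fdr > 0, fdr < 1, fold >= 1)
  crit <- if (use_raw_p) table$p else table$q
  sel <- crit < fdr & abs(table$lfc) >= log2(fold)
  entries <- data.frame(gene = table$gene[sel],
                        direction = table$direction[sel],
                        weight = table$lfc[sel],
                        stringsAsFactors = FALSE)
  new_gene_signature(entries, name = name,
                     time = if (nrow(table)) table$time[1L] else NA_character_,
                     fdr = fdr, fold = fold)
}

# internal constructor shared with the signature TSV reader;
# gene symbols are uppercased for cross-platform matching
new_gene_signature <- function(entries, name, time, fdr, fold) {
  entries$gene <- toupper(entries$gene)
  stopifnot(!anyDuplicated(entries$gene),
            all(entries$direction %in% c("up", "down")))
  if (nrow(entries) && any(sign(entries$weight) != ifelse(entries$direction == "up", 1, -1) &
                           entries$weight != 0))
    stop("signature weight signs disagree with directions")
  structure(list(entries = entries, name = name, time = time,
                 thresholds = c(fdr = fdr, fold = fold),
                 n_up = sum(entries$direction == "up"),
                 n_down = sum(entries$direction == "down")),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s' (%s): %d genes (%d up, %d down), q<%g & fold>=%g\n",
              x$name, x$time, nrow(x$entries), x$n_up, x$n_down,
              x$thresholds["fdr"], x$thresholds["fold"]))
  invisible(x)
}

#' Full differential stage for one time point
#'
#' [fit_gene_models()], then [estimate_prior()], then [moderate_t()].
#'
#' @inheritParams fit_gene_models
#' @return a `differential_table`.
#' @export
run_differential <- function(dataset, contrast = c("perturbed", "control"), time) {
  fit <- fit_gene_models(dataset, contrast, time)
  prior <- estimate_prior(fit$s_sq, fit$df_residual)
  moderate_t(fit, prior, time = time)
}
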