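#' Filter probes flagged absent in every sample
#'
#' Probes whose signal is indistinguishable from array background in every
#' single sample carry no information and inflate the multiple-testing
#' burden; they are removed before any transformation. The primary rule uses
#' the dataset's detection calls; if the dataset has none, an intensity
#' fallback can be enabled: a probe is absent in a sample when its intensity
#' falls below the `background_quantile` of all intensities in that dataset.
#' A probe detected ("present") in even one sample is always retained.
#'
#' @param dataset an [expression_dataset()].
#' @param fallback_quantile if the dataset has no detection calls, treat
#'   intensities below this overall quantile as absent; `NULL` (default)
#'   means no fallback, and a dataset without detection calls is an error.
#' @return list with `dataset` (retained probes, original order) and
#'   `removed_ids` (character).
#' @export
filter_absent_probes <- function(dataset, fallback_quantile = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is.null(dataset$detection)) {
    absent_all <- rowSums(dataset$detection) == 0L
  } else if (!is.null(fallback_quantile)) {
    stopifnot(fallback_quantile > 0, fallback_quantile < 1)
    bg <- stats::quantile(dataset$values, fallback_quantile, names = FALSE)
    absent_all <- rowSums(dataset$values >= bg) == 0L
  } else {
    stop("dataset has no detection calls; supply `fallback_quantile` to use the ",
         "background-intensity rule")
  }
  removed <- rownames(dataset$values)[absent_all]
  list(dataset = subset_features(dataset, !absent_all), removed_ids = removed)
}

#' Generalized-log (glog2) transform
#'
#' `glog2(x) = log2((x + sqrt(x^2 + c^2)) / 2)`: asymptotically `log2(x)` for
#' large `x`, approximately linear near 0, strictly monotone everywhere. The
#' offset `c` is the intensity at which additive and multiplicative noise
#' contribute equally.
#'
#' @param x numeric vector or matrix.
#' @param c positive offset parameter.
#' @return transformed values, same shape as `x`.
#' @examples
#' glog2(8, c = 1e-8)   # ~ log2(8) = 3
#' glog2(0, c = 2)      # log2(2/2) = 0
#' @export
glog2 <- function(x, c) {
  stopifnot(c > 0)
  log2((x + sqrt(x^2 + c^2)) / 2)
}

#' Fit variance-stabilizing transform parameters from replicate variation
#'
#' Under an additive + multiplicative error model the within-replicate
#' variance follows `Var ~ a + b * mean^2` (`a` = additive variance,
#' `b` = squared multiplicative CV). Per-probe replicate means and variances
#' are pooled across replicate groups, binned by mean, and the binned
#' variance regressed on squared binned mean; the glog offset is
#' `c = sqrt(a / b)` (the noise-crossover intensity), capped to
#' `[1e-3, 1e6]`.
#'
#' @param dataset an [expression_dataset()] on the linear scale.
#' @param replicate_groups list of character vectors of sample ids; each
#'   vector is one replicate group (same biological condition). Groups with
#'   fewer than 2 samples are ignored; at least one usable group is required.
#' @param n_bins number of mean-quantile bins for the trend regression.
#' @return a `vst_params` list with elements `c`, `a`, `b`,
#'   `fitted_from = "replicate-trend"`.
#' @export
fit_vst <- function(dataset, replicate_groups, n_bins = 50L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale != "linear")
    stop("fit_vst expects linear-scale data, got scale=", dataset$scale)
  groups <- Filter(function(g) length(g) >= 2L, replicate_groups)
  if (length(groups) == 0L)
    stop("no replicate group with >= 2 samples; use vst_params() with a fixed c")
  m <- v <- NULL
  for (g in groups) {
    sub <- dataset$values[, g, drop = FALSE]
    mg <- rowMeans(sub)
    m <- c(m, mg)
    v <- c(v, rowSums((sub - mg)^2) / (length(g) - 1L))
  }
  ok <- is.finite(m) & is.finite(v)
  m <- m[ok]; v <- v[ok]
  bins <- cut(rank(m, ties.method = "first"), breaks = n_bins, labels = FALSE)
  bm2 <- tapply(m^2, bins, mean)
  bv <- tapply(v, bins, mean)
  fit <- stats::lm(bv ~ bm2)
  a <- max(unname(stats::coef(fit)[1L]), 0)
  b <- max(unname(stats::coef(fit)[2L]), 0)
  c_hat <- if (b <= 0) 1e6 else sqrt(a / b)
  c_hat <- min(max(c_hat, 1e-3), 1e6)
  structure(list(c = c_hat, a = a, b = b, fitted_from = "replicate-trend"),
            class = "vst_params")
}

#' Fixed variance-stabilizing transform parameters
#'
#' @param c positive glog offset.
#' @return a `vst_params` list with `fitted_from = "fixed"`.
#' @export
vst_params <- function(c) {
  stopifnot(is.numeric(c), length(c) == 1L, c > 0)
  structure(list(c = c, a = NA_real_, b = NA_real_, fitted_from = "fixed"),
            class = "vst_params")
}

#' Apply the variance-stabilizing transform
#'
#' Transforms every value with [glog2()] at the fitted offset. Inputs below
#' `-c` (possible after aggressive background subtraction upstream) are
#' clipped to the transform's value at 0 and counted in a warning.
#'
#' @param dataset an [expression_dataset()] on the linear scale.
#' @param params a `vst_params` object from [fit_vst()] or [vst_params()].
#' @return the dataset with transformed values and scale `"log2-vst"`.
#' @export
apply_vst <- function(dataset, params) {
  stopifnot(inherits(dataset, "expression_dataset"), inherits(params, "vst_params"))
  x <- dataset$values
  low <- x < -params$c
  if (any(low)) {
    warning(sum(low), " value(s) below -c clipped to the transform's value at 0")
    x[low] <- 0
  }
  dataset$values <- glog2(x, params$c)
  dataset$scale <- "log2-vst"
  dataset
}

# quantile-normalize a numeric matrix; ties within a column get the mean of
# the reference quantile values they span
.quantile_normalize_matrix <- function(x) {
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    v <- x[o, j]
    res <- ref
    r <- rle(v)
    if (any(r$lengths > 1L)) {
      ends <- cumsum(r$lengths)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      for (g in which(r$lengths > 1L)) {
        idx <- starts[g]:ends[g]
        res[idx] <- mean(ref[idx])
      }
    }
    out[o, j] <- res
  }
  out
}

#' Quantile normalization
#'
#' Forces every sample to share the same empirical distribution: each
#' column's sorted values are replaced by the across-column mean of sorted
#' values, mapped back by rank. Ties within a column receive the mean of the
#' reference quantile values they span, so the result is independent of the
#' input ordering. Rejects missing values; a single-sample dataset is
#' returned unchanged with a warning.
#'
#' @param dataset an [expression_dataset()].
#' @return the dataset with normalized values (scale tag unchanged).
#' @examples
#' m <- matrix(c(2, 6, 4, 8), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
#' quantile_normalize(expression_dataset(m, "linear"))$values  # rows (3,3),(7,7)
#' @export
quantile_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (anyNA(dataset$values))
    stop("quantile_normalize does not accept missing values")
  if (ncol(dataset$values) < 2L) {
    warning("single-sample dataset: quantile normalization is the identity")
    return(dataset)
  }
  dataset$values <- .quantile_normalize_matrix(dataset$values)
  dataset
}

#' Run the full preprocessing chain
#'
#' Absent-probe filtering, then VST (offset fitted from replicate groups
#' derived from the condition x time annotations), then quantile
#' normalization — the canonical order for bead-array data where filtering
#' must precede the variance-trend fit and normalization expects a
#' variance-stabilized scale.
#'
#' @param dataset a linear-scale [expression_dataset()] with `condition` and
#'   `time` annotations.
#' @param fallback_quantile passed to [filter_absent_probes()].
#' @return list with `dataset` (filtered, transformed, normalized),
#'   `removed_ids`, and `vst` (the fitted `vst_params`).
#' @export
preprocess_experiment <- function(dataset, fallback_quantile = NULL) {
  filt <- filter_absent_probes(dataset, fallback_quantile = fallback_quantile)
  ann <- filt$dataset$annotations
  if (is.null(ann) || !all(c("condition", "time") %in% names(ann)))
    stop("preprocess_experiment needs condition and time annotations")
  groups <- split(ann$sample_id, paste(ann$condition, ann$time))
  vst <- fit_vst(filt$dataset, groups)
  out <- quantile_normalize(apply_vst(filt$dataset, vst))
  list(dataset = out, removed_ids = filt$removed_ids, vst = vst)
}
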