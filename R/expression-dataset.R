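#' Expression dataset container
#'
#' The universal currency of the pipeline: a numeric feature x sample matrix
#' with a declared measurement scale, per-sample annotations, and optional
#' per-cell detection calls (as produced by bead-array scanners, where a
#' probe may be flagged indistinguishable from array background).
#'
#' @param values numeric matrix, features in rows, samples in columns. Must
#'   carry unique, non-empty rownames (feature ids; uppercased on ingest) and
#'   colnames (sample ids).
#' @param scale one of `"linear"` (raw intensities), `"log2-vst"`
#'   (generalized-log transformed) or `"log-ratio"` (centered two-color style
#'   data).
#' @param annotations data.frame with a `sample_id` column covering every
#'   sample, plus any of `condition`, `time`, `subset`. May be `NULL`.
#' @param detection optional logical matrix of the same shape as `values`;
#'   `TRUE` means the probe was detected ("present") in that sample.
#' @return an object of class `"expression_dataset"`: a list with elements
#'   `values`, `scale`, `annotations`, `detection`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("FN1", "BGN", "COMP"), c("s1", "s2")))
#' ds <- expression_dataset(m, scale = "linear")
#' dim(ds$values)
#' @export
expression_dataset <- function(values, scale = c("linear", "log2-vst", "log-ratio"),
                               annotations = NULL, detection = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature ids as rownames and sample ids as colnames")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!is.null(detection)) {
    if (!is.logical(detection) || !identical(dim(detection), dim(values)))
      stop("`detection` must be a logical matrix with the same shape as `values`")
    dimnames(detection) <- dimnames(values)
  }
  if (!is.null(annotations)) {
    if (!is.data.frame(annotations) || !"sample_id" %in% names(annotations))
      stop("`annotations` must be a data.frame with a `sample_id` column")
    missing <- setdiff(colnames(values), annotations$sample_id)
    if (length(missing))
      stop("annotations missing for sample(s): ", paste(missing, collapse = ", "))
    annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                               drop = FALSE]
    rownames(annotations) <- NULL
  }
  structure(list(values = values, scale = scale,
                 annotations = annotations, detection = detection),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d features x %d samples [scale=%s]%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$detection)) "" else ", with detection calls"))
  if (!is.null(x$annotations))
    cat("annotations:", paste(setdiff(names(x$annotations), "sample_id"),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# subset features keeping everything aligned
subset_features <- function(ds, keep) {
  ds$values <- ds$values[keep, , drop = FALSE]
  if (!is.null(ds$detection)) ds$detection <- ds$detection[keep, , drop = FALSE]
  ds
}

# select sample columns by id, keeping annotations aligned
subset_samples <- function(ds, ids) {
  stopifnot(all(ids %in% colnames(ds$values)))
  ds$values <- ds$values[, ids, drop = FALSE]
  if (!is.null(ds$detection)) ds$detection <- ds$detection[, ids, drop = FALSE]
  if (!is.null(ds$annotations))
    ds$annotations <- ds$annotations[match(ids, ds$annotations$sample_id), ,
                                     drop = FALSE]
  ds
}
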