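#' Write an expression dataset to tab-separated files
#'
#' The matrix file has leading `#key=value` metadata lines (at least
#' `#scale=`), then a header row `feature_id<TAB>sample ids...`. Values are
#' written with 15 significant digits so that a write/read round trip
#' reproduces them to better than 1e-12 relative error. No quoting, UNIX
#' newlines, `NA` for missing values.
#'
#' @param dataset an [expression_dataset()].
#' @param path output path for the value matrix.
#' @param annotations_path optional path for the sample-annotation table.
#' @param detection_path optional path for the 0/1 detection-call matrix.
#' @return invisibly, the matrix `path`.
#' @export
write_expression_tsv <- function(dataset, path, annotations_path = NULL,
                                 detection_path = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  if (ncol(v) == 0L) stop("refusing to write a dataset with 0 samples")
  if (nrow(v) == 0L) stop("refusing to write a dataset with 0 features")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#scale=%s", dataset$scale),
               paste(c("feature_id", colnames(v)), collapse = "\t")),
             con, sep = "\n")
  body <- apply(v, 2, function(col) ifelse(is.na(col), "NA", sprintf("%.15g", col)))
  if (nrow(v) == 1L) body <- matrix(body, nrow = 1L)
  writeLines(paste(rownames(v), apply(body, 1, paste, collapse = "\t"), sep = "\t"),
             con, sep = "\n")
  if (!is.null(detection_path)) {
    if (is.null(dataset$detection)) stop("dataset has no detection calls to write")
    d <- dataset$detection
    dcon <- file(detection_path, open = "wb")
    writeLines(paste(c("feature_id", colnames(d)), collapse = "\t"), dcon, sep = "\n")
    writeLines(paste(rownames(d),
                     apply(matrix(as.integer(d), nrow(d)), 1, paste, collapse = "\t"),
                     sep = "\t"), dcon, sep = "\n")
    close(dcon)
  }
  if (!is.null(annotations_path)) {
    if (is.null(dataset$annotations)) stop("dataset has no annotations to write")
    utils::write.table(dataset$annotations, annotations_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA", eol = "\n")
  }
  invisible(path)
}

#' Read an expression dataset from tab-separated files
#'
#' Counterpart of [write_expression_tsv()]. Readers reject rather than
#' coerce: ragged rows, duplicate feature ids, non-numeric cells and
#' annotation/sample mismatches are errors naming the file and location.
#'
#' @param path matrix TSV (leading `#key=value` lines allowed; `#scale=`
#'   respected, default `"linear"`).
#' @param annotations_path optional sample-annotation TSV with a `sample_id`
#'   column.
#' @param detection_path optional 0/1 detection matrix TSV aligned to the
#'   value matrix.
#' @return an [expression_dataset()].
#' @export
read_expression_tsv <- function(path, annotations_path = NULL,
                                detection_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta_idx <- meta_idx[meta_idx == seq_along(meta_idx)]  # leading block only
  scale <- "linear"
  for (l in lines[meta_idx]) {
    kv <- sub("^#", "", l)
    if (startsWith(kv, "scale=")) scale <- sub("^scale=", "", kv)
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  if (length(body) < 2L) stop(path, ": need a header row and at least one feature row")
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expected <- length(header)
  sample_ids <- header[-1L]
  if (length(sample_ids) == 0L) stop(path, ": header row has no sample ids")
  rows <- fields[-1L]
  nf <- lengths(rows)
  if (any(nf != ncol_expected)) {
    bad <- which(nf != ncol_expected)[1L]
    stop(sprintf("%s: line %d has %d fields, expected %d",
                 path, bad + length(meta_idx) + 1L, nf[bad], ncol_expected))
  }
  ids <- toupper(vapply(rows, `[[`, "", 1L))
  if (anyDuplicated(ids))
    stop(path, ": duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- vapply(rows, function(r) r[-1L], character(ncol_expected - 1L))
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = 1L) else t(cells)
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(vals) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: non-numeric value '%s' at feature %s, sample %s",
                 path, cells[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  dimnames(vals) <- list(ids, sample_ids)
  detection <- NULL
  if (!is.null(detection_path)) {
    d <- utils::read.delim(detection_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    dm <- as.matrix(d[, -1L, drop = FALSE])
    rownames(dm) <- toupper(d[[1L]])
    if (!identical(dim(dm), dim(vals)) ||
        !identical(rownames(dm), rownames(vals)) ||
        !identical(colnames(dm), colnames(vals)))
      stop(detection_path, ": detection matrix does not align with ", path)
    detection <- dm == 1
  }
  annotations <- NULL
  if (!is.null(annotations_path)) {
    annotations <- utils::read.delim(annotations_path, check.names = FALSE,
                                     stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(annotations))
      stop(annotations_path, ": missing `sample_id` column")
  }
  expression_dataset(vals, scale = scale, annotations = annotations,
                     detection = detection)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#' Member ids are uppercased and de-duplicated within each set; lines with
#' fewer than three fields are parse errors naming the line.
#'
#' @param path GMT file.
#' @return a named list of character vectors of gene ids, with a
#'   `"descriptions"` attribute (named character vector).
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("ECM\tmatrix genes\tCOL4A1\tBGN\tFN1", f)
#' read_gmt(f)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("%s: line %d has %d field(s); GMT requires name, description, >=1 member",
                 path, which(nf < 3L)[1L], nf[which(nf < 3L)[1L]]))
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_))
    stop(path, ": duplicate set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- names_
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2L), names_)
  sets
}

#' Write a gene signature to TSV
#'
#' Columns `gene`, `direction`, `weight`; leading `#key=value` lines record
#' the signature name, time point and thresholds.
#'
#' @param signature a [gene_signature] as returned by [derive_signature()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_signature_tsv <- function(signature, path) {
  stopifnot(inherits(signature, "gene_signature"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#name=%s", signature$name),
               sprintf("#time=%s", signature$time),
               sprintf("#fdr=%.15g", signature$thresholds["fdr"]),
               sprintf("#fold=%.15g", signature$thresholds["fold"]),
               "gene\tdirection\tweight",
               sprintf("%s\t%s\t%.15g", signature$entries$gene,
                       signature$entries$direction, signature$entries$weight)),
             con, sep = "\n")
  invisible(path)
}

#' Read a gene signature written by [write_signature_tsv()]
#'
#' @param path signature TSV.
#' @return a `gene_signature` object.
#' @export
read_signature_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getm <- function(key, default) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^#", key, "="), "", hit[1L]) else default
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "direction", "weight") %in% names(df)))
    stop(path, ": signature TSV needs columns gene, direction, weight")
  new_gene_signature(entries = data.frame(gene = toupper(df$gene),
                                          direction = df$direction,
                                          weight = df$weight,
                                          stringsAsFactors = FALSE),
                     name = getm("name", basename(path)),
                     time = getm("time", NA_character_),
                     fdr = as.numeric(getm("fdr", NA)),
                     fold = as.numeric(getm("fold", NA)))
}
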