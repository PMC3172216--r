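#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` counts category members among `n` draws without
#' replacement from a universe of `N` genes containing `K` category members:
#' `sum_{j=k}^{min(K,n)} C(K,j) C(N-K, n-j) / C(N,n)`. Terms are accumulated
#' in log space (log-sum-exp over `lchoose`) so large universes do not
#' overflow; the result is exact for small `N`.
#'
#' @param N universe size.
#' @param K category members in the universe.
#' @param n signature (draw) size.
#' @param k observed overlap.
#' @return the upper-tail probability in `(0, 1]`.
#' @examples
#' hypergeom_upper_tail(20, 5, 4, 3)  # 155/4845
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) != round(c(N, K, n, k))))
    stop("N, K, n, k must be integers")
  if (K > N || n > N || k < 0 || k > min(K, n) || N < 0)
    stop(sprintf("inconsistent counts: N=%d K=%d n=%d k=%d (need 0 <= k <= min(K,n), K,n <= N)",
                 N, K, n, k))
  if (k == 0L) return(1)
  j <- k:min(K, n)
  lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(lt)
  min(exp(m + log(sum(exp(lt - m)))), 1)
}

#' Hypergeometric over-representation of a signature in gene sets
#'
#' For each gene set, counts how many signature genes fall in it relative to
#' a stated gene universe (typically all probes surviving the absent-probe
#' filter) and computes the one-sided over-representation p-value, with
#' Benjamini-Hochberg q-values across the tested sets. Signature and sets
#' are intersected with the universe first; sets with no member in the
#' universe are dropped.
#'
#' @param signature a `gene_signature` (or character vector of gene ids).
#' @param sets named list of gene-id vectors (see [read_gmt()]).
#' @param universe character vector of gene ids defining the background.
#' @param p_cutoff rows with `p < p_cutoff` are flagged significant
#'   (default 0.001, unadjusted, with q reported alongside).
#' @return data.frame sorted by p: `set_name`, `N`, `K`, `n`, `k`, `p`, `q`,
#'   `significant`, `overlap_genes` (comma-separated).
#' @export
enrich <- function(signature, sets, universe, p_cutoff = 0.001) {
  stopifnot(p_cutoff > 0, p_cutoff < 1)
  sig_genes <- if (inherits(signature, "gene_signature"))
    signature$entries$gene else as.character(signature)
  universe <- unique(toupper(universe))
  if (length(universe) == 0L) stop("empty universe")
  sig_u <- intersect(toupper(sig_genes), universe)
  if (length(sig_u) == 0L)
    stop("signature has no genes in the universe")
  N <- length(universe)
  n <- length(sig_u)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(toupper(sets[[nm]])), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    ov <- intersect(members, sig_u)
    k <- length(ov)
    data.frame(set_name = nm, N = N, K = K, n = n, k = k,
               p = hypergeom_upper_tail(N, K, n, k),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no gene set has members in the universe")
  rows$q <- bh_adjust(rows$p)
  rows$significant <- rows$p < p_cutoff
  rows <- rows[order(rows$p, rows$set_name),
               c("set_name", "N", "K", "n", "k", "p", "q", "significant",
                 "overlap_genes")]
  rownames(rows) <- NULL
  rows
}
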