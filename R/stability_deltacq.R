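#' Comparative delta-Cq stability
#'
#' Ranks candidate reference genes by the mean standard deviation of their
#' pairwise Cq differences. For every gene pair (j, k) the per-sample
#' difference dCq = Cq_j - Cq_k is formed; its sample SD (n - 1 denominator)
#' measures how much the pair's relative expression moves across samples. A
#' gene's score is the arithmetic mean of its G - 1 pair SDs; lower is more
#' stable. Because a shared per-sample loading shift cancels in every
#' difference, the score is invariant to RNA-input variation.
#'
#' @param m A complete \code{\link{cq_matrix}} (no missing cells) with
#'   >= 2 genes and >= 3 samples.
#' @return Data frame with columns \code{gene}, \code{mean_pair_sd},
#'   \code{rank}, ordered as the input genes. Ties rank by input order.
#' @export
delta_cq_stability <- function(m) {
  v <- m$values
  if (anyNA(v)) stop("delta-Cq requires a complete matrix; use complete_case_submatrix()")
  G <- nrow(v)
  if (G < 2) stop("need >= 2 genes")
  if (ncol(v) < 3) stop("insufficient data: need >= 3 samples")
  pair_sd <- matrix(0, G, G, dimnames = list(rownames(v), rownames(v)))
  for (j in seq_len(G - 1)) {
    for (k in (j + 1):G) {
      s <- stats::sd(v[j, ] - v[k, ])
      pair_sd[j, k] <- pair_sd[k, j] <- s
    }
  }
  score <- rowSums(pair_sd) / (G - 1)
  data.frame(gene = rownames(v),
             mean_pair_sd = unname(score),
             rank = .rank_first(score),
             stringsAsFactors = FALSE)
}

# Competition-free integer ranks, ties broken by position (input order).
.rank_first <- function(x) as.integer(rank(x, ties.method = "first"))
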