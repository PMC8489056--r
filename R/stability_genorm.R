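#' Transform Cq values to relative quantities
#'
#' For each gene, the sample with the minimum Cq is the calibrator with
#' relative quantity 1; every other sample gets
#' q = (1 + E/100)^(Cq_min - Cq), which for the default E = 100\% is the
#' familiar 2^-dCq transform. All quantities lie in (0, 1].
#'
#' @param m A complete \code{\link{cq_matrix}}.
#' @param efficiency Optional per-gene amplification efficiency in percent;
#'   a single value is recycled; a named vector is matched by gene.
#' @return Matrix of relative quantities (gene x sample).
#' @export
to_relative_quantities <- function(m, efficiency = 100) {
  v <- m$values
  if (anyNA(v)) stop("relative quantities require a complete matrix")
  if (any(efficiency <= 0)) stop("efficiency must be positive (percent)")
  eff <- rep(100, nrow(v))
  names(eff) <- rownames(v)
  if (!is.null(names(efficiency))) {
    unknown <- setdiff(names(efficiency), rownames(v))
    if (length(unknown) > 0) stop("efficiency for unknown genes: ",
                                  paste(unknown, collapse = ", "))
    eff[names(efficiency)] <- efficiency
  } else {
    eff[] <- efficiency
  }
  base <- 1 + eff / 100
  q <- base^(apply(v, 1, min) - v)     # rows recycle: (min_g - Cq_gs)
  dimnames(q) <- dimnames(v)
  q
}

#' geNorm M values (single pass)
#'
#' For each gene pair (j, k) the per-sample log2 expression ratio
#' A = log2(q_j / q_k) is formed; its SD across samples is the pair
#' variation V_jk. A gene's expression stability M is the arithmetic mean of
#' its pairwise variations with all other candidates; lower M means more
#' stable. M = 1.5 is the conventional ceiling for a usable reference gene.
#'
#' @param q Relative-quantity matrix from \code{\link{to_relative_quantities}}.
#' @return Data frame with columns \code{gene}, \code{M}, \code{rank},
#'   \code{stable} (full-panel M <= 1.5), and attribute \code{mode}
#'   \code{"single_pass"}.
#' @export
genorm_m_values <- function(q) {
  .check_q(q)
  G <- nrow(q)
  if (G < 3) stop("geNorm M needs >= 3 genes")
  if (ncol(q) < 3) stop("insufficient data: need >= 3 samples")
  lq <- log2(q)
  M <- vapply(seq_len(G), function(j) {
    vjk <- vapply(setdiff(seq_len(G), j), function(k) {
      stats::sd(lq[j, ] - lq[k, ])
    }, numeric(1))
    mean(vjk)
  }, numeric(1))
  out <- data.frame(gene = rownames(q), M = M, rank = .rank_first(M),
                    stable = M <= 1.5, stringsAsFactors = FALSE)
  attr(out, "mode") <- "single_pass"
  out
}

#' geNorm stepwise-exclusion ranking
#'
#' Classical geNorm ranking: M values are recomputed on the remaining panel
#' and the gene with the highest M is excluded, repeatedly, until two genes
#' remain; those two cannot be distinguished by the procedure and jointly
#' occupy the top of the ranking (both reported with rank 1.5). Each gene's
#' reported M is its value at the step where it was excluded (for the final
#' pair, the two-gene panel's common pair SD). A gene is flagged unstable if
#' its full-panel M exceeds 1.5.
#'
#' @inheritParams genorm_m_values
#' @return Data frame with columns \code{gene}, \code{M} (at exclusion),
#'   \code{rank} (final pair share 1.5), \code{exclusion_step},
#'   \code{stable}; attribute \code{mode} is \code{"stepwise"}.
#' @export
genorm_stepwise_ranking <- function(q) {
  .check_q(q)
  G <- nrow(q)
  if (G < 3) stop("stepwise geNorm needs >= 3 genes")
  full <- genorm_m_values(q)
  remaining <- rownames(q)
  M_at_exclusion <- stats::setNames(numeric(G), rownames(q))
  rank_out <- stats::setNames(numeric(G), rownames(q))
  step <- 0L
  step_out <- stats::setNames(integer(G), rownames(q))
  while (length(remaining) > 2) {
    step <- step + 1L
    Mr <- genorm_m_values(q[remaining, , drop = FALSE])
    # highest M leaves; ties resolved toward the later gene in input order
    worst_M <- max(Mr$M)
    worst <- Mr$gene[Mr$M == worst_M]
    worst <- worst[length(worst)]
    M_at_exclusion[worst] <- worst_M
    rank_out[worst] <- length(remaining)
    step_out[worst] <- step
    remaining <- setdiff(remaining, worst)
  }
  # the final pair: their mutual pair SD is the common M of the 2-gene panel
  final_M <- stats::sd(log2(q[remaining[1], ]) - log2(q[remaining[2], ]))
  M_at_exclusion[remaining] <- final_M
  rank_out[remaining] <- 1.5
  step_out[remaining] <- step + 1L
  out <- data.frame(
    gene = rownames(q),
    M = unname(M_at_exclusion[rownames(q)]),
    rank = unname(rank_out[rownames(q)]),
    exclusion_step = unname(step_out[rownames(q)]),
    stable = full$M <= 1.5,
    stringsAsFactors = FALSE
  )
  attr(out, "mode") <- "stepwise"
  out
}

#' Pairwise-variation curve and optimal number of reference genes
#'
#' Builds normalization factors NF_n (per-sample geometric mean of the
#' relative quantities of the top-n ranked genes) for n = 2..G, and the
#' pairwise variation V_n/n+1 = SD over samples of log2(NF_n / NF_n+1).
#' The optimal number of reference genes is the smallest n whose V falls
#' below the threshold (default 0.15); if none does, all G genes are
#' recommended.
#'
#' @inheritParams genorm_m_values
#' @param ranking Character vector of genes ordered most to least stable
#'   (e.g. from \code{\link{genorm_stepwise_ranking}}); default orders by
#'   single-pass M.
#' @param threshold Pairwise-variation cutoff below which adding another
#'   reference gene is unnecessary.
#' @return List with \code{n} (vector of n), \code{V} (V_n/n+1 for each n),
#'   \code{threshold}, \code{optimal_n}, \code{ranking}.
#' @export
pairwise_variation_curve <- function(q, ranking = NULL, threshold = 0.15) {
  .check_q(q)
  G <- nrow(q)
  if (G < 3) stop("pairwise variation needs >= 3 genes")
  if (is.null(ranking)) {
    mm <- genorm_m_values(q)
    ranking <- mm$gene[order(mm$rank)]
  }
  if (!setequal(ranking, rownames(q)) && !all(ranking %in% rownames(q))) {
    stop("ranking must be a subset of the panel genes")
  }
  if (length(ranking) < 3) stop("ranking must cover >= 3 genes")
  lq <- log2(q[ranking, , drop = FALSE])
  nf_log2 <- function(n) colMeans(lq[seq_len(n), , drop = FALSE])
  ns <- 2:(length(ranking) - 1)
  V <- vapply(ns, function(n) {
    stats::sd(nf_log2(n) - nf_log2(n + 1))
  }, numeric(1))
  below <- ns[V < threshold]
  optimal_n <- if (length(below) > 0) min(below) else length(ranking)
  list(n = ns, V = V, threshold = threshold, optimal_n = optimal_n,
       ranking = ranking)
}

.check_q <- function(q) {
  if (!is.matrix(q)) stop("q must be a matrix of relative quantities")
  if (anyNA(q) || any(q <= 0)) stop("relative quantities must be positive and complete")
  invisible(TRUE)
}
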