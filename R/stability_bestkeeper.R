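#' BestKeeper index
#'
#' The per-sample geometric mean of the Cq values of all candidate genes.
#' Unlike the difference-based methods, BestKeeper works on raw Cq, so
#' covariation of a gene with the index (which tracks shared RNA loading) is
#' informative rather than removed.
#'
#' @param m A complete \code{\link{cq_matrix}} with all Cq > 0.
#' @return Named numeric vector, one index value (cycles) per sample.
#' @export
bestkeeper_index <- function(m) {
  v <- m$values
  if (anyNA(v)) stop("BestKeeper requires a complete matrix")
  if (any(v <= 0)) stop("Cq values must be positive")
  exp(colMeans(log(v)))
}

#' BestKeeper descriptive statistics and index correlations
#'
#' Per-gene descriptives of raw Cq (geometric and arithmetic mean, range,
#' dispersion, coefficient of variation), the Pearson correlation of each
#' gene with the BestKeeper index (with two-sided p-value), and the full
#' gene-by-gene Pearson correlation matrix. Genes are ranked by descending
#' correlation with the index. Dispersion defaults to the mean absolute
#' deviation from the arithmetic mean (BestKeeper's "SD (+- Cq)" is an
#' average deviation); \code{dispersion_mode = "sd"} uses the sample SD.
#' Genes with dispersion above 1 cycle are flagged inconsistent but never
#' excluded.
#'
#' @param m A complete \code{\link{cq_matrix}} with >= 3 samples.
#' @param dispersion_mode \code{"mad"} (mean absolute deviation, default) or
#'   \code{"sd"}.
#' @return List with \code{stats} (data frame: \code{gene}, \code{gm_cq},
#'   \code{am_cq}, \code{min_cq}, \code{max_cq}, \code{dispersion},
#'   \code{sd_cq}, \code{cv_percent}, \code{r_vs_index}, \code{p_vs_index},
#'   \code{rank}, \code{inconsistent}), \code{index} (per-sample),
#'   \code{cor_matrix} and \code{p_matrix} (gene x gene).
#' @export
bestkeeper_stats <- function(m, dispersion_mode = c("mad", "sd")) {
  dispersion_mode <- match.arg(dispersion_mode)
  v <- m$values
  if (anyNA(v)) stop("BestKeeper requires a complete matrix")
  if (ncol(v) < 3) stop("insufficient data: need >= 3 samples")
  idx <- bestkeeper_index(m)
  G <- nrow(v)
  am <- rowMeans(v)
  mad_cq <- rowMeans(abs(v - am))
  sd_cq <- apply(v, 1, stats::sd)
  disp <- if (dispersion_mode == "mad") mad_cq else sd_cq
  r_vs_index <- rep(NA_real_, G)
  p_vs_index <- rep(NA_real_, G)
  zero_var <- sd_cq == 0
  for (j in seq_len(G)) {
    if (zero_var[j] || stats::sd(idx) == 0) next
    ct <- stats::cor.test(v[j, ], idx)
    r_vs_index[j] <- unname(ct$estimate)
    p_vs_index[j] <- ct$p.value
  }
  # descending r; undefined r ranks last, ties by input order
  rank_key <- ifelse(is.na(r_vs_index), -Inf, r_vs_index)
  rnk <- .rank_first(-rank_key)
  stats_df <- data.frame(
    gene = rownames(v),
    gm_cq = exp(rowMeans(log(v))),
    am_cq = am,
    min_cq = apply(v, 1, min),
    max_cq = apply(v, 1, max),
    dispersion = disp,
    sd_cq = sd_cq,
    cv_percent = disp / am * 100,
    r_vs_index = r_vs_index,
    p_vs_index = p_vs_index,
    rank = rnk,
    inconsistent = disp > 1,
    r_undefined = zero_var,
    stringsAsFactors = FALSE
  )
  cor_m <- matrix(NA_real_, G, G, dimnames = list(rownames(v), rownames(v)))
  p_m <- cor_m
  for (j in seq_len(G)) {
    cor_m[j, j] <- 1
    p_m[j, j] <- 0
    if (j == G) break
    for (k in (j + 1):G) {
      if (zero_var[j] || zero_var[k]) next
      ct <- stats::cor.test(v[j, ], v[k, ])
      cor_m[j, k] <- cor_m[k, j] <- unname(ct$estimate)
      p_m[j, k] <- p_m[k, j] <- ct$p.value
    }
  }
  list(stats = stats_df, index = idx, cor_matrix = cor_m, p_matrix = p_m,
       dispersion_mode = dispersion_mode)
}
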