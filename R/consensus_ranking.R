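#' Aggregate method-specific rankings into a consensus
#'
#' Comprehensive ranking in the RefFinder spirit: each method contributes a
#' rank per gene (ties as average ranks) and genes are ordered by the
#' unweighted geometric mean of their ranks across methods; the lowest
#' geometric mean is the most stable gene.
#'
#' @param rankings Named list, one element per method. Each element is
#'   either a numeric vector of ranks named by gene (average ranks allowed)
#'   or a character vector of genes ordered most to least stable.
#' @return Data frame with columns \code{gene}, one \code{rank_<method>}
#'   column per method, \code{geomean_rank} and \code{final_rank}, ordered by
#'   the gene order of the first method. Final-rank ties break by input
#'   order.
#' @export
aggregate_rankings <- function(rankings) {
  if (length(rankings) < 1) stop("need at least one ranking")
  if (is.null(names(rankings)) || any(names(rankings) == "")) {
    stop("rankings must be a named list (method names)")
  }
  as_rank_vec <- function(r) {
    if (is.character(r)) {
      stats::setNames(seq_along(r), r)
    } else {
      if (is.null(names(r))) stop("numeric rankings must be named by gene")
      r
    }
  }
  rank_vecs <- lapply(rankings, as_rank_vec)
  genes <- names(rank_vecs[[1]])
  for (nm in names(rank_vecs)) {
    missing_genes <- setdiff(genes, names(rank_vecs[[nm]]))
    extra <- setdiff(names(rank_vecs[[nm]]), genes)
    if (length(missing_genes) > 0 || length(extra) > 0) {
      stop("method '", nm, "' does not rank the same gene set")
    }
  }
  rank_mat <- vapply(rank_vecs, function(r) unname(r[genes]),
                     numeric(length(genes)))
  if (is.null(dim(rank_mat))) rank_mat <- matrix(rank_mat, nrow = length(genes))
  geo <- exp(rowMeans(log(rank_mat)))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (i in seq_along(rank_vecs)) {
    out[[paste0("rank_", names(rank_vecs)[i])]] <- rank_mat[, i]
  }
  out$geomean_rank <- geo
  out$final_rank <- .rank_first(geo)
  out
}

#' Average ranks for an ordered gene list with ties
#'
#' Converts a stability metric into average ranks (ascending: smaller metric
#' = better rank); tied metric values share the mean of the positions they
#' occupy, the convention used when feeding method rankings into
#' \code{\link{aggregate_rankings}}.
#'
#' @param metric Numeric vector of per-gene stability metrics, named by gene.
#' @param descending Rank larger values first (e.g. BestKeeper's r).
#' @return Named numeric vector of (possibly fractional) ranks.
#' @export
average_ranks <- function(metric, descending = FALSE) {
  if (is.null(names(metric))) stop("metric must be named by gene")
  r <- rank(if (descending) -metric else metric, ties.method = "average")
  stats::setNames(as.numeric(r), names(metric))
}
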