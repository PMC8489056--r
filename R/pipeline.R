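#' Run the full reference-gene stability pipeline
#'
#' Collapses technical replicates, takes the complete-case submatrix, runs
#' the four stability algorithms (comparative delta-Cq, geNorm single-pass
#' and stepwise, NormFinder, BestKeeper), aggregates them into a consensus
#' ranking, and computes the geNorm pairwise-variation curve with the
#' optimal number of reference genes.
#'
#' @param cq Either a path to a long-layout Cq CSV or a data frame of raw
#'   Cq records (see \code{\link{read_cq_table}}), or an already-collapsed
#'   \code{\link{cq_matrix}}.
#' @param meta Either a path to a metadata CSV, a metadata data frame, or
#'   \code{NULL} (single group).
#' @param outlier_range Technical-replicate range flag threshold, cycles.
#' @param efficiency Optional per-gene efficiencies (percent) for the
#'   relative-quantity transform.
#' @param v_threshold Pairwise-variation cutoff for the optimal reference
#'   number.
#' @param dispersion_mode BestKeeper dispersion mode, \code{"mad"} or
#'   \code{"sd"}.
#' @return Object of class \code{stability_report}: list with elements
#'   \code{matrix} (the complete-case \code{cq_matrix}), \code{deltacq},
#'   \code{genorm} (single-pass), \code{genorm_stepwise},
#'   \code{normfinder}, \code{bestkeeper}, \code{consensus},
#'   \code{v_curve}, \code{provenance}.
#' @export
run_stability_pipeline <- function(cq, meta = NULL, outlier_range = 0.5,
                                   efficiency = 100, v_threshold = 0.15,
                                   dispersion_mode = "mad") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  if (inherits(cq, "cq_matrix")) {
    m <- cq
  } else {
    records <- stage("read", {
      if (is.character(cq)) read_cq_table(cq, layout = "long") else cq
    })
    meta_df <- stage("metadata", {
      if (is.character(meta)) read_sample_meta(meta) else meta
    })
    m <- stage("collapse", collapse_replicates(records, outlier_range,
                                               meta = meta_df))
  }
  mc <- stage("complete_cases", complete_case_submatrix(m))
  deltacq <- stage("deltacq", delta_cq_stability(mc))
  q <- stage("relative_quantities", to_relative_quantities(mc, efficiency))
  genorm <- stage("genorm", genorm_m_values(q))
  genorm_step <- stage("genorm_stepwise", genorm_stepwise_ranking(q))
  grouped <- length(unique(mc$meta$group)) > 1 &&
    all(table(mc$meta$group) >= 2)
  normfinder <- stage("normfinder", normfinder_stability(mc, grouped = grouped))
  bestkeeper <- stage("bestkeeper", bestkeeper_stats(mc, dispersion_mode))
  consensus <- stage("consensus", aggregate_rankings(list(
    deltacq = average_ranks(stats::setNames(deltacq$mean_pair_sd, deltacq$gene)),
    genorm = average_ranks(stats::setNames(genorm$M, genorm$gene)),
    normfinder = average_ranks(stats::setNames(normfinder$SV, normfinder$gene)),
    bestkeeper = average_ranks(stats::setNames(bestkeeper$stats$r_vs_index,
                                               bestkeeper$stats$gene),
                               descending = TRUE)
  )))
  step_order <- genorm_step$gene[order(genorm_step$rank, genorm_step$gene)]
  v_curve <- stage("v_curve", pairwise_variation_curve(q, ranking = step_order,
                                                      threshold = v_threshold))
  out <- list(matrix = mc, deltacq = deltacq, genorm = genorm,
              genorm_stepwise = genorm_step, normfinder = normfinder,
              bestkeeper = bestkeeper, consensus = consensus,
              v_curve = v_curve,
              provenance = list(
                n_genes = nrow(mc$values), n_samples = ncol(mc$values),
                dropped_samples = attr(mc, "dropped_samples"),
                groups = unique(mc$meta$group), grouped = grouped,
                efficiency = efficiency, v_threshold = v_threshold,
                dispersion_mode = dispersion_mode,
                package_version = as.character(utils::packageVersion("refstab"))))
  class(out) <- "stability_report"
  out
}

#' Combined four-method stability table
#'
#' One row per gene with each method's metric and rank plus the consensus,
#' the layout reference-gene studies print.
#'
#' @param report A \code{stability_report}.
#' @return Data frame with columns \code{gene}, \code{deltacq_sd},
#'   \code{deltacq_rank}, \code{genorm_M}, \code{genorm_rank},
#'   \code{normfinder_SV}, \code{normfinder_rank}, \code{bestkeeper_r},
#'   \code{bestkeeper_rank}, \code{geomean_rank}, \code{final_rank},
#'   ordered by consensus rank.
#' @export
stability_table <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  g <- report$consensus$gene
  bk <- report$bestkeeper$stats
  df <- data.frame(
    gene = g,
    deltacq_sd = report$deltacq$mean_pair_sd[match(g, report$deltacq$gene)],
    deltacq_rank = report$deltacq$rank[match(g, report$deltacq$gene)],
    genorm_M = report$genorm$M[match(g, report$genorm$gene)],
    genorm_rank = report$genorm$rank[match(g, report$genorm$gene)],
    normfinder_SV = report$normfinder$SV[match(g, report$normfinder$gene)],
    normfinder_rank = report$normfinder$rank[match(g, report$normfinder$gene)],
    bestkeeper_r = bk$r_vs_index[match(g, bk$gene)],
    bestkeeper_rank = bk$rank[match(g, bk$gene)],
    geomean_rank = report$consensus$geomean_rank,
    final_rank = report$consensus$final_rank,
    stringsAsFactors = FALSE
  )
  df[order(df$final_rank), , drop = FALSE]
}

#' @export
print.stability_report <- function(x, ...) {
  p <- x$provenance
  cat("Reference-gene stability report: ", p$n_genes, " genes x ",
      p$n_samples, " samples (", length(p$groups), " group(s), ",
      p$dropped_samples, " incomplete sample(s) dropped)\n\n", sep = "")
  tab <- stability_table(x)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(col) round(col, 3))
  print(tab, row.names = FALSE)
  cat("\nPairwise variation: ",
      paste(sprintf("V%d/%d=%.3f", x$v_curve$n, x$v_curve$n + 1,
                    x$v_curve$V), collapse = "  "),
      "\nOptimal number of reference genes: ", x$v_curve$optimal_n,
      " (threshold ", x$v_curve$threshold, ")\n", sep = "")
  invisible(x)
}

#' Write a stability report to JSON
#'
#' Deterministic machine-readable surface of the pipeline (no timestamps):
#' the four method tables, consensus, pairwise-variation curve and
#' provenance.
#'
#' @param report A \code{stability_report}.
#' @param path Output JSON path.
#' @export
write_stability_report <- function(report, path) {
  stopifnot(inherits(report, "stability_report"))
  payload <- list(
    table = stability_table(report),
    genorm_stepwise = report$genorm_stepwise,
    bestkeeper = report$bestkeeper$stats,
    v_curve = report$v_curve[c("n", "V", "threshold", "optimal_n", "ranking")],
    provenance = report$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
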