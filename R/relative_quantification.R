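#' Per-sample reference Cq from one or more reference genes
#'
#' The per-sample arithmetic mean of the reference genes' Cq values —
#' equivalent, on the quantity scale, to the log2 of the geometric mean of
#' their relative quantities, the multi-gene normalization rule geNorm
#' recommends.
#'
#' @param m A \code{\link{cq_matrix}}.
#' @param reference_genes Character vector of reference gene names.
#' @return Named numeric vector of reference Cq per sample.
#' @export
reference_cq <- function(m, reference_genes) {
  if (length(reference_genes) == 0) stop("empty reference gene set")
  unknown <- setdiff(reference_genes, rownames(m$values))
  if (length(unknown) > 0) stop("unknown reference genes: ",
                                paste(unknown, collapse = ", "))
  v <- m$values[reference_genes, , drop = FALSE]
  if (anyNA(v)) stop("reference genes must be complete across samples")
  colMeans(v)
}

#' 2^-ddCq fold changes
#'
#' Livak relative quantification: per sample, dCq = target Cq - reference
#' Cq; fold change = 2^-(dCq - dCq_calibrator). The calibrator may be a
#' single sample or a group (its dCq is then the mean over the group's
#' samples), or a fixed dCq value supplied directly via
#' \code{calibrator_dcq} — the mechanism behind a calibrator shared across
#' several target genes (e.g. every profile scaled to one target gene in one
#' stage).
#'
#' @param target_cq Named per-sample target Cq (cycles).
#' @param ref_cq Named per-sample reference Cq, same samples.
#' @param calibrator Sample id or group label identifying the calibrator.
#' @param groups Optional named vector mapping sample id to group label
#'   (required when \code{calibrator} is a group).
#' @param calibrator_dcq Optional numeric dCq to calibrate against,
#'   overriding \code{calibrator}.
#' @return Data frame with columns \code{sample}, \code{dcq},
#'   \code{fold_change}; attribute \code{calibrator_dcq}.
#' @export
ddcq_fold_change <- function(target_cq, ref_cq, calibrator = NULL,
                             groups = NULL, calibrator_dcq = NULL) {
  if (is.null(names(target_cq)) || is.null(names(ref_cq))) {
    stop("target_cq and ref_cq must be named by sample")
  }
  samples <- names(target_cq)
  if (!setequal(samples, names(ref_cq))) {
    stop("target and reference cover different samples")
  }
  dcq <- target_cq - ref_cq[samples]
  if (is.null(calibrator_dcq)) {
    if (is.null(calibrator)) stop("supply a calibrator sample/group or calibrator_dcq")
    if (calibrator %in% samples) {
      calibrator_dcq <- unname(dcq[calibrator])
    } else if (!is.null(groups) && calibrator %in% groups) {
      in_cal <- samples[groups[samples] == calibrator]
      if (length(in_cal) == 0) stop("calibrator group has no samples")
      calibrator_dcq <- mean(dcq[in_cal])
    } else {
      stop("calibrator '", calibrator, "' matches no sample or group")
    }
  }
  data.frame(sample = samples,
             dcq = unname(dcq),
             fold_change = 2^-(unname(dcq) - calibrator_dcq),
             stringsAsFactors = FALSE) -> out
  attr(out, "calibrator_dcq") <- calibrator_dcq
  out
}

#' Relative expression of target genes against a reference panel
#'
#' Convenience wrapper: computes 2^-ddCq fold changes for several target
#' genes normalized to a shared reference panel. With
#' \code{shared_calibrator = TRUE} all targets are scaled to the calibrator
#' dCq of the \emph{first} target (so cross-target comparisons share one
#' baseline, the convention used when several genes are plotted against one
#' gene's level in one condition); otherwise each target is scaled to its
#' own calibrator dCq.
#'
#' @param m A complete \code{\link{cq_matrix}} containing targets and
#'   references.
#' @param targets Character vector of target genes.
#' @param reference_genes Character vector of reference genes.
#' @param calibrator Sample id or group label.
#' @param shared_calibrator Scale every target to the first target's
#'   calibrator dCq.
#' @return Data frame with columns \code{target}, \code{sample},
#'   \code{group}, \code{fold_change}.
#' @export
relative_expression <- function(m, targets, reference_genes, calibrator,
                                shared_calibrator = FALSE) {
  unknown <- setdiff(targets, rownames(m$values))
  if (length(unknown) > 0) stop("unknown targets: ", paste(unknown, collapse = ", "))
  refs <- reference_cq(m, reference_genes)
  groups <- stats::setNames(m$meta$group, m$meta$sample_id)
  shared_dcq <- NULL
  res <- lapply(targets, function(tg) {
    tcq <- m$values[tg, ]
    ft <- ddcq_fold_change(tcq, refs, calibrator = calibrator, groups = groups,
                           calibrator_dcq = shared_dcq)
    if (shared_calibrator && is.null(shared_dcq)) {
      shared_dcq <<- attr(ft, "calibrator_dcq")
    }
    data.frame(target = tg, sample = ft$sample,
               group = unname(groups[ft$sample]),
               fold_change = ft$fold_change, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Between-run (between-plate) correction of quantities
#'
#' Removes plate-to-plate scale shifts using calibrator samples measured on
#' every plate: each plate's factor is the geometric mean of its calibrator
#' quantities divided by the geometric mean of the calibrator quantities
#' over all plates; factors are renormalized to unit geometric mean and each
#' quantity is divided by its plate's factor.
#'
#' @param quantities Data frame with columns \code{sample}, \code{plate},
#'   \code{quantity} (positive, linear scale).
#' @param calibrator_samples Sample ids present on every plate.
#' @return List with \code{factors} (data frame \code{plate}, \code{factor})
#'   and \code{corrected} (input data frame with a \code{corrected} column).
#' @export
between_run_correction <- function(quantities, calibrator_samples) {
  stopifnot(all(c("sample", "plate", "quantity") %in% names(quantities)))
  if (any(quantities$quantity <= 0)) stop("quantities must be positive")
  plates <- unique(quantities$plate)
  cal <- quantities[quantities$sample %in% calibrator_samples, , drop = FALSE]
  for (p in plates) {
    have <- unique(cal$sample[cal$plate == p])
    miss <- setdiff(calibrator_samples, have)
    if (length(miss) > 0) {
      stop("plate '", p, "' is missing calibrator sample(s): ",
           paste(miss, collapse = ", "))
    }
  }
  gm <- function(x) exp(mean(log(x)))
  overall <- gm(cal$quantity)
  factors <- vapply(plates, function(p) gm(cal$quantity[cal$plate == p]) / overall,
                    numeric(1))
  factors <- factors / gm(factors)      # unit geometric mean over plates
  corrected <- quantities
  corrected$corrected <- quantities$quantity /
    factors[match(quantities$plate, plates)]
  list(factors = data.frame(plate = plates, factor = unname(factors),
                            stringsAsFactors = FALSE),
       corrected = corrected)
}
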