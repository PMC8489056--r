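# Sentinel strings that mean "no amplification" in exported Cq tables.
.cq_sentinels <- c("", "NA", "N/A", "Undetermined", "undetermined", "Undet.")

#' Read a table of raw Cq values
#'
#' Parses a CSV of quantification-cycle (Cq) values in either long or wide
#' layout into a data frame of raw Cq records, one row per technical
#' replicate. Empty cells and instrument sentinels ("Undetermined", "NA")
#' become missing Cq values (no amplification), flagged in the
#' \code{no_amplification} column.
#'
#' @param path Path to a CSV file (UTF-8, "." decimal separator).
#' @param layout Either \code{"long"} (columns \code{sample,gene,rep,plate,Cq};
#'   \code{rep} and \code{plate} optional) or \code{"wide"} (first column
#'   \code{sample}, one column per gene; technical replicates as repeated
#'   sample rows).
#' @return A data frame with columns \code{sample_id}, \code{gene},
#'   \code{technical_rep}, \code{plate}, \code{Cq}, \code{no_amplification}.
#' @export
read_cq_table <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop("Cq table not found: ", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (layout == "long") {
    required <- c("sample", "gene", "Cq")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      stop("long layout requires columns ", paste(missing_cols, collapse = ", "))
    }
    rep_col <- if ("rep" %in% names(raw)) as.integer(raw$rep) else
      stats::ave(seq_len(nrow(raw)), raw$sample, raw$gene, FUN = seq_along)
    plate_col <- if ("plate" %in% names(raw)) raw$plate else "plate1"
    rec <- data.frame(
      sample_id = raw$sample,
      gene = raw$gene,
      technical_rep = rep_col,
      plate = plate_col,
      Cq = .parse_cq(raw$Cq, rows = seq_len(nrow(raw)), column = "Cq"),
      stringsAsFactors = FALSE
    )
  } else {
    if (names(raw)[1] != "sample") {
      stop("wide layout requires first column 'sample'")
    }
    genes <- names(raw)[-1]
    if (length(genes) == 0) stop("wide layout has no gene columns")
    rep_idx <- stats::ave(seq_len(nrow(raw)), raw$sample, FUN = seq_along)
    rec_list <- lapply(genes, function(g) {
      data.frame(
        sample_id = raw$sample,
        gene = g,
        technical_rep = rep_idx,
        plate = "plate1",
        Cq = .parse_cq(raw[[g]], rows = seq_len(nrow(raw)), column = g),
        stringsAsFactors = FALSE
      )
    })
    rec <- do.call(rbind, rec_list)
  }
  rec$no_amplification <- is.na(rec$Cq)
  key <- paste(rec$sample_id, rec$gene, rec$technical_rep, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- rec[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate (sample, gene, technical_rep): (",
         dup$sample_id, ", ", dup$gene, ", ", dup$technical_rep, ")")
  }
  bad <- !is.na(rec$Cq) & (!is.finite(rec$Cq) | rec$Cq <= 0)
  if (any(bad)) {
    stop("non-positive or non-finite Cq for (",
         rec$sample_id[bad][1], ", ", rec$gene[bad][1], ")")
  }
  rownames(rec) <- NULL
  rec
}

.parse_cq <- function(x, rows, column) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  keep <- !(x %in% .cq_sentinels) & !is.na(x)
  suppressWarnings(vals <- as.numeric(x[keep]))
  if (anyNA(vals)) {
    bad_row <- rows[keep][which(is.na(vals))[1]]
    stop("malformed numeric Cq cell at data row ", bad_row,
         ", column '", column, "': \"", x[keep][which(is.na(vals))[1]], "\"")
  }
  out[keep] <- vals
  out
}

#' Read sample metadata
#'
#' @param path CSV with columns \code{sample,group,biological_rep}.
#' @return Data frame with columns \code{sample_id}, \code{group},
#'   \code{biological_rep}.
#' @export
read_sample_meta <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample", "group", "biological_rep")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("metadata requires columns ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$sample)) {
    stop("duplicated sample_id in metadata: ", raw$sample[duplicated(raw$sample)][1])
  }
  data.frame(sample_id = raw$sample, group = raw$group,
             biological_rep = as.integer(raw$biological_rep),
             stringsAsFactors = FALSE)
}

#' Construct a Cq matrix object
#'
#' A \code{cq_matrix} holds technical-replicate-collapsed Cq values as a
#' gene-by-sample matrix plus sample metadata and per-cell quality flags.
#'
#' @param values Numeric gene-by-sample matrix of Cq values (cycles); rows
#'   named by gene, columns by sample_id. \code{NA} marks no amplification.
#' @param meta Optional data frame with columns \code{sample_id},
#'   \code{group}, \code{biological_rep}; defaults to one group.
#' @param flags Optional logical matrix (same shape) marking cells whose
#'   technical replicates disagreed beyond the outlier range.
#' @param plate Optional character vector of plate labels per sample.
#' @return An object of class \code{cq_matrix}.
#' @export
cq_matrix <- function(values, meta = NULL, flags = NULL, plate = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated gene labels")
  if (anyDuplicated(colnames(values))) stop("duplicated sample labels")
  if (any(!is.na(values) & (!is.finite(values) | values <= 0))) {
    stop("Cq values must be finite and > 0 (or NA for no amplification)")
  }
  if (is.null(meta)) {
    meta <- data.frame(sample_id = colnames(values), group = "all",
                       biological_rep = seq_len(ncol(values)),
                       stringsAsFactors = FALSE)
  }
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta) > 0) {
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(flags)) {
    flags <- matrix(FALSE, nrow(values), ncol(values),
                    dimnames = dimnames(values))
  }
  structure(list(values = values, meta = meta, flags = flags, plate = plate),
            class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat("cq_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples, ", length(unique(x$meta$group)), " group(s)\n", sep = "")
  cat("genes: ", paste(rownames(x$values), collapse = ", "), "\n", sep = "")
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat("missing cells: ", n_na, "\n", sep = "")
  n_flag <- sum(x$flags)
  if (n_flag > 0) cat("replicate-discordant cells: ", n_flag, "\n", sep = "")
  invisible(x)
}

#' @export
dim.cq_matrix <- function(x) dim(x$values)

#' Collapse technical replicates into a Cq matrix
#'
#' Each (gene, sample) cell becomes the arithmetic mean of its non-missing
#' technical-replicate Cq values (Cq is already log-scale, so the arithmetic
#' mean is the scale-appropriate average). Cells whose replicate range exceeds
#' \code{outlier_range} are flagged, never dropped; cells with no surviving
#' replicate are missing.
#'
#' @param records Data frame as returned by \code{\link{read_cq_table}}.
#' @param outlier_range Maximum tolerated within-cell replicate range, cycles.
#' @param meta Optional sample metadata (see \code{\link{cq_matrix}}).
#' @return A \code{\link{cq_matrix}}.
#' @export
collapse_replicates <- function(records, outlier_range = 0.5, meta = NULL) {
  genes <- unique(records$gene)
  samples <- unique(records$sample_id)
  values <- matrix(NA_real_, length(genes), length(samples),
                   dimnames = list(genes, samples))
  flags <- matrix(FALSE, length(genes), length(samples),
                  dimnames = list(genes, samples))
  split_idx <- split(seq_len(nrow(records)),
                     list(gene = factor(records$gene, genes),
                          sample = factor(records$sample_id, samples)),
                     drop = TRUE)
  for (idx in split_idx) {
    cq <- records$Cq[idx]
    cq <- cq[!is.na(cq)]
    g <- records$gene[idx[1]]
    s <- records$sample_id[idx[1]]
    if (length(cq) == 0) next
    values[g, s] <- mean(cq)
    if (length(cq) >= 2 && diff(range(cq)) > outlier_range) {
      flags[g, s] <- TRUE
    }
  }
  plate <- vapply(samples, function(s) {
    records$plate[records$sample_id == s][1]
  }, character(1))
  cq_matrix(values, meta = meta, flags = flags, plate = unname(plate))
}

#' Restrict a Cq matrix to complete cases
#'
#' Returns the matrix restricted to the requested genes and to samples with
#' no missing value in any of them. The number of dropped samples is stored
#' in the \code{"dropped_samples"} attribute.
#'
#' @param m A \code{\link{cq_matrix}}.
#' @param genes Genes to retain (default all).
#' @return A complete \code{\link{cq_matrix}}.
#' @export
complete_case_submatrix <- function(m, genes = rownames(m$values)) {
  unknown <- setdiff(genes, rownames(m$values))
  if (length(unknown) > 0) {
    stop("unknown genes: ", paste(unknown, collapse = ", "))
  }
  v <- m$values[genes, , drop = FALSE]
  keep <- colSums(is.na(v)) == 0
  if (sum(keep) < 3) {
    stop("insufficient data: only ", sum(keep),
         " complete samples for the requested genes (need >= 3)")
  }
  out <- cq_matrix(v[, keep, drop = FALSE],
                   meta = m$meta[keep, , drop = FALSE],
                   flags = m$flags[genes, keep, drop = FALSE],
                   plate = if (!is.null(m$plate)) m$plate[keep] else NULL)
  attr(out, "dropped_samples") <- sum(!keep)
  out
}

#' Write a Cq matrix in long CSV layout
#'
#' Inverse of \code{read_cq_table(..., layout = "long")} followed by
#' \code{collapse_replicates} on already-collapsed data: one row per
#' (sample, gene) cell with \code{rep = 1}.
#'
#' @param m A \code{\link{cq_matrix}}.
#' @param path Output CSV path.
#' @export
write_cq_table <- function(m, path) {
  long <- expand.grid(gene = rownames(m$values), sample = colnames(m$values),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long <- long[order(match(long$sample, colnames(m$values)),
                     match(long$gene, rownames(m$values))), ]
  df <- data.frame(sample = long$sample, gene = long$gene, rep = 1L,
                   plate = if (is.null(m$plate)) "plate1" else
                     m$plate[match(long$sample, colnames(m$values))],
                   Cq = m$values[cbind(long$gene, long$sample)],
                   stringsAsFactors = FALSE)
  # full precision so a write/read round trip is bit-exact
  df$Cq <- sprintf("%.17g", df$Cq)
  df$Cq[df$Cq == "NA"] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
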