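#' Amplification efficiency from a standard-curve slope
#'
#' Converts the slope of a Cq-versus-log10(template amount) regression into
#' percent amplification efficiency, E\% = (10^(-1/slope) - 1) * 100. A
#' perfectly doubling assay has slope -3.3219 and E = 100\%.
#'
#' @param slope Regression slope, cycles per log10 dilution step.
#' @return Efficiency in percent.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.finite(slope) || slope == 0) {
    stop("slope must be finite and non-zero")
  }
  (10^(-1 / slope) - 1) * 100
}

#' Fit a dilution-series standard curve
#'
#' Ordinary least squares of Cq on log10(relative template amount). By
#' default replicate Cq values are averaged per dilution level before the
#' regression; \code{pooled = TRUE} regresses on all replicate points.
#'
#' @param series Data frame with columns \code{relative_amount} (positive)
#'   and \code{Cq}; optionally \code{gene} and \code{rep}.
#' @param pooled Regress on individual replicates instead of level means.
#' @return An object of class \code{standard_curve_fit} with elements
#'   \code{gene}, \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{efficiency_percent}, \code{n_levels}, \code{positive_slope_flag}.
#' @export
fit_standard_curve <- function(series, pooled = FALSE) {
  stopifnot(is.data.frame(series),
            all(c("relative_amount", "Cq") %in% names(series)))
  series <- series[!is.na(series$Cq), , drop = FALSE]
  if (any(series$relative_amount <= 0)) {
    stop("relative amounts must be positive")
  }
  levels_present <- unique(series$relative_amount)
  if (length(levels_present) < 3) {
    stop("need >= 3 distinct dilution levels with data, got ",
         length(levels_present))
  }
  if (length(levels_present) < 2) stop("rank-deficient dilution design")
  if (pooled) {
    df <- data.frame(x = log10(series$relative_amount), y = series$Cq)
  } else {
    agg <- stats::aggregate(Cq ~ relative_amount, data = series, FUN = mean)
    df <- data.frame(x = log10(agg$relative_amount), y = agg$Cq)
  }
  fit <- stats::lm(y ~ x, data = df)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless fits are legitimate here
  if (!is.finite(slope)) stop("rank-deficient dilution design")
  out <- list(
    gene = if ("gene" %in% names(series)) series$gene[1] else NA_character_,
    slope = slope,
    intercept = intercept,
    r_squared = r2,
    efficiency_percent = efficiency_from_slope(slope),
    n_levels = length(levels_present),
    positive_slope_flag = slope > 0
  )
  if (out$positive_slope_flag) {
    warning("positive standard-curve slope; check dilution orientation")
  }
  class(out) <- "standard_curve_fit"
  out
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat("standard curve", if (!is.na(x$gene)) paste0(" [", x$gene, "]"), ":\n",
      sep = "")
  cat(sprintf("  slope %.4f  intercept %.4f  R^2 %.4f  E %.2f%%\n",
              x$slope, x$intercept, x$r_squared, x$efficiency_percent))
  invisible(x)
}

#' Read a dilution-series CSV
#'
#' @param path CSV with columns \code{gene,relative_amount,rep,Cq}.
#' @return Data frame of dilution points.
#' @export
read_dilution_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("gene", "relative_amount", "Cq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("dilution CSV requires columns ", paste(missing_cols, collapse = ", "))
  }
  df
}
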