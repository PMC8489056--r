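#' NormFinder model-based stability
#'
#' Decomposes each candidate gene's variation into an intragroup variance and
#' a (shrunken) intergroup deviation and combines the two into a stability
#' value SV; lower SV means more stable. The algorithm operates on log2
#' expression x = -Cq, to which it is equivalent for any per-gene affine
#' recoding of the input (so working on -Cq, on 2^-dCq or on 2^dCq gives
#' identical SV values).
#'
#' Steps, with G genes, K groups, n_g samples in group g:
#' \enumerate{
#'   \item sample-center: z = x minus the per-sample mean over genes
#'     (removes shared loading effects);
#'   \item per gene x group, the interaction deviation \code{d_ig} (group
#'     mean of z, centered within gene across groups) and variance
#'     \code{s2_ig};
#'   \item intragroup variance
#'     \code{sigma2_ig = max(0, (s2_ig - sum_i' s2_i'g / (G^2 (1 - 1/G))) / (1 - 2/G))}
#'     (the correction undoes the contraction that centering over a finite
#'     gene panel induces);
#'   \item common intergroup variance
#'     \code{gamma2 = max(0, sum d_ig^2 / ((G-1)(K-1)) - mean(sigma2_ig / n_g) / 1)}
#'     with the mean taken over all (i, g);
#'   \item shrunken deviations
#'     \code{d_ig_tilde = d_ig * gamma2 / (gamma2 + sigma2_ig / n_g)};
#'   \item \code{SV_i = mean over g of (|d_ig_tilde| + sqrt(sigma2_ig / n_g))}.
#' }
#' With a single group (K = 1) steps 4-5 are skipped and
#' \code{SV_i = sqrt(sigma2_i)}.
#'
#' @param m A complete \code{\link{cq_matrix}} with >= 3 genes; its metadata
#'   \code{group} column defines the groups (every group needs >= 2 samples).
#' @param grouped Set \code{FALSE} to ignore groups (single-group mode).
#' @return Data frame with columns \code{gene}, \code{SV}, \code{rank};
#'   attributes \code{intragroup_var} (gene x group matrix),
#'   \code{intergroup_dev} (shrunken d, gene x group), \code{gamma2}.
#' @export
normfinder_stability <- function(m, grouped = TRUE) {
  v <- m$values
  if (anyNA(v)) stop("NormFinder requires a complete matrix")
  G <- nrow(v)
  if (G < 3) stop("insufficient genes: NormFinder's variance correction needs >= 3")
  groups <- if (grouped) m$meta$group else rep("all", ncol(v))
  glev <- unique(groups)
  K <- length(glev)
  n_g <- table(factor(groups, glev))
  if (any(n_g < 2)) {
    stop("insufficient replication: every group needs >= 2 samples")
  }
  x <- -v                                  # log2 expression scale
  z <- sweep(x, 2, colMeans(x))            # remove per-sample loading
  d_hat <- matrix(0, G, K, dimnames = list(rownames(v), glev))
  s2 <- matrix(0, G, K, dimnames = list(rownames(v), glev))
  for (g in seq_len(K)) {
    zg <- z[, groups == glev[g], drop = FALSE]
    d_hat[, g] <- rowMeans(zg)
    s2[, g] <- apply(zg, 1, stats::var)
  }
  # group deviations are gene x group interaction residuals: remove each
  # gene's own mean so per-gene baselines (and constant recodings) cancel
  d_hat <- d_hat - rowMeans(d_hat)
  # step 3: undo the gene-centering contraction, floor at zero
  sigma2 <- sweep(s2, 2, colSums(s2) / (G^2 * (1 - 1 / G)))
  sigma2 <- pmax(sigma2 / (1 - 2 / G), 0)

  if (K == 1) {
    SV <- sqrt(sigma2[, 1])
    out <- data.frame(gene = rownames(v), SV = unname(SV),
                      rank = .rank_first(SV), stringsAsFactors = FALSE)
    attr(out, "intragroup_var") <- sigma2
    attr(out, "intergroup_dev") <- d_hat
    attr(out, "gamma2") <- NA_real_
    return(out)
  }
  se2 <- sweep(sigma2, 2, as.numeric(n_g), "/")   # sigma2_ig / n_g
  gamma2 <- max(0, sum(d_hat^2) / ((G - 1) * (K - 1)) - sum(se2) / (G * K))
  d_tilde <- d_hat * gamma2 / (gamma2 + se2)
  SV <- rowMeans(abs(d_tilde) + sqrt(se2))
  out <- data.frame(gene = rownames(v), SV = unname(SV),
                    rank = .rank_first(SV), stringsAsFactors = FALSE)
  attr(out, "intragroup_var") <- sigma2
  attr(out, "intergroup_dev") <- d_tilde
  attr(out, "gamma2") <- gamma2
  out
}
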