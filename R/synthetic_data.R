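#' Simulation configuration for Cq datasets
#'
#' Describes the variance-component model the stability methods assume:
#' Cq for gene i, group g, biological sample j, technical replicate r is
#' \deqn{Cq = mu_i + L_{gj} + delta_{ig} + eta_{igj} + plate_{p} + eps_{igjr}}
#' with independent normal components: \code{delta ~ N(0, tau_i^2)} (gene-
#' specific group effect — biologically variable expression across stages),
#' \code{eta ~ N(0, sigma_i^2)} (sample-level biological noise),
#' \code{L ~ N(0, loading_sd^2)} (shared per-sample RNA loading),
#' \code{eps ~ N(0, tech_sd^2)} (technical replicate noise), and an optional
#' per-plate shift. A gene's true instability is
#' \code{sqrt(tau_i^2 + sigma_i^2)}.
#'
#' The default configuration mirrors a developmental-stage reference-gene
#' study: 7 candidate genes across 8 stage/sex groups with 3 biological and
#' 3 technical replicates, loading SD 0.5 cycles, technical SD 0.1 cycles,
#' and gene stabilities spanning 0.1 to 1.0 cycles.
#'
#' @param genes Data frame with columns \code{name}, \code{mu} (baseline
#'   Cq), \code{tau} (group-effect SD, cycles), \code{sigma} (sample-level
#'   SD, cycles).
#' @param groups Character vector of group labels.
#' @param n_per_group Biological replicates per group.
#' @param loading_sd Shared per-sample loading SD, cycles.
#' @param tech_sd Technical replicate SD, cycles.
#' @param tech_reps Technical replicates per (gene, sample).
#' @param plates Optional character vector assigning each biological sample
#'   (in group x replicate order) to a plate.
#' @param plate_shift_sd SD of per-plate Cq shifts, cycles.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(genes = NULL,
                       groups = c("N1", "N2m", "N2f", "N3m", "N3f", "N4m",
                                  "Am", "Af"),
                       n_per_group = 3,
                       loading_sd = 0.5,
                       tech_sd = 0.1,
                       tech_reps = 3,
                       plates = NULL,
                       plate_shift_sd = 0) {
  if (is.null(genes)) {
    stability <- seq(0.1, 1.0, length.out = 7)
    genes <- data.frame(
      name = paste0("g", 1:7),
      mu = seq(16, 22, length.out = 7),
      # split total stability evenly between group and sample components
      tau = stability / sqrt(2),
      sigma = stability / sqrt(2),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("name", "mu", "tau", "sigma") %in% names(genes)),
            all(genes$tau >= 0), all(genes$sigma >= 0),
            length(groups) >= 1, n_per_group >= 1,
            loading_sd >= 0, tech_sd >= 0, tech_reps >= 1,
            plate_shift_sd >= 0)
  if (anyDuplicated(genes$name)) stop("duplicated gene names")
  n_samples <- length(groups) * n_per_group
  if (!is.null(plates) && length(plates) != n_samples) {
    stop("plates must assign each of the ", n_samples, " samples")
  }
  structure(list(genes = genes, groups = groups, n_per_group = n_per_group,
                 loading_sd = loading_sd, tech_sd = tech_sd,
                 tech_reps = tech_reps, plates = plates,
                 plate_shift_sd = plate_shift_sd),
            class = "sim_config")
}

#' Generate a Cq dataset with known ground truth
#'
#' Draws a full technical-replicate-level Cq dataset from the variance-
#' component model of \code{\link{sim_config}}, together with the simulation
#' truth needed for recovery tests.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return List with \code{records} (raw Cq data frame as from
#'   \code{\link{read_cq_table}}), \code{meta} (sample metadata) and
#'   \code{truth} (list: \code{true_stability} named per gene,
#'   \code{ordering} most to least stable, \code{config}).
#' @export
generate_cq_dataset <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  rng <- .local_rng(seed)
  genes <- config$genes
  G <- nrow(genes)
  K <- length(config$groups)
  n <- config$n_per_group
  R <- config$tech_reps
  sample_grid <- expand.grid(biological_rep = seq_len(n),
                             group = config$groups,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sample_grid$sample_id <- paste0(sample_grid$group, "_b",
                                  sample_grid$biological_rep)
  S <- nrow(sample_grid)
  plates <- if (is.null(config$plates)) rep("plate1", S) else config$plates
  plate_levels <- unique(plates)
  plate_shift <- stats::setNames(
    rng(function() stats::rnorm(length(plate_levels), 0, config$plate_shift_sd)),
    plate_levels)
  L <- rng(function() stats::rnorm(S, 0, config$loading_sd))
  delta <- matrix(rng(function() stats::rnorm(G * K)), G, K) * genes$tau
  eta <- matrix(rng(function() stats::rnorm(G * S)), G, S) * genes$sigma
  grp_idx <- match(sample_grid$group, config$groups)
  cell <- genes$mu + delta[, grp_idx, drop = FALSE] + eta +
    matrix(L, G, S, byrow = TRUE) +
    matrix(plate_shift[plates], G, S, byrow = TRUE)
  eps <- array(rng(function() stats::rnorm(G * S * R, 0, config$tech_sd)),
               c(G, S, R))
  records <- do.call(rbind, lapply(seq_len(R), function(r) {
    data.frame(sample_id = rep(sample_grid$sample_id, each = G),
               gene = rep(genes$name, S),
               technical_rep = r,
               plate = rep(plates, each = G),
               Cq = as.vector(cell + eps[, , r]),
               stringsAsFactors = FALSE)
  }))
  records$no_amplification <- FALSE
  meta <- data.frame(sample_id = sample_grid$sample_id,
                     group = sample_grid$group,
                     biological_rep = sample_grid$biological_rep,
                     stringsAsFactors = FALSE)
  true_stability <- stats::setNames(sqrt(genes$tau^2 + genes$sigma^2),
                                    genes$name)
  ordering <- names(sort(true_stability))   # ties: sort() keeps name order
  list(records = records, meta = meta,
       truth = list(true_stability = true_stability, ordering = ordering,
                    loading = stats::setNames(L, sample_grid$sample_id),
                    config = config, seed = seed))
}

#' Generate a dilution-series Cq table with known efficiency
#'
#' Cq = cq_at_unity - log(amount) / log(1 + E/100) + normal noise; with
#' E = 100\% each halving of template raises Cq by exactly one cycle.
#'
#' @param gene Gene name.
#' @param true_efficiency_percent True amplification efficiency, percent.
#' @param cq_at_unity Cq at relative amount 1.
#' @param levels Relative template amounts (default the threefold series
#'   1/3, 1/9, ..., 1/6561).
#' @param reps Technical replicates per level.
#' @param noise_sd Normal noise SD on Cq, cycles.
#' @param seed Integer seed.
#' @return Data frame with columns \code{gene}, \code{relative_amount},
#'   \code{rep}, \code{Cq}.
#' @export
generate_dilution_series <- function(gene = "g1",
                                     true_efficiency_percent = 100,
                                     cq_at_unity = 15,
                                     levels = 1 / 3^(1:8),
                                     reps = 3,
                                     noise_sd = 0,
                                     seed = 1) {
  if (true_efficiency_percent <= 0) stop("efficiency must be positive")
  rng <- .local_rng(seed)
  base <- 1 + true_efficiency_percent / 100
  grid <- expand.grid(relative_amount = levels, rep = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE)
  noise <- rng(function() stats::rnorm(nrow(grid), 0, noise_sd))
  data.frame(gene = gene,
             relative_amount = grid$relative_amount,
             rep = grid$rep,
             Cq = cq_at_unity - log(grid$relative_amount) / log(base) + noise,
             stringsAsFactors = FALSE)
}

#' Inject a differentially expressed target gene into a simulated dataset
#'
#' Adds a target gene whose Cq is lowered by log2(fold) in each group
#' relative to its baseline, sharing the dataset's per-sample loading and
#' noise structure (loading is recovered from the existing records via the
#' per-sample mean residual, so reference-normalized fold changes are
#' recoverable).
#'
#' @param dataset Result of \code{\link{generate_cq_dataset}}.
#' @param name Target gene name.
#' @param fold_pattern Named positive vector: fold change per group (1 =
#'   baseline).
#' @param base_cq Target baseline Cq at fold 1.
#' @param sigma Sample-level biological SD of the target, cycles.
#' @param seed Integer seed for the target's own noise.
#' @return The dataset with the target appended to \code{records} and its
#'   true fold pattern recorded in \code{truth$target_folds[[name]]}.
#' @export
inject_target_gene <- function(dataset, name, fold_pattern, base_cq = 24,
                               sigma = 0.1, seed = 1) {
  cfg <- dataset$truth$config
  unknown <- setdiff(names(fold_pattern), cfg$groups)
  if (length(unknown) > 0) stop("unknown group(s): ", paste(unknown, collapse = ", "))
  if (any(fold_pattern <= 0)) stop("fold changes must be positive")
  folds <- stats::setNames(rep(1, length(cfg$groups)), cfg$groups)
  folds[names(fold_pattern)] <- fold_pattern
  rng <- .local_rng(seed)
  meta <- dataset$meta
  rec <- dataset$records
  # share the dataset's per-sample loading effect: take it from the truth if
  # recorded, else recover it as the mean Cq residual of the existing genes
  if (!is.null(dataset$truth$loading)) {
    loading <- dataset$truth$loading[meta$sample_id]
  } else {
    mu <- stats::setNames(cfg$genes$mu, cfg$genes$name)
    resid <- rec$Cq - mu[rec$gene]
    loading <- tapply(resid, rec$sample_id, mean)[meta$sample_id]
  }
  eta <- rng(function() stats::rnorm(nrow(meta), 0, sigma))
  cell <- base_cq - log2(folds[meta$group]) + as.numeric(loading) + eta
  R <- cfg$tech_reps
  eps <- matrix(rng(function() stats::rnorm(nrow(meta) * R, 0, cfg$tech_sd)),
                nrow(meta), R)
  plates <- rec$plate[match(meta$sample_id, rec$sample_id)]
  new_rec <- do.call(rbind, lapply(seq_len(R), function(r) {
    data.frame(sample_id = meta$sample_id, gene = name, technical_rep = r,
               plate = plates, Cq = cell + eps[, r],
               no_amplification = FALSE, stringsAsFactors = FALSE)
  }))
  dataset$records <- rbind(dataset$records, new_rec)
  dataset$truth$target_folds[[name]] <- folds
  dataset
}

# Runs draws under a private RNG stream so simulation never disturbs (or
# depends on) the caller's global random state beyond the given seed.
.local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  function(draw) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- draw()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out
  }
}
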