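test_that("relative-quantity transform anchors each gene's best sample at 1", {
  m <- cq_matrix(matrix(c(18, 20), 1, 2,
                        dimnames = list("g", c("s1", "s2"))))
  expect_equal(as.numeric(to_relative_quantities(m)), c(1, 0.25))
  expect_equal(to_relative_quantities(m, efficiency = 100),
               to_relative_quantities(m))
  # frozen from independent evaluation of 1.85^-2
  q85 <- to_relative_quantities(m, efficiency = 85)
  expect_equal(as.numeric(q85), c(1, 0.2921841), tolerance = 1e-6)
  expect_error(to_relative_quantities(m, efficiency = -5), "positive")

  ds <- generate_cq_dataset(sim_config(), seed = 2)
  mc <- complete_case_submatrix(collapse_replicates(ds$records, meta = ds$meta))
  q <- to_relative_quantities(mc)
  expect_true(all(q > 0 & q <= 1))
  expect_equal(unname(apply(q, 1, max)), rep(1, nrow(q)))
})

test_that("single-pass M matches hand computation and brute-force oracle", {
  # three pairwise-parallel genes: all log-ratios constant, M = 0
  v <- rbind(a = c(20, 21, 22), b = c(22, 23, 24), c = c(18, 19, 20))
  colnames(v) <- paste0("s", 1:3)
  expect_equal(genorm_m_values(to_relative_quantities(cq_matrix(v)))$M,
               rep(0, 3), tolerance = 1e-12)

  # the 3-gene fixture: log2 ratios differ from -dCq by a constant, so the
  # pair SDs coincide with the hand-computed dCq pair SDs
  q <- to_relative_quantities(abc_matrix())
  res <- genorm_m_values(q)
  expect_equal(res$M, c(0.5, 0.5, 1.0), tolerance = 1e-12)
  expect_equal(res$rank, c(1L, 2L, 3L))

  for (seed in 1:20) {
    m <- random_cq_matrix(G = 5, S = 8, seed = seed + 100)
    q <- to_relative_quantities(m)
    expect_equal(genorm_m_values(q)$M, brute_force_genorm_m(q),
                 tolerance = 1e-12)
  }
})

test_that("for G = 3, M is the mean of the gene's two pair SDs (closed form)", {
  for (seed in 1:10) {
    m <- random_cq_matrix(G = 3, S = 8, seed = seed)
    q <- to_relative_quantities(m)
    lq <- log2(q)
    pair_sd <- function(j, k) sd(lq[j, ] - lq[k, ])
    expected <- c(mean(c(pair_sd(1, 2), pair_sd(1, 3))),
                  mean(c(pair_sd(2, 1), pair_sd(2, 3))),
                  mean(c(pair_sd(3, 1), pair_sd(3, 2))))
    expect_equal(genorm_m_values(q)$M, expected, tolerance = 1e-12)
  }
})

test_that("geNorm quantities are exactly invariant to per-sample Cq shifts", {
  m <- random_cq_matrix(G = 5, S = 8, seed = 7)
  shift <- rnorm(8)
  m2 <- cq_matrix(sweep(m$values, 2, shift, "+"))
  q1 <- to_relative_quantities(m)
  q2 <- to_relative_quantities(m2)
  expect_equal(genorm_m_values(q2)$M, genorm_m_values(q1)$M, tolerance = 1e-10)
  r1 <- genorm_stepwise_ranking(q1)
  r2 <- genorm_stepwise_ranking(q2)
  expect_equal(r2$rank, r1$rank)
  v1 <- pairwise_variation_curve(q1)
  v2 <- pairwise_variation_curve(q2)
  expect_equal(v2$V, v1$V, tolerance = 1e-10)
})

test_that("stepwise exclusion matches a naive re-ranking oracle", {
  naive_stepwise_order <- function(q) {
    remaining <- rownames(q)
    excluded <- character(0)
    while (length(remaining) > 2) {
      M <- brute_force_genorm_m(q[remaining, , drop = FALSE])
      worst_idx <- which(M == max(M))
      worst <- remaining[worst_idx[length(worst_idx)]]
      excluded <- c(worst, excluded)
      remaining <- setdiff(remaining, worst)
    }
    c(sort(remaining), excluded)  # final pair first (alphabetical), then by stability
  }
  for (seed in 1:20) {
    m <- random_cq_matrix(G = 5, S = 8, seed = seed + 200)
    q <- to_relative_quantities(m)
    res <- genorm_stepwise_ranking(q)
    got_order <- res$gene[order(res$rank, res$gene)]
    expect_equal(got_order, naive_stepwise_order(q))
  }
})

test_that("stepwise exclusion removes a pure-noise gene first", {
  genes <- data.frame(name = paste0("g", 1:4),
                      mu = c(17, 18, 19, 20),
                      tau = c(0.02, 0.02, 0.02, 1.5),
                      sigma = c(0.02, 0.02, 0.02, 1.5))
  hits <- vapply(1:20, function(s) {
    ds <- generate_cq_dataset(sim_config(genes = genes), seed = s)
    mc <- complete_case_submatrix(collapse_replicates(ds$records,
                                                      meta = ds$meta))
    res <- genorm_stepwise_ranking(to_relative_quantities(mc))
    res$gene[res$exclusion_step == 1] == "g4"
  }, logical(1))
  expect_true(all(hits))
})

test_that("the final stepwise pair shares the top of the ranking", {
  m <- random_cq_matrix(G = 5, S = 8, seed = 303)
  res <- genorm_stepwise_ranking(to_relative_quantities(m))
  expect_equal(sort(res$rank), c(1.5, 1.5, 3, 4, 5))
})

test_that("full-panel M above 1.5 flags a gene unstable", {
  genes <- data.frame(name = paste0("g", 1:4),
                      mu = c(17, 18, 19, 20),
                      tau = c(0.02, 0.02, 0.02, 3),
                      sigma = c(0.02, 0.02, 0.02, 3))
  ds <- generate_cq_dataset(sim_config(genes = genes), seed = 5)
  mc <- complete_case_submatrix(collapse_replicates(ds$records, meta = ds$meta))
  q <- to_relative_quantities(mc)
  full <- genorm_m_values(q)
  expect_gt(full$M[full$gene == "g4"], 1.5)
  expect_false(full$stable[full$gene == "g4"])
  expect_false(genorm_stepwise_ranking(q)$stable[4])
})

test_that("pairwise-variation curve: parallel genes give V = 0 and optimal 2", {
  v <- rbind(a = c(20, 21, 22, 23), b = c(22, 23, 24, 25),
             c = c(18, 19, 20, 21), d = c(19, 20, 21, 22))
  colnames(v) <- paste0("s", 1:4)
  q <- to_relative_quantities(cq_matrix(v))
  vc <- pairwise_variation_curve(q)
  expect_equal(vc$V, rep(0, 2), tolerance = 1e-12)
  expect_equal(vc$optimal_n, 2)

  # impossible threshold: fall back to the whole panel
  vc0 <- pairwise_variation_curve(to_relative_quantities(random_cq_matrix(
    G = 4, S = 6, seed = 9)), threshold = 0)
  expect_equal(vc0$optimal_n, 4)
})

test_that("two near-noiseless genes usually suffice (V2/3 below 0.15)", {
  genes <- data.frame(name = paste0("g", 1:7),
                      mu = seq(16, 22, length.out = 7),
                      tau = c(0.02, 0.02, rep(0.5, 5)) / sqrt(2),
                      sigma = c(0.02, 0.02, rep(0.5, 5)) / sqrt(2))
  v23 <- vapply(1:100, function(s) {
    ds <- generate_cq_dataset(sim_config(genes = genes), seed = s)
    mc <- complete_case_submatrix(collapse_replicates(ds$records,
                                                      meta = ds$meta))
    q <- to_relative_quantities(mc)
    st <- genorm_stepwise_ranking(q)
    pairwise_variation_curve(q, ranking = st$gene[order(st$rank, st$gene)])$V[1]
  }, numeric(1))
  expect_gt(mean(v23 < 0.15), 0.5)
})
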