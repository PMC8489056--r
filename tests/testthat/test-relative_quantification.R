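test_that("reference Cq is the per-sample mean of the reference genes", {
  v <- rbind(ACT = c(16, 17), GAPDH = c(18, 19), tgt = c(24, 23))
  colnames(v) <- c("s1", "s2")
  m <- cq_matrix(v)
  expect_equal(unname(reference_cq(m, c("ACT", "GAPDH"))), c(17, 18))
  expect_equal(unname(reference_cq(m, "ACT")), c(16, 17))
  expect_error(reference_cq(m, character(0)), "empty")
})

test_that("2^-ddCq fold changes hit the calibrator conventions", {
  target <- c(s1 = 24, s2 = 23, s3 = 22)
  refs <- c(s1 = 17, s2 = 17, s3 = 17)
  ft <- ddcq_fold_change(target, refs, calibrator = "s1")
  expect_equal(ft$fold_change, c(1, 2, 4))  # one doubling per cycle below

  # group calibrator: mean dCq over its samples
  groups <- c(s1 = "N1", s2 = "N1", s3 = "N2")
  ftg <- ddcq_fold_change(target, refs, calibrator = "N1", groups = groups)
  expect_equal(attr(ftg, "calibrator_dcq"), mean(c(7, 6)))
  expect_error(ddcq_fold_change(target, refs, calibrator = "nope"),
               "matches no sample or group")

  # reference normalized against itself: fold 1 everywhere
  ft_self <- ddcq_fold_change(refs, refs, calibrator = "s1")
  expect_equal(ft_self$fold_change, c(1, 1, 1))
})

test_that("fold changes are invariant to shared per-sample loading", {
  set.seed(12)
  target <- setNames(rnorm(6, 24), paste0("s", 1:6))
  refs <- setNames(rnorm(6, 17), paste0("s", 1:6))
  load <- rnorm(6)
  f1 <- ddcq_fold_change(target, refs, calibrator = "s1")$fold_change
  f2 <- ddcq_fold_change(target + load, refs + load,
                         calibrator = "s1")$fold_change
  expect_equal(f2, f1, tolerance = 1e-12)
})

test_that("a simulated 4x up-regulation is recovered", {
  folds <- vapply(1:100, function(s) {
    ds <- generate_cq_dataset(sim_config(), seed = s)
    ds <- inject_target_gene(ds, "tgt", c(N3m = 4), sigma = 0.1,
                             seed = s + 10000)
    m <- complete_case_submatrix(collapse_replicates(ds$records,
                                                     meta = ds$meta))
    fe <- relative_expression(m, "tgt", c("g1", "g2"), calibrator = "N1")
    mean(fe$fold_change[fe$group == "N3m"])
  }, numeric(1))
  expect_gte(mean(folds), 3.5)
  expect_lte(mean(folds), 4.5)
})

test_that("a two-gene reference beats a single noisy reference on RMSE", {
  rmse <- function(x, y) sqrt(mean((x - y)^2))
  res <- vapply(1:100, function(s) {
    genes <- data.frame(name = c("stable", "noisy"),
                        mu = c(17, 19),
                        tau = c(0.05, 0.6), sigma = c(0.05, 0.6))
    ds <- generate_cq_dataset(sim_config(genes = genes), seed = s)
    ds <- inject_target_gene(ds, "tgt", c(N3m = 4), sigma = 0.05,
                             seed = s + 20000)
    m <- complete_case_submatrix(collapse_replicates(ds$records,
                                                     meta = ds$meta))
    truth <- ds$truth$target_folds$tgt[m$meta$group]
    truth <- truth / truth[m$meta$group == "N1"][1]
    single <- relative_expression(m, "tgt", "noisy", calibrator = "N1")
    combo <- relative_expression(m, "tgt", c("stable", "noisy"),
                                 calibrator = "N1")
    c(single = rmse(single$fold_change, truth),
      combo = rmse(combo$fold_change, truth))
  }, numeric(2))
  expect_lt(mean(res["combo", ]), mean(res["single", ]))
})

test_that("shared-calibrator mode scales all targets to one baseline", {
  ds <- generate_cq_dataset(sim_config(), seed = 41)
  ds <- inject_target_gene(ds, "t1", c(N3m = 4), base_cq = 24, seed = 42)
  ds <- inject_target_gene(ds, "t2", c(N3m = 2), base_cq = 26, seed = 43)
  m <- complete_case_submatrix(collapse_replicates(ds$records, meta = ds$meta))
  shared <- relative_expression(m, c("t1", "t2"), c("g1", "g2"),
                                calibrator = "N1", shared_calibrator = TRUE)
  own <- relative_expression(m, c("t1", "t2"), c("g1", "g2"),
                             calibrator = "N1", shared_calibrator = FALSE)
  # t1 identical either way; t2 rescaled by a common factor in shared mode
  expect_equal(shared$fold_change[shared$target == "t1"],
               own$fold_change[own$target == "t1"])
  ratio <- shared$fold_change[shared$target == "t2"] /
    own$fold_change[own$target == "t2"]
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-9)
  # t2 sits lower than t1 on the shared baseline (higher base Cq)
  expect_lt(mean(shared$fold_change[shared$target == "t2" &
                                      shared$group == "N1"]), 1)
})

test_that("between-run correction removes a plate scale shift", {
  q <- data.frame(sample = c("cal", "a", "cal", "a"),
                  plate = c("p1", "p1", "p2", "p2"),
                  quantity = c(1, 2, 2, 4))
  res <- between_run_correction(q, "cal")
  expect_equal(sort(res$factors$factor), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  corrected <- res$corrected
  expect_equal(corrected$corrected[corrected$sample == "a" &
                                     corrected$plate == "p1"],
               corrected$corrected[corrected$sample == "a" &
                                     corrected$plate == "p2"],
               tolerance = 1e-12)
  # unit geometric mean of factors
  expect_equal(exp(mean(log(res$factors$factor))), 1, tolerance = 1e-12)

  # single plate and identical calibrators are no-ops
  q1 <- q[q$plate == "p1", ]
  expect_equal(between_run_correction(q1, "cal")$factors$factor, 1)
  q2 <- q
  q2$quantity <- c(1, 2, 1, 3)
  expect_equal(between_run_correction(q2, "cal")$factors$factor, c(1, 1))

  # plate relabeling leaves corrected values unchanged
  q3 <- q
  q3$plate <- c("x", "x", "y", "y")
  expect_equal(between_run_correction(q3, "cal")$corrected$corrected,
               res$corrected$corrected)

  # missing calibrator is an error
  expect_error(between_run_correction(q[-3, ], "cal"), "missing calibrator")
})
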