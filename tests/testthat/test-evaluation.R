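test_that("weight enumeration matches a brute-force lattice oracle exactly", {
  w <- enumerate_weights()
  oracle <- weight_oracle()
  expect_equal(nrow(w), nrow(oracle))
  key <- function(m) sort(apply(round(m * 20), 1, paste, collapse = "_"))
  expect_identical(key(as.matrix(w)), key(oracle))
  expect_true(all(abs(rowSums(as.matrix(w)) - 1) < 1e-9))
})

test_that("degenerate weight ranges enumerate the expected tuples", {
  w1 <- enumerate_weights(fp_range = c(1, 1))
  expect_equal(nrow(w1), 1L)
  expect_equal(unlist(w1[1, ], use.names = FALSE), c(1, 0, 0, 0))
  # fp fixed at 0.9: cd+hd+fg = 0.1 on the 0.05 lattice with cd <= 0.4
  w9 <- enumerate_weights(fp_range = c(0.9, 0.9))
  expect_equal(nrow(w9), 6L)
  expect_error(enumerate_weights(fp_step = 0.09), "divide ranges")
})

test_that("stage-1 grids have one run per fingerprint x coefficient pair", {
  ds <- fixture30("a")[1:10, ]
  g <- stage1_grid(list(d1 = ds), fp_types = c("default", "maccs"),
                   binary_ids = c(3, 37, 44))
  expect_equal(nrow(g), 6L)
  expect_setequal(paste(g$fingerprint, g$binary_id),
                  c(t(outer(c("default", "maccs"), c(3, 37, 44), paste))))
  expect_true(all(c("r2_d1", "rmse_d1", "des", "uti", "rank_des", "rank_uti")
                  %in% names(g)))
  g1 <- suppressWarnings(
    stage1_grid(list(d1 = ds), fp_types = "default", binary_ids = 3)
  )
  expect_equal(nrow(g1), 1L)
})

test_that("the same dataset passed twice yields identical per-dataset metrics", {
  ds <- fixture30("a")[1:10, ]
  g <- stage1_grid(list(x = ds, y = ds), fp_types = "default",
                   binary_ids = c(1, 3))
  expect_equal(g$r2_x, g$r2_y)
  expect_equal(g$rmse_x, g$rmse_y)
})

test_that("stage-2 grids cover weights x non-binary coefficients", {
  ds <- fixture30("a")[1:10, ]
  w <- enumerate_weights(fp_range = c(0.9, 0.9))
  g <- stage2_grid(list(d1 = ds), weights = w[1:2, ], nonbinary_ids = c(3, 6))
  expect_equal(nrow(g), 4L)
  expect_true(all(g$des >= 0 & g$des <= 1))
  expect_true(all(g$uti >= 0 & g$uti <= 1))
  # the shipped default weights are on the enumerated calibration grid
  wfull <- enumerate_weights()
  expect_true(any(wfull$w_fp == 0.4 & wfull$w_cd == 0.35 &
                  wfull$w_hd == 0.1 & wfull$w_fg == 0.15))
})

test_that("rank_results scales, scores and ranks as the closed forms require", {
  batch <- tibble::tibble(
    cfg = c("best", "worst", "mixed"),
    r2_a = c(1, 0, 1), rmse_a = c(0.1, 1.1, 1.1),
    r2_b = c(1, 0, 1), rmse_b = c(0.2, 1.2, 1.2)
  )
  r <- rank_results(batch)
  best <- r[r$cfg == "best", ]
  expect_equal(unlist(best[, c("p1", "p2", "p3", "p4")], use.names = FALSE),
               c(1, 1, 1, 1))
  expect_equal(best$des, 1); expect_equal(best$uti, 1)
  expect_equal(best$rank_des, 1L); expect_equal(best$rank_uti, 1L)
  worst <- r[r$cfg == "worst", ]
  expect_equal(worst$des, 0); expect_equal(worst$uti, 0)
  # scaled params (1,1,0,0): geometric mean 0, arithmetic mean 0.5, exactly
  mixed <- r[r$cfg == "mixed", ]
  expect_equal(unlist(mixed[, c("p1", "p2", "p3", "p4")], use.names = FALSE),
               c(1, 1, 0, 0))
  expect_identical(mixed$des, 0)
  expect_identical(mixed$uti, 0.5)
})

test_that("dominance: a run at least as good on all scaled params ranks no worse", {
  set.seed(33)
  for (rep in 1:50) {
    n <- 6
    batch <- tibble::tibble(
      r2_a = stats::runif(n), rmse_a = stats::runif(n),
      r2_b = stats::runif(n), rmse_b = stats::runif(n)
    )
    r <- rank_results(batch)
    P <- as.matrix(r[, c("p1", "p2", "p3", "p4")])
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (all(P[i, ] >= P[j, ]) && any(P[i, ] > P[j, ])) {
        expect_gte(r$des[i], r$des[j])
        expect_gt(r$uti[i], r$uti[j])
      }
    }
  }
})

test_that("rankings are invariant to a constant shift of all RMSE values", {
  set.seed(44)
  batch <- tibble::tibble(
    r2_a = stats::runif(8), rmse_a = stats::runif(8),
    r2_b = stats::runif(8), rmse_b = stats::runif(8)
  )
  r1 <- rank_results(batch)
  batch2 <- batch
  batch2$rmse_a <- batch2$rmse_a + 5
  batch2$rmse_b <- batch2$rmse_b + 2
  r2 <- rank_results(batch2)
  expect_identical(r1$rank_des, r2$rank_des)
  expect_identical(r1$rank_uti, r2$rank_uti)
  expect_equal(r1$des, r2$des)
})

test_that("zero-spread metrics are set to 1 with a warning", {
  batch <- tibble::tibble(r2_a = c(0.5, 0.5), rmse_a = c(0.3, 0.6))
  expect_warning(r <- rank_results(batch), "zero spread")
  expect_equal(r$p1, c(1, 1))
})

test_that("ranks are a permutation and the agreement prefix is computed", {
  set.seed(55)
  batch <- tibble::tibble(r2_a = stats::runif(10), rmse_a = stats::runif(10))
  r <- rank_results(batch)
  expect_setequal(r$rank_des, 1:10)
  expect_setequal(r$rank_uti, 1:10)
  pr <- ranking_agreement_prefix(r)
  expect_gte(pr, 0); expect_lte(pr, 10)
})

test_that("grid CSV writing is deterministic", {
  ds <- fixture30("a")[1:8, ]
  g <- stage1_grid(list(d = ds), fp_types = "default", binary_ids = c(1, 3, 37))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_grid_csv(g, f1); write_grid_csv(g, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  p <- autoplot(g)
  expect_s3_class(p, "ggplot")
})
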