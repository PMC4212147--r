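test_that("confusion counts match direct set arithmetic", {
  x <- make_fp(0:9, length = 166L, type = "maccs")
  k <- confusion_counts(x, x)
  expect_equal(unlist(k[, c("a", "b", "c", "d")]),
               c(a = 10, b = 0, c = 0, d = 156))

  x2 <- make_fp(c(0, 1), length = 6L)
  y2 <- make_fp(c(0, 2), length = 6L)
  expect_equal(unlist(confusion_counts(x2, y2)[, 1:4]),
               c(a = 1, b = 1, c = 1, d = 3))

  expect_error(confusion_counts(x, x2), "same type")
})

test_that("confusion counts agree with brute force over all length-4 pairs", {
  combos <- expand.grid(replicate(4, c(0, 1), simplify = FALSE))
  for (i in seq_len(16)) {
    for (j in seq_len(16)) {
      xi <- as.numeric(combos[i, ]); yj <- as.numeric(combos[j, ])
      k <- confusion_counts(make_fp(which(xi == 1) - 1L, 4L),
                            make_fp(which(yj == 1) - 1L, 4L))
      expect_equal(k$a, sum(xi == 1 & yj == 1))
      expect_equal(k$b, sum(xi == 1 & yj == 0))
      expect_equal(k$c, sum(xi == 0 & yj == 1))
      expect_equal(k$d, sum(xi == 0 & yj == 0))
    }
  }
})

test_that("binary coefficient examples evaluate correctly", {
  expect_equal(binary_similarity(3, c(10, 0, 0, 156)), 1.0) # Jaccard, identical
  expect_equal(binary_similarity(1, c(1, 1, 1, 3)), 4 / 6)  # simple matching
  # Maxwell-Pilliner self-similarity with a > 0 and d > 0 is maximal
  expect_equal(binary_similarity(37, c(5, 0, 0, 11)), 1.0)
  expect_error(binary_similarity(99, c(1, 1, 1, 1)), "unknown binary")
  expect_error(binary_similarity(3, c(-1, 1, 1, 1)), "nonnegative")
})

test_that("the binary registry lists 44 coefficients with Todeschini-roster names", {
  tb <- binary_coefficients()
  expect_equal(tb$id, 1:44)
  expect_equal(tb$name[3], "Jaccard/Tanimoto")
  expect_equal(tb$name[37], "Maxwell-Pilliner")
  expect_equal(tb$name[44], "Austin-Colwell angular coeff.")
  expect_true(tb$reflexive[37])
  expect_false(tb$reflexive[5]) # Russel-Rao self-similarity is a/n < 1
})

test_that("all binary coefficients stay in [0,1]; symmetric ones commute, asymmetric ones transpose", {
  set.seed(101)
  counts <- data.frame(a = sample(0:20, 300, TRUE), b = sample(0:20, 300, TRUE),
                       c = sample(0:20, 300, TRUE), d = sample(0:20, 300, TRUE))
  counts <- counts[rowSums(counts) > 0, ]
  swapped <- data.frame(a = counts$a, b = counts$c, c = counts$b, d = counts$d)
  tb <- binary_coefficients()
  for (id in tb$id[tb$symmetric]) {
    s <- binary_similarity(id, counts)
    expect_true(all(s >= 0 & s <= 1), info = id)
    expect_equal(s, binary_similarity(id, swapped), info = id)
  }
  # the asymmetric roster entries come in transpose pairs
  for (pair in list(c(24, 25), c(31, 32), c(35, 36))) {
    s1 <- binary_similarity(pair[1], counts)
    s2 <- binary_similarity(pair[2], counts)
    expect_true(all(s1 >= 0 & s1 <= 1) && all(s2 >= 0 & s2 <= 1))
    expect_equal(binary_similarity(pair[1], swapped), s2,
                 info = paste(pair, collapse = "/"))
  }
})

test_that("reflexive coefficients score identical fingerprints at 1", {
  tb <- binary_coefficients()
  set.seed(7)
  for (id in tb$id[tb$reflexive]) {
    a <- sample(1:30, 5); d <- sample(1:30, 5)
    s <- binary_similarity(id, data.frame(a = a, b = 0, c = 0, d = d))
    expect_equal(s, rep(1, 5), info = id)
  }
  # identical all-zero fingerprints score 1 for every coefficient policy
  for (id in tb$id[tb$reflexive]) {
    expect_equal(binary_similarity(id, c(0, 0, 0, 8)), 1, info = id)
  }
})

test_that("non-binary coefficient examples evaluate correctly", {
  expect_equal(nonbinary_similarity(3, c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(nonbinary_similarity(3, c(2, 0), c(0, 2)), 0.0)
  expect_equal(nonbinary_similarity(3, c(1, 2, 3), c(2, 2, 2)), 1 - 2 / 12)
  expect_error(nonbinary_similarity(3, c(1, -1), c(1, 1)), "nonnegative")
  expect_error(nonbinary_similarity(3, c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(nonbinary_similarity(9, c(1), c(1)), "unknown non-binary")
  tb <- nonbinary_coefficients()
  expect_equal(tb$code, c("MC", "Div", "BC", "Dice", "SS1", "Cos"))
})

test_that("all non-binary coefficients are reflexive, symmetric and in [0,1]", {
  set.seed(202)
  for (r in 1:50) {
    x <- stats::runif(10, 0, 5) * stats::rbinom(10, 1, 0.7)
    y <- stats::runif(10, 0, 5) * stats::rbinom(10, 1, 0.7)
    for (id in 1:6) {
      sxx <- nonbinary_similarity(id, x, x)
      expect_equal(sxx, 1, info = id)
      sxy <- nonbinary_similarity(id, x, y)
      expect_equal(sxy, nonbinary_similarity(id, y, x), info = id)
      expect_true(sxy >= 0 && sxy <= 1, info = id)
    }
  }
})

test_that("similarity config validates its components and weights", {
  cfg <- similarity_config()
  expect_equal(cfg$fingerprint, "extended")
  expect_equal(cfg$binary_id, 37L)
  expect_equal(cfg$nonbinary_id, 3L)
  expect_equal(unname(cfg$weights), c(0.4, 0.35, 0.1, 0.15))
  expect_error(similarity_config(weights = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(similarity_config(weights = c(1.2, -0.2, 0, 0)), "\\[0, 1\\]")
  expect_error(similarity_config(fingerprint = "nope"), "unknown fingerprint")
  expect_error(similarity_config(binary_id = 0), "unknown binary")
  expect_error(similarity_config(nonbinary_id = 7), "unknown non-binary")
})

test_that("weighted geometric combination follows the zero-weight and closed-form rules", {
  comb <- simdex:::combine_components
  cfg_geo <- similarity_config(weights = c(fp = 0.5, cd = 0.5 / 3,
                                           hd = 0.5 / 3, fg = 0.5 / 3))
  expect_equal(comb(0.81, 1, 1, 1, cfg_geo), 0.81^0.5)
  # single-component reduction in both modes
  w1 <- similarity_config(weights = c(fp = 1, cd = 0, hd = 0, fg = 0))
  expect_equal(comb(0.37, 0, 0.2, 0.9, w1), 0.37)
  w1a <- similarity_config(weights = c(fp = 1, cd = 0, hd = 0, fg = 0),
                           mode = "arithmetic")
  expect_equal(comb(0.37, 0, 0.2, 0.9, w1a), 0.37)
  # all components 1 -> SI 1
  expect_equal(comb(1, 1, 1, 1, similarity_config()), 1)
})

test_that("increasing the weight of the smallest component never increases the geometric SI", {
  comb <- simdex:::combine_components
  set.seed(5)
  for (r in 1:100) {
    s <- stats::runif(4, 0.05, 1)
    w <- stats::runif(4); w <- w / sum(w)
    i <- which.min(s)
    delta <- min(0.2, 1 - w[i])
    w2 <- w; w2[i] <- w[i] + delta
    w2[-i] <- w[-i] * (1 - w2[i]) / sum(w[-i])
    names(w) <- names(w2) <- c("fp", "cd", "hd", "fg")
    si1 <- comb(s[1], s[2], s[3], s[4], similarity_config(weights = w))
    si2 <- comb(s[1], s[2], s[3], s[4], similarity_config(weights = w2))
    expect_lte(si2, si1 + 1e-12)
  }
})

test_that("combined similarity on molecules is symmetric, reflexive and component-consistent", {
  mols <- probe_molecules()
  cfg <- similarity_config()
  keys <- molecule_keys(mols[1:4], config = cfg)
  ks <- simdex:::keys_slice
  for (i in 1:4) {
    sii <- combined_similarity(ks(keys, i), ks(keys, i), cfg)
    expect_equal(as.numeric(sii), 1, tolerance = 1e-12)
  }
  s12 <- combined_similarity(ks(keys, 1), ks(keys, 2), cfg)
  s21 <- combined_similarity(ks(keys, 2), ks(keys, 1), cfg)
  expect_equal(as.numeric(s12), as.numeric(s21))
  comp <- attr(s12, "components")
  expect_equal(as.numeric(s12),
               comp[["fp"]]^0.4 * comp[["cd"]]^0.35 * comp[["hd"]]^0.1 *
                 comp[["fg"]]^0.15)
  # weights (1,0,0,0) reduce the SI to the bare fingerprint similarity
  w1 <- similarity_config(weights = c(fp = 1, cd = 0, hd = 0, fg = 0))
  s_fp_only <- combined_similarity(ks(keys, 1), ks(keys, 2), w1)
  expect_equal(as.numeric(s_fp_only), unname(comp["fp"]))
})

test_that("pairwise similarity emits one row per unordered pair", {
  mols <- probe_molecules()[1:5]
  tb <- pairwise_similarity(mols)
  expect_equal(nrow(tb), choose(5, 2))
  expect_true(all(tb$si >= 0 & tb$si <= 1))
  expect_true(all(tb$si <= pmax(tb$s_fp, tb$s_cd, tb$s_hd, tb$s_fg) + 1e-12))
})

test_that("YAML configuration files round-trip", {
  tf <- tempfile(fileext = ".yml")
  writeLines(c(
    "fingerprint: maccs", "binary_coefficient: 3", "nonbinary_coefficient: 6",
    "weights:", "  fp: 0.25", "  cd: 0.25", "  hd: 0.25", "  fg: 0.25",
    "mode: arithmetic"
  ), tf)
  cfg <- read_similarity_config(tf)
  expect_equal(cfg$fingerprint, "maccs")
  expect_equal(cfg$binary_id, 3L)
  expect_equal(cfg$nonbinary_id, 6L)
  expect_equal(unname(cfg$weights), rep(0.25, 4))
  expect_equal(cfg$mode, "arithmetic")
})
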