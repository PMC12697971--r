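test_that("label entropy and information gain follow the base-2 definitions", {
  expect_equal(entropy_bits(c(0, 0, 1, 1)), 1)
  expect_equal(entropy_bits(c(0, 0, 0)), 0)
  expect_equal(entropy_bits(c(0, 1, 2, 3)), 2)
  expect_error(entropy_bits(integer(0)), "empty")

  y <- c(0, 0, 1, 1)
  expect_equal(information_gain(y, list(1:2, 3:4)), 1)  # perfect split
  expect_equal(information_gain(y, list(1:4)), 0)
  expect_equal(information_gain(y, list(c(1, 3), c(2, 4))), 0)  # uninformative split
  expect_error(information_gain(y, list(1:2, 2:4)), "exactly once")
})

test_that("forest pre-screen recovers a planted label copy and is deterministic", {
  set.seed(9)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  m <- cbind(y + rnorm(n, sd = 0.01), matrix(rnorm(n * 199), n, 199))
  ds <- expression_dataset(m, y)
  r1 <- rf_fim_rank(ds, 10, seed = 1, num_trees = 200)
  expect_true(1L %in% r1$feature[1:5])
  expect_equal(nrow(r1), 10L)
  expect_true(all(diff(r1$score) <= 0))
  r2 <- rf_fim_rank(ds, 10, seed = 1, num_trees = 200)
  expect_identical(r1, r2)
  expect_error(rf_fim_rank(ds, 0), "out of range")
  expect_error(rf_fim_rank(ds, 500), "out of range")
})

test_that("mutual information reproduces the printed worked examples in nats", {
  expect_equal(mutual_information(c(0, 1, 2, 3, 4), c(0.2, 0.8, 2.3, 3.6, 4.8)),
               1.609, tolerance = 0.001)
  expect_equal(mutual_information(c(0, 1, 2, 3, 4), c(0.2, 0.4, 0.2, 0.4, 0.2)),
               0.673, tolerance = 0.001)
  expect_equal(mutual_information(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("mutual information is symmetric and self-MI equals entropy in nats", {
  set.seed(21)
  for (i in 1:25) {
    x <- sample(0:3, 30, replace = TRUE)
    y <- sample(0:2, 30, replace = TRUE)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    expect_gte(mutual_information(x, y), -1e-12)
    p <- as.numeric(table(x)) / 30
    expect_equal(mutual_information(x, x), -sum(p * log(p)))
  }
})

test_that("maximum-MI pick prefers a label copy and breaks ties by lowest index", {
  set.seed(4)
  y <- rep(c(0, 1), 10)
  m <- cbind(rnorm(20), as.numeric(y), rnorm(20), 5, 5)
  ds <- expression_dataset(m, y)
  got <- mmi(2:3, ds)
  expect_equal(got$feature, 2L)
  expect_equal(got$value, log(2))  # H(label), balanced binary, nats
  tie <- mmi(4:5, ds)  # both constant: MI 0, lowest index wins
  expect_equal(tie$feature, 4L)
  expect_equal(tie$value, 0)
  expect_error(mmi(integer(0), ds), "empty")
})

test_that("Spearman via the printed formula matches the worked example and its limits", {
  expect_equal(spearman_coef(c(0.8, 0.8, 0.7, 0.4, 0.9, 0.6, 0.7),
                             c(0.5, 0, 0, 0.1, 0.5, 0.1, 0.1)),
               0.384, tolerance = 0.001)
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_coef(x, x), 1)
  expect_equal(spearman_coef(1:4, 4:1), -1)
  expect_error(spearman_coef(1:3, 1:2), "equal length")
  expect_error(spearman_coef(1, 2), "at least 2")
})

test_that("on tie-free data the printed formula equals the Pearson correlation of ranks", {
  set.seed(31)
  for (i in 1:100) {
    x <- sample(seq(0, 1, length.out = 500), 15)
    y <- sample(seq(2, 3, length.out = 500), 15)
    expect_equal(spearman_coef(x, y), cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("least-redundant picks agree with exhaustive pairwise search", {
  set.seed(12)
  ds <- expression_dataset(matrix(rnorm(20 * 12), 20, 12), rep(0:1, 10))
  # known feature vs candidates
  got <- ms1(1, 2:7, ds)
  vals <- sapply(2:7, function(j) oracle_spearman(ds$matrix[, 1], ds$matrix[, j]))
  expect_equal(got$feature, (2:7)[which.min(vals)])
  expect_equal(got$value, min(vals))
  expect_equal(ms1(1, 5, ds)$feature, 5L)  # single candidate
  expect_error(ms1(1, c(1, 2), ds), "must not be among")

  # exact anticorrelation wins
  m <- cbind(1:6, 1:6, 6:1)
  ds2 <- expression_dataset(m, rep(0:1, 3))
  expect_equal(ms1(1, 2:3, ds2), list(feature = 3L, value = -1))

  # set-vs-set agrees with brute force over all candidate x selected pairs
  sel <- c(1, 4, 9)
  cand <- c(2, 3, 5, 7, 11)
  got2 <- ms2(sel, cand, ds)
  brute <- sapply(cand, function(j)
    min(sapply(sel, function(s) oracle_spearman(ds$matrix[, j], ds$matrix[, s]))))
  expect_equal(got2$feature, cand[which.min(brute)])
  expect_equal(got2$value, min(brute))
  expect_equal(ms2(4, cand, ds), ms1(4, cand, ds))  # single-element reduction
  expect_error(ms2(c(1, 2), c(2, 3), ds), "disjoint")
})

test_that("relevance/redundancy weights traverse the unit quarter-circle", {
  expect_equal(sy_schedule(0, 10), c(s = 1, y = 0))
  expect_equal(sy_schedule(10, 10), c(s = 0, y = 1))
  expect_equal(sy_schedule(5, 10), c(s = sqrt(2) / 2, y = sqrt(2) / 2))
  for (i in 0:20) {
    sy <- sy_schedule(i, 20)
    expect_equal(sum(sy^2), 1)
  }
  ss <- sapply(0:20, function(i) sy_schedule(i, 20)[["s"]])
  expect_true(all(diff(ss) <= 0))
  expect_error(sy_schedule(11, 10), "i <= I")
})

test_that("feature budgets stay inside the clamp and grow with the baseline", {
  b <- filter_budget()
  set.seed(1)
  draws <- replicate(1000, feature_budget(c(2000, 62), b, "M2"))
  expect_true(all(draws >= b$k_min & draws <= 2000))
  m1 <- replicate(50, feature_budget(c(2000, 62), b, "M1"))
  expect_true(all(m1 >= b$k_min & m1 <= 2000))

  # cos(0.8 * 60) < 0 makes the raw value strongly negative: clamped to k_min
  set.seed(2)
  expect_equal(feature_budget(c(2000, 60), b, "M2"), b$k_min)

  # same underlying uniforms, shifted baseline range: non-decreasing output
  lo <- filter_budget(randnum_a_low = 10, randnum_a_high = 20)
  hi <- filter_budget(randnum_a_low = 110, randnum_a_high = 120)
  set.seed(3); k_lo <- feature_budget(c(500, 62), lo, "M2")
  set.seed(3); k_hi <- feature_budget(c(500, 62), hi, "M2")
  expect_gte(k_hi, k_lo)

  # the upper clamp respects the available-feature cap
  set.seed(4)
  expect_lte(feature_budget(c(2000, 62), b, "M2", available = 8), 8)
})

test_that("greedy filter degenerates to an MI ranking when redundancy has no weight", {
  set.seed(17)
  spec <- synthetic_spec(n_samples = 30, n_features = 12, n_informative = 3,
                         n_redundant_per_informative = 1, seed = 17)
  ds <- generate_synthetic_omics(spec)
  sel <- msmmi_select(1:12, ds, 12, sy_schedule(0, 10), mi_mode = "equal_width",
                      mi_bins = 4)
  mi <- sapply(1:12, function(j)
    mutual_information(ds$labels, ds$matrix[, j], mode = "equal_width", bins = 4))
  expect_equal(sel, order(-mi, 1:12))
  expect_equal(msmmi_select(1:12, ds, 1, sy_schedule(0, 10), mi_mode = "equal_width",
                            mi_bins = 4),
               which.max(mi))
  expect_error(msmmi_select(1:4, ds, 5), "exceeds")
})

test_that("greedy filter output is a duplicate-free subset, invariant to candidate order", {
  set.seed(23)
  ds <- expression_dataset(matrix(rnorm(24 * 15), 24, 15), rep(0:2, 8))
  cand <- c(2, 5, 7, 9, 11, 14)
  sy <- sy_schedule(3, 10)
  a <- msmmi_select(cand, ds, 4, sy)
  b <- msmmi_select(rev(cand), ds, 4, sy)
  expect_identical(a, b)
  expect_true(all(a %in% cand))
  expect_false(anyDuplicated(a) > 0)
  expect_length(a, 4)
})

test_that("greedy filter matches an independent brute-force recurrence", {
  set.seed(29)
  for (rep in 1:30) {
    n <- sample(12:20, 1)
    p <- sample(5:8, 1)
    ds <- expression_dataset(matrix(round(rnorm(n * p), 1), n, p),
                             c(0, 1, sample(0:1, n - 2, replace = TRUE)))
    k2 <- sample(2:p, 1)
    i <- sample(0:10, 1)
    sy <- sy_schedule(i, 10)
    sel <- msmmi_select(seq_len(p), ds, k2, sy)
    expect_length(sel, k2)
    expect_greedy_optimal(sel, seq_len(p), ds, sy[["s"]], sy[["y"]])
  }
})
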