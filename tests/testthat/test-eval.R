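test_that("jackknife matches an explicitly unrolled leave-one-out loop", {
  set.seed(25)
  x <- matrix(rnorm(10), 5, 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- c(1, 1, 1, -1, -1)
  x[, 1] <- y * 1.5 + rnorm(5, sd = 0.4)
  jk <- jackknife_evaluate(x, y, C = 3)
  for (i in 1:5) {
    fit <- fit_linear_svm(x[-i, ], y[-i], C = 3)
    expect_equal(jk$decisions[i],
                 unname(decision_values(fit, x[i, , drop = FALSE])))
  }
  expect_equal(jk$predictions, ifelse(jk$decisions >= 0, 1, -1))
})

test_that("jackknife is exact on strongly separable data", {
  set.seed(33)
  dat <- make_separable(n_per_class = 10, D = 5, informative = 1:2,
                        gap = 6, sd = 0.2)
  jk <- jackknife_evaluate(dat$x, dat$y, C = 10,
                           features = c("f1", "f2"))
  expect_equal(metrics_from_counts(jk$counts)$Acc, 1)
})

test_that("permuted labels carry no positive class signal", {
  # Leave-one-out with a class-sensitive learner on label-permuted data
  # is anti-predictive, not chance-level: removing a sample tilts the
  # training fold against its own class, and with no signal left that
  # tilt decides every fold. The guard is therefore one-sided: no
  # spurious *positive* signal may appear.
  set.seed(55)
  d <- generate_dataset(synthetic_config(n_hot = 25, n_cold = 25,
                                         length_range = c(150, 250),
                                         planted = c(CG = 2.5),
                                         seed = 77))
  x <- encode_dataset(d$sequences, k_max = 2, omega = 3)
  y_perm <- sample(d$labels)
  jk <- jackknife_evaluate(x, y_perm, C = 8)
  acc <- suppressMessages(metrics_from_counts(jk$counts))$Acc
  auc <- roc_auc(y_perm, jk$decisions)$auc
  expect_lte(acc, 0.65)
  expect_lte(auc, 0.65)
})

test_that("a fold losing its class falls back to the fold majority", {
  x <- matrix(c(1, 1.1, 0.9, -1), 4, 1,
              dimnames = list(NULL, "f1"))
  y <- c(1, 1, 1, -1)
  expect_message(jk <- jackknife_evaluate(x, y, C = 1), "majority")
  expect_equal(jk$predictions[4], 1)  # remaining fold is all-hotspot
})

test_that("grid search returns the accuracy surface and honors ties", {
  set.seed(35)
  dat <- make_separable(n_per_class = 8, D = 6, informative = 1:2,
                        gap = 5, sd = 0.3)
  rk <- rfe_rank(dat$x, dat$y, C = 1)
  gs <- suppressMessages(
    grid_search(dat$x, dat$y, rk, C_grid = 4, N_grid = 3))
  expect_equal(gs$C, 4)
  expect_equal(gs$Dim, 3)
  expect_equal(nrow(gs$surface), 1)
  # duplicated grid values change nothing
  gs2 <- suppressMessages(
    grid_search(dat$x, dat$y, rk, C_grid = c(4, 4, 4), N_grid = c(3, 3)))
  expect_equal(gs2[c("C", "Dim", "acc")], gs[c("C", "Dim", "acc")])
  # separable data: several (C, N) points reach accuracy 1; the
  # reported pair must be the smallest N, then the smallest C
  gs3 <- suppressMessages(
    grid_search(dat$x, dat$y, rk, C_grid = c(1, 8), N_grid = c(2, 4, 6)))
  top <- gs3$surface[gs3$surface$accuracy == max(gs3$surface$accuracy), ]
  expect_equal(gs3$Dim, min(top$N))
  expect_equal(gs3$C, min(top$C[top$N == gs3$Dim]))
})

test_that("grid search recovers a planted feature dimension (loosely,
           across seeds)", {
  # five individually weak, jointly informative features: accuracy
  # should keep improving past N = 1 and the chosen dimension should
  # sit near the planted count on aggregate
  dims <- integer(0); acc1 <- numeric(0); acc5 <- numeric(0)
  for (seed in 1:5) {
    set.seed(seed + 400)
    n <- 40; D <- 12
    x <- matrix(rnorm(n * D), n, D,
                dimnames = list(NULL, paste0("f", 1:D)))
    y <- rep(c(1, -1), each = n / 2)
    for (j in 1:5) x[, j] <- 0.5 * y + rnorm(n, sd = 1)
    rk <- rfe_rank(x, y, C = 1)
    gs <- suppressMessages(
      grid_search(x, y, rk, C_grid = 1, N_grid = c(1, 2, 3, 5, 8, 12)))
    s <- gs$surface
    dims <- c(dims, gs$Dim)
    acc1 <- c(acc1, s$accuracy[s$N == 1])
    acc5 <- c(acc5, s$accuracy[s$N == 5])
    # accuracy at the chosen dimension is the maximum of its C-slice
    expect_equal(max(s$accuracy[s$C == gs$C]), gs$acc)
  }
  expect_gte(stats::median(dims), 3)
  expect_gt(mean(acc5), mean(acc1))
})

test_that("grid search surfaces are reproducible bit-for-bit", {
  set.seed(47)
  dat <- make_separable(n_per_class = 7, D = 5)
  rk <- rfe_rank(dat$x, dat$y, C = 1)
  g1 <- suppressMessages(grid_search(dat$x, dat$y, rk,
                                     C_grid = c(1, 4), N_grid = c(2, 5)))
  g2 <- suppressMessages(grid_search(dat$x, dat$y, rk,
                                     C_grid = c(1, 4), N_grid = c(2, 5)))
  expect_identical(g1$surface, g2$surface)
})

test_that("identical halves select identical top features", {
  set.seed(49)
  dat <- make_separable(n_per_class = 8, D = 6, informative = 1:2)
  x <- rbind(dat$x, dat$x)
  y <- c(dat$y, dat$y)
  ov <- feature_overlap(x, y, C = 1, N = 4,
                        split = rep(c(TRUE, FALSE), each = 16))
  expect_identical(ov$top_s1, ov$top_s2)
  expect_length(ov$common, 4)
})

test_that("planted features survive in every top list of a random split", {
  set.seed(51)
  dat <- make_separable(n_per_class = 14, D = 10, informative = 1:2,
                        gap = 5, sd = 0.3)
  ov <- feature_overlap(dat$x, dat$y, C = 5, N = 4, seed = 99)
  expect_true(all(c("f1", "f2") %in% ov$top_full))
  expect_true(all(c("f1", "f2") %in% ov$top_s1))
  expect_true(all(c("f1", "f2") %in% ov$top_s2))
  expect_true(all(c("f1", "f2") %in% ov$common))
})

test_that("half-split overlap on pure noise is near its hypergeometric
           expectation", {
  # two independent rankings of D features share about N^2/D of their
  # top-N entries; averaged over seeds the observed overlap should sit
  # in a wide band around that
  set.seed(53)
  D <- 20; N <- 5
  overlaps <- vapply(1:10, function(s) {
    x <- matrix(rnorm(30 * D), 30, D,
                dimnames = list(NULL, paste0("f", 1:D)))
    y <- rep(c(1, -1), 15)
    ov <- feature_overlap(x, y, C = 1, N = N, seed = s)
    length(intersect(ov$top_s1, ov$top_s2))
  }, numeric(1))
  expected <- N^2 / D  # 1.25
  expect_gte(mean(overlaps), 0)
  expect_lte(mean(overlaps), expected + 4 * sqrt(expected / 10) + 1)
})
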