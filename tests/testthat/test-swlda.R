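test_that("feature extraction yields 32 samples per channel", {
  # direct count: multiples of 1/64 s in [0.2, 0.7) are 13..44 -> 32
  tpl <- erp_templates("movement")
  set.seed(50)
  e <- generate_synthetic_epochs(tpl, c(TT = 2, TR = 2, FA = 2, SO = 2),
                                 noise_sd = 1)
  f <- preprocess_epochs(e, preprocess_config(c(1, 10)))
  expect_equal(ncol(f), 8 * 32)
  expect_equal(nrow(f), 8)
})

test_that("constant signals vanish after filtering and baseline correction", {
  times <- seq(-0.5, 1, by = 1 / 500)
  sig <- matrix(5, nrow = 8, ncol = length(times))
  f <- preprocess_epoch(sig, times, 500, preprocess_config(c(1, 10)))
  expect_lt(max(abs(f)), 1e-6)
})

test_that("out-of-band oscillations are strongly attenuated", {
  times <- seq(-0.5, 1, by = 1 / 500)
  sig <- matrix(rep(sin(2 * pi * 50 * times), each = 8), nrow = 8)
  f <- preprocess_epoch(sig, times, 500, preprocess_config(c(1, 10)))
  expect_lt(max(abs(f)), 0.05)  # residual below 5% of unit amplitude
  # in-band content survives
  sig5 <- matrix(rep(sin(2 * pi * 5 * times), each = 8), nrow = 8)
  f5 <- preprocess_epoch(sig5, times, 500, preprocess_config(c(1, 10)))
  expect_gt(max(abs(f5)), 0.5)
})

test_that("preprocessing is linear", {
  times <- seq(-0.5, 1, by = 1 / 500)
  set.seed(51)
  a <- matrix(rnorm(8 * length(times)), nrow = 8)
  b <- matrix(rnorm(8 * length(times)), nrow = 8)
  cfg <- preprocess_config(c(1, 32))
  expect_equal(preprocess_epoch(a + b, times, 500, cfg),
               preprocess_epoch(a, times, 500, cfg) +
                 preprocess_epoch(b, times, 500, cfg),
               tolerance = 1e-8)
})

test_that("stepwise selection finds a separating feature among noise", {
  set.seed(52)
  n <- 120
  x <- matrix(rnorm(n * 40), n, 40)
  y <- rep(c("a", "b"), each = n / 2)
  x[, 17] <- ifelse(y == "b", 2, -2) + rnorm(n, sd = 0.3)
  m <- swlda_fit(x, y)
  expect_equal(m$selected[1], 17)
  expect_equal(unname(predict(m, x)), y)
})

test_that("stepwise selection stays sparse under the null", {
  set.seed(53)
  n <- 200
  x <- matrix(rnorm(n * 50), n, 50)
  y <- rep(c("a", "b"), each = n / 2)
  m <- swlda_fit(x, y, entry_p = 0.05)
  expect_lte(length(m$selected), 8)
})

test_that("only one of two duplicated informative features is retained", {
  set.seed(54)
  n <- 100
  x <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c("a", "b"), each = n / 2)
  x[, 3] <- ifelse(y == "b", 1, -1) + rnorm(n, sd = 0.4)
  x[, 7] <- x[, 3]
  m <- swlda_fit(x, y)
  expect_equal(sum(c(3, 7) %in% m$selected), 1)
})

test_that("stepwise selection matches an add1/drop1 reference trace", {
  set.seed(55)
  for (rep in 1:5) {
    n <- 60
    x <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    y <- rep(c("a", "b"), each = n / 2)
    x[, 2] <- x[, 2] + ifelse(y == "b", 1.2, 0)
    x[, 5] <- x[, 5] + ifelse(y == "b", 0, 0.8)
    y01 <- as.numeric(y == "b")
    m <- swlda_fit(x, y)
    ref <- oracle_stepwise(x, y01)
    expect_setequal(m$selected, ref)
    # weights agree with the least-squares fit on the selected set
    fit <- lm(y01 ~ x[, m$selected])
    expect_equal(unname(m$weights), unname(coef(fit)[-1]),
                 tolerance = 1e-10)
  }
})

test_that("degenerate label sets are rejected", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(swlda_fit(x, rep("a", 10)), "two classes")
  expect_error(swlda_fit(x, c("a", rep("b", 9))), "2 trials per class")
})

test_that("stage-1 routing fully determines the stage-2 branch", {
  tpl <- erp_templates("movement")
  set.seed(56)
  e <- generate_synthetic_epochs(tpl, c(TT = 10, TR = 10, FA = 10, SO = 10),
                                 noise_sd = 0.5)
  tree <- fit_classifier_tree(e)
  tr <- classify_movement(tree, e, trace = TRUE)
  expect_true(all(tr$class[tr$stage1 == "correct"] %in% c("TT", "TR")))
  expect_true(all(tr$class[tr$stage1 == "error"] %in% c("FA", "SO")))
  expect_gt(mean(tr$class == e$labels), 0.9)  # far above 25% chance
})

test_that("noise-free identification epochs classify exactly", {
  tpl <- erp_templates("identification")
  set.seed(57)
  e <- generate_synthetic_epochs(tpl, c(CTI = 6, FTI = 6), noise_sd = 0,
                                 amp_jitter = 0.05)
  clf <- fit_ti_classifier(e)
  expect_equal(unname(classify_ti(clf, e)), e$labels)
})

test_that("leave-one-out counts conserve per-class totals", {
  tpl <- erp_templates("identification")
  set.seed(58)
  e <- generate_synthetic_epochs(tpl, c(CTI = 8, FTI = 8), noise_sd = 0.5)
  A <- loo_likelihood(e)
  counts <- attr(A, "counts")
  expect_equal(unname(colSums(counts)), c(8, 8))
  expect_true(all(abs(colSums(A) - 1) < 1e-9))
})

test_that("synthetic epochs honour counts, determinism and noise scaling", {
  tpl <- erp_templates("movement")
  set.seed(59)
  e <- generate_synthetic_epochs(tpl, c(TT = 7, TR = 3, FA = 2, SO = 1),
                                 noise_sd = 1)
  expect_equal(as.vector(table(factor(e$labels, MOVEMENT_CLASSES))),
               c(7, 3, 2, 1))
  set.seed(60)
  a <- generate_synthetic_epochs(tpl, c(TT = 3, TR = 3, FA = 3, SO = 3))
  set.seed(60)
  b <- generate_synthetic_epochs(tpl, c(TT = 3, TR = 3, FA = 3, SO = 3))
  expect_identical(a, b)
  # zero noise and zero jitter reproduce the templates exactly
  set.seed(61)
  pure <- generate_synthetic_epochs(tpl, c(SO = 2), noise_sd = 0,
                                    amp_jitter = 0)
  expect_equal(pure$data[, , 1], tpl$waves$SO)
  # error-class peaks exceed correct-class peaks (per-channel)
  expect_true(all(apply(abs(tpl$waves$SO), 1, max) >
                  apply(abs(tpl$waves$TT), 1, max)))
})

test_that("the 85/15 split is stratified and partitioned", {
  tpl <- erp_templates("movement")
  set.seed(62)
  e <- generate_synthetic_epochs(tpl, c(TT = 20, TR = 20, FA = 20, SO = 20),
                                 noise_sd = 1)
  sp <- split_train_test(e, 0.85)
  expect_equal(length(sp$train$labels) + length(sp$test$labels), 80)
  expect_equal(as.vector(table(sp$train$labels)), rep(17, 4))
  expect_equal(as.vector(table(sp$test$labels)), rep(3, 4))
})

test_that("epoch sets round-trip through the on-disk layout", {
  tpl <- erp_templates("identification")
  set.seed(63)
  e <- generate_synthetic_epochs(tpl, c(CTI = 2, FTI = 2), noise_sd = 0.5)
  d <- withr::local_tempdir()
  write_epochs_dir(e, d)
  back <- read_epochs_dir(d)
  expect_equal(back$labels, e$labels)
  expect_equal(back$srate, e$srate)
  expect_equal(back$data, e$data, ignore_attr = TRUE, tolerance = 1e-12)
})
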