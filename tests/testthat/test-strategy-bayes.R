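test_that("counterfactual classes reproduce the 1-D worked example", {
  # move from location 5 to 6 on the 9x1 grid
  g <- grid_world(9, 1)
  cf <- vapply(1:9, function(t)
    counterfactual_state(g, c(5, 1), c(6, 1), c(t, 1)), character(1))
  expect_equal(cf, c("FA", "FA", "FA", "FA", "SO", "TR", "TT", "TT", "TT"))
})

test_that("posterior updates match cell-by-cell enumeration", {
  g <- grid_world(9, 1)
  A <- likelihood_matrix(cbind(c(0.7, 0.1, 0.1, 0.1),
                               c(0.1, 0.7, 0.1, 0.1),
                               c(0.1, 0.1, 0.7, 0.1),
                               c(0.1, 0.1, 0.1, 0.7)),
                         "movement", floor = 0)
  got <- bayes_update_movement(posterior_init(g), g, c(5, 1), c(6, 1),
                               "TT", A)
  want <- oracle_bayes_movement(rep(1 / 9, 9), 9, 1, c(5, 1), c(6, 1),
                                "TT", A)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-9)
})

test_that("posterior updates agree with the oracle on random instances", {
  set.seed(20)
  for (i in 1:200) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    if (nr * nc < 2) nc <- nc + 1
    g <- grid_world(nr, nc)
    A <- likelihood_matrix(matrix(rgamma(16, 1), 4, 4), "movement")
    prior <- rgamma(g$n_cells, 1); prior <- prior / sum(prior)
    oc <- sample(g$n_cells, 1)
    nb <- g$nbrs[[oc]]
    dc <- nb[sample.int(length(nb), 1)]
    obs <- sample(MOVEMENT_CLASSES, 1)
    origin <- cell_to_pos(g, oc); dest <- cell_to_pos(g, dc)
    got <- bayes_update_movement(prior, g, origin, dest, obs, A)
    want <- oracle_bayes_movement(prior, nr, nc, origin, dest, obs, A)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("degenerate and uniform likelihoods give the limiting posteriors", {
  g <- grid_world(9, 1)
  unif <- likelihood_matrix(matrix(1, 4, 4), "movement", floor = 0)
  p0 <- posterior_init(g)
  expect_equal(bayes_update_movement(p0, g, c(5, 1), c(6, 1), "FA", unif),
               p0)
  ident <- likelihood_matrix(diag(4), "movement", floor = 0)
  p1 <- bayes_update_movement(p0, g, c(5, 1), c(6, 1), "TR", ident)
  expect_equal(p1, c(rep(0, 5), 1, rep(0, 3)))
})

test_that("deselection downdates the identified cell", {
  g <- grid_world(9, 1)
  A2 <- likelihood_matrix(cbind(c(0.8, 0.2), c(0.2, 0.8)),
                          "identification", floor = 0)
  got <- bayes_update_ti(posterior_init(g), g, c(4, 1), "FTI", A2)
  # hand evaluation: identified cell 0.2 against 0.8 everywhere else
  expect_equal(got[4], 0.2 / (0.2 + 8 * 0.8), tolerance = 1e-12)
  expect_equal(got, oracle_bayes_ti(rep(1 / 9, 9), 9, 1, c(4, 1), "FTI",
                                    A2),
               tolerance = 1e-12)
  ident <- likelihood_matrix(diag(2), "identification", floor = 0)
  z <- bayes_update_ti(posterior_init(g), g, c(4, 1), "FTI", ident)
  expect_equal(z[4], 0)
  expect_equal(sum(z), 1)
  unif <- likelihood_matrix(matrix(1, 2, 2), "identification", floor = 0)
  expect_equal(bayes_update_ti(posterior_init(g), g, c(4, 1), "FTI", unif),
               posterior_init(g))
})

test_that("the observation marginal divisor cancels under normalisation", {
  set.seed(21)
  g <- grid_world(4, 5)
  A <- likelihood_matrix(matrix(rgamma(16, 1), 4, 4), "movement")
  prior <- rgamma(20, 1); prior <- prior / sum(prior)
  with_div <- bayes_update_movement(prior, g, c(2, 2), c(2, 3), "SO", A)
  # recompute dropping the marginal entirely
  cls <- vapply(1:20, function(k)
    counterfactual_state(g, c(2, 2), c(2, 3), cell_to_pos(g, k)),
    character(1))
  lik <- A["SO", cls]
  no_div <- lik * prior / sum(lik * prior)
  expect_equal(with_div, unname(no_div), tolerance = 1e-12)
})

test_that("soft observations form weighted likelihood columns", {
  g <- grid_world(9, 1)
  set.seed(22)
  A <- likelihood_matrix(matrix(rgamma(16, 1), 4, 4), "movement")
  p0 <- posterior_init(g)
  hard <- bayes_update_movement(p0, g, c(5, 1), c(6, 1), "TT", A)
  soft1 <- bayes_update_movement(p0, g, c(5, 1), c(6, 1), c(1, 0, 0, 0), A)
  expect_equal(soft1, hard, tolerance = 1e-12)
  mix <- bayes_update_movement(p0, g, c(5, 1), c(6, 1),
                               c(0.75, 0.25, 0, 0), A)
  expect_false(isTRUE(all.equal(mix, hard)))
  expect_equal(sum(mix), 1, tolerance = 1e-9)
})

test_that("identification thresholds reproduce the printed anchors", {
  th1 <- stringency_thresholds(0.1)
  expect_equal(th1$lower, 0.1)
  expect_equal(th1$upper, 2 / 3)
  expect_true(decide_identification(0.15, "TR", th1))
  expect_true(decide_identification(0.70, "TT", th1))
  expect_false(decide_identification(0.66, "TT", th1))
  th9 <- stringency_thresholds(0.9)
  expect_equal(th9$upper, 1.0 / 1.1)
  expect_false(decide_identification(0.50, "TR", th9))
  expect_false(decide_identification(0.905, "TT", th9))
  # binary variant uses the upper formula regardless of the output
  for (s in seq(0.1, 0.9, 0.1)) {
    th <- stringency_thresholds(s)
    expect_equal(th$upper, (s + 0.1) / (s + 0.2))
    expect_true(decide_identification(th$upper + 1e-9, "correct", th,
                                      binary = TRUE))
    expect_false(decide_identification(th$upper - 1e-9, "correct", th,
                                       binary = TRUE))
  }
  expect_error(decide_identification(0.5, "CTI", th1), "movement")
  expect_error(stringency_thresholds(0.05), "stringency")
})

test_that("raising stringency never turns not-identify into identify", {
  set.seed(23)
  for (i in 1:200) {
    p <- runif(1)
    obs <- sample(MOVEMENT_CLASSES, 1)
    s <- sort(runif(2, 0.1, 0.9))
    lo <- decide_identification(p, obs, stringency_thresholds(s[1]))
    hi <- decide_identification(p, obs, stringency_thresholds(s[2]))
    expect_false(!lo && hi)
  }
})

test_that("action selection follows the posterior argmax", {
  g <- grid_world(9, 1)
  th <- stringency_thresholds(0.5)
  peaked <- c(rep(0, 8), 1)
  act <- next_action_bayes(peaked, g, c(2, 1), "TT", th)
  expect_equal(act$type, "move")
  expect_equal(act$cell, c(3, 1))
  # identification fires from the current cell when thresholds are met
  actid <- next_action_bayes(c(0, 0.9, rep(0.1 / 7, 7)), g, c(2, 1),
                             "TR", th)
  expect_equal(actid$type, "identify")
  expect_equal(actid$cell, c(2, 1))
  # argmax at the current cell without identification: move towards the
  # runner-up
  p <- c(0.05, 0.5, 0.05, 0.05, 0.3, 0.02, 0.01, 0.01, 0.01)
  act2 <- next_action_bayes(p, g, c(2, 1), "TT", th)
  expect_equal(act2$type, "move")
  expect_equal(act2$cell, c(3, 1))  # towards cell 5, the best other cell
  # full tie: both neighbours occur over repeated draws
  set.seed(24)
  moves <- replicate(60, next_action_bayes(posterior_init(g), g, c(5, 1),
                                           "TT", th)$cell[1])
  expect_setequal(unique(moves), c(4, 6))
})
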