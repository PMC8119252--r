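test_that("exact state probabilities follow the Ising measure", {
  J <- matrix(c(0, 1, 1, 0), 2)
  sp <- ising_state_probs(J, c(0, 0))
  # two coupled nodes at zero thresholds: P(1,1) = e / (3 + e)
  expect_equal(sp$prob[sp$Var1 == 1 & sp$Var2 == 1], exp(1) / (3 + exp(1)),
               tolerance = 1e-12)
  expect_equal(sp$prob[sp$Var1 == 0 & sp$Var2 == 0], 1 / (3 + exp(1)),
               tolerance = 1e-12)
  # independence: all four patterns equally likely
  sp0 <- ising_state_probs(matrix(0, 2, 2), c(0, 0))
  expect_equal(sp0$prob, rep(0.25, 4))
})

test_that("exact sampler frequencies match the exact distribution", {
  J <- matrix(c(0, 1, 1, 0), 2)
  set.seed(51)
  x <- sample_ising_exact(J, c(0, 0), 1e5)
  p11 <- mean(x$responses[, 1] == 1 & x$responses[, 2] == 1)
  expect_equal(p11, exp(1) / (3 + exp(1)), tolerance = 0.006)
  x1 <- sample_ising_exact(J, c(0, 0), 500, seed = 7)
  x2 <- sample_ising_exact(J, c(0, 0), 500, seed = 7)
  expect_identical(x1$responses, x2$responses)
  expect_error(sample_ising_exact(matrix(0, 21, 21), rep(0, 21), 10),
               "p > 20")
})

test_that("gibbs sampler hits independent marginals and couplings", {
  x <- sample_ising_gibbs(matrix(0, 10, 10), rep(0, 10), 3000, seed = 52)
  expect_true(all(abs(colMeans(x$responses) - 0.5) < 0.04))
  J <- matrix(0, 3, 3); J[1, 2] <- J[2, 1] <- 1
  y <- sample_ising_gibbs(J, rep(0, 3), 3000, seed = 53)
  expect_gt(cor(y$responses[, 1], y$responses[, 2]), 0.1)
  expect_error(sample_ising_gibbs(J, rep(0, 3), 100, burn_in = 10), "burn_in")
  y2 <- sample_ising_gibbs(J, rep(0, 3), 300, seed = 54)
  y3 <- sample_ising_gibbs(J, rep(0, 3), 300, seed = 54)
  expect_identical(y2$responses, y3$responses)
})

test_that("gibbs and exact samplers agree on pairwise correlations", {
  # moderately coupled 15-node model, stable regime
  plant <- planted_coupling_matrix(c(5, 5, 5), 0.5, 0.1)
  tau <- seq(-1.5, 0.5, length.out = 15)
  set.seed(55)
  xe <- sample_ising_exact(plant$J, tau, 4e4)
  xg <- sample_ising_gibbs(plant$J, tau, 4e4, burn_in = 500, thin = 5)
  ce <- cor(xe$responses)
  cg <- cor(xg$responses)
  expect_lt(max(abs(ce - cg)), 0.02)
  expect_lt(max(abs(colMeans(xe$responses) - colMeans(xg$responses))), 0.02)
})

test_that("threshold calibration reaches target endorsement rates", {
  plant <- planted_coupling_matrix(c(4, 4), 0.5, 0.1)
  targets <- seq(0.15, 0.65, length.out = 8)
  cal <- calibrate_thresholds(plant$J, targets, seed = 56)
  expect_lt(max(abs(cal$achieved - targets)), 0.02)
  set.seed(57)
  x <- sample_ising_gibbs(plant$J, cal$tau, 20000, burn_in = 500, thin = 5)
  expect_lt(max(abs(colMeans(x$responses) - targets)), 0.025)
})

test_that("planted generator returns calibrated ground truth", {
  gen <- planted_solife_generator(n = 300, seed = 58)
  expect_equal(length(gen$data$item_ids), 43)
  expect_equal(gen$partition$k, 4)
  expect_equal(as.vector(table(gen$partition$labels)), c(12, 11, 10, 10))
  targets <- unlist(lapply(c(12, 11, 10, 10),
                           function(sz) seq(0.1, 0.7, length.out = sz)))
  expect_lt(max(abs(gen$achieved_rates - targets)), 0.02)
  expect_true(all(gen$network$weights[gen$partition$labels[col(gen$network$weights)] !=
                                        gen$partition$labels[row(gen$network$weights)]] == 0))
  gen2 <- planted_solife_generator(n = 300, seed = 58)
  expect_identical(gen$data$responses, gen2$data$responses)
})

test_that("partition agreement collapses when couplings are uniform", {
  # no-structure control: with j_within = j_between the "blocks" are a
  # fiction, so agreement with them must fall far below the structured run
  # (on 15 nodes the chance level of NMI is well above zero, so the
  # structured counterpart anchors the comparison)
  uni <- planted_solife_generator(n = 2500, block_sizes = c(5, 5, 5),
                                  j_within = 0.2, j_between = 0.2,
                                  seed = 59, burn_in = 300, thin = 3)
  net_u <- estimate_network(uni$data, gamma = 0.25)
  part_u <- suppressWarnings(fast_greedy(net_u))
  nmi_u <- nmi(part_u, uni$partition)
  str <- planted_solife_generator(n = 2500, block_sizes = c(5, 5, 5),
                                  j_within = 0.8, j_between = 0, seed = 59)
  net_s <- estimate_network(str$data, gamma = 0.25)
  nmi_s <- nmi(fast_greedy(net_s), str$partition)
  expect_gte(nmi_s, 0.9)
  expect_lt(nmi_u, 0.5)
  expect_gt(nmi_s - nmi_u, 0.4)
})

test_that("generated data round-trips through the CSV loader", {
  gen <- planted_solife_generator(n = 120, block_sizes = c(4, 4, 4),
                                  j_within = 0.8, seed = 60)
  dir <- withr::local_tempdir()
  paths <- write_generated(gen, dir)
  expect_true(all(file.exists(paths)))
  x <- load_responses(paths[["data"]])
  expect_equal(x$responses, gen$data$responses)
  truth <- utils::read.csv(paths[["edges"]])
  expect_equal(nrow(truth), edge_count(gen$network))
})
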