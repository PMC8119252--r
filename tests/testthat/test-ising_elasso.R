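test_that("ebic formula reduces to BIC at gamma 0 and matches arithmetic", {
  expect_equal(ebic(-100, 3, 1000, 42, 1),
               200 + 3 * log(1000) + 6 * log(42), tolerance = 1e-12)
  expect_equal(ebic(-100, 3, 1000, 42, 1), 243.15, tolerance = 0.01)
  expect_equal(ebic(-50, 0, 500, 10, 2), 100)
  expect_equal(ebic(-80, 4, 600, 20, 0),
               -2 * -80 + 4 * log(600))
})

test_that("regularisation path starts empty and is monotone in lambda", {
  gen <- make_small_planted()
  path <- nodewise_path(gen$data, node = 1)
  expect_equal(sum(path$coefs[, 1] != 0), 0)  # all slopes zero at lambda_max
  expect_true(all(diff(path$lambda) < 0))
  # nonzero count non-increasing as lambda increases
  expect_true(all(diff(path$df) >= 0))
  expect_equal(path$which_min, which.min(path$ebic))
  expect_error(nodewise_path(resp(cbind(rep(1, 20),
                                        matrix(rbinom(40, 1, .5), 20))),
                             node = 1), "constant")
})

test_that("independent balanced items yield zero slopes along the path", {
  # all 8 patterns of 3 items equally often: exact empirical independence
  pats <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  x <- resp(pats[rep(1:8, each = 10), ])
  path <- nodewise_path(x, node = 1)
  expect_lt(max(abs(path$coefs)), 1e-6)
  net <- estimate_network(x, gamma = 0.5)
  expect_equal(edge_count(net), 0)
})

test_that("small-lambda path coefficients approach the unpenalised fit", {
  J <- matrix(0, 3, 3)
  J[1, 2] <- J[2, 1] <- 1
  set.seed(11)
  x <- sample_ising_exact(J, rep(0, 3), 2000)
  path <- nodewise_path(x, node = 1, lambda_min_ratio = 1e-4)
  fit <- glm(x$responses[, 1] ~ x$responses[, -1], family = binomial)
  last <- path$coefs[, ncol(path$coefs)]
  # the strong true coupling is close to the MLE; the absent edge stays small
  expect_equal(unname(last[1]), unname(coef(fit)[2]), tolerance = 0.1)
  expect_gt(last[1], 0.5)
  expect_lt(abs(last[2]), 0.15)
})

test_that("estimated networks are symmetric with AND a subset of OR", {
  gen <- make_small_planted()
  net_and <- estimate_network(gen$data, gamma = 0.5, rule = "and")
  net_or <- estimate_network(gen$data, gamma = 0.5, rule = "or")
  expect_identical(net_and$weights, t(net_and$weights))
  expect_equal(diag(net_and$weights), setNames(rep(0, 10), net_and$item_ids))
  and_edges <- net_and$weights != 0
  or_edges <- net_or$weights != 0
  expect_true(all(or_edges[and_edges]))
  expect_gte(sum(or_edges), sum(and_edges))
})

test_that("increasing gamma never adds edges", {
  gen <- make_small_planted(n = 600)
  counts <- vapply(c(0, 0.25, 0.5, 1), function(g) {
    edge_count(estimate_network(gen$data, gamma = g))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("EBIC-lasso neighbourhood selection matches all-subsets search at p = 3", {
  # oracle: exhaustive unpenalised logistic fits over all predictor subsets,
  # scored with the same EBIC
  subset_oracle <- function(x, node, gamma) {
    y <- x$responses[, node]
    pred <- x$responses[, -node, drop = FALSE]
    subsets <- list(integer(0), 1L, 2L, 1:2)
    scores <- vapply(subsets, function(s) {
      fit <- if (length(s)) glm(y ~ pred[, s, drop = FALSE], family = binomial)
             else glm(y ~ 1, family = binomial)
      ebic(as.numeric(logLik(fit)), length(s), length(y), ncol(pred), gamma)
    }, numeric(1))
    sort(subsets[[which.min(scores)]])
  }
  scenarios <- list(
    list(j = 1.2, seed = 21),   # strong real edge
    list(j = 0, seed = 22),     # no edges
    list(j = 2, seed = 23)
  )
  for (sc in scenarios) {
    J <- matrix(0, 3, 3)
    J[1, 2] <- J[2, 1] <- sc$j
    x <- sample_ising_exact(J, c(-0.3, 0.2, 0), 300, seed = sc$seed)
    path <- nodewise_path(x, node = 1, gamma = 0.25,
                          lambda_min_ratio = 1e-4)
    selected <- sort(as.integer(which(path$coefs[, path$which_min] != 0)))
    expect_equal(selected, as.integer(subset_oracle(x, 1, 0.25)))
  }
})

test_that("planted structure in the stable coupling regime is recovered", {
  # 10-node two-block design with J = 0.8: each node has 4 neighbours, so
  # the block stays below the mean-field instability and marginals vary
  hits <- t(sapply(1:10, function(s) {
    gen <- planted_solife_generator(n = 4000, block_sizes = c(5, 5),
                                    j_within = 0.8, seed = s)
    net <- estimate_network(gen$data, gamma = 1)
    ut <- upper.tri(net$weights)
    true_e <- gen$network$weights[ut] != 0
    est_e <- net$weights[ut] != 0
    c(sens = mean(est_e[true_e]), spec = mean(!est_e[!true_e]))
  }))
  expect_gte(mean(hits[, "sens"]), 0.9)
  expect_gte(mean(hits[, "spec"]), 0.9)
})

test_that("constant columns are isolated instead of breaking estimation", {
  gen <- make_small_planted(n = 600)
  m <- gen$data$responses
  m[, 3] <- 0L
  x <- resp(m)
  expect_warning(net <- estimate_network(x, gamma = 0.5), "constant")
  expect_equal(unname(net$weights[3, ]), rep(0, 10))
  expect_equal(unname(net$weights[, 3]), rep(0, 10))
})

test_that("edge list and network files round-trip", {
  gen <- make_small_planted(n = 600)
  net <- estimate_network(gen$data, gamma = 0.5)
  el <- edge_list(net)
  expect_true(all(el$weight != 0))
  expect_equal(nrow(el), edge_count(net))
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["edges"]])
  expect_equal(nrow(back), nrow(el))
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::ecount(g), nrow(el))
})
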