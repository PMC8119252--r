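two_triangles <- function(bridge = 1) {
  W <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    W[e[1], e[2]] <- W[e[2], e[1]] <- 1
  }
  W[3, 4] <- W[4, 3] <- bridge
  W
}

test_that("modularity matches hand-derived and literal-sum values", {
  net <- ising_network(two_triangles())
  part <- new_partition(c(1, 1, 1, 2, 2, 2))
  expect_equal(modularity_q(net, part), 5 / 14, tolerance = 1e-12)
  # trivial partition: the two sums cancel
  expect_equal(modularity_q(net, new_partition(rep(1, 6))), 0,
               tolerance = 1e-12)
  # label permutation leaves Q unchanged
  expect_equal(modularity_q(net, new_partition(c(2, 2, 2, 1, 1, 1))),
               5 / 14, tolerance = 1e-12)
  expect_error(modularity_q(ising_network(matrix(0, 3, 3)),
                            new_partition(1:3)), "no edges")
})

test_that("modularity agrees with the literal double sum and igraph", {
  set.seed(12)
  for (rep in 1:20) {
    p <- sample(4:7, 1)
    W <- random_weights(p, density = 0.6)
    if (all(W == 0)) next
    net <- ising_network(W)
    lab <- sample(1:3, p, replace = TRUE)
    part <- new_partition(lab)
    expect_equal(modularity_q(net, part),
                 oracle_modularity(abs(W), part$labels), tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_q(net, part),
                 igraph::modularity(g, part$labels,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
  }
})

test_that("fast greedy recovers planted cliques and is self-consistent", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  W[4, 5] <- W[5, 4] <- 0.1
  net <- ising_network(W)
  part <- fast_greedy(net)
  expect_equal(part$k, 2)
  expect_equal(unname(part$labels[1:4]), rep(part$labels[[1]], 4))
  expect_equal(unname(part$labels[5:8]), rep(part$labels[[5]], 4))
  # recomputed Q equals the partition's stored Q, and matches the
  # exhaustive-search optimum on this well-separated case
  expect_equal(part$q, modularity_q(net, part))
  expect_equal(part$q, oracle_best_modularity(abs(W)), tolerance = 1e-10)
  # single clique: any split lowers Q
  clique <- ising_network(matrix(1, 5, 5) - diag(5))
  expect_equal(fast_greedy(clique)$k, 1)
})

test_that("fast greedy never exceeds the exhaustive modularity optimum", {
  set.seed(13)
  for (rep in 1:12) {
    p <- sample(5:8, 1)
    W <- random_weights(p, density = 0.5, signed = FALSE)
    if (sum(W != 0) < 4) next
    net <- ising_network(W)
    part <- suppressWarnings(fast_greedy(net))
    if (part$k == length(part$labels)) next
    expect_lte(part$q, oracle_best_modularity(abs(W)) + 1e-10)
  }
})

test_that("empty networks fall back to singleton communities", {
  net <- ising_network(matrix(0, 4, 4))
  expect_warning(part <- fast_greedy(net), "no edges")
  expect_equal(part$k, 4)
})

test_that("nmi is 1 for identical, 0 against the trivial partition", {
  p1 <- new_partition(c(1, 1, 2, 2, 3, 3))
  expect_equal(nmi(p1, p1), 1)
  p_shuffled <- new_partition(c(3, 3, 1, 1, 2, 2))
  expect_equal(nmi(p1, p_shuffled), 1)  # label permutation invariance
  expect_equal(nmi(p1, new_partition(rep(1, 6))), 0)
  p2 <- new_partition(c(1, 1, 1, 2, 2, 2))
  expect_equal(nmi(p1, p2), nmi(p2, p1))  # symmetry
  expect_gt(nmi(p1, p2), 0)
  expect_lt(nmi(p1, p2), 1)
})

test_that("nmi uses the arithmetic-mean normalisation", {
  p1 <- new_partition(c(1, 1, 2, 2))
  p2 <- new_partition(c(1, 2, 1, 2))
  # independent margins: joint counts all 1, I = 0
  expect_equal(nmi(p1, p2), 0)
  # hand-computed case: p1 = {a,b | c,d}, p2 = {a,b,c | d}
  p3 <- new_partition(c(1, 1, 1, 2))
  h1 <- -sum(rep(0.5, 2) * log(0.5))
  h2 <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  mi <- 0.5 * log(0.5 / (0.5 * 0.75)) + 0.25 * log(0.25 / (0.5 * 0.75)) +
    0.25 * log(0.25 / (0.5 * 0.25))
  expect_equal(nmi(p1, p3), 2 * mi / (h1 + h2), tolerance = 1e-12)
  # cross-check against igraph's implementation of the same variant
  expect_equal(nmi(p1, p3),
               igraph::compare(p1$labels, p3$labels, method = "nmi"),
               tolerance = 1e-10)
})

test_that("overlap percent uses optimal matching and lists mismatches", {
  ref <- new_partition(setNames(rep(1:4, c(12, 11, 10, 10)),
                                as.character(1:43)))
  ov <- overlap_percent(ref, ref)
  expect_equal(ov$percent, 100)
  expect_equal(length(ov$mismatched), 0)
  # move three items to other communities: 40/43 agree
  lab <- ref$labels
  lab[c("8", "19", "38")] <- c(4, 4, 1)
  det <- new_partition(lab)
  ov2 <- overlap_percent(det, ref)
  expect_equal(ov2$percent, 100 * 40 / 43)
  expect_equal(round(ov2$percent), 93)
  expect_setequal(ov2$mismatched, c("8", "19", "38"))
  # matching must be immune to label permutation of the detected side
  det_perm <- new_partition(setNames(c(5, 3, 1, 2)[lab], names(lab)))
  expect_equal(overlap_percent(det_perm, ref)$percent, ov2$percent)
})

test_that("overlap handles unequal community counts", {
  ref <- new_partition(c(1, 1, 1, 2, 2, 2))
  det <- new_partition(c(1, 1, 2, 3, 3, 3))  # an extra splinter community
  ov <- overlap_percent(det, ref)
  expect_equal(ov$percent, 100 * 5 / 6)
  expect_equal(length(ov$mismatched), 1)
})

test_that("partition table mirrors the catalog layout", {
  cat43 <- load_catalog()
  det <- catalog_partition(cat43)
  tab <- partition_table(det, cat43)
  expect_equal(nrow(tab), 43)
  expect_true(all(tab$match))
  expect_equal(tab$subscale[tab$item_id == "5"], "IA")
})
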