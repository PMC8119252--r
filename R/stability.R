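upper_vec <- function(W) W[upper.tri(W)]

#' Split-half stability of the estimated network
#'
#' Participants are randomly halved `n_splits` times; a network is estimated
#' on each half and its upper-triangle edge vector (zeros included) is
#' correlated (Spearman) with the full-sample network's. The half-vs-half
#' correlation of each split is also reported.
#'
#' @param data an `item_responses` object with `N >= 4p`.
#' @param gamma EBIC hyperparameter passed to [estimate_network()].
#' @param n_splits number of random splits (default 10).
#' @param seed RNG seed.
#' @param rule edge rule, see [estimate_network()].
#' @return list of class `split_half_summary`: `rho` (per half-network
#'   correlation with the full network, 2 per split), `rho_half_vs_half`,
#'   `median`, `range`, `n_splits`, `gamma`, `failed` (count of halves where
#'   estimation failed and was skipped with a warning).
#' @export
split_half <- function(data, gamma = 1, n_splits = 10, seed = NULL,
                       rule = "and") {
  stopifnot(inherits(data, "item_responses"))
  n <- data$n_participants
  p <- length(data$item_ids)
  if (n < 4 * p) stop("split-half needs N >= 4p")
  if (!is.null(seed)) set.seed(seed)
  full <- estimate_network(data, gamma = gamma, rule = rule)
  fv <- upper_vec(full$weights)
  rho <- numeric(0)
  hvh <- numeric(0)
  failed <- 0L
  for (s in seq_len(n_splits)) {
    idx <- sample.int(n, floor(n / 2))
    halves <- list(idx, setdiff(seq_len(n), idx))
    nets <- lapply(halves, function(h) {
      tryCatch(
        estimate_network(
          structure(list(responses = data$responses[h, , drop = FALSE],
                         item_ids = data$item_ids,
                         n_participants = length(h)),
                    class = "item_responses"),
          gamma = gamma, rule = rule),
        error = function(e) {
          warning("half-sample estimation failed in split ", s, ": ",
                  conditionMessage(e))
          NULL
        })
    })
    vecs <- lapply(nets, function(nt) if (is.null(nt)) NULL else
      upper_vec(nt$weights))
    for (v in vecs) {
      if (is.null(v)) failed <- failed + 1L
      else rho <- c(rho, stats::cor(v, fv, method = "spearman"))
    }
    if (!is.null(vecs[[1]]) && !is.null(vecs[[2]])) {
      hvh <- c(hvh, stats::cor(vecs[[1]], vecs[[2]], method = "spearman"))
    }
  }
  structure(list(rho = rho, rho_half_vs_half = hvh,
                 median = stats::median(rho), range = range(rho),
                 n_splits = n_splits, gamma = gamma, failed = failed),
            class = "split_half_summary")
}

#' @exportS3Method base::print
print.split_half_summary <- function(x, ...) {
  cat(sprintf(
    "Split-half stability (%d splits, gamma = %g): median rho = %.3f, range %.3f-%.3f\n",
    x$n_splits, x$gamma, x$median, x$range[1], x$range[2]))
  invisible(x)
}

#' Nonparametric bootstrap of edge weights and centralities
#'
#' Case-resampling bootstrap: participants are resampled with replacement B
#' times and the network re-estimated on each resample. Per-edge and
#' per-node expected-influence 2.5/97.5 percent quantile intervals are
#' returned, along with the raw bootstrap draws (needed by
#' [centrality_difference_test()]). Columns that become constant in a
#' resample are isolated (couplings 0) for that resample, as in estimation.
#'
#' @param data an `item_responses` object.
#' @param gamma EBIC hyperparameter.
#' @param B number of resamples (>= 100; default 1000).
#' @param seed RNG seed (results are bit-reproducible given the seed).
#' @param rule edge rule.
#' @param metrics centrality draws to keep; any of `"expected_influence"`,
#'   `"strength"`, `"closeness"`, `"betweenness"`.
#' @return list of class `bootstrap_summary`: `edge_quantiles` (data.frame
#'   item_i, item_j, estimate, lower, upper), `centrality_quantiles`,
#'   `edge_draws` (B x n_pairs), `centrality_draws` (list of B x p
#'   matrices), `B`, `seed`, `gamma`.
#' @export
bootstrap_edges <- function(data, gamma = 1, B = 1000, seed = NULL,
                            rule = "and",
                            metrics = c("expected_influence", "strength",
                                        "closeness", "betweenness")) {
  stopifnot(inherits(data, "item_responses"), B >= 100)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n <- data$n_participants
  p <- length(data$item_ids)
  full <- estimate_network(data, gamma = gamma, rule = rule)
  pair_idx <- which(upper.tri(full$weights), arr.ind = TRUE)
  edge_draws <- matrix(NA_real_, B, nrow(pair_idx))
  cent_draws <- lapply(metrics, function(m) matrix(NA_real_, B, p))
  names(cent_draws) <- metrics
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bd <- structure(list(responses = data$responses[idx, , drop = FALSE],
                         item_ids = data$item_ids, n_participants = n),
                    class = "item_responses")
    net <- suppressWarnings(estimate_network(bd, gamma = gamma, rule = rule))
    edge_draws[b, ] <- upper_vec(net$weights)
    for (m in metrics) {
      cent_draws[[m]][b, ] <- switch(m,
        expected_influence = expected_influence(net),
        strength = node_strength(net),
        closeness = closeness_centrality(net)$closeness,
        betweenness = betweenness_centrality(net))
    }
  }
  qs <- t(apply(edge_draws, 2L, stats::quantile, probs = c(0.025, 0.975)))
  edge_q <- data.frame(item_i = data$item_ids[pair_idx[, 1]],
                       item_j = data$item_ids[pair_idx[, 2]],
                       estimate = upper_vec(full$weights),
                       lower = qs[, 1], upper = qs[, 2],
                       stringsAsFactors = FALSE)
  cent_q <- do.call(rbind, lapply(metrics, function(m) {
    q <- t(apply(cent_draws[[m]], 2L, stats::quantile,
                 probs = c(0.025, 0.975)))
    est <- switch(m,
      expected_influence = expected_influence(full),
      strength = node_strength(full),
      closeness = closeness_centrality(full)$closeness,
      betweenness = betweenness_centrality(full))
    data.frame(metric = m, item_id = data$item_ids, estimate = unname(est),
               lower = q[, 1], upper = q[, 2], stringsAsFactors = FALSE)
  }))
  structure(list(edge_quantiles = edge_q, centrality_quantiles = cent_q,
                 edge_draws = edge_draws, centrality_draws = cent_draws,
                 item_ids = data$item_ids, B = B, seed = seed, gamma = gamma),
            class = "bootstrap_summary")
}

#' @exportS3Method base::print
print.bootstrap_summary <- function(x, ...) {
  cat("Bootstrap summary: B =", x$B, "resamples,",
      nrow(x$edge_quantiles), "edges,",
      length(x$item_ids), "nodes\n")
  invisible(x)
}

#' Bootstrapped centrality difference test
#'
#' Two nodes differ significantly on a centrality metric when the bootstrap
#' quantile interval of their difference excludes zero.
#'
#' @param boot a `bootstrap_summary` holding draws for `metric`.
#' @param node_a,node_b node ids or indices.
#' @param metric one of the metrics kept in `boot`.
#' @param level interval level (default 0.95).
#' @return list: `significant` (logical), `lower`, `upper`, `estimate_diff`.
#' @export
centrality_difference_test <- function(boot, node_a, node_b,
                                       metric = "expected_influence",
                                       level = 0.95) {
  stopifnot(inherits(boot, "bootstrap_summary"))
  if (!metric %in% names(boot$centrality_draws)) {
    stop("metric not kept in bootstrap: ", metric)
  }
  ia <- if (is.character(node_a)) match(node_a, boot$item_ids) else node_a
  ib <- if (is.character(node_b)) match(node_b, boot$item_ids) else node_b
  if (is.na(ia) || is.na(ib)) stop("unknown node")
  d <- boot$centrality_draws[[metric]][, ia] -
    boot$centrality_draws[[metric]][, ib]
  alpha <- (1 - level) / 2
  ci <- stats::quantile(d, probs = c(alpha, 1 - alpha), names = FALSE)
  list(significant = ci[1] > 0 || ci[2] < 0,
       lower = ci[1], upper = ci[2], estimate_diff = mean(d))
}
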