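#' One-step expected influence
#'
#' Sum of a node's signed edge weights (diagonal excluded). Equals strength
#' when all edges are non-negative.
#'
#' @param net an `ising_network`.
#' @param node node index or id; `NULL` (default) returns all nodes.
#' @return named numeric vector (or scalar for a single node).
#' @export
expected_influence <- function(net, node = NULL) {
  ei <- rowSums(net$weights)
  if (is.null(node)) ei else ei[node]
}

#' Node strength
#'
#' Sum of a node's absolute edge weights.
#'
#' @inheritParams expected_influence
#' @return named numeric vector (or scalar).
#' @export
node_strength <- function(net, node = NULL) {
  s <- rowSums(abs(net$weights))
  if (is.null(node)) s else s[node]
}

#' Edge weights to shortest-path distances
#'
#' The conventional transform for centrality on association networks:
#' `d_ij = 1 / |J_ij|` for nonzero edges, `Inf` for absent edges, 0 on the
#' diagonal. Stronger (absolute) connections are shorter.
#'
#' @param net an `ising_network`.
#' @return p x p distance matrix.
#' @export
weight_to_distance <- function(net) {
  W <- abs(net$weights)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  dimnames(D) <- dimnames(net$weights)
  D
}

graph_distances <- function(net) {
  g <- as_igraph(net, mode = "abs")
  w <- igraph::E(g)$weight
  igraph::distances(g, weights = 1 / w)
}

#' Closeness centrality on inverse-weight distances
#'
#' `1 / sum_j d(node, j)` over all other nodes, with shortest-path distances
#' on `1/|weight|` edge lengths. In a disconnected graph the sum runs over
#' the node's own component only, and the node is flagged; a fully isolated
#' node gets closeness 0.
#'
#' @param net an `ising_network`.
#' @param node node index or id; `NULL` (default) for all nodes.
#' @return for all nodes, a data.frame with columns `closeness` and
#'   `component_flag` (TRUE when the value was computed within a proper
#'   subcomponent); for one node, the scalar closeness.
#' @export
closeness_centrality <- function(net, node = NULL) {
  D <- graph_distances(net)
  p <- nrow(D)
  cl <- numeric(p)
  flag <- logical(p)
  for (i in seq_len(p)) {
    d <- D[i, -i]
    reach <- is.finite(d)
    flag[i] <- !all(reach)
    cl[i] <- if (!any(reach)) 0 else 1 / sum(d[reach])
  }
  names(cl) <- net$item_ids
  if (!is.null(node)) return(cl[node])
  data.frame(item_id = net$item_ids, closeness = unname(cl),
             component_flag = flag, stringsAsFactors = FALSE)
}

#' Betweenness centrality on inverse-weight distances
#'
#' Brandes betweenness: for each unordered pair of other nodes, the fraction
#' of shortest paths (on `1/|weight|` edge lengths) passing through the
#' node, with fractional credit for tied shortest paths.
#'
#' @inheritParams closeness_centrality
#' @return named numeric vector (or scalar for one node).
#' @export
betweenness_centrality <- function(net, node = NULL) {
  g <- as_igraph(net, mode = "abs")
  w <- igraph::E(g)$weight
  b <- igraph::betweenness(g, weights = if (length(w)) 1 / w else NULL,
                           directed = FALSE)
  names(b) <- net$item_ids
  if (is.null(node)) b else b[node]
}

#' Node predictability (correct classification rate)
#'
#' How well a node's 0/1 state is classified by an (unpenalised) logistic
#' model on its estimated network neighbourhood: `CC` is the proportion of
#' participants classified correctly at a 0.5 probability threshold, and
#' `nCC = (CC - CC_marg) / (1 - CC_marg)` normalises beyond the accuracy
#' `CC_marg` of always guessing the node's majority category. A node with an
#' empty neighbourhood falls back to the intercept-only model (CC = CC_marg,
#' nCC = 0); when `CC_marg = 1` the normalised value is undefined (`NA`).
#'
#' @param data the `item_responses` the network was estimated from.
#' @param net an `ising_network`.
#' @param node node index or id; `NULL` (default) for all nodes.
#' @return data.frame with columns `item_id`, `cc`, `ncc` (or a named vector
#'   `c(cc, ncc)` for a single node).
#' @export
predictability <- function(data, net, node = NULL) {
  stopifnot(inherits(data, "item_responses"), inherits(net, "ising_network"))
  x <- data$responses
  one <- function(i) {
    y <- x[, i]
    marg <- max(mean(y), 1 - mean(y))
    nb <- which(net$weights[, i] != 0)
    if (length(nb) == 0) {
      cc <- marg
    } else {
      df <- data.frame(y = y, x[, nb, drop = FALSE])
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      cc <- mean((stats::fitted(fit) >= 0.5) == (y == 1))
    }
    ncc <- if (marg >= 1) NA_real_ else (cc - marg) / (1 - marg)
    c(cc = cc, ncc = ncc)
  }
  if (!is.null(node)) {
    i <- if (is.character(node)) match(node, net$item_ids) else node
    return(one(i))
  }
  res <- t(vapply(seq_along(net$item_ids), one, numeric(2)))
  data.frame(item_id = net$item_ids, cc = res[, "cc"], ncc = res[, "ncc"],
             stringsAsFactors = FALSE)
}

#' Full centrality table
#'
#' Per-node expected influence, strength, closeness, betweenness and
#' (optionally, when the data are supplied) predictability, together with
#' z-standardised versions of each column (mean 0, SD 1 over nodes).
#'
#' @param net an `ising_network`.
#' @param data optional `item_responses` for predictability columns.
#' @return data.frame of class `centrality_table`, one row per node.
#' @export
centrality_table <- function(net, data = NULL) {
  cl <- closeness_centrality(net)
  tab <- data.frame(item_id = net$item_ids,
                    expected_influence = unname(expected_influence(net)),
                    strength = unname(node_strength(net)),
                    closeness = cl$closeness,
                    betweenness = unname(betweenness_centrality(net)),
                    component_flag = cl$component_flag,
                    stringsAsFactors = FALSE)
  if (!is.null(data)) {
    pr <- predictability(data, net)
    tab$predictability_cc <- pr$cc
    tab$predictability_ncc <- pr$ncc
  }
  zcols <- setdiff(names(tab), c("item_id", "component_flag"))
  for (cn in zcols) {
    v <- tab[[cn]]
    s <- stats::sd(v, na.rm = TRUE)
    tab[[paste0("z_", cn)]] <- if (isTRUE(s > 0)) (v - mean(v, na.rm = TRUE)) / s
                               else rep(NA_real_, length(v))
  }
  class(tab) <- c("centrality_table", "data.frame")
  tab
}
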