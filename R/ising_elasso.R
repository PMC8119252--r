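#' Extended Bayesian Information Criterion
#'
#' `EBIC = -2 * loglik + k * log(n) + 2 * gamma * k * log(p_cand)`, where `k`
#' is the number of nonzero slope coefficients and `p_cand` the number of
#' candidate predictors. `gamma = 0` reduces to ordinary BIC; larger `gamma`
#' favours sparser models.
#'
#' @param loglik fitted log-likelihood.
#' @param k nonzero slope count.
#' @param n sample size.
#' @param p_cand candidate predictor count.
#' @param gamma EBIC hyperparameter (>= 0).
#' @return EBIC score (smaller is better).
#' @export
ebic <- function(loglik, k, n, p_cand, gamma) {
  stopifnot(n >= 1, p_cand >= 1, gamma >= 0)
  -2 * loglik + k * log(n) + 2 * gamma * k * log(p_cand)
}

logistic_loglik <- function(y, eta) {
  # stable binomial log-likelihood at linear predictor eta
  sum(y * eta - log1p(exp(eta)))
}

#' Nodewise lasso-penalised logistic regularisation path
#'
#' Regresses one item on all remaining items with an l1 penalty along a
#' log-spaced lambda grid from `lambda_max` (all slopes zero) down to
#' `lambda_max * lambda_min_ratio`, and scores each fit with the EBIC.
#' Predictors are standardised internally during fitting and coefficients
#' are reported on the original 0/1 scale; the intercept is unpenalised.
#'
#' @param data an `item_responses` object.
#' @param node item index (column) to regress on the others.
#' @param gamma EBIC hyperparameter (default 1, favouring sparsity).
#' @param n_lambda number of grid points (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max
#'   (default 0.01).
#' @return A list of class `regularization_path`: `lambda` (decreasing),
#'   `coefs` ((p-1) x n_lambda slope matrix), `intercepts`, `loglik`, `df`
#'   (nonzero slope counts), `ebic`, `which_min` (index of the EBIC-optimal
#'   lambda), `node`, `gamma`.
#' @export
nodewise_path <- function(data, node, gamma = 1, n_lambda = 100,
                          lambda_min_ratio = 0.01) {
  stopifnot(inherits(data, "item_responses"))
  x <- data$responses
  y <- x[, node]
  if (length(unique(y)) < 2) {
    stop("node ", node, " has a constant response column")
  }
  pred <- x[, -node, drop = FALSE]
  fit <- glmnet::glmnet(pred, y, family = "binomial", alpha = 1,
                        nlambda = n_lambda,
                        lambda.min.ratio = lambda_min_ratio,
                        standardize = TRUE)
  beta <- as.matrix(fit$beta)
  a0 <- fit$a0
  n <- length(y)
  eta <- cbind(1, pred) %*% rbind(a0, beta)
  ll <- vapply(seq_along(fit$lambda),
               function(j) logistic_loglik(y, eta[, j]), numeric(1))
  k <- fit$df
  scores <- ebic(ll, k, n, p_cand = ncol(pred), gamma = gamma)
  structure(list(lambda = fit$lambda, coefs = beta, intercepts = as.numeric(a0),
                 loglik = ll, df = as.integer(k), ebic = as.numeric(scores),
                 which_min = which.min(scores), node = node, gamma = gamma),
            class = "regularization_path")
}

#' Estimate a sparse Ising network by nodewise EBIC-lasso (eLasso)
#'
#' For each item, fits the l1-penalised logistic regression of that item on
#' all others and selects the penalty minimising the EBIC. An edge i-j is
#' retained iff item j has a nonzero slope in i's selected regression AND
#' vice versa (`rule = "and"`, the default), or if either does
#' (`rule = "or"`). Retained edge weights are the mean of the two slopes;
#' node thresholds are the selected intercepts. Under the generating model
#' `P(x) \\propto exp(sum_i tau_i x_i + sum_{i<j} J_ij x_i x_j)`,
#' `x in {0,1}^p`, the slopes estimate the pairwise couplings `J_ij`.
#'
#' @inheritParams nodewise_path
#' @param rule `"and"` (edge needs both regressions, the eLasso default) or
#'   `"or"`.
#' @param progress print per-node progress (default FALSE).
#' @return An object of class `ising_network`: `weights` (symmetric p x p,
#'   zero diagonal), `thresholds` (p intercepts), `gamma`, `rule`,
#'   `item_ids`, and `constant_nodes` (indices of columns that were constant
#'   and isolated with a warning).
#' @export
estimate_network <- function(data, gamma = 1, rule = c("and", "or"),
                             n_lambda = 100, lambda_min_ratio = 0.01,
                             progress = FALSE) {
  stopifnot(inherits(data, "item_responses"))
  rule <- match.arg(rule)
  x <- data$responses
  p <- ncol(x)
  n <- nrow(x)
  if (n < 2 * p) stop("need at least ", 2 * p, " rows for p = ", p)
  constant <- which(apply(x, 2L, function(v) length(unique(v)) < 2))
  if (length(constant)) {
    warning("constant column(s) isolated: ",
            paste(data$item_ids[constant], collapse = ", "))
  }
  B <- matrix(0, p, p)  # B[j, i] = slope of predictor j in node i's model
  tau <- numeric(p)
  for (i in seq_len(p)) {
    if (i %in% constant) {
      tau[i] <- NA_real_
      next
    }
    path <- nodewise_path(data, i, gamma = gamma, n_lambda = n_lambda,
                          lambda_min_ratio = lambda_min_ratio)
    sel <- path$which_min
    B[-i, i] <- path$coefs[, sel]
    tau[i] <- path$intercepts[sel]
    if (progress) message("node ", i, "/", p, ": df = ", path$df[sel])
  }
  present <- B != 0
  keep <- if (rule == "and") present & t(present) else present | t(present)
  W <- (B + t(B)) / 2
  # under the OR rule a one-sided slope contributes half its value, matching
  # the eLasso convention of averaging the two regressions
  W[!keep] <- 0
  diag(W) <- 0
  dimnames(W) <- list(data$item_ids, data$item_ids)
  names(tau) <- data$item_ids
  structure(list(weights = W, thresholds = tau, gamma = gamma, rule = rule,
                 item_ids = data$item_ids,
                 constant_nodes = as.integer(constant)),
            class = "ising_network")
}

#' Construct an Ising network from known parameters
#'
#' @param weights symmetric numeric matrix with zero diagonal (couplings).
#' @param thresholds numeric vector of per-node main effects (default 0).
#' @param item_ids node identifiers (default from `weights` dimnames).
#' @param gamma,rule provenance fields (optional).
#' @return An `ising_network` object.
#' @export
ising_network <- function(weights, thresholds = NULL, item_ids = NULL,
                          gamma = NA_real_, rule = NA_character_) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  stopifnot(ncol(weights) == p)
  if (max(abs(weights - t(weights))) > 1e-8) stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(thresholds)) thresholds <- numeric(p)
  stopifnot(length(thresholds) == p)
  if (is.null(item_ids)) {
    item_ids <- if (!is.null(rownames(weights))) rownames(weights) else
      as.character(seq_len(p))
  }
  dimnames(weights) <- list(item_ids, item_ids)
  names(thresholds) <- item_ids
  structure(list(weights = weights, thresholds = thresholds, gamma = gamma,
                 rule = rule, item_ids = item_ids,
                 constant_nodes = integer(0)),
            class = "ising_network")
}

#' @exportS3Method base::print
print.ising_network <- function(x, ...) {
  p <- length(x$item_ids)
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("Ising network:", p, "nodes,", ne, "edges (density",
      sprintf("%.3f", ne / (p * (p - 1) / 2)), ")\n")
  if (!is.na(x$gamma)) cat("  estimated with EBIC gamma =", x$gamma,
                           "and the", toupper(x$rule), "rule\n")
  invisible(x)
}

#' Number of (upper-triangle) edges in a network
#' @param net an `ising_network`.
#' @return integer edge count.
#' @export
edge_count <- function(net) {
  sum(net$weights[upper.tri(net$weights)] != 0)
}

#' Export a network as an edge-list data.frame
#'
#' @param net an `ising_network`.
#' @param keep_zeros include zero-weight pairs (default FALSE).
#' @return data.frame with columns `item_i`, `item_j`, `weight` (one row per
#'   unordered pair).
#' @export
edge_list <- function(net, keep_zeros = FALSE) {
  W <- net$weights
  idx <- which(upper.tri(W), arr.ind = TRUE)
  out <- data.frame(item_i = net$item_ids[idx[, 1]],
                    item_j = net$item_ids[idx[, 2]],
                    weight = W[idx],
                    stringsAsFactors = FALSE)
  if (!keep_zeros) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert an Ising network to an igraph graph
#'
#' @param net an `ising_network`.
#' @param mode `"abs"` uses absolute weights (required by modularity-based
#'   community detection), `"signed"` keeps signs.
#' @return an undirected weighted `igraph` graph (zero-weight pairs omitted).
#' @export
as_igraph <- function(net, mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  W <- net$weights
  if (mode == "abs") W <- abs(W)
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Write network artifacts to disk
#'
#' Writes the weighted edge list as CSV, the thresholds as CSV, and the
#' graph as GraphML.
#'
#' @param net an `ising_network`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"network"`).
#' @return Invisibly, the written paths.
#' @export
write_network <- function(net, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges_path <- file.path(dir, paste0(prefix, "_edges.csv"))
  thr_path <- file.path(dir, paste0(prefix, "_thresholds.csv"))
  gml_path <- file.path(dir, paste0(prefix, ".graphml"))
  utils::write.csv(edge_list(net), edges_path, row.names = FALSE)
  utils::write.csv(data.frame(item_id = net$item_ids,
                              threshold = unname(net$thresholds)),
                   thr_path, row.names = FALSE)
  g <- as_igraph(net, mode = "signed")
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edges = edges_path, thresholds = thr_path, graphml = gml_path))
}
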