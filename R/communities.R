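#' Construct a partition
#'
#' @param labels integer (or coercible) community labels, optionally named by
#'   node id; labels are recoded to contiguous 1..K in order of first
#'   appearance.
#' @param q optional modularity of the partition on the graph it came from.
#' @return list of class `partition`: `labels` (named integer, 1..K), `k`,
#'   `q`.
#' @export
new_partition <- function(labels, q = NA_real_) {
  lv <- unique(labels)
  lab <- as.integer(match(labels, lv))
  names(lab) <- names(labels)
  structure(list(labels = lab, k = length(lv), q = q), class = "partition")
}

#' @exportS3Method base::print
print.partition <- function(x, ...) {
  cat("Partition of", length(x$labels), "nodes into", x$k, "communities")
  if (!is.na(x$q)) cat(sprintf(" (Q = %.3f)", x$q))
  cat("\n")
  invisible(x)
}

#' Newman modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)` with
#' weighted degrees `k` and total edge weight `m`. Community detection on
#' association networks runs on absolute weights (`weight_mode = "abs"`,
#' the default), since modularity is undefined for negative weights.
#'
#' @param net an `ising_network`.
#' @param partition a `partition` covering all nodes.
#' @param weight_mode `"abs"` (default) or `"raw"` (caller guarantees
#'   non-negative weights).
#' @return modularity Q in \[-1, 1\].
#' @export
modularity_q <- function(net, partition, weight_mode = c("abs", "raw")) {
  weight_mode <- match.arg(weight_mode)
  A <- if (weight_mode == "abs") abs(net$weights) else net$weights
  m2 <- sum(A)  # 2m
  if (m2 == 0) stop("modularity undefined: network has no edges")
  k <- rowSums(A)
  lab <- partition$labels
  stopifnot(length(lab) == nrow(A))
  same <- outer(lab, lab, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

#' Fast-greedy community detection
#'
#' Agglomerative modularity maximisation: starting from singleton
#' communities, repeatedly merge the pair of communities with the largest
#' modularity gain, and cut the resulting dendrogram at the maximum of Q.
#' Runs on absolute edge weights. Deterministic given the weight matrix.
#'
#' @param net an `ising_network` with at least one nonzero edge (an empty
#'   graph returns the all-singleton partition with a warning).
#' @return a `partition` with its modularity `q` filled in.
#' @export
fast_greedy <- function(net) {
  g <- as_igraph(net, mode = "abs")
  if (igraph::ecount(g) == 0) {
    warning("network has no edges; returning singleton partition")
    lab <- seq_along(net$item_ids)
    names(lab) <- net$item_ids
    return(new_partition(lab))
  }
  cm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  # cut the dendrogram at the modularity maximum ourselves: the stored
  # membership can stop one merge short when the final gains are ~0
  steps <- which.max(cm$modularity) - 1L
  lab <- igraph::cut_at(cm, steps = steps)
  names(lab) <- net$item_ids
  part <- new_partition(lab)
  part$q <- modularity_q(net, part, weight_mode = "abs")
  part
}

partition_entropy <- function(counts) {
  pr <- counts / sum(counts)
  pr <- pr[pr > 0]
  -sum(pr * log(pr))
}

#' Normalised mutual information between two partitions
#'
#' `NMI = 2 I(p1; p2) / (H(p1) + H(p2))` from the contingency table of joint
#' label counts (arithmetic-mean normalisation). 1 for identical partitions,
#' 0 when one partition is a single community (zero entropy) unless both
#' are, in which case the partitions are identical and NMI is 1.
#'
#' @param p1,p2 `partition` objects over the same node set (compared in
#'   order; named labels are aligned by name).
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(p1, p2) {
  l1 <- p1$labels
  l2 <- p2$labels
  if (length(l1) != length(l2)) stop("partitions cover different node sets")
  if (!is.null(names(l1)) && !is.null(names(l2))) {
    if (!setequal(names(l1), names(l2))) {
      stop("partitions cover different node sets")
    }
    l2 <- l2[names(l1)]
  }
  tab <- table(l1, l2)
  h1 <- partition_entropy(rowSums(tab))
  h2 <- partition_entropy(colSums(tab))
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) {
    if (p1$k == 1 && p2$k == 1) return(1)
    return(0)
  }
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0) {
        mi <- mi + nij / n * log(nij * n / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
  }
  2 * mi / (h1 + h2)
}

# maximum-weight one-to-one assignment on a (small) count matrix by
# exhaustive enumeration over injective maps from rows to columns;
# requires nrow(M) <= ncol(M)
best_assignment <- function(M) {
  nr <- nrow(M)
  nc <- ncol(M)
  stopifnot(nr <= nc)
  best <- list(score = -Inf, map = integer(nr))
  rec <- function(row, used, score, map) {
    if (row > nr) {
      if (score > best$score) best <<- list(score = score, map = map)
      return()
    }
    for (col in seq_len(nc)) {
      if (!used[col]) {
        used[col] <- TRUE
        map[row] <- col
        rec(row + 1L, used, score + M[row, col], map)
        used[col] <- FALSE
      }
    }
  }
  rec(1L, logical(nc), 0, integer(nr))
  best
}

#' Percent overlap between a detected and a reference partition
#'
#' Matches detected communities one-to-one to reference classes by
#' maximum-weight assignment on shared-item counts; the overlap is the
#' percentage of items lying in a matched (community, class) cell, and the
#' remaining items are listed as mismatches.
#'
#' @param detected,reference `partition` objects over the same node set.
#' @return list with `percent`, `mismatched` (node ids or indices) and
#'   `mapping` (detected community -> reference class, NA if unmatched).
#' @export
overlap_percent <- function(detected, reference) {
  ld <- detected$labels
  lr <- reference$labels
  if (length(ld) != length(lr)) stop("partitions cover different node sets")
  if (!is.null(names(ld)) && !is.null(names(lr))) lr <- lr[names(ld)]
  tab <- table(ld, lr)
  counts <- matrix(as.numeric(tab), nrow(tab), ncol(tab))
  if (nrow(counts) <= ncol(counts)) {
    asg <- best_assignment(counts)
    mapping <- asg$map  # detected row -> reference column
  } else {
    asg <- best_assignment(t(counts))  # reference row -> detected column
    mapping <- rep(NA_integer_, nrow(counts))
    mapping[asg$map] <- seq_len(ncol(counts))
  }
  ref_levels <- as.integer(colnames(tab))
  det_levels <- as.integer(rownames(tab))
  matched <- !is.na(mapping[match(ld, det_levels)]) &
    ref_levels[mapping[match(ld, det_levels)]] == lr
  ids <- if (!is.null(names(ld))) names(ld) else seq_along(ld)
  list(percent = 100 * sum(matched) / length(ld),
       mismatched = ids[!matched],
       mapping = stats::setNames(ref_levels[mapping], det_levels))
}

#' Partition summary table in catalog style
#'
#' One row per item: detected community, a priori subscale, and whether the
#' item fell in a matched community under the optimal one-to-one matching.
#'
#' @param detected a `partition` (named by item id).
#' @param catalog an `item_catalog`.
#' @return data.frame with columns `item_id`, `short_label`, `subscale`,
#'   `community`, `match`.
#' @export
partition_table <- function(detected, catalog) {
  ref <- catalog_partition(catalog)
  ids <- names(detected$labels)
  ref_lab <- ref$labels[ids]
  ov <- overlap_percent(detected, new_partition(ref_lab))
  data.frame(item_id = ids,
             short_label = catalog$short_label[match(ids, catalog$item_id)],
             subscale = as.character(catalog$subscale[match(ids, catalog$item_id)]),
             community = unname(detected$labels),
             match = !(ids %in% ov$mismatched),
             stringsAsFactors = FALSE)
}
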