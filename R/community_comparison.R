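#' Kruskal-Wallis omnibus test
#'
#' Rank-based H with tie correction; p from the chi-square approximation on
#' K - 1 degrees of freedom. When every value is identical, H = 0 and p = 1.
#'
#' @param groups list of numeric vectors (K >= 2, each nonempty).
#' @return list: `h`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) > 0))
  if (length(unique(unlist(groups))) == 1) {
    return(list(h = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(h = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Mann-Whitney U test
#'
#' U statistic with average ranks for ties; p-value from the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric vectors (nonempty).
#' @return list: `u` (number of (x, y) pairs with x > y, ties counted 1/2),
#'   `p`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Cliff's delta dominance effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n m)`: the probability that
#' a value from `x` exceeds one from `y`, minus the reverse. Computed from
#' joint ranks, so ties are handled exactly and large groups stay cheap.
#'
#' @param x,y numeric vectors (nonempty).
#' @return delta in \[-1, 1\].
#' @export
cliffs_delta <- function(x, y) {
  n <- length(x)
  m <- length(y)
  stopifnot(n > 0, m > 0)
  r <- rank(c(x, y))
  # with average ranks, sum of x-ranks = U_x + n(n+1)/2 + (ties counted 1/2)
  ux <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  2 * ux / (n * m) - 1
}

run_group_comparison <- function(groups, alpha = 0.05) {
  omnibus <- kruskal_wallis(groups)
  sizes <- lengths(groups)
  gnames <- names(groups)
  if (is.null(gnames)) gnames <- as.character(seq_along(groups))
  pairwise <- NULL
  if (omnibus$p < alpha) {
    usable <- which(sizes > 1)
    if (length(usable) < length(groups)) {
      warning("size-1 group(s) excluded from pairwise tests: ",
              paste(gnames[sizes <= 1], collapse = ", "))
    }
    if (length(usable) >= 2) {
      prs <- utils::combn(usable, 2)
      pairwise <- do.call(rbind, apply(prs, 2L, function(ij) {
        a <- groups[[ij[1]]]
        b <- groups[[ij[2]]]
        mw <- mann_whitney(a, b)
        data.frame(group_a = gnames[ij[1]], group_b = gnames[ij[2]],
                   u = mw$u, p = mw$p, cliffs_delta = cliffs_delta(a, b),
                   stringsAsFactors = FALSE)
      }))
      rownames(pairwise) <- NULL
    }
  }
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 group_sizes = stats::setNames(as.integer(sizes), gnames),
                 alpha = alpha),
            class = "group_comparison")
}

#' @exportS3Method base::print
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared(%d) = %.2f, p = %.4g\n",
              x$omnibus$df, x$omnibus$h, x$omnibus$p))
  if (!is.null(x$pairwise)) {
    cat("Pairwise Mann-Whitney tests (run because omnibus p <",
        x$alpha, "):\n")
    print(format(x$pairwise, digits = 3), row.names = FALSE)
  } else {
    cat("No pairwise tests (omnibus not significant at", x$alpha, ")\n")
  }
  invisible(x)
}

#' Compare node centralities across communities
#'
#' Kruskal-Wallis omnibus over the per-community distributions of a node
#' centrality; when the omnibus is significant at `alpha`, all pairwise
#' Mann-Whitney tests with Cliff's delta are run (size-1 communities enter
#' the omnibus but are excluded from pairwise tests with a warning). No
#' multiplicity correction is applied to the post hoc tests.
#'
#' @param cent a `centrality_table`.
#' @param partition a `partition` over the same nodes.
#' @param metric column of `cent` to compare (e.g. `"closeness"`,
#'   `"betweenness"`, `"expected_influence"`).
#' @param alpha omnibus significance gate for post hocs (default 0.05).
#' @return a `group_comparison` object.
#' @export
compare_centralities_by_community <- function(cent, partition,
                                              metric = "closeness",
                                              alpha = 0.05) {
  if (!metric %in% names(cent)) stop("metric column not present: ", metric)
  lab <- partition$labels
  if (!is.null(names(lab))) lab <- lab[cent$item_id]
  v <- cent[[metric]]
  groups <- split(v, lab)
  names(groups) <- paste0("community_", names(groups))
  run_group_comparison(groups, alpha = alpha)
}

#' Absolute edge weights grouped within and between communities
#'
#' For each community, the `|J_ij|` of every node pair inside it; for each
#' unordered community pair, the `|J_ij|` of every cross pair. Zero-weight
#' pairs are included, so group sizes equal the pair counts implied by the
#' community sizes and total `p(p-1)/2`.
#'
#' @param net an `ising_network`.
#' @param partition a `partition` covering the nodes.
#' @return list with `within` (named list per community) and `between`
#'   (named list per community pair).
#' @export
within_between_edge_weights <- function(net, partition) {
  W <- abs(net$weights)
  lab <- partition$labels
  if (!is.null(names(lab))) lab <- lab[net$item_ids]
  stopifnot(length(lab) == nrow(W))
  ks <- sort(unique(lab))
  within <- lapply(ks, function(k) {
    idx <- which(lab == k)
    if (length(idx) < 2) return(numeric(0))
    upper_vec(W[idx, idx, drop = FALSE])
  })
  names(within) <- paste0("within_", ks)
  prs <- utils::combn(ks, 2)
  between <- lapply(seq_len(ncol(prs)), function(j) {
    a <- which(lab == prs[1, j])
    b <- which(lab == prs[2, j])
    as.numeric(W[a, b, drop = FALSE])
  })
  names(between) <- paste0("between_", prs[1, ], "_", prs[2, ])
  list(within = within, between = between)
}

#' Compare groups of absolute edge weights
#'
#' Kruskal-Wallis omnibus over the supplied weight groups, with pairwise
#' Mann-Whitney and Cliff's delta when the omnibus is significant.
#'
#' @param groups named list of numeric vectors (e.g. the `within` or
#'   `between` element of [within_between_edge_weights()]); empty groups are
#'   dropped.
#' @param alpha omnibus gate (default 0.05).
#' @return a `group_comparison` object.
#' @export
compare_edge_weight_groups <- function(groups, alpha = 0.05) {
  groups <- groups[lengths(groups) > 0]
  run_group_comparison(groups, alpha = alpha)
}
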