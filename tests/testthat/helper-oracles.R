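# Independent brute-force oracles used to validate graph and statistics
# code. These deliberately share no code path with the package: distances
# come from Floyd-Warshall, betweenness from explicit enumeration of all
# simple paths, modularity from the literal double sum, and the optimal
# partition from exhaustive search over all set partitions.

# Floyd-Warshall all-pairs shortest distances on 1/|w| edge lengths
oracle_distances <- function(W) {
  p <- nrow(W)
  D <- ifelse(abs(W) > 0, 1 / abs(W), Inf)
  diag(D) <- 0
  for (k in seq_len(p)) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_closeness <- function(W) {
  D <- oracle_distances(W)
  p <- nrow(W)
  sapply(seq_len(p), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / sum(d)
  })
}

# all simple paths between s and t, as lists of node sequences
all_simple_paths_oracle <- function(W, s, t) {
  p <- nrow(W)
  paths <- list()
  walk <- function(path, visited) {
    cur <- path[length(path)]
    if (cur == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (nxt in seq_len(p)) {
      if (!visited[nxt] && abs(W[cur, nxt]) > 0) {
        visited[nxt] <- TRUE
        walk(c(path, nxt), visited)
        visited[nxt] <- FALSE
      }
    }
  }
  v <- logical(p)
  v[s] <- TRUE
  walk(s, v)
  paths
}

path_length <- function(W, path) {
  if (length(path) < 2) return(0)
  sum(1 / abs(W[cbind(path[-length(path)], path[-1])]))
}

# betweenness by enumerating, for every unordered pair, all shortest paths
# and crediting interior nodes fractionally
oracle_betweenness <- function(W, tol = 1e-9) {
  p <- nrow(W)
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in seq(s + 1, p)) {
      paths <- all_simple_paths_oracle(W, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, function(pt) path_length(W, pt), numeric(1))
      short <- paths[lens <= min(lens) + tol]
      for (pt in short) {
        interior <- setdiff(pt, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(short)
      }
    }
  }
  btw
}

# literal modularity double sum on non-negative weights
oracle_modularity <- function(A, labels) {
  m2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  p <- nrow(A)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (labels[i] == labels[j]) q <- q + A[i, j] - k[i] * k[j] / m2
    }
  }
  q / m2
}

# all set partitions of 1..p (restricted growth strings); Bell(8) = 4140
all_partitions <- function(p) {
  out <- list()
  rec <- function(i, labels, kmax) {
    if (i > p) {
      out[[length(out) + 1]] <<- labels
      return()
    }
    for (lab in seq_len(kmax + 1)) {
      labels[i] <- lab
      rec(i + 1, labels, max(kmax, lab))
    }
  }
  rec(1L, integer(p), 0L)
  out
}

oracle_best_modularity <- function(A) {
  parts <- all_partitions(nrow(A))
  max(vapply(parts, function(lb) oracle_modularity(A, lb), numeric(1)))
}

# random symmetric weight matrix (possibly with negative weights)
random_weights <- function(p, density = 0.5, signed = TRUE) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (stats::runif(1) < density) {
        w <- stats::runif(1, 0.2, 1.5) * if (signed && stats::runif(1) < 0.3) -1 else 1
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  W
}

# Cliff's delta by brute force over all pairs
oracle_cliffs_delta <- function(x, y) {
  gt <- 0
  lt <- 0
  for (xi in x) {
    for (yj in y) {
      if (xi > yj) gt <- gt + 1
      if (xi < yj) lt <- lt + 1
    }
  }
  (gt - lt) / (length(x) * length(y))
}

# small planted dataset reused across tests: two 5-node blocks, stable
# coupling regime
make_small_planted <- function(n = 1500, seed = 42, j_within = 0.8) {
  planted_solife_generator(n = n, block_sizes = c(5, 5), j_within = j_within,
                           seed = seed)
}

# matrix -> item_responses without triggering min-N validation paths
resp <- function(x) {
  colnames(x) <- as.character(seq_len(ncol(x)))
  structure(list(responses = x, item_ids = colnames(x),
                 n_participants = nrow(x)),
            class = "item_responses")
}
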