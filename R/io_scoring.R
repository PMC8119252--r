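#' Item catalog for the 43-item sO-LIFE
#'
#' The short Oxford-Liverpool Inventory of Feelings and Experiences (sO-LIFE)
#' has 43 yes/no items in four a priori subscales: Unusual Experiences (UE,
#' 12 items), Cognitive Disorganisation (CD, 11 items), Impulsive
#' Nonconformity (IN, 10 items) and Introvertive Anhedonia (IA, 10 items).
#' The catalog shipped with the package maps each item (by position and id)
#' to its short label and subscale.
#'
#' @param path Optional path to a catalog file (tab-separated, columns
#'   `item_id`, `short_label`, `subscale`, `reverse_keyed`). Defaults to the
#'   sO-LIFE catalog shipped in `inst/extdata`.
#' @return A data.frame of class `item_catalog` with columns `item_id`
#'   (character), `short_label`, `subscale` (factor with levels UE, CD, IN,
#'   IA) and `reverse_keyed` (logical). Input data are assumed to be coded so
#'   that 1 is the schizotypy-consistent response; `reverse_keyed` defaults
#'   to `FALSE` for every shipped item and exists so users can flag raw,
#'   unkeyed data.
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "solife_catalog.tsv", package = "solifenet",
                        mustWork = TRUE)
  }
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(item_id = "character"))
  required <- c("item_id", "short_label", "subscale")
  if (!all(required %in% names(cat))) {
    stop("catalog must have columns item_id, short_label, subscale")
  }
  if (anyDuplicated(cat$item_id)) stop("catalog item_id values must be unique")
  if (is.null(cat$reverse_keyed)) cat$reverse_keyed <- FALSE
  cat$reverse_keyed <- as.logical(cat$reverse_keyed)
  cat$subscale <- factor(cat$subscale, levels = c("UE", "CD", "IN", "IA"))
  if (anyNA(cat$subscale)) stop("subscale must be one of UE, CD, IN, IA")
  class(cat) <- c("item_catalog", "data.frame")
  cat
}

#' The a priori subscale assignment as a partition
#'
#' @param catalog An `item_catalog`.
#' @return A [partition] object with one community per subscale, in catalog
#'   item order.
#' @export
catalog_partition <- function(catalog) {
  labels <- as.integer(catalog$subscale)
  names(labels) <- catalog$item_id
  new_partition(labels)
}

#' Load a binary item-response matrix from CSV
#'
#' Reads a participant-by-item CSV (header row of item identifiers, cells 0
#' or 1). Rows containing any missing or non-binary cell are dropped listwise
#' with a warning reporting the count.
#'
#' @param path CSV file path.
#' @param catalog Optional `item_catalog`; when given, every column of the
#'   file must appear in the catalog, and reverse-keyed items are flipped
#'   (`1 - x`) on load.
#' @return An object of class `item_responses`: a list with `responses`
#'   (N x p integer matrix of 0/1), `item_ids` (character) and
#'   `n_participants`.
#' @details Estimation downstream refuses samples with fewer than `2 * p`
#'   complete rows; that check is applied here so malformed files fail early.
#' @export
load_responses <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop("malformed CSV: ", conditionMessage(e))
  )
  if (ncol(df) < 3) stop("need at least 3 item columns, got ", ncol(df))
  x <- suppressWarnings(vapply(df, function(col) as.numeric(as.character(col)),
                               numeric(nrow(df))))
  if (nrow(df) == 1L) x <- matrix(x, nrow = 1L)
  colnames(x) <- names(df)
  as_item_responses(x, catalog = catalog)
}

#' Construct an item-response object from a matrix
#'
#' @param x numeric matrix with column names as item ids; cells must be 0/1.
#'   Rows violating this are dropped with a warning.
#' @param catalog optional `item_catalog` used to validate ids and apply
#'   reverse keying.
#' @param min_rows_factor minimum N as a multiple of p (default 2).
#' @return An `item_responses` object.
#' @export
as_item_responses <- function(x, catalog = NULL, min_rows_factor = 2) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  item_ids <- colnames(x)
  if (anyDuplicated(item_ids)) stop("item identifiers must be unique")
  p <- ncol(x)
  if (p < 3) stop("need at least 3 items, got ", p)
  bad <- apply(x, 1L, function(r) anyNA(r) || !all(r %in% c(0, 1)))
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing or non-binary cells dropped")
    x <- x[!bad, , drop = FALSE]
  }
  if (!is.null(catalog)) {
    unknown <- setdiff(item_ids, catalog$item_id)
    if (length(unknown)) {
      stop("item id(s) not in catalog: ", paste(unknown, collapse = ", "))
    }
    rev_ids <- catalog$item_id[catalog$reverse_keyed]
    flip <- intersect(item_ids, rev_ids)
    if (length(flip)) x[, flip] <- 1 - x[, flip]
  }
  if (nrow(x) < min_rows_factor * p) {
    stop("need at least ", min_rows_factor * p, " complete rows for p = ", p,
         " items, got ", nrow(x))
  }
  structure(list(responses = matrix(as.integer(x), nrow(x), p,
                                    dimnames = list(NULL, item_ids)),
                 item_ids = item_ids,
                 n_participants = nrow(x)),
            class = "item_responses")
}

#' @exportS3Method base::print
print.item_responses <- function(x, ...) {
  cat("Binary item responses:", x$n_participants, "participants x",
      length(x$item_ids), "items\n")
  invisible(x)
}

#' Per-participant subscale sum scores
#'
#' Sums the item responses within each subscale. Higher scores indicate
#' higher expression of the trait; reverse-keyed items are assumed to have
#' been flipped at load time.
#'
#' @param data An `item_responses` object.
#' @param catalog An `item_catalog` covering every item in `data`.
#' @return Integer matrix, participants x subscales (columns UE, CD, IN, IA
#'   restricted to subscales present).
#' @export
score_subscales <- function(data, catalog) {
  stopifnot(inherits(data, "item_responses"))
  unknown <- setdiff(data$item_ids, catalog$item_id)
  if (length(unknown)) {
    stop("item id(s) not in catalog: ", paste(unknown, collapse = ", "))
  }
  sub <- catalog$subscale[match(data$item_ids, catalog$item_id)]
  scales <- levels(droplevels(sub))
  out <- vapply(scales, function(s) {
    as.integer(rowSums(data$responses[, sub == s, drop = FALSE]))
  }, integer(data$n_participants))
  if (data$n_participants == 1L) out <- matrix(out, 1L, dimnames = list(NULL, scales))
  out
}

#' Descriptive statistics for score distributions
#'
#' Computes, per column, the mean, sample SD (N-1 denominator), median, IQR
#' (Q3 - Q1), moment-based skewness g1 = m3 / m2^(3/2) and excess kurtosis
#' g2 = m4 / m2^2 - 3, plus pairwise Pearson and Spearman correlations
#' between columns. Zero-variance columns get `NA` skewness and kurtosis.
#'
#' @param scores numeric matrix (participants x score columns).
#' @return List with a `summary` data.frame (one row per column) and
#'   `pearson` / `spearman` correlation matrices.
#' @export
descriptives <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need at least 2 participants")
  one <- function(v) {
    m <- mean(v)
    d <- v - m
    m2 <- mean(d^2)
    if (m2 > 0) {
      skew <- mean(d^3) / m2^1.5
      kurt <- mean(d^4) / m2^2 - 3
    } else {
      skew <- NA_real_
      kurt <- NA_real_
    }
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    c(mean = m, sd = stats::sd(v), median = stats::median(v),
      iqr = q[2] - q[1], skewness = skew, kurtosis = kurt)
  }
  sm <- t(apply(scores, 2L, one))
  list(summary = data.frame(score = colnames(scores), sm, row.names = NULL),
       pearson = stats::cor(scores, method = "pearson"),
       spearman = stats::cor(scores, method = "spearman"))
}

#' Cronbach's alpha
#'
#' Internal-consistency alpha from the item variance decomposition:
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)`, with sample variances
#' (N-1 denominator). For binary items this equals KR-20.
#'
#' @param items numeric matrix, participants x items (k >= 2 columns).
#' @return alpha (scalar).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2 || nrow(items) < 2) stop("need >= 2 items and >= 2 participants")
  vt <- stats::var(rowSums(items))
  if (vt == 0) stop("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2L, stats::var)) / vt)
}

#' First-order partial correlation
#'
#' Pearson correlation between `x` and `y` controlling for `z`:
#' `(r_xy - r_xz * r_zy) / sqrt((1 - r_xz^2) * (1 - r_zy^2))`.
#'
#' @param x,y,z numeric vectors of equal length >= 4.
#' @return partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n || n < 4) {
    stop("x, y, z must have equal length >= 4")
  }
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  rzy <- stats::cor(z, y)
  den <- (1 - rxz^2) * (1 - rzy^2)
  if (den <= .Machine$double.eps) {
    stop("partial correlation undefined: z is collinear with x or y")
  }
  (rxy - rxz * rzy) / sqrt(den)
}
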