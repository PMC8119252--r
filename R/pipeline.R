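#' Default pipeline configuration
#'
#' Every analysis choice the underlying study design leaves open is an
#' explicit field here and is echoed into the report's provenance block.
#'
#' @param gamma EBIC hyperparameter (default 1, the value selected by
#'   split-half stability in the reference analysis).
#' @param rule edge-combination rule, `"and"` or `"or"`.
#' @param n_splits split-half splits (0 disables the stability stage).
#' @param B bootstrap resamples (0 disables the bootstrap stage).
#' @param seed master RNG seed.
#' @param weight_mode weights used for community detection (`"abs"`).
#' @param alpha omnibus significance gate for post hoc tests.
#' @param centrality_metrics metrics compared across communities.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(gamma = 1, rule = "and", n_splits = 10, B = 0,
                            seed = 1, weight_mode = "abs", alpha = 0.05,
                            centrality_metrics = c("closeness", "betweenness",
                                                   "expected_influence")) {
  list(gamma = gamma, rule = rule, n_splits = n_splits, B = B, seed = seed,
       weight_mode = weight_mode, alpha = alpha,
       centrality_metrics = centrality_metrics)
}

#' Run the full network analysis pipeline
#'
#' Executes, in order: Ising network estimation (eLasso), fast-greedy
#' community detection, centralities and predictability, split-half (and
#' optionally bootstrap) stability, community-level comparisons of
#' centralities, within/between-community edge-weight comparisons, and
#' agreement (NMI, percent overlap) with a reference partition (the a priori
#' subscales when a catalog is given, or the planted partition for
#' generated data). Any stage failure is captured in the report's `errors`
#' section and later stages that depend on it are skipped.
#'
#' @param data an `item_responses` object, or `NULL` to generate data.
#' @param catalog optional `item_catalog` giving the reference partition.
#' @param generator optional named list of arguments to
#'   [planted_solife_generator()]; used when `data` is `NULL`.
#' @param config a [pipeline_config()] list.
#' @param out_dir optional directory; when given, all artifacts (edge list,
#'   GraphML, partition CSV, centrality CSV, JSON report) are written there.
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(data = NULL, catalog = NULL, generator = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  report <- list(provenance = c(config,
                                list(package_version =
                                       as.character(utils::packageVersion("solifenet")))),
                 errors = list())
  fail <- function(stage, e) {
    report$errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  set.seed(config$seed)

  reference <- NULL
  if (is.null(data)) {
    gen_args <- if (is.null(generator)) list() else generator
    if (is.null(gen_args$seed)) gen_args$seed <- config$seed
    gen <- tryCatch(do.call(planted_solife_generator, gen_args),
                    error = function(e) fail("generate", e))
    if (is.null(gen)) return(finish_report(report, out_dir))
    data <- gen$data
    reference <- gen$partition
    report$generator <- list(achieved_rates = gen$achieved_rates,
                             true_network = gen$network)
  }
  if (!is.null(catalog)) {
    reference <- catalog_partition(catalog)
    reference$labels <- reference$labels[data$item_ids]
  }
  report$data_summary <- list(n = data$n_participants,
                              p = length(data$item_ids))

  net <- tryCatch(estimate_network(data, gamma = config$gamma,
                                   rule = config$rule),
                  error = function(e) fail("estimate", e))
  if (is.null(net)) return(finish_report(report, out_dir))
  report$network <- net
  p <- length(net$item_ids)
  report$network_summary <- list(p = p, edges = edge_count(net),
                                 density = edge_count(net) / (p * (p - 1) / 2))

  part <- tryCatch(fast_greedy(net), error = function(e) fail("communities", e))
  report$partition <- part

  cent <- tryCatch(centrality_table(net, data = data),
                   error = function(e) fail("centrality", e))
  report$centrality <- cent

  if (config$n_splits > 0) {
    report$split_half <- tryCatch(
      split_half(data, gamma = config$gamma, n_splits = config$n_splits,
                 seed = config$seed, rule = config$rule),
      error = function(e) fail("split_half", e))
  }
  if (config$B > 0) {
    report$bootstrap <- tryCatch(
      bootstrap_edges(data, gamma = config$gamma, B = config$B,
                      seed = config$seed, rule = config$rule),
      error = function(e) fail("bootstrap", e))
  }

  if (!is.null(part) && !is.null(cent)) {
    report$centrality_comparisons <- lapply(
      stats::setNames(config$centrality_metrics, config$centrality_metrics),
      function(m) tryCatch(
        compare_centralities_by_community(cent, part, metric = m,
                                          alpha = config$alpha),
        error = function(e) fail(paste0("compare_", m), e)))
    wb <- tryCatch(within_between_edge_weights(net, part),
                   error = function(e) fail("edge_groups", e))
    if (!is.null(wb)) {
      report$within_comparison <- tryCatch(
        compare_edge_weight_groups(wb$within, alpha = config$alpha),
        error = function(e) fail("compare_within", e))
      report$between_comparison <- tryCatch(
        compare_edge_weight_groups(wb$between, alpha = config$alpha),
        error = function(e) fail("compare_between", e))
    }
  }

  if (!is.null(part) && !is.null(reference)) {
    report$agreement <- tryCatch({
      ov <- overlap_percent(part, reference)
      list(k_detected = part$k, k_reference = reference$k,
           nmi = nmi(part, reference), overlap_percent = ov$percent,
           mismatched_items = ov$mismatched)
    }, error = function(e) fail("agreement", e))
    if (!is.null(catalog)) {
      report$partition_table <- tryCatch(partition_table(part, catalog),
                                         error = function(e) fail("partition_table", e))
    }
  }
  finish_report(report, out_dir)
}

finish_report <- function(report, out_dir) {
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @exportS3Method base::print
print.pipeline_report <- function(x, ...) {
  cat("== Network pipeline report ==\n")
  if (!is.null(x$network_summary)) {
    with(x$network_summary,
         cat(sprintf("Network: %d nodes, %d edges (density %.3f)\n",
                     p, edges, density)))
  }
  if (!is.null(x$partition)) print(x$partition)
  if (!is.null(x$agreement)) {
    cat(sprintf("Agreement with reference: overlap %.1f%%, NMI %.3f (%d vs %d communities)\n",
                x$agreement$overlap_percent, x$agreement$nmi,
                x$agreement$k_detected, x$agreement$k_reference))
    if (length(x$agreement$mismatched_items)) {
      cat("  mismatched items:",
          paste(x$agreement$mismatched_items, collapse = ", "), "\n")
    }
  }
  if (!is.null(x$split_half)) print(x$split_half)
  for (m in names(x$centrality_comparisons)) {
    cat("--", m, "by community --\n")
    print(x$centrality_comparisons[[m]])
  }
  if (!is.null(x$within_comparison)) {
    cat("-- within-community |edge weights| --\n")
    print(x$within_comparison)
  }
  if (!is.null(x$between_comparison)) {
    cat("-- between-community |edge weights| --\n")
    print(x$between_comparison)
  }
  if (length(x$errors)) {
    cat("!! stage errors:\n")
    for (s in names(x$errors)) cat("  ", s, ": ", x$errors[[s]], "\n", sep = "")
  }
  invisible(x)
}

comparison_to_list <- function(gc) {
  if (is.null(gc)) return(NULL)
  list(h = gc$omnibus$h, df = gc$omnibus$df, p = gc$omnibus$p,
       group_sizes = as.list(gc$group_sizes),
       pairwise = if (is.null(gc$pairwise)) NULL else gc$pairwise)
}

#' Write pipeline artifacts
#'
#' Writes the edge list, thresholds, GraphML, partition CSV, centrality CSV
#' and a machine-readable JSON report into `dir`.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON report path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$network)) write_network(report$network, dir)
  if (!is.null(report$partition)) {
    utils::write.csv(
      data.frame(item_id = names(report$partition$labels),
                 community = unname(report$partition$labels)),
      file.path(dir, "partition.csv"), row.names = FALSE)
  }
  if (!is.null(report$partition_table)) {
    utils::write.csv(report$partition_table,
                     file.path(dir, "partition_table.csv"), row.names = FALSE)
  }
  if (!is.null(report$centrality)) {
    utils::write.csv(report$centrality, file.path(dir, "centrality.csv"),
                     row.names = FALSE)
  }
  js <- list(
    provenance = report$provenance,
    data_summary = report$data_summary,
    network_summary = report$network_summary,
    partition = if (!is.null(report$partition))
      list(k = report$partition$k, q = report$partition$q,
           labels = as.list(report$partition$labels)),
    agreement = report$agreement,
    split_half = if (!is.null(report$split_half))
      list(median = report$split_half$median,
           range = report$split_half$range,
           rho = report$split_half$rho),
    centrality_comparisons = lapply(report$centrality_comparisons,
                                    comparison_to_list),
    within_comparison = comparison_to_list(report$within_comparison),
    between_comparison = comparison_to_list(report$between_comparison),
    errors = report$errors)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js[!vapply(js, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
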