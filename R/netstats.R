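# Protein-interaction-network metrics and group-comparison statistics.

#' Per-node network metrics
#'
#' Computes degree, exact (Brandes) unnormalized shortest-path betweenness
#' centrality on the undirected simple graph, and — when an ortholog map is
#' supplied — the number of neighbors lacking an ortholog in the other
#' species (the per-node re-wiring score). Duplicate edges and self-loops
#' are dropped.
#'
#' @param edges data frame whose first two columns are node identifiers of
#'   an undirected edge list.
#' @param ortholog_map optional: either a character vector of nodes that
#'   have an ortholog, or a two-column data frame mapping nodes across
#'   species (the column sharing more identifiers with this network is
#'   used).
#' @return A tibble with columns `node`, `degree`, `betweenness`,
#'   `nonortholog_neighbors` (NA when no map is supplied).
#' @examples
#' star <- tibble::tibble(a = "hub", b = paste0("leaf", 1:4))
#' compute_metrics(star)
#' @export
compute_metrics <- function(edges, ortholog_map = NULL) {
  edges <- as_tibble(edges)
  if (nrow(edges) == 0) abort("empty graph")
  el <- tibble(node_a = as.character(edges[[1]]),
               node_b = as.character(edges[[2]])) |>
    dplyr::filter(.data$node_a != .data$node_b) |>
    dplyr::mutate(lo = pmin(.data$node_a, .data$node_b),
                  hi = pmax(.data$node_a, .data$node_b)) |>
    dplyr::distinct(.data$lo, .data$hi)
  if (nrow(el) == 0) abort("empty graph after dropping self-loops")
  g <- igraph::graph_from_edgelist(as.matrix(el), directed = FALSE)
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)

  non_orth <- rep(NA_integer_, length(nodes))
  if (!is.null(ortholog_map)) {
    orth_nodes <- if (is.data.frame(ortholog_map)) {
      c1 <- as.character(ortholog_map[[1]])
      c2 <- as.character(ortholog_map[[2]])
      if (sum(nodes %in% c1) >= sum(nodes %in% c2)) c1 else c2
    } else {
      as.character(ortholog_map)
    }
    adj <- igraph::adjacent_vertices(g, igraph::V(g))
    non_orth <- vapply(adj, function(v) {
      sum(!(igraph::V(g)$name[v] %in% orth_nodes))
    }, integer(1))
  }
  tibble(node = nodes, degree = as.integer(deg), betweenness = unname(btw),
         nonortholog_neighbors = as.integer(non_orth))
}

# nodes at or above the (1 - top_fraction) quantile of `score`
top_quantile_set <- function(metrics, score, top_fraction) {
  thr <- quantile(metrics[[score]], 1 - top_fraction, names = FALSE)
  metrics$node[metrics[[score]] >= thr]
}

bottom_quantile_set <- function(metrics, score, bottom_fraction) {
  thr <- quantile(metrics[[score]], bottom_fraction, names = FALSE)
  metrics$node[metrics[[score]] <= thr]
}

#' Select hubs and non-hubs by degree
#'
#' Hubs are the most highly connected nodes (top `top_fraction` of the
#' degree distribution) and non-hubs the least connected (bottom
#' `bottom_fraction`); quantile ties are included on the qualifying side.
#'
#' @param metrics tibble from [compute_metrics()].
#' @param top_fraction,bottom_fraction decile cutoffs (defaults 0.10).
#' @return A list with character vectors `hubs`, `non_hubs` and logical
#'   `degenerate` (TRUE when all degrees are equal, in which case both sets
#'   contain every node).
#' @export
select_hubs <- function(metrics, top_fraction = 0.10, bottom_fraction = 0.10) {
  if (nrow(metrics) < 10) abort("need at least 10 nodes for decile selection")
  degenerate <- length(unique(metrics$degree)) == 1L
  list(
    hubs = top_quantile_set(metrics, "degree", top_fraction),
    non_hubs = bottom_quantile_set(metrics, "degree", bottom_fraction),
    degenerate = degenerate
  )
}

#' Select bottlenecks and non-bottlenecks by betweenness
#'
#' Bottlenecks are nodes in the top `top_fraction` of betweenness
#' centrality that are not also hubs; non-bottlenecks are the bottom
#' `bottom_fraction` of betweenness.
#'
#' @param metrics tibble from [compute_metrics()].
#' @param hubs character vector of hub nodes (from [select_hubs()]).
#' @param top_fraction,bottom_fraction decile cutoffs (defaults 0.10).
#' @return A list with `bottlenecks`, `non_bottlenecks`, `degenerate`.
#' @export
select_bottlenecks <- function(metrics, hubs, top_fraction = 0.10,
                               bottom_fraction = 0.10) {
  if (nrow(metrics) < 10) abort("need at least 10 nodes for decile selection")
  degenerate <- length(unique(metrics$betweenness)) == 1L
  top <- top_quantile_set(metrics, "betweenness", top_fraction)
  list(
    bottlenecks = setdiff(top, hubs),
    non_bottlenecks = bottom_quantile_set(metrics, "betweenness",
                                          bottom_fraction),
    degenerate = degenerate
  )
}

#' Consensus re-wired nodes across two networks
#'
#' A node is called re-wired when it sits in the top `top_fraction` of
#' non-orthologous-neighbor counts in its own network; the consensus set
#' contains the ortholog pairs whose members qualify in both networks
#' (interactions with proteins lacking an ortholog in the other species
#' must be species-specific, so a high count on both sides is conservative
#' evidence of re-wiring). Nodes with zero non-orthologous neighbors never
#' qualify, so fully orthologous network pairs yield an empty consensus.
#'
#' @param metrics_a,metrics_b tibbles from [compute_metrics()], each
#'   computed with the shared `ortholog_map`.
#' @param ortholog_map two-column data frame mapping network-a node names to
#'   network-b node names.
#' @param top_fraction decile cutoff (default 0.10).
#' @return A tibble of consensus pairs with columns `node_a`, `node_b`
#'   (possibly empty).
#' @export
rewired_consensus <- function(metrics_a, metrics_b, ortholog_map,
                              top_fraction = 0.10) {
  stopifnot(all(c("nonortholog_neighbors") %in% names(metrics_a)))
  top_set <- function(metrics) {
    x <- metrics$nonortholog_neighbors
    if (anyNA(x)) abort("metrics lack non-ortholog neighbor counts")
    thr <- quantile(x, 1 - top_fraction, names = FALSE)
    metrics$node[x >= thr & x > 0]
  }
  ta <- top_set(metrics_a)
  tb <- top_set(metrics_b)
  map <- tibble(node_a = as.character(ortholog_map[[1]]),
                node_b = as.character(ortholog_map[[2]]))
  dplyr::filter(map, .data$node_a %in% ta & .data$node_b %in% tb)
}

#' Standardized mean difference (Cohen's d)
#'
#' `(mean(x) - mean(y))` divided by the pooled standard deviation (n - 1
#' denominators); the sign follows the first argument.
#'
#' @param x,y numeric samples, each with at least 2 values.
#' @return The standardized mean difference.
#' @examples
#' smd(rnorm(100, 1), rnorm(100, 0))
#' @export
smd <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) abort("each sample needs at least 2 values")
  pooled <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
                   (nx + ny - 2))
  if (pooled == 0) abort("zero pooled standard deviation")
  (mean(x) - mean(y)) / pooled
}

#' Group-comparison tests
#'
#' Two-sided Wilcoxon rank-sum test with attached standardized mean
#' difference for two numeric samples, or Fisher's exact test for a 2x2
#' contingency table. When every value in both samples is identical there
#' is no evidence either way and p = 1 by convention.
#'
#' @param x numeric sample, or a 2x2 matrix/table of counts.
#' @param y numeric sample (ignored for the contingency-table form).
#' @return A one-row tibble: `statistic_name`, `statistic`, `p_value`,
#'   `smd` (NA for Fisher), `n_x`, `n_y`.
#' @examples
#' group_tests(rnorm(20), rnorm(20, 1))
#' group_tests(matrix(c(10, 0, 0, 10), 2))
#' @export
group_tests <- function(x, y = NULL) {
  if (is.matrix(x) || is.table(x)) {
    ft <- fisher.test(x)
    return(tibble(statistic_name = "fisher_exact",
                  statistic = unname(ft$estimate %||% NA_real_),
                  p_value = ft$p.value, smd = NA_real_,
                  n_x = sum(x[1, ]), n_y = sum(x[2, ])))
  }
  if (length(x) == 0 || length(y) == 0) abort("empty group")
  if (length(unique(c(x, y))) == 1L) {
    return(tibble(statistic_name = "wilcoxon_rank_sum",
                  statistic = NA_real_, p_value = 1,
                  smd = 0, n_x = length(x), n_y = length(y)))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  effect <- tryCatch(smd(x, y), error = function(e) NA_real_)
  tibble(statistic_name = "wilcoxon_rank_sum",
         statistic = unname(wt$statistic), p_value = wt$p.value,
         smd = effect, n_x = length(x), n_y = length(y))
}
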