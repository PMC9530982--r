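#' Maximum number of potential ties among n participants
#'
#' The denominator of the density formula: the number of unordered pairs,
#' n(n-1)/2.
#'
#' @param n Node count, at least 1.
#' @return Integer pair count.
#' @examples
#' max_potential_ties(660)  # 217470
#' @export
max_potential_ties <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    stop("n must be a single integer >= 1")
  }
  as.numeric(n) * (n - 1) / 2
}

#' Network density with reciprocated duplicates collapsed
#'
#' Two participants are counted as tied when at least one of them regards
#' the other as a confidant; the undirected tie count (directed ties minus
#' the duplicates arising from reciprocated pairs) is divided by the
#' number of potential ties n(n-1)/2.
#'
#' @param net A [confidant_network()] with at least 2 nodes.
#' @return Density in `[0, 1]` (full precision; see
#'   [describe_network()] for the 3-decimal reporting convention).
#' @export
network_density <- function(net) {
  n <- network_size(net)
  if (n < 2) stop("density needs at least 2 nodes")
  undirected_tie_count(net) / max_potential_ties(n)
}

# number of unordered tied pairs (i.e. duplicates collapsed)
undirected_tie_count <- function(net) {
  if (!nrow(net$edges)) return(0L)
  key <- ifelse(net$edges$from < net$edges$to,
                paste(net$edges$from, net$edges$to, sep = "\r"),
                paste(net$edges$to, net$edges$from, sep = "\r"))
  length(unique(key))
}

#' Partition directed ties into one-way and reciprocal
#'
#' Classifies every directed tie by whether its reverse is also present.
#' The reciprocal count is twice the number of mutual dyads (both
#' directions counted), so the two counts sum to the directed tie count.
#'
#' @param net A [confidant_network()].
#' @return Named integer vector `c(one_way = ..., reciprocal = ...)`.
#' @export
reciprocity_partition <- function(net) {
  e <- net$edges
  if (!nrow(e)) return(c(one_way = 0L, reciprocal = 0L))
  fwd <- paste(e$from, e$to, sep = "\r")
  rev <- paste(e$to, e$from, sep = "\r")
  recip <- sum(rev %in% fwd)
  c(one_way = nrow(e) - recip, reciprocal = recip)
}

#' Components and geodesic distances of the collapsed network
#'
#' On the undirected collapse of the network (a tie wherever at least one
#' direction exists), with isolated nodes excluded: counts the connected
#' components ("number of social networks"), their size range, and the
#' mean geodesic (shortest-path) distance over all unordered pairs of
#' nodes lying in the same component.
#'
#' @param net A [confidant_network()].
#' @return A list `component_count`, `size_range` (length-2 integer),
#'   `mean_geodesic` (`NA` when there are no ties).
#' @export
components_and_geodesics <- function(net) {
  if (!nrow(net$edges)) {
    return(list(component_count = 0L, size_range = c(NA_integer_,
                NA_integer_), mean_geodesic = NA_real_))
  }
  g <- as_igraph(net, collapse = TRUE)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  comp <- igraph::components(g)
  d <- igraph::distances(g)
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  list(
    component_count = comp$no,
    size_range = range(comp$csize),
    mean_geodesic = if (length(finite)) mean(finite) else NA_real_
  )
}

#' Distribution of symptom-score differences across ties
#'
#' For every directed tie, the absolute difference of the two endpoints'
#' scores on the given attribute; returns the histogram together with the
#' number of exactly matched ties and of ties within five points.
#'
#' @param net A [confidant_network()] whose `node_data` contains
#'   `attribute`.
#' @param attribute Node attribute name (e.g. "gds_total", "apathy").
#' @return A list `histogram` (table over observed differences),
#'   `n_ties_scored`, `n_ties_dropped` (ties with a missing endpoint
#'   score), `n_exact_match` and `n_within_five`.
#' @export
score_difference_profile <- function(net, attribute = "gds_total") {
  if (is.null(net$node_data) || !(attribute %in% names(net$node_data))) {
    stop("node attribute not found: ", attribute)
  }
  x <- net$node_data[[attribute]][match(net$edges$from, net$nodes)]
  y <- net$node_data[[attribute]][match(net$edges$to, net$nodes)]
  ok <- !is.na(x) & !is.na(y)
  d <- abs(x[ok] - y[ok])
  list(
    histogram = table(factor(d, levels = if (length(d)) 0:max(d) else
      integer(0))),
    n_ties_scored = sum(ok),
    n_ties_dropped = sum(!ok),
    n_exact_match = sum(d == 0),
    n_within_five = sum(d <= 5)
  )
}

#' Network-level descriptive statistics
#'
#' The descriptive surface for a directed confidant network: node and tie
#' counts, the one-way/reciprocal partition, tie provenance counts,
#' duplicate-collapsed density, component structure and mean geodesic
#' distance.
#'
#' @param net A [confidant_network()].
#' @return An object of class `network_descriptives` (a list; see
#'   fields in the source). `density` is full precision;
#'   `print()` rounds it to 3 decimals.
#' @export
describe_network <- function(net) {
  n <- network_size(net)
  rp <- reciprocity_partition(net)
  cg <- components_and_geodesics(net)
  prov <- table(factor(net$edges$provenance,
                       levels = c("household", "community")))
  g <- as_igraph(net, collapse = TRUE)
  vertices_with_tie <- sum(igraph::degree(g) > 0)
  out <- list(
    n = n,
    directed_tie_count = nrow(net$edges),
    one_way_tie_count = unname(rp["one_way"]),
    reciprocal_directed_tie_count = unname(rp["reciprocal"]),
    household_tie_count = unname(prov[["household"]]),
    community_tie_count = unname(prov[["community"]]),
    vertices_with_tie = vertices_with_tie,
    undirected_tie_count = undirected_tie_count(net),
    max_potential_ties = max_potential_ties(n),
    density = if (n >= 2) network_density(net) else NA_real_,
    component_count = cg$component_count,
    component_size_range = cg$size_range,
    mean_geodesic = cg$mean_geodesic
  )
  class(out) <- "network_descriptives"
  out
}

#' @export
print.network_descriptives <- function(x, ...) {
  cat("Confidant network descriptives\n")
  cat(sprintf("  participants (n)             %d\n", x$n))
  cat(sprintf("  density                      %.3f\n", x$density))
  cat(sprintf("  vertices with >=1 tie        %d\n", x$vertices_with_tie))
  cat(sprintf("  total directed ties          %d\n", x$directed_tie_count))
  cat(sprintf("    inside the household       %d\n", x$household_tie_count))
  cat(sprintf("    outside the household      %d\n", x$community_tie_count))
  cat(sprintf("    one-way                    %d\n", x$one_way_tie_count))
  cat(sprintf("    reciprocal (two-way)       %d\n",
              x$reciprocal_directed_tie_count))
  cat(sprintf("  social networks (size range) %d (%s-%s)\n",
              x$component_count, x$component_size_range[1],
              x$component_size_range[2]))
  cat(sprintf("  mean geodesic distance       %.1f\n", x$mean_geodesic))
  invisible(x)
}

#' Flatten descriptives to a two-column data frame
#' @param x A `network_descriptives` object.
#' @param ... Unused.
#' @return Data frame with `statistic` and `value` columns (density
#'   reported to 3 decimals, mean geodesic to 1).
#' @export
as.data.frame.network_descriptives <- function(x, ...) {
  data.frame(
    statistic = c("Density", "Number of vertices with more than one tie",
                  "Total confidant ties", "Inside the household",
                  "Outside the household", "Unique",
                  "Reciprocal (two-way) ties",
                  "Number of social networks", "Smallest network size",
                  "Largest network size",
                  "Mean geodesic distance within the participants"),
    value = c(round(x$density, 3), x$vertices_with_tie,
              x$directed_tie_count, x$household_tie_count,
              x$community_tie_count, x$one_way_tie_count,
              x$reciprocal_directed_tie_count, x$component_count,
              x$component_size_range[1], x$component_size_range[2],
              round(x$mean_geodesic, 1)),
    stringsAsFactors = FALSE
  )
}
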