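#' Construct a directed confidant network
#'
#' The container used by the descriptive and model-fitting functions: an
#' ordered node set, a directed edge list (an edge i -> j means "i regards
#' j as a confidant"), per-node attribute data and, optionally, a
#' provenance label per edge ("household" or "community").
#'
#' @param nodes Character vector of unique participant ids.
#' @param edges A data frame with character columns `from` and `to` (and
#'   optionally `provenance`), or a 2-column matrix. Self-ties are
#'   rejected; duplicate directed edges are collapsed.
#' @param node_data Optional data frame of node attributes with a
#'   `participant_id` column covering every node.
#' @return An object of class `confidant_network`.
#' @export
confidant_network <- function(nodes, edges = NULL, node_data = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate participant ids in node set")
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        provenance = character(), stringsAsFactors = FALSE)
  }
  if (is.matrix(edges)) {
    edges <- data.frame(from = edges[, 1], to = edges[, 2],
                        stringsAsFactors = FALSE)
  }
  if (!all(c("from", "to") %in% names(edges))) {
    stop("edges need 'from' and 'to' columns")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!("provenance" %in% names(edges))) {
    edges$provenance <- rep(NA_character_, nrow(edges))
  }
  edges <- edges[, c("from", "to", "provenance")]
  if (any(edges$from == edges$to)) stop("self-ties are not allowed")
  unknown <- setdiff(c(edges$from, edges$to), nodes)
  if (length(unknown)) {
    stop("edge endpoints not in node set: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  dup <- duplicated(edges[, c("from", "to")])
  edges <- edges[!dup, , drop = FALSE]
  o <- order(match(edges$from, nodes), match(edges$to, nodes))
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(node_data)) {
    if (!("participant_id" %in% names(node_data))) {
      stop("node_data needs a participant_id column")
    }
    node_data$participant_id <- as.character(node_data$participant_id)
    if (!all(nodes %in% node_data$participant_id)) {
      stop("node_data does not cover every node")
    }
    node_data <- node_data[match(nodes, node_data$participant_id), ,
                           drop = FALSE]
    rownames(node_data) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, node_data = node_data),
            class = "confidant_network")
}

#' Number of nodes in a confidant network
#' @param net A `confidant_network`.
#' @return Integer node count.
#' @export
network_size <- function(net) length(net$nodes)

#' Directed adjacency matrix of a confidant network
#' @param net A `confidant_network`.
#' @return A logical n x n matrix with `[i, j] = TRUE` iff i -> j.
#' @export
as_adjacency <- function(net) {
  n <- network_size(net)
  a <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    a[cbind(match(net$edges$from, net$nodes),
            match(net$edges$to, net$nodes))] <- TRUE
  }
  a
}

#' @export
print.confidant_network <- function(x, ...) {
  rp <- reciprocity_partition(x)
  cat("Directed confidant network\n")
  cat("  nodes:", network_size(x), "\n")
  cat(sprintf("  directed ties: %d (%d reciprocal, %d one-way)\n",
              nrow(x$edges), rp[["reciprocal"]], rp[["one_way"]]))
  if (!is.null(x$node_data)) {
    cat("  node attributes:",
        paste(setdiff(names(x$node_data), "participant_id"),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert to an igraph graph
#' @param net A `confidant_network`.
#' @param collapse Collapse to an undirected graph (an undirected edge
#'   wherever at least one direction is present)?
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net, collapse = FALSE) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = net$nodes)
  )
  if (collapse) g <- igraph::as_undirected(g, mode = "collapse")
  g
}
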