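#' Specify a dyad-separable directed ERGM
#'
#' Parses a character term specification into the model's term table.
#' Supported term kinds (all dyad-separable, which is what makes the
#' exact per-dyad likelihood of [fit_exact()] available):
#' \describe{
#'   \item{`edges`}{number of directed ties (the intercept).}
#'   \item{`mutual`}{number of reciprocated dyads (both directions
#'     present); the "reciprocity" structural term.}
#'   \item{`nodal:<attr>`}{nodal main effect: the sum over directed ties
#'     of the attribute values of both endpoints, x_i + x_j
#'     (sender+receiver convention; see [dyad_design()] for variants).}
#'   \item{`absdiff:<attr>`}{similarity / homophily term: the sum over
#'     directed ties of |x_i - x_j|. A negative coefficient means ties
#'     are more likely between similar nodes.}
#' }
#'
#' @param spec Character vector, e.g.
#'   `c("edges", "mutual", "absdiff:gds_total", "nodal:female")`.
#'   `nodal_main:` and `nodecov:` are accepted aliases for `nodal:`.
#' @return A data frame of class `ergm_terms` with columns `kind`,
#'   `attribute` and `label`.
#' @export
ergm_terms <- function(spec) {
  if (inherits(spec, "ergm_terms")) return(spec)
  stopifnot(is.character(spec), length(spec) >= 1)
  parts <- strsplit(spec, ":", fixed = TRUE)
  kind <- vapply(parts, `[`, "", 1)
  kind[kind %in% c("nodal_main", "nodecov")] <- "nodal"
  attribute <- vapply(parts, function(p) if (length(p) > 1) p[2] else
    NA_character_, "")
  ok_kind <- kind %in% c("edges", "mutual", "nodal", "absdiff")
  if (!all(ok_kind)) {
    stop("unknown term kind(s): ", paste(unique(kind[!ok_kind]),
                                         collapse = ", "))
  }
  needs_attr <- kind %in% c("nodal", "absdiff")
  if (any(needs_attr & is.na(attribute))) {
    stop("terms ", paste(spec[needs_attr & is.na(attribute)],
                         collapse = ", "), " need an attribute, ",
         "e.g. 'absdiff:gds_total'")
  }
  if (any(!needs_attr & !is.na(attribute))) {
    stop("edges/mutual terms take no attribute")
  }
  label <- ifelse(is.na(attribute), kind, paste(kind, attribute, sep = "."))
  if (anyDuplicated(label)) stop("duplicate terms: ",
                                 paste(label[duplicated(label)],
                                       collapse = ", "))
  structure(data.frame(kind = kind, attribute = attribute, label = label,
                       stringsAsFactors = FALSE),
            class = c("ergm_terms", "data.frame"))
}

#' Default model term sets
#'
#' The term set of the full homophily model: edges, reciprocity, the
#' absolute-difference similarity term on the chosen symptom score, and
#' nodal main effects for the symptom score and the demographic
#' covariates (sex, age 75+, living with family, disability, education
#' dummies).
#'
#' @param similarity Attribute carrying the homophily term and its nodal
#'   main effect: "gds_total" (overall depressivity), "apathy" or
#'   "suicidal_ideation".
#' @param covariates Nodal covariate attributes to adjust for.
#' @return An [ergm_terms()] object.
#' @export
default_model_terms <- function(similarity = "gds_total",
                                covariates = c("female", "age_ge75",
                                               "lives_with_family",
                                               "disability", "edu_10_12",
                                               "edu_13plus")) {
  ergm_terms(c("edges", "mutual",
               paste0("absdiff:", similarity),
               paste0("nodal:", covariates),
               paste0("nodal:", similarity)))
}

#' Per-dyad design of a dyad-separable ERGM
#'
#' For every unordered dyad \{i, j\} (i < j in node order), the
#' contribution of a single asymmetric tie to each model statistic. For
#' this term family both asymmetric states contribute identically, and
#' the mutual state contributes twice the asymmetric row plus one on the
#' `mutual` column, so this matrix together with the mutual-column index
#' fully determines the per-dyad four-state distribution.
#'
#' @param node_data Data frame of node attributes (one row per node, in
#'   node order) containing every attribute the terms reference.
#' @param terms An [ergm_terms()] object (or character spec).
#' @param allowed Optional logical vector over dyads (or D x 2 index
#'   matrix of permitted dyads) restricting the dyad support; dyads not
#'   allowed are structurally null and excluded from likelihoods and
#'   simulation.
#' @param nodal_mode "sum" (default, x_i + x_j per directed tie),
#'   "sender" (x_i only) or "receiver" (x_j only).
#' @return A list: `n`, `pairs` (D x 2 integer matrix of node indices,
#'   i < j), `A` (D x p asymmetric-state contribution matrix),
#'   `mutual_col` (0 when no mutual term), `labels`.
#' @export
dyad_design <- function(node_data, terms, allowed = NULL,
                        nodal_mode = c("sum", "sender", "receiver")) {
  terms <- ergm_terms(terms)
  nodal_mode <- match.arg(nodal_mode)
  n <- nrow(node_data)
  if (n < 2) stop("need at least 2 nodes")
  pairs <- pair_index(n)
  if (!is.null(allowed)) {
    if (is.matrix(allowed)) {
      key <- paste(pmin(allowed[, 1], allowed[, 2]),
                   pmax(allowed[, 1], allowed[, 2]))
      allowed <- paste(pairs[, 1], pairs[, 2]) %in% key
    }
    stopifnot(length(allowed) == nrow(pairs))
    pairs <- pairs[allowed, , drop = FALSE]
  }
  p <- nrow(terms)
  A <- matrix(0, nrow(pairs), p, dimnames = list(NULL, terms$label))
  for (k in seq_len(p)) {
    kind <- terms$kind[k]
    if (kind == "edges") {
      A[, k] <- 1
    } else if (kind == "mutual") {
      A[, k] <- 0
    } else {
      attr_name <- terms$attribute[k]
      if (!(attr_name %in% names(node_data))) {
        stop("node attribute not found: ", attr_name)
      }
      x <- node_data[[attr_name]]
      if (anyNA(x)) {
        bad <- which(is.na(x))[1]
        stop("missing value of attribute '", attr_name, "' at node ",
             if (!is.null(node_data$participant_id))
               node_data$participant_id[bad] else bad,
             "; drop incomplete nodes before building the design")
      }
      xi <- x[pairs[, 1]]
      xj <- x[pairs[, 2]]
      if (kind == "absdiff") {
        A[, k] <- abs(xi - xj)
      } else if (nodal_mode == "sum") {
        A[, k] <- xi + xj
      } else {
        # sender/receiver variants break the i<->j symmetry only when the
        # attribute differs within a dyad; they are not supported by the
        # symmetric dyad design and require the ordered-pair MPLE path
        stop("nodal_mode '", nodal_mode,
             "' is not dyad-symmetric; only 'sum' is supported here")
      }
    }
  }
  mutual_col <- match("mutual", terms$kind, nomatch = 0L)
  list(n = n, pairs = pairs, A = A, mutual_col = mutual_col,
       labels = terms$label, terms = terms)
}

# unordered pairs (i, j), i < j, in a fixed deterministic order
pair_index <- function(n) {
  j <- rep(2:n, times = 1:(n - 1))
  i <- sequence(1:(n - 1))
  cbind(i = i, j = j)
}

# per-dyad state from a logical adjacency matrix:
# 0 null, 1 i->j, 2 j->i, 3 mutual
dyad_states <- function(adj, pairs) {
  as.integer(adj[pairs] + 2L * adj[pairs[, c(2, 1), drop = FALSE]])
}

# observed statistic vector from a design and per-dyad states
design_statistics <- function(design, states) {
  asym <- as.numeric(states == 1L | states == 2L)
  mut <- as.numeric(states == 3L)
  s <- drop(crossprod(design$A, asym + 2 * mut))
  if (design$mutual_col) s[design$mutual_col] <- s[design$mutual_col] +
      sum(mut)
  setNames(s, design$labels)
}

#' Model statistics of an observed network
#'
#' The sufficient statistic vector s(y): directed tie count, mutual-dyad
#' count, and the nodal / absolute-difference sums over directed ties.
#'
#' @param net A [confidant_network()] with node attributes covering the
#'   terms.
#' @param terms An [ergm_terms()] object or character spec.
#' @return Named numeric vector of statistics.
#' @export
term_statistics <- function(net, terms) {
  design <- dyad_design(net$node_data, terms)
  adj <- as_adjacency(net)
  design_statistics(design, dyad_states(adj, design$pairs))
}

#' Change statistic of one directed tie
#'
#' The difference in the statistic vector from toggling the tie i -> j on,
#' holding the rest of the network fixed: +1 on edges, +Y_ji on mutual,
#' +(x_i + x_j) on nodal terms, +|x_i - x_j| on absolute-difference terms.
#' theta times this vector is the conditional log-odds of the tie.
#'
#' @param net A [confidant_network()].
#' @param terms Term specification.
#' @param from,to Participant ids of the ordered pair (distinct).
#' @return Named numeric change-statistic vector.
#' @export
change_statistic <- function(net, terms, from, to) {
  if (identical(from, to)) stop("self-ties have no change statistic")
  terms <- ergm_terms(terms)
  i <- match(from, net$nodes)
  j <- match(to, net$nodes)
  if (is.na(i) || is.na(j)) stop("unknown node id")
  adj <- as_adjacency(net)
  delta <- numeric(nrow(terms))
  for (k in seq_len(nrow(terms))) {
    delta[k] <- switch(terms$kind[k],
      edges = 1,
      mutual = as.numeric(adj[j, i]),
      nodal = {
        x <- net$node_data[[terms$attribute[k]]]
        x[i] + x[j]
      },
      absdiff = {
        x <- net$node_data[[terms$attribute[k]]]
        abs(x[i] - x[j])
      })
  }
  setNames(delta, terms$label)
}
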