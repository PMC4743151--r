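#' Causal Bayesian network over discrete nodes
#'
#' Bundles a topology, a per-node state space and one conditional probability
#' table (CPT) per node. States are canonically the integers `0..k-1`;
#' display labels (e.g. low/medium/high) are cosmetic and resolved back to
#' integer states wherever a state may be given by name.
#'
#' Each CPT is a numeric array whose first dimension ranges over the child's
#' states and whose remaining dimensions range over the states of the
#' parents in canonical (lexicographic) order; `names(dimnames(cpt))` names
#' the variables. For every parent configuration the entries over child
#' states sum to one.
#'
#' @param topology a [cbn_topology].
#' @param states either a named integer vector of state counts (labels
#'   default to `"0"..."k-1"`) or a named list of character label vectors,
#'   one entry per node, each of length >= 2.
#' @param cpts optional named list of CPT arrays; nodes without an entry get
#'   the uniform CPT.
#' @param data optional discretised data matrix (variables x samples,
#'   integer states, `NA` = missing) retained for re-estimating CPTs after
#'   edge interventions.
#' @return an object of class `cbn`.
#' @seealso [fit_cbn()], [validate_network()], [make_sprinkler()]
#' @export
cbn <- function(topology, states, cpts = NULL, data = NULL) {
  stopifnot(inherits(topology, "cbn_topology"))
  nodes <- topology$nodes
  states <- as_state_labels(states, nodes)
  parents <- node_parents(topology)
  net <- structure(
    list(topology = topology, states = states, parents = parents,
         cpts = NULL, data = NULL),
    class = "cbn")
  full <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    full[[v]] <- if (!is.null(cpts) && !is.null(cpts[[v]])) {
      as_cpt(cpts[[v]], net, v)
    } else {
      uniform_cpt(net, v)
    }
  }
  net$cpts <- full
  if (!is.null(data)) net$data <- check_discrete_data(data, net)
  net
}

as_state_labels <- function(states, nodes) {
  if (!is.list(states)) {
    if (is.null(names(states))) stop("states must be named per node")
    states <- lapply(stats::setNames(as.integer(states), names(states)),
                     function(k) as.character(seq_len(k) - 1L))
  }
  missing <- setdiff(nodes, names(states))
  if (length(missing)) {
    stop("no state space for node(s): ", paste(missing, collapse = ", "))
  }
  states <- states[nodes]
  for (v in nodes) {
    lab <- as.character(states[[v]])
    if (length(lab) < 2L) stop("node ", v, " needs at least 2 states")
    if (anyDuplicated(lab)) stop("duplicate state labels for node ", v)
    states[[v]] <- lab
  }
  states
}

nstates <- function(net, nodes = net$topology$nodes) {
  vapply(net$states[nodes], length, integer(1))
}

cpt_dim <- function(net, node) {
  unname(nstates(net, c(node, net$parents[[node]])))
}

uniform_cpt <- function(net, node) {
  d <- cpt_dim(net, node)
  vars <- c(node, net$parents[[node]])
  array(1 / d[1L], dim = d,
        dimnames = stats::setNames(net$states[vars], vars))
}

# coerce a user-supplied table to the canonical CPT array for `node`
as_cpt <- function(x, net, node) {
  d <- cpt_dim(net, node)
  vars <- c(node, net$parents[[node]])
  if (length(x) != prod(d)) {
    stop("CPT for ", node, " has ", length(x), " entries, expected ", prod(d))
  }
  if (!is.null(dim(x)) && length(dim(x)) == length(d)) {
    nm <- names(dimnames(x))
    if (!is.null(nm) && !identical(nm, vars)) {
      if (!setequal(nm, vars)) stop("CPT for ", node, ": variables ",
                                    paste(nm, collapse = ","),
                                    " do not match family ",
                                    paste(vars, collapse = ","))
      x <- aperm(x, match(vars, nm))
    }
    if (!identical(unname(dim(x)), d)) {
      stop("CPT for ", node, ": dimensions do not match state counts")
    }
  }
  array(as.numeric(x), dim = d,
        dimnames = stats::setNames(net$states[vars], vars))
}

check_discrete_data <- function(data, net) {
  if (!is.matrix(data)) stop("data must be a matrix (variables x samples)")
  missing <- setdiff(net$topology$nodes, rownames(data))
  if (length(missing)) {
    stop("data lack variable(s): ", paste(missing, collapse = ", "))
  }
  k <- nstates(net)
  for (v in net$topology$nodes) {
    x <- data[v, ]
    bad <- !is.na(x) & (x < 0 | x >= k[[v]] | x != floor(x))
    if (any(bad)) stop("data for ", v, " contain states outside 0..",
                       k[[v]] - 1L)
  }
  data
}

#' Validate a causal Bayesian network
#'
#' Reporting operation: checks that every node has a CPT, that each CPT's
#' variables mirror the node's current graph parents, that dimensions match
#' the state spaces, that all entries lie in `[0, 1]` and that every parent
#' configuration's column sums to one (tolerance 1e-9).
#'
#' @param n a [cbn] network.
#' @return character vector of human-readable violations; empty iff valid.
#' @export
validate_network <- function(n) {
  stopifnot(inherits(n, "cbn"))
  bad <- character(0)
  for (v in n$topology$nodes) {
    cpt <- n$cpts[[v]]
    if (is.null(cpt)) {
      bad <- c(bad, paste0("missing CPT for node ", v))
      next
    }
    vars <- names(dimnames(cpt))
    want <- c(v, n$parents[[v]])
    if (!identical(vars, want)) {
      bad <- c(bad, paste0("parent mismatch for node ", v, ": CPT over (",
                           paste(vars, collapse = ","), "), graph family (",
                           paste(want, collapse = ","), ")"))
      next
    }
    if (!identical(unname(dim(cpt)), cpt_dim(n, v))) {
      bad <- c(bad, paste0("CPT dimensions for node ", v,
                           " do not match state counts"))
      next
    }
    if (any(cpt < -1e-12 | cpt > 1 + 1e-12)) {
      bad <- c(bad, paste0("CPT for node ", v, " has entries outside [0,1]"))
    }
    m <- matrix(cpt, nrow = dim(cpt)[1L])
    sums <- colSums(m)
    off <- which(abs(sums - 1) > 1e-9)
    for (j in off) {
      bad <- c(bad, paste0("CPT for node ", v, ", parent configuration ",
                           config_label(n, v, j), " sums to ",
                           format(sums[j], digits = 10)))
    }
  }
  bad
}

# 1-based linear parent-configuration index (first parent fastest,
# column-major) -> "p1=s1,p2=s2" label; "-" for a root
config_label <- function(net, node, j) {
  ps <- net$parents[[node]]
  if (!length(ps)) return("-")
  k <- nstates(net, ps)
  idx <- arrayInd(j, k)
  paste(paste0(ps, "=", idx - 1L), collapse = ",")
}

#' @export
print.cbn <- function(x, ...) {
  k <- nstates(x)
  cat("Causal Bayesian network:", length(x$topology$nodes), "nodes,",
      nrow(x$topology$edges), "edges\n")
  cat("  state counts:",
      paste0(names(k), "(", k, ")", collapse = " "), "\n")
  if (!is.null(x$data)) {
    cat("  training data retained:", ncol(x$data), "samples\n")
  }
  invisible(x)
}

#' Plot the network graph
#'
#' Draws the DAG with igraph's layered Sugiyama layout when igraph is
#' installed.
#'
#' @param x a [cbn].
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.cbn <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting requires the igraph package")
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(x$topology$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = x$topology$nodes))
  plot(g, layout = igraph::layout_with_sugiyama(g)$layout, ...)
  invisible(x)
}
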