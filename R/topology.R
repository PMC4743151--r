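#' Directed acyclic network topology
#'
#' Constructs a directed acyclic graph over named nodes. A topology is the
#' structural half of a causal Bayesian network: nodes are variables, and a
#' directed edge from parent to child asserts a direct causal influence.
#'
#' @param nodes character vector of unique, non-empty node names.
#' @param edges two-column character matrix (or data frame) of directed
#'   edges, first column parent, second column child. May have zero rows.
#' @return an object of class `cbn_topology` with components `nodes`
#'   (character vector) and `edges` (two-column character matrix with
#'   columns `from`, `to`).
#' @examples
#' tp <- cbn_topology(c("R", "S", "W"),
#'                    rbind(c("R", "S"), c("R", "W"), c("S", "W")))
#' topological_order(tp)
#' @export
cbn_topology <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) stop("a topology needs at least one node")
  if (anyNA(nodes) || any(!nzchar(nodes))) stop("node names must be non-empty")
  if (anyDuplicated(nodes)) {
    stop("duplicate node name(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns (from, to)")
    storage.mode(edges) <- "character"
  }
  colnames(edges) <- c("from", "to")
  rownames(edges) <- NULL
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown)) {
    stop("edge endpoint(s) not declared as nodes: ",
         paste(unknown, collapse = ", "))
  }
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edge(s)")
  tp <- structure(list(nodes = nodes, edges = edges), class = "cbn_topology")
  topological_order(tp)  # raises on cycles
  tp
}

#' @export
print.cbn_topology <- function(x, ...) {
  cat("Topology:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  nodes:", paste(x$nodes, collapse = " "), "\n")
  if (nrow(x$edges)) {
    cat("  edges:",
        paste(x$edges[, 1L], "->", x$edges[, 2L], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Deterministic topological order of a topology
#'
#' Kahn's algorithm with lexicographic tie-breaking: among the nodes whose
#' parents have all been emitted, the alphabetically smallest is emitted
#' first, so the order is unique and reproducible.
#'
#' @param t a [cbn_topology].
#' @return character vector: a permutation of `t$nodes` in which every
#'   parent precedes each of its children.
#' @export
topological_order <- function(t) {
  stopifnot(inherits(t, "cbn_topology"))
  nodes <- t$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(t$edges[, 2L])
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  indeg <- indeg[indeg > 0L]
  from <- t$edges[, 1L]; to <- t$edges[, 2L]
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    for (ch in to[from == v]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) {
        indeg <- indeg[names(indeg) != ch]
        avail <- sort(c(avail, ch))
      }
    }
  }
  if (length(out) != length(nodes)) {
    stop("cycle detected involving node(s): ",
         paste(sort(setdiff(nodes, out)), collapse = ", "))
  }
  out
}

#' Test whether one node is an ancestor of another
#'
#' @param t a [cbn_topology].
#' @param a,b node names. `is_ancestor(t, x, x)` is `FALSE` by convention.
#' @return `TRUE` iff a directed path `a -> ... -> b` exists.
#' @export
is_ancestor <- function(t, a, b) {
  stopifnot(inherits(t, "cbn_topology"))
  for (v in c(a, b)) {
    if (!v %in% t$nodes) stop("unknown node: ", v)
  }
  if (a == b) return(FALSE)
  b %in% descendants(t, a)
}

# all strict descendants of `a` (internal)
descendants <- function(t, a) {
  from <- t$edges[, 1L]; to <- t$edges[, 2L]
  seen <- character(0)
  frontier <- a
  while (length(frontier)) {
    nxt <- unique(to[from %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# parents of every node, each list element sorted lexicographically;
# canonical parent order used for all CPT dimensions
node_parents <- function(t) {
  out <- stats::setNames(vector("list", length(t$nodes)), t$nodes)
  for (v in t$nodes) out[[v]] <- character(0)
  if (nrow(t$edges)) {
    sp <- split(t$edges[, 1L], t$edges[, 2L])
    for (v in names(sp)) out[[v]] <- sort(unique(sp[[v]]))
  }
  out
}

node_children <- function(t, v) unique(t$edges[t$edges[, 1L] == v, 2L])
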