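#' Exact posterior inference by variable elimination
#'
#' Computes the joint posterior distribution `P(targets | evidence)` on a
#' discrete causal Bayesian network by variable elimination: every CPT is
#' turned into a factor, factors are reduced by the evidence, all remaining
#' variables are summed out along a min-fill elimination order, and the
#' resulting table is normalised.
#'
#' @param n a [cbn] network (or a [fit_cbn()] result).
#' @param targets character vector of query nodes (non-empty, disjoint from
#'   the evidence nodes).
#' @param evidence named vector or list mapping observed nodes to states
#'   (0-based integers or display labels); `NULL` for none.
#' @param elim_order optional explicit elimination order over the
#'   non-target, non-evidence variables; overrides the heuristic.
#' @param tie `"lex"` (default) or `"revlex"`: tie-breaking direction in the
#'   min-fill heuristic. The order affects cost only, never the result.
#' @return a [cbn_factor] over `targets` (in the given order) summing to 1.
#' @section Errors: evidence with probability zero raises an "inconsistent
#'   evidence" error naming the evidence, rather than returning `0/0`.
#' @examples
#' net <- make_sprinkler()
#' variable_elimination(net, "R", c(W = 1))
#' @export
variable_elimination <- function(n, targets, evidence = NULL,
                                 elim_order = NULL,
                                 tie = c("lex", "revlex")) {
  n <- as_cbn(n)
  tie <- match.arg(tie)
  targets <- as.character(targets)
  if (!length(targets)) stop("at least one target node is required")
  ev <- resolve_evidence(n, evidence)
  unknown <- setdiff(targets, n$topology$nodes)
  if (length(unknown)) stop("unknown target node(s): ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(targets)) stop("duplicate target node(s)")
  clash <- intersect(targets, names(ev))
  if (length(clash)) stop("node(s) both target and evidence: ",
                          paste(clash, collapse = ", "))

  factors <- lapply(n$topology$nodes, function(v) {
    reduce_and_slice(cpt_factor(n, v), ev)
  })
  elim <- setdiff(n$topology$nodes, c(targets, names(ev)))
  if (is.null(elim_order)) {
    elim_order <- min_fill_order(factors, elim, tie)
  } else {
    if (!setequal(elim_order, elim)) {
      stop("elim_order must cover exactly the non-target, non-evidence nodes")
    }
  }
  for (v in elim_order) factors <- eliminate_var(factors, v)
  res <- Reduce(factor_product, factors)
  for (v in intersect(names(ev), res$scope)) res <- factor_marginalize(res, v)
  total <- sum(res$values)
  if (total <= 0) {
    stop("inconsistent evidence (probability 0): ",
         paste(paste0(names(ev), "=", ev), collapse = ", "))
  }
  res$values <- res$values / total
  factor_permute(res, targets)
}

# reduce by evidence, then sum the (now single-slice) evidence variables
# out immediately; identical result, much smaller intermediate factors
reduce_and_slice <- function(f, ev) {
  f <- factor_reduce(f, ev)
  for (v in intersect(names(ev), f$scope)) f <- factor_marginalize(f, v)
  f
}

# sum one variable out of the current factor list
eliminate_var <- function(factors, v) {
  has <- vapply(factors, function(f) v %in% f$scope, logical(1))
  if (!any(has)) return(factors)
  prod <- Reduce(factor_product, factors[has])
  c(factors[!has], list(factor_marginalize(prod, v)))
}

# min-fill heuristic over the factor interaction graph; deterministic
# tie-breaking by node name
min_fill_order <- function(factors, elim, tie = "lex") {
  adj <- list()
  link <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  for (f in factors) {
    sc <- f$scope
    if (length(sc) >= 1L) for (a in sc) adj[[a]] <- union(adj[[a]], character(0))
    if (length(sc) >= 2L) {
      for (i in seq_len(length(sc) - 1L)) {
        for (j in seq(i + 1L, length(sc))) link(sc[i], sc[j])
      }
    }
  }
  remaining <- elim
  order <- character(0)
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- adj[[v]]
      if (length(nb) < 2L) return(0L)
      cnt <- 0L
      for (i in seq_len(length(nb) - 1L)) {
        for (j in seq(i + 1L, length(nb))) {
          if (!nb[j] %in% adj[[nb[i]]]) cnt <- cnt + 1L
        }
      }
      cnt
    }, integer(1))
    cand <- remaining[fill == min(fill)]
    cand <- sort(cand)
    v <- if (tie == "lex") cand[1L] else cand[length(cand)]
    nb <- adj[[v]]
    if (length(nb) >= 2L) {
      for (i in seq_len(length(nb) - 1L)) {
        for (j in seq(i + 1L, length(nb))) link(nb[i], nb[j])
      }
    }
    for (u in nb) adj[[u]] <- setdiff(adj[[u]], v)
    adj[[v]] <- NULL
    remaining <- setdiff(remaining, v)
    order <- c(order, v)
  }
  order
}

# reorder a factor's scope (must be a permutation of `order`)
factor_permute <- function(f, order) {
  if (identical(f$scope, order)) return(f)
  if (!setequal(f$scope, order)) stop("scope mismatch in factor_permute")
  a <- array(f$values, dim = f$card)
  perm <- match(order, f$scope)
  a <- aperm(a, perm)
  cbn_factor(order, unname(f$card[perm]), as.vector(a))
}

#' Posterior probability of a joint state assignment
#'
#' @param n a [cbn] network (or fit).
#' @param target named vector/list mapping target nodes to states (integer
#'   or label); for several nodes the joint posterior probability is
#'   returned.
#' @param evidence as in [variable_elimination()].
#' @return scalar probability in `[0, 1]`.
#' @export
posterior_probability <- function(n, target, evidence = NULL) {
  n <- as_cbn(n)
  tg <- resolve_states(n, target)
  f <- variable_elimination(n, names(tg), evidence)
  idx <- 1
  for (j in seq_along(f$scope)) {
    stride <- if (j == 1L) 1 else prod(f$card[seq_len(j - 1L)])
    idx <- idx + tg[[f$scope[j]]] * stride
  }
  unname(f$values[idx])
}

#' Most likely posterior state of a node
#'
#' Ties are broken towards the smallest state index.
#'
#' @param n a [cbn] network (or fit).
#' @param target single node name.
#' @param evidence as in [variable_elimination()].
#' @return list with `state` (0-based integer), `label`, and `probability`.
#' @export
argmax_posterior <- function(n, target, evidence = NULL) {
  n <- as_cbn(n)
  if (length(target) != 1L) stop("argmax takes a single target node")
  f <- variable_elimination(n, target, evidence)
  s <- which.max(f$values)  # first maximum = smallest state index
  list(state = s - 1L, label = n$states[[target]][s],
       probability = unname(f$values[s]))
}

# total probability mass of the evidence; 1 for empty evidence
prob_evidence <- function(n, evidence) {
  n <- as_cbn(n)
  ev <- resolve_evidence(n, evidence)
  factors <- lapply(n$topology$nodes, function(v) {
    reduce_and_slice(cpt_factor(n, v), ev)
  })
  elim <- setdiff(n$topology$nodes, names(ev))
  for (v in min_fill_order(factors, elim)) factors <- eliminate_var(factors, v)
  res <- Reduce(factor_product, factors)
  for (v in intersect(names(ev), res$scope)) res <- factor_marginalize(res, v)
  sum(res$values)
}

# --- state / evidence resolution helpers --------------------------------

# named states (labels or 0-based integers) -> named 0-based integer vector
resolve_states <- function(net, x) {
  x <- as.list(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("states must be a named vector/list (node = state)")
  }
  out <- stats::setNames(integer(length(x)), names(x))
  for (i in seq_along(x)) {
    v <- names(x)[i]
    if (!v %in% net$topology$nodes) stop("unknown node: ", v)
    out[i] <- resolve_state(net, v, x[[i]])
  }
  out
}

resolve_state <- function(net, node, s) {
  labels <- net$states[[node]]
  if (is.character(s)) {
    pos <- match(s, labels)
    if (is.na(pos)) {
      suppressWarnings(si <- as.integer(s))
      if (!is.na(si)) return(resolve_state(net, node, si))
      stop("unknown state '", s, "' for node ", node)
    }
    return(pos - 1L)
  }
  s <- as.integer(s)
  if (is.na(s) || s < 0L || s >= length(labels)) {
    stop("state ", s, " out of range for node ", node,
         " (0..", length(labels) - 1L, ")")
  }
  s
}

resolve_evidence <- function(net, evidence) {
  if (is.null(evidence) || length(evidence) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  ev <- resolve_states(net, evidence)
  if (anyDuplicated(names(ev))) stop("duplicate evidence node(s)")
  ev
}

as_cbn <- function(x) {
  if (inherits(x, "cbn_fit")) return(x$network)
  stopifnot(inherits(x, "cbn"))
  x
}
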