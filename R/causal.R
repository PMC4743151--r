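#' Interventions on a causal network
#'
#' Three kinds of external intervention are supported, mirroring the query
#' language: fixed-value do-assignments (`do N = v`), edge additions
#' (`+ N M`) and edge removals (`- N M`).
#'
#' @param node,state node and assigned state for a do-assignment.
#' @param from,to edge endpoints for edge interventions.
#' @return an object of class `cbn_intervention`.
#' @name interventions
NULL

#' @rdname interventions
#' @export
do_intervention <- function(node, state) {
  structure(list(kind = "do", node = node, state = state),
            class = "cbn_intervention")
}

#' @rdname interventions
#' @export
add_edge_intervention <- function(from, to) {
  structure(list(kind = "add_edge", from = from, to = to),
            class = "cbn_intervention")
}

#' @rdname interventions
#' @export
remove_edge_intervention <- function(from, to) {
  structure(list(kind = "remove_edge", from = from, to = to),
            class = "cbn_intervention")
}

#' @export
format.cbn_intervention <- function(x, ...) {
  switch(x$kind,
         do = paste("do", x$node, "=", x$state),
         add_edge = paste("+", x$from, x$to),
         remove_edge = paste("-", x$from, x$to))
}

#' @export
print.cbn_intervention <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Apply do-assignments by graph mutilation
#'
#' Every intervened node loses all incoming edges and its CPT becomes a
#' point mass on the assigned state; no other CPT is touched. This is
#' Pearl's graph surgery: downstream of the intervention the network
#' behaves as before, but the intervened nodes no longer listen to their
#' causes — which is what distinguishes `P(T | do(X = x))` from the
#' observational `P(T | X = x)`.
#'
#' @param n a [cbn] network (or fit).
#' @param assignments named vector/list mapping nodes to assigned states
#'   (integer or label).
#' @return the mutilated [cbn].
#' @examples
#' net <- make_sprinkler()
#' posterior_probability(apply_do(net, c(S = 1)), c(W = 1))  # 0.918
#' posterior_probability(net, c(W = 1), evidence = c(S = 1)) # 0.9006
#' @export
apply_do <- function(n, assignments) {
  n <- as_cbn(n)
  asg <- resolve_states(n, assignments)
  if (anyDuplicated(names(asg))) stop("duplicate do-assignment node(s)")
  tp <- n$topology
  keep <- !(tp$edges[, 2L] %in% names(asg))
  n$topology <- cbn_topology(tp$nodes, tp$edges[keep, , drop = FALSE])
  n$parents <- node_parents(n$topology)
  for (v in names(asg)) {
    k <- nstates(n, v)
    vals <- numeric(k)
    vals[asg[[v]] + 1L] <- 1
    n$cpts[[v]] <- array(vals, dim = k,
                         dimnames = stats::setNames(n$states[v], v))
  }
  n
}

#' Add or remove an edge as an intervention
#'
#' Updates the topology and re-estimates the affected child's CPT. When the
#' network retains training data the child's CPT is re-learned over the new
#' parent set from those data (closed-form counts when the family rows are
#' complete, a family-local EM otherwise). Without training data, an added
#' parent starts independent (the old CPT is replicated across its states)
#' and a removed parent is averaged out weighted by its marginal
#' distribution.
#'
#' @param n a [cbn] network (or fit).
#' @param kind `"add"` or `"remove"`.
#' @param from,to edge endpoints.
#' @return the modified [cbn].
#' @export
apply_edge_intervention <- function(n, kind = c("add", "remove"), from, to) {
  n <- as_cbn(n)
  kind <- match.arg(kind)
  for (v in c(from, to)) {
    if (!v %in% n$topology$nodes) stop("unknown node: ", v)
  }
  tp <- n$topology
  present <- any(tp$edges[, 1L] == from & tp$edges[, 2L] == to)
  if (kind == "add") {
    if (present) stop("edge ", from, " -> ", to, " already present")
    if (from == to || is_ancestor(tp, to, from)) {
      stop("adding edge ", from, " -> ", to, " would create a cycle")
    }
    n$topology <- cbn_topology(tp$nodes, rbind(tp$edges, c(from, to)))
  } else {
    if (!present) stop("edge ", from, " -> ", to, " is not present")
    keep <- !(tp$edges[, 1L] == from & tp$edges[, 2L] == to)
    n$topology <- cbn_topology(tp$nodes, tp$edges[keep, , drop = FALSE])
  }
  old_parents <- n$parents[[to]]
  old_cpt <- n$cpts[[to]]
  n$parents <- node_parents(n$topology)
  n$cpts[[to]] <- if (!is.null(n$data)) {
    refit_family(n, to)
  } else if (kind == "add") {
    replicate_cpt(n, to, old_parents, old_cpt)
  } else {
    marginalise_cpt(n, to, old_parents, old_cpt, removed = from,
                    weights = variable_elimination(
                      structure(
                        list(topology = tp, states = n$states,
                             parents = node_parents(tp),
                             cpts = replace(n$cpts, to, list(old_cpt)),
                             data = NULL),
                        class = "cbn"),
                      from)$values)
  }
  n
}

# re-estimate one family's CPT from the retained training data
refit_family <- function(n, child) {
  fam <- c(child, n$parents[[child]])
  d <- n$data[fam, , drop = FALSE]
  sub_tp <- cbn_topology(fam, if (length(fam) > 1L) {
    cbind(fam[-1L], child)
  })
  sub <- cbn(sub_tp, n$states[fam])
  if (anyNA(d)) {
    fit <- em_fit(sub, d, em_config())
    cpt <- fit$network$cpts[[child]]
  } else {
    cpt <- ml_counts(sub, d)$cpts[[child]]
  }
  as_cpt(cpt, n, child)
}

# spread the old CPT unchanged across the states of a newly added parent
replicate_cpt <- function(n, child, old_parents, old_cpt) {
  new <- uniform_cpt(n, child)
  fam_new <- c(child, n$parents[[child]])
  fam_old <- c(child, old_parents)
  card_new <- nstates(n, fam_new)
  card_old <- nstates(n, fam_old)
  idx <- rep(1, prod(card_new))
  for (j in seq_along(fam_old)) {
    pos <- match(fam_old[j], fam_new)
    stride <- if (j == 1L) 1 else prod(card_old[seq_len(j - 1L)])
    idx <- idx + cell_states(card_new, pos) * stride
  }
  new[] <- as.vector(old_cpt)[idx]
  new
}

# average the old CPT over a removed parent, weighted by its marginal
marginalise_cpt <- function(n, child, old_parents, old_cpt, removed,
                            weights) {
  new <- uniform_cpt(n, child)
  fam_new <- c(child, n$parents[[child]])
  fam_old <- c(child, old_parents)
  card_new <- nstates(n, fam_new)
  card_old <- nstates(n, fam_old)
  vals <- numeric(prod(card_new))
  kr <- nstates(n, removed)
  rpos <- match(removed, fam_old)
  for (s in seq_len(kr)) {
    idx <- rep(1, prod(card_new))
    for (j in seq_along(fam_old)) {
      stride <- if (j == 1L) 1 else prod(card_old[seq_len(j - 1L)])
      sv <- if (j == rpos) {
        rep(s - 1L, prod(card_new))
      } else {
        cell_states(card_new, match(fam_old[j], fam_new))
      }
      idx <- idx + sv * stride
    }
    vals <- vals + weights[s] * as.vector(old_cpt)[idx]
  }
  new[] <- vals
  new
}

# apply a list of cbn_intervention objects in order
apply_interventions <- function(n, interventions) {
  n <- as_cbn(n)
  if (inherits(interventions, "cbn_intervention")) {
    interventions <- list(interventions)
  }
  dos <- list()
  for (iv in interventions) {
    stopifnot(inherits(iv, "cbn_intervention"))
    if (iv$kind == "do") {
      if (iv$node %in% names(dos)) {
        stop("node ", iv$node, " appears in more than one do-assignment")
      }
      dos[[iv$node]] <- iv$state
    } else {
      n <- apply_edge_intervention(n,
                                   if (iv$kind == "add_edge") "add" else
                                     "remove",
                                   iv$from, iv$to)
    }
  }
  if (length(dos)) n <- apply_do(n, dos)
  n
}

#' Build the twin network for a counterfactual query
#'
#' Pearl's twin-network construction: nodes unaffected by the
#' interventions are shared between the factual and the counterfactual
#' world, while every intervened node and each of its descendants (in the
#' post-intervention graph) gets a counterfactual copy. A copy's parents
#' are the counterfactual counterparts of its post-intervention parents
#' (or the shared originals), its CPT is the post-intervention CPT, and
#' the interventions themselves apply only to the copies.
#'
#' Because the model stores CPTs rather than structural equations with
#' explicit exogenous noise, each copied node's stochastic mechanism is
#' redrawn independently in the counterfactual world; only the shared
#' (non-descendant) nodes couple the two worlds. See the package vignette
#' for the semantic consequences of this choice.
#'
#' @param n a [cbn] network (or fit).
#' @param interventions list of [interventions] objects.
#' @return list of class `cbn_twin` with `network` (the combined [cbn])
#'   and `map`, a named character vector sending each original node to the
#'   name of its counterfactual counterpart (itself when shared).
#' @export
build_twin_network <- function(n, interventions) {
  n <- as_cbn(n)
  if (inherits(interventions, "cbn_intervention")) {
    interventions <- list(interventions)
  }
  n2 <- apply_interventions(n, interventions)
  changed <- unique(unlist(lapply(interventions, function(iv) {
    if (iv$kind == "do") iv$node else iv$to
  })))
  affected <- unique(c(changed,
                       unlist(lapply(changed, descendants, t = n2$topology))))
  affected <- intersect(n$topology$nodes, affected)
  suffix <- "_cf"
  while (any(paste0(affected, suffix) %in% n$topology$nodes)) {
    suffix <- paste0(suffix, "_")
  }
  map <- stats::setNames(n$topology$nodes, n$topology$nodes)
  map[affected] <- paste0(affected, suffix)
  nodes <- c(n$topology$nodes, unname(map[affected]))
  edges <- n$topology$edges
  cpts <- n$cpts
  states <- n$states
  for (a in affected) {
    for (p in n2$parents[[a]]) {
      edges <- rbind(edges, c(map[[p]], map[[a]]))
    }
    cpt <- n2$cpts[[a]]
    vars <- names(dimnames(cpt))
    names(dimnames(cpt)) <- unname(map[vars])
    for (j in seq_along(vars)) {
      dimnames(cpt)[[j]] <- n2$states[[vars[j]]]
    }
    cpts[[map[[a]]]] <- cpt
    states[[map[[a]]]] <- n2$states[[a]]
  }
  tw <- cbn(cbn_topology(nodes, edges), states, cpts)
  structure(list(network = tw, map = map), class = "cbn_twin")
}

#' Evaluate a counterfactual query
#'
#' Conditions on factual evidence in the observed world while evaluating
#' the targets in the intervened world of the twin network: "given that we
#' observed E, what would T have been under do(X = x)?". With no
#' interventions this reduces to an ordinary conditional query; with no
#' evidence it reduces to an interventional query on the mutilated
#' network.
#'
#' @param n a [cbn] network (or fit).
#' @param targets character vector of query nodes (original names).
#' @param factual_evidence named states observed in the factual world.
#' @param interventions list of [interventions] objects.
#' @return a [cbn_factor] over `targets` (original names), normalised.
#' @export
counterfactual_query <- function(n, targets, factual_evidence = NULL,
                                 interventions = list()) {
  n <- as_cbn(n)
  if (inherits(interventions, "cbn_intervention")) {
    interventions <- list(interventions)
  }
  if (!length(interventions)) {
    return(variable_elimination(n, targets, factual_evidence))
  }
  tw <- build_twin_network(n, interventions)
  ev <- resolve_evidence(n, factual_evidence)
  res <- variable_elimination(tw$network, unname(tw$map[targets]), ev)
  res$scope <- targets
  names(res$card) <- targets
  res
}
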