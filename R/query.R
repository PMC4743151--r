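#' Parse a query-language string
#'
#' The query language mirrors printed causal questions. Every query starts
#' with `?` and a list of targets — fixed assignments (`N = v`) or
#' `argmax(N)` terms. Evidence follows `|`, interventions follow `!`:
#' \preformatted{query  := "?" target {target} ["|" evid {evid}] ["!" ivn {ivn}]
#' target := NODE "=" STATE | "argmax" "(" NODE ")"
#' evid   := NODE "=" STATE
#' ivn    := "do" NODE "=" STATE | "+" NODE NODE | "-" NODE NODE}
#' `STATE` is an integer state index or a display label. Examples:
#' `"? argmax(AKT) ! do ERK = 2"`, `"? argmax(PKA) | ERK = 0"`.
#'
#' @param text a single query string.
#' @return an object of class `cbn_query` with `targets`, `evidence` and
#'   `interventions`; `format()` un-parses it back to the surface syntax.
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- query_tokens(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  expect <- function(what) {
    t <- advance()
    if (is.na(t) || t != what) {
      stop("query syntax error at token ", pos - 1L, ": expected '", what,
           "', got ", if (is.na(t)) "end of query" else paste0("'", t, "'"))
    }
    t
  }
  name_tok <- function(role) {
    t <- advance()
    if (is.na(t) || t %in% c("?", "|", "!", "=", "(", ")", "+", "-", "do")) {
      stop("query syntax error at token ", pos - 1L, ": expected a ", role,
           ", got ", if (is.na(t)) "end of query" else paste0("'", t, "'"))
    }
    t
  }
  expect("?")
  targets <- list()
  repeat {
    t <- peek()
    if (is.na(t) || t %in% c("|", "!")) break
    if (t == "argmax") {
      advance(); expect("(")
      node <- name_tok("node name")
      expect(")")
      targets[[length(targets) + 1L]] <- list(kind = "argmax", node = node)
    } else {
      node <- name_tok("node name")
      expect("=")
      state <- name_tok("state")
      targets[[length(targets) + 1L]] <- list(kind = "assign", node = node,
                                              state = state)
    }
  }
  if (!length(targets)) stop("query has no targets (nothing after '?')")
  evidence <- list()
  if (!is.na(peek()) && peek() == "|") {
    advance()
    repeat {
      t <- peek()
      if (is.na(t) || t == "!") break
      node <- name_tok("node name")
      expect("=")
      evidence[[length(evidence) + 1L]] <- list(node = node,
                                                state = name_tok("state"))
    }
    if (!length(evidence)) stop("'|' must be followed by evidence")
  }
  interventions <- list()
  if (!is.na(peek()) && peek() == "!") {
    advance()
    repeat {
      t <- peek()
      if (is.na(t)) break
      if (t == "do") {
        advance()
        node <- name_tok("node name")
        expect("=")
        interventions[[length(interventions) + 1L]] <-
          do_intervention(node, name_tok("state"))
      } else if (t == "+") {
        advance()
        interventions[[length(interventions) + 1L]] <-
          add_edge_intervention(name_tok("node name"), name_tok("node name"))
      } else if (t == "-") {
        advance()
        interventions[[length(interventions) + 1L]] <-
          remove_edge_intervention(name_tok("node name"),
                                   name_tok("node name"))
      } else {
        stop("query syntax error at token ", pos,
             ": expected 'do', '+' or '-', got '", t, "'")
      }
    }
    if (!length(interventions)) stop("'!' must be followed by interventions")
  }
  if (!is.na(peek())) {
    stop("query syntax error at token ", pos, ": unexpected '", peek(), "'")
  }
  ev_nodes <- vapply(evidence, `[[`, character(1), "node")
  if (anyDuplicated(ev_nodes)) {
    stop("evidence node(s) listed twice: ",
         paste(unique(ev_nodes[duplicated(ev_nodes)]), collapse = ", "))
  }
  do_nodes <- unlist(lapply(interventions,
                            function(iv) if (iv$kind == "do") iv$node))
  if (anyDuplicated(do_nodes)) {
    stop("node(s) with more than one do-assignment: ",
         paste(unique(do_nodes[duplicated(do_nodes)]), collapse = ", "))
  }
  structure(list(targets = targets, evidence = evidence,
                 interventions = interventions),
            class = "cbn_query")
}

query_tokens <- function(text) {
  spaced <- gsub("([?|!()=+-])", " \\1 ", text)
  toks <- strsplit(trimws(spaced), "[ \t]+")[[1]]
  toks[nzchar(toks)]
}

#' @export
format.cbn_query <- function(x, ...) {
  tg <- vapply(x$targets, function(t) {
    if (t$kind == "argmax") paste0("argmax(", t$node, ")")
    else paste(t$node, "=", t$state)
  }, character(1))
  out <- paste("?", paste(tg, collapse = " "))
  if (length(x$evidence)) {
    ev <- vapply(x$evidence, function(e) paste(e$node, "=", e$state),
                 character(1))
    out <- paste(out, "|", paste(ev, collapse = " "))
  }
  if (length(x$interventions)) {
    iv <- vapply(x$interventions, format, character(1))
    out <- paste(out, "!", paste(iv, collapse = " "))
  }
  out
}

#' @export
print.cbn_query <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Validate a query against a network
#'
#' Reporting operation: collects unknown nodes, out-of-range states,
#' cycle-creating edge additions, additions of present edges and removals
#' of absent edges. An empty report means the query is evaluable.
#'
#' @param q a [cbn_query] (or query string).
#' @param n a [cbn] network (or fit).
#' @return character vector of problems; empty iff valid.
#' @export
validate_query <- function(q, n) {
  if (is.character(q)) q <- parse_query(q)
  n <- as_cbn(n)
  nodes <- n$topology$nodes
  bad <- character(0)
  chk_state <- function(node, state, where) {
    if (!node %in% nodes) {
      bad <<- c(bad, paste0("unknown node ", node, " in ", where))
      return()
    }
    ok <- tryCatch({
      resolve_state(n, node, state)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      bad <<- c(bad, paste0("state ", state, " out of range for node ",
                            node, " in ", where))
    }
  }
  for (t in q$targets) {
    if (t$kind == "argmax") {
      if (!t$node %in% nodes) bad <- c(bad, paste0("unknown node ", t$node,
                                                   " in target"))
    } else {
      chk_state(t$node, t$state, "target")
    }
  }
  for (e in q$evidence) chk_state(e$node, e$state, "evidence")
  tp <- n$topology
  for (iv in q$interventions) {
    if (iv$kind == "do") {
      chk_state(iv$node, iv$state, "intervention")
      next
    }
    ends <- c(iv$from, iv$to)
    unknown <- setdiff(ends, nodes)
    if (length(unknown)) {
      bad <- c(bad, paste0("unknown node ", unknown, " in edge intervention"))
      next
    }
    present <- any(tp$edges[, 1L] == iv$from & tp$edges[, 2L] == iv$to)
    if (iv$kind == "add_edge") {
      if (present) {
        bad <- c(bad, paste0("edge ", iv$from, " -> ", iv$to,
                             " already present"))
      } else if (iv$from == iv$to || is_ancestor(tp, iv$to, iv$from)) {
        bad <- c(bad, paste0("adding edge ", iv$from, " -> ", iv$to,
                             " would create a cycle"))
      } else {
        tp <- cbn_topology(tp$nodes, rbind(tp$edges, c(iv$from, iv$to)))
      }
    } else {
      if (!present) {
        bad <- c(bad, paste0("edge ", iv$from, " -> ", iv$to,
                             " is not present"))
      } else {
        keep <- !(tp$edges[, 1L] == iv$from & tp$edges[, 2L] == iv$to)
        tp <- cbn_topology(tp$nodes, tp$edges[keep, , drop = FALSE])
      }
    }
  }
  bad
}

#' Evaluate a query on a network
#'
#' Dispatch follows the query's shape: interventions alone are evaluated
#' on the mutilated/modified network; evidence alone (or neither) by plain
#' posterior inference; a query that both conditions and intervenes is a
#' counterfactual and is evaluated on the twin network (use
#' `worlds = "single"` to instead condition and intervene in one world,
#' i.e. `P(T | Z = z, do(X = x))`).
#'
#' @param q a [cbn_query] or query string.
#' @param n a [cbn] network (or fit).
#' @param worlds `"twin"` (default) or `"single"`; only relevant when the
#'   query has both evidence and interventions.
#' @return object of class `cbn_query_result`: `query` (normalised
#'   string), `argmax` (data frame `node`, `state`, `label`,
#'   `probability`; one row per argmax target) and, when the query has
#'   assignment targets, `assignments` plus their `joint_probability`.
#' @export
evaluate_query <- function(q, n, worlds = c("twin", "single")) {
  if (is.character(q)) q <- parse_query(q)
  stopifnot(inherits(q, "cbn_query"))
  n <- as_cbn(n)
  worlds <- match.arg(worlds)
  bad <- validate_query(q, n)
  if (length(bad)) stop("invalid query: ", paste(bad, collapse = "; "))
  ev <- if (length(q$evidence)) {
    stats::setNames(lapply(q$evidence, `[[`, "state"),
                    vapply(q$evidence, `[[`, character(1), "node"))
  }
  counterfactual <- length(q$interventions) && length(q$evidence) &&
    worlds == "twin"
  if (counterfactual) {
    # resolve do-states against the original network before mutilation
    ivs <- lapply(q$interventions, function(iv) {
      if (iv$kind == "do") iv$state <- resolve_state(n, iv$node, iv$state)
      iv
    })
    tw <- build_twin_network(n, ivs)
    net_eval <- tw$network
    map <- tw$map
    ev_eval <- ev
  } else {
    net_eval <- if (length(q$interventions)) {
      ivs <- lapply(q$interventions, function(iv) {
        if (iv$kind == "do") iv$state <- resolve_state(n, iv$node, iv$state)
        iv
      })
      apply_interventions(n, ivs)
    } else {
      n
    }
    map <- stats::setNames(n$topology$nodes, n$topology$nodes)
    ev_eval <- ev
  }
  am <- NULL
  for (t in q$targets) {
    if (t$kind != "argmax") next
    r <- argmax_posterior(net_eval, unname(map[t$node]), ev_eval)
    am <- rbind(am, data.frame(node = t$node, state = r$state,
                               label = r$label, probability = r$probability,
                               stringsAsFactors = FALSE))
  }
  assign_t <- Filter(function(t) t$kind == "assign", q$targets)
  joint <- NULL
  assignments <- NULL
  if (length(assign_t)) {
    assignments <- stats::setNames(
      vapply(assign_t, function(t) resolve_state(n, t$node, t$state),
             integer(1)),
      vapply(assign_t, `[[`, character(1), "node"))
    tg <- stats::setNames(as.list(assignments),
                          unname(map[names(assignments)]))
    joint <- posterior_probability(net_eval, tg, ev_eval)
  }
  structure(list(query = format(q), argmax = am, assignments = assignments,
                 joint_probability = joint),
            class = "cbn_query_result")
}

#' @export
format.cbn_query_result <- function(x, precision = 3L, ...) {
  res <- character(0); prob <- character(0)
  if (!is.null(x$argmax)) {
    res <- c(res, as.character(x$argmax$state))
    prob <- c(prob, sprintf(paste0("%.", precision, "f"),
                            x$argmax$probability))
  }
  if (!is.null(x$joint_probability)) {
    res <- c(res, paste(paste(names(x$assignments), "=", x$assignments),
                        collapse = " "))
    prob <- c(prob, sprintf(paste0("%.", precision, "f"),
                            x$joint_probability))
  }
  paste(x$query, paste(res, collapse = " "), paste(prob, collapse = " "),
        sep = "\t")
}

#' @export
print.cbn_query_result <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}
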