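#' Fit a causal Bayesian network to observations
#'
#' User-facing front end of the parameter-learning machinery. Takes a
#' topology (or a pre-built [cbn]) together with observations, discretises
#' continuous data when a specification is supplied, and estimates every
#' CPT — by [em_fit()] when entries are missing (the default), or by the
#' closed-form [ml_counts()] when `method = "ml"` and the data are
#' complete.
#'
#' @param n a [cbn_topology] or a [cbn]. For a bare topology the state
#'   spaces are taken from the discretised data.
#' @param data numeric matrix, variables x samples (`NA` = missing). Raw
#'   continuous values are allowed when `spec` is given.
#' @param spec optional discretisation specification
#'   ([read_discretisation_spec()]) or single method name applied to every
#'   variable.
#' @param method `"em"` (default; handles missing data) or `"ml"`
#'   (complete data only).
#' @param config an [em_config()].
#' @param ... passed to [discretise_matrix()] for a single-method `spec`.
#' @return an object of class `cbn_fit` with `print`, `summary`, `coef`,
#'   `logLik`, `simulate` and `predict` methods.
#' @examples
#' net <- make_sprinkler()
#' d <- forward_sample(net, 500, seed = 7)
#' fit <- fit_cbn(net, d)
#' coef(fit)$R
#' predict(fit, "R", evidence = c(W = 1))
#' @export
fit_cbn <- function(n, data, spec = NULL, method = c("em", "ml"),
                    config = em_config(), ...) {
  method <- match.arg(method)
  if (!is.null(spec)) data <- discretise_matrix(data, spec, ...)
  if (inherits(n, "cbn_topology")) {
    ns <- attr(data, "nstates")
    if (is.null(ns)) {
      ns <- apply(data[n$nodes, , drop = FALSE], 1, max, na.rm = TRUE) + 1L
      ns <- pmax(as.integer(ns), 2L)
      names(ns) <- n$nodes
    }
    n <- cbn(n, ns)
  }
  n <- as_cbn(n)
  if (method == "ml") {
    net <- ml_counts(n, data, pseudo_count = config$pseudo_count)
    ll <- log_likelihood(net, data)
    return(structure(list(network = net, logLik = ll,
                          restarts = data.frame(restart = 1L,
                                                scheme = "ml",
                                                iterations = 1L,
                                                logLik = ll),
                          winner = 1L, trace = list(ll),
                          nobs = ncol(data), config = config),
                     class = "cbn_fit"))
  }
  em_fit(n, data, config)
}

#' @export
print.cbn_fit <- function(x, ...) {
  cat("Fitted causal Bayesian network (",
      length(x$network$topology$nodes), " nodes, ",
      nrow(x$network$topology$edges), " edges)\n", sep = "")
  cat("  samples:", x$nobs, "  log-likelihood:",
      format(x$logLik, digits = 7), "\n")
  w <- x$restarts[x$winner, ]
  cat("  winning restart: ", w$restart, " (", w$scheme, ", ",
      w$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' @export
summary.cbn_fit <- function(object, ...) {
  structure(list(fit = object,
                 violations = validate_network(object$network),
                 parameters = write_parameters(object$network)),
            class = "summary.cbn_fit")
}

#' @export
print.summary.cbn_fit <- function(x, ...) {
  print(x$fit)
  cat("\nRestarts:\n")
  print(x$fit$restarts, row.names = FALSE)
  if (length(x$violations)) {
    cat("\nValidation problems:\n ",
        paste(x$violations, collapse = "\n  "), "\n")
  }
  cat("\nParameters:\n")
  cat(x$parameters)
  invisible(x)
}

#' @export
coef.cbn_fit <- function(object, ...) object$network$cpts

#' @export
logLik.cbn_fit <- function(object, ...) {
  net <- object$network
  df <- sum(vapply(net$topology$nodes, function(v) {
    d <- dim(net$cpts[[v]])
    (d[1L] - 1L) * prod(d[-1L])
  }, numeric(1)))
  structure(object$logLik, df = df, nobs = object$nobs, class = "logLik")
}

#' @export
simulate.cbn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  forward_sample(object$network, nsim, seed = if (is.null(seed)) 1L else seed)
}

#' Posterior predictions from a fitted network
#'
#' @param object a `cbn_fit`.
#' @param targets character vector of query nodes (ignored when `query` is
#'   given).
#' @param evidence named states to condition on.
#' @param query optional query-language string (see [parse_query()]);
#'   evaluated with [evaluate_query()].
#' @param type `"distribution"` returns the joint posterior factor over
#'   `targets`; `"argmax"` the most likely state of a single target.
#' @param ... unused.
#' @export
predict.cbn_fit <- function(object, targets = NULL, evidence = NULL,
                            query = NULL,
                            type = c("distribution", "argmax"), ...) {
  if (!is.null(query)) return(evaluate_query(query, object))
  type <- match.arg(type)
  if (is.null(targets)) stop("supply targets or a query string")
  if (type == "argmax") {
    return(argmax_posterior(object, targets, evidence))
  }
  variable_elimination(object, targets, evidence)
}
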