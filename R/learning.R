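#' Maximum-likelihood CPT estimation from complete data
#'
#' Closed-form frequency estimation: every CPT cell becomes
#' `#(child = v, parents = config) / #(parents = config)`. Parent
#' configurations never observed get the uniform distribution over the
#' child's states. An optional Laplace pseudo-count is added to every cell
#' before normalising (default 0: pure frequencies).
#'
#' @param n a [cbn] network.
#' @param d discretised data matrix (variables x samples, no missing
#'   entries) covering every node of `n`.
#' @param pseudo_count nonnegative Laplace smoothing constant.
#' @return a [cbn] with re-estimated CPTs; `d` is retained as training
#'   data.
#' @export
ml_counts <- function(n, d, pseudo_count = 0) {
  n <- as_cbn(n)
  d <- check_discrete_data(d, n)
  if (anyNA(d[n$topology$nodes, , drop = FALSE])) {
    stop("ml_counts requires complete data; use fit_cbn/em_fit for ",
         "missing entries")
  }
  for (v in n$topology$nodes) {
    counts <- family_counts_complete(n, v, d)
    n$cpts[[v]][] <- normalise_counts(counts, dim(n$cpts[[v]])[1L],
                                      pseudo_count)
  }
  n$data <- d
  n
}

family_counts_complete <- function(n, v, d) {
  fam <- c(v, n$parents[[v]])
  k <- nstates(n, fam)
  idx <- rep(1, ncol(d))
  stride <- 1
  for (j in seq_along(fam)) {
    idx <- idx + d[fam[j], ] * stride
    stride <- stride * k[j]
  }
  tabulate(idx, nbins = prod(k))
}

# counts vector (child state fastest) -> normalised CPT values;
# zero-mass configurations become uniform
normalise_counts <- function(counts, k, pseudo_count = 0) {
  m <- matrix(counts + pseudo_count, nrow = k)
  tot <- colSums(m)
  zero <- tot == 0
  m[, zero] <- 1 / k
  m[, !zero] <- sweep(m[, !zero, drop = FALSE], 2, tot[!zero], "/")
  as.vector(m)
}

#' Log-likelihood of (possibly incomplete) data under a network
#'
#' Sum over samples of `log P(observed entries)`, with each sample's
#' missing entries marginalised out exactly by variable elimination. A
#' fully missing sample contributes `log 1 = 0`. Returns `-Inf` when any
#' sample's observed pattern has probability zero.
#'
#' @param n a [cbn] network (or fit).
#' @param d discretised data matrix with `NA` for missing entries.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(n, d) {
  n <- as_cbn(n)
  d <- check_discrete_data(d, n)
  pat <- data_patterns(n, d)
  pattern_loglik(n, pat)
}

# group identical sample columns (values + missingness) so inference runs
# once per distinct pattern
data_patterns <- function(n, d) {
  nodes <- n$topology$nodes
  d <- d[nodes, , drop = FALSE]
  key <- apply(d, 2, paste, collapse = "\r")
  tab <- table(key)
  cols <- match(names(tab), key)
  list(states = d[, cols, drop = FALSE], weight = as.numeric(tab),
       nodes = nodes)
}

pattern_loglik <- function(n, pat) {
  ll <- 0
  for (j in seq_along(pat$weight)) {
    x <- stats::setNames(pat$states[, j], pat$nodes)
    obs <- x[!is.na(x)]
    p <- if (length(obs)) prob_evidence(n, obs) else 1
    if (p <= 0) return(-Inf)
    ll <- ll + pat$weight[j] * log(p)
  }
  ll
}

#' EM configuration
#'
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence tolerance on the absolute change of the
#'   log-likelihood between iterations.
#' @param restarts number of restarts (>= 1); restart `r` uses
#'   `schemes[(r - 1) %% length(schemes) + 1]`.
#' @param schemes ordered initialisation schemes, from
#'   `"uniform"`, `"random"`, `"complete_case"`.
#' @param seed integer seed driving the random initialisations.
#' @param pseudo_count Laplace pseudo-count used in every M-step
#'   (default 0).
#' @return list of class `cbn_em_config`.
#' @export
em_config <- function(max_iter = 100L, tol = 1e-6, restarts = 3L,
                      schemes = c("uniform", "random", "complete_case"),
                      seed = 1L, pseudo_count = 0) {
  stopifnot(tol > 0, restarts >= 1, max_iter >= 1, pseudo_count >= 0)
  schemes <- match.arg(schemes, c("uniform", "random", "complete_case"),
                       several.ok = TRUE)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 restarts = as.integer(restarts), schemes = schemes,
                 seed = as.integer(seed), pseudo_count = pseudo_count),
            class = "cbn_em_config")
}

#' Initialise CPTs for an EM restart
#'
#' Schemes: `uniform` sets every CPT row uniform; `random` draws every row
#' from a flat Dirichlet (reproducible under `seed`); `complete_case`
#' applies [ml_counts()] to the subset of samples without any missing
#' entry (uniform fallback when there is none).
#'
#' @param n a [cbn] network.
#' @param scheme one of `"uniform"`, `"random"`, `"complete_case"`.
#' @param seed integer seed (used by `"random"`).
#' @param data discretised data matrix (used by `"complete_case"`).
#' @return a [cbn] with initialised CPTs.
#' @export
init_cpts <- function(n, scheme, seed = 1L, data = NULL) {
  n <- as_cbn(n)
  scheme <- match.arg(scheme, c("uniform", "random", "complete_case"))
  if (scheme == "uniform") {
    for (v in n$topology$nodes) n$cpts[[v]] <- uniform_cpt(n, v)
  } else if (scheme == "random") {
    local_seed(seed, {
      for (v in n$topology$nodes) {
        d <- dim(n$cpts[[v]])
        g <- matrix(stats::rgamma(prod(d), shape = 1), nrow = d[1L])
        n$cpts[[v]][] <- as.vector(sweep(g, 2, colSums(g), "/"))
      }
    })
  } else {
    if (is.null(data)) stop("complete_case initialisation requires data")
    nodes <- n$topology$nodes
    complete <- !colSums(is.na(data[nodes, , drop = FALSE]))
    if (any(complete)) {
      fit <- ml_counts(n, data[, complete, drop = FALSE])
      n$cpts <- fit$cpts
    } else {
      for (v in nodes) n$cpts[[v]] <- uniform_cpt(n, v)
    }
  }
  n
}

#' Fit CPTs by expectation-maximisation with restarts
#'
#' Learns the network parameters from discretised data that may contain
#' missing entries. Each restart initialises the CPTs by its scheme and
#' alternates an E-step (expected family counts: for every sample, the
#' exact posterior of each family's missing members given the sample's
#' observed entries, computed by variable elimination) with an M-step
#' (normalised expected counts; zero-mass parent configurations become
#' uniform) until the absolute log-likelihood change falls below `tol` or
#' `max_iter` is reached. The restart with the highest final
#' log-likelihood wins. Within every restart the log-likelihood is
#' non-decreasing across iterations — the EM guarantee, asserted in the
#' test-suite. With complete data the first iteration already lands on the
#' closed-form [ml_counts()] estimate for every scheme.
#'
#' Identical sample columns are grouped, so the E-step cost scales with
#' the number of distinct observation patterns rather than the sample
#' count.
#'
#' @param n a [cbn] network.
#' @param d discretised data matrix with `NA` for missing entries.
#' @param config an [em_config()].
#' @return object of class `cbn_fit`: list with `network` (fitted [cbn]
#'   retaining `d` as training data), `logLik`, `restarts` (data frame of
#'   per-restart scheme, iterations and final log-likelihood), `winner`
#'   (index of the winning restart), and `trace` (per-restart
#'   log-likelihood sequences).
#' @seealso [fit_cbn()] for the user-facing front end.
#' @export
em_fit <- function(n, d, config = em_config()) {
  n <- as_cbn(n)
  stopifnot(inherits(config, "cbn_em_config"))
  d <- check_discrete_data(d, n)
  if (ncol(d) == 0L) stop("empty data: no samples")
  pat <- data_patterns(n, d)
  best <- NULL
  rows <- NULL
  traces <- list()
  for (r in seq_len(config$restarts)) {
    scheme <- config$schemes[(r - 1L) %% length(config$schemes) + 1L]
    cur <- init_cpts(n, scheme, seed = config$seed + r - 1L, data = d)
    trace <- pattern_loglik(cur, pat)
    iters <- 0L
    if (is.finite(trace[1L])) {
      for (it in seq_len(config$max_iter)) {
        cur <- em_step(cur, pat, config$pseudo_count)
        ll <- pattern_loglik(cur, pat)
        trace <- c(trace, ll)
        iters <- it
        if (!is.finite(ll) || abs(ll - trace[length(trace) - 1L]) <
              config$tol) break
      }
    }
    final <- trace[length(trace)]
    rows <- rbind(rows, data.frame(restart = r, scheme = scheme,
                                   iterations = iters, logLik = final))
    traces[[r]] <- trace
    if (is.null(best) || final > best$logLik) {
      best <- list(network = cur, logLik = final, winner = r)
    }
  }
  best$network$data <- d
  structure(list(network = best$network, logLik = best$logLik,
                 restarts = rows, winner = best$winner, trace = traces,
                 nobs = ncol(d), config = config),
            class = "cbn_fit")
}

# one E+M sweep over the grouped patterns
em_step <- function(n, pat, pseudo_count = 0) {
  nodes <- pat$nodes
  counts <- lapply(nodes, function(v) numeric(prod(cpt_dim(n, v))))
  names(counts) <- nodes
  for (j in seq_along(pat$weight)) {
    x <- stats::setNames(pat$states[, j], pat$nodes)
    w <- pat$weight[j]
    obs <- x[!is.na(x)]
    for (v in nodes) {
      fam <- c(v, n$parents[[v]])
      k <- nstates(n, fam)
      mis <- fam[is.na(x[fam])]
      if (!length(mis)) {
        idx <- 1 + sum(x[fam] * c(1, cumprod(k))[seq_along(fam)])
        counts[[v]][idx] <- counts[[v]][idx] + w
      } else {
        post <- variable_elimination(n, mis, obs)
        m <- length(post$values)
        idx <- rep(1, m)
        for (fj in seq_along(fam)) {
          stride <- c(1, cumprod(k))[fj]
          var <- fam[fj]
          sv <- if (var %in% mis) {
            cell_states(post$card, match(var, post$scope))
          } else {
            rep(x[var], m)
          }
          idx <- idx + sv * stride
        }
        counts[[v]][idx] <- counts[[v]][idx] + w * post$values
      }
    }
  }
  for (v in nodes) {
    n$cpts[[v]][] <- normalise_counts(counts[[v]], dim(n$cpts[[v]])[1L],
                                      pseudo_count)
  }
  n
}

# run `expr` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
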