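#' The sprinkler fixture network
#'
#' The canonical three-node teaching network — Rain, Sprinkler, Wet grass —
#' with fixed literal CPTs, used throughout the test-suite because every
#' posterior can be checked by brute-force enumeration over its eight
#' joint states: `P(R=1) = 0.2`; `P(S=1|R=0) = 0.4`, `P(S=1|R=1) = 0.01`;
#' `P(W=1|S=0,R=0) = 0`, `P(W=1|S=0,R=1) = 0.8`, `P(W=1|S=1,R=0) = 0.9`,
#' `P(W=1|S=1,R=1) = 0.99`.
#'
#' @return a valid [cbn] with nodes `R`, `S`, `W`.
#' @export
make_sprinkler <- function() {
  tp <- cbn_topology(c("R", "S", "W"),
                     rbind(c("R", "S"), c("R", "W"), c("S", "W")))
  cpts <- list(
    R = c(0.8, 0.2),
    # dims (S, R): columns are R = 0, 1
    S = array(c(0.6, 0.4, 0.99, 0.01), dim = c(2, 2),
              dimnames = list(S = c("0", "1"), R = c("0", "1"))),
    # dims (W, R, S) in canonical parent order
    W = array(c(1, 0,        # R=0, S=0
                0.2, 0.8,    # R=1, S=0
                0.1, 0.9,    # R=0, S=1
                0.01, 0.99), # R=1, S=1
              dim = c(2, 2, 2),
              dimnames = list(W = c("0", "1"), R = c("0", "1"),
                              S = c("0", "1"))))
  cbn(tp, c(R = 2L, S = 2L, W = 2L), cpts)
}

#' Forward (ancestral) sampling from a network
#'
#' Draws samples in topological order, each node from its CPT row given
#' the already-sampled parent states. Reproducible under `seed`.
#'
#' @param n a [cbn] network (or fit).
#' @param count number of samples (0 gives an empty matrix with the right
#'   variable rows).
#' @param seed integer seed.
#' @return integer matrix, variables x samples, with attribute `nstates`.
#' @export
forward_sample <- function(n, count, seed = 1L) {
  n <- as_cbn(n)
  count <- as.integer(count)
  stopifnot(count >= 0)
  nodes <- n$topology$nodes
  out <- matrix(NA_integer_, nrow = length(nodes), ncol = count,
                dimnames = list(nodes,
                                if (count) paste0("s", seq_len(count))))
  if (count) {
    local_seed(seed, {
      for (v in topological_order(n$topology)) {
        ps <- n$parents[[v]]
        k <- nstates(n, v)
        m <- matrix(n$cpts[[v]], nrow = k)
        cfg <- rep(1L, count)
        if (length(ps)) {
          kp <- nstates(n, ps)
          stride <- c(1, cumprod(kp))
          for (j in seq_along(ps)) {
            cfg <- cfg + out[ps[j], ] * stride[j]
          }
        }
        draws <- integer(count)
        for (cj in unique(cfg)) {
          idx <- which(cfg == cj)
          draws[idx] <- sample.int(k, length(idx), replace = TRUE,
                                   prob = m[, cj]) - 1L
        }
        out[v, ] <- draws
      }
    })
  }
  attr(out, "nstates") <- nstates(n)
  out
}

#' Inject missing-completely-at-random entries
#'
#' Each cell is independently replaced by `NA` with probability `rate`
#' (MCAR). Reproducible under `seed`.
#'
#' @param d data matrix.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the matrix with injected `NA`s.
#' @export
inject_missing <- function(d, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)")
  }
  if (rate == 0) return(d)
  local_seed(seed, {
    mask <- matrix(stats::runif(length(d)) < rate, nrow = nrow(d))
    d[mask] <- NA
  })
  d
}

#' Continuous observations with per-state Gaussian emission
#'
#' Forward-samples discrete states, then emits for every cell a normal
#' draw centred on that state's mean — a simple generative stand-in for
#' continuous measurements (e.g. phosphorylation levels) whose
#' discretisation should recover the underlying states. It does not
#' emulate heavy tails, batch effects or state-dependent variance of real
#' assays.
#'
#' @param n a [cbn] network (or fit).
#' @param count number of samples.
#' @param seed integer seed.
#' @param state_means named list: per variable, a strictly increasing
#'   numeric vector with one mean per state.
#' @param state_sd emission standard deviation (common to all states;
#'   `0` makes discretisation exactly invertible with thresholds between
#'   the means).
#' @return list with `raw` (numeric matrix, variables x samples) and
#'   `states` (the generating discrete matrix).
#' @export
sample_continuous <- function(n, count, seed = 1L, state_means,
                              state_sd = 0.25) {
  n <- as_cbn(n)
  k <- nstates(n)
  for (v in n$topology$nodes) {
    mu <- state_means[[v]]
    if (is.null(mu) || length(mu) != k[[v]]) {
      stop("state_means must supply one mean per state for node ", v)
    }
    if (any(diff(mu) <= 0)) {
      stop("state means for node ", v, " must be strictly increasing")
    }
  }
  states <- forward_sample(n, count, seed = seed)
  raw <- matrix(NA_real_, nrow = nrow(states), ncol = ncol(states),
                dimnames = dimnames(states))
  if (count) {
    local_seed(seed + 1L, {
      for (v in n$topology$nodes) {
        mu <- state_means[[v]][states[v, ] + 1L]
        raw[v, ] <- stats::rnorm(count, mean = mu, sd = state_sd)
      }
    })
  }
  list(raw = raw, states = states)
}

#' Random network fixture
#'
#' Draws a random DAG (edges only from earlier to later in a shuffled
#' node order) with random state counts and flat-Dirichlet CPT rows.
#' Used by the property tests that compare variable elimination with
#' full-joint enumeration.
#'
#' @param node_count number of nodes (>= 1); nodes are named `N1..`.
#' @param max_parents cap on each node's parent count.
#' @param max_states states per node drawn uniformly from `2..max_states`.
#' @param seed integer seed.
#' @param edge_prob probability of keeping each admissible edge (before
#'   the parent cap).
#' @return a valid [cbn].
#' @export
make_random_network <- function(node_count, max_parents = 3L,
                                max_states = 3L, seed = 1L,
                                edge_prob = 0.5) {
  stopifnot(node_count >= 1, max_states >= 2)
  local_seed(seed, {
    nodes <- paste0("N", seq_len(node_count))
    order <- sample(nodes)
    edges <- NULL
    if (max_parents > 0L && node_count > 1L) {
      for (j in 2:node_count) {
        cand <- order[seq_len(j - 1L)]
        keep <- cand[stats::runif(length(cand)) < edge_prob]
        if (length(keep) > max_parents) {
          keep <- sample(keep, max_parents)
        }
        if (length(keep)) edges <- rbind(edges, cbind(keep, order[j]))
      }
    }
    tp <- cbn_topology(nodes, edges)
    k <- stats::setNames(sample(2:max_states, node_count, replace = TRUE),
                         nodes)
    net <- cbn(tp, k)
    for (v in nodes) {
      d <- dim(net$cpts[[v]])
      g <- matrix(stats::rgamma(prod(d), shape = 1) + 1e-6, nrow = d[1L])
      net$cpts[[v]][] <- as.vector(sweep(g, 2, colSums(g), "/"))
    }
    net
  })
}
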