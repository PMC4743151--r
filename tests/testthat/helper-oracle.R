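# Independent brute-force oracles: enumerate the full joint table directly
# from the CPT arrays, without touching the package's factor algebra or
# variable elimination. Only feasible for small networks, which is the
# point - the fast path is checked against exhaustive enumeration.

enum_joint <- function(net) {
  nodes <- net$topology$nodes
  k <- vapply(net$states[nodes], length, integer(1))
  g <- expand.grid(lapply(k, function(x) 0:(x - 1)), KEEP.OUT.ATTRS = FALSE)
  names(g) <- nodes
  p <- rep(1, nrow(g))
  for (v in nodes) {
    fam <- c(v, net$parents[[v]])
    idx <- rep(1, nrow(g))
    stride <- 1
    for (f in fam) {
      idx <- idx + g[[f]] * stride
      stride <- stride * k[[f]]
    }
    p <- p * as.vector(net$cpts[[v]])[idx]
  }
  list(grid = g, p = p)
}

# P(targets | evidence) by summing the enumerated joint; returns the
# distribution in row-major order over targets (first target fastest),
# matching the package's factor layout
enum_posterior <- function(net, targets, evidence = NULL) {
  jt <- enum_joint(net)
  g <- jt$grid
  p <- jt$p
  if (!is.null(evidence) && length(evidence)) {
    for (v in names(evidence)) p[g[[v]] != evidence[[v]]] <- 0
  }
  k <- vapply(net$states[targets], length, integer(1))
  idx <- rep(1, nrow(g))
  stride <- 1
  for (j in seq_along(targets)) {
    idx <- idx + g[[targets[j]]] * stride
    stride <- stride * k[j]
  }
  tot <- sum(p)
  if (tot <= 0) stop("evidence has probability zero")
  as.vector(rowsum(p, idx, reorder = TRUE)) / tot
}

sprinkler_net <- function() make_sprinkler()

# two-node chain X -> Y used in the counterfactual examples
chain_xy <- function(p_y1_x1 = 0.9, p_y1_x0 = 0.1, p_x1 = 0.5) {
  tp <- cbn_topology(c("X", "Y"), rbind(c("X", "Y")))
  cbn(tp, c(X = 2L, Y = 2L),
      list(X = c(1 - p_x1, p_x1),
           Y = array(c(1 - p_y1_x0, p_y1_x0, 1 - p_y1_x1, p_y1_x1),
                     dim = c(2, 2),
                     dimnames = list(Y = c("0", "1"), X = c("0", "1")))))
}

sachs_topology <- function() {
  read_sif(system.file("extdata", "sachs_consensus.sif",
                       package = "causalbn", mustWork = TRUE))
}

# Synthetic parameterisation of the consensus signalling topology: every
# node gets three states; ERK's level strongly drives AKT's while PKA is
# upstream of ERK. This is a stand-in network for exercising the query
# machinery - its probabilities are NOT the published ones.
synthetic_sachs <- function(seed = 2024L) {
  tp <- sachs_topology()
  net <- cbn(tp, stats::setNames(rep(3L, length(tp$nodes)), tp$nodes))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (v in tp$nodes) {
    d <- dim(net$cpts[[v]])
    g <- matrix(stats::rgamma(prod(d), shape = 2) + 0.05, nrow = d[1L])
    net$cpts[[v]][] <- as.vector(sweep(g, 2, colSums(g), "/"))
  }
  # AKT listens mostly to ERK: P(AKT = a | ERK = e, PKA) decays with |a - e|
  ak <- net$cpts$AKT  # dims (AKT, ERK, PKA)
  for (e in 1:3) for (p in 1:3) {
    w <- exp(-1.8 * abs((1:3) - e))
    ak[, e, p] <- w / sum(w)
  }
  net$cpts$AKT <- ak
  net
}

# min-fill order over a network's CPT factors (wraps the internal heuristic)
min_fill_order_for <- function(net, elim) {
  factors <- lapply(net$topology$nodes,
                    function(v) causalbn:::cpt_factor(net, v))
  causalbn:::min_fill_order(factors, elim)
}

table1_queries <- c(
  "? argmax(AKT)",
  "? argmax(AKT) ! do ERK = 2",
  "? argmax(AKT) ! do ERK = 0",
  "? argmax(PKA)",
  "? argmax(PKA) ! do ERK = 2",
  "? argmax(PKA) ! do ERK = 0",
  "? argmax(PKA) | ERK = 2",
  "? argmax(PKA) | ERK = 0")
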