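test_that("sprinkler posteriors match brute-force enumeration", {
  net <- make_sprinkler()
  # frozen values from the enumeration oracle over the 8 joint states
  expect_equal(posterior_probability(net, c(R = 1), c(W = 1)), 0.3577,
               tolerance = 5e-5)
  expect_equal(posterior_probability(net, c(R = 1), c(W = 1)),
               enum_posterior(net, "R", c(W = 1))[2], tolerance = 1e-12)
  am <- argmax_posterior(net, "R", c(W = 1))
  expect_equal(am$state, 0L)
  expect_equal(am$probability, 0.6423, tolerance = 5e-5)
})

test_that("a root with no evidence returns its prior CPT", {
  net <- make_sprinkler()
  f <- variable_elimination(net, "R")
  expect_equal(f$values, as.vector(net$cpts$R))
})

test_that("zero-probability evidence raises an informative error", {
  tp <- cbn_topology(c("A", "W"), rbind(c("A", "W")))
  net <- cbn(tp, c(A = 2L, W = 2L),
             list(A = c(0.5, 0.5),
                  W = array(c(1, 0, 1, 0), c(2, 2),
                            dimnames = list(W = c("0", "1"),
                                            A = c("0", "1")))))
  expect_error(variable_elimination(net, "A", c(W = 1)),
               "inconsistent evidence")
  # targets must be disjoint from evidence
  expect_error(variable_elimination(net, "A", c(A = 0)),
               "both target and evidence")
})

test_that("variable elimination equals full-joint enumeration", {
  worst <- 0
  for (i in 1:60) {
    net <- make_random_network(2L + (i %% 9L), max_parents = 3,
                               max_states = 3, seed = 4000L + i)
    nodes <- net$topology$nodes
    set.seed(i)
    tg <- sample(nodes, min(length(nodes), sample(1:2, 1)))
    rest <- setdiff(nodes, tg)
    evn <- if (length(rest)) {
      sample(rest, sample(0:min(2, length(rest)), 1))
    } else {
      character(0)
    }
    ev <- if (length(evn)) {
      stats::setNames(lapply(evn, function(v) {
        sample(seq_along(net$states[[v]]), 1) - 1L
      }), evn)
    }
    f <- variable_elimination(net, tg, ev)
    worst <- max(worst, max(abs(f$values - enum_posterior(net, tg, ev))))
    expect_equal(sum(f$values), 1, tolerance = 1e-9)
  }
  expect_lt(worst, 1e-9)
})

test_that("the elimination order affects cost, never the value", {
  for (i in 1:10) {
    net <- make_random_network(8, max_parents = 3, seed = 5000L + i)
    f1 <- variable_elimination(net, "N1", c(N8 = 0), tie = "lex")
    f2 <- variable_elimination(net, "N1", c(N8 = 0), tie = "revlex")
    expect_equal(f1$values, f2$values, tolerance = 1e-12)
    # explicit reversed order gives the same posterior too
    elim <- setdiff(net$topology$nodes, c("N1", "N8"))
    f3 <- variable_elimination(net, "N1", c(N8 = 0),
                               elim_order = rev(min_fill_order_for(net,
                                                                   elim)))
    expect_equal(f1$values, f3$values, tolerance = 1e-12)
  }
})

test_that("assignment and argmax queries are mutually consistent", {
  net <- make_sprinkler()
  # probabilities over all states sum to one
  tot <- sum(vapply(0:1, function(s) {
    posterior_probability(net, c(S = s), c(W = 1))
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
  # argmax equals the max over assignment queries
  am <- argmax_posterior(net, "S", c(W = 1))
  probs <- vapply(0:1, function(s) {
    posterior_probability(net, c(S = s), c(W = 1))
  }, numeric(1))
  expect_equal(am$probability, max(probs))
  expect_equal(am$state, which.max(probs) - 1L)
  # uniform posterior: tie broken towards state 0
  tp <- cbn_topology("U")
  u <- cbn(tp, c(U = 2L))
  expect_equal(argmax_posterior(u, "U")$state, 0L)
  # deterministic node given observed parents
  det <- cbn(cbn_topology(c("A", "B"), rbind(c("A", "B"))),
             c(A = 2L, B = 2L),
             list(A = c(0.5, 0.5),
                  B = array(c(1, 0, 0, 1), c(2, 2),
                            dimnames = list(B = c("0", "1"),
                                            A = c("0", "1")))))
  expect_equal(argmax_posterior(det, "B", c(A = 1))$probability, 1)
})
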