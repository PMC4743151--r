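test_that("do-assignment differs from conditioning on the sprinkler", {
  net <- make_sprinkler()
  p_do <- posterior_probability(apply_do(net, c(S = 1)), c(W = 1))
  p_cond <- posterior_probability(net, c(W = 1), evidence = c(S = 1))
  expect_equal(p_do, 0.918, tolerance = 5e-5)
  expect_equal(p_cond, 0.9006, tolerance = 5e-5)
  expect_gt(abs(p_do - p_cond), 0.01)
  # both agree with brute-force enumeration on the (mutilated) network
  expect_equal(p_do, enum_posterior(apply_do(net, c(S = 1)), "W")[2],
               tolerance = 1e-12)
  expect_equal(p_cond, enum_posterior(net, "W", c(S = 1))[2],
               tolerance = 1e-12)
})

test_that("mutilation is local and removes incoming influence only", {
  net <- make_sprinkler()
  mut <- apply_do(net, c(S = 1))
  expect_equal(mut$cpts$R, net$cpts$R)
  expect_equal(mut$cpts$W, net$cpts$W)
  expect_equal(as.vector(mut$cpts$S), c(0, 1))
  expect_false(any(mut$topology$edges[, 2] == "S"))
  # do on a childless node leaves every other marginal unchanged
  mut2 <- apply_do(net, c(W = 1))
  for (v in c("R", "S")) {
    expect_equal(variable_elimination(mut2, v)$values,
                 variable_elimination(net, v)$values, tolerance = 1e-12)
  }
  expect_error(apply_do(net, c(S = 7)), "out of range")
})

test_that("non-ancestor interventions leave posteriors invariant", {
  for (i in 1:12) {
    net <- make_random_network(7, max_parents = 2, max_states = 3,
                               seed = 7000L + i)
    nodes <- net$topology$nodes
    base <- lapply(nodes, function(v) variable_elimination(net, v)$values)
    names(base) <- nodes
    for (x in nodes) {
      non_desc <- Filter(function(t) t != x &&
                           !is_ancestor(net$topology, x, t), nodes)
      if (!length(non_desc)) next
      for (s in seq_along(net$states[[x]]) - 1L) {
        mut <- apply_do(net, stats::setNames(s, x))
        for (t in non_desc) {
          expect_lt(max(abs(variable_elimination(mut, t)$values -
                              base[[t]])), 1e-9)
        }
      }
    }
  }
})

test_that("edge interventions re-estimate the child from retained data", {
  net <- make_sprinkler()
  d <- forward_sample(net, 4000, seed = 30)
  fit <- ml_counts(net, d)
  # removing the only incoming edge leaves the marginal frequency
  rs <- apply_edge_intervention(fit, "remove", "R", "S")
  expect_equal(unname(rs$cpts$S[2]), mean(d["S", ]), tolerance = 1e-12)
  # add then remove with the same data restores the network exactly
  back <- apply_edge_intervention(
    apply_edge_intervention(fit, "remove", "S", "W"), "add", "S", "W")
  for (v in c("R", "S", "W")) {
    expect_equal(back$cpts[[v]], fit$cpts[[v]], tolerance = 1e-12)
  }
  expect_length(validate_network(rs), 0)
  expect_error(apply_edge_intervention(fit, "add", "W", "R"), "cycle")
  expect_error(apply_edge_intervention(fit, "remove", "W", "R"),
               "not present")
  expect_error(apply_edge_intervention(fit, "add", "R", "S"),
               "already present")
})

test_that("edge addition replicates and removal averages when no data", {
  n <- chain_xy(p_y1_x1 = 0.9, p_y1_x0 = 0.1, p_x1 = 0.3)
  # removal: Y's CPT becomes its marginal 0.3*0.9 + 0.7*0.1 = 0.34
  cut <- apply_edge_intervention(n, "remove", "X", "Y")
  expect_equal(as.vector(cut$cpts$Y), c(0.66, 0.34), tolerance = 1e-12)
  expect_length(validate_network(cut), 0)
  # addition: old CPT replicated across the new parent's states
  iso <- cbn(cbn_topology(c("X", "Y")), c(X = 2L, Y = 2L),
             list(X = c(0.3, 0.7), Y = c(0.2, 0.8)))
  wired <- apply_edge_intervention(iso, "add", "X", "Y")
  expect_equal(as.vector(wired$cpts$Y), c(0.2, 0.8, 0.2, 0.8))
  expect_length(validate_network(wired), 0)
})

test_that("twin networks share non-descendants and copy the rest", {
  # chain X -> Y under do(X = 1): both worlds' copies diverge
  tw <- build_twin_network(chain_xy(), list(do_intervention("X", 1)))
  expect_equal(unname(tw$map), c("X_cf", "Y_cf"))
  expect_length(validate_network(tw$network), 0)
  expect_equal(as.vector(tw$network$cpts$X_cf), c(0, 1))

  # collider A -> C <- B under do(C = c): A and B shared, C copied
  tpc <- cbn_topology(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  col <- cbn(tpc, c(A = 2L, B = 2L, C = 2L))
  twc <- build_twin_network(col, list(do_intervention("C", 0)))
  expect_equal(twc$map, c(A = "A", B = "B", C = "C_cf"))
  expect_length(validate_network(twc$network), 0)

  # no interventions: everything shared, network unchanged
  tw0 <- build_twin_network(col, list())
  expect_equal(tw0$map, c(A = "A", B = "B", C = "C"))
  expect_setequal(tw0$network$topology$nodes, col$topology$nodes)
})

test_that("counterfactual queries follow the twin-network semantics", {
  n <- chain_xy()
  # observed X=0, Y=0; what would Y be under do(X = 1)?
  r <- counterfactual_query(n, "Y", c(X = 0, Y = 0),
                            list(do_intervention("X", 1)))
  expect_equal(r$values[2], 0.9, tolerance = 1e-12)
  expect_identical(r$scope, "Y")
  # empty evidence: reduces to the interventional query
  r2 <- counterfactual_query(n, "Y", NULL, list(do_intervention("X", 1)))
  expect_equal(r2$values,
               variable_elimination(apply_do(n, c(X = 1)), "Y")$values,
               tolerance = 1e-12)
  # empty interventions: reduces to the ordinary conditional
  r3 <- counterfactual_query(n, "Y", c(X = 1), list())
  expect_equal(r3$values, variable_elimination(n, "Y", c(X = 1))$values,
               tolerance = 1e-12)
  # inconsistent factual evidence propagates
  det <- chain_xy(p_y1_x1 = 1, p_y1_x0 = 0)
  expect_error(counterfactual_query(det, "Y", c(X = 0, Y = 1),
                                    list(do_intervention("X", 1))),
               "inconsistent evidence")
})

test_that("twin networks stay acyclic for accepted intervention sets", {
  for (i in 1:8) {
    net <- make_random_network(6, max_parents = 2, seed = 8000L + i)
    x <- net$topology$nodes[1 + (i %% 6)]
    tw <- build_twin_network(net, list(do_intervention(x, 0)))
    expect_error(topological_order(tw$network$topology), NA)
    expect_length(validate_network(tw$network), 0)
  }
})
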