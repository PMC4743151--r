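test_that("the parser recovers targets, evidence and interventions", {
  q <- parse_query("? argmax(AKT) ! do ERK = 2")
  expect_length(q$targets, 1)
  expect_equal(q$targets[[1]]$kind, "argmax")
  expect_equal(q$targets[[1]]$node, "AKT")
  expect_length(q$evidence, 0)
  expect_equal(q$interventions[[1]]$kind, "do")
  expect_equal(q$interventions[[1]]$node, "ERK")
  expect_equal(q$interventions[[1]]$state, "2")

  q2 <- parse_query("? argmax(PKA) | ERK = 0")
  expect_equal(q2$evidence[[1]], list(node = "ERK", state = "0"))
  expect_length(q2$interventions, 0)

  q3 <- parse_query("? A = 1 B = 0 | C = 2 ! do D = 1 + E F - G H")
  expect_length(q3$targets, 2)
  expect_equal(q3$targets[[2]]$kind, "assign")
  expect_length(q3$interventions, 3)
  expect_equal(q3$interventions[[2]]$kind, "add_edge")
  expect_equal(q3$interventions[[3]],
               remove_edge_intervention("G", "H"))
})

test_that("syntax errors carry a position and structural rules hold", {
  expect_error(parse_query("? ! do A = 1"), "no targets")
  expect_error(parse_query("argmax(A)"), "expected '\\?'")
  expect_error(parse_query("? argmax(A"), "expected '\\)'")
  expect_error(parse_query("? A = "), "expected a state")
  expect_error(parse_query("? A = 1 |"), "followed by evidence")
  expect_error(parse_query("? A = 1 !"), "followed by interventions")
  expect_error(parse_query("? A = 1 | B = 0 B = 1"), "listed twice")
  expect_error(parse_query("? A = 1 ! do B = 0 do B = 1"),
               "more than one do-assignment")
})

test_that("parse/unparse is the identity on the printed surface syntax", {
  for (s in table1_queries) {
    expect_identical(format(parse_query(s)), s)
  }
  deep <- "? A = 1 argmax(B) | C = 0 D = 2 ! do E = 1 + F G - H I"
  expect_identical(format(parse_query(deep)), deep)
})

test_that("validation reports unknown nodes, bad states and bad edges", {
  net <- synthetic_sachs()
  expect_length(validate_query("? argmax(AKT) ! do ERK = 2", net), 0)
  expect_match(validate_query("? argmax(FOO)", net), "unknown node FOO",
               all = FALSE)
  expect_match(validate_query("? argmax(AKT) ! do ERK = 7", net),
               "out of range", all = FALSE)
  expect_match(validate_query("? argmax(AKT) ! - ERK FOO", net),
               "unknown node FOO", all = FALSE)
  expect_match(validate_query("? argmax(AKT) ! - PKA Raf + Raf PKC", net),
               "cycle", all = FALSE)
  expect_match(validate_query("? argmax(AKT) ! - AKT ERK", net),
               "not present", all = FALSE)
})

test_that("query dispatch matches direct module calls", {
  net <- make_sprinkler()
  # evidence only == plain inference
  r <- evaluate_query("? R = 1 | W = 1", net)
  expect_equal(r$joint_probability,
               posterior_probability(net, c(R = 1), c(W = 1)))
  # plain marginal on a single binary node
  u <- cbn(cbn_topology("A"), c(A = 2L), list(A = c(0.75, 0.25)))
  expect_equal(evaluate_query("? A = 0", u)$joint_probability, 0.75)
  # interventions only == mutilated-network inference
  r2 <- evaluate_query("? argmax(W) ! do S = 1", net)
  expect_equal(r2$argmax$probability,
               argmax_posterior(apply_do(net, c(S = 1)), "W")$probability)
  # evidence + intervention == counterfactual (twin) semantics
  ch <- chain_xy()
  r3 <- evaluate_query("? Y = 1 | X = 0 Y = 0 ! do X = 1", ch)
  expect_equal(r3$joint_probability, 0.9, tolerance = 1e-12)
  # ... and single-world semantics on request
  r4 <- evaluate_query("? Y = 1 | X = 0 ! do Y = 1", ch, worlds = "single")
  expect_equal(r4$joint_probability, 1)
  # argmax probability equals the max over assignment queries
  r5 <- evaluate_query("? argmax(S) | W = 1", net)
  probs <- vapply(0:1, function(s) {
    evaluate_query(sprintf("? S = %d | W = 1", s), net)$joint_probability
  }, numeric(1))
  expect_equal(r5$argmax$probability, max(probs))
})

test_that("display labels resolve to states in queries", {
  tp <- cbn_topology(c("G", "P"), rbind(c("G", "P")))
  net <- cbn(tp, list(G = c("low", "high"), P = c("low", "high")),
             list(G = c(0.4, 0.6),
                  P = array(c(0.9, 0.1, 0.2, 0.8), c(2, 2),
                            dimnames = list(P = c("low", "high"),
                                            G = c("low", "high")))))
  expect_equal(evaluate_query("? P = high | G = high", net)$joint_probability,
               0.8, tolerance = 1e-12)
  expect_equal(evaluate_query("? P = high ! do G = low", net)$joint_probability,
               0.1, tolerance = 1e-12)
  expect_match(validate_query("? P = tall", net), "out of range",
               all = FALSE)
})

test_that("evaluating an invalid query fails loudly", {
  net <- make_sprinkler()
  expect_error(evaluate_query("? argmax(Q)", net), "invalid query")
  expect_error(evaluate_query("? R = 9", net), "invalid query")
})
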