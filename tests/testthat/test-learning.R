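test_that("ml_counts reproduces hand-tabulated frequencies", {
  tp <- cbn_topology("A")
  net <- cbn(tp, c(A = 2L))
  d <- matrix(c(1L, 1L, 0L, 1L), nrow = 1,
              dimnames = list("A", paste0("s", 1:4)))
  expect_equal(as.vector(ml_counts(net, d)$cpts$A), c(0.25, 0.75))

  # chain A -> B on 4 complete samples, checked against hand counting
  ch <- cbn(cbn_topology(c("A", "B"), rbind(c("A", "B"))),
            c(A = 2L, B = 2L))
  d2 <- rbind(A = c(0L, 0L, 1L, 1L), B = c(0L, 1L, 1L, 1L))
  colnames(d2) <- paste0("s", 1:4)
  fit <- ml_counts(ch, d2)
  expect_equal(as.vector(fit$cpts$A), c(0.5, 0.5))
  expect_equal(fit$cpts$B[, "0"], c("0" = 0.5, "1" = 0.5))
  expect_equal(fit$cpts$B[, "1"], c("0" = 0, "1" = 1))

  # never-observed parent configuration becomes uniform
  d3 <- rbind(A = c(0L, 0L), B = c(0L, 1L))
  colnames(d3) <- paste0("s", 1:2)
  expect_equal(ml_counts(ch, d3)$cpts$B[, "1"], c("0" = 0.5, "1" = 0.5))

  d4 <- rbind(A = c(0L, NA), B = c(0L, 1L))
  colnames(d4) <- c("s1", "s2")
  expect_error(ml_counts(ch, d4), "complete data")
})

test_that("log-likelihood factorises for complete samples, marginalises gaps", {
  net <- make_sprinkler()
  d <- forward_sample(net, 10, seed = 20)
  # chain-rule: sum of log CPT entries along the topological order
  by_hand <- sum(apply(d, 2, function(x) {
    log(net$cpts$R[x["R"] + 1]) +
      log(net$cpts$S[x["S"] + 1, x["R"] + 1]) +
      log(net$cpts$W[x["W"] + 1, x["R"] + 1, x["S"] + 1])
  }))
  expect_equal(log_likelihood(net, d), by_hand, tolerance = 1e-10)

  # a fully missing sample contributes log 1 = 0
  dm <- cbind(d, sNA = c(R = NA, S = NA, W = NA))
  expect_equal(log_likelihood(net, dm), by_hand, tolerance = 1e-10)

  # single binary node, P(1) = 0.5, samples [1, 0]
  u <- cbn(cbn_topology("A"), c(A = 2L))
  du <- matrix(c(1L, 0L), nrow = 1, dimnames = list("A", c("s1", "s2")))
  expect_equal(log_likelihood(u, du), 2 * log(0.5))

  # zero-probability sample reports -Inf
  det <- cbn(cbn_topology("A"), c(A = 2L), list(A = c(1, 0)))
  expect_identical(log_likelihood(det, du), -Inf)
})

test_that("EM reaches the closed-form fixed point on [1,1,0,missing]", {
  net <- cbn(cbn_topology("A"), c(A = 2L))
  d <- matrix(c(1L, 1L, 0L, NA), nrow = 1,
              dimnames = list("A", paste0("s", 1:4)))
  # p = (2 + p) / 4  =>  p = 2/3, from every initialisation scheme
  for (scheme in c("uniform", "random", "complete_case")) {
    fit <- em_fit(net, d, em_config(restarts = 1, schemes = scheme,
                                    tol = 1e-10, seed = 3))
    expect_equal(fit$network$cpts$A[2], 2 / 3, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("EM on complete data degenerates to ml_counts for all schemes", {
  net <- make_sprinkler()
  d <- forward_sample(net, 400, seed = 21)
  ml <- ml_counts(net, d)
  for (scheme in c("uniform", "random", "complete_case")) {
    fit <- em_fit(net, d, em_config(restarts = 1, schemes = scheme))
    for (v in c("R", "S", "W")) {
      expect_equal(fit$network$cpts[[v]], ml$cpts[[v]], tolerance = 1e-12)
    }
  }
})

test_that("log-likelihood never decreases within any restart", {
  net <- make_sprinkler()
  d <- inject_missing(forward_sample(net, 1000, seed = 22), 0.2, seed = 23)
  fit <- em_fit(net, d, em_config(restarts = 3, seed = 7))
  for (tr in fit$trace) {
    expect_true(all(diff(tr) > -1e-9))
  }
  expect_equal(fit$logLik, max(fit$restarts$logLik))
  expect_equal(fit$restarts$logLik[fit$winner], fit$logLik)
})

test_that("EM recovers the generating CPTs under 20% MCAR missingness", {
  net <- make_sprinkler()
  d <- inject_missing(forward_sample(net, 50000, seed = 24), 0.2, seed = 25)
  fit <- em_fit(net, d, em_config(restarts = 2, seed = 8))
  err <- max(abs(unlist(fit$network$cpts) - unlist(net$cpts)))
  expect_lt(err, 0.03)
})

test_that("initialisation schemes behave as documented", {
  net <- make_sprinkler()
  u <- init_cpts(net, "uniform")
  expect_true(all(abs(unlist(u$cpts) - 0.5) < 1e-12))

  r1 <- init_cpts(net, "random", seed = 11)
  r2 <- init_cpts(net, "random", seed = 11)
  r3 <- init_cpts(net, "random", seed = 12)
  expect_equal(r1$cpts, r2$cpts)
  expect_false(isTRUE(all.equal(r1$cpts, r3$cpts)))
  expect_length(validate_network(r1), 0)

  d <- forward_sample(net, 200, seed = 26)
  cc <- init_cpts(net, "complete_case", data = d)
  expect_equal(cc$cpts, ml_counts(net, d)$cpts)
  # no complete samples: uniform fallback
  d2 <- d
  d2["R", ] <- NA
  cc2 <- init_cpts(net, "complete_case", data = d2)
  expect_true(all(abs(unlist(cc2$cpts) - 0.5) < 1e-12))

  expect_error(init_cpts(net, "oracle"), "arg")
  expect_error(em_fit(net, d[, 0, drop = FALSE]), "empty data")
})
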