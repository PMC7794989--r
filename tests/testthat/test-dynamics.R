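# Steady-state machinery, checked against closed forms and an independent
# 1-D fixed-point oracle for the toggle switch.

test_that("shifted Hill function satisfies its closed-form identities", {
  for (lambda in c(0.01, 0.5, 2, 100)) {
    for (n in c(1L, 3L, 6L)) {
      mu <- 7.3
      expect_equal(shifted_hill(0, mu, lambda, n), 1)
      expect_equal(shifted_hill(mu, mu, lambda, n), (1 + lambda) / 2)
      expect_equal(shifted_hill(1e6 * mu, mu, lambda, n), lambda,
                   tolerance = 1e-4)
      # bounded and monotone in p
      p <- 10^seq(-3, 4, length.out = 200) * mu
      h <- shifted_hill(p, mu, lambda, n)
      expect_true(all(h >= min(1, lambda) - 1e-12 & h <= max(1, lambda) + 1e-12))
      expect_true(all(diff(h) * sign(lambda - 1) >= -1e-12))
    }
  }
  expect_error(shifted_hill(1, -1, 2, 1), "positive")
})

test_that("the ODE right-hand side reduces correctly for isolated nodes", {
  iso <- circuit_topology(c("A", "B"),
                          data.frame(source = "A", target = "B",
                                     sign = "activation"), name = "chain2")
  p <- manual_params(iso, g = c(4, 2), k = c(0.5, 1), lambda = 3, mu = 5, n = 2)
  # A has no inputs: fixed point at g/k, derivative g at the origin
  expect_equal(circuit_rhs(c(A = 8, B = 1), p, iso)[1], 0)
  expect_equal(circuit_rhs(c(A = 1e-300, B = 1), p, iso)[1], 4,
               tolerance = 1e-12)
  expect_error(circuit_rhs(c(1, 2, 3), p, iso), "node count")
})

test_that("trajectory solver matches the exhaustive toggle-switch oracle", {
  topo <- toggle_topology()
  cases <- list(
    list(g = 50, k = 1, lambda = 0.01, mu = 16, n = 4), # deep bistable
    list(g = 20, k = 0.5, lambda = 0.05, mu = 30, n = 3),
    list(g = 10, k = 1, lambda = 0.5, mu = 10, n = 2)   # weak: monostable
  )
  set.seed(17)
  for (cs in cases) {
    p <- manual_params(topo, cs$g, cs$k, cs$lambda, cs$mu, cs$n)
    oracle <- toggle_roots(cs$g, cs$k, cs$lambda, cs$mu, cs$n)
    ics <- sample_initial_conditions(p, topo, 50)
    res <- find_steady_states(p, topo, ics)
    expect_equal(res$n_states, length(oracle$stable))
    # every reported state matches an oracle root in both coordinates and
    # has a tiny scale-free residual
    for (i in seq_len(res$n_states)) {
      st <- res$states[i, ]
      expect_true(min(abs(log2(st["A"]) - log2(oracle$stable))) < 0.05)
      expect_true(min(abs(log2(st["B"]) - log2(oracle$stable))) < 0.05)
      resid <- circuit_rhs(st, p, topo)
      expect_true(all(abs(resid) < 1e-8 * (cs$g / cs$k)))
    }
  }
})

test_that("unregulated nodes converge to g/k from any start", {
  iso <- circuit_topology(c("A", "B"),
                          data.frame(source = "A", target = "B",
                                     sign = "activation"), name = "chain2")
  p <- manual_params(iso, g = c(10, 5), k = c(1, 1), lambda = 2, mu = 5, n = 2)
  ics <- matrix(c(0.01, 0.01, 500, 700, 10, 10), ncol = 2, byrow = TRUE)
  colnames(ics) <- iso$nodes
  res <- find_steady_states(p, iso, ics)
  expect_equal(res$n_states, 1L)
  expect_equal(unname(res$states[1, "A"]), 10, tolerance = 1e-6)
  expect_equal(res$conv_frac, 1)
})

test_that("deduplication is idempotent and multistability labels count states", {
  topo <- toggle_topology()
  p <- manual_params(topo, 50, 1, 0.01, 16, 4)
  ics <- sample_initial_conditions(p, topo, 10)
  dup <- rbind(ics, ics, ics)
  r1 <- find_steady_states(p, topo, ics)
  r2 <- find_steady_states(p, topo, dup)
  expect_equal(r1$states, r2$states)

  expect_equal(classify_multistability(1L), "monostable")
  expect_equal(classify_multistability(2L), "bistable")
  expect_equal(classify_multistability(3L), "tristable")
  expect_equal(classify_multistability(7L), "quadrastable+")
  expect_error(classify_multistability(0L), "at least one")
})

test_that("ensembles are deterministic, bounded, and account for every model", {
  topo <- builtin_circuit("base")
  r <- sampling_ranges(threshold_rule = "half_functional")
  e1 <- run_ensemble(topo, r, n_models = 40, n_inits = 20, seed = 31)
  e2 <- run_ensemble(topo, r, n_models = 40, n_inits = 20, seed = 31)
  expect_identical(e1$solutions, e2$solutions)
  expect_identical(e1$edge_params, e2$edge_params)

  fr <- multistability_fractions(e1)
  expect_equal(sum(fr), 1)
  # every state positive and below its model's upper bound G/k
  np <- e1$node_params
  for (nd in topo$nodes) {
    ub <- setNames(np$G[np$node == nd] / np$k[np$node == nd],
                   np$model_id[np$node == nd])
    lev <- e1$solutions[[nd]]
    expect_true(all(lev > 0))
    expect_true(all(lev <= ub[as.character(e1$solutions$model_id)] * 1.001))
  }
  expect_error(run_ensemble(topo, r, n_models = 0), "n_models")
})
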