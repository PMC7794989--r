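# The sampler draws all kinetic parameters; tests use degenerate ranges to
# pin individual quantities, and the cheap Monte-Carlo threshold rule where
# the rule itself is not under test.

quick_ranges <- function(...) {
  sampling_ranges(threshold_rule = "half_functional", ...)
}

test_that("sampled parameters respect their ranges and sign conventions", {
  topo <- builtin_circuit("base")
  r <- quick_ranges()
  set.seed(1)
  ref <- threshold_reference_levels(topo, r)
  for (i in 1:50) {
    p <- sample_parameter_set(topo, r, ref_levels = ref)
    act <- p$edges$sign == "activation"
    expect_true(all(p$edges$lambda[act] > 1))
    expect_true(all(p$edges$lambda[!act] > 0 & p$edges$lambda[!act] < 1))
    expect_true(all(p$edges$mu > 0))
    expect_true(all(p$edges$n >= 1 & p$edges$n <= 6))
    expect_true(all(p$G > 0 & p$g > 0 & p$k > 0))
    # maximal production identity: G = g * prod(activating lambda), exactly
    for (nd in topo$nodes) {
      lam_act <- p$edges$lambda[p$edges$target == nd & act]
      expect_equal(p$G[[nd]], p$g[[nd]] * prod(lam_act), tolerance = 1e-12)
    }
  }
})

test_that("basal rate derivation matches the saturated-production convention", {
  # two activators with lambda forced to 2: g = G / (2*2)
  topo <- circuit_topology(
    c("A", "B", "C"),
    data.frame(source = c("A", "B"), target = c("C", "C"),
               sign = "activation"), name = "ff"
  )
  r <- quick_ranges(G_range = c(100, 100), lambda_range = c(2, 2))
  set.seed(2)
  p <- sample_parameter_set(topo, r)
  expect_equal(unname(p$G[["C"]]), 100)
  expect_equal(unname(p$g[["C"]]), 25)
  # nodes without incoming activators keep g == G
  expect_equal(p$g[["A"]], p$G[["A"]])
})

test_that("fold-change perturbations scale only the named node's G range", {
  r <- quick_ranges()
  topo <- builtin_circuit("base")
  up <- apply_fold_change(r, perturbation("ZEB", 10), topo)
  expect_equal(.subset2(up, "G_fold")[["ZEB"]], 10)
  # effective range endpoints scale by the fold
  set.seed(3)
  ref <- threshold_reference_levels(topo, r)
  G_up <- replicate(200, sample_parameter_set(topo, up, ref_levels = ref)$G[["ZEB"]])
  expect_true(all(G_up >= 10 & G_up <= 1000))
  dn <- apply_fold_change(r, perturbation("ZEB", 0.1), topo)
  G_dn <- replicate(200, sample_parameter_set(topo, dn, ref_levels = ref)$G[["ZEB"]])
  expect_true(all(G_dn >= 0.1 & G_dn <= 10))
  # identity fold changes nothing; unknown node errors
  id <- apply_fold_change(r, perturbation("ZEB", 1), topo)
  expect_equal(.subset2(id, "G_fold")[["ZEB"]], 1)
  expect_error(apply_fold_change(r, perturbation("nope", 2), topo),
               "unknown node")
  # thresholds are calibrated on unperturbed ranges: same mu distribution
  set.seed(4); mu_ref <- sample_parameter_set(topo, r, ref_levels = ref)$edges$mu
  set.seed(4); mu_up <- sample_parameter_set(topo, up, ref_levels = ref)$edges$mu
  expect_identical(mu_ref, mu_up)
})

test_that("initial conditions are log-uniform between the reachable bounds", {
  # isolated node: lower == upper == G/k
  iso <- circuit_topology(c("A", "B"),
                          data.frame(source = "A", target = "B",
                                     sign = "inhibition"), name = "chain")
  r <- quick_ranges(G_range = c(10, 10), k_range = c(0.5, 0.5),
                    lambda_range = c(10, 10))
  set.seed(5)
  p <- sample_parameter_set(iso, r)
  ics <- sample_initial_conditions(p, iso, 25)
  expect_equal(unname(ics[, "A"]), rep(20, 25))
  # inhibited node with lambda = 1/10: levels within [0.1, 1] * G/k
  expect_true(all(ics[, "B"] >= 0.1 * 20 - 1e-12 & ics[, "B"] <= 20 + 1e-12))

  # goodness of fit: log levels uniform on [log L, log U] (KS at alpha 0.01)
  set.seed(6)
  draws <- sample_initial_conditions(p, iso, 10000)[, "B"]
  ks <- suppressWarnings(ks.test(log(draws), "punif", log(2), log(20)))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling is reproducible under a fixed seed", {
  topo <- builtin_circuit("base")
  r <- quick_ranges()
  ref <- threshold_reference_levels(topo, r)
  set.seed(11); a <- sample_parameter_set(topo, r, ref_levels = ref)
  set.seed(11); b <- sample_parameter_set(topo, r, ref_levels = ref)
  expect_identical(a, b)
})

test_that("threshold reference levels follow the configured rule", {
  topo <- builtin_circuit("base")
  med <- threshold_reference_levels(topo, sampling_ranges(threshold_rule = "median"))
  expect_true(all(med == 50.5 / 0.55))
  hf <- threshold_reference_levels(topo, quick_ranges())
  # unregulated node keeps ~G/k median; regulated nodes sit lower
  expect_gt(hf[["NFkB"]], 80)
  expect_lt(hf[["ZEB"]], hf[["NFkB"]])
  # deterministic and side-effect free on the caller's RNG
  set.seed(42); x1 <- runif(1)
  set.seed(42); invisible(threshold_reference_levels(topo, quick_ranges()))
  x2 <- runif(1)
  expect_identical(x1, x2)
})
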