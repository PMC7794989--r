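# Properties of the base-circuit ensemble at review scale. These use the
# shared cached run (5 replicates x 1,000 models x 100 initial conditions).

test_that("ensemble bookkeeping is complete and consistent", {
  an <- base_desk_analysis()
  pr <- an$multistability$per_replicate
  expect_equal(unname(rowSums(pr[, -1])), rep(1, 5))
  # every solution labeled, every model's states all present
  expect_false(anyNA(an$solutions$label))
  for (r in 1:5) {
    z <- an$solutions[an$solutions$replicate == r, ]
    per_model <- table(z$model_id)
    ns <- tapply(z$n_states, z$model_id, unique)
    expect_equal(as.integer(per_model), as.integer(ns[names(per_model)]))
  }
})

test_that("cluster structure mirrors the four-phenotype geometry", {
  an <- base_desk_analysis()
  z <- an$solutions[an$solutions$replicate == 1, ]
  med <- sapply(split(z$miR200, z$label), median)
  # miR-200 separates the e/he pair from the hm/m pair, but is similar
  # within each pair (a coarse-grained EMT readout)
  gap <- min(med["e"], med["he"]) - max(med["hm"], med["m"])
  expect_gt(gap, 0.5)
  expect_lt(abs(med["e"] - med["he"]), gap)
  expect_lt(abs(med["hm"] - med["m"]), gap)
  # ZEB medians strictly ordered e < he < hm < m by construction
  medz <- sapply(split(z$ZEB, z$label), median)
  expect_true(all(diff(medz[c("e", "he", "hm", "m")]) > 0))
})

test_that("self-normalization leaves each node standardized per replicate", {
  an <- base_desk_analysis()
  for (r in c(1, 3)) {
    z <- an$solutions[an$solutions$replicate == r, ]
    for (nd in c("miR200", "ZEB", "LIN28", "let7", "SNAIL", "NFkB")) {
      expect_equal(mean(z[[nd]]), 0, tolerance = 1e-6)
      expect_equal(sd(z[[nd]]), 1, tolerance = 1e-6)
    }
  }
})

test_that("monostable solutions are dominated by the e and m phenotypes", {
  an <- base_desk_analysis()
  mp <- an$monostable_proportions
  get <- function(ph) mp$mean[mp$phenotype == ph]
  expect_gt(get("e"), get("he"))
  expect_gt(get("e"), get("hm"))
  expect_gt(get("m"), get("he"))
  expect_gt(get("m"), get("hm"))
})

test_that("enrichment probabilities are reproducible from the stored table", {
  an <- base_desk_analysis()
  sol <- an$solutions
  again <- conditional_probabilities(sol$label, sol$LIN28, an$window,
                                     sol$replicate)
  expect_identical(again$summary, an$enrichment$summary)
  # excluding monostable parameter sets preserves the hybrid enrichment
  multi <- sol[sol$n_states > 1, ]
  cp <- conditional_probabilities(multi$label, multi$LIN28, an$window,
                                  multi$replicate)
  expect_gt(hybrid_sum(cp$summary, "p1_mean"), nonhybrid_sum(cp$summary, "p1_mean"))
  expect_gt(hybrid_sum(cp$summary, "p2_mean"), nonhybrid_sum(cp$summary, "p2_mean"))
})

test_that("coupling-link metrics separate phenotypes as the model predicts", {
  an <- base_desk_analysis()
  ens <- an$ensembles[[1]]
  z <- an$solutions[an$solutions$replicate == 1, ]
  cpl <- strength_by_phenotype(ens, z$label,
                               edge1 = c("miR200", "LIN28"),
                               edge2 = c("let7", "ZEB"), metric = "coupling")
  # net coupling strongest for e, weakest for m
  expect_gt(cpl$medians[["e"]], cpl$medians[["m"]])
  asym <- strength_by_phenotype(ens, z$label,
                                edge1 = c("ZEB", "miR200"),
                                edge2 = c("miR200", "ZEB"),
                                metric = "asymmetry")
  # ZEB's suppression of miR-200 strongest in the mesenchymal-side states
  expect_gt(min(asym$medians[["hm"]], asym$medians[["m"]]),
            max(asym$medians[["e"]], asym$medians[["he"]]))
})
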