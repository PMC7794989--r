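# Orchestration: replicates, circuits, perturbation sweeps, significance
# tests, and the cross-replicate summaries mirroring the study's figures.

#' Run configuration
#'
#' @param circuit Builtin circuit name (see [builtin_circuit()]) or a path to
#'   a `.topo` file.
#' @param n_models Random parameter sets per replicate.
#' @param n_inits Initial conditions per parameter set.
#' @param n_replicates Independent replicates (each a fresh ensemble).
#' @param seed Base integer seed; replicate r uses `seed + r - 1`.
#' @param k Cluster count for phenotype assignment.
#' @param restarts K-means restarts.
#' @param f Stemness-window fraction.
#' @param ranges A [sampling_ranges()].
#' @param solver A [solver_config()].
#' @return List of class `run_config`.
#' @export
run_config <- function(circuit = "base", n_models = 1000, n_inits = 100,
                       n_replicates = 5, seed = 1, k = 4, restarts = 10,
                       f = 0.30, ranges = sampling_ranges(),
                       solver = solver_config()) {
  stopifnot(n_models >= 1, n_inits >= 1, n_replicates >= 1, f > 0, f <= 1)
  structure(
    list(circuit = circuit, n_models = n_models, n_inits = n_inits,
         n_replicates = n_replicates, seed = as.integer(seed), k = k,
         restarts = restarts, f = f, ranges = ranges, solver = solver),
    class = "run_config"
  )
}

.resolve_circuit <- function(circuit) {
  if (inherits(circuit, "circuit_topology")) return(circuit)
  if (circuit %in% .builtin_circuit_names) return(builtin_circuit(circuit))
  load_topology(circuit)
}

# Simulate the per-replicate ensembles of one circuit (+ perturbations).
.simulate_replicates <- function(topo, cfg, perturbations = list()) {
  lapply(seq_len(cfg$n_replicates), function(r) {
    run_ensemble(topo, cfg$ranges, cfg$n_models, cfg$n_inits,
                 perturbations, seed = cfg$seed + r - 1L, config = cfg$solver)
  })
}

# Normalize + cluster one replicate's solutions against reference stats.
.annotate_replicate <- function(ensemble, norm_stats, replicate, cfg) {
  z <- normalize_solutions(ensemble$solutions, norm_stats)
  asg <- kmeans_phenotypes(z, k = cfg$k, restarts = cfg$restarts,
                           seed = cfg$seed + 7919L * replicate)
  z$label <- asg$labels
  z$replicate <- replicate
  list(z = z, assignment = asg)
}

#' Full analysis of one circuit
#'
#' For each replicate: sample and solve the ensemble, normalize gene-wise
#' against the replicate's own (unperturbed) solutions, cluster into
#' phenotypes, label multistable phases, place the stemness window, and
#' compute the enrichment probabilities; then summarize across replicates.
#'
#' @param cfg A [run_config()].
#' @return List of class `circuit_analysis` with elements
#'   `solutions` (pooled z table: `replicate`, `model_id`, `n_states`, node
#'   z columns, `label`), `ensembles`, `norm_stats` (per replicate),
#'   `assignments`, `multistability` (per-replicate fractions and
#'   mean/sd summary), `phases` (per-replicate frequency tables),
#'   `monostable_proportions`, `pca` (per replicate + mean variance
#'   fractions), `window`, `enrichment` (p1/p2), `config`.
#' @export
run_full_analysis <- function(cfg) {
  topo <- .resolve_circuit(cfg$circuit)
  ensembles <- .simulate_replicates(topo, cfg)
  norm_stats <- lapply(ensembles, function(e) {
    normalization_stats(e$solutions, nodes = topo$nodes)
  })
  ann <- Map(function(e, ns, r) .annotate_replicate(e, ns, r, cfg),
             ensembles, norm_stats, seq_along(ensembles))
  sol <- do.call(rbind, lapply(ann, `[[`, "z"))
  assignments <- lapply(ann, `[[`, "assignment")

  ms <- t(vapply(ensembles, multistability_fractions, numeric(4)))
  ms_df <- data.frame(replicate = seq_len(nrow(ms)), ms, check.names = FALSE)
  ms_summary <- data.frame(
    class = colnames(ms),
    mean = colMeans(ms),
    sd = apply(ms, 2, sd)
  )
  rownames(ms_summary) <- NULL

  phases <- lapply(seq_along(ann), function(r) {
    z <- ann[[r]]$z
    label_phases(z$label, z$model_id, z$n_states)
  })

  mono_prop <- .monostable_proportions(sol)

  pca_rep <- lapply(ann, function(a) pca_summary(a$z))
  pc_var <- t(vapply(pca_rep, function(p) p$variance_fraction[1:2], numeric(2)))
  colnames(pc_var) <- c("PC1", "PC2")

  window <- stemness_window(sol$LIN28, sol$replicate, f = cfg$f)
  enrichment <- conditional_probabilities(sol$label, sol$LIN28, window,
                                          sol$replicate)

  structure(
    list(solutions = sol, ensembles = ensembles, norm_stats = norm_stats,
         assignments = assignments,
         multistability = list(per_replicate = ms_df, summary = ms_summary),
         phases = phases, monostable_proportions = mono_prop,
         pca = list(per_replicate = pca_rep, variance = pc_var,
                    variance_mean = colMeans(pc_var)),
         window = window, enrichment = enrichment,
         circuit = topo, config = cfg),
    class = "circuit_analysis"
  )
}

# Phenotype shares among monostable solutions, mean across replicates.
.monostable_proportions <- function(sol, states = 1L) {
  per_rep <- lapply(split(sol, sol$replicate), function(d) {
    d <- d[d$n_states %in% states, ]
    tb <- table(d$label)
    as.vector(tb) / sum(tb)
  })
  mat <- do.call(rbind, per_rep)
  colnames(mat) <- levels(sol$label)
  data.frame(phenotype = colnames(mat), mean = colMeans(mat),
             sd = apply(mat, 2, sd), row.names = NULL)
}

#' Perturbation sweep over one node's production range
#'
#' Runs the circuit unperturbed (the reference), then once per fold change
#' of the target node. Each perturbed replicate is normalized against the
#' same replicate's reference statistics, and the reference run's stemness
#' window is reused, so compositions are comparable across folds.
#'
#' @param cfg A [run_config()].
#' @param node Node to perturb.
#' @param folds Positive fold changes (e.g. `c(0.1, 1, 10)` for de10,
#'   reference, oe10). A fold of 1 reuses the reference ensembles.
#' @return List of class `perturbation_sweep` with `reference` (the
#'   [run_full_analysis()] bundle) and `per_fold` — one entry per fold with
#'   `solutions` (labeled z table), `multistability`,
#'   `monostable_proportions`, `phases`, `enrichment`.
#' @export
perturbation_sweep <- function(cfg, node, folds = c(0.1, 1, 10)) {
  stopifnot(all(folds > 0))
  ref <- run_full_analysis(cfg)
  topo <- ref$circuit
  if (!node %in% topo$nodes) stop("perturbation_sweep: unknown node ", node)
  per_fold <- list()
  for (fold in folds) {
    key <- format(fold)
    if (fold == 1) {
      sol <- ref$solutions
      ms <- ref$multistability
      phases <- ref$phases
      mono <- ref$monostable_proportions
      enr <- ref$enrichment
    } else {
      perts <- list(perturbation(node, fold))
      ens <- .simulate_replicates(topo, cfg, perts)
      ann <- Map(function(e, ns, r) .annotate_replicate(e, ns, r, cfg),
                 ens, ref$norm_stats, seq_along(ens))
      sol <- do.call(rbind, lapply(ann, `[[`, "z"))
      msm <- t(vapply(ens, multistability_fractions, numeric(4)))
      ms <- list(
        per_replicate = data.frame(replicate = seq_len(nrow(msm)), msm,
                                   check.names = FALSE),
        summary = data.frame(class = colnames(msm), mean = colMeans(msm),
                             sd = apply(msm, 2, sd))
      )
      phases <- lapply(ann, function(a) {
        label_phases(a$z$label, a$z$model_id, a$z$n_states)
      })
      mono <- .monostable_proportions(sol)
      enr <- conditional_probabilities(sol$label, sol$LIN28, ref$window,
                                       sol$replicate)
    }
    per_fold[[key]] <- list(fold = fold, solutions = sol,
                            multistability = ms, phases = phases,
                            monostable_proportions = mono, enrichment = enr)
  }
  structure(list(reference = ref, node = node, folds = folds,
                 per_fold = per_fold),
            class = "perturbation_sweep")
}

#' Mean phase frequency across replicates
#'
#' @param phases The `phases` element of a [run_full_analysis()] bundle (a
#'   list of per-replicate [label_phases()] results).
#' @param class Multistability class to summarize.
#' @return Data frame `phase`, `freq` (mean across replicates; phases absent
#'   in a replicate count as 0), sorted by decreasing frequency.
#' @export
phase_frequency_summary <- function(phases, class = "bistable") {
  tabs <- lapply(phases, function(ph) {
    d <- ph$frequencies
    d[d$class == class, c("phase", "freq")]
  })
  all_ph <- unique(unlist(lapply(tabs, `[[`, "phase")))
  mat <- vapply(tabs, function(d) {
    v <- setNames(rep(0, length(all_ph)), all_ph)
    v[d$phase] <- d$freq
    v
  }, numeric(length(all_ph)))
  mat <- matrix(mat, nrow = length(all_ph),
                dimnames = list(all_ph, NULL))
  out <- data.frame(phase = all_ph, freq = rowMeans(mat), row.names = NULL)
  out[order(-out$freq), , drop = FALSE]
}

# Statistics ------------------------------------------------------------------

#' Two-sided Mann-Whitney U (rank-sum) test
#'
#' For within-replicate comparisons of solution-level distributions, where n
#' is large. Also reports median-based effect-size surrogates, since at
#' ensemble sample sizes tiny differences reach significance.
#'
#' @param a,b Numeric samples.
#' @return List with `statistic` (U for the first sample), `p_value`,
#'   `median_ratio`, `median_diff`, `degenerate` (TRUE when all values are
#'   tied).
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  degenerate <- length(unique(c(a, b))) == 1L
  if (degenerate) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                median_ratio = 1, median_diff = 0, degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_ratio = median(a) / median(b),
       median_diff = median(a) - median(b), degenerate = FALSE)
}

#' Welch's unequal-variance t-test
#'
#' For cross-replicate comparisons of proportions (small n, approximate
#' normality), with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric vectors of per-replicate proportions (each length >=
#'   2).
#' @return List with `statistic`, `p_value`, `df`, `mean_diff`,
#'   `degenerate` (TRUE when both samples have zero variance; equal means
#'   then give p = 1).
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    return(list(statistic = if (mean(a) == mean(b)) 0 else Inf,
                p_value = if (mean(a) == mean(b)) 1 else 0,
                df = NA_real_, mean_diff = mean(a) - mean(b),
                degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(a) - mean(b),
       degenerate = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, input order preserved.
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1 | is.na(pvals))) {
    stop("holm_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "holm")
}
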