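# Random kinetic parameterization of a circuit: the ensemble's data generator.

#' Default kinetic sampling ranges
#'
#' Ranges from which each model's kinetic parameters are drawn uniformly:
#' maximal production rate G (molecules/time), degradation rate k (1/time),
#' integer Hill coefficient n, and regulatory fold change lambda (activation
#' samples lambda in `lambda_range`; inhibition uses the reciprocal,
#' 1/Uniform(`lambda_range`)). Regulation thresholds mu are drawn from
#' `U[mu_lo_frac * M, mu_hi_frac * M]` where M is the source node's
#' reference level under the configured `threshold_rule`, keeping each link
#' roughly half-functional (see [threshold_reference_levels()]).
#'
#' @param G_range,k_range,lambda_range Numeric length-2 ranges (min, max).
#' @param n_support Integer support of the Hill coefficient.
#' @param mu_lo_frac,mu_hi_frac Threshold range as fractions of the source
#'   node's reference level M.
#' @param threshold_rule How the reference level M of each node — the center
#'   of the threshold range of links leaving it — is obtained. All variants
#'   aim at the "half-functional" principle: a link's threshold should have
#'   about even odds of sitting above or below its regulator's realized
#'   level. `"calibrated"` (default) finds M self-consistently: starting
#'   from a Monte-Carlo estimate, it simulates small pilot ensembles of the
#'   circuit and updates M toward the per-node median of the realized
#'   steady-state levels (damped on the log scale), so that the final
#'   thresholds are half-functional against the distribution the sampler
#'   itself generates. `"half_functional"` stops at the Monte-Carlo
#'   estimate: median of `G/k` times one factor per incoming link, each
#'   `1/lambda` or `1` with equal odds (the regulator below or above its
#'   own threshold). `"half_functional_uniform"` draws that factor uniformly
#'   on `[1/lambda, 1]` instead. `"median"` uses
#'   `median(G range)/median(k range)` for every node regardless of
#'   regulation. M always uses the unperturbed reference ranges, so
#'   fold-change perturbations shift production only.
#' @param threshold_mc Monte Carlo draws for the half-functional estimate.
#' @param calibration_models,calibration_inits,calibration_iters Pilot
#'   ensemble size (models, initial conditions) and damped iterations of the
#'   `"calibrated"` rule.
#' @return An object of class `sampling_ranges`: a list of the above, plus a
#'   `G_fold` named numeric of per-node fold changes applied to `G_range`
#'   (empty until [apply_fold_change()] is used).
#' @export
sampling_ranges <- function(G_range = c(1, 100),
                            k_range = c(0.1, 1),
                            n_support = 1:6,
                            lambda_range = c(1, 100),
                            mu_lo_frac = 0.02,
                            mu_hi_frac = 1.98,
                            threshold_rule = c("calibrated",
                                               "half_functional",
                                               "half_functional_uniform",
                                               "median"),
                            threshold_mc = 20000,
                            calibration_models = 500,
                            calibration_inits = 60,
                            calibration_iters = 6) {
  threshold_rule <- match.arg(threshold_rule)
  stopifnot(
    length(G_range) == 2L, all(G_range > 0), G_range[1] <= G_range[2],
    length(k_range) == 2L, all(k_range > 0), k_range[1] <= k_range[2],
    length(n_support) >= 1L, all(n_support >= 1L),
    length(lambda_range) == 2L, all(lambda_range > 0),
    lambda_range[1] <= lambda_range[2],
    mu_lo_frac > 0, mu_hi_frac >= mu_lo_frac
  )
  structure(
    list(
      G_range = as.numeric(G_range), k_range = as.numeric(k_range),
      n_support = as.integer(n_support),
      lambda_range = as.numeric(lambda_range),
      mu_lo_frac = mu_lo_frac, mu_hi_frac = mu_hi_frac,
      threshold_rule = threshold_rule, threshold_mc = threshold_mc,
      calibration_models = calibration_models,
      calibration_inits = calibration_inits,
      calibration_iters = calibration_iters,
      G_fold = numeric(0)
    ),
    class = "sampling_ranges"
  )
}

#' Define a node perturbation
#'
#' A fold-change perturbation of one node's production-rate sampling range:
#' `fold = 10` is a 10-fold over-expression (oe10), `fold = 0.1` a 10-fold
#' down-expression (de10).
#'
#' @param node Node name.
#' @param fold Positive scalar multiplier of the node's G sampling range.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(node, fold) {
  stopifnot(is.character(node), length(node) == 1L,
            is.numeric(fold), length(fold) == 1L, fold > 0)
  structure(list(node = node, fold = fold), class = "perturbation")
}

#' Apply a fold-change perturbation to sampling ranges
#'
#' Multiplies both endpoints of the named node's maximal-production sampling
#' range by `fold`; all other ranges are unchanged. Threshold calibration
#' (the reference level M) always uses the unperturbed ranges, so a
#' perturbation shifts production only.
#'
#' @param ranges A `sampling_ranges`.
#' @param pert A [perturbation()].
#' @param topo Optional `circuit_topology`; if supplied, the perturbed node
#'   must be one of its nodes.
#' @return A new `sampling_ranges` with the fold recorded in `G_fold`.
#' @export
apply_fold_change <- function(ranges, pert, topo = NULL) {
  stopifnot(inherits(ranges, "sampling_ranges"), inherits(pert, "perturbation"))
  if (!is.null(topo) && !pert$node %in% topo$nodes) {
    stop("perturbation names unknown node '", pert$node, "'")
  }
  prev <- if (pert$node %in% names(ranges$G_fold)) ranges$G_fold[[pert$node]] else 1
  ranges$G_fold[[pert$node]] <- prev * pert$fold
  ranges
}

.node_G_range <- function(ranges, node) {
  fold <- if (node %in% names(ranges$G_fold)) ranges$G_fold[[node]] else 1
  ranges$G_range * fold
}

#' Per-node reference levels for threshold calibration
#'
#' Returns the reference level M of every node, used to center the
#' threshold sampling range `U[0.02 M, 1.98 M]` of any link leaving that
#' node. Under the default `"half_functional"` rule, M is the median over a
#' Monte Carlo of `(G/k) * prod(f_e)` with `G ~ U(G range)`,
#' `k ~ U(k range)` and, for each of the node's incoming links, a Hill
#' factor `f_e` drawn uniformly on `[1/lambda_e, 1]` with
#' `lambda_e ~ U(lambda range)` — the node's plausible level given that its
#' regulators may be anywhere between silent and saturating. Under
#' `"median"`, M is `median(G range)/median(k range)` for every node.
#'
#' Always computed from the unperturbed reference ranges (fold-change
#' perturbations shift production, not thresholds) with an internal fixed
#' RNG substream, so the result is a pure function of topology and ranges.
#'
#' @param topo A `circuit_topology`.
#' @param ranges A [sampling_ranges()].
#' @return Named numeric vector of reference levels, one per node.
#' @export
threshold_reference_levels <- function(topo, ranges = sampling_ranges()) {
  M0 <- median(ranges$G_range) / median(ranges$k_range)
  if (ranges$threshold_rule == "median") {
    return(setNames(rep(M0, length(topo$nodes)), topo$nodes))
  }
  if (ranges$threshold_rule == "calibrated") {
    key <- .calibration_key(topo, ranges)
    cached <- .calibration_cache[[key]]
    if (!is.null(cached)) return(cached)
  }
  # isolate from the caller's RNG stream
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(193939L)
  M <- .mc_reference_levels(topo, ranges)
  if (ranges$threshold_rule == "calibrated") {
    M <- .calibrate_reference_levels(topo, ranges, M)
    .calibration_cache[[.calibration_key(topo, ranges)]] <- M
  }
  M
}

.calibration_cache <- new.env(parent = emptyenv())

.calibration_key <- function(topo, ranges) {
  r <- ranges[setdiff(names(ranges), "G_fold")]
  paste(paste(topo$nodes, collapse = ","),
        paste(topo$edges$source, topo$edges$target, topo$edges$sign,
              collapse = ";"),
        paste(unlist(r), collapse = ","), sep = "|")
}

# Monte-Carlo estimate of each node's median level over the kinetic ranges.
.mc_reference_levels <- function(topo, ranges) {
  indeg <- vapply(topo$nodes, function(nd) sum(topo$edges$target == nd), 0L)
  mc <- ranges$threshold_mc
  binary <- ranges$threshold_rule %in% c("half_functional", "calibrated")
  M <- setNames(numeric(length(topo$nodes)), topo$nodes)
  for (i in seq_along(topo$nodes)) {
    lev <- runif(mc, ranges$G_range[1], ranges$G_range[2]) /
      runif(mc, ranges$k_range[1], ranges$k_range[2])
    if (indeg[i] > 0) {
      for (e in seq_len(indeg[i])) {
        lam <- runif(mc, ranges$lambda_range[1], ranges$lambda_range[2])
        lev <- lev * if (binary) {
          # regulator above or below its own threshold with equal odds
          ifelse(runif(mc) < 0.5, 1, 1 / lam)
        } else {
          1 / lam + runif(mc) * (1 - 1 / lam)
        }
      }
    }
    M[i] <- median(lev)
  }
  M
}

# Damped fixed-point iteration: simulate a pilot ensemble with the current
# M, move M half-way (log scale) toward the log-scale center of the realized
# per-node level distribution. For the strongly bimodal levels this circuit
# produces, the log center sits in the valley between the off and on modes
# (where a threshold discriminates the two states), whereas the plain median
# sits on whichever mode holds >50% of the mass and makes the fixed point
# oscillate. Runs inside the isolated RNG stream set up by the caller.
.calibrate_reference_levels <- function(topo, ranges, M) {
  for (it in seq_len(ranges$calibration_iters)) {
    set.seed(193939L + it)
    sols <- vector("list", ranges$calibration_models)
    for (m in seq_len(ranges$calibration_models)) {
      p <- sample_parameter_set(topo, ranges, ref_levels = M)
      ics <- sample_initial_conditions(p, topo, ranges$calibration_inits)
      res <- find_steady_states(p, topo, ics)
      if (res$n_states > 0) sols[[m]] <- res$states
    }
    lev <- do.call(rbind, sols)
    ctr <- apply(lev, 2, function(x) 2^mean(log2(x)))
    M <- exp((log(M) + log(ctr)) / 2)
  }
  M
}

#' Sample one random kinetic parameterization
#'
#' Draws a full parameter set for a circuit: per node, maximal production
#' `G ~ U(G range)` (fold-scaled if perturbed) and degradation
#' `k ~ U(k range)`; per edge, Hill coefficient `n` uniform on its integer
#' support, fold change `lambda ~ U(lambda range)` for activations and
#' `1/U(lambda range)` for inhibitions, and threshold
#' `mu ~ U[0.02 M, 1.98 M]` with M the source node's reference level (see
#' [threshold_reference_levels()]). The
#' basal production rate is derived as `g = G / prod(lambda)` over incoming
#' activating edges, so G is the production rate with all activators
#' saturated and all inhibitors silent.
#'
#' Draws consume the current R RNG stream; call `set.seed()` upstream for
#' reproducibility.
#'
#' @param topo A `circuit_topology`.
#' @param ranges A `sampling_ranges`.
#' @param perturbations List of [perturbation()] objects applied to `ranges`
#'   before sampling.
#' @param ref_levels Optional precomputed [threshold_reference_levels()]
#'   (computed on the fly otherwise; precompute when sampling many models).
#' @return An object of class `model_params`: list with numeric vectors `G`,
#'   `g`, `k` (named by node) and a data frame `edges` with per-edge
#'   `lambda`, `mu`, `n` alongside `source`, `target`, `sign`.
#' @export
sample_parameter_set <- function(topo, ranges = sampling_ranges(),
                                 perturbations = list(), ref_levels = NULL) {
  if (is.null(ref_levels)) ref_levels <- threshold_reference_levels(topo, ranges)
  for (p in perturbations) ranges <- apply_fold_change(ranges, p, topo)
  nn <- length(topo$nodes)
  G <- numeric(nn)
  for (i in seq_len(nn)) {
    gr <- .node_G_range(ranges, topo$nodes[i])
    G[i] <- runif(1, gr[1], gr[2])
  }
  k <- runif(nn, ranges$k_range[1], ranges$k_range[2])
  names(G) <- names(k) <- topo$nodes

  ne <- nrow(topo$edges)
  lambda <- mu <- numeric(ne)
  nhill <- integer(ne)
  for (e in seq_len(ne)) {
    lam_raw <- runif(1, ranges$lambda_range[1], ranges$lambda_range[2])
    lambda[e] <- if (topo$edges$sign[e] == "activation") lam_raw else 1 / lam_raw
    nhill[e] <- ranges$n_support[
      if (length(ranges$n_support) == 1L) 1L
      else sample.int(length(ranges$n_support), 1L)
    ]
    M <- ref_levels[[topo$edges$source[e]]]
    mu[e] <- runif(1, ranges$mu_lo_frac * M, ranges$mu_hi_frac * M)
  }
  edges <- topo$edges
  edges$lambda <- lambda
  edges$mu <- mu
  edges$n <- nhill

  g <- G
  for (i in seq_len(nn)) {
    act_in <- which(edges$target == topo$nodes[i] & edges$sign == "activation")
    if (length(act_in) > 0L) g[i] <- G[i] / prod(lambda[act_in])
  }
  structure(
    list(G = G, g = g, k = k, edges = edges, circuit = topo$name),
    class = "model_params"
  )
}

# Per-node bounds of the reachable steady-state levels:
# upper U = G/k (all activators saturated, inhibitors off);
# lower L = (G / prod(lambda+)) * prod(lambda-) / k (the opposite).
.state_bounds <- function(params, topo) {
  nn <- length(topo$nodes)
  L <- U <- numeric(nn)
  for (i in seq_len(nn)) {
    node <- topo$nodes[i]
    inc <- which(params$edges$target == node)
    lam <- params$edges$lambda[inc]
    act <- params$edges$sign[inc] == "activation"
    U[i] <- params$G[i] / params$k[i]
    L[i] <- params$g[i] * prod(lam[!act]) / params$k[i]
  }
  names(L) <- names(U) <- topo$nodes
  list(lower = L, upper = U)
}

#' Sample random initial conditions for one model
#'
#' Each node's initial level is drawn log-uniformly between the smallest
#' possible steady state (activators off, inhibitors maximally active) and
#' the largest possible steady state (`G/k`). A node with no incoming edges
#' has both bounds equal to `G/k` and always starts there.
#'
#' @param params A `model_params`.
#' @param topo The `circuit_topology` the parameters were sampled for.
#' @param count Number of initial conditions (rows).
#' @return Numeric matrix `count x n_nodes`, columns named by node.
#' @export
sample_initial_conditions <- function(params, topo, count) {
  stopifnot(count >= 1)
  b <- .state_bounds(params, topo)
  logL <- log(b$lower)
  logU <- log(b$upper)
  nn <- length(topo$nodes)
  u <- matrix(runif(count * nn), nrow = count)
  ics <- exp(sweep(sweep(u, 2, logU - logL, `*`), 2, logL, `+`))
  colnames(ics) <- topo$nodes
  ics
}
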