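# ODE model and steady-state enumeration.
#
# Node i with incoming regulators {A} follows
#   dp_i/dt = g_i * prod_{j in A} HS(p_j, mu_ji, lambda_ji, n_ji) - k_i p_i
# where HS is the shifted Hill function. Steady states are enumerated by
# integrating from many random initial conditions, polishing endpoints with
# Newton's method, filtering out saddles by the Jacobian spectrum, and
# merging duplicates in log2 space.

#' Shifted Hill regulatory response
#'
#' `HS(p) = mu^n / (mu^n + p^n) + lambda * p^n / (mu^n + p^n)`: equals 1 with
#' no regulator (`p = 0`), crosses `(1 + lambda)/2` at `p = mu`, and
#' saturates at the fold change `lambda` (`> 1` activation, `< 1`
#' inhibition). Vectorized over `p`.
#'
#' @param p Regulator level(s), non-negative.
#' @param mu Threshold, positive.
#' @param lambda Fold change, positive.
#' @param n Hill coefficient, integer >= 1.
#' @return Dimensionless response factor(s) in `[min(1, lambda), max(1, lambda)]`.
#' @export
shifted_hill <- function(p, mu, lambda, n) {
  if (any(mu <= 0)) stop("shifted_hill: threshold mu must be positive")
  stopifnot(all(p >= 0), all(lambda > 0), all(n >= 1))
  r <- (p / mu)^n
  out <- (1 + lambda * r) / (1 + r)
  out[is.infinite(r)] <- lambda
  out
}

#' Right-hand side of the circuit ODE system
#'
#' @param state Named (or topology-ordered) numeric state vector, positive.
#' @param params A `model_params`.
#' @param topo The matching `circuit_topology`.
#' @return Numeric derivative vector in topology node order.
#' @export
circuit_rhs <- function(state, params, topo) {
  nn <- length(topo$nodes)
  if (length(state) != nn) {
    stop("state vector length ", length(state), " != node count ", nn)
  }
  if (!is.null(names(state))) state <- state[topo$nodes]
  prod <- params$g
  ed <- params$edges
  idx <- .node_index(topo)
  for (e in seq_len(nrow(ed))) {
    prod[idx[ed$target[e]]] <- prod[idx[ed$target[e]]] *
      shifted_hill(state[idx[ed$source[e]]], ed$mu[e], ed$lambda[e], ed$n[e])
  }
  unname(prod - params$k * state)
}

#' Solver configuration for steady-state search
#'
#' @param rtol Relative tolerance of the adaptive integrator.
#' @param conv_tol Scale-free convergence criterion:
#'   `max_i |dp_i/dt| / (k_i |p_i|) < conv_tol` at the endpoint.
#' @param dedup_log2 Two states are merged when all node levels agree within
#'   this tolerance in log2 space.
#' @param stab_tol Endpoints with any Jacobian eigenvalue real part above
#'   this are discarded as saddles.
#' @param tmax_factor Integration time budget `tmax_factor / min(k)`.
#' @return List of solver settings.
#' @export
solver_config <- function(rtol = 1e-6, conv_tol = 1e-6, dedup_log2 = 0.05,
                          stab_tol = 1e-8, tmax_factor = 200) {
  list(rtol = rtol, conv_tol = conv_tol, dedup_log2 = dedup_log2,
       stab_tol = stab_tol, tmax_factor = tmax_factor)
}

#' Find the distinct stable steady states of one model
#'
#' Integrates every initial condition to convergence, Newton-polishes the
#' endpoints, discards saddles, and deduplicates.
#'
#' @param params A `model_params`.
#' @param topo The matching `circuit_topology`.
#' @param ics Matrix of initial conditions (rows), e.g. from
#'   [sample_initial_conditions()].
#' @param config A [solver_config()].
#' @return An object of class `steady_state_result`: list with `states`
#'   (matrix, one row per distinct stable state, columns named by node),
#'   `n_states`, `conv_frac` (fraction of initial conditions meeting the
#'   convergence criterion) and `degenerate` (TRUE if nothing converged).
#' @export
find_steady_states <- function(params, topo, ics, config = solver_config()) {
  if (is.null(dim(ics))) ics <- matrix(ics, nrow = 1)
  stopifnot(nrow(ics) >= 1, ncol(ics) == length(topo$nodes))
  ei <- .edge_indices(topo)
  b <- .state_bounds(params, topo)
  tmax <- config$tmax_factor / min(params$k)
  res <- .cpp_find_states(
    unname(params$g), unname(params$k),
    ei$src - 1L, ei$tgt - 1L,
    params$edges$lambda, params$edges$mu, as.integer(params$edges$n),
    ics, unname(b$upper),
    config$rtol, config$conv_tol, config$dedup_log2, config$stab_tol, tmax
  )
  states <- res$states
  colnames(states) <- topo$nodes
  structure(
    list(states = states, n_states = nrow(states),
         conv_frac = res$conv_frac, degenerate = res$n_converged == 0L),
    class = "steady_state_result"
  )
}

#' Label a model by its number of coexisting stable states
#'
#' @param result A `steady_state_result`, or an integer state count.
#' @return One of `"monostable"`, `"bistable"`, `"tristable"`,
#'   `"quadrastable+"`.
#' @export
classify_multistability <- function(result) {
  n <- if (inherits(result, "steady_state_result")) result$n_states else result
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("classify_multistability: need at least one distinct state")
  }
  if (n <= 3L) c("monostable", "bistable", "tristable")[n] else "quadrastable+"
}

#' Simulate a random-parameter ensemble of one circuit
#'
#' Samples `n_models` kinetic parameterizations, solves each from `n_inits`
#' log-uniform initial conditions, and pools all distinct stable states.
#' Deterministic given `seed`.
#'
#' @param topo A `circuit_topology`.
#' @param ranges A [sampling_ranges()].
#' @param n_models Number of random parameter sets.
#' @param n_inits Initial conditions per parameter set.
#' @param perturbations List of [perturbation()] objects.
#' @param seed Integer seed for the replicate's RNG stream.
#' @param config A [solver_config()].
#' @return An object of class `ensemble_result`: list with
#'   \describe{
#'     \item{solutions}{data frame, one row per distinct stable state:
#'       `model_id`, `n_states`, then one column per node (linear scale).}
#'     \item{models}{data frame of per-model summaries: `model_id`,
#'       `n_states`, `conv_frac`, `degenerate`.}
#'     \item{node_params}{data frame `model_id`, `node`, `G`, `g`, `k`.}
#'     \item{edge_params}{data frame `model_id`, `source`, `target`, `sign`,
#'       `lambda`, `mu`, `n`.}
#'     \item{circuit, seed, n_models, n_inits}{provenance.}
#'   }
#' @export
run_ensemble <- function(topo, ranges = sampling_ranges(), n_models = 1000,
                         n_inits = 100, perturbations = list(), seed = 1,
                         config = solver_config()) {
  stopifnot(n_models >= 1, n_inits >= 1)
  ref_levels <- threshold_reference_levels(topo, ranges)
  set.seed(as.integer(seed))
  nn <- length(topo$nodes)
  sol_chunks <- vector("list", n_models)
  n_states <- integer(n_models)
  conv_frac <- numeric(n_models)
  degenerate <- logical(n_models)
  G_mat <- g_mat <- k_mat <- matrix(NA_real_, n_models, nn,
                                    dimnames = list(NULL, topo$nodes))
  ne <- nrow(topo$edges)
  lam_mat <- mu_mat <- matrix(NA_real_, n_models, ne)
  nh_mat <- matrix(NA_integer_, n_models, ne)

  for (m in seq_len(n_models)) {
    params <- sample_parameter_set(topo, ranges, perturbations, ref_levels)
    ics <- sample_initial_conditions(params, topo, n_inits)
    res <- find_steady_states(params, topo, ics, config)
    G_mat[m, ] <- params$G
    g_mat[m, ] <- params$g
    k_mat[m, ] <- params$k
    lam_mat[m, ] <- params$edges$lambda
    mu_mat[m, ] <- params$edges$mu
    nh_mat[m, ] <- params$edges$n
    n_states[m] <- res$n_states
    conv_frac[m] <- res$conv_frac
    degenerate[m] <- res$degenerate
    if (res$n_states > 0L) {
      sol_chunks[[m]] <- cbind(model_id = m, n_states = res$n_states,
                               res$states)
    }
  }
  sol <- do.call(rbind, sol_chunks)
  solutions <- as.data.frame(sol)
  models <- data.frame(model_id = seq_len(n_models), n_states = n_states,
                       conv_frac = conv_frac, degenerate = degenerate)
  node_params <- data.frame(
    model_id = rep(seq_len(n_models), each = nn),
    node = rep(topo$nodes, times = n_models),
    G = as.vector(t(G_mat)), g = as.vector(t(g_mat)), k = as.vector(t(k_mat))
  )
  edge_params <- data.frame(
    model_id = rep(seq_len(n_models), each = ne),
    source = rep(topo$edges$source, times = n_models),
    target = rep(topo$edges$target, times = n_models),
    sign = rep(topo$edges$sign, times = n_models),
    lambda = as.vector(t(lam_mat)), mu = as.vector(t(mu_mat)),
    n = as.vector(t(nh_mat))
  )
  structure(
    list(solutions = solutions, models = models, node_params = node_params,
         edge_params = edge_params, circuit = topo$name, nodes = topo$nodes,
         seed = seed, n_models = n_models, n_inits = n_inits),
    class = "ensemble_result"
  )
}

#' Multistability composition of an ensemble
#'
#' Fractions of non-degenerate parameter sets that are monostable, bistable,
#' tristable, or higher, which sum to 1.
#'
#' @param ensemble An `ensemble_result` (or its `models` data frame).
#' @return Named numeric vector of fractions.
#' @export
multistability_fractions <- function(ensemble) {
  models <- if (inherits(ensemble, "ensemble_result")) ensemble$models else ensemble
  ok <- !models$degenerate & models$n_states >= 1L
  n <- models$n_states[ok]
  lab <- ifelse(n == 1L, "monostable",
         ifelse(n == 2L, "bistable",
         ifelse(n == 3L, "tristable", "quadrastable+")))
  lab <- factor(lab, levels = c("monostable", "bistable", "tristable",
                                "quadrastable+"))
  fr <- as.vector(table(lab)) / length(n)
  setNames(fr, levels(lab))
}
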