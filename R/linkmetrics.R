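# Parameter-level (expression-free) link potency metrics.
#
# The strength of an edge j -> i is l = lambda_eff * (G_j/k_j) / mu, with
# lambda_eff = lambda for an activation and 1/lambda for an inhibition: the
# threshold mu is normalized by G/k of the SOURCE node, its maximum possible
# steady-state level. A link with lambda_eff = 1 and mu = G/k has l = 1.
# For a two-edge feedback loop, asymmetry = log2(l1/l2) and coupling
# strength = log2(l1) + log2(l2); the pair (asymmetry, coupling) is an
# invertible transform of (log2 l1, log2 l2).

#' Effective strength of one regulatory link
#'
#' @param params A `model_params`.
#' @param source,target Node names identifying the edge.
#' @return List of class `link_strength` with `l`, `log2_l`, `source`,
#'   `target`, `sign`.
#' @export
link_strength <- function(params, source, target) {
  e <- which(params$edges$source == source & params$edges$target == target)
  if (length(e) != 1L) stop("edge ", source, " -> ", target, " not in model")
  lam <- params$edges$lambda[e]
  mu <- params$edges$mu[e]
  if (mu <= 0) stop("link_strength: threshold mu must be positive")
  lam_eff <- if (params$edges$sign[e] == "activation") lam else 1 / lam
  l <- lam_eff * (params$G[[source]] / params$k[[source]]) / mu
  structure(list(l = l, log2_l = log2(l), source = source, target = target,
                 sign = params$edges$sign[e]),
            class = "link_strength")
}

.strength_value <- function(x) if (inherits(x, "link_strength")) x$l else x

#' Asymmetry of a two-link feedback loop
#'
#' `log2(l1 / l2)`; antisymmetric under swapping the two links.
#'
#' @param l1,l2 `link_strength` objects or positive scalars.
#' @return Signed log2 ratio.
#' @export
loop_asymmetry <- function(l1, l2) {
  a <- .strength_value(l1)
  b <- .strength_value(l2)
  stopifnot(a > 0, b > 0)
  log2(a / b)
}

#' Combined coupling strength of two links
#'
#' `log2(l1) + log2(l2)`; symmetric in its arguments.
#'
#' @param l1,l2 `link_strength` objects or positive scalars.
#' @return Scalar combined strength.
#' @export
coupling_strength <- function(l1, l2) {
  a <- .strength_value(l1)
  b <- .strength_value(l2)
  stopifnot(a > 0, b > 0)
  log2(a) + log2(b)
}

# Vectorized per-model link strengths from an ensemble's parameter tables.
.ensemble_link_strength <- function(ensemble, source, target) {
  ep <- ensemble$edge_params
  sel <- ep$source == source & ep$target == target
  if (!any(sel)) stop("edge ", source, " -> ", target, " not in ensemble circuit")
  ep <- ep[sel, ]
  np <- ensemble$node_params
  np <- np[np$node == source, ]
  stopifnot(all(ep$model_id == np$model_id))
  lam_eff <- ifelse(ep$sign == "activation", ep$lambda, 1 / ep$lambda)
  data.frame(model_id = ep$model_id, l = lam_eff * (np$G / np$k) / ep$mu)
}

#' Link-metric distributions by phenotype
#'
#' Computes a per-model link metric for an edge pair — `"coupling"`
#' (log2 l1 + log2 l2) or `"asymmetry"` (log2 l1/l2) — attaches it to every
#' solution of that model, and summarizes its distribution per phenotype
#' with pairwise two-sided rank-sum tests (Holm-adjusted).
#'
#' @param ensemble An `ensemble_result`.
#' @param labels Phenotype label per row of `ensemble$solutions`.
#' @param edge1,edge2 Length-2 character vectors `c(source, target)`.
#' @param metric `"coupling"` or `"asymmetry"`.
#' @return List with `values` (data frame `model_id`, `phenotype`, `value`),
#'   `medians` (named numeric per phenotype), `tests` (data frame of
#'   pairwise comparisons with raw and Holm-adjusted p-values).
#' @export
strength_by_phenotype <- function(ensemble, labels, edge1, edge2,
                                  metric = c("coupling", "asymmetry")) {
  metric <- match.arg(metric)
  stopifnot(length(labels) == nrow(ensemble$solutions))
  s1 <- .ensemble_link_strength(ensemble, edge1[1], edge1[2])
  s2 <- .ensemble_link_strength(ensemble, edge2[1], edge2[2])
  val <- if (metric == "coupling") log2(s1$l) + log2(s2$l) else log2(s1$l / s2$l)
  per_model <- setNames(val, s1$model_id)
  values <- data.frame(
    model_id = ensemble$solutions$model_id,
    phenotype = as.character(labels),
    value = unname(per_model[as.character(ensemble$solutions$model_id)])
  )
  present <- names(which(table(values$phenotype) > 0))
  lev <- intersect(c(.phenotype_levels, sort(unique(values$phenotype))), present)
  medians <- vapply(lev, function(ph) median(values$value[values$phenotype == ph]), 0)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- values$value[values$phenotype == pr[1]]
    b <- values$value[values$phenotype == pr[2]]
    t <- rank_sum_test(a, b)
    data.frame(group1 = pr[1], group2 = pr[2], statistic = t$statistic,
               p_value = t$p_value, median_diff = t$median_diff)
  }))
  tests$p_adjusted <- holm_adjust(tests$p_value)
  list(values = values, medians = medians, tests = tests)
}
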