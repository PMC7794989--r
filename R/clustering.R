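# Gene-wise normalization, phenotype clustering, PCA, and phase labels.

.core_nodes <- c("miR200", "ZEB", "LIN28", "let7")
.phenotype_levels <- c("e", "he", "hm", "m")

#' Gene-wise normalization of steady-state solutions
#'
#' Normalizes every node column to z scores in log2 space against a
#' reference ensemble:
#' `z_i = (log2 p_i - mean(log2 p_ref_i)) / sd(log2 p_ref_i)`.
#' The reference is the unperturbed circuit; perturbed ensembles are
#' normalized against the unperturbed run's statistics so that z values are
#' comparable across perturbations.
#'
#' @param solutions Data frame with one column per node (linear scale,
#'   strictly positive); extra columns (`model_id`, ...) pass through.
#' @param reference Either a data frame of reference solutions with the same
#'   node columns, or precomputed statistics from [normalization_stats()].
#' @param nodes Node columns to normalize; defaults to the intersection of
#'   the reference nodes and `solutions` columns.
#' @return Data frame like `solutions` with node columns replaced by z
#'   scores; the reference statistics attached as attribute `"norm_stats"`.
#' @export
normalize_solutions <- function(solutions, reference, nodes = NULL) {
  stats <- if (is.data.frame(reference)) {
    normalization_stats(reference, nodes = nodes %||% intersect(colnames(reference),
                                                                colnames(solutions)))
  } else {
    reference
  }
  nodes <- names(stats$mean)
  out <- solutions
  for (nd in nodes) {
    if (!nd %in% colnames(out)) next
    p <- out[[nd]]
    if (any(p <= 0)) stop("normalize_solutions: non-positive level in node ", nd)
    out[[nd]] <- (log2(p) - stats$mean[[nd]]) / stats$sd[[nd]]
  }
  attr(out, "norm_stats") <- stats
  out
}

#' Reference statistics for gene-wise normalization
#'
#' Mean and SD of log2 levels per node, computed once per replicate from the
#' unperturbed circuit and reused for its perturbed variants.
#'
#' @param reference Data frame of reference solutions (linear scale).
#' @param nodes Node columns to summarize.
#' @return List with named numeric vectors `mean` and `sd`.
#' @export
normalization_stats <- function(reference, nodes) {
  stopifnot(nrow(reference) > 0, length(nodes) > 0)
  mu <- sdv <- setNames(numeric(length(nodes)), nodes)
  for (nd in nodes) {
    p <- reference[[nd]]
    if (is.null(p)) stop("normalization_stats: reference lacks node ", nd)
    if (any(p <= 0)) stop("normalization_stats: non-positive level in node ", nd)
    lp <- log2(p)
    mu[[nd]] <- mean(lp)
    sdv[[nd]] <- sd(lp)
    if (!is.finite(sdv[[nd]]) || sdv[[nd]] == 0) {
      stop("normalization_stats: zero reference variance for node ", nd)
    }
  }
  list(mean = mu, sd = sdv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Order cluster indices by ascending median ZEB (tie: descending median
# miR-200), returning a permutation old index -> rank.
.order_clusters_by_zeb <- function(z_zeb, z_mir, cl, k) {
  med_zeb <- vapply(seq_len(k), function(i) median(z_zeb[cl == i]), 0)
  med_mir <- vapply(seq_len(k), function(i) median(z_mir[cl == i]), 0)
  order(med_zeb, -med_mir)
}

#' K-means phenotype assignment
#'
#' Partitions normalized solutions by K-means on the four core nodes only
#' (miR-200, ZEB, LIN28, let-7; SNAIL, NF-kB and PSF nodes are excluded as
#' features), keeping the best of `restarts` random initializations. At
#' `k = 4` clusters are named by ascending cluster-median ZEB: `e < he < hm
#' < m` (ties broken by descending median miR-200); for other `k` the labels
#' are `c1 < c2 < ...` in the same order.
#'
#' @param tbl Normalized solution table (z scores) containing the core-node
#'   columns.
#' @param k Number of clusters, >= 2.
#' @param restarts Random initializations; the lowest-inertia fit is kept.
#' @param seed Integer seed (K-means initialization is stochastic).
#' @return An object of class `phenotype_assignment`: list with `labels`
#'   (factor, one per row of `tbl`), `centers` (matrix, rows in label
#'   order), `inertia` (total within-cluster sum of squares), `k`,
#'   `features`.
#' @export
kmeans_phenotypes <- function(tbl, k = 4, restarts = 10, seed = 1) {
  stopifnot(k >= 2)
  feats <- .core_nodes
  missing <- setdiff(feats, colnames(tbl))
  if (length(missing) > 0) {
    stop("kmeans_phenotypes: missing core node column(s): ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(tbl[, feats])
  if (k > nrow(unique(X))) stop("kmeans_phenotypes: k exceeds distinct rows")
  set.seed(as.integer(seed))
  km <- kmeans(X, centers = k, nstart = restarts, iter.max = 100)
  perm <- .order_clusters_by_zeb(X[, "ZEB"], X[, "miR200"], km$cluster, k)
  rank_of <- integer(k)
  rank_of[perm] <- seq_len(k)
  lev <- if (k == 4) .phenotype_levels else paste0("c", seq_len(k))
  labels <- factor(lev[rank_of[km$cluster]], levels = lev)
  centers <- km$centers[perm, , drop = FALSE]
  rownames(centers) <- lev
  structure(
    list(labels = labels, centers = centers, inertia = km$tot.withinss,
         k = k, features = feats),
    class = "phenotype_assignment"
  )
}

# Calinski-Harabasz: (SSB/(k-1)) / (SSW/(n-k))
.calinski_harabasz <- function(X, cl) {
  k <- length(unique(cl))
  n <- nrow(X)
  gm <- colMeans(X)
  ssb <- 0
  ssw <- 0
  for (i in unique(cl)) {
    Xi <- X[cl == i, , drop = FALSE]
    ci <- colMeans(Xi)
    ssb <- ssb + nrow(Xi) * sum((ci - gm)^2)
    ssw <- ssw + sum(sweep(Xi, 2, ci)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Davies-Bouldin: mean over clusters of max_j (s_i + s_j) / d_ij
.davies_bouldin <- function(X, cl) {
  ids <- sort(unique(cl))
  k <- length(ids)
  cent <- t(vapply(ids, function(i) colMeans(X[cl == i, , drop = FALSE]),
                   numeric(ncol(X))))
  s <- vapply(seq_len(k), function(i) {
    Xi <- X[cl == ids[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2, cent[i, ])^2)))
  }, 0)
  db <- 0
  for (i in seq_len(k)) {
    ratio <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      ratio <- max(ratio, (s[i] + s[j]) / d)
    }
    db <- db + ratio
  }
  db / k
}

#' Cluster-count quality sweep
#'
#' Runs K-means over a range of cluster counts and reports, per k: average
#' silhouette width (on a subsample if the table is large), the
#' Calinski-Harabasz and Davies-Bouldin indices, and K-means inertia. The
#' average silhouette width peaking at k = 4 is the primary evidence for
#' four phenotypes.
#'
#' @param tbl Normalized solution table with the core-node columns.
#' @param k_range Integer vector of candidate cluster counts, each >= 2.
#' @param restarts Random initializations per k.
#' @param seed Integer seed.
#' @param silhouette_cap Maximum rows used for the silhouette (random
#'   subsample beyond this; recorded in the output).
#' @return Data frame with columns `k`, `silhouette`, `calinski_harabasz`,
#'   `davies_bouldin`, `inertia`, `silhouette_n`.
#' @export
cluster_quality_sweep <- function(tbl, k_range = 2:8, restarts = 10, seed = 1,
                                  silhouette_cap = 5000) {
  stopifnot(all(k_range >= 2))
  X <- as.matrix(tbl[, .core_nodes])
  set.seed(as.integer(seed))
  sub <- if (nrow(X) > silhouette_cap) {
    sort(sample.int(nrow(X), silhouette_cap))
  } else {
    seq_len(nrow(X))
  }
  dsub <- dist(X[sub, , drop = FALSE])
  out <- data.frame(k = k_range, silhouette = NA_real_,
                    calinski_harabasz = NA_real_, davies_bouldin = NA_real_,
                    inertia = NA_real_, silhouette_n = length(sub))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    km <- kmeans(X, centers = k, nstart = restarts, iter.max = 100)
    sil <- cluster::silhouette(km$cluster[sub], dsub)
    out$silhouette[i] <- mean(sil[, "sil_width"])
    out$calinski_harabasz[i] <- .calinski_harabasz(X, km$cluster)
    out$davies_bouldin[i] <- .davies_bouldin(X, km$cluster)
    out$inertia[i] <- km$tot.withinss
  }
  out
}

#' PCA summary of normalized solutions
#'
#' Principal component analysis over the six base-circuit nodes (or any
#' supplied feature set). The sign of PC1 is fixed so that the ZEB loading
#' is negative, orienting PC1 as an epithelial-to-mesenchymal axis read
#' right to left.
#'
#' @param tbl Normalized solution table.
#' @param nodes Feature columns; defaults to the six base nodes present.
#' @return List with `variance_fraction` (named numeric, sums to 1),
#'   `loadings` (orthonormal columns), `scores`.
#' @export
pca_summary <- function(tbl, nodes = NULL) {
  base6 <- c("miR200", "ZEB", "SNAIL", "LIN28", "let7", "NFkB")
  nodes <- nodes %||% intersect(base6, colnames(tbl))
  X <- as.matrix(tbl[, nodes])
  stopifnot(nrow(X) >= 2)
  const <- apply(X, 2, function(x) sd(x) == 0 || !is.finite(sd(x)))
  if (any(const)) warning("constant column(s): ", paste(nodes[const], collapse = ", "))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  names(vf) <- colnames(pc$rotation)
  if ("ZEB" %in% rownames(pc$rotation) && pc$rotation["ZEB", 1] > 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  list(variance_fraction = vf, loadings = pc$rotation, scores = pc$x)
}

#' Phase labels and frequencies by multistability class
#'
#' A parameter set's phase is the multiset of phenotype labels of its
#' coexisting states, written in canonical order, e.g. `{e,m}` or
#' `{e,he,m}`. Returns phase frequencies within each multistability class.
#'
#' @param labels Factor/character of per-solution phenotype labels.
#' @param model_id Parameter-set id per solution.
#' @param n_states Number of states per solution's parameter set (used to
#'   check completeness).
#' @return List with `phases` (data frame `model_id`, `n_states`, `phase`)
#'   and `frequencies` (data frame `class`, `phase`, `freq`; `freq` sums to
#'   1 within each class).
#' @export
label_phases <- function(labels, model_id, n_states) {
  stopifnot(length(labels) == length(model_id), length(labels) == length(n_states))
  if (anyNA(labels)) stop("label_phases: unlabeled solution(s)")
  ord <- order(model_id)
  labels <- as.character(labels)[ord]
  model_id <- model_id[ord]
  n_states <- n_states[ord]
  lev <- .phenotype_levels
  by_model <- split(labels, model_id)
  ns <- vapply(split(n_states, model_id), `[[`, 0, 1L)
  got <- lengths(by_model)
  if (any(got != ns)) {
    stop("label_phases: parameter set(s) with missing labeled solutions")
  }
  phase <- vapply(by_model, function(x) {
    x <- x[order(match(x, lev))]
    paste0("{", paste(x, collapse = ","), "}")
  }, "")
  phases <- data.frame(model_id = as.integer(names(by_model)),
                       n_states = unname(ns), phase = unname(phase))
  cls <- ifelse(phases$n_states == 1, "monostable",
         ifelse(phases$n_states == 2, "bistable",
         ifelse(phases$n_states == 3, "tristable", "quadrastable+")))
  freq_list <- lapply(split(phases$phase, cls), function(ph) {
    tb <- table(ph)
    data.frame(phase = names(tb), freq = as.vector(tb) / length(ph))
  })
  frequencies <- do.call(rbind, Map(function(cl, df) cbind(class = cl, df),
                                    names(freq_list), freq_list))
  rownames(frequencies) <- NULL
  list(phases = phases, frequencies = frequencies)
}

#' Ward dendrogram cross-check
#'
#' Agglomerative hierarchical clustering (Ward's minimum-variance criterion,
#' `ward.D2` on Euclidean distances) over the core-node features, with the
#' 4-group cut reported for comparison against the K-means partition.
#'
#' @param tbl Normalized solution table with core-node columns.
#' @param max_rows Subsample cap (Ward needs a full dissimilarity matrix).
#' @param seed Seed for the subsample.
#' @param groups Number of groups to cut.
#' @return List with `hclust` (the linkage), `cut` (group per used row),
#'   `rows` (row indices used), `subsampled`.
#' @export
ward_dendrogram <- function(tbl, max_rows = 4000, seed = 1, groups = 4) {
  X <- as.matrix(tbl[, .core_nodes])
  set.seed(as.integer(seed))
  rows <- if (nrow(X) > max_rows) sort(sample.int(nrow(X), max_rows)) else seq_len(nrow(X))
  hc <- hclust(dist(X[rows, , drop = FALSE]), method = "ward.D2")
  list(hclust = hc, cut = cutree(hc, k = groups), rows = rows,
       subsampled = nrow(X) > max_rows)
}

#' Best label agreement between two partitions
#'
#' Maximum fraction of rows on which two partitions agree over all label
#' permutations of the second (feasible for small k).
#'
#' @param a,b Cluster label vectors of equal length (at most 8 distinct
#'   labels in `b`).
#' @return Agreement fraction in `[0, 1]`.
#' @export
partition_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- unclass(table(a, b))
  ka <- nrow(tab)
  kb <- ncol(tab)
  stopifnot(max(ka, kb) <= 8)
  if (ka < kb) {
    tab <- rbind(tab, matrix(0, kb - ka, kb))
    ka <- kb
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(ka))) {
    hit <- sum(tab[cbind(p[seq_len(kb)], seq_len(kb))])
    best <- max(best, hit)
  }
  best / length(a)
}
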