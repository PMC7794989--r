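# LIN28 stemness window and conditional enrichment probabilities.
#
# Intermediate LIN28 (a direct regulator of OCT4) is taken as the stem-like
# readout: the "biological range" is median +/- one interquartile range of
# the pooled LIN28 distribution (median and IQR averaged across replicates),
# and the stemness window is the middle fraction f of that range, centered
# on the median (default f = 0.30).

#' Define the LIN28 stemness window
#'
#' With per-replicate median `m_r` and interquartile range `q_r` of the
#' pooled LIN28 values, and `m`, `q` their across-replicate means, the
#' biological range is `[m - q, m + q]` and the window is
#' `[m - f*q, m + f*q]`.
#'
#' @param lin28 Numeric vector of LIN28 levels (analysis/z scale).
#' @param replicate Replicate id per value (a single replicate if omitted).
#' @param f Window fraction of the biological range, in (0, 1].
#' @return An object of class `stemness_window`: list with `lower`, `upper`,
#'   `median`, `iqr`, `f`.
#' @export
stemness_window <- function(lin28, replicate = NULL, f = 0.30) {
  stopifnot(f > 0, f <= 1, length(lin28) > 0)
  if (is.null(replicate)) replicate <- rep(1L, length(lin28))
  med <- vapply(split(lin28, replicate), median, 0)
  iqr <- vapply(split(lin28, replicate), IQR, 0)
  m <- mean(med)
  q <- mean(iqr)
  if (q == 0) stop("stemness_window: degenerate LIN28 distribution (IQR = 0)")
  structure(
    list(lower = m - f * q, upper = m + f * q, median = m, iqr = q, f = f),
    class = "stemness_window"
  )
}

#' Membership in a stemness window
#'
#' Closed interval: boundary values count as inside.
#'
#' @param lin28 Numeric LIN28 levels.
#' @param window A `stemness_window`.
#' @return Logical vector.
#' @export
in_window <- function(lin28, window) {
  lin28 >= window$lower & lin28 <= window$upper
}

#' Conditional enrichment probabilities p1 and p2
#'
#' For each phenotype c: `p1(c) = P(in window | phenotype c)` — the
#' proportion of that phenotype's solutions lying in the stemness window —
#' and `p2(c) = P(phenotype c | in window)` — that phenotype's share of the
#' in-window pool. Computed per replicate, then summarized as mean +/- SD
#' across replicates. `sum_c p2(c) = 1` within every replicate whose window
#' is occupied.
#'
#' @param labels Phenotype label per solution.
#' @param lin28 LIN28 level per solution (same scale as the window).
#' @param window A [stemness_window()].
#' @param replicate Replicate id per solution (single replicate if omitted).
#' @return List with `per_replicate` (data frame `replicate`, `phenotype`,
#'   `p1`, `p2`, `n`, `n_in_window`) and `summary` (data frame `phenotype`,
#'   `p1_mean`, `p1_sd`, `p2_mean`, `p2_sd`). Replicates with an empty
#'   window get `p2 = NA` and a warning.
#' @export
conditional_probabilities <- function(labels, lin28, window, replicate = NULL) {
  stopifnot(length(labels) == length(lin28))
  if (anyNA(labels)) stop("conditional_probabilities: unlabeled solution(s)")
  if (is.null(replicate)) replicate <- rep(1L, length(labels))
  lev <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  inw <- in_window(lin28, window)
  rows <- list()
  for (r in unique(replicate)) {
    sel <- replicate == r
    n_in <- sum(inw[sel])
    if (n_in == 0) warning("empty stemness window in replicate ", r)
    for (ph in lev) {
      ns <- sum(sel & labels == ph)
      niw <- sum(sel & labels == ph & inw)
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, phenotype = ph,
        p1 = if (ns > 0) niw / ns else NA_real_,
        p2 = if (n_in > 0) niw / n_in else NA_real_,
        n = ns, n_in_window = niw
      )
    }
  }
  per_rep <- do.call(rbind, rows)
  per_rep$phenotype <- factor(per_rep$phenotype, levels = lev)
  agg <- lapply(split(per_rep, per_rep$phenotype), function(d) {
    data.frame(phenotype = d$phenotype[1],
               p1_mean = mean(d$p1, na.rm = TRUE), p1_sd = sd(d$p1),
               p2_mean = mean(d$p2, na.rm = TRUE), p2_sd = sd(d$p2))
  })
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  list(per_replicate = per_rep, summary = summary)
}

#' Window-width sensitivity of the stemness composition
#'
#' Recomputes the window and the enrichment probabilities for a list of
#' window fractions. As f grows past ~1/3 the hybrid share of the window
#' degrades toward the overall phenotype frequencies.
#'
#' @param labels,lin28,replicate As in [conditional_probabilities()].
#' @param f_list Window fractions in (0, 1].
#' @return Data frame with one row per (f, phenotype): `f`, `lower`,
#'   `upper`, `n_in_window`, `phenotype`, `p1`, `p2` (cross-replicate
#'   means).
#' @export
window_sensitivity <- function(labels, lin28, replicate = NULL,
                               f_list = c(0.1, 0.2, 0.3, 1 / 3, 0.4, 0.5,
                                          0.75, 1)) {
  stopifnot(all(f_list > 0), all(f_list <= 1))
  out <- list()
  for (f in f_list) {
    w <- stemness_window(lin28, replicate, f = f)
    cp <- conditional_probabilities(labels, lin28, w, replicate)
    s <- cp$summary
    niw <- sum(cp$per_replicate$n_in_window)
    out[[length(out) + 1]] <- data.frame(
      f = f, lower = w$lower, upper = w$upper, n_in_window = niw,
      phenotype = s$phenotype, p1 = s$p1_mean, p2 = s$p2_mean
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
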