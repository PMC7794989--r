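# Small fixture circuits and hand-built parameter sets used across tests.

# Symmetric two-node toggle switch (mutual inhibition).
toggle_topology <- function() {
  circuit_topology(
    nodes = c("A", "B"),
    edges = data.frame(
      source = c("A", "B"), target = c("B", "A"),
      sign = c("inhibition", "inhibition")
    ),
    name = "toggle"
  )
}

# Hand-built parameter set for a topology: every edge gets the same
# (lambda, mu, n); G is derived from g and incoming activations.
manual_params <- function(topo, g, k, lambda, mu, n) {
  nn <- length(topo$nodes)
  g <- rep_len(g, nn)
  k <- rep_len(k, nn)
  names(g) <- names(k) <- topo$nodes
  edges <- topo$edges
  edges$lambda <- rep_len(lambda, nrow(edges))
  edges$mu <- rep_len(mu, nrow(edges))
  edges$n <- rep_len(n, nrow(edges))
  G <- g
  for (i in seq_len(nn)) {
    act <- which(edges$target == topo$nodes[i] & edges$sign == "activation")
    if (length(act)) G[i] <- g[i] * prod(edges$lambda[act])
  }
  structure(list(G = G, g = g, k = k, edges = edges, circuit = topo$name),
            class = "model_params")
}

# Independent 1-D fixed-point oracle for a symmetric 2-node toggle:
# steady states satisfy p_A = g/k * HS(p_B), p_B = g/k * HS(p_A), so roots
# of f(p) = g/k * HS(g/k * HS(p)) - p enumerate all steady states. With
# F decreasing, the continuous-time Jacobian eigenvalues at a root are
# -k (1 -+ sqrt(g')) for the composed map g = F o F, so the state is stable
# iff g'(root) < 1, i.e. f'(root) < 0. Roots are found by dense sign-change
# scanning + uniroot, nothing shared with the trajectory solver.
toggle_roots <- function(g, k, lambda, mu, n, grid_n = 20000) {
  hs <- function(p) (mu^n + lambda * p^n) / (mu^n + p^n)
  f <- function(p) (g / k) * hs((g / k) * hs(p)) - p
  hi <- g / k
  lo <- g * lambda / k
  ps <- exp(seq(log(lo) - 1, log(hi) + 1, length.out = grid_n))
  fv <- f(ps)
  roots <- c()
  for (i in seq_len(grid_n - 1)) {
    if (sign(fv[i]) != sign(fv[i + 1])) {
      roots <- c(roots, uniroot(f, c(ps[i], ps[i + 1]), tol = 1e-12)$root)
    }
  }
  eps <- 1e-6
  stable <- vapply(roots, function(r) {
    (f(r + eps * r) - f(r - eps * r)) / (2 * eps * r) < 0
  }, TRUE)
  list(all = roots, stable = roots[stable])
}

# Four well-separated Gaussian blobs in the core-node z space; blob centers
# 20x the within-blob SD apart.
blob_table <- function(n_per = 50, sd = 0.05, seed = 99) {
  set.seed(seed)
  centers <- rbind(
    e = c(1, -1, -1, 1),
    he = c(1, -0.33, 1, -1),
    hm = c(-1, 0.33, -1, 1),
    m = c(-1, 1, 1, -1)
  )
  colnames(centers) <- c("miR200", "ZEB", "LIN28", "let7")
  X <- do.call(rbind, lapply(seq_len(4), function(i) {
    sweep(matrix(rnorm(n_per * 4, sd = sd), ncol = 4), 2, centers[i, ], `+`)
  }))
  tbl <- as.data.frame(X)
  colnames(tbl) <- colnames(centers)
  tbl$truth <- rep(rownames(centers), each = n_per)
  tbl
}
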