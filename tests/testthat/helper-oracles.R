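# Independent oracles used across the suite. These deliberately use naive
# path-walking / dense-matrix / exhaustive-loop computations, not the code
# paths they are checking.

# --- phylogeny oracles -----------------------------------------------------

# root-to-node path (vector of edge indices) by walking the edge matrix
.path_to_root <- function(tree, node) {
  n <- length(tree$tip.label)
  root <- n + 1L
  path <- integer(0)
  cur <- node
  while (cur != root) {
    e <- which(tree$edge[, 2] == cur)
    path <- c(path, e)
    cur <- tree$edge[e, 1]
  }
  path
}

# shared path length of two nodes = summed lengths of common root-path edges
oracle_shared_path <- function(tree, a, b) {
  pa <- .path_to_root(tree, a); pb <- .path_to_root(tree, b)
  sum(tree$edge.length[intersect(pa, pb)])
}

oracle_tree_cov <- function(tree) {
  n <- length(tree$tip.label)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    V[i, j] <- if (i == j) sum(tree$edge.length[.path_to_root(tree, i)])
    else oracle_shared_path(tree, i, j)
  }
  V
}

# Blomberg's K evaluated directly from the dense GLS formula
oracle_blomberg_k <- function(tree, x) {
  x <- x[tree$tip.label]
  V <- oracle_tree_cov(tree)
  Vi <- solve(V)
  n <- length(x)
  one <- rep(1, n)
  a <- as.numeric(t(one) %*% Vi %*% x) / as.numeric(t(one) %*% Vi %*% one)
  mse0 <- as.numeric(t(x - a) %*% (x - a)) / (n - 1)
  mse <- as.numeric(t(x - a) %*% Vi %*% (x - a)) / (n - 1)
  expected <- (sum(diag(V)) - n / as.numeric(t(one) %*% Vi %*% one)) / (n - 1)
  (mse0 / mse) / expected
}

# ancestral states by conditioning the joint Gaussian of (nodes, tips) built
# entirely by path walking
oracle_ancestral <- function(tree, x) {
  n <- length(tree$tip.label)
  x <- x[tree$tip.label]
  all_ids <- seq_len(n + tree$Nnode)
  S <- matrix(0, length(all_ids), length(all_ids))
  for (i in all_ids) for (j in all_ids) {
    S[i, j] <- if (i == j) sum(tree$edge.length[.path_to_root(tree, i)])
    else oracle_shared_path(tree, i, j)
  }
  tips <- seq_len(n); nodes <- n + seq_len(tree$Nnode)
  Vtt <- S[tips, tips]; Cnt <- S[nodes, tips]
  Vi <- solve(Vtt)
  one <- rep(1, n)
  a <- as.numeric(t(one) %*% Vi %*% x) / as.numeric(t(one) %*% Vi %*% one)
  anc <- a + Cnt %*% Vi %*% (x - a)
  stats::setNames(as.numeric(anc), nodes)
}

# --- statistical oracles ---------------------------------------------------

# exact two-sided rank-sum p by enumerating all group assignments (no ties)
oracle_wilcox_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  centre <- n1 * n2 / 2
  mean(abs(ws - centre) >= abs(w_obs - centre) - 1e-12)
}

# studentized-range upper tail by direct double quadrature
oracle_tukey_p <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      f <- function(z)
        stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * si))^(k - 1)
      k * stats::integrate(f, -8, 8, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  # density of s = sqrt(chi2_df / df)
  fs <- function(s) 2 * s * df * stats::dchisq(df * s^2, df)
  cdf <- stats::integrate(function(s) fs(s) * inner(s), 0, 10,
                          rel.tol = 1e-8)$value
  1 - cdf
}

# --- spatial oracles -------------------------------------------------------

# greedy constrained-Ward hierarchy recomputed from the pseudo-inertia
# definition at every stage (exhaustive over merge pairs)
oracle_ward_history <- function(D0, D1, alpha, scale = TRUE) {
  n <- nrow(D0)
  if (scale) { D0 <- D0 / max(D0); D1 <- D1 / max(D1) }
  pin <- function(D2, mem)
    if (length(mem) < 2) 0 else sum(D2[mem, mem]) / (2 * length(mem))
  cost <- function(ma, mb)
    (1 - alpha) * (pin(D0^2, c(ma, mb)) - pin(D0^2, ma) - pin(D0^2, mb)) +
    alpha * (pin(D1^2, c(ma, mb)) - pin(D1^2, ma) - pin(D1^2, mb))
  clusters <- as.list(seq_len(n))
  history <- list()
  while (length(clusters) > 1) {
    best <- NULL; bcost <- Inf
    for (a in seq_len(length(clusters) - 1))
      for (b in (a + 1):length(clusters)) {
        d <- cost(clusters[[a]], clusters[[b]])
        if (d < bcost - 1e-12) { bcost <- d; best <- c(a, b) }
      }
    history[[length(history) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  history
}

# member sets per merge from a cluster_solution merge matrix
merge_sets <- function(merge, n) {
  sets <- vector("list", nrow(merge))
  for (m in seq_len(nrow(merge))) {
    a <- merge[m, 1]; b <- merge[m, 2]
    sets[[m]] <- sort(c(if (a < 0) -a else sets[[a]],
                        if (b < 0) -b else sets[[b]]))
  }
  sets
}

# naive mean filter by explicit window loops
oracle_mean_filter <- function(m, window) {
  h <- (window - 1) / 2
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ri <- max(1, i - h):min(nrow(m), i + h)
    rj <- max(1, j - h):min(ncol(m), j + h)
    out[i, j] <- mean(m[ri, rj])
  }
  out
}

# naive MESS by per-cell per-variable loops
oracle_mess <- function(reference, query) {
  vars <- names(reference)
  out <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    scores <- vapply(vars, function(v) {
      ref <- reference[[v]]; p <- query[i, v]
      rmin <- min(ref); rmax <- max(ref)
      f <- 100 * sum(ref < p) / length(ref)
      if (f == 0) 100 * (p - rmin) / (rmax - rmin)
      else if (f <= 50) 2 * f
      else if (f < 100) 2 * (100 - f)
      else 100 * (rmax - p) / (rmax - rmin)
    }, numeric(1))
    out[i] <- min(scores)
  }
  out
}

# empirical semivariogram over distance bins
oracle_semivariogram <- function(g, breaks) {
  xy <- grid_coords(g)
  v <- as.vector(g$values)
  idx <- sample.int(length(v), min(500, length(v)))
  d <- as.matrix(stats::dist(xy[idx, ]))
  sq <- outer(v[idx], v[idx], "-")^2 / 2
  bin <- cut(d[upper.tri(d)], breaks)
  tapply(sq[upper.tri(sq)], bin, mean)
}

# --- shared fixtures -------------------------------------------------------

# tiny fixed trees written as Newick, parsed with ape
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
tree5 <- function() ape::read.tree(
  text = "(((A:0.5,B:0.5):1,C:1.5):0.7,(D:1.2,E:1.2):1);")

small_bundle <- function(seed = 1, n_tips = 25, n_plots = 20,
                         stems_per_plot = 40, cell_size = 200, ...) {
  simulate_bundle(sim_config(seed = seed, n_tips = n_tips,
                             n_plots = n_plots,
                             stems_per_plot = stems_per_plot,
                             cell_size = cell_size, n_sites = 8, ...))
}
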