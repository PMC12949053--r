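#' @keywords internal
.check_dissim <- function(D, name) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) ||
      any(abs(diag(D)) > 1e-12) || any(D < 0))
    stop(name, " must be a symmetric non-negative matrix with zero diagonal",
         call. = FALSE)
  D
}

# Ward pseudo-inertia of one cluster from a squared-dissimilarity matrix
# (uniform unit weights): I(C) = sum_{i<j in C} d^2(i,j) / |C|.
.pseudo_inertia <- function(D2, members) {
  if (length(members) < 2) return(0)
  sum(D2[members, members]) / (2 * length(members))
}

# cut an agglomeration history (hclust-style merge matrix) at k clusters:
# replay the first n - k merges tracking member sets, then label the
# surviving sets and untouched singletons
.cut_merges <- function(merge, n, k) {
  node_sets <- vector("list", nrow(merge))
  for (m in seq_len(n - k)) {
    a <- merge[m, 1]; b <- merge[m, 2]
    sa <- if (a < 0) -a else node_sets[[a]]
    sb <- if (b < 0) -b else node_sets[[b]]
    node_sets[[m]] <- c(sa, sb)
  }
  used <- logical(n)
  cluster <- integer(n); cid <- 0L
  consumed <- rep(FALSE, max(0, n - k))
  for (m in seq_len(n - k)) for (s in merge[m, ])
    if (s > 0 && s <= n - k) consumed[s] <- TRUE
  for (m in seq_len(n - k)) {
    if (!consumed[m]) {
      cid <- cid + 1L
      cluster[node_sets[[m]]] <- cid
      used[node_sets[[m]]] <- TRUE
    }
  }
  for (i in which(!used)) {
    cid <- cid + 1L
    cluster[i] <- cid
  }
  cluster
}

#' Geographically constrained Ward-like hierarchical clustering
#'
#' Agglomerative clustering over two dissimilarity matrices: \code{D0} in
#' feature space and \code{D1} in geographic (constraint) space. At each
#' stage the pair of clusters merged is the one minimising the convex
#' combination \eqn{(1-\alpha)\,\delta_0 + \alpha\,\delta_1} of the Ward
#' pseudo-inertia increments computed from the two matrices
#' (\eqn{\alpha = 0} reduces to plain Ward clustering of \code{D0};
#' \eqn{\alpha = 1} clusters on geography alone). Increments are updated
#' with the Lance-Williams recurrence; the explained pseudo-inertia
#' proportions Q0 and Q1 report, for each space, one minus the ratio of
#' within-cluster to total pseudo-inertia at the chosen cut.
#'
#' @param D0 feature-space dissimilarity matrix (or \code{dist}).
#' @param D1 geographic dissimilarity matrix of the same size.
#' @param alpha mixing fraction in \[0, 1\] (weight of \code{D1}).
#' @param k number of clusters to cut.
#' @param scale logical: divide each matrix by its maximum before mixing so
#'   alpha is comparable across spaces (default TRUE).
#' @return A list of class \code{cluster_solution}: \code{assignment}
#'   (integer vector, names from \code{D0} if present), \code{k},
#'   \code{alpha}, \code{Q0}, \code{Q1}, \code{merge}, \code{height},
#'   \code{sizes}.
#' @export
constrained_ward <- function(D0, D1, alpha, k, scale = TRUE) {
  D0 <- .check_dissim(D0, "D0"); D1 <- .check_dissim(D1, "D1")
  if (!identical(dim(D0), dim(D1)))
    stop("D0 and D1 must have the same size", call. = FALSE)
  stopifnot(alpha >= 0, alpha <= 1, k >= 1, k <= nrow(D0))
  n <- nrow(D0)
  labels <- rownames(D0)
  if (scale) {
    if (max(D0) > 0) D0 <- D0 / max(D0)
    if (max(D1) > 0) D1 <- D1 / max(D1)
  }
  D0sq <- D0^2; D1sq <- D1^2
  # initial Ward merge costs between singletons: delta(i,j) = d^2 / 2
  cost <- ((1 - alpha) * D0sq + alpha * D1sq) / 2
  diag(cost) <- Inf
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  id <- -seq_len(n)                       # hclust-style leaf coding
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- cost[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[min(best)]; j <- idx[max(best)]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    merge[m, ] <- sort(c(id[i], id[j]))
    height[m] <- cost[i, j]
    # Lance-Williams (Ward) update of merge costs against cluster i := i+j
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      newc <- ((ni + nk) * cost[i, others] + (nj + nk) * cost[j, others] -
                 nk * cost[i, j]) / (ni + nj + nk)
      cost[i, others] <- newc; cost[others, i] <- newc
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    cost[j, ] <- Inf; cost[, j] <- Inf
    id[i] <- m
  }
  assign <- .cut_merges(merge, n, k)
  if (!is.null(labels)) names(assign) <- labels
  tot0 <- sum(D0sq) / (2 * n); tot1 <- sum(D1sq) / (2 * n)
  within0 <- sum(vapply(seq_len(k), function(c)
    .pseudo_inertia(D0sq, which(assign == c)), numeric(1)))
  within1 <- sum(vapply(seq_len(k), function(c)
    .pseudo_inertia(D1sq, which(assign == c)), numeric(1)))
  structure(list(assignment = assign, k = k, alpha = alpha,
                 Q0 = if (tot0 > 0) 1 - within0 / tot0 else 1,
                 Q1 = if (tot1 > 0) 1 - within1 / tot1 else 1,
                 merge = merge, height = height,
                 sizes = tabulate(assign, k)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf(
    "constrained Ward: k = %d, alpha = %.2f, Q0 = %.3f, Q1 = %.3f\n",
    x$k, x$alpha, x$Q0, x$Q1))
  cat("  cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Choose the mixing parameter alpha from explained-inertia curves
#'
#' Evaluates the constrained clustering over a grid of alpha values,
#' recording the explained pseudo-inertia in feature space (Q0) and
#' geographic space (Q1) at \code{k} clusters, and returns the largest
#' alpha whose Q0 has not dropped more than \code{q0_tolerance} below the
#' feature-space-only baseline Q0(min(grid)) — i.e. the most spatially
#' contiguous solution that does not deteriorate the feature-space fit.
#' The full curves are returned so the trade-off can be inspected.
#'
#' @inheritParams constrained_ward
#' @param alpha_grid grid of alpha values within \[0, 1\].
#' @param q0_tolerance maximum tolerated drop in Q0.
#' @return A list of class \code{alpha_selection}: \code{alpha},
#'   \code{curves} (data.frame alpha, Q0, Q1), \code{k},
#'   \code{q0_tolerance}.
#' @export
select_alpha <- function(D0, D1, k, alpha_grid = seq(0, 1, by = 0.1),
                         q0_tolerance = 0.1, scale = TRUE) {
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1))
  alpha_grid <- sort(alpha_grid)
  sols <- lapply(alpha_grid, function(a)
    constrained_ward(D0, D1, alpha = a, k = k, scale = scale))
  curves <- data.frame(alpha = alpha_grid,
                       Q0 = vapply(sols, `[[`, numeric(1), "Q0"),
                       Q1 = vapply(sols, `[[`, numeric(1), "Q1"))
  base <- curves$Q0[1]
  ok <- curves$Q0 >= base - q0_tolerance
  structure(list(alpha = max(curves$alpha[ok]), curves = curves, k = k,
                 q0_tolerance = q0_tolerance),
            class = "alpha_selection")
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat(sprintf("selected alpha = %.2f (k = %d, Q0 tolerance = %.2g)\n",
              x$alpha, x$k, x$q0_tolerance))
  print(x$curves, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-k clustering diagnostics
#'
#' Emits, for each candidate cluster count, the explained-inertia
#' proportions and the mean silhouette width in feature space, leaving the
#' choice of k to the analyst.
#'
#' @inheritParams constrained_ward
#' @param k_range integer vector of cluster counts to evaluate.
#' @return A data.frame (k, Q0, Q1, mean_silhouette).
#' @export
cluster_diagnostics <- function(D0, D1, alpha, k_range = 2:8,
                                scale = TRUE) {
  D0m <- .check_dissim(D0, "D0")
  rows <- lapply(k_range, function(k) {
    sol <- constrained_ward(D0, D1, alpha, k, scale = scale)
    sil <- .mean_silhouette(D0m, sol$assignment)
    data.frame(k = k, Q0 = sol$Q0, Q1 = sol$Q1, mean_silhouette = sil)
  })
  do.call(rbind, rows)
}

# mean silhouette width from a dissimilarity matrix and hard assignment
.mean_silhouette <- function(D, assign) {
  n <- nrow(D)
  ks <- sort(unique(assign))
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assign == assign[i]
    a <- if (sum(own) > 1) sum(D[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(ks[ks != assign[i]], function(c)
      mean(D[i, assign == c]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}
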