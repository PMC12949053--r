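#' Phylogenetic covariance matrix of shared path lengths
#'
#' Returns the Brownian-motion covariance structure implied by a rooted tree
#' with branch lengths: \code{V[i, j]} is the branch-length distance from the
#' root to the most recent common ancestor of tips i and j, and the diagonal
#' holds root-to-tip distances.
#'
#' @param tree an \code{ape::phylo} tree with branch lengths.
#' @param tips character vector of tip labels selecting (and ordering) the
#'   rows/columns; default all tips in tree order.
#' @return A symmetric positive semi-definite matrix with dimnames
#'   \code{tips}.
#' @export
tree_covariance <- function(tree, tips = tree$tip.label) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  V <- ape::vcv(tree)
  V[tips, tips, drop = FALSE]
}

# apply the {none, sqrt, cbrt} transformation; sqrt and cbrt act on
# |values|, so for negative Psi50 larger transformed values mean more
# resistant xylem. "none" leaves the trait untouched.
.apply_transformation <- function(values, transformation) {
  transformation <- match.arg(transformation, c("none", "sqrt", "cbrt"))
  switch(transformation, none = values, sqrt = sqrt(abs(values)),
         cbrt = abs(values)^(1 / 3))
}

# Blomberg's K for one or more trait vectors sharing a tree.
# X: n x m matrix of trait columns; returns length-m vector of K values.
.k_stat <- function(V, Vi, X) {
  n <- nrow(V)
  u <- colSums(Vi)                       # t(1) %*% Vi (Vi symmetric)
  a_hat <- as.numeric(u %*% X) / sum(u)  # phylogenetic GLS mean per column
  Xc <- X - rep(a_hat, each = n)
  mse0 <- colSums(Xc^2) / (n - 1)
  mse <- colSums((Vi %*% Xc) * Xc) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  if (any(mse0 < .Machine$double.eps * n))
    stop("trait has zero variance across tips (degenerate data)",
         call. = FALSE)
  (mse0 / mse) / expected
}

# align a named trait vector with the tree, dropping unmatched names
.match_tip_values <- function(tree, values) {
  if (is.null(names(values)))
    stop("'values' must be named by tip label", call. = FALSE)
  common <- intersect(tree$tip.label, names(values))
  if (length(common) < 3)
    stop("fewer than 3 tips with trait data match the tree", call. = FALSE)
  dropped_values <- length(values) - length(common)
  if (dropped_values > 0)
    message(dropped_values,
            " trait value(s) without a matching tip were dropped")
  dropped_tips <- length(tree$tip.label) - length(common)
  if (dropped_tips > 0)
    message(dropped_tips, " tree tip(s) without trait data were dropped")
  tree <- ape::keep.tip(tree, common)
  list(tree = tree, values = values[tree$tip.label])
}

.safe_solve <- function(V) {
  out <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(out))
    stop("phylogenetic covariance matrix is singular (ill-conditioned tree)",
         call. = FALSE)
  out
}

#' Blomberg's K for a continuous trait on a phylogeny
#'
#' Measures phylogenetic signal as the ratio of observed to
#' Brownian-expected variance structure:
#' \deqn{K = \frac{MSE_0 / MSE}{E_{BM}[MSE_0 / MSE]}}
#' with the phylogenetic GLS mean
#' \eqn{\hat a = (1'V^{-1}1)^{-1} 1'V^{-1}x}, \eqn{MSE_0} the mean squared
#' deviation about \eqn{\hat a}, \eqn{MSE} its GLS analogue under V, and the
#' Brownian expectation \eqn{[tr(V) - n/(1'V^{-1}1)]/(n-1)}. K is 1 in
#' expectation under Brownian evolution and approaches 0 for a trait with no
#' signal. The trait is transformed on the absolute scale first (so for
#' \eqn{\Psi_{50}}, larger transformed values mean more resistant xylem).
#'
#' @param tree an \code{ape::phylo} tree with branch lengths.
#' @param values named numeric vector of trait values (names = tip labels);
#'   tips without data are dropped with a message.
#' @param transformation one of \code{"none"}, \code{"sqrt"}, \code{"cbrt"},
#'   applied to \code{abs(values)}.
#' @return A list of class \code{blomberg_k}: \code{k}, \code{n_genera},
#'   \code{transformation}, \code{gls_mean} (on the transformed scale).
#' @examples
#' tr <- simulate_yule_tree(30, 1, seed = 2)
#' x <- simulate_bm_traits(tr, 1, 1, 0, seed = 3)
#' blomberg_k(tr, x)$k
#' @export
blomberg_k <- function(tree, values, transformation = "none") {
  m <- .match_tip_values(tree, values)
  n <- length(m$values)
  if (n < 20)
    warning("Blomberg's K is unreliable below ~20 tips (n = ", n, ")",
            call. = FALSE)
  x <- .apply_transformation(m$values, transformation)
  V <- tree_covariance(m$tree)
  Vi <- .safe_solve(V)
  u <- colSums(Vi)
  k <- .k_stat(V, Vi, matrix(x, ncol = 1))
  structure(list(k = unname(k), n_genera = n,
                 transformation = transformation,
                 gls_mean = sum(u * x) / sum(u)),
            class = "blomberg_k")
}

#' @export
print.blomberg_k <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f (n = %d tips, transformation = %s)\n",
              x$k, x$n_genera, x$transformation))
  invisible(x)
}

#' Permutation test of phylogenetic signal (Blomberg's K)
#'
#' Shuffles the assignment of trait values to tips \code{n_permutations}
#' times, recomputing K each time, and compares the observed K to the null
#' distribution. Significance follows the two-sided percentile rule: the
#' observed K is significant at \code{alpha} when it falls outside the
#' central \code{1 - alpha} percentile range of the null (default outside
#' \[2.5\%, 97.5\%\]). The reported p-value is the two-sided permutation
#' p with the +1/+1 correction that counts the observed statistic as part of
#' its own null.
#'
#' @inheritParams blomberg_k
#' @param n_permutations number of tip randomisations (>= 100).
#' @param alpha significance level for the percentile rule.
#' @param seed optional integer seed.
#' @return A list of class \code{signal_test}: \code{k}, \code{p_value},
#'   \code{significant}, \code{null_distribution}, \code{n_genera},
#'   \code{n_permutations}, \code{transformation}.
#' @export
permutation_test <- function(tree, values, transformation = "none",
                             n_permutations = 1000, alpha = 0.05,
                             seed = NULL) {
  if (n_permutations < 100)
    stop("n_permutations must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- .match_tip_values(tree, values)
  n <- length(m$values)
  x <- .apply_transformation(m$values, transformation)
  V <- tree_covariance(m$tree)
  Vi <- .safe_solve(V)
  k_obs <- .k_stat(V, Vi, matrix(x, ncol = 1))
  P <- vapply(seq_len(n_permutations), function(i) x[sample.int(n)],
              numeric(n))
  k_null <- .k_stat(V, Vi, P)
  p_up <- (1 + sum(k_null >= k_obs)) / (1 + n_permutations)
  p_lo <- (1 + sum(k_null <= k_obs)) / (1 + n_permutations)
  q <- stats::quantile(k_null, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(k = unname(k_obs), p_value = min(1, 2 * min(p_up, p_lo)),
                 significant = k_obs < q[1] || k_obs > q[2],
                 null_distribution = unname(k_null), n_genera = n,
                 n_permutations = n_permutations, alpha = alpha,
                 transformation = transformation),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat(sprintf(
    "Blomberg's K = %.4f, permutation p = %.4g (%d permutations, n = %d)\n",
    x$k, x$p_value, x$n_permutations, x$n_genera))
  cat(sprintf("  %ssignificant at the two-sided %.3g percentile rule\n",
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

# linear operator mapping tip values to BM/GLS ancestral reconstructions:
# anc = A %*% x with A = 1 w' + C V^{-1} (I - 1 w'), w the GLS-mean weights
# and C the node-to-tip shared path length matrix. Precomputing A makes the
# 1000-fold tip randomisation a single matrix product.
.anc_operator <- function(tree) {
  n <- length(tree$tip.label)
  V <- tree_covariance(tree)
  Vi <- .safe_solve(V)
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  nodes <- n + seq_len(tree$Nnode)
  C <- matrix(depth[mr[nodes, seq_len(n)]], nrow = tree$Nnode)
  w <- colSums(Vi) / sum(Vi)
  A <- outer(rep(1, tree$Nnode), w) +
    C %*% Vi %*% (diag(n) - outer(rep(1, n), w))
  rownames(A) <- nodes
  A
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Maximum-likelihood (GLS-equivalent) reconstruction of internal-node trait
#' values: the conditional expectation of each node under the joint Gaussian
#' Brownian model, with the root mean set to the phylogenetic GLS mean. The
#' root reconstruction therefore equals the GLS mean used by
#' \code{\link{blomberg_k}}.
#'
#' @inheritParams blomberg_k
#' @param values named numeric vector covering every tip of \code{tree}.
#' @return Named numeric vector of reconstructions for internal nodes, named
#'   by ape node id (root first).
#' @export
ancestral_states <- function(tree, values) {
  missing <- setdiff(tree$tip.label, names(values))
  if (length(missing))
    stop("values missing for tips: ", paste(missing, collapse = ", "),
         call. = FALSE)
  A <- .anc_operator(tree)
  x <- values[tree$tip.label]
  stats::setNames(as.numeric(A %*% x), rownames(A))
}

#' Node-level randomisation test for locally elevated trait values
#'
#' Localises phylogenetic signal by comparing each internal node's
#' reconstructed ancestral value to the distribution of reconstructions
#' obtained by randomising trait values across tips \code{n_permutations}
#' times. A node is flagged when its observed reconstruction falls beyond
#' the configured tail of its permutation null at level \code{alpha} — with
#' the default \code{tail = "upper"} and a transformed absolute
#' \eqn{\Psi_{50}} trait, flagged nodes are those with more embolism-resistant
#' reconstructed values than expected by chance.
#'
#' @inheritParams ancestral_states
#' @param n_permutations number of tip randomisations.
#' @param alpha significance level per node.
#' @param tail \code{"upper"}, \code{"lower"}, or \code{"two_sided"}.
#' @param seed optional integer seed.
#' @return A list of class \code{node_randomisation} with a \code{nodes}
#'   data.frame (\code{node}, \code{value}, \code{quantile}, \code{p},
#'   \code{flagged}) plus the test settings.
#' @export
node_randomisation <- function(tree, values, n_permutations = 1000,
                               alpha = 0.05,
                               tail = c("upper", "lower", "two_sided"),
                               seed = NULL) {
  tail <- match.arg(tail)
  if (!is.null(seed)) set.seed(seed)
  missing <- setdiff(tree$tip.label, names(values))
  if (length(missing))
    stop("values missing for tips: ", paste(missing, collapse = ", "),
         call. = FALSE)
  A <- .anc_operator(tree)
  x <- as.numeric(values[tree$tip.label])
  obs <- as.numeric(A %*% x)
  n <- length(x)
  P <- vapply(seq_len(n_permutations), function(i) x[sample.int(n)],
              numeric(n))
  null <- A %*% P                      # nodes x permutations
  tol <- 1e-8 * (abs(obs) + 1)         # guard against fp jitter at ties
  ge <- rowSums(null >= obs - tol)
  le <- rowSums(null <= obs + tol)
  p_up <- (1 + ge) / (1 + n_permutations)
  p_lo <- (1 + le) / (1 + n_permutations)
  p <- switch(tail, upper = p_up, lower = p_lo,
              two_sided = pmin(1, 2 * pmin(p_up, p_lo)))
  flagged <- p <= alpha
  structure(list(
    nodes = data.frame(node = as.integer(rownames(A)), value = obs,
                       quantile = rowSums(null < obs) / n_permutations,
                       p = p, flagged = flagged),
    n_permutations = n_permutations, alpha = alpha, tail = tail),
    class = "node_randomisation")
}

#' @export
print.node_randomisation <- function(x, ...) {
  cat(sprintf(
    "node randomisation: %d/%d nodes flagged (%s tail, alpha = %.3g, %d permutations)\n",
    sum(x$nodes$flagged), nrow(x$nodes), x$tail, x$alpha, x$n_permutations))
  invisible(x)
}
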