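#' IDW parameter pair
#'
#' @param idp inverse-distance power (>= 0); 0 gives an unweighted mean of
#'   the neighbours.
#' @param nmax maximum number of nearest neighbours used per prediction.
#' @return A list of class \code{idw_params}.
#' @export
idw_params <- function(idp = 2, nmax = Inf) {
  stopifnot(idp >= 0, nmax >= 1)
  structure(list(idp = idp, nmax = nmax), class = "idw_params")
}

# tolerance below which a query is treated as coincident with a data point
.idw_eps <- 1e-9

#' Inverse distance weighted interpolation
#'
#' Predicts each query location as the weighted mean of the values at the
#' \code{nmax} nearest data points, with weights \eqn{d^{-idp}}. A query
#' within 1e-9 map units of a data point returns that point's value exactly
#' (no division by zero). Predictions are convex combinations, hence
#' bounded by the neighbour values used.
#'
#' @param points data.frame with columns \code{x}, \code{y}, \code{value}.
#' @param queries data.frame (or 2-column matrix) of \code{x}, \code{y}.
#' @param params an \code{\link{idw_params}}.
#' @return Numeric vector of predictions, one per query row.
#' @export
idw_predict <- function(points, queries, params = idw_params()) {
  stopifnot(nrow(points) >= 1)
  qx <- queries[, 1]; qy <- queries[, 2]
  nmax <- min(params$nmax, nrow(points))
  idp <- params$idp
  out <- numeric(length(qx))
  # distances computed in blocks to bound memory on large grids
  block <- max(1L, floor(2e6 / nrow(points)))
  px <- points$x; py <- points$y; pv <- points$value
  for (s in seq(1, length(qx), by = block)) {
    e <- min(s + block - 1, length(qx))
    d <- sqrt(outer(qx[s:e], px, "-")^2 + outer(qy[s:e], py, "-")^2)
    for (r in seq_len(e - s + 1)) {
      di <- d[r, ]
      hit <- which(di < .idw_eps)
      if (length(hit)) {
        out[s + r - 1] <- pv[hit[1]]
        next
      }
      o <- order(di)[seq_len(nmax)]
      w <- di[o]^(-idp)
      out[s + r - 1] <- sum(w * pv[o]) / sum(w)
    }
  }
  out
}

#' Leave-one-out cross-validation RMSE for one IDW parametrisation
#'
#' @param points data.frame with \code{x}, \code{y}, \code{value}.
#' @param params an \code{\link{idw_params}}.
#' @return RMSE (same units as \code{value}) over the n hold-one-out
#'   predictions.
#' @export
loocv_rmse <- function(points, params = idw_params()) {
  n <- nrow(points)
  stopifnot(n >= 3)
  d <- as.matrix(stats::dist(points[, c("x", "y")]))
  nmax <- min(params$nmax, n - 1)
  pred <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    vv <- points$value[-i]
    hit <- which(di < .idw_eps)
    if (length(hit)) return(vv[hit[1]])
    o <- order(di)[seq_len(nmax)]
    w <- di[o]^(-params$idp)
    sum(w * vv[o]) / sum(w)
  }, numeric(1))
  sqrt(mean((pred - points$value)^2))
}

#' Coarse-to-fine LOOCV search for IDW parameters
#'
#' Evaluates every combination of the idp and nmax grids by leave-one-out
#' RMSE, then repeatedly refines the idp grid around the incumbent optimum
#' (span shrunk by \code{shrink} per step) for \code{n_refine_steps} steps
#' in total. Ties are broken toward smaller idp, then smaller nmax, so the
#' search is deterministic.
#'
#' @param points data.frame with \code{x}, \code{y}, \code{value}.
#' @param idp_grid initial grid of inverse-distance powers.
#' @param nmax_grid grid of neighbour counts.
#' @param n_refine_steps total number of search steps (>= 1).
#' @param shrink factor by which the idp search span shrinks per step.
#' @return A list of class \code{loocv_search}: \code{params} (best
#'   \code{idw_params}), \code{rmse}, \code{trace} (data.frame step, idp,
#'   nmax, rmse).
#' @export
loocv_search <- function(points, idp_grid = seq(0.1, 3, by = 0.5),
                         nmax_grid = c(8, 16, 32, 64),
                         n_refine_steps = 3, shrink = 3) {
  stopifnot(nrow(points) >= 3, length(idp_grid) >= 1,
            length(nmax_grid) >= 1, n_refine_steps >= 1)
  nmax_grid <- sort(unique(pmin(nmax_grid, nrow(points) - 1)))
  trace <- list()
  best <- NULL
  grid <- sort(unique(idp_grid))
  for (step in seq_len(n_refine_steps)) {
    for (idp in grid) for (nm in nmax_grid) {
      r <- loocv_rmse(points, idw_params(idp, nm))
      trace[[length(trace) + 1]] <-
        data.frame(step = step, idp = idp, nmax = nm, rmse = r)
      better <- is.null(best) || r < best$rmse - 1e-12 ||
        (abs(r - best$rmse) <= 1e-12 &&
           (idp < best$idp - 1e-12 ||
              (abs(idp - best$idp) <= 1e-12 && nm < best$nmax)))
      if (better) best <- list(idp = idp, nmax = nm, rmse = r)
    }
    if (step < n_refine_steps) {
      span <- if (length(grid) > 1) diff(range(grid)) / shrink else
        grid[1] / shrink
      grid <- seq(max(best$idp - span / 2, 1e-3),
                  best$idp + span / 2, length.out = 7)
      grid <- sort(unique(round(grid, 6)))
    }
  }
  structure(list(params = idw_params(best$idp, best$nmax),
                 rmse = best$rmse,
                 trace = do.call(rbind, trace)),
            class = "loocv_search")
}

#' @export
print.loocv_search <- function(x, ...) {
  cat(sprintf("LOOCV search: idp = %.3g, nmax = %d, RMSE = %.4f\n",
              x$params$idp, x$params$nmax, x$rmse))
  invisible(x)
}

#' Fold-averaged, smoothed IDW surface
#'
#' For each cross-validation fold, interpolates a surface from the points of
#' all the other folds, smooths it with a \code{smooth_window} x
#' \code{smooth_window} mean convolution filter (truncated at the grid
#' edges), and returns the cell-wise mean of the fold surfaces. Averaging
#' over fold surfaces damps the influence of any single spatial cluster of
#' plots; the smoothing suppresses linear artefacts of uneven sampling.
#'
#' @param points data.frame with \code{x}, \code{y}, \code{value}.
#' @param folds integer vector assigning each point to a fold (>= 2 folds,
#'   none containing every point). Ignored when
#'   \code{use_all_points = TRUE}.
#' @param params an \code{\link{idw_params}}.
#' @param grid a \code{grid_raster} (values ignored) or an extent to pass
#'   to \code{\link{grid_skeleton}} together with \code{cell}.
#' @param smooth_window odd mean-filter width in cells (1 = no smoothing).
#' @param cell cell size when \code{grid} is an extent.
#' @param use_all_points logical; build a single surface from all points
#'   instead of fold-averaging.
#' @return A \code{grid_raster} with attributes \code{params} and
#'   \code{provenance} (\code{"averaged"} or \code{"all_points"}).
#' @export
fold_averaged_surface <- function(points, folds, params, grid,
                                  smooth_window = 9, cell = NULL,
                                  use_all_points = FALSE) {
  if (!inherits(grid, "grid_raster")) grid <- grid_skeleton(grid, cell)
  qc <- grid_coords(grid)
  if (use_all_points) {
    v <- idw_predict(points, qc, params)
    m <- mean_filter(matrix(v, grid$nrow, grid$ncol), smooth_window)
    grid$values <- m
    attr(grid, "params") <- params
    attr(grid, "provenance") <- "all_points"
    return(grid)
  }
  fold_ids <- sort(unique(folds))
  if (length(fold_ids) < 2)
    stop("need at least 2 folds", call. = FALSE)
  if (any(vapply(fold_ids, function(f) all(folds == f), logical(1))))
    stop("a fold contains all points (invalid folds)", call. = FALSE)
  acc <- matrix(0, grid$nrow, grid$ncol)
  for (f in fold_ids) {
    train <- points[folds != f, , drop = FALSE]
    v <- idw_predict(train, qc, params)
    acc <- acc + mean_filter(matrix(v, grid$nrow, grid$ncol),
                             smooth_window)
  }
  grid$values <- acc / length(fold_ids)
  attr(grid, "params") <- params
  attr(grid, "provenance") <- "averaged"
  grid
}

#' Spatially constrained k-fold cross-validation of the interpolation
#'
#' Uses the spatial clusters as folds: each fold's points are predicted by
#' IDW from the points of the remaining folds. Reports per-fold and pooled
#' RMSE and the cross-validation variance explained
#' \deqn{VEcv = \left(1 - \frac{\sum (obs - pred)^2}{\sum (obs -
#' \overline{obs})^2}\right) \times 100.}
#' When a surface is supplied, also compares each cluster's point-average
#' value with the mean of the interpolated cells inside the cluster's
#' convex hull (point vs interpolated averages).
#'
#' @inheritParams fold_averaged_surface
#' @param surface optional \code{grid_raster} for the cluster-agreement
#'   comparison.
#' @return A list of class \code{cv_report}: \code{folds} (data.frame fold,
#'   n, rmse), \code{rmse} (pooled), \code{vecv} (percent),
#'   \code{cluster_agreement} (data.frame or NULL), \code{predictions}.
#' @export
spatial_cv <- function(points, folds, params, surface = NULL) {
  fold_ids <- sort(unique(folds))
  if (length(fold_ids) < 2)
    stop("need at least 2 folds", call. = FALSE)
  if (any(vapply(fold_ids, function(f) all(folds == f), logical(1))))
    stop("a fold contains all points (invalid folds)", call. = FALSE)
  pred <- numeric(nrow(points))
  for (f in fold_ids) {
    test <- folds == f
    pred[test] <- idw_predict(points[!test, , drop = FALSE],
                              points[test, c("x", "y"), drop = FALSE],
                              params)
  }
  err <- pred - points$value
  fold_tab <- data.frame(
    fold = fold_ids,
    n = vapply(fold_ids, function(f) sum(folds == f), integer(1)),
    rmse = vapply(fold_ids, function(f)
      sqrt(mean(err[folds == f]^2)), numeric(1)))
  vecv <- (1 - sum(err^2) / sum((points$value - mean(points$value))^2)) * 100
  agreement <- NULL
  if (!is.null(surface)) {
    qc <- grid_coords(surface)
    agreement <- do.call(rbind, lapply(fold_ids, function(f) {
      m <- folds == f
      pt_avg <- mean(points$value[m])
      xy <- as.matrix(points[m, c("x", "y")])
      interp_avg <- NA_real_
      if (sum(m) >= 3) {
        hull <- xy[grDevices::chull(xy), , drop = FALSE]
        inside <- mgcv::in.out(rbind(hull, hull[1, ]), qc)
        if (any(inside))
          interp_avg <- mean(surface$values[inside], na.rm = TRUE)
      }
      data.frame(cluster = f, point_avg = pt_avg,
                 interp_avg = interp_avg)
    }))
  }
  structure(list(folds = fold_tab, rmse = sqrt(mean(err^2)), vecv = vecv,
                 cluster_agreement = agreement, predictions = pred),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("spatial CV: pooled RMSE = %.3f, VEcv = %.2f%%\n",
              x$rmse, x$vecv))
  print(x$folds, row.names = FALSE, digits = 3)
  if (!is.null(x$cluster_agreement)) {
    cat("cluster point vs interpolated averages:\n")
    print(x$cluster_agreement, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
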