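test_that("constrained ward at alpha 0 equals plain Ward on D0", {
  set.seed(51)
  D0 <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
  D1 <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
  sol <- constrained_ward(D0, D1, alpha = 0, k = 5, scale = FALSE)
  ct <- stats::cutree(stats::hclust(stats::as.dist(D0^2 / 2),
                                    method = "ward.D"), 5)
  tab <- table(sol$assignment, ct)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("constrained ward recovers pure spatial blobs at alpha 1", {
  set.seed(52)
  xy <- rbind(matrix(rnorm(24, 0, 0.3), 12, 2),
              matrix(rnorm(24, 8, 0.3), 12, 2))
  D1 <- as.matrix(dist(xy))
  D0 <- as.matrix(dist(rnorm(24)))     # feature space uninformative
  sol <- constrained_ward(D0, D1, alpha = 1, k = 2)
  expect_length(unique(sol$assignment[1:12]), 1)
  expect_length(unique(sol$assignment[13:24]), 1)
  expect_false(sol$assignment[1] == sol$assignment[24])
})

test_that("merge hierarchy matches the exhaustive-definition oracle (n <= 8)", {
  set.seed(53)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    D0 <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
    D1 <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
    alpha <- sample(c(0, 0.3, 0.5, 0.8, 1), 1)
    sol <- constrained_ward(D0, D1, alpha = alpha, k = 1)
    expect_identical(merge_sets(sol$merge, n),
                     oracle_ward_history(D0, D1, alpha))
  }
})

test_that("pseudo-inertia is conserved and Q proportions are sane", {
  set.seed(54)
  pts <- matrix(rnorm(50), 25, 2)
  D0 <- as.matrix(dist(pts))
  D1 <- as.matrix(dist(matrix(rnorm(50), 25, 2)))
  sol <- constrained_ward(D0, D1, alpha = 0.4, k = 4, scale = FALSE)
  # Euclidean identity: total = within + between (centroid form)
  asg <- sol$assignment
  I_tot <- sum(D0^2) / (2 * 25)
  wi <- sum(vapply(1:4, function(c) {
    m <- which(asg == c)
    if (length(m) < 2) 0 else sum(D0[m, m]^2) / (2 * length(m))
  }, numeric(1)))
  xb <- colMeans(pts)
  bt <- sum(vapply(1:4, function(c) {
    m <- which(asg == c)
    length(m) * sum((colMeans(pts[m, , drop = FALSE]) - xb)^2)
  }, numeric(1)))
  expect_equal(I_tot, wi + bt, tolerance = 1e-8)
  expect_equal(sol$Q0, bt / I_tot, tolerance = 1e-8)
  expect_true(sol$Q0 >= 0 && sol$Q0 <= 1 && sol$Q1 >= 0 && sol$Q1 <= 1)
  expect_equal(sum(sol$sizes), 25)
  expect_error(constrained_ward(D0[, 1:10], D1, 0.5, 2), "symmetric")
})

test_that("alpha selection follows the Q0-tolerance rule", {
  set.seed(55)
  D0 <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  # identical spaces: every alpha equivalent, return the grid maximum
  sel_same <- select_alpha(D0, D0, k = 3)
  expect_equal(sel_same$alpha, 1)

  D1 <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  sel <- select_alpha(D0, D1, k = 4, q0_tolerance = 0.1)
  # grid-walk oracle over the emitted curves
  ok <- sel$curves$Q0 >= sel$curves$Q0[1] - 0.1
  expect_equal(sel$alpha, max(sel$curves$alpha[ok]))

  sel0 <- select_alpha(D0, D1, k = 4, q0_tolerance = 0)
  if (all(diff(sel0$curves$Q0) < 0)) expect_equal(sel0$alpha, 0)
  expect_true(sel0$alpha %in% sel0$curves$alpha)
})

test_that("idw respects exact hits, symmetry, idp 0 and convexity", {
  pts <- data.frame(x = c(0, 2, 5), y = c(0, 0, 1), value = c(1, 3, 10))
  expect_equal(idw_predict(pts, data.frame(x = 2, y = 0), idw_params(2)), 3)
  expect_equal(idw_predict(pts[1:2, ], data.frame(x = 1, y = 0),
                           idw_params(4.2)), 2)
  expect_equal(idw_predict(pts, data.frame(x = 1, y = 9), idw_params(0, 3)),
               mean(pts$value))
  set.seed(56)
  rp <- data.frame(x = runif(40), y = runif(40), value = rnorm(40))
  q <- data.frame(x = runif(25), y = runif(25))
  pred <- idw_predict(rp, q, idw_params(1.7, 6))
  expect_true(all(pred >= min(rp$value) & pred <= max(rp$value)))
  expect_error(idw_predict(rp[0, ], q), "1")
})

test_that("loocv rmse equals the naive hold-one-out loop", {
  set.seed(57)
  pts <- data.frame(x = runif(25, 0, 10), y = runif(25, 0, 10),
                    value = rnorm(25))
  for (par in list(idw_params(0.5, 4), idw_params(2, 10))) {
    naive <- sqrt(mean((vapply(seq_len(25), function(i)
      idw_predict(pts[-i, ], pts[i, c("x", "y")], par), numeric(1)) -
        pts$value)^2))
    expect_equal(loocv_rmse(pts, par), naive, tolerance = 1e-12)
  }
})

test_that("loocv search recovers planted parameters and honours tie-breaks", {
  set.seed(58)
  gen <- data.frame(x = runif(60, 0, 100), y = runif(60, 0, 100))
  anchors <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100),
                        value = rnorm(12, 0, 2))
  gen$value <- idw_predict(anchors, gen, idw_params(1.1, 12)) +
    rnorm(60, 0, 0.005)
  found <- loocv_search(gen, idp_grid = c(0.1, 0.6, 1.1, 1.6, 2.1),
                        nmax_grid = c(4, 12, 32), n_refine_steps = 2)
  expect_lt(abs(found$params$idp - 1.1), 0.6)

  const <- data.frame(x = runif(10), y = runif(10), value = 5)
  tie <- loocv_search(const, idp_grid = c(0.5, 1, 2), nmax_grid = c(3, 6),
                      n_refine_steps = 1)
  expect_equal(tie$rmse, 0)
  expect_equal(tie$params$idp, 0.5)
  expect_equal(tie$params$nmax, 3)
})

test_that("fold-averaged surface preserves constants and matches dense loops", {
  set.seed(59)
  pts <- data.frame(x = runif(20, 0, 100), y = runif(20, 0, 100),
                    value = 2.5)
  folds <- rep(1:4, 5)
  s <- fold_averaged_surface(pts, folds, idw_params(2, 8), c(0, 100, 0, 100),
                             smooth_window = 9, cell = 5)
  expect_true(max(abs(s$values - 2.5)) < 1e-12)

  pts$value <- rnorm(20)
  par <- idw_params(1.5, 6)
  s1 <- fold_averaged_surface(pts, folds, par, c(0, 100, 0, 100),
                              smooth_window = 3, cell = 5)
  # dense re-computation: per fold, per cell, then truncated window means
  g <- grid_skeleton(c(0, 100, 0, 100), 5)
  acc <- matrix(0, g$nrow, g$ncol)
  qc <- grid_coords(g)
  for (f in 1:4) {
    tr <- pts[folds != f, ]
    v <- matrix(idw_predict(tr, qc, par), g$nrow, g$ncol)
    acc <- acc + oracle_mean_filter(v, 3)
  }
  expect_equal(s1$values, acc / 4, tolerance = 1e-12)

  # window 1 is the identity filter
  s2 <- fold_averaged_surface(pts, folds, par, c(0, 100, 0, 100),
                              smooth_window = 1, cell = 5)
  acc2 <- matrix(0, g$nrow, g$ncol)
  for (f in 1:4)
    acc2 <- acc2 + matrix(idw_predict(pts[folds != f, ], qc, par),
                          g$nrow, g$ncol)
  expect_equal(s2$values, acc2 / 4, tolerance = 1e-12)
  expect_error(fold_averaged_surface(pts, rep(1, 20), par,
                                     c(0, 100, 0, 100), cell = 5),
               "folds")
})

test_that("mean filter matches the naive loop oracle on odd shapes", {
  set.seed(60)
  m <- matrix(rnorm(35), 5, 7)
  expect_equal(mean_filter(m, 3), oracle_mean_filter(m, 3), tolerance = 1e-12)
  expect_equal(mean_filter(m, 5), oracle_mean_filter(m, 5), tolerance = 1e-12)
  expect_identical(mean_filter(m, 1), m)
})

test_that("spatial cv reproduces definitional bounds and the naive loop", {
  set.seed(61)
  pts <- data.frame(x = runif(30, 0, 50), y = runif(30, 0, 50),
                    value = rnorm(30, -3))
  folds <- rep(1:5, 6)
  par <- idw_params(1, 8)
  cv <- spatial_cv(pts, folds, par)
  # naive per-fold loop oracle
  pred <- numeric(30)
  for (f in 1:5) {
    idx <- which(folds == f)
    for (i in idx)
      pred[i] <- idw_predict(pts[folds != f, ], pts[i, c("x", "y")], par)
  }
  expect_equal(cv$rmse, sqrt(mean((pred - pts$value)^2)), tolerance = 1e-12)
  expect_equal(cv$vecv,
               (1 - sum((pred - pts$value)^2) /
                  sum((pts$value - mean(pts$value))^2)) * 100,
               tolerance = 1e-10)
  # perfect predictions: RMSE 0, VEcv 100 (single shared value per fold pair)
  pts2 <- pts; pts2$value <- 4
  cv2 <- spatial_cv(pts2, folds, par)
  expect_equal(cv2$rmse, 0)
  # VEcv invariance to adding a constant; RMSE invariant to translation
  pts3 <- pts; pts3$value <- pts$value + 100
  cv3 <- spatial_cv(pts3, folds, par)
  expect_equal(cv3$vecv, cv$vecv, tolerance = 1e-8)
  pts4 <- pts; pts4$x <- pts$x + 1000; pts4$y <- pts$y - 500
  cv4 <- spatial_cv(pts4, folds, par)
  expect_equal(cv4$rmse, cv$rmse, tolerance = 1e-10)
})

test_that("cluster agreement compares point and hull-interpolated averages", {
  set.seed(62)
  # two well-separated clusters with distinct levels
  pts <- data.frame(x = c(runif(10, 0, 20), runif(10, 80, 100)),
                    y = c(runif(10, 0, 20), runif(10, 80, 100)),
                    value = c(rnorm(10, -1, 0.05), rnorm(10, -5, 0.05)))
  folds <- rep(1:2, each = 10)
  surf <- fold_averaged_surface(pts, folds, idw_params(2, 5),
                                c(0, 100, 0, 100), smooth_window = 1,
                                cell = 2, use_all_points = TRUE)
  cv <- spatial_cv(pts, folds, idw_params(2, 5), surface = surf)
  ag <- cv$cluster_agreement
  expect_equal(nrow(ag), 2)
  # interpolated averages inside each hull track the point averages
  expect_lt(abs(ag$point_avg[1] - ag$interp_avg[1]), 0.5)
  expect_lt(abs(ag$point_avg[2] - ag$interp_avg[2]), 0.5)
})

test_that("mess reproduces boundary cases and the per-cell oracle", {
  set.seed(63)
  ref <- data.frame(a = rnorm(100), b = runif(100))
  qmin <- data.frame(a = min(ref$a), b = stats::median(ref$b))
  expect_equal(mess(ref, qmin)$score, 0, tolerance = 1e-12)
  qout <- data.frame(a = min(ref$a) - 1, b = 0.5)
  expect_lt(mess(ref, qout)$score, 0)

  q <- data.frame(a = rnorm(150, 0, 1.5), b = runif(150, -0.2, 1.2))
  got <- mess(ref, q)
  expect_equal(got$score, oracle_mess(ref, q), tolerance = 1e-10)

  # the reference median is the deepest achievable interior point
  qmed <- data.frame(a = stats::median(ref$a), b = stats::median(ref$b))
  grid_scores <- oracle_mess(ref, q)
  expect_gte(mess(ref, qmed)$score, max(grid_scores))

  # raster mode matches vector mode cell by cell
  g <- grid_raster(matrix(rnorm(24), 4, 6), 0, 0, 10)
  h <- grid_raster(matrix(runif(24), 4, 6), 0, 0, 10)
  ml <- mess(ref, list(a = g, b = h))
  expect_s3_class(ml$score, "grid_raster")
  vec <- mess(ref, data.frame(a = as.vector(g$values),
                              b = as.vector(h$values)))
  expect_equal(as.vector(ml$score$values), vec$score, tolerance = 1e-12)

  # zero-range reference variable
  refc <- data.frame(a = rep(2, 10))
  expect_warning(sc <- mess(refc, data.frame(a = c(2, 3))), "zero range")
  expect_equal(sc$score[1], 100)
  expect_lt(sc$score[2], -1e6)
})

test_that("esri ascii grids round-trip", {
  g <- grid_raster(matrix(c(1.5, NA, 3, 4, 5, 6), 2, 3), xmin = 10,
                   ymin = -5, cell = 2.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, path)
  g2 <- read_esri_ascii(path)
  expect_equal(g2$values, g$values)
  expect_equal(g2$xmin, 10)
  expect_equal(g2$ymin, -5)
  expect_equal(g2$cell, 2.5)
})
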