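#' Default pipeline configuration
#'
#' Returns the declarative configuration driving
#' \code{\link{run_pipeline}}: either a \code{simulate} block (arguments to
#' \code{\link{sim_config}}) or an \code{inputs} block of file paths
#' (\code{tree} Newick, \code{traits} and \code{inventory} CSV,
#' \code{mcwd} and \code{wtd} ESRI ASCII rasters), stage toggles, and
#' per-stage parameter blocks mirroring the analysis knobs: trait
#' transformation and permutation count, the coverage threshold, the alpha
#' grid and cluster count, the IDW search grids, the smoothing window.
#'
#' @param seed global seed recorded in the manifest.
#' @return A nested list of class \code{run_config}.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_tips = 88L, n_plots = 448L, stems_per_plot = 400L,
                    n_sites = 11L, signal_lambda = 1, bm_sigma2 = 0.8,
                    gradient_strength = 6,
                    domain_extent = c(0, 3000, 0, 2000), cell_size = 50),
    inputs = NULL,
    stages = c("signal", "familystats", "cwm", "cluster", "interpolate",
               "crossval", "mess"),
    signal = list(transformation = NULL, n_permutations = 1000L,
                  alpha = 0.05, tail = "upper"),
    familystats = list(min_sites = 3L, focal_family = NULL),
    cwm = list(coverage_threshold = 0.60, level_mean = "record",
               min_species_frac = 0.5),
    cluster = list(alpha_grid = seq(0, 1, by = 0.1), k = 5L,
                   q0_tolerance = 0.1),
    interpolate = list(idp_grid = seq(0.1, 3, by = 0.5),
                       nmax_grid = c(8, 16, 32, 64),
                       n_refine_steps = 3L, smooth_window = 9L,
                       cell_size = NULL),
    mess = list()),
    class = "run_config")
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config(seed = if (!is.null(config$seed)) config$seed else 1L)
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(base[[nm]])) {
      for (k in names(config[[nm]])) base[[nm]][[k]] <- config[[nm]][[k]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base
}

#' Validate pipeline inputs against the expected schemas
#'
#' Collects (rather than fail-fasts) schema problems: required columns,
#' the negative-MPa sign convention for \eqn{\Psi_{50}}, positive basal
#' areas, coordinates, raster grid consistency, and tree/taxonomy
#' cross-references. Inventory taxa absent from the trait table are a
#' warning, not an error, because gap-filling can still resolve them via
#' the plot mean.
#'
#' @param config a \code{run_config} list, or a path to a YAML file.
#' @param data optional pre-loaded data list (\code{tree}, \code{traits},
#'   \code{inventory}, \code{rasters}); when NULL, data are loaded or
#'   simulated per the config.
#' @return A list of class \code{validation_report}: \code{ok},
#'   \code{errors}, \code{warnings}, \code{data} (the loaded inputs).
#' @export
validate_inputs <- function(config, data = NULL) {
  config <- .load_config(config)
  errors <- character(); warnings <- character()
  if (is.null(data)) data <- .load_inputs(config)
  tr <- data$traits
  req <- c("species", "genus", "family", "site", "psi50")
  miss <- setdiff(req, names(tr))
  if (length(miss)) {
    errors <- c(errors, paste("trait table missing columns:",
                              paste(miss, collapse = ", ")))
  } else {
    if (any(tr$psi50 >= 0))
      errors <- c(errors, "trait table has non-negative psi50 values (sign convention: MPa, negative)")
    g2f <- tapply(tr$family, tr$genus, function(f) length(unique(f)))
    if (any(g2f > 1))
      errors <- c(errors, paste("genera mapped to multiple families:",
                                paste(names(g2f)[g2f > 1], collapse = ", ")))
  }
  inv <- data$inventory
  reqi <- c("plot_id", "x", "y", "species", "genus", "family",
            "basal_area", "dicot")
  missi <- setdiff(reqi, names(inv))
  if (length(missi)) {
    errors <- c(errors, paste("inventory missing columns:",
                              paste(missi, collapse = ", ")))
  } else {
    if (any(inv$basal_area <= 0))
      errors <- c(errors, "inventory has non-positive basal areas")
    if (any(is.na(inv$x) | is.na(inv$y)))
      errors <- c(errors, "inventory plots with missing coordinates")
    if (!length(miss)) {
      dic_fams <- unique(inv$family[inv$dicot])
      unmatched <- dic_fams[!.norm_name(dic_fams) %in%
                              .norm_name(tr$family)]
      if (length(unmatched))
        warnings <- c(warnings,
                      paste("inventory families without trait data (gap-fill will use the plot mean):",
                            paste(unmatched, collapse = ", ")))
    }
  }
  if (!is.null(data$tree)) {
    if (is.null(data$tree$edge.length))
      errors <- c(errors, "tree has no branch lengths")
    else if (!length(miss)) {
      absent <- setdiff(unique(tr$genus), data$tree$tip.label)
      if (length(absent))
        warnings <- c(warnings,
                      paste("trait genera absent from the tree (dropped in signal stage):",
                            paste(absent, collapse = ", ")))
    }
  }
  if (!is.null(data$rasters)) {
    g1 <- data$rasters[[1]]
    same <- vapply(data$rasters, function(g)
      identical(c(g$nrow, g$ncol, g$cell, g$xmin, g$ymin),
                c(g1$nrow, g1$ncol, g1$cell, g1$xmin, g1$ymin)),
      logical(1))
    if (!all(same))
      errors <- c(errors, "environmental rasters are on inconsistent grids")
  }
  structure(list(ok = length(errors) == 0, errors = errors,
                 warnings = warnings, data = data),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("input validation: %s (%d error(s), %d warning(s))\n",
              if (x$ok) "OK" else "FAILED", length(x$errors),
              length(x$warnings)))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

.load_inputs <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    list(tree = ape::read.tree(inp$tree),
         traits = utils::read.csv(inp$traits),
         inventory = utils::read.csv(inp$inventory),
         rasters = list(mcwd = read_esri_ascii(inp$mcwd),
                        wtd = read_esri_ascii(inp$wtd)))
  } else {
    sc <- do.call(sim_config, c(list(seed = config$seed), config$simulate))
    b <- simulate_bundle(sc)
    list(tree = b$tree, traits = b$traits, inventory = b$inventory,
         rasters = b$rasters, resistant_family = b$resistant_family)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — signal (Blomberg's K
#' with permutation test, ancestral reconstruction, node randomisation),
#' familystats (nested ANOVA, family one-way ANOVA with Tukey letters,
#' focal-family rank-sum contrast), cwm (coverage filter, gap-fill,
#' community-weighted means, gap-fill validation), cluster (alpha selection
#' and constrained Ward at k), interpolate (LOOCV parameter search and the
#' fold-averaged smoothed surface), crossval (spatial k-fold CV), mess —
#' writing delimited outputs to \code{outdir} and a YAML run manifest
#' (config snapshot, stage seeds, output checksums, timings) last. All
#' randomness flows from the config seed via fixed per-stage offsets, so a
#' rerun with the same config reproduces identical outputs.
#'
#' @param config a \code{run_config} list or YAML path
#'   (see \code{\link{default_config}}).
#' @param outdir output directory.
#' @return The results list (class \code{pipeline_result}) with one element
#'   per executed stage plus \code{manifest}, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile()) {
  t0 <- Sys.time()
  config <- .load_config(config)
  val <- validate_inputs(config)
  if (!val$ok)
    stop("input validation failed:\n  ",
         paste(val$errors, collapse = "\n  "), call. = FALSE)
  data <- val$data
  stages <- config$stages
  deps <- list(crossval = "cluster", interpolate = c("cwm", "cluster"),
               cluster = "cwm", mess = c("cwm", "interpolate"))
  for (s in stages) {
    need <- setdiff(deps[[s]], stages)
    if (length(need))
      stop("stage '", s, "' requires disabled stage(s): ",
           paste(need, collapse = ", "), call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  seeds <- list()
  timing <- list()
  emit <- function(df, name) utils::write.csv(df, file.path(
    outdir, paste0(name, ".csv")), row.names = FALSE)

  if ("signal" %in% stages) {
    ts <- Sys.time()
    seeds$signal <- .stage_seed(config$seed, 11L)
    gm <- tapply(data$traits$psi50, data$traits$genus, mean)
    trf <- config$signal$transformation
    if (is.null(trf))
      trf <- choose_transformation(gm)$transformation
    st <- permutation_test(data$tree, gm, transformation = trf,
                           n_permutations = config$signal$n_permutations,
                           alpha = config$signal$alpha,
                           seed = seeds$signal)
    x <- .apply_transformation(gm, trf)
    nr <- node_randomisation(data$tree, x,
                             n_permutations = config$signal$n_permutations,
                             alpha = config$signal$alpha,
                             tail = config$signal$tail,
                             seed = seeds$signal + 1L)
    res$signal <- list(test = st, nodes = nr, transformation = trf)
    emit(data.frame(k = st$k, p_value = st$p_value,
                    significant = st$significant, n_genera = st$n_genera,
                    n_permutations = st$n_permutations,
                    transformation = trf), "signal")
    emit(nr$nodes, "signal_nodes")
    timing$signal <- as.numeric(Sys.time() - ts, units = "secs")
  }

  if ("familystats" %in% stages) {
    ts <- Sys.time()
    sub <- select_nested_subset(data$traits)
    na_fit <- nested_anova(sub)
    fa <- family_anova_tukey(data$traits,
                             min_sites = config$familystats$min_sites)
    focal <- config$familystats$focal_family
    if (is.null(focal)) {
      focal <- if (!is.null(data$resistant_family)) data$resistant_family
      else "Fabaceae"
    }
    fc <- fabaceae_contrast(data$traits, family = focal)
    res$familystats <- list(nested = na_fit, family_anova = fa,
                            contrast = fc, subset_counts = attr(sub, "counts"))
    emit(na_fit$table, "nested_anova")
    emit(fa$tukey, "tukey")
    emit(data.frame(family = names(fa$letters), letter = fa$letters),
         "tukey_letters")
    emit(data.frame(focal_family = focal, W = fc$W, p_value = fc$p_value,
                    mean_focal = fc$mean_a, sd_focal = fc$sd_a,
                    mean_other = fc$mean_b, sd_other = fc$sd_b),
         "family_contrast")
    timing$familystats <- as.numeric(Sys.time() - ts, units = "secs")
  }

  if ("cwm" %in% stages) {
    ts <- Sys.time()
    cov <- coverage_filter(data$inventory, data$traits,
                           threshold = config$cwm$coverage_threshold)
    keep <- cov$plot_id[cov$pass]
    inv <- data$inventory[data$inventory$plot_id %in% keep, , drop = FALSE]
    filled <- gap_fill(inv, data$traits,
                       level_mean = config$cwm$level_mean)
    cwm <- community_weighted_mean(filled)
    cwm$coverage <- cov$coverage[match(cwm$plot_id, cov$plot_id)]
    gv <- tryCatch(gapfill_validation(data$inventory, data$traits,
                                      min_species_frac =
                                        config$cwm$min_species_frac,
                                      level_mean = config$cwm$level_mean),
                   error = function(e) NULL)
    res$cwm <- list(coverage = cov, table = cwm, validation = gv)
    emit(cov, "coverage")
    emit(as.data.frame(cwm), "cwm")
    if (!is.null(gv))
      emit(data.frame(r_squared = gv$r_squared, slope = gv$slope,
                      intercept = gv$intercept, p_value = gv$p_value,
                      n_plots = gv$n_plots), "gapfill_validation")
    timing$cwm <- as.numeric(Sys.time() - ts, units = "secs")
  }

  if ("cluster" %in% stages) {
    ts <- Sys.time()
    cwm <- res$cwm$table
    feats <- cbind(cwm_psi50 = cwm$cwm_psi50,
                   mcwd = grid_extract(data$rasters$mcwd, cwm$x, cwm$y),
                   wtd = grid_extract(data$rasters$wtd, cwm$x, cwm$y))
    feats_std <- scale(feats)
    D0 <- as.matrix(stats::dist(feats_std))
    D1 <- as.matrix(stats::dist(cwm[, c("x", "y")]))
    sel <- select_alpha(D0, D1, k = config$cluster$k,
                        alpha_grid = config$cluster$alpha_grid,
                        q0_tolerance = config$cluster$q0_tolerance)
    sol <- constrained_ward(D0, D1, alpha = sel$alpha,
                            k = config$cluster$k)
    res$cluster <- list(selection = sel, solution = sol, features = feats)
    emit(sel$curves, "alpha_curves")
    emit(data.frame(plot_id = cwm$plot_id, cluster = sol$assignment),
         "clusters")
    timing$cluster <- as.numeric(Sys.time() - ts, units = "secs")
  }

  if ("interpolate" %in% stages) {
    ts <- Sys.time()
    cwm <- res$cwm$table
    pts <- data.frame(x = cwm$x, y = cwm$y, value = cwm$cwm_psi50)
    search <- loocv_search(pts,
                           idp_grid = config$interpolate$idp_grid,
                           nmax_grid = config$interpolate$nmax_grid,
                           n_refine_steps = config$interpolate$n_refine_steps)
    cell <- config$interpolate$cell_size
    if (is.null(cell)) cell <- data$rasters$mcwd$cell
    ext <- c(data$rasters$mcwd$xmin,
             data$rasters$mcwd$xmin + data$rasters$mcwd$ncol *
               data$rasters$mcwd$cell,
             data$rasters$mcwd$ymin,
             data$rasters$mcwd$ymin + data$rasters$mcwd$nrow *
               data$rasters$mcwd$cell)
    folds <- res$cluster$solution$assignment
    surf <- fold_averaged_surface(pts, folds, search$params, ext,
                                  smooth_window =
                                    config$interpolate$smooth_window,
                                  cell = cell)
    res$interpolate <- list(search = search, surface = surf, points = pts)
    write_esri_ascii(surf, file.path(outdir, "surface.asc"))
    emit(search$trace, "loocv_trace")
    timing$interpolate <- as.numeric(Sys.time() - ts, units = "secs")
  }

  if ("crossval" %in% stages) {
    ts <- Sys.time()
    pts <- res$interpolate$points
    if (is.null(pts)) {
      cwm <- res$cwm$table
      pts <- data.frame(x = cwm$x, y = cwm$y, value = cwm$cwm_psi50)
    }
    params <- if (!is.null(res$interpolate)) res$interpolate$search$params
    else idw_params(config$interpolate$idp_grid[1],
                    config$interpolate$nmax_grid[1])
    cv <- spatial_cv(pts, res$cluster$solution$assignment, params,
                     surface = res$interpolate$surface)
    res$crossval <- cv
    emit(cv$folds, "cv_folds")
    emit(data.frame(rmse = cv$rmse, vecv = cv$vecv), "cv_summary")
    if (!is.null(cv$cluster_agreement))
      emit(cv$cluster_agreement, "cluster_agreement")
    timing$crossval <- as.numeric(Sys.time() - ts, units = "secs")
  }

  if ("mess" %in% stages) {
    ts <- Sys.time()
    cwm <- res$cwm$table
    ref <- data.frame(mcwd = grid_extract(data$rasters$mcwd, cwm$x, cwm$y),
                      wtd = grid_extract(data$rasters$wtd, cwm$x, cwm$y))
    ml <- mess(ref, data$rasters)
    res$mess <- ml
    write_esri_ascii(ml$score, file.path(outdir, "mess.asc"))
    timing$mess <- as.numeric(Sys.time() - ts, units = "secs")
  }

  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    config = config,
    version = tryCatch(as.character(utils::packageVersion("hydromap")),
                       error = function(e) "dev"),
    stage_seeds = seeds,
    checksums = as.list(tools::md5sum(files)),
    timing_seconds = timing,
    total_seconds = as.numeric(Sys.time() - t0, units = "secs"))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yml"))
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result with stages:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  invisible(x)
}
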