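#' Simulation configuration for a synthetic analysis bundle
#'
#' Bundles the knobs of the synthetic-data generator. Defaults emulate the
#' scale of the pan-Amazonian setting the package targets: 88 genus tips, an
#' 11-site trait campaign, 448 inventory plots over a 3000 x 2000 km domain,
#' and Brownian-motion trait variation whose tip standard deviation is close
#' to 1 MPa.
#'
#' @param seed integer master seed; stage seeds are derived from it
#'   deterministically.
#' @param n_tips number of genus tips in the simulated phylogeny (>= 2).
#' @param birth_rate Yule speciation rate per unit time (> 0).
#' @param bm_sigma2 Brownian-motion trait variance per unit branch length.
#' @param signal_lambda fraction in \[0, 1\] mixing the Brownian realisation
#'   (1) against i.i.d. white noise of matched marginal variance (0).
#' @param root_value trait value (absolute \eqn{\Psi_{50}}, MPa) at the root.
#' @param n_sites number of trait-campaign sites.
#' @param n_plots number of inventory plots.
#' @param stems_per_plot stems per plot (>= 1).
#' @param domain_extent planar bounding box \code{c(xmin, xmax, ymin, ymax)}
#'   in km.
#' @param gradient_strength dimensionless logistic effect of the west-east
#'   coordinate on the basal-area share of the designated resistant family
#'   (0 = spatially homogeneous composition).
#' @param cell_size raster cell size in km for synthetic covariates.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_tips = 88L, birth_rate = 1,
                       bm_sigma2 = 0.8, signal_lambda = 1, root_value = 2,
                       n_sites = 11L, n_plots = 448L, stems_per_plot = 400L,
                       domain_extent = c(0, 3000, 0, 2000),
                       gradient_strength = 6, cell_size = 50) {
  stopifnot(n_tips >= 2, birth_rate > 0, bm_sigma2 >= 0,
            signal_lambda >= 0, signal_lambda <= 1,
            n_sites >= 1, n_plots >= 1, stems_per_plot >= 1,
            length(domain_extent) == 4, cell_size > 0)
  structure(list(seed = as.integer(seed), n_tips = as.integer(n_tips),
                 birth_rate = birth_rate, bm_sigma2 = bm_sigma2,
                 signal_lambda = signal_lambda, root_value = root_value,
                 n_sites = as.integer(n_sites), n_plots = as.integer(n_plots),
                 stems_per_plot = as.integer(stems_per_plot),
                 domain_extent = domain_extent,
                 gradient_strength = gradient_strength,
                 cell_size = cell_size),
            class = "sim_config")
}

# stage seeds derived from the bundle seed; kept < 2^31
.stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + stage
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Lineages split at a constant per-lineage rate; the process is stopped one
#' exponential waiting time after the split that creates the \code{n_tips}-th
#' lineage, so all pendant branch lengths are strictly positive. With this
#' construction the root-to-tip depth is
#' \eqn{\sum_{k=2}^{n-1} E_k + E_n}, \eqn{E_k \sim Exp(k\lambda)}, with mean
#' \eqn{(H_n - 1)/\lambda} (harmonic number \eqn{H_n}) — a closed form used
#' by the test suite.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate per-lineage speciation rate (> 0).
#' @param seed optional integer seed.
#' @param tip_prefix prefix for tip labels (default \code{"g"}, genera).
#' @return An ultrametric rooted binary \code{ape::phylo} tree.
#' @examples
#' tr <- simulate_yule_tree(10, 1, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                               tip_prefix = "g") {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  # event k (k = 1..n-1) creates lineage pair; waits while k lineages exist
  waits <- stats::rexp(n, rate = birth_rate * seq_len(n))
  # the root split is event 1 at relative time 0; later events at cumsum
  etime <- c(0, cumsum(waits[2:(n - 1)]))          # event times, root = 0
  if (n == 2) etime <- 0
  present <- if (n == 2) waits[2] else etime[n - 1] + waits[n]
  # lineage bookkeeping: parent event, birth time, terminal event (NA = tip)
  max_lin <- 2L * (n - 1L)
  par_ev <- integer(max_lin); birth <- numeric(max_lin)
  split_ev <- rep(NA_integer_, max_lin)
  par_ev[1:2] <- 1L; birth[1:2] <- 0
  alive <- c(1L, 2L); n_lin <- 2L
  for (ev in seq_len(n - 2L)) {
    ev_id <- ev + 1L
    who <- alive[sample.int(length(alive), 1L)]
    split_ev[who] <- ev_id
    c1 <- n_lin + 1L; c2 <- n_lin + 2L
    par_ev[c(c1, c2)] <- ev_id
    birth[c(c1, c2)] <- etime[ev_id]
    alive <- c(alive[alive != who], c1, c2)
    n_lin <- n_lin + 2L
  }
  # ape numbering: tips 1..n, internal nodes n+1..2n-1, root = n+1 = event 1
  tip_ids <- alive
  node_of_event <- n + seq_len(n - 1L)
  tip_no <- integer(max_lin)
  tip_no[tip_ids] <- seq_len(n)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  for (l in seq_len(n_lin)) {
    from <- node_of_event[par_ev[l]]
    if (is.na(split_ev[l])) {
      to <- tip_no[l]; end <- present
    } else {
      to <- node_of_event[split_ev[l]]; end <- etime[split_ev[l]]
    }
    edge[l, ] <- c(from, to)
    elen[l] <- end - birth[l]
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0(tip_prefix, seq_len(n)),
                        Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate tip traits under Brownian motion with a tunable signal fraction
#'
#' Evolves a trait along the tree as Brownian motion with rate
#' \code{sigma2}, then mixes the tip deviations with i.i.d. Gaussian noise
#' whose marginal variance matches the Brownian marginal variance at each tip
#' (\code{sigma2} times root-to-tip depth):
#' \code{x = root + lambda * (bm - root) + (1 - lambda) * noise}. At
#' \code{signal_lambda = 1} the trait is a pure Brownian realisation
#' (Blomberg's K near 1 in expectation); at 0 it carries no phylogenetic
#' signal.
#'
#' @param tree an \code{ape::phylo} tree with branch lengths.
#' @param sigma2 Brownian variance per unit branch length (>= 0).
#' @param signal_lambda signal fraction in \[0, 1\].
#' @param root_value trait value at the root.
#' @param seed optional integer seed.
#' @return Named numeric vector of tip values (names = tip labels).
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, signal_lambda = 1,
                               root_value = 0, seed = NULL) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  stopifnot(sigma2 >= 0, signal_lambda >= 0, signal_lambda <= 1)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tree$tip.label)
  nval <- numeric(n + tree$Nnode)
  root <- n + 1L
  nval[root] <- root_value
  steps <- stats::rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  for (e in seq_len(nrow(tree$edge)))
    nval[tree$edge[e, 2]] <- nval[tree$edge[e, 1]] + steps[e]
  depth <- ape::node.depth.edgelength(tree)[seq_len(n)]
  noise <- stats::rnorm(n, 0, sqrt(sigma2 * depth))
  x <- root_value + signal_lambda * (nval[seq_len(n)] - root_value) +
    (1 - signal_lambda) * noise
  names(x) <- tree$tip.label
  x
}

# cut an ultrametric tree into monophyletic groups at a fraction of its depth
.clade_groups <- function(tree, frac, prefix) {
  cop <- stats::as.dist(ape::cophenetic.phylo(tree))
  hc <- stats::hclust(cop, method = "single")
  depth <- max(ape::node.depth.edgelength(tree))
  # cophenetic distance = 2 * (depth - MRCA depth); cut height picks clades
  grp <- stats::cutree(hc, h = 2 * depth * frac)
  stats::setNames(paste0(prefix, grp), tree$tip.label)
}

#' Simulate a species-by-site trait table with taxonomic structure
#'
#' Genus-level trait values (absolute \eqn{\Psi_{50}}, MPa) are taken from
#' \code{genus_values}; families and orders are defined as the clades
#' obtained by cutting the ultrametric tree at fixed fractions of its depth,
#' so taxonomy is consistent with the phylogeny. Each genus contributes one
#' to three species, each observed at one or more of \code{n_sites} sites
#' with site-level noise; sites carry a dry-season-length climate class.
#'
#' @param tree genus-level phylogeny.
#' @param genus_values named vector of absolute \eqn{\Psi_{50}} per genus
#'   (positive scale, MPa).
#' @param n_sites number of sites.
#' @param species_sd,site_sd standard deviations of species- and record-level
#'   deviations (MPa).
#' @param family_frac,order_frac tree-depth fractions at which family and
#'   order clades are cut.
#' @param seed optional integer seed.
#' @return A \code{data.frame} with columns \code{species}, \code{genus},
#'   \code{family}, \code{order}, \code{site}, \code{forest_type},
#'   \code{psi50} (negative MPa).
#' @export
simulate_trait_table <- function(tree, genus_values, n_sites = 11L,
                                 species_sd = 0.3, site_sd = 0.25,
                                 family_frac = 0.45, order_frac = 0.75,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genera <- tree$tip.label
  stopifnot(all(genera %in% names(genus_values)))
  fam <- .clade_groups(tree, family_frac, "fam")
  ord <- .clade_groups(tree, order_frac, "ord")
  types <- c("long_DSL", "intermediate_DSL", "everwet")
  site_type <- sample(types, n_sites, replace = TRUE,
                      prob = c(0.25, 0.5, 0.25))
  rec <- list(); ri <- 1L
  for (g in genera) {
    n_sp <- sample.int(3L, 1L)
    for (s in seq_len(n_sp)) {
      sp_name <- paste0(g, "_sp", s)
      sp_mean <- genus_values[[g]] + stats::rnorm(1, 0, species_sd)
      k_sites <- sample.int(min(3L, n_sites), 1L)
      sites <- sample.int(n_sites, k_sites)
      for (st in sites) {
        val <- sp_mean + stats::rnorm(1, 0, site_sd)
        rec[[ri]] <- data.frame(species = sp_name, genus = g,
                                family = unname(fam[g]), order = unname(ord[g]),
                                site = paste0("site", st),
                                forest_type = site_type[st],
                                psi50 = -pmax(val, 0.2))
        ri <- ri + 1L
      }
    }
  }
  do.call(rbind, rec)
}

#' Simulate plot inventories with a west-east compositional gradient
#'
#' Plots are placed uniformly in the domain. Per stem, the family is the
#' designated resistant family with probability
#' \code{plogis(gradient_strength * (x / width - 0.5))} (so the expected
#' basal-area share of that family rises monotonically west to east), and
#' otherwise drawn from the remaining families in proportion to their record
#' counts in \code{traits}. Genera and species are drawn within the chosen
#' family; a fraction of stems get unmeasured species epithets (exercising
#' genus-level gap-filling), a small fraction get unknown genera (family-level
#' fill), and a small fraction are monocot palms without trait data. Basal
#' areas are log-normal, emulating right-skewed stem size distributions.
#'
#' @param tree genus-level phylogeny (used for taxonomy via \code{traits}).
#' @param traits trait table from \code{\link{simulate_trait_table}}.
#' @param config a \code{\link{sim_config}}.
#' @param resistant_family family name to put on the gradient; default the
#'   family with the most negative mean \eqn{\Psi_{50}} in \code{traits}.
#' @param p_unmeasured_species probability a stem's species epithet is absent
#'   from the trait table.
#' @param p_unknown_genus probability a stem is identified only to family.
#' @param p_monocot probability a stem is a palm (monocot, no trait family).
#' @return A \code{data.frame} with columns \code{plot_id}, \code{x},
#'   \code{y}, \code{species}, \code{genus}, \code{family},
#'   \code{basal_area}, \code{dicot}.
#' @export
simulate_inventories <- function(tree, traits, config,
                                 resistant_family = NULL,
                                 p_unmeasured_species = 0.35,
                                 p_unknown_genus = 0.05,
                                 p_monocot = 0.03) {
  stopifnot(nrow(traits) > 0)
  set.seed(.stage_seed(config$seed, 3L))
  ext <- config$domain_extent
  fam_mean <- tapply(traits$psi50, traits$family, mean)
  if (is.null(resistant_family))
    resistant_family <- names(which.min(fam_mean))
  fam_tab <- table(traits$family)
  other_fams <- setdiff(names(fam_tab), resistant_family)
  fam_by_genus <- tapply(traits$family, traits$genus, function(f) f[1])
  genera_by_fam <- split(names(fam_by_genus), unname(fam_by_genus))
  species_by_genus <- lapply(split(traits$species, traits$genus), unique)
  n_stem <- config$n_plots * config$stems_per_plot
  px <- stats::runif(config$n_plots, ext[1], ext[2])
  py <- stats::runif(config$n_plots, ext[3], ext[4])
  plot_id <- rep(sprintf("plot%03d", seq_len(config$n_plots)),
                 each = config$stems_per_plot)
  x <- rep(px, each = config$stems_per_plot)
  y <- rep(py, each = config$stems_per_plot)
  u <- (x - ext[1]) / (ext[2] - ext[1])
  p_res <- stats::plogis(config$gradient_strength * (u - 0.5))
  is_mono <- stats::runif(n_stem) < p_monocot
  is_res <- !is_mono & (stats::runif(n_stem) < p_res)
  fam <- character(n_stem)
  fam[is_mono] <- "Arecaceae_syn"
  fam[is_res] <- resistant_family
  n_other <- sum(!is_mono & !is_res)
  fam[!is_mono & !is_res] <- sample(other_fams, n_other, replace = TRUE,
                                    prob = fam_tab[other_fams])
  genus <- character(n_stem); species <- character(n_stem)
  dic <- !is_mono
  genus[is_mono] <- "PalmGenus"
  species[is_mono] <- "PalmGenus_sp1"
  idx <- which(!is_mono)
  genus[idx] <- vapply(fam[idx], function(f) {
    gs <- genera_by_fam[[f]]
    gs[sample.int(length(gs), 1L)]
  }, character(1))
  unk <- idx[stats::runif(length(idx)) < p_unknown_genus]
  unmeas <- setdiff(idx[stats::runif(length(idx)) < p_unmeasured_species], unk)
  known <- setdiff(idx, union(unk, unmeas))
  genus[unk] <- paste0(genus[unk], "_indet")
  species[unk] <- paste0(genus[unk], "_sp")
  species[unmeas] <- paste0(genus[unmeas], "_unm")
  species[known] <- vapply(genus[known], function(g) {
    sp <- species_by_genus[[g]]
    sp[sample.int(length(sp), 1L)]
  }, character(1))
  ba <- stats::rlnorm(n_stem, meanlog = -2.9, sdlog = 1)
  data.frame(plot_id = plot_id, x = x, y = y, species = species,
             genus = genus, family = fam, basal_area = ba, dicot = dic)
}

#' Simulate smooth environmental rasters (MCWD- and WTD-like)
#'
#' Gaussian white noise on the grid is smoothed with repeated mean filters,
#' giving spatially autocorrelated fields, then rescaled to plausible ranges:
#' MCWD-like in roughly \[-600, 0\] mm and WTD-like in \[0, 40\] m. A weak
#' deterministic west-east trend is added to the MCWD field so the two
#' synthetic covariates are not independent of the compositional gradient.
#'
#' @param domain_extent \code{c(xmin, xmax, ymin, ymax)} in km.
#' @param cell_size cell size in km.
#' @param seed optional integer seed.
#' @param smooth_window,smooth_passes smoothing filter width (odd) and number
#'   of passes controlling the autocorrelation range.
#' @param constant optional named list, e.g. \code{list(mcwd = -300)}, to
#'   produce constant fields (degenerate mode used in tests).
#' @return A named list of two \code{grid_raster}s: \code{mcwd}, \code{wtd}.
#' @export
simulate_env_rasters <- function(domain_extent, cell_size, seed = NULL,
                                 smooth_window = NULL, smooth_passes = 3,
                                 constant = NULL) {
  stopifnot(cell_size > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- grid_skeleton(domain_extent, cell_size)
  if (is.null(smooth_window)) {
    smooth_window <- max(3L, 2L * (min(g$nrow, g$ncol) %/% 8L) + 1L)
  }
  field <- function() {
    m <- matrix(stats::rnorm(g$nrow * g$ncol), g$nrow, g$ncol)
    for (i in seq_len(smooth_passes)) m <- mean_filter(m, smooth_window)
    (m - mean(m)) / stats::sd(m)
  }
  xs <- (seq_len(g$ncol) - 0.5) / g$ncol
  trend <- matrix(rep(xs - 0.5, each = g$nrow), g$nrow, g$ncol)
  mcwd <- g; wtd <- g
  mcwd$values <- if (!is.null(constant$mcwd))
    matrix(constant$mcwd, g$nrow, g$ncol)
  else -300 + 120 * field() - 120 * trend
  wtd$values <- if (!is.null(constant$wtd))
    matrix(constant$wtd, g$nrow, g$ncol)
  else pmax(12 + 7 * field(), 0)
  list(mcwd = mcwd, wtd = wtd)
}

#' Simulate a complete synthetic analysis bundle
#'
#' Runs the four generators with stage seeds derived from the master seed,
#' yielding a phylogeny, a trait table, plot inventories and environmental
#' rasters that are mutually consistent (every trait genus is a tip; every
#' dicot inventory family resolves to the trait table).
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list of class \code{synthetic_bundle} with elements \code{tree},
#'   \code{traits}, \code{inventory}, \code{rasters}, \code{config},
#'   \code{resistant_family}.
#' @examples
#' b <- simulate_bundle(sim_config(seed = 1, n_tips = 20, n_plots = 10,
#'                                 stems_per_plot = 25))
#' head(b$traits)
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_yule_tree(config$n_tips, config$birth_rate,
                             seed = .stage_seed(config$seed, 1L))
  gv <- simulate_bm_traits(tree, sigma2 = config$bm_sigma2,
                           signal_lambda = config$signal_lambda,
                           root_value = config$root_value,
                           seed = .stage_seed(config$seed, 2L))
  traits <- simulate_trait_table(tree, gv, n_sites = config$n_sites,
                                 seed = .stage_seed(config$seed, 2L) + 500L)
  inv <- simulate_inventories(tree, traits, config)
  rasters <- simulate_env_rasters(config$domain_extent, config$cell_size,
                                  seed = .stage_seed(config$seed, 4L))
  fam_mean <- tapply(traits$psi50, traits$family, mean)
  structure(list(tree = tree, traits = traits, inventory = inv,
                 rasters = rasters, config = config,
                 resistant_family = names(which.min(fam_mean))),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:\n")
  cat(sprintf("  tree: %d genus tips\n", length(x$tree$tip.label)))
  cat(sprintf("  traits: %d records, %d species, %d families\n",
              nrow(x$traits), length(unique(x$traits$species)),
              length(unique(x$traits$family))))
  cat(sprintf("  inventory: %d stems in %d plots\n", nrow(x$inventory),
              length(unique(x$inventory$plot_id))))
  cat(sprintf("  resistant family: %s\n", x$resistant_family))
  invisible(x)
}

#' Write a synthetic bundle to a directory
#'
#' Emits the tree as Newick, trait and inventory tables as CSV, and the two
#' environmental rasters as ESRI ASCII grids.
#'
#' @param bundle a \code{synthetic_bundle}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(bundle$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$inventory, file.path(dir, "inventory.csv"),
                   row.names = FALSE)
  write_esri_ascii(bundle$rasters$mcwd, file.path(dir, "mcwd.asc"))
  write_esri_ascii(bundle$rasters$wtd, file.path(dir, "wtd.asc"))
  invisible(dir)
}
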