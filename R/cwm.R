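#' @keywords internal
.norm_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

# trait-table lookup means at species / genus / family level.
# level_mean = "record": mean over all species-site records in the group;
# level_mean = "species": mean of species means (mean of means).
.trait_lookups <- function(traits, level_mean = c("record", "species")) {
  level_mean <- match.arg(level_mean)
  sp_mean <- tapply(traits$psi50, .norm_name(traits$species), mean)
  if (level_mean == "record") {
    gen_mean <- tapply(traits$psi50, .norm_name(traits$genus), mean)
    fam_mean <- tapply(traits$psi50, .norm_name(traits$family), mean)
  } else {
    sp_df <- unique(data.frame(sp = .norm_name(traits$species),
                               gen = .norm_name(traits$genus),
                               fam = .norm_name(traits$family)))
    spm <- sp_mean[sp_df$sp]
    gen_mean <- tapply(spm, sp_df$gen, mean)
    fam_mean <- tapply(spm, sp_df$fam, mean)
  }
  list(species = sp_mean, genus = gen_mean, family = fam_mean)
}

#' Taxonomic gap-filling of trait values onto inventory stems
#'
#' Assigns a \eqn{\Psi_{50}} value to every inventory record from the finest
#' available taxonomic level: the species mean when the species was
#' measured, else the genus mean, else the family mean, else the plot mean
#' (the basal-area-weighted mean of the records in the same plot already
#' resolved at a finer level). Name matching is exact after whitespace and
#' case normalisation.
#'
#' @param inventory inventory table with columns \code{plot_id},
#'   \code{species}, \code{genus}, \code{family}, \code{basal_area}.
#' @param traits trait table with \code{species}, \code{genus},
#'   \code{family}, \code{psi50}.
#' @param level_mean how genus/family means aggregate the trait records:
#'   \code{"record"} (mean over species-site records, default) or
#'   \code{"species"} (mean of species means).
#' @param plot_mean_weighted logical; basal-area-weight the plot-mean
#'   fallback (default TRUE, consistent with the CWM) or use the unweighted
#'   mean.
#' @return \code{inventory} with two extra columns: \code{psi50_filled}
#'   (MPa) and \code{fill_level} (factor: species, genus, family,
#'   plot_mean).
#' @export
gap_fill <- function(inventory, traits, level_mean = "record",
                     plot_mean_weighted = TRUE) {
  stopifnot(all(c("plot_id", "species", "genus", "family", "basal_area")
                %in% names(inventory)))
  lk <- .trait_lookups(traits, level_mean)
  sp <- .norm_name(inventory$species)
  gen <- .norm_name(inventory$genus)
  fam <- .norm_name(inventory$family)
  val <- as.vector(lk$species[sp])
  level <- ifelse(!is.na(val), "species", NA)
  idx <- is.na(val)
  val[idx] <- as.vector(lk$genus[gen[idx]])
  level[idx & !is.na(val)] <- "genus"
  idx <- is.na(val)
  val[idx] <- as.vector(lk$family[fam[idx]])
  level[idx & !is.na(val)] <- "family"
  idx <- is.na(val)
  if (any(idx)) {
    for (p in unique(inventory$plot_id[idx])) {
      inplot <- inventory$plot_id == p
      resolved <- inplot & !is.na(val)
      if (!any(resolved))
        stop("plot ", p, " has no records resolvable at any level ",
             "(unfillable plot)", call. = FALSE)
      pm <- if (plot_mean_weighted)
        stats::weighted.mean(val[resolved], inventory$basal_area[resolved])
      else mean(val[resolved])
      val[inplot & is.na(val)] <- pm
      level[inplot & is.na(level)] <- "plot_mean"
    }
  }
  out <- inventory
  out$psi50_filled <- val
  out$fill_level <- factor(level,
                           levels = c("species", "genus", "family",
                                      "plot_mean"))
  out
}

#' Family-composition coverage filter for the mapping exercise
#'
#' Computes, per plot, the fraction of dicotyledonous basal area belonging
#' to families present in the trait database, and flags plots reaching the
#' coverage threshold (60\% by default). Monocots are excluded from the
#' denominator.
#'
#' @param inventory inventory table with a logical \code{dicot} column.
#' @param traits trait table.
#' @param threshold minimum coverage fraction for a plot to pass.
#' @return A data.frame (\code{plot_id}, \code{coverage}, \code{pass}).
#' @export
coverage_filter <- function(inventory, traits, threshold = 0.60) {
  stopifnot("dicot" %in% names(inventory))
  covered_fams <- unique(.norm_name(traits$family))
  d <- inventory[inventory$dicot, , drop = FALSE]
  tot <- tapply(d$basal_area, d$plot_id, sum)
  if (any(is.na(tot)) || any(tot == 0) ||
      !all(unique(inventory$plot_id) %in% names(tot)))
    stop("plot(s) with zero dicot basal area: coverage undefined",
         call. = FALSE)
  cov_ba <- tapply(d$basal_area * (.norm_name(d$family) %in% covered_fams),
                   d$plot_id, sum)
  data.frame(plot_id = names(tot), coverage = unname(cov_ba / tot),
             pass = unname(cov_ba / tot >= threshold),
             row.names = NULL)
}

#' Community-weighted mean Psi50 per plot
#'
#' The CWM weights each record's (gap-filled) trait value by its share of
#' the plot's total basal area:
#' \eqn{CWM = \sum_i BA_i \psi_i / \sum_i BA_i}. The fill profile reports
#' which fraction of the basal area was resolved at each taxonomic level.
#'
#' @param filled output of \code{\link{gap_fill}} (columns
#'   \code{psi50_filled}, \code{fill_level} present).
#' @return A data.frame of class \code{cwm_table}: \code{plot_id}, plot
#'   coordinates if present (\code{x}, \code{y}), \code{cwm_psi50},
#'   \code{total_ba} and fill-profile fractions \code{frac_species},
#'   \code{frac_genus}, \code{frac_family}, \code{frac_plot_mean}.
#' @export
community_weighted_mean <- function(filled) {
  stopifnot(all(c("psi50_filled", "fill_level") %in% names(filled)))
  plots <- split(filled, filled$plot_id)
  rows <- lapply(plots, function(p) {
    tot <- sum(p$basal_area)
    if (tot <= 0) stop("plot ", p$plot_id[1],
                       " has zero total basal area", call. = FALSE)
    prof <- tapply(p$basal_area, p$fill_level, sum, default = 0) / tot
    out <- data.frame(plot_id = p$plot_id[1],
                      cwm_psi50 = sum(p$basal_area * p$psi50_filled) / tot,
                      total_ba = tot,
                      frac_species = prof[["species"]],
                      frac_genus = prof[["genus"]],
                      frac_family = prof[["family"]],
                      frac_plot_mean = prof[["plot_mean"]])
    if (all(c("x", "y") %in% names(p))) {
      out$x <- p$x[1]; out$y <- p$y[1]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cwm_table", "data.frame")
  out
}

#' @export
print.cwm_table <- function(x, ...) {
  cat(sprintf("cwm_table: %d plots, CWM Psi50 in [%.2f, %.2f] MPa\n",
              nrow(x), min(x$cwm_psi50), max(x$cwm_psi50)))
  NextMethod()
}

#' Validate the gap-filling procedure against species-level CWMs
#'
#' For plots whose stems can all be resolved at the species level, computes
#' the CWM twice — once from species values and once with every species
#' value replaced by its family mean (simulating the coarsest informative
#' gap-fill) — and regresses the family-filled CWM on the species-level CWM.
#' High \eqn{R^2} indicates that between-family differences carry most of
#' the community-level trait structure, justifying family-level imputation.
#'
#' @param inventory inventory table.
#' @param traits trait table.
#' @param min_species_frac minimum fraction of a plot's basal area that must
#'   be resolvable at species level for the plot to enter the validation.
#' @param level_mean passed to \code{\link{gap_fill}} lookups.
#' @return A list of class \code{gapfill_validation}: \code{r_squared},
#'   \code{slope}, \code{intercept}, \code{p_value}, \code{n_plots},
#'   \code{plots} (data.frame of the paired CWMs).
#' @export
gapfill_validation <- function(inventory, traits, min_species_frac = 1,
                               level_mean = "record") {
  lk <- .trait_lookups(traits, level_mean)
  sp <- .norm_name(inventory$species)
  fam <- .norm_name(inventory$family)
  sp_val <- as.vector(lk$species[sp])
  ok <- !is.na(sp_val)
  frac <- tapply(inventory$basal_area * ok, inventory$plot_id, sum) /
    tapply(inventory$basal_area, inventory$plot_id, sum)
  use_plots <- names(frac)[frac >= min_species_frac]
  d <- inventory[inventory$plot_id %in% use_plots & ok, , drop = FALSE]
  if (length(use_plots) < 3)
    stop("fewer than 3 plots with species-level support", call. = FALSE)
  fam_val <- as.vector(lk$family[.norm_name(d$family)])
  spv <- as.vector(lk$species[.norm_name(d$species)])
  cwm_sp <- tapply(d$basal_area * spv, d$plot_id, sum) /
    tapply(d$basal_area, d$plot_id, sum)
  cwm_fam <- tapply(d$basal_area * fam_val, d$plot_id, sum) /
    tapply(d$basal_area, d$plot_id, sum)
  fit <- stats::lm(cwm_fam ~ cwm_sp)
  sm <- summary(fit)
  structure(list(r_squared = sm$r.squared,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = sm$coefficients[2, 4],
                 n_plots = length(cwm_sp),
                 plots = data.frame(plot_id = names(cwm_sp),
                                    cwm_species = unname(cwm_sp),
                                    cwm_family = unname(cwm_fam))),
            class = "gapfill_validation")
}

#' @export
print.gapfill_validation <- function(x, ...) {
  cat(sprintf(
    "gap-fill validation: R^2 = %.3f, slope = %.3f, p = %.3g (%d plots)\n",
    x$r_squared, x$slope, x$p_value, x$n_plots))
  invisible(x)
}
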