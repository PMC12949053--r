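#' Replication-based subset for the nested taxonomic ANOVA
#'
#' Restricts a species-by-site trait table to groups with enough internal
#' replication for a family/genus/species nested analysis of variance:
#' a genus is kept when it has more than one species, or when one of its
#' species was sampled in more than one site; a family is kept when it has
#' at least two genera, or when one of its genera was sampled in more than
#' one site. Records must satisfy both the genus and the family rule.
#'
#' @param table trait table with columns \code{species}, \code{genus},
#'   \code{family}, \code{site}, \code{psi50}.
#' @return The filtered table, with attribute \code{counts} (named vector:
#'   families, genera, species, records).
#' @export
select_nested_subset <- function(table) {
  stopifnot(all(c("species", "genus", "family", "site") %in% names(table)))
  sp_per_genus <- tapply(table$species, table$genus,
                         function(s) length(unique(s)))
  multi_site_sp <- tapply(table$site, paste(table$genus, table$species),
                          function(s) length(unique(s)) > 1)
  genus_of_pair <- sub(" .*$", "", names(multi_site_sp))
  genus_multi <- tapply(multi_site_sp, genus_of_pair, any)
  genus_ok <- names(sp_per_genus)[sp_per_genus > 1 |
                                    genus_multi[names(sp_per_genus)]]
  gen_per_family <- tapply(table$genus, table$family,
                           function(g) length(unique(g)))
  multi_site_gen <- tapply(table$site, paste(table$family, table$genus),
                           function(s) length(unique(s)) > 1)
  family_of_pair <- sub(" .*$", "", names(multi_site_gen))
  family_multi <- tapply(multi_site_gen, family_of_pair, any)
  family_ok <- names(gen_per_family)[gen_per_family >= 2 |
                                       family_multi[names(gen_per_family)]]
  out <- table[table$genus %in% genus_ok & table$family %in% family_ok, ,
               drop = FALSE]
  if (nrow(out) == 0)
    stop("replication filter removed every record (empty subset)",
         call. = FALSE)
  attr(out, "counts") <- c(families = length(unique(out$family)),
                           genera = length(unique(out$genus)),
                           species = length(unique(out$species)),
                           records = nrow(out))
  out
}

#' Nested ANOVA of Psi50 across taxonomic levels
#'
#' Sequential (Type-I) analysis of variance with species nested in genus
#' nested in family, each term tested against the residual mean square.
#' The trait is transformed first (square root of \eqn{|\Psi_{50}|} by
#' default, the conventional normalising transform for this right-skewed
#' trait).
#'
#' @param table trait table (see \code{\link{select_nested_subset}}).
#' @param transformation \code{"none"}, \code{"sqrt"}, or \code{"cbrt"},
#'   applied via \code{abs(psi50)}.
#' @return A list of class \code{nested_anova} with a \code{table}
#'   data.frame (term, df, ss, ms, statistic, p) including the residual row,
#'   plus \code{transformation}.
#' @export
nested_anova <- function(table, transformation = "sqrt") {
  y <- .apply_transformation(table$psi50, transformation)
  d <- data.frame(y = y, family = factor(table$family))
  # explicit nested factors keep the design matrix at one column per group
  d$genus <- interaction(d$family, factor(table$genus), drop = TRUE)
  d$species <- interaction(d$genus, factor(table$species), drop = TRUE)
  if (nlevels(d$family) < 2)
    stop("need at least 2 families", call. = FALSE)
  fit <- stats::aov(y ~ family + genus + species, data = d)
  sm <- summary(fit)[[1]]
  if (sm[nrow(sm), "Df"] == 0)
    stop("no residual degrees of freedom (saturated model)", call. = FALSE)
  terms <- c("family", "genus_in_family", "species_in_genus", "residual")
  out <- data.frame(term = terms[seq_len(nrow(sm))],
                    df = sm[, "Df"], ss = sm[, "Sum Sq"],
                    ms = sm[, "Mean Sq"],
                    statistic = sm[, "F value"], p = sm[, "Pr(>F)"])
  structure(list(table = out, transformation = transformation),
            class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat("Nested ANOVA (family / genus / species), transformation =",
      x$transformation, "\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# Piepho-style insert-and-absorb compact letter display.
# 'diff' is a logical matrix (upper triangle used) of significant pairs.
.letter_display <- function(levels, diff) {
  groups <- list(seq_along(levels))
  for (i in seq_along(levels)) for (j in seq_along(levels)) {
    if (j <= i || !diff[i, j]) next
    new_groups <- list()
    for (g in groups) {
      if (i %in% g && j %in% g) {
        new_groups <- c(new_groups, list(setdiff(g, i)), list(setdiff(g, j)))
      } else {
        new_groups <- c(new_groups, list(g))
      }
    }
    # absorb: drop groups contained in another group
    keep <- rep(TRUE, length(new_groups))
    for (a in seq_along(new_groups)) for (b in seq_along(new_groups)) {
      if (a == b || !keep[a] || !keep[b]) next
      sub <- all(new_groups[[a]] %in% new_groups[[b]])
      proper <- length(new_groups[[a]]) < length(new_groups[[b]])
      if (sub && (proper || a > b)) keep[a] <- FALSE
    }
    groups <- new_groups[keep]
  }
  letters_out <- vapply(seq_along(levels), function(i) {
    paste(letters[which(vapply(groups, function(g) i %in% g, logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(letters_out, levels)
}

#' One-way ANOVA across families with Tukey HSD letters
#'
#' Keeps families sampled in at least \code{min_sites} distinct sites,
#' fits a one-way ANOVA of \eqn{\Psi_{50}} on family, runs Tukey's HSD on
#' all family pairs (studentized-range adjustment), and summarises the
#' pairwise pattern as a compact letter display in which families sharing a
#' letter do not differ at \code{alpha}.
#'
#' @param table trait table.
#' @param min_sites minimum number of distinct sites a family must occur in.
#' @param alpha significance level for the letter display.
#' @param transformation trait transformation (default none: MPa scale).
#' @return A list of class \code{family_anova}: \code{anova} (one-row
#'   data.frame with statistic, df1, df2, p), \code{tukey} (pairwise table),
#'   \code{letters} (named character), \code{families}, \code{min_sites}.
#' @export
family_anova_tukey <- function(table, min_sites = 3, alpha = 0.05,
                               transformation = "none") {
  sites_per_fam <- tapply(table$site, table$family,
                          function(s) length(unique(s)))
  fams <- names(sites_per_fam)[sites_per_fam >= min_sites]
  if (length(fams) < 2)
    stop("fewer than 2 families pass the min_sites filter", call. = FALSE)
  d <- table[table$family %in% fams, , drop = FALSE]
  d$y <- .apply_transformation(d$psi50, transformation)
  d$family <- factor(d$family)
  fit <- stats::aov(y ~ family, data = d)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$family
  lev <- levels(d$family)
  diffm <- matrix(FALSE, length(lev), length(lev),
                  dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_len(nrow(tk))) {
    i <- pairs[[r]][1]; j <- pairs[[r]][2]
    sig <- tk[r, "p adj"] < alpha
    diffm[i, j] <- diffm[j, i] <- sig
  }
  structure(list(
    anova = data.frame(statistic = sm[1, "F value"], df1 = sm[1, "Df"],
                       df2 = sm[2, "Df"], p = sm[1, "Pr(>F)"]),
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                       p_adj = tk[, "p adj"], row.names = NULL),
    letters = .letter_display(lev, diffm),
    families = fams, min_sites = min_sites, alpha = alpha),
    class = "family_anova")
}

#' @export
print.family_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA across %d families (>= %d sites): F = %.3f, df = %d, p = %.4g\n",
    length(x$families), x$min_sites, x$anova$statistic, x$anova$df1,
    x$anova$p))
  cat("Tukey HSD letters:\n")
  print(x$letters)
  invisible(x)
}

#' Wilcoxon rank-sum test (Mann-Whitney) between two groups
#'
#' W is the rank sum of the first group minus its minimum possible value
#' (so \code{0 <= W <= n1 * n2}), using midranks for ties. The p-value is
#' exact (enumeration) when both groups have fewer than 50 values and no
#' ties are present, and otherwise uses the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction — the standard
#' "rank sum test with continuity correction".
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @return A list of class \code{rank_test}: \code{W}, \code{p_value},
#'   \code{n_a}, \code{n_b}, \code{mean_a}, \code{sd_a}, \code{mean_b},
#'   \code{sd_b}, \code{method}.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            correct = TRUE))
  structure(list(W = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(group_a), n_b = length(group_b),
                 mean_a = mean(group_a), sd_a = stats::sd(group_a),
                 mean_b = mean(group_b), sd_b = stats::sd(group_b),
                 method = wt$method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank sum: W = %g, p = %.4g (n = %d vs %d)\n",
              x$W, x$p_value, x$n_a, x$n_b))
  cat(sprintf("  group means: %.2f +/- %.2f vs %.2f +/- %.2f\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  invisible(x)
}

#' Contrast one family against all others in Psi50
#'
#' Rank-sum comparison of a focal family (Fabaceae in the motivating
#' analysis) against all other records, optionally within one forest type
#' (dry-season-length class). The focal family is group A, so small W with
#' more negative \eqn{\Psi_{50}} values indicates a more embolism-resistant
#' focal family.
#'
#' @param table trait table with \code{family}, \code{psi50} and (if
#'   filtering) \code{forest_type}.
#' @param family focal family name.
#' @param forest_type optional forest-type filter
#'   (\code{"long_DSL"}, \code{"intermediate_DSL"}, \code{"everwet"}).
#' @return A \code{rank_test} (see \code{\link{wilcoxon_rank_sum}}) with
#'   extra fields \code{family} and \code{forest_type}.
#' @export
fabaceae_contrast <- function(table, family = "Fabaceae",
                              forest_type = NULL) {
  d <- table
  if (!is.null(forest_type)) {
    d <- d[d$forest_type == forest_type, , drop = FALSE]
  }
  a <- d$psi50[d$family == family]
  b <- d$psi50[d$family != family]
  if (!length(a) || !length(b))
    stop("insufficient data: one of the partitions is empty",
         call. = FALSE)
  out <- wilcoxon_rank_sum(a, b)
  out$family <- family
  out$forest_type <- if (is.null(forest_type)) "all" else forest_type
  out
}

#' Choose a normalising transformation by Shapiro-Wilk screening
#'
#' Applies the candidate transformations \code{none}, \code{sqrt},
#' \code{cbrt} to \code{abs(values)} in that order and returns the first
#' whose Shapiro-Wilk normality p-value reaches \code{threshold}; if none
#' does, the transformation with the largest p-value is returned. This
#' codifies the usual screen-histograms-then-test workflow for right-skewed
#' hydraulic traits.
#'
#' @param values numeric vector (n >= 3, non-constant).
#' @param threshold Shapiro-Wilk p-value considered "normal enough".
#' @return A list of class \code{transformation_choice}:
#'   \code{transformation}, \code{report} (data.frame of candidate,
#'   shapiro_w, shapiro_p, selected), \code{threshold}.
#' @export
choose_transformation <- function(values, threshold = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3)
    stop("need at least 3 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("values are constant (degenerate)", call. = FALSE)
  cand <- c("none", "sqrt", "cbrt")
  res <- lapply(cand, function(tr) {
    v <- .apply_transformation(values, tr)
    sw <- stats::shapiro.test(v)
    c(w = unname(sw$statistic), p = sw$p.value)
  })
  rep_df <- data.frame(candidate = cand,
                       shapiro_w = vapply(res, `[[`, numeric(1), "w"),
                       shapiro_p = vapply(res, `[[`, numeric(1), "p"))
  hit <- which(rep_df$shapiro_p >= threshold)
  chosen <- if (length(hit)) rep_df$candidate[hit[1]] else
    rep_df$candidate[which.max(rep_df$shapiro_p)]
  rep_df$selected <- rep_df$candidate == chosen
  structure(list(transformation = chosen, report = rep_df,
                 threshold = threshold),
            class = "transformation_choice")
}

#' @export
print.transformation_choice <- function(x, ...) {
  cat("chosen transformation:", x$transformation, "\n")
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}
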