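make_trait_table <- function(families, genera, species, sites, psi50) {
  data.frame(family = families, genus = genera, species = species,
             site = sites, psi50 = psi50,
             forest_type = "intermediate_DSL")
}

test_that("nested-subset filter applies the replication rules", {
  tab <- make_trait_table(
    families = c("F1", "F1", "F1", "F2", "F3", "F3"),
    genera   = c("g1", "g1", "g2", "g3", "g4", "g4"),
    species  = c("s1", "s2", "s3", "s4", "s5", "s5"),
    sites    = c("a", "a", "a", "a", "a", "b"),
    psi50    = c(-1, -2, -3, -4, -5, -6))
  sub <- select_nested_subset(tab)
  # F2 has one genus, one species, one site: excluded entirely
  expect_false("F2" %in% sub$family)
  # g1 has two species: retained; g2 rides along in F1 only if it qualifies
  expect_true("g1" %in% sub$genus)
  expect_false("g2" %in% sub$genus)   # single species, single site
  # g4/F3: same species sampled in two sites: retained
  expect_true("g4" %in% sub$genus)

  # rule-by-rule oracle written as explicit set passes
  b <- small_bundle(seed = 31)$traits
  genus_ok <- vapply(unique(b$genus), function(g) {
    d <- b[b$genus == g, ]
    length(unique(d$species)) > 1 ||
      any(vapply(unique(d$species), function(s)
        length(unique(d$site[d$species == s])) > 1, logical(1)))
  }, logical(1))
  family_ok <- vapply(unique(b$family), function(f) {
    d <- b[b$family == f, ]
    length(unique(d$genus)) >= 2 ||
      any(vapply(unique(d$genus), function(g)
        length(unique(d$site[d$genus == g])) > 1, logical(1)))
  }, logical(1))
  want <- b[b$genus %in% names(genus_ok)[genus_ok] &
              b$family %in% names(family_ok)[family_ok], ]
  got <- select_nested_subset(b)
  expect_equal(got$psi50, want$psi50)
  expect_equal(got$species, want$species)
})

test_that("nested anova reproduces a hand-computed balanced decomposition", {
  # 2 families x 2 genera x 2 species x 3 replicates, integer-friendly data
  d <- expand.grid(rep = 1:3, species = 1:2, genus = 1:2, family = 1:2)
  d$species <- paste0("f", d$family, "g", d$genus, "s", d$species)
  d$genus <- paste0("f", d$family, "g", d$genus)
  d$family <- paste0("f", d$family)
  set.seed(5)
  eff <- c(f1 = 1, f2 = 4)
  geff <- stats::setNames(c(0, 1, 0, 2), unique(d$genus))
  seff <- stats::setNames(seq(0, 0.7, .1), unique(d$species))
  y <- eff[d$family] + geff[d$genus] + seff[d$species] + round(rnorm(24), 1)
  d$psi50 <- -y
  d$site <- "a"
  res <- nested_anova(d, transformation = "none")
  # oracle: sequential decomposition from group means (balanced design)
  yv <- d$psi50
  gm <- mean(yv)
  fm <- tapply(yv, d$family, mean)[d$family]
  gmn <- tapply(yv, d$genus, mean)[d$genus]
  smn <- tapply(yv, d$species, mean)[d$species]
  ss_f <- sum((fm - gm)^2)
  ss_g <- sum((gmn - fm)^2)
  ss_s <- sum((smn - gmn)^2)
  ss_r <- sum((yv - smn)^2)
  expect_equal(res$table$ss, c(ss_f, ss_g, ss_s, ss_r), tolerance = 1e-10)
  expect_equal(res$table$df, c(1, 2, 4, 16))
  expect_equal(res$table$statistic[1], (ss_f / 1) / (ss_r / 16),
               tolerance = 1e-10)
})

test_that("nested anova SS are invariant to record order and dominated by a planted family split", {
  b <- small_bundle(seed = 32)$traits
  sub <- select_nested_subset(b)
  r1 <- nested_anova(sub)
  r2 <- nested_anova(sub[sample(nrow(sub)), ])
  expect_equal(r1$table$ss, r2$table$ss, tolerance = 1e-10)

  tab <- make_trait_table(
    families = rep(c("F1", "F2"), each = 6),
    genera = rep(c("g1", "g2", "g3", "g4"), each = 3),
    species = rep(paste0("s", 1:4), each = 3),
    sites = rep(c("a", "b", "c"), 4),
    psi50 = c(rnorm(6, -1, 0.05), rnorm(6, -6, 0.05)))
  res <- nested_anova(tab, transformation = "none")
  expect_gt(res$table$ss[1] / sum(res$table$ss), 0.9)
})

test_that("family anova + tukey separates constructed groups and letters behave", {
  set.seed(8)
  tab <- make_trait_table(
    families = rep(c("A", "B", "C"), each = 10),
    genera = "g", species = "s",
    sites = rep(c("x", "y", "z"), 10),
    psi50 = c(rnorm(10, -1, 0.1), rnorm(10, -2, 0.1), rnorm(10, -3, 0.1)))
  fa <- family_anova_tukey(tab, min_sites = 1)
  expect_length(unique(fa$letters), 3)

  tab2 <- tab
  tab2$psi50 <- rep(rnorm(10, -2, 0.1), 3)
  fa2 <- family_anova_tukey(tab2, min_sites = 1)
  expect_equal(unname(fa2$letters), rep("a", 3))
  expect_lt(fa2$anova$statistic, 1e-10)

  expect_error(family_anova_tukey(tab, min_sites = 99), "min_sites")
})

test_that("tukey adjusted p matches the studentized-range quadrature oracle", {
  set.seed(9)
  tab <- make_trait_table(
    families = rep(c("A", "B", "C"), each = 8),
    genera = "g", species = "s", sites = "x",
    psi50 = -c(rnorm(8, 1.0, 0.4), rnorm(8, 1.4, 0.4), rnorm(8, 1.8, 0.4)))
  fa <- family_anova_tukey(tab, min_sites = 1)
  fit <- stats::aov(psi50 ~ family, data = transform(tab, family = factor(family)))
  msq <- summary(fit)[[1]][2, "Mean Sq"]
  df <- summary(fit)[[1]][2, "Df"]
  means <- tapply(tab$psi50, tab$family, mean)
  for (r in seq_len(nrow(fa$tukey))) {
    pr <- strsplit(fa$tukey$pair[r], "-")[[1]]
    q <- abs(means[pr[1]] - means[pr[2]]) / sqrt(msq / 8)
    expect_equal(fa$tukey$p_adj[r], oracle_tukey_p(q, 3, df),
                 tolerance = 1e-4)
  }
  # Tukey adjustment never reports smaller p than the unadjusted pairwise
  # comparison on the same pooled error
  for (r in seq_len(nrow(fa$tukey))) {
    pr <- strsplit(fa$tukey$pair[r], "-")[[1]]
    tstat <- abs(means[pr[1]] - means[pr[2]]) / sqrt(2 * msq / 8)
    p_unadj <- 2 * stats::pt(-tstat, df)
    expect_gte(fa$tukey$p_adj[r], p_unadj - 1e-10)
  }
})

test_that("wilcoxon rank sum matches enumeration, symmetry and swap identities", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$W, 0)
  expect_equal(w$p_value, 0.1)
  expect_equal(w$p_value, oracle_wilcox_exact(c(1, 2, 3), c(4, 5, 6)))

  set.seed(10)
  a <- rnorm(7); b <- rnorm(7)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value, oracle_wilcox_exact(a, b),
               tolerance = 1e-12)

  # swapping groups maps W -> n_a n_b - W with the same p
  wab <- wilcoxon_rank_sum(a, b); wba <- wilcoxon_rank_sum(b, a)
  expect_equal(wab$W, 49 - wba$W)
  expect_equal(wab$p_value, wba$p_value)

  # identical multisets: W = n^2 / 2 (midranks), p near 1
  v <- c(1, 2, 3, 4)
  ws <- wilcoxon_rank_sum(v, v)
  expect_equal(ws$W, 8)
  expect_gt(ws$p_value, 0.9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("family contrast detects planted shifts and errors on empty partitions", {
  set.seed(12)
  shifted <- function(seed) {
    set.seed(seed)
    make_trait_table(
      families = rep(c("Fabaceae", "Other"), each = 30),
      genera = "g", species = "s", sites = "x",
      psi50 = c(rnorm(30, -3, 1), rnorm(30, -2, 1)))
  }
  hits <- vapply(1:40, function(s)
    fabaceae_contrast(shifted(s))$p_value < 0.05, logical(1))
  expect_gte(mean(hits), 0.8)

  tab <- shifted(1)
  tab$forest_type <- rep(c("everwet", "long_DSL"), 30)
  tab$forest_type[tab$family == "Fabaceae"] <- "everwet"
  expect_error(fabaceae_contrast(tab, forest_type = "long_DSL"),
               "insufficient")
})

test_that("null family contrast p-values are uniform", {
  pv <- vapply(1:150, function(s) {
    set.seed(20000 + s)
    tab <- make_trait_table(
      families = rep(c("Fabaceae", "Other"), each = 15),
      genera = "g", species = "s", sites = "x",
      psi50 = rnorm(30, -2, 1))
    fabaceae_contrast(tab)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("transformation chooser follows the shapiro-wilk rule", {
  set.seed(14)
  x <- rnorm(200, 10)
  expect_equal(choose_transformation(x)$transformation, "none")

  y <- abs(rnorm(200))^4    # heavily right-skewed: sqrt insufficient
  ct <- choose_transformation(y)
  rep <- ct$report
  # the chooser must agree with its own stated rule
  hit <- which(rep$shapiro_p >= 0.05)
  want <- if (length(hit)) rep$candidate[hit[1]] else
    rep$candidate[which.max(rep$shapiro_p)]
  expect_equal(ct$transformation, want)
  expect_true(ct$transformation %in% c("cbrt", "sqrt"))
  expect_gt(rep$shapiro_p[rep$candidate == "cbrt"],
            rep$shapiro_p[rep$candidate == "none"])

  expect_error(choose_transformation(c(1, 2)), "at least 3")
  expect_error(choose_transformation(rep(5, 10)), "constant")
})
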