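# Statistical comparisons applied to relatedness summaries and colony
# metrics. All omnibus/pairwise machinery is delegated to base R
# (aov/TukeyHSD, kruskal.test, cor.test, t.test, fisher.test, lm); the
# Nemenyi post hoc test is implemented here since it has no base
# equivalent.

new_test_report <- function(test, statistic, p_value, posthoc = NULL,
                            transform = "none", unit = NA_character_,
                            details = NULL) {
  structure(
    list(test = test, statistic = unname(statistic), p_value = unname(p_value),
         posthoc = posthoc, transform = transform, sampling_unit = unit,
         details = details),
    class = "test_report"
  )
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$test, x$statistic, x$p_value))
  if (x$transform != "none") cat(" (", x$transform, "-transformed)", sep = "")
  cat("\n")
  if (!is.null(x$posthoc) && nrow(x$posthoc)) {
    for (k in seq_len(nrow(x$posthoc))) {
      cat(sprintf("  %s vs %s: p = %.4g\n", x$posthoc$group1[k],
                  x$posthoc$group2[k], x$posthoc$p_value[k]))
    }
  }
  invisible(x)
}

# Nemenyi pairwise rank comparisons after a Kruskal-Wallis test, using
# the chi-square approximation with the tie correction.
nemenyi_posthoc <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  N <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  n_i <- tapply(rk, groups, length)
  ties <- table(rk)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  cmb <- utils::combn(levels(groups), 2L)
  p <- numeric(ncol(cmb)); stat <- numeric(ncol(cmb))
  for (m in seq_len(ncol(cmb))) {
    a <- cmb[1L, m]; b <- cmb[2L, m]
    D <- abs(mean_rank[a] - mean_rank[b])
    chi <- D^2 / ((N * (N + 1) / 12) * (1 / n_i[a] + 1 / n_i[b])) / C
    stat[m] <- chi
    p[m] <- stats::pchisq(chi, df = k - 1, lower.tail = FALSE)
  }
  data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ], statistic = stat,
             p_value = p, stringsAsFactors = FALSE)
}

#' Compare a per-tree metric among species
#'
#' Omnibus test with post hoc pairwise comparisons: either one-way ANOVA
#' with Tukey's honest significant difference test, or a Kruskal-Wallis
#' test with the Nemenyi post hoc test (chi-square approximation with tie
#' correction). The family is the caller's choice — by convention made on
#' inspection of the metric's distribution, not an automated gate.
#'
#' @param values numeric per-tree metric.
#' @param groups species label per value.
#' @param family `"anova"` (+ Tukey HSD) or `"kwt"` (+ Nemenyi).
#' @return a `test_report` with the omnibus statistic, p-value and a
#'   post hoc pairwise table.
#' @export
compare_species <- function(values, groups, family = c("anova", "kwt")) {
  family <- match.arg(family)
  if (length(values) != length(groups)) stop_arg("length mismatch")
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  tab <- table(groups)
  if (nlevels(groups) < 2L || any(tab < 2L)) {
    stop_arg("need >= 2 groups with >= 2 values each")
  }
  if (stats::var(values) == 0) stop_arg("constant data: no variance to test")
  if (family == "anova") {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$groups
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    posthoc <- data.frame(
      group1 = vapply(nm, `[`, character(1), 1L),
      group2 = vapply(nm, `[`, character(1), 2L),
      statistic = tk[, "diff"], p_value = tk[, "p adj"],
      stringsAsFactors = FALSE
    )
    new_test_report("ANOVA + Tukey HSD", an$`F value`[1L], an$`Pr(>F)`[1L],
                    posthoc, unit = "tree")
  } else {
    kw <- stats::kruskal.test(values, groups)
    posthoc <- nemenyi_posthoc(values, groups)
    new_test_report("Kruskal-Wallis + Nemenyi", kw$statistic, kw$p.value,
                    posthoc, unit = "tree")
  }
}

#' One-tailed t test of between-tree relatedness against zero
#'
#' Tests whether a species' between-tree relatedness distribution is
#' greater than zero, with tree-pair means as the sampling unit.
#'
#' @param values numeric vector (per-tree-pair means).
#' @return a `test_report`.
#' @export
ttest_vs_zero <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop_arg("need at least two values")
  if (stats::sd(values) == 0 && values[1L] == 0) {
    # all values exactly zero: t = 0/0; under the symmetric null the
    # one-tailed p sits at its boundary value of 0.5
    return(new_test_report("one-tailed t vs 0", 0, 0.5, unit = "tree pair"))
  }
  tt <- stats::t.test(values, mu = 0, alternative = "greater")
  new_test_report("one-tailed t vs 0", tt$statistic, tt$p.value,
                  unit = "tree pair")
}

#' Tree-size effects on a colony metric
#'
#' Correlation between a per-tree metric and tree size (height), plus an
#' analysis of covariance `metric ~ species + size` (no interaction
#' term). The correlation is Pearson (optionally on square-root
#' transformed metric values, the convention for mate counts) or
#' Spearman.
#'
#' @param metric numeric per-tree metric.
#' @param size per-tree size covariate (height in m, or stem diameter).
#' @param species species label per tree.
#' @param method `"pearson"` or `"spearman"` for the overall correlation.
#' @param transform `"none"` or `"sqrt"` (applied to the metric before a
#'   Pearson correlation and the ANCOVA).
#' @return a list with `correlation` and `ancova` `test_report`s; the
#'   ANCOVA report carries the covariate's F and p (species-adjusted).
#' @export
tree_size_effects <- function(metric, size, species,
                              method = c("pearson", "spearman"),
                              transform = c("none", "sqrt")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (length(metric) != length(size) || length(metric) != length(species)) {
    stop_arg("metric, size and species must have equal length")
  }
  ok <- stats::complete.cases(metric, size, species)
  metric <- metric[ok]; size <- size[ok]
  species <- factor(as.character(species[ok]))
  if (any(size <= 0)) stop_arg("tree sizes must be positive")
  y <- if (transform == "sqrt") sqrt(metric) else metric
  ct <- suppressWarnings(stats::cor.test(y, size, method = method))
  correlation <- new_test_report(
    paste0(method, " correlation vs tree size"), ct$estimate, ct$p.value,
    transform = transform, unit = "tree"
  )
  ancova <- NULL
  if (nlevels(species) >= 2L) {
    fit <- stats::lm(y ~ species + size)
    an <- suppressWarnings(stats::anova(fit))
    ancova <- new_test_report(
      "ANCOVA metric ~ species + size", an["size", "F value"],
      an["size", "Pr(>F)"], transform = transform, unit = "tree",
      details = an
    )
  }
  list(correlation = correlation, ancova = ancova)
}

#' Fisher's exact test on queen-kinship counts
#'
#' Two-sided Fisher's exact test comparing the proportion of sibling
#' (related) queen pairs within trees to that between trees, on the 2 x 2
#' table `[[related-within, unrelated-within], [related-between,
#' unrelated-between]]`.
#'
#' @param table a `queen_kinship_table` from [queen_kinship()], or a
#'   2 x 2 numeric matrix in the row order within/between, column order
#'   related/unrelated.
#' @return a `test_report` (statistic is the odds ratio estimate).
#' @export
fisher_queen_sibship <- function(table) {
  counts <- if (inherits(table, "queen_kinship_table")) table$counts else table
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L))) {
    stop_arg("need a 2 x 2 table")
  }
  if (any(counts < 0) || sum(counts) < 1) {
    stop_arg("counts must be non-negative with at least one observation")
  }
  ft <- stats::fisher.test(counts)
  new_test_report("Fisher's exact (within vs between)", ft$estimate,
                  ft$p.value, unit = "queen pair")
}
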