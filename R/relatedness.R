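#' Sample allele frequencies from a genotype matrix
#'
#' Reference-allele frequency per locus, pooled over all individuals'
#' non-missing calls: `(2 * hom-ref + het) / (2 * non-missing)`.
#' Frequencies of exactly 0 or 1 indicate monomorphic loci that should
#' have been removed by the MAF filter; they are clamped just inside
#' (0, 1) with a warning so downstream estimators remain finite.
#'
#' @param g a [geno_matrix] (one species).
#' @return an [allele_freqs] panel.
#' @export
sample_allele_frequencies <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  nonmiss <- colSums(!is.na(g$calls))
  if (any(nonmiss == 0L)) {
    stop_arg("locus with no non-missing calls; filter loci first")
  }
  alt <- colSums(g$calls, na.rm = TRUE)
  p <- 1 - alt / (2 * nonmiss)
  degen <- p <= 0 | p >= 1
  if (any(degen)) {
    warning(sum(degen), " monomorphic locus/loci; frequencies clamped ",
            "(apply the MAF filter upstream)", call. = FALSE)
    eps <- 1 / (4 * max(nonmiss))
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  allele_freqs(p, loci = g$loci)
}

# Per-locus numerator/denominator of one reference direction of the two
# moment estimators, vectorised over loci. gx is the reference individual
# (alleles a,b), gy the proband (alleles c,d); calls are alt-allele counts.
pair_locus_terms <- function(gx, gy, p, estimator) {
  # allele indicators: 0 = reference allele, 1 = alternate
  a <- as.numeric(gx == 2L); b <- as.numeric(gx >= 1L)
  c_ <- as.numeric(gy == 2L); d <- as.numeric(gy >= 1L)
  pa <- ifelse(a == 1, 1 - p, p)
  pb <- ifelse(b == 1, 1 - p, p)
  Sab <- as.numeric(a == b)
  Sac <- as.numeric(a == c_); Sad <- as.numeric(a == d)
  Sbc <- as.numeric(b == c_); Sbd <- as.numeric(b == d)
  if (estimator == "lr") {
    num <- pa * (Sbc + Sbd) + pb * (Sac + Sad) - 4 * pa * pb
    den <- (1 + Sab) * (pa + pb) - 4 * pa * pb
  } else {
    num <- 0.5 * (Sac + Sad + Sbc + Sbd) - pa - pb
    den <- 1 + Sab - pa - pb
  }
  list(num = num, den = den)
}

# One direction-averaged multilocus estimate for a pair of call vectors.
pair_estimate <- function(gx, gy, p, estimator) {
  use <- !is.na(gx) & !is.na(gy)
  if (!any(use)) {
    return(list(r = NA_real_, n_loci = 0L))
  }
  gx <- gx[use]; gy <- gy[use]; p <- p[use]
  t1 <- pair_locus_terms(gx, gy, p, estimator)
  t2 <- pair_locus_terms(gy, gx, p, estimator)
  d1 <- sum(t1$den); d2 <- sum(t2$den)
  if (abs(d1) < .Machine$double.eps || abs(d2) < .Machine$double.eps) {
    return(list(r = NA_real_, n_loci = sum(use)))
  }
  list(r = 0.5 * (sum(t1$num) / d1 + sum(t2$num) / d2), n_loci = sum(use))
}

#' Pairwise relatedness estimates
#'
#' Moment estimators of pairwise relatedness for biallelic SNP data:
#' `"lr"` (Lynch-Ritland) and `"qg"` (Queller-Goodnight). Both are
#' reference-individual estimators; each direction combines loci as a
#' ratio of summed per-locus numerators and denominators (weighting loci
#' by their denominators), and the reported estimate is the mean of the
#' two directions, making it symmetric in the pair. Loci missing in
#' either individual are skipped; pairs with no usable loci (or a
#' degenerate denominator) get an `NA` estimate and are excluded from
#' aggregation.
#'
#' @param g a [geno_matrix]; all unordered pairs of its individuals are
#'   estimated.
#' @param freqs reference [allele_freqs]; defaults to
#'   [sample_allele_frequencies()] of `g`.
#' @param estimator `"lr"`, `"qg"`, or `"both"`.
#' @return a data frame with columns `id1`, `id2`, `tree1`, `tree2`,
#'   `estimator`, `r`, `n_loci`.
#' @references Lynch M & Ritland K (1999) Genetics 152:1753-1766.
#'   Queller DC & Goodnight KF (1989) Evolution 43:258-275.
#' @export
pairwise_relatedness <- function(g, freqs = NULL,
                                 estimator = c("lr", "qg", "both")) {
  stopifnot(inherits(g, "geno_matrix"))
  estimator <- match.arg(estimator)
  ests <- if (estimator == "both") c("lr", "qg") else estimator
  freqs <- freqs %||% sample_allele_frequencies(g)
  if (length(freqs$p) != ncol(g$calls)) {
    stop_arg("frequency panel does not match the locus count")
  }
  n <- nrow(g$calls)
  if (n < 2L) stop_arg("need at least two individuals")
  idx <- utils::combn(n, 2L)
  out <- vector("list", length(ests))
  for (e in seq_along(ests)) {
    r <- numeric(ncol(idx)); nl <- integer(ncol(idx))
    for (k in seq_len(ncol(idx))) {
      est <- pair_estimate(g$calls[idx[1L, k], ], g$calls[idx[2L, k], ],
                           freqs$p, ests[e])
      r[k] <- est$r; nl[k] <- est$n_loci
    }
    out[[e]] <- data.frame(
      id1 = g$info$id[idx[1L, ]], id2 = g$info$id[idx[2L, ]],
      tree1 = g$info$tree[idx[1L, ]], tree2 = g$info$tree[idx[2L, ]],
      estimator = ests[e], r = r, n_loci = nl, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Relatedness for one pair of individuals
#'
#' @param gx,gy integer call vectors (0/1/2/`NA`) of the two individuals.
#' @param freqs reference [allele_freqs].
#' @param estimator `"lr"` or `"qg"`.
#' @return a list with `r` (direction-averaged estimate; `NA` when
#'   undefined) and `n_loci` used.
#' @export
relatedness_pair <- function(gx, gy, freqs, estimator = c("lr", "qg")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(freqs, "allele_freqs"),
            length(gx) == length(freqs$p), length(gy) == length(freqs$p))
  pair_estimate(as.integer(gx), as.integer(gy), freqs$p, estimator)
}

#' Aggregate pairwise relatedness within and between trees
#'
#' Within-tree: pair values of workers from the same tree are averaged
#' per tree, and the species value is the mean (with standard error) of
#' these per-tree means. Between-tree: pair values are averaged per
#' unordered tree pair, and the species value is the mean (with SE) over
#' tree pairs. Individuals flagged as mothers of sampled workers
#' (`exclude`) are dropped before averaging; known queens that are
#' sisters of the workers stay in. `NA` estimates are dropped. Trees with
#' fewer than two retained individuals contribute no within-tree value.
#'
#' @param pairs data frame from [pairwise_relatedness()] (one estimator).
#' @param exclude character vector of individual ids to drop (e.g. a
#'   collected queen identified as the workers' mother).
#' @return a list of class `tree_relatedness_summary`: `within_tree`
#'   (tree, mean_r, n_pairs), `between_tree` (tree1, tree2, mean_r,
#'   n_pairs), and `species` (one-row data frame with within/between
#'   means and SEs).
#' @export
aggregate_within_between <- function(pairs, exclude = character()) {
  stopifnot(is.data.frame(pairs))
  if (length(unique(pairs$estimator)) > 1L) {
    stop_arg("aggregate one estimator at a time")
  }
  keep <- !(pairs$id1 %in% exclude | pairs$id2 %in% exclude) & !is.na(pairs$r)
  pairs <- pairs[keep, , drop = FALSE]
  same <- pairs$tree1 == pairs$tree2
  within <- pairs[same, , drop = FALSE]
  between <- pairs[!same, , drop = FALSE]
  within_tree <- if (nrow(within)) {
    agg <- stats::aggregate(r ~ tree1, data = within,
                            FUN = function(x) c(mean(x), length(x)))
    data.frame(tree = agg$tree1, mean_r = agg$r[, 1L],
               n_pairs = as.integer(agg$r[, 2L]), stringsAsFactors = FALSE)
  } else {
    data.frame(tree = character(), mean_r = numeric(), n_pairs = integer())
  }
  between_tree <- if (nrow(between)) {
    key1 <- pmin(between$tree1, between$tree2)
    key2 <- pmax(between$tree1, between$tree2)
    agg <- stats::aggregate(between$r, list(tree1 = key1, tree2 = key2),
                            FUN = function(x) c(mean(x), length(x)))
    data.frame(tree1 = agg$tree1, tree2 = agg$tree2, mean_r = agg$x[, 1L],
               n_pairs = as.integer(agg$x[, 2L]), stringsAsFactors = FALSE)
  } else {
    data.frame(tree1 = character(), tree2 = character(), mean_r = numeric(),
               n_pairs = integer())
  }
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  species <- data.frame(
    within_mean = if (nrow(within_tree)) mean(within_tree$mean_r) else NA_real_,
    within_se = se(within_tree$mean_r),
    n_trees = nrow(within_tree),
    between_mean = if (nrow(between_tree)) mean(between_tree$mean_r) else NA_real_,
    between_se = se(between_tree$mean_r),
    n_tree_pairs = nrow(between_tree)
  )
  structure(
    list(within_tree = within_tree, between_tree = between_tree,
         species = species),
    class = "tree_relatedness_summary"
  )
}

#' @export
print.tree_relatedness_summary <- function(x, ...) {
  s <- x$species
  cat(sprintf(
    "relatedness summary: within-tree %.3f +/- %.3f (%d trees); between-tree %.3f +/- %.3f (%d tree pairs)\n",
    s$within_mean, s$within_se, s$n_trees, s$between_mean, s$between_se,
    s$n_tree_pairs
  ))
  invisible(x)
}
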