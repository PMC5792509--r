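test_that("identical groups give a null omnibus result", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  rep_a <- compare_species(v, g, "anova")
  expect_lt(rep_a$statistic, 1e-10)
  expect_gt(rep_a$p_value, 0.99)
  expect_error(compare_species(rep(1, 6), g, "anova"), "constant")
  expect_error(compare_species(1:3, c("a", "a", "b"), "anova"), "2 groups")
})

test_that("shifted groups are detected with high power", {
  set.seed(1)
  hits <- 0L
  for (i in 1:100) {
    a <- rnorm(15); b <- rnorm(15, 2) # shift of 2 SD
    p <- compare_species(c(a, b), rep(c("a", "b"), each = 15), "anova")$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("omnibus tests hold their nominal type-I rate under the null", {
  set.seed(2)
  rejections <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    v <- rnorm(40)
    g <- rep(letters[1:4], each = 10)
    if (compare_species(v, g, "kwt")$p_value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  rate <- rejections / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 2 * se + 1e-9)
})

test_that("the KWT family reports all pairwise Nemenyi comparisons", {
  set.seed(3)
  v <- rnorm(24)
  g <- rep(letters[1:4], 6)
  rep_k <- compare_species(v, g, "kwt")
  expect_equal(nrow(rep_k$posthoc), choose(4, 2))
  expect_true(all(rep_k$posthoc$p_value >= 0 & rep_k$posthoc$p_value <= 1))
  # order invariance
  o <- sample(length(v))
  rep_o <- compare_species(v[o], g[o], "kwt")
  expect_equal(rep_k$p_value, rep_o$p_value)
  expect_equal(rep_k$posthoc$p_value, rep_o$posthoc$p_value)
})

test_that("the one-tailed t test behaves at the boundary and under signal", {
  expect_equal(ttest_vs_zero(rep(0, 10))$p_value, 0.5)
  set.seed(4)
  strong <- rnorm(20, 0.5, 0.1)
  expect_lt(ttest_vs_zero(strong)$p_value, 1e-3)
  expect_error(ttest_vs_zero(0.3), "two values")
})

test_that("tree-size tests handle exact and null relationships", {
  h <- c(1.2, 1.8, 2.1, 2.6, 3.0, 3.3, 1.5, 2.2)
  sp <- rep(c("a", "b"), each = 4)
  exact <- tree_size_effects(2 * h, h, sp)
  expect_equal(unname(exact$correlation$statistic), 1)
  expect_false(is.null(exact$ancova))
  # square-root transform is applied before the Pearson correlation
  tr <- tree_size_effects(h^2 * 4, h, sp, transform = "sqrt")
  expect_equal(unname(tr$correlation$statistic), 1)
  expect_equal(tr$correlation$transform, "sqrt")
  # independence by construction: p is approximately uniform
  set.seed(5)
  ps <- vapply(1:100, function(i) {
    tree_size_effects(rnorm(20), rlnorm(20, log(2), 0.3),
                      rep(c("a", "b"), 10))$correlation$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 2 * sqrt(0.05 * 0.95 / 100) + 0.001)
})

test_that("Fisher's exact test matches a brute-force hypergeometric oracle", {
  # two-sided p = sum of probabilities of tables as or less probable,
  # with margins fixed (enumerated directly)
  brute_fisher <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1])
    prob <- function(a) dhyper(a, r1, r2, c1)
    p_obs <- prob(tab[1, 1])
    support <- max(0, c1 - r2):min(r1, c1)
    sum(vapply(support, prob, numeric(1))[
      vapply(support, prob, numeric(1)) <= p_obs * (1 + 1e-7)
    ])
  }
  tables <- list(
    matrix(c(8, 31, 52, 504), 2, byrow = TRUE),
    matrix(c(4, 40, 39, 658), 2, byrow = TRUE),
    matrix(c(1, 4, 8, 197), 2, byrow = TRUE),
    matrix(c(3, 7, 12, 18), 2, byrow = TRUE)
  )
  for (tab in tables) {
    expect_equal(fisher_queen_sibship(tab)$p_value, brute_fisher(tab),
                 tolerance = 1e-8)
  }
  expect_equal(fisher_queen_sibship(matrix(c(5, 5, 50, 50), 2, byrow = TRUE))$p_value, 1)
  expect_error(fisher_queen_sibship(matrix(0, 2, 2)), "at least one")
})
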