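test_that("sample allele frequencies match hand counts and HWE simulations", {
  # calls {hom-ref, het} -> p = 3/4
  g <- make_geno(rbind(0L, 1L))
  expect_equal(sample_allele_frequencies(g)$p, 0.75)
  # monomorphic locus flagged as degenerate
  expect_warning(sample_allele_frequencies(make_geno(rbind(2L, 2L))),
                 "monomorphic")
  # large HWE sample recovers p within 3 binomial SE
  set.seed(42)
  sim <- make_geno(matrix(rbinom(1000, 2, 0.7), ncol = 1)) # alt freq 0.7
  p_hat <- sample_allele_frequencies(sim)$p
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("per-locus estimator terms match hand-evaluated examples", {
  # self-comparison of a heterozygote: r = 1 (numerator = denominator = 0.16)
  f <- allele_freqs(0.3)
  expect_equal(relatedness_pair(1L, 1L, f, "lr")$r, 1)
  # Queller-Goodnight self-comparison across a hom + het locus: the
  # heterozygous locus contributes 0 to both sums, the homozygote 1.4
  f2 <- allele_freqs(c(0.3, 0.3))
  expect_equal(relatedness_pair(c(0L, 1L), c(0L, 1L), f2, "qg")$r, 1)
  # Lynch-Ritland, reference (A,A) vs proband (A,B) at p_A = 0.8:
  # one-direction numerator -0.96, denominator 0.64, ratio -1.5
  t1 <- antcolonykin:::pair_locus_terms(0L, 1L, 0.8, "lr")
  expect_equal(t1$num, -0.96)
  expect_equal(t1$den, 0.64)
  expect_equal(t1$num / t1$den, -1.5)
  # Queller-Goodnight self-comparison of (A,A) at p_A = 0.3: 1.4 / 1.4
  t2 <- antcolonykin:::pair_locus_terms(0L, 0L, 0.3, "qg")
  expect_equal(t2$num, 1.4)
  expect_equal(t2$den, 1.4)
})

test_that("direction-averaged estimates are exactly symmetric", {
  f <- draw_allele_frequencies(60, seed = 1)
  sim <- simulate_relationship_pairs("half-sib", 20, f, seed = 2)
  calls <- sim$genotypes$calls
  for (k in c(1, 7, 13)) {
    ab <- relatedness_pair(calls[2 * k - 1, ], calls[2 * k, ], f, "lr")$r
    ba <- relatedness_pair(calls[2 * k, ], calls[2 * k - 1, ], f, "lr")$r
    expect_identical(ab, ba)
  }
})

test_that("both estimators are unbiased for all four relationship classes", {
  f <- draw_allele_frequencies(500, maf_low = 0.1, maf_high = 0.5, seed = 3)
  truths <- c("parent-offspring" = 0.5, "full-sib" = 0.5,
              "half-sib" = 0.25, "unrelated" = 0)
  for (i in seq_along(truths)) {
    sim <- simulate_relationship_pairs(names(truths)[i], 100, f, seed = 10 + i)
    for (est in c("lr", "qg")) {
      r <- vapply(seq_len(100), function(k) {
        relatedness_pair(sim$genotypes$calls[2 * k - 1, ],
                         sim$genotypes$calls[2 * k, ], f, est)$r
      }, numeric(1))
      se <- sd(r) / sqrt(length(r))
      expect_lt(abs(mean(r) - truths[[i]]), 3 * se)
    }
  }
})

test_that("estimates are robust to 10% random locus loss", {
  f <- draw_allele_frequencies(500, seed = 5)
  sim <- simulate_relationship_pairs("full-sib", 60, f, seed = 6)
  calls <- sim$genotypes$calls
  est_mean <- function(m) {
    mean(vapply(seq_len(60), function(k) {
      relatedness_pair(m[2 * k - 1, ], m[2 * k, ], f, "lr")$r
    }, numeric(1)))
  }
  full <- est_mean(calls)
  thinned <- calls
  set.seed(7)
  thinned[matrix(runif(length(thinned)) < 0.1, nrow(thinned))] <- NA_integer_
  expect_lt(abs(est_mean(thinned) - full), 3 * 0.011) # 3 x SE at this n
})

test_that("pairs with no shared loci yield an undefined estimate", {
  f <- allele_freqs(c(0.4, 0.6))
  g1 <- c(0L, NA); g2 <- c(NA, 2L)
  expect_true(is.na(relatedness_pair(g1, g2, f, "lr")$r))
  expect_true(is.na(relatedness_pair(g1, g2, f, "qg")$r))
})

test_that("aggregation averages pairs per tree, then trees per species", {
  pairs <- data.frame(
    id1 = c("w1", "w1", "w2", "x1", "x2", "w1", "w1"),
    id2 = c("w2", "w3", "w3", "x2", "x3", "x1", "x2"),
    tree1 = c("t1", "t1", "t1", "t2", "t2", "t1", "t1"),
    tree2 = c("t1", "t1", "t1", "t2", "t2", "t2", "t2"),
    estimator = "lr",
    r = c(0.6, 0.3, 0.3, 0.2, 0.4, -0.1, 0.1),
    n_loci = 100L, stringsAsFactors = FALSE
  )
  s <- aggregate_within_between(pairs)
  expect_equal(s$within_tree$mean_r[s$within_tree$tree == "t1"], 0.4)
  expect_equal(s$within_tree$mean_r[s$within_tree$tree == "t2"], 0.3)
  expect_equal(s$species$within_mean, 0.35)
  expect_equal(s$between_tree$mean_r, 0)
  expect_equal(s$species$between_mean, 0)

  # a constant field aggregates to that constant at every level
  const <- pairs; const$r <- 0.2
  sc <- aggregate_within_between(const)
  expect_equal(sc$species$within_mean, 0.2)
  expect_equal(sc$species$between_mean, 0.2)

  # excluding a collected mother removes her pairs before averaging
  sx <- aggregate_within_between(pairs, exclude = "w1")
  expect_equal(sx$within_tree$mean_r[sx$within_tree$tree == "t1"], 0.3)
  expect_equal(nrow(sx$between_tree), 0L)
})

test_that("monogynous, singly-mated colonies show the haplodiploid signature", {
  f <- draw_allele_frequencies(500, seed = 8)
  sim <- simulate_colonies(
    colony_design(n_trees = 4, workers_per_tree = 5),
    f, seed = 9
  )
  pr <- pairwise_relatedness(sim$genotypes, f, "lr")
  s <- aggregate_within_between(pr)
  expect_lt(abs(s$species$within_mean - 0.75), 0.05)
  expect_lt(abs(s$species$between_mean), 0.05)
})
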