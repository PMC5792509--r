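test_that("allele frequency panels respect bounds, orientation and determinism", {
  expect_error(draw_allele_frequencies(0), "n_loci")
  expect_error(draw_allele_frequencies(10, maf_low = 0, maf_high = 0.5))
  expect_error(draw_allele_frequencies(10, maf_low = 0.3, maf_high = 0.2))

  f <- draw_allele_frequencies(309, maf_low = 0.1, maf_high = 0.5, seed = 7)
  expect_length(f$p, 309)
  maf <- pmin(f$p, 1 - f$p)
  expect_true(all(maf >= 0.1 & maf <= 0.5))
  # orientation randomised: reference frequencies fall on both sides of 0.5
  expect_gt(sum(f$p > 0.5), 50)
  expect_gt(sum(f$p < 0.5), 50)

  fp <- draw_allele_frequencies(1000, maf_low = 0.25, maf_high = 0.25, seed = 1)
  expect_true(all(abs(pmin(fp$p, 1 - fp$p) - 0.25) < 1e-12))

  expect_identical(
    draw_allele_frequencies(50, seed = 3),
    draw_allele_frequencies(50, seed = 3)
  )
})

test_that("colony simulation respects haplodiploid inheritance exactly", {
  f <- draw_allele_frequencies(200, seed = 1)
  sim <- simulate_colonies(
    colony_design(n_trees = 3, workers_per_tree = 6, queens_per_tree = 2,
                  males_per_queen = 2),
    f, seed = 2
  )
  truth <- sim$truth
  calls <- sim$clean$calls
  # pre-noise, every worker call = one maternal allele + the father's allele
  for (w in seq_len(nrow(calls))) {
    row <- truth$parents[truth$parents$worker == rownames(calls)[w], ]
    fg <- truth$fathers[row$father, ]
    mg <- truth$queens[row$mother, ]
    mat <- calls[w, ] - fg
    expect_true(all(mat %in% 0:1))
    expect_true(all(mg[mat == 1] >= 1)) # mother carries the alt she gave
    expect_true(all(mg[mat == 0] <= 1)) # and the ref she gave
  }
})

test_that("single queen, single male yields one full-sib family sharing a paternal haplotype", {
  f <- draw_allele_frequencies(150, seed = 4)
  sim <- simulate_colonies(
    colony_design(n_trees = 1, workers_per_tree = 8),
    f, seed = 5
  )
  expect_equal(length(unique(sim$truth$parents$mother)), 1L)
  expect_equal(length(unique(sim$truth$parents$father)), 1L)
  # constant paternal allele: worker calls at a locus span at most {f, f+1}
  rng <- apply(sim$clean$calls, 2, function(x) max(x) - min(x))
  expect_true(all(rng <= 1))
})

test_that("worker mothers come from the design's queen set", {
  f <- draw_allele_frequencies(60, seed = 1)
  sim <- simulate_colonies(
    colony_design(n_trees = 2, workers_per_tree = 6, queens_per_tree = 3),
    f, seed = 9
  )
  for (tr in unique(sim$truth$parents$tree)) {
    mothers <- unique(sim$truth$parents$mother[sim$truth$parents$tree == tr])
    expect_lte(length(mothers), 3L)
    expect_true(all(mothers %in% names(sim$truth$queen_tree)[sim$truth$queen_tree == tr]))
  }
})

test_that("sample allele frequencies of many unrelated individuals recover the panel", {
  f <- draw_allele_frequencies(80, maf_low = 0.2, maf_high = 0.5, seed = 2)
  sim <- simulate_relationship_pairs("unrelated", 300, f, seed = 3)
  est <- sample_allele_frequencies(sim$genotypes)
  n <- 2 * nrow(sim$pairs)
  se <- sqrt(f$p * (1 - f$p) / (2 * n))
  expect_true(all(abs(est$p - f$p) <= 3 * se + 1e-9))
})

test_that("observation noise follows the two-class error mechanics", {
  f <- draw_allele_frequencies(100, seed = 1)
  sim <- simulate_colonies(colony_design(n_trees = 2), f, seed = 2)
  g <- sim$clean

  expect_identical(apply_observation_noise(g, 0, 0, 0)$calls, g$calls)
  expect_true(all(is.na(apply_observation_noise(g, 0, 0, 1)$calls)))

  # per-allele miscall: expected flip count on homozygotes is 2 * n * rate
  hom <- make_geno(matrix(0L, 100, 100))
  noisy <- apply_observation_noise(hom, 0, 0.0025, 0, seed = 11)
  flips <- sum(noisy$calls) # each flipped allele adds 1 to the alt count
  expected <- 2 * 10000 * 0.0025
  expect_lt(abs(flips - expected), 3 * sqrt(2 * 10000 * 0.0025 * 0.9975))

  # dropout turns heterozygotes into homozygotes, never missing
  het <- make_geno(matrix(1L, 50, 100))
  dropped <- apply_observation_noise(het, 0.5, 0, 0, seed = 12)
  expect_true(all(dropped$calls %in% c(0L, 1L, 2L)))
  n_dropped <- sum(dropped$calls != 1L)
  expect_lt(abs(n_dropped - 2500), 3 * sqrt(5000 * 0.25))
  # dropped calls split evenly between the two homozygotes
  expect_lt(abs(sum(dropped$calls == 0L) - sum(dropped$calls == 2L)),
            3 * sqrt(n_dropped))
})

test_that("relationship dyads carry the correct true relatedness and counts", {
  f <- draw_allele_frequencies(50, seed = 1)
  expect_error(simulate_relationship_pairs("cousin", 10, f), "relationship")

  truths_dd <- c("parent-offspring" = 0.5, "full-sib" = 0.5,
                 "half-sib" = 0.25, "unrelated" = 0)
  for (rel in names(truths_dd)) {
    sim <- simulate_relationship_pairs(rel, 100, f, seed = 2)
    expect_equal(nrow(sim$genotypes$calls), 200L)
    expect_equal(nrow(sim$pairs), 100L)
    expect_true(all(sim$pairs$true_r == truths_dd[[rel]]))
  }
  hs <- simulate_relationship_pairs("full-sib", 5, f, mode = "haplodiploid",
                                    seed = 3)
  expect_true(all(hs$pairs$true_r == 0.75))
})

test_that("haplodiploid full sisters show mean relatedness near 0.75", {
  f <- draw_allele_frequencies(500, seed = 6)
  sim <- simulate_relationship_pairs("full-sib", 100, f,
                                     mode = "haplodiploid", seed = 7)
  r <- vapply(seq_len(100), function(k) {
    relatedness_pair(sim$genotypes$calls[2 * k - 1, ],
                     sim$genotypes$calls[2 * k, ], f, "lr")$r
  }, numeric(1))
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 0.75), 3 * se)
})

test_that("the generator is deterministic under a fixed seed", {
  f <- draw_allele_frequencies(40, seed = 1)
  d <- colony_design(n_trees = 2, queens_per_tree = 2, p_missing = 0.2,
                     dropout = 0.01, miscall = 0.01)
  s1 <- simulate_colonies(d, f, seed = 99)
  s2 <- simulate_colonies(d, f, seed = 99)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$truth$parents, s2$truth$parents)
})
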