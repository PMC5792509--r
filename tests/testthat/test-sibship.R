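test_that("a single worker's likelihood marginalises to its HWE probability", {
  # hom-ref worker at p = 0.5: sum over 3 x 2 parental states gives 0.25
  g <- make_geno(matrix(0L, 1, 1))
  ll <- config_loglik(g, list(list(1L)), allele_freqs(0.5), error_model(0, 0))
  expect_equal(exp(ll), 0.25)
  # and for a heterozygote at p = 0.3: 2 * 0.3 * 0.7
  g2 <- make_geno(matrix(1L, 1, 1))
  ll2 <- config_loglik(g2, list(list(1L)), allele_freqs(0.3), error_model(0, 0))
  expect_equal(exp(ll2), 0.42)
  # diplodiploid marginalisation gives the same HWE mass
  ll3 <- config_loglik(g, list(list(1L)), allele_freqs(0.5), error_model(0, 0),
                       mode = "diplodiploid")
  expect_equal(exp(ll3), 0.25)
})

test_that("configuration enumeration matches the independent recursive count", {
  expect_equal(length(enumerate_configs(1)), 1L)
  expect_equal(length(enumerate_configs(2)), 3L)
  for (n in 3:5) {
    expect_equal(length(enumerate_configs(n)), nested_partition_count(n))
  }
  # each configuration appears exactly once
  keys <- vapply(enumerate_configs(4), function(cfg) {
    paste(sort(vapply(cfg, function(fam) {
      paste(sort(vapply(fam, paste, character(1), collapse = ",")),
            collapse = "|")
    }, character(1))), collapse = ";")
  }, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(enumerate_configs(9), "refusing")
})

test_that("impossible data under zero error has -Inf log-likelihood", {
  # two workers homozygous for opposite alleles cannot share a father
  g <- make_geno(rbind(rep(0L, 5), rep(2L, 5)))
  f <- allele_freqs(rep(0.5, 5))
  ll_full <- config_loglik(g, list(list(c(1L, 2L))), f, error_model(0, 0))
  expect_identical(ll_full, -Inf)
  ll_split <- config_loglik(g, list(list(1L), list(2L)), f, error_model(0, 0))
  expect_true(is.finite(ll_split))
})

test_that("workers sharing no alleles prefer separate maternal families", {
  set.seed(3)
  f <- draw_allele_frequencies(120, maf_low = 0.3, maf_high = 0.5, seed = 3)
  q <- 1 - f$p
  g <- make_geno(rbind(rbinom(120, 2, q), rbinom(120, 2, q)))
  same_pat <- config_loglik(g, list(list(c(1L, 2L))), f)
  separate <- config_loglik(g, list(list(1L), list(2L)), f)
  expect_lt(same_pat, separate)
})

test_that("evidence against a wrong configuration accumulates with loci", {
  # per-locus pattern that favours separate families; replicating it can
  # only deepen the deficit of the wrong (shared-father) configuration
  pat1 <- c(0L, 2L, 1L); pat2 <- c(2L, 0L, 1L)
  deltas <- vapply(c(1, 4, 12), function(k) {
    g <- make_geno(rbind(rep(pat1, k), rep(pat2, k)))
    f <- allele_freqs(rep(0.5, 3 * k))
    config_loglik(g, list(list(c(1L, 2L))), f, error_model(1e-3, 1e-3)) -
      config_loglik(g, list(list(1L), list(2L)), f, error_model(1e-3, 1e-3))
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))
})

test_that("reconstruction recovers known pedigrees", {
  f <- draw_allele_frequencies(300, seed = 1)
  # one queen, one male: a single full-sib family
  s1 <- simulate_colonies(colony_design(n_trees = 1, workers_per_tree = 6),
                          f, seed = 2)
  c1 <- reconstruct(s1$genotypes, f, error_model(0, 0))
  expect_equal(c1$n_mothers, 1L)
  expect_equal(c1$n_fathers, 1L)
  # three unrelated queens
  s3 <- simulate_colonies(
    colony_design(n_trees = 1, workers_per_tree = 6, queens_per_tree = 3),
    f, seed = 5
  )
  c3 <- reconstruct(s3$genotypes, f)
  expect_equal(c3$n_mothers,
               length(unique(s3$truth$parents$mother)))
})

test_that("annealing attains the exhaustive maximum on a small brood", {
  f <- draw_allele_frequencies(150, seed = 7)
  sim <- simulate_colonies(
    colony_design(n_trees = 1, workers_per_tree = 5, queens_per_tree = 2,
                  males_per_queen = 2),
    f, seed = 8
  )
  exh <- reconstruct(sim$genotypes, f)
  ann <- reconstruct(sim$genotypes, f, search = "anneal", seed = 99)
  expect_equal(ann$loglik, exh$loglik, tolerance = 1e-8)
})

test_that("a matching candidate queen is assigned as mother", {
  f <- draw_allele_frequencies(200, seed = 11)
  sim <- simulate_colonies(colony_design(n_trees = 1, workers_per_tree = 5),
                           f, seed = 12)
  true_queen <- sim$truth$queens[1, ]
  cand <- candidate_queen(true_queen, prior = queen_prior(13), id = "Q-collected")
  cfg <- reconstruct(sim$genotypes, f, error_model(0, 0), candidate = cand)
  expect_true(any(cfg$candidate_assigned))
  expect_true("Q-collected" %in% cfg$mother_ids)
  # an unrelated candidate is not adopted
  set.seed(13)
  rand <- rbinom(200, 2, 1 - f$p)
  cfg2 <- reconstruct(sim$genotypes, f, error_model(0, 0),
                      candidate = candidate_queen(rand, 0.5 / 13))
  expect_false(any(cfg2$candidate_assigned))
})

test_that("maternal genotype recovery masks low-posterior alleles", {
  f <- draw_allele_frequencies(250, seed = 21)
  sim <- simulate_colonies(
    colony_design(n_trees = 1, workers_per_tree = 6, queens_per_tree = 1),
    f, seed = 22
  )
  cfg <- reconstruct(sim$genotypes, f, error_model(0, 0))
  mothers <- infer_maternal_genotypes(cfg, threshold = 0.9)
  expect_equal(nrow(mothers$calls), 1L)
  expect_true(all(mothers$info$caste == "queen"))
  # where the posterior is certain the true queen genotype is recovered
  post <- cfg$mother_posterior[[1]]
  certain <- apply(post, 2, max) > 0.999
  expect_true(any(certain))
  expect_equal(unname(mothers$calls[1, certain]),
               unname(sim$truth$queens[1, certain]))
  # masked calls exist exactly where allele support is below threshold,
  # and a disabled threshold masks nothing
  none <- infer_maternal_genotypes(cfg, threshold = 0)
  expect_false(anyNA(none$calls))
  expect_gte(sum(is.na(mothers$calls)), 0L)
})

test_that("per-tree reconstruction keeps trees independent", {
  f <- draw_allele_frequencies(150, seed = 31)
  sim <- simulate_colonies(colony_design(n_trees = 3, workers_per_tree = 4),
                           f, seed = 32)
  cfgs <- reconstruct_colonies(sim$genotypes, f)
  expect_named(cfgs, c("t01", "t02", "t03"))
  expect_true(all(vapply(cfgs, function(x) x$n_mothers, integer(1)) == 1L))
})
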