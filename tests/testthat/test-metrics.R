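# Build a sibship_config by hand for index arithmetic tests.
manual_config <- function(families, tree = "t1") {
  ids <- unlist(families)
  structure(
    list(families = families, loglik = -1, n_mothers = length(families),
         n_fathers = sum(lengths(families)),
         mother_ids = sprintf("%s_M%d", tree, seq_along(families)),
         candidate_assigned = rep(FALSE, length(families)),
         mother_posterior = NULL, father_posterior = NULL,
         tree = tree, mode = "haplodiploid", ids = ids, loci = "L1",
         species = "sp1", search = "manual"),
    class = "sibship_config"
  )
}

test_that("indices, dominance and the minimum-offspring rule match hand values", {
  # 6 workers, 1 mother, 1 father
  mono <- manual_config(list(list(paste0("w", 1:6))))
  m <- polygyny_polyandry(mono)
  expect_equal(m$polygyny, 1L)
  expect_equal(m$polyandry, 1L)
  expect_equal(m$queen_dominance, 1)
  expect_equal(m$male_dominance, 1)
  expect_equal(unname(m$males_per_queen), 1L)

  # 6 workers split 4/2; the 4-worker family has 3 fathers
  split <- manual_config(list(
    list(c("w1", "w2"), "w3", "w4"), # mother 1: 4 workers, 3 fathers
    list(c("w5", "w6"))              # mother 2: 2 workers, 1 father
  ))
  m2 <- polygyny_polyandry(split)
  expect_equal(m2$polygyny, 2L)
  expect_equal(m2$polyandry, 4L)
  expect_equal(m2$queen_dominance, 4 / 6)
  expect_equal(m2$male_dominance, 2 / 6)
  # the 2-offspring queen is excluded by the >= 4 rule
  expect_equal(unname(m2$males_per_queen), 3L)
  # the rule's threshold is a parameter
  m3 <- polygyny_polyandry(split, min_offspring = 2)
  expect_equal(sort(unname(m3$males_per_queen)), c(1L, 3L))

  # dominance times workers is always an integer family size
  expect_equal(m2$queen_dominance * m2$n_workers, 4)

  expect_error(polygyny_polyandry(manual_config(list())), "empty")
})

test_that("indices recover sampled-truth family counts on clean simulations", {
  f <- draw_allele_frequencies(300, seed = 41)
  hits <- 0L
  n_rep <- 10L
  for (i in seq_len(n_rep)) {
    sim <- simulate_colonies(
      colony_design(n_trees = 1, workers_per_tree = 6,
                    queens_per_tree = sample(1:3, 1), males_per_queen = 2),
      f, seed = 500 + i
    )
    cfg <- reconstruct(sim$genotypes, f, error_model(0, 0))
    truth_m <- length(unique(sim$truth$parents$mother))
    truth_f <- length(unique(sim$truth$parents$father))
    met <- polygyny_polyandry(cfg)
    expect_lte(met$polygyny, met$n_workers)
    if (met$polygyny == truth_m && met$polyandry == truth_f) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("queen kinship classifies simulated sisters and strangers", {
  f <- draw_allele_frequencies(300, seed = 51)
  # two full-sister queens on each of two trees, plus two lone strangers
  sim <- simulate_colonies(
    colony_design(n_trees = 2, workers_per_tree = 2, queens_per_tree = 2,
                  p_sister_queens = 1, mode = "diplodiploid"),
    f, seed = 52
  )
  qg <- sim$truth$queens
  info <- data.frame(
    id = rownames(qg), species = "sp1",
    tree = sim$truth$queen_tree[rownames(qg)], caste = "queen",
    stringsAsFactors = FALSE
  )
  set.seed(53)
  strangers <- matrix(rbinom(2 * ncol(qg), 2, 1 - f$p), 2, byrow = TRUE)
  rownames(strangers) <- c("s1", "s2")
  all_q <- geno_matrix(
    rbind(qg, strangers),
    info = rbind(info, data.frame(id = c("s1", "s2"), species = "sp1",
                                  tree = c("t03", "t04"), caste = "queen")),
    loci = f$loci
  )
  qk <- queen_kinship(all_q, f)
  # strata are exhaustive and exclusive over all queen pairs
  expect_equal(sum(qk$counts), choose(nrow(all_q$calls), 2))
  pairs <- qk$pairs
  sisters <- pairs[pairs$tree1 == pairs$tree2, ]
  expect_true(all(sisters$related))
  cross <- pairs[pairs$tree1 != pairs$tree2, ]
  expect_lt(mean(cross$related), 0.5)
  # fewer than two queens yields an empty table
  empty <- queen_kinship(subset_geno(all_q, 1L))
  expect_equal(sum(empty$counts), 0)
})

test_that("unrelated queens are rarely called siblings at 300 loci", {
  f <- draw_allele_frequencies(300, seed = 61)
  set.seed(62)
  n_q <- 10L
  calls <- matrix(rbinom(n_q * 300, 2, rep(1 - f$p, each = n_q)), n_q, 300)
  qs <- geno_matrix(calls, info = data.frame(
    id = paste0("q", 1:n_q), species = "sp1",
    tree = rep(paste0("t", 1:5), each = 2), caste = "queen"
  ), loci = f$loci)
  qk <- queen_kinship(qs, f, search = "anneal", seed = 63)
  expect_lt(mean(qk$pairs$related), 0.1)
})
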