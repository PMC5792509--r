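#' Allele frequency panel
#'
#' Per-locus population frequency of the reference allele of a biallelic
#' SNP panel. The alternate-allele frequency is `1 - p`.
#'
#' @param p numeric vector of reference-allele frequencies, all in (0, 1).
#' @param loci optional locus ids.
#' @return an object of class `allele_freqs` with elements `p` and `loci`.
#' @export
allele_freqs <- function(p, loci = NULL) {
  p <- as.numeric(p)
  if (length(p) < 1L) stop_arg("empty frequency panel")
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop_arg("allele frequencies must lie strictly in (0, 1)")
  }
  loci <- loci %||% names(p) %||% paste0("L", seq_along(p))
  if (length(loci) != length(p)) stop_arg("'loci' length mismatch")
  structure(list(p = unname(p), loci = as.character(loci)),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("allele_freqs:", length(x$p), "loci; minor allele frequency range",
      sprintf("[%.3f, %.3f]\n", min(pmin(x$p, 1 - x$p)), max(pmin(x$p, 1 - x$p))))
  invisible(x)
}

#' Draw a synthetic allele-frequency panel
#'
#' Minor allele frequencies are drawn i.i.d. uniform on
#' `[maf_low, maf_high]` and the reference/alternate orientation of each
#' locus is randomized, so reference frequencies land symmetrically on
#' both sides of 0.5.
#'
#' @param n_loci number of loci (>= 1).
#' @param maf_low,maf_high bounds for the minor allele frequency;
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param seed optional integer seed for reproducibility.
#' @return an [allele_freqs] panel.
#' @examples
#' f <- draw_allele_frequencies(309, 0.1, 0.5, seed = 1)
#' range(pmin(f$p, 1 - f$p))
#' @export
draw_allele_frequencies <- function(n_loci, maf_low = 0.1, maf_high = 0.5,
                                    seed = NULL) {
  if (!is.numeric(n_loci) || n_loci < 1) stop_arg("'n_loci' must be >= 1")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop_arg("need 0 < maf_low <= maf_high <= 0.5")
  }
  with_seed(seed, {
    maf <- stats::runif(n_loci, maf_low, maf_high)
    flip <- stats::runif(n_loci) < 0.5
    allele_freqs(ifelse(flip, 1 - maf, maf))
  })
}

#' Colony design for the synthetic-data generator
#'
#' Describes a set of trees (one colony per tree) from which workers are
#' sampled. Non-integer `queens_per_tree` / `males_per_queen` are treated
#' as means: each tree (queen) draws the floor or ceiling so the design
#' mean is matched in expectation.
#'
#' @param n_trees number of trees (colonies).
#' @param workers_per_tree workers sampled per tree.
#' @param queens_per_tree (mean) number of egg-laying queens per tree.
#' @param males_per_queen (mean) number of males each queen has mated with.
#' @param skew_alpha concentration of the symmetric Dirichlet distribution
#'   over queens' shares of the sampled workers; `alpha = 1` yields a
#'   dominant-queen share near the 0.5-0.7 range observed in polygynous
#'   field colonies, smaller values yield stronger skew.
#' @param p_sister_queens probability that an additional same-tree queen is
#'   a full sister of the first queen (sister queens are daughters of one
#'   auxiliary mother-father pair per tree).
#' @param mode `"haplodiploid"` (default; fathers haploid) or
#'   `"diplodiploid"`.
#' @param dropout,miscall,p_missing observation-noise rates passed to
#'   [apply_observation_noise()] by [simulate_colonies()]; zero by default
#'   at generation so tests can add noise explicitly.
#' @param species species label attached to all individuals.
#' @return an object of class `colony_design`.
#' @export
colony_design <- function(n_trees = 15, workers_per_tree = 6,
                          queens_per_tree = 1, males_per_queen = 1,
                          skew_alpha = 1, p_sister_queens = 0,
                          mode = c("haplodiploid", "diplodiploid"),
                          dropout = 0, miscall = 0, p_missing = 0,
                          species = "sp1") {
  mode <- match.arg(mode)
  if (n_trees < 1 || workers_per_tree < 1 || queens_per_tree < 1 ||
      males_per_queen < 1) {
    stop_arg("n_trees, workers_per_tree, queens_per_tree, males_per_queen must all be >= 1")
  }
  if (skew_alpha <= 0) stop_arg("'skew_alpha' must be positive")
  probs <- c(p_sister_queens, dropout, miscall, p_missing)
  if (any(probs < 0) || any(probs > 1)) stop_arg("probabilities must lie in [0, 1]")
  structure(
    list(n_trees = as.integer(n_trees), workers_per_tree = as.integer(workers_per_tree),
         queens_per_tree = queens_per_tree, males_per_queen = males_per_queen,
         skew_alpha = skew_alpha, p_sister_queens = p_sister_queens,
         mode = mode, dropout = dropout, miscall = miscall,
         p_missing = p_missing, species = species),
    class = "colony_design"
  )
}

# Draw an integer with the given (possibly fractional) mean: floor or
# ceiling with the matching probability.
draw_count <- function(mean, n = 1L) {
  lo <- floor(mean)
  lo + stats::rbinom(n, 1L, mean - lo)
}

# n diploid Hardy-Weinberg genotypes (alt-allele counts) at freqs.
hwe_diploid <- function(n, freqs) {
  q <- 1 - freqs$p
  matrix(stats::rbinom(n * length(q), 2L, rep(q, each = n)), n,
         length(q), dimnames = list(NULL, freqs$loci))
}

# n haploid genotypes (0 = reference allele, 1 = alternate).
haploid_draw <- function(n, freqs) {
  q <- 1 - freqs$p
  matrix(stats::rbinom(n * length(q), 1L, rep(q, each = n)), n, length(q))
}

# One transmitted allele per locus from each diploid genotype row.
transmit_allele <- function(geno) {
  (geno == 2L) + (geno == 1L) * matrix(
    stats::rbinom(length(geno), 1L, 0.5), nrow(geno), ncol(geno)
  )
}

#' Simulate colonies with known pedigree ground truth
#'
#' Queens are drawn from Hardy-Weinberg proportions at the supplied
#' frequencies (sister queens as daughters of one auxiliary mother-father
#' pair per tree); each father is a single haplotype (haplodiploid mode)
#' or a diploid Hardy-Weinberg genotype (diplodiploid mode). Workers are
#' assigned to queens by the Dirichlet skew distribution and uniformly to
#' that queen's males, and inherit one uniformly chosen maternal allele
#' plus the paternal allele. Observation noise is applied afterwards with
#' the design's rates.
#'
#' @param design a [colony_design].
#' @param freqs an [allele_freqs] panel.
#' @param seed optional integer seed.
#' @return a list with elements `genotypes` (worker [geno_matrix], after
#'   noise), `truth` (class `pedigree_truth`: `queens` and `fathers`
#'   genotype matrices, `parents` data frame mapping worker to mother and
#'   father ids, `queen_sibling_pairs` data frame), and `clean` (the
#'   pre-noise worker matrix, for inheritance checks).
#' @examples
#' f <- draw_allele_frequencies(100, seed = 1)
#' sim <- simulate_colonies(colony_design(n_trees = 2, queens_per_tree = 2),
#'   f,
#'   seed = 2
#' )
#' table(sim$truth$parents$mother)
#' @export
simulate_colonies <- function(design, freqs, seed = NULL) {
  stopifnot(inherits(design, "colony_design"), inherits(freqs, "allele_freqs"))
  with_seed(seed, {
    L <- length(freqs$p)
    worker_rows <- list(); worker_info <- list()
    queen_rows <- list(); queen_ids <- character(); queen_tree <- character()
    father_rows <- list(); father_ids <- character()
    parents <- list(); sib_pairs <- list()
    for (t in seq_len(design$n_trees)) {
      tree_id <- sprintf("t%02d", t)
      Q <- draw_count(design$queens_per_tree)
      # queen genotypes; sisters share one auxiliary parental pair
      aux_mother <- hwe_diploid(1L, freqs)
      aux_father <- if (design$mode == "haplodiploid") {
        haploid_draw(1L, freqs)
      } else {
        hwe_diploid(1L, freqs)
      }
      queen_from_aux <- function() {
        mat <- transmit_allele(aux_mother)
        pat <- if (design$mode == "haplodiploid") aux_father else transmit_allele(aux_father)
        mat + pat
      }
      is_sister <- logical(Q)
      if (design$p_sister_queens > 0 && Q >= 1L) {
        is_sister[1L] <- TRUE
        if (Q > 1L) {
          is_sister[2:Q] <- stats::runif(Q - 1L) < design$p_sister_queens
        }
      }
      qg <- matrix(0L, Q, L)
      for (qi in seq_len(Q)) {
        qg[qi, ] <- if (is_sister[qi]) queen_from_aux() else hwe_diploid(1L, freqs)
      }
      q_ids <- sprintf("%s_q%d", tree_id, seq_len(Q))
      sis <- which(is_sister)
      if (length(sis) >= 2L) {
        cmb <- utils::combn(sis, 2L)
        sib_pairs[[length(sib_pairs) + 1L]] <- data.frame(
          tree = tree_id, queen1 = q_ids[cmb[1L, ]], queen2 = q_ids[cmb[2L, ]],
          stringsAsFactors = FALSE
        )
      }
      # fathers per queen
      M <- draw_count(design$males_per_queen, Q)
      f_ids_by_queen <- vector("list", Q)
      tree_fathers <- list()
      for (qi in seq_len(Q)) {
        fg <- if (design$mode == "haplodiploid") {
          haploid_draw(M[qi], freqs)
        } else {
          hwe_diploid(M[qi], freqs)
        }
        ids <- sprintf("%s_m%d", q_ids[qi], seq_len(M[qi]))
        rownames(fg) <- ids
        f_ids_by_queen[[qi]] <- ids
        tree_fathers[[qi]] <- fg
        father_rows[[length(father_rows) + 1L]] <- fg
        father_ids <- c(father_ids, ids)
      }
      tree_fathers <- do.call(rbind, tree_fathers)
      # assign workers to queens by Dirichlet shares, then to males uniformly
      shares <- stats::rgamma(Q, design$skew_alpha)
      shares <- shares / sum(shares)
      w_mother <- sample.int(Q, design$workers_per_tree, replace = TRUE, prob = shares)
      n_w <- design$workers_per_tree
      wg <- matrix(0L, n_w, L)
      w_father <- character(n_w)
      for (w in seq_len(n_w)) {
        qi <- w_mother[w]
        fid <- f_ids_by_queen[[qi]][sample.int(length(f_ids_by_queen[[qi]]), 1L)]
        mat <- transmit_allele(qg[qi, , drop = FALSE])
        fg_row <- tree_fathers[fid, , drop = FALSE]
        pat <- if (design$mode == "haplodiploid") fg_row else transmit_allele(fg_row)
        wg[w, ] <- mat + pat
        w_father[w] <- fid
      }
      w_ids <- sprintf("%s_w%d", tree_id, seq_len(n_w))
      worker_rows[[t]] <- wg
      worker_info[[t]] <- data.frame(
        id = w_ids, species = design$species, tree = tree_id, caste = "worker",
        stringsAsFactors = FALSE
      )
      parents[[t]] <- data.frame(
        worker = w_ids, mother = q_ids[w_mother], father = w_father,
        tree = tree_id, stringsAsFactors = FALSE
      )
      queen_rows[[t]] <- qg
      queen_ids <- c(queen_ids, q_ids)
      queen_tree <- c(queen_tree, rep(tree_id, Q))
    }
    calls <- do.call(rbind, worker_rows)
    info <- do.call(rbind, worker_info)
    clean <- geno_matrix(calls, info = info, loci = freqs$loci)
    queens <- do.call(rbind, queen_rows)
    rownames(queens) <- queen_ids
    fathers <- do.call(rbind, father_rows)
    rownames(fathers) <- father_ids
    truth <- structure(
      list(
        queens = queens, queen_tree = stats::setNames(queen_tree, queen_ids),
        fathers = fathers,
        parents = do.call(rbind, parents),
        queen_sibling_pairs = if (length(sib_pairs)) {
          do.call(rbind, sib_pairs)
        } else {
          data.frame(tree = character(), queen1 = character(),
                     queen2 = character(), stringsAsFactors = FALSE)
        },
        mode = design$mode
      ),
      class = "pedigree_truth"
    )
    noisy <- apply_observation_noise(clean, dropout = design$dropout,
                                     miscall = design$miscall,
                                     p_missing = design$p_missing)
    list(genotypes = noisy, truth = truth, clean = clean)
  })
}

#' Apply genotyping noise to a matrix of true genotypes
#'
#' Independently per genotype: with probability `p_missing` the call is
#' set missing; otherwise a heterozygote loses one uniformly chosen allele
#' with probability `dropout` (becoming homozygous for the other), and
#' then each allele of the resulting call is flipped to the alternate
#' allele independently with probability `miscall`. This is the
#' generative counterpart of the two-class error model used by the
#' sibship likelihood.
#'
#' @param g a [geno_matrix] of true calls.
#' @param dropout allelic dropout rate (heterozygotes only).
#' @param miscall per-allele miscall rate.
#' @param p_missing per-genotype missing probability.
#' @param seed optional integer seed.
#' @return a `geno_matrix` of the same shape and labels.
#' @export
apply_observation_noise <- function(g, dropout = 1e-4, miscall = 2.5e-3,
                                    p_missing = 0, seed = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  rates <- c(dropout, miscall, p_missing)
  if (any(rates < 0) || any(rates > 1)) stop_arg("rates must lie in [0, 1]")
  with_seed(seed, {
    calls <- g$calls
    n <- length(calls)
    if (dropout > 0) {
      het <- !is.na(calls) & calls == 1L
      do_drop <- het & stats::runif(n) < dropout
      calls[do_drop] <- 2L * stats::rbinom(sum(do_drop), 1L, 0.5)
    }
    if (miscall > 0) {
      ok <- !is.na(calls)
      a1 <- (calls == 2L); a2 <- (calls >= 1L)
      f1 <- ok & stats::runif(n) < miscall
      f2 <- ok & stats::runif(n) < miscall
      a1[f1] <- !a1[f1]; a2[f2] <- !a2[f2]
      calls[ok] <- (a1 + a2)[ok]
    }
    if (p_missing > 0) {
      calls[stats::runif(n) < p_missing] <- NA_integer_
    }
    geno_matrix(calls, info = g$info, loci = g$loci)
  })
}

#' Simulate dyads of known relationship
#'
#' Generates pairs of individuals with an explicit shared pedigree:
#' parent-offspring, full siblings, half siblings, or unrelated. Under
#' diplodiploid inheritance the attached true relatedness values are 0.5,
#' 0.5, 0.25 and 0; under haplodiploid inheritance (female-female pairs)
#' they are 0.5 (mother-daughter), 0.75 (full sisters), 0.25 (maternal
#' half sisters) and 0.
#'
#' @param relationship one of `"parent-offspring"`, `"full-sib"`,
#'   `"half-sib"`, `"unrelated"`.
#' @param n_pairs number of dyads (>= 1).
#' @param freqs an [allele_freqs] panel.
#' @param mode `"diplodiploid"` (default, as in estimator-evaluation
#'   experiments) or `"haplodiploid"`.
#' @param seed optional integer seed.
#' @return a list with `genotypes` (a [geno_matrix] with `2 * n_pairs`
#'   rows; members of pair *i* are tagged with tree `pair<i>`) and
#'   `pairs` (data frame: `pair`, `id1`, `id2`, `true_r`).
#' @export
simulate_relationship_pairs <- function(relationship, n_pairs, freqs,
                                        mode = c("diplodiploid", "haplodiploid"),
                                        seed = NULL) {
  rels <- c("parent-offspring", "full-sib", "half-sib", "unrelated")
  if (!is.character(relationship) || length(relationship) != 1L ||
      !relationship %in% rels) {
    stop_arg("'relationship' must be one of: ", paste(rels, collapse = ", "))
  }
  if (n_pairs < 1) stop_arg("'n_pairs' must be >= 1")
  mode <- match.arg(mode)
  stopifnot(inherits(freqs, "allele_freqs"))
  with_seed(seed, {
    n <- as.integer(n_pairs)
    father_geno <- function(k) {
      if (mode == "haplodiploid") haploid_draw(k, freqs) else hwe_diploid(k, freqs)
    }
    paternal_allele <- function(fg) {
      if (mode == "haplodiploid") fg else transmit_allele(fg)
    }
    offspring <- function(mg, fg) transmit_allele(mg) + paternal_allele(fg)
    if (relationship == "parent-offspring") {
      a <- hwe_diploid(n, freqs)                      # the mother
      b <- offspring(a, father_geno(n))
      true_r <- 0.5
    } else if (relationship == "full-sib") {
      m <- hwe_diploid(n, freqs); f <- father_geno(n)
      a <- offspring(m, f); b <- offspring(m, f)
      true_r <- if (mode == "haplodiploid") 0.75 else 0.5
    } else if (relationship == "half-sib") {
      m <- hwe_diploid(n, freqs)                      # shared mother
      a <- offspring(m, father_geno(n)); b <- offspring(m, father_geno(n))
      true_r <- 0.25
    } else {
      a <- hwe_diploid(n, freqs); b <- hwe_diploid(n, freqs)
      true_r <- 0
    }
    ids_a <- sprintf("pair%03d_a", seq_len(n))
    ids_b <- sprintf("pair%03d_b", seq_len(n))
    calls <- rbind(a, b)[rep(seq_len(n), each = 2L) + c(0L, n), , drop = FALSE]
    ids <- as.vector(rbind(ids_a, ids_b))
    info <- data.frame(
      id = ids, species = "sim", tree = rep(sprintf("pair%03d", seq_len(n)), each = 2L),
      caste = "worker", stringsAsFactors = FALSE
    )
    list(
      genotypes = geno_matrix(calls, info = info, loci = freqs$loci),
      pairs = data.frame(pair = seq_len(n), id1 = ids_a, id2 = ids_b,
                         true_r = true_r, stringsAsFactors = FALSE)
    )
  })
}

#' Write pedigree ground truth to TSV files
#'
#' @param truth a `pedigree_truth` object from [simulate_colonies()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`parents.tsv`,
#'   `queen_sibling_pairs.tsv`).
#' @export
write_pedigree_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "pedigree_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "parents.tsv")
  p2 <- file.path(dir, "queen_sibling_pairs.tsv")
  utils::write.table(truth$parents, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$queen_sibling_pairs, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
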