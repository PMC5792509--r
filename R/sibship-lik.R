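# Likelihood machinery for sibship reconstruction.
#
# Model: loci independent. Within one maternal family the mother's diploid
# genotype is integrated over a Hardy-Weinberg prior (or mixed with a
# candidate queen's known genotype); within each paternal sub-family the
# father's contribution is a single allele (haploid father under
# haplodiploidy) or one allele transmitted from an integrated diploid
# genotype (diplodiploid mode). Offspring observations pass through a
# two-class error kernel: a heterozygote drops one allele with probability
# dropout (becoming either homozygote with dropout/2), then each allele is
# miscalled independently with probability miscall. Missing genotypes
# contribute likelihood 1.

#' Genotyping-error model for sibship likelihoods
#'
#' @param dropout allelic dropout rate (a true heterozygote is observed
#'   as a homozygote with this total probability, split evenly between
#'   the two homozygotes).
#' @param miscall additional per-allele error rate (each allele of the
#'   call is flipped independently).
#' @return an object of class `error_model`.
#' @export
error_model <- function(dropout = 1e-4, miscall = 2.5e-3) {
  if (dropout < 0 || dropout >= 1 || miscall < 0 || miscall >= 1) {
    stop_arg("error rates must lie in [0, 1)")
  }
  structure(list(dropout = dropout, miscall = miscall), class = "error_model")
}

#' Candidate queen for sibship reconstruction
#'
#' A genotyped putative mother offered to the reconstruction alongside
#' inferred (latent) mothers. Each maternal family weighs her as its
#' mother with prior probability `prior`; the conventional prior is 0.5
#' divided by the number of trees in the data set.
#'
#' @param genotype integer call vector (0/1/2/`NA`) of the candidate.
#' @param prior prior probability in (0, 1) that she is the mother of any
#'   given offspring.
#' @param id identifier used when she is assigned as a mother.
#' @return an object of class `candidate_queen`.
#' @export
candidate_queen <- function(genotype, prior, id = "candidate_queen") {
  if (!(prior > 0 && prior < 1)) stop_arg("'prior' must lie in (0, 1)")
  genotype <- as.integer(genotype)
  if (any(!genotype[!is.na(genotype)] %in% 0:2)) {
    stop_arg("candidate genotype must be 0/1/2/NA calls")
  }
  structure(list(genotype = genotype, prior = prior, id = id),
            class = "candidate_queen")
}

#' Default candidate-queen prior
#'
#' @param n_trees number of trees (colonies) in the data set.
#' @return `0.5 / n_trees`.
#' @export
queen_prior <- function(n_trees) {
  if (n_trees < 1) stop_arg("'n_trees' must be >= 1")
  0.5 / n_trees
}

# 3x3 observation kernel E[true + 1, obs + 1] = P(obs | true).
obs_error_matrix <- function(err) {
  ed <- err$dropout
  eo <- err$miscall
  dropout <- rbind(
    c(1, 0, 0),
    c(ed / 2, 1 - ed, ed / 2),
    c(0, 0, 1)
  )
  miscall <- rbind(
    c((1 - eo)^2, 2 * eo * (1 - eo), eo^2),
    c(eo * (1 - eo), (1 - eo)^2 + eo^2, eo * (1 - eo)),
    c(eo^2, 2 * eo * (1 - eo), (1 - eo)^2)
  )
  dropout %*% miscall
}

# Per-worker observation likelihood: 3 x L x n array A[g, l, w] =
# P(observed call | true genotype g); missing calls contribute 1.
precompute_obs_lik <- function(calls, err) {
  E <- obs_error_matrix(err)
  n <- nrow(calls)
  L <- ncol(calls)
  arr <- array(1, dim = c(3L, L, n))
  for (w in seq_len(n)) {
    obs <- calls[w, ]
    ok <- !is.na(obs)
    arr[, ok, w] <- E[, obs[ok] + 1L]
  }
  arr
}

# Transmission tables: rows are parental combos (mother genotype-major),
# columns true offspring genotypes. Mother transmits a uniformly chosen
# allele; the father contributes his haplotype allele (haplodiploid) or a
# uniformly chosen allele of his diploid genotype (diplodiploid).
allele_dist_from_geno <- function(g) {
  # P(transmitted allele = alt) for genotype g in 0:2
  c(0, 0.5, 1)[g + 1L]
}

transmission_table <- function(mode) {
  if (mode == "haplodiploid") {
    father_states <- 0:1
  } else {
    father_states <- 0:2
  }
  nf <- length(father_states)
  Ttab <- matrix(0, 3L * nf, 3L)
  for (gm in 0:2) {
    pm <- allele_dist_from_geno(gm) # P(maternal allele = alt)
    for (fi in seq_len(nf)) {
      pf <- if (mode == "haplodiploid") father_states[fi] else {
        allele_dist_from_geno(father_states[fi])
      }
      row <- gm * nf + fi
      # offspring genotype = maternal allele + paternal allele
      Ttab[row, 1L] <- (1 - pm) * (1 - pf)
      Ttab[row, 2L] <- pm * (1 - pf) + (1 - pm) * pf
      Ttab[row, 3L] <- pm * pf
    }
  }
  Ttab
}

# Per-locus father-state prior: 2 x L (haploid allele frequencies) or
# 3 x L (Hardy-Weinberg genotype proportions).
father_prior <- function(p, mode) {
  if (mode == "haplodiploid") {
    rbind(p, 1 - p)
  } else {
    rbind(p^2, 2 * p * (1 - p), (1 - p)^2)
  }
}

# Hardy-Weinberg mother-genotype prior, 3 x L.
hwe_prior <- function(p) {
  rbind(p^2, 2 * p * (1 - p), (1 - p)^2)
}

# Point-mass mother prior from a candidate's calls; her missing loci fall
# back to the Hardy-Weinberg prior.
candidate_prior <- function(genotype, p) {
  pr <- hwe_prior(p)
  ok <- !is.na(genotype)
  pr[, ok] <- 0
  pr[cbind(genotype[ok] + 1L, which(ok))] <- 1
  pr
}

# Likelihood of one maternal family under a fixed mother prior.
# obs: 3 x L x n array; members: list of integer worker-index vectors
# (paternal families); returns log-likelihood and, if posteriors = TRUE,
# the mother genotype posterior (3 x L) and per-paternal-family father
# state posteriors.
maternal_family_lik <- function(obs, members, mprior, fprior, Ttab,
                                posteriors = FALSE) {
  nf <- nrow(fprior)
  L <- dim(obs)[2L]
  inner <- vector("list", length(members)) # each 3 x L
  pf_rows <- vector("list", length(members))
  for (b in seq_along(members)) {
    PF <- matrix(1, 3L * nf, L)
    for (w in members[[b]]) {
      PF <- PF * (Ttab %*% obs[, , w, drop = TRUE])
    }
    I <- matrix(0, 3L, L)
    for (gm in 0:2) {
      rows <- gm * nf + seq_len(nf)
      I[gm + 1L, ] <- colSums(fprior * PF[rows, , drop = FALSE])
    }
    inner[[b]] <- I
    if (posteriors) pf_rows[[b]] <- PF
  }
  fam <- mprior
  for (b in seq_along(members)) fam <- fam * inner[[b]]
  per_locus <- colSums(fam)
  ll <- sum(log(per_locus))
  if (!posteriors) {
    return(list(loglik = ll))
  }
  post_m <- sweep(fam, 2L, ifelse(per_locus > 0, per_locus, 1), "/")
  father_post <- lapply(seq_along(members), function(b) {
    PF <- pf_rows[[b]]
    I <- inner[[b]]
    fp <- matrix(0, nf, L)
    for (gm in 0:2) {
      rows <- gm * nf + seq_len(nf)
      contrib <- sweep(fprior * PF[rows, , drop = FALSE], 2L,
                       ifelse(I[gm + 1L, ] > 0, I[gm + 1L, ], 1), "/")
      fp <- fp + sweep(contrib, 2L, post_m[gm + 1L, ], "*")
    }
    fp
  })
  list(loglik = ll, mother_posterior = post_m, father_posterior = father_post)
}

# Family log-likelihood with optional candidate-queen mixture. Returns
# loglik plus whether the candidate branch dominates (posterior > 0.5).
family_loglik <- function(obs, members, ctx) {
  base <- maternal_family_lik(obs, members, ctx$mprior_hwe, ctx$fprior, ctx$Ttab)
  if (is.null(ctx$candidate)) {
    return(list(loglik = base$loglik, candidate_assigned = FALSE))
  }
  cand <- maternal_family_lik(obs, members, ctx$mprior_cand, ctx$fprior, ctx$Ttab)
  pi <- ctx$candidate$prior
  ll <- logsumexp(c(log(pi) + cand$loglik, log1p(-pi) + base$loglik))
  assigned <- (log(pi) + cand$loglik) > (log1p(-pi) + base$loglik)
  list(loglik = ll, candidate_assigned = assigned)
}

# Shared precomputed context for one brood.
sibship_context <- function(calls, freqs, err, candidate, mode) {
  obs <- precompute_obs_lik(calls, err)
  ctx <- list(
    obs = obs,
    Ttab = transmission_table(mode),
    fprior = father_prior(freqs$p, mode),
    mprior_hwe = hwe_prior(freqs$p),
    candidate = candidate,
    mode = mode
  )
  if (!is.null(candidate)) {
    if (length(candidate$genotype) != length(freqs$p)) {
      stop_arg("candidate genotype length does not match the locus count")
    }
    ctx$mprior_cand <- candidate_prior(candidate$genotype, freqs$p)
  }
  ctx
}

canonical_family_key <- function(members) {
  paste(sort(vapply(members, function(v) paste(sort(v), collapse = ","),
                    character(1))), collapse = ";")
}

# Cached family log-likelihood (cache: environment key -> result).
family_loglik_cached <- function(members, ctx, cache) {
  key <- canonical_family_key(members)
  hit <- cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  res <- family_loglik(ctx$obs, members, ctx)
  cache[[key]] <- res
  res
}

config_total_loglik <- function(cfg, ctx, cache) {
  sum(vapply(cfg, function(fam) family_loglik_cached(fam, ctx, cache)$loglik,
             numeric(1)))
}

validate_cover <- function(cfg, n) {
  got <- sort(unlist(cfg))
  if (!identical(got, seq_len(n))) {
    stop_arg("configuration is not an exact cover of the workers")
  }
}

#' Log-likelihood of a nested sibship configuration
#'
#' Evaluates the full-integration likelihood of a proposed partition of a
#' brood into maternal families and nested paternal families, under the
#' two-class genotyping-error model. A configuration containing a worker
#' genotype impossible under every parental state (with zero error rates)
#' has log-likelihood `-Inf`.
#'
#' @param g a [geno_matrix] holding the brood (one tree's workers).
#' @param config a list of maternal families; each maternal family is a
#'   list of paternal families given as integer row indices or worker id
#'   character vectors. Must cover each worker exactly once.
#' @param freqs reference [allele_freqs].
#' @param err an [error_model].
#' @param candidate optional [candidate_queen].
#' @param mode `"haplodiploid"` (default) or `"diplodiploid"`.
#' @return the total log-likelihood (numeric scalar).
#' @export
config_loglik <- function(g, config, freqs = NULL, err = error_model(),
                          candidate = NULL,
                          mode = c("haplodiploid", "diplodiploid")) {
  stopifnot(inherits(g, "geno_matrix"), inherits(err, "error_model"))
  mode <- match.arg(mode)
  freqs <- freqs %||% sample_allele_frequencies(g)
  if (length(freqs$p) != ncol(g$calls)) {
    stop_arg("frequency panel does not match the locus count")
  }
  cfg <- lapply(config, function(fam) {
    lapply(fam, function(v) {
      if (is.character(v)) {
        idx <- match(v, g$info$id)
        if (anyNA(idx)) stop_arg("unknown worker id in configuration")
        idx
      } else {
        as.integer(v)
      }
    })
  })
  validate_cover(cfg, nrow(g$calls))
  ctx <- sibship_context(g$calls, freqs, err, candidate, mode)
  sum(vapply(cfg, function(fam) family_loglik(ctx$obs, fam, ctx)$loglik,
             numeric(1)))
}
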