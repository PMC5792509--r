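# Search over nested sibship configurations: exact maximisation by
# per-maternal-block enumeration for small broods, simulated annealing on
# split/merge/move proposals otherwise.

# Best paternal sub-partition (and its log-likelihood) for one maternal
# block, by enumeration. Ties go to fewer paternal families.
best_block <- function(block, ctx, cache) {
  key <- paste(sort(block), collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  best <- NULL
  for (sp in set_partitions(length(block))) {
    fam <- map_partition(sp, block)
    ll <- family_loglik(ctx$obs, fam, ctx)$loglik
    if (is.null(best) || ll > best$loglik + 1e-9 ||
        (ll > best$loglik - 1e-9 && length(fam) < length(best$family))) {
      best <- list(loglik = ll, family = fam)
    }
  }
  cache[[key]] <- best
  best
}

search_exhaustive <- function(n, ctx) {
  cache <- new.env(parent = emptyenv())
  best <- NULL
  for (mp in set_partitions(n)) {
    blocks <- lapply(mp, best_block, ctx = ctx, cache = cache)
    ll <- sum(vapply(blocks, `[[`, numeric(1), "loglik"))
    n_m <- length(mp)
    n_f <- sum(vapply(blocks, function(b) length(b$family), integer(1)))
    better <- is.null(best) || ll > best$loglik + 1e-9 ||
      (ll > best$loglik - 1e-9 &&
         (n_m < best$n_mothers ||
            (n_m == best$n_mothers && n_f < best$n_fathers)))
    if (better) {
      best <- list(loglik = ll, config = lapply(blocks, `[[`, "family"),
                   n_mothers = n_m, n_fathers = n_f)
    }
  }
  best
}

# --- annealing ---------------------------------------------------------

random_bipartition <- function(v) {
  repeat {
    side <- stats::runif(length(v)) < 0.5
    if (any(side) && !all(side)) {
      return(list(v[side], v[!side]))
    }
  }
}

drop_empty <- function(cfg) {
  cfg <- lapply(cfg, function(fam) fam[lengths(fam) > 0L])
  cfg[lengths(cfg) > 0L]
}

propose_move <- function(cfg, n) {
  kind <- sample.int(5L, 1L)
  if (kind == 1L) { # move one worker
    w <- sample.int(n, 1L)
    cfg <- lapply(cfg, function(fam) lapply(fam, function(v) v[v != w]))
    cfg <- drop_empty(cfg)
    n_m <- length(cfg)
    # destination: existing paternal family, new paternal family in an
    # existing maternal family, or a brand-new maternal family
    slots <- list()
    for (m in seq_len(n_m)) {
      for (f in seq_along(cfg[[m]])) slots[[length(slots) + 1L]] <- c(m, f)
      slots[[length(slots) + 1L]] <- c(m, 0L) # new paternal family here
    }
    slots[[length(slots) + 1L]] <- c(0L, 0L)  # new maternal family
    pick <- slots[[sample.int(length(slots), 1L)]]
    if (pick[1L] == 0L) {
      cfg[[n_m + 1L]] <- list(w)
    } else if (pick[2L] == 0L) {
      cfg[[pick[1L]]][[length(cfg[[pick[1L]]]) + 1L]] <- w
    } else {
      cfg[[pick[1L]]][[pick[2L]]] <- sort(c(cfg[[pick[1L]]][[pick[2L]]], w))
    }
  } else if (kind == 2L) { # split a paternal family
    cand <- which(vapply(cfg, function(fam) any(lengths(fam) >= 2L), logical(1)))
    if (length(cand)) {
      m <- cand[sample.int(length(cand), 1L)]
      fs <- which(lengths(cfg[[m]]) >= 2L)
      f <- fs[sample.int(length(fs), 1L)]
      halves <- random_bipartition(cfg[[m]][[f]])
      cfg[[m]][[f]] <- halves[[1L]]
      cfg[[m]][[length(cfg[[m]]) + 1L]] <- halves[[2L]]
    }
  } else if (kind == 3L) { # merge two paternal families
    cand <- which(lengths(cfg) >= 2L)
    if (length(cand)) {
      m <- cand[sample.int(length(cand), 1L)]
      fs <- sample.int(length(cfg[[m]]), 2L)
      cfg[[m]][[fs[1L]]] <- sort(c(cfg[[m]][[fs[1L]]], cfg[[m]][[fs[2L]]]))
      cfg[[m]][[fs[2L]]] <- integer()
      cfg <- drop_empty(cfg)
    }
  } else if (kind == 4L) { # split a maternal family
    cand <- which(vapply(cfg, function(fam) {
      length(fam) >= 2L || any(lengths(fam) >= 2L)
    }, logical(1)))
    if (length(cand)) {
      m <- cand[sample.int(length(cand), 1L)]
      fam <- cfg[[m]]
      if (length(fam) >= 2L) {
        halves <- random_bipartition(seq_along(fam))
        cfg[[m]] <- fam[halves[[1L]]]
        cfg[[length(cfg) + 1L]] <- fam[halves[[2L]]]
      } else {
        halves <- random_bipartition(fam[[1L]])
        cfg[[m]] <- list(halves[[1L]])
        cfg[[length(cfg) + 1L]] <- list(halves[[2L]])
      }
    }
  } else { # merge two maternal families
    if (length(cfg) >= 2L) {
      ms <- sample.int(length(cfg), 2L)
      cfg[[ms[1L]]] <- c(cfg[[ms[1L]]], cfg[[ms[2L]]])
      cfg[[ms[2L]]] <- list()
      cfg <- drop_empty(cfg)
    }
  }
  drop_empty(cfg)
}

search_anneal <- function(n, ctx, control = list()) {
  iterations <- control$iterations %||% max(2000L, 400L * n)
  t0 <- control$t0 %||% 2
  cooling <- control$cooling %||% exp(log((control$t_end %||% 0.02) / t0) / iterations)
  cache <- new.env(parent = emptyenv())
  cfg <- list(lapply(seq_len(n), function(w) w)) # one mother, singleton fathers
  ll <- config_total_loglik(cfg, ctx, cache)
  best <- list(config = cfg, loglik = ll)
  temp <- t0
  for (it in seq_len(iterations)) {
    prop <- propose_move(cfg, n)
    ll_prop <- config_total_loglik(prop, ctx, cache)
    if (ll_prop >= ll || stats::runif(1) < exp((ll_prop - ll) / temp)) {
      cfg <- prop
      ll <- ll_prop
      if (ll > best$loglik) best <- list(config = cfg, loglik = ll)
    }
    temp <- temp * cooling
  }
  canon <- lapply(best$config, function(fam) {
    fam[order(vapply(fam, min, integer(1)))]
  })
  canon <- canon[order(vapply(canon, function(fam) min(unlist(fam)), integer(1)))]
  list(loglik = best$loglik, config = canon,
       n_mothers = length(canon),
       n_fathers = sum(lengths(canon)))
}

#' Reconstruct sibships for one brood
#'
#' Finds the maximum-likelihood partition of a set of workers into
#' maternal families and nested paternal families, under haplodiploid
#' (default) or diplodiploid inheritance with the two-class
#' genotyping-error model, a polygamous mating system for both sexes, and
#' an optional genotyped candidate queen weighted by her prior. The
#' `"exhaustive"` search enumerates per-maternal-block optima and is
#' exact; `"anneal"` runs simulated annealing with geometric cooling over
#' split/merge/move proposals and returns the best configuration visited.
#' `"auto"` picks exhaustive up to `cap` workers.
#'
#' @param g a [geno_matrix] with the brood (typically one tree's workers).
#' @param freqs reference [allele_freqs]; defaults to sample frequencies
#'   of `g`.
#' @param err an [error_model].
#' @param candidate optional [candidate_queen].
#' @param mode `"haplodiploid"` or `"diplodiploid"`.
#' @param search `"auto"`, `"exhaustive"` or `"anneal"`.
#' @param seed integer seed for the annealing search.
#' @param cap largest brood size the exhaustive search accepts.
#' @param control list of annealing settings: `iterations`, `t0`,
#'   `cooling` (geometric factor per iteration), `t_end` (used to derive
#'   `cooling` when not given).
#' @return an object of class `sibship_config`: list with `families`
#'   (maternal families as lists of character paternal-family vectors),
#'   `loglik`, `n_mothers`, `n_fathers`, `mother_ids`,
#'   `candidate_assigned` (logical per maternal family),
#'   `mother_posterior` (list of 3 x L matrices: genotype posterior per
#'   mother), `father_posterior`, plus bookkeeping (`tree`, `mode`,
#'   `ids`, `loci`, `search`).
#' @examples
#' f <- draw_allele_frequencies(120, seed = 1)
#' sim <- simulate_colonies(colony_design(n_trees = 1, queens_per_tree = 2),
#'   f,
#'   seed = 2
#' )
#' cfg <- reconstruct(sim$genotypes, f)
#' cfg$n_mothers
#' @export
reconstruct <- function(g, freqs = NULL, err = error_model(), candidate = NULL,
                        mode = c("haplodiploid", "diplodiploid"),
                        search = c("auto", "exhaustive", "anneal"),
                        seed = NULL, cap = 7L, control = list()) {
  stopifnot(inherits(g, "geno_matrix"), inherits(err, "error_model"))
  mode <- match.arg(mode)
  search <- match.arg(search)
  n <- nrow(g$calls)
  freqs <- freqs %||% sample_allele_frequencies(g)
  if (length(freqs$p) != ncol(g$calls)) {
    stop_arg("frequency panel does not match the locus count")
  }
  ctx <- sibship_context(g$calls, freqs, err, candidate, mode)
  if (search == "auto") {
    search <- if (n <= cap) "exhaustive" else "anneal"
  }
  if (search == "exhaustive" && n > cap) {
    stop_arg("exhaustive search refused for ", n, " workers (cap ", cap, ")")
  }
  res <- if (search == "exhaustive") {
    search_exhaustive(n, ctx)
  } else {
    with_seed(seed, search_anneal(n, ctx, control))
  }
  finalize_config(res, g, ctx, search)
}

finalize_config <- function(res, g, ctx, search) {
  cfg <- res$config
  tree <- unique(g$info$tree)
  tree_id <- if (length(tree) == 1L) tree else "pooled"
  mother_ids <- character(length(cfg))
  assigned <- logical(length(cfg))
  mpost <- vector("list", length(cfg))
  fpost <- vector("list", length(cfg))
  for (m in seq_along(cfg)) {
    fl <- family_loglik(ctx$obs, cfg[[m]], ctx)
    assigned[m] <- fl$candidate_assigned
    mprior <- if (assigned[m]) ctx$mprior_cand else ctx$mprior_hwe
    det <- maternal_family_lik(ctx$obs, cfg[[m]], mprior, ctx$fprior,
                               ctx$Ttab, posteriors = TRUE)
    mpost[[m]] <- det$mother_posterior
    fpost[[m]] <- det$father_posterior
    mother_ids[m] <- if (assigned[m]) {
      ctx$candidate$id
    } else {
      sprintf("%s_M%d", tree_id, m)
    }
  }
  mother_ids <- make.unique(mother_ids)
  families <- lapply(cfg, function(fam) lapply(fam, function(v) g$info$id[v]))
  structure(
    list(
      families = families, loglik = res$loglik,
      n_mothers = length(cfg), n_fathers = sum(lengths(cfg)),
      mother_ids = mother_ids, candidate_assigned = assigned,
      mother_posterior = mpost, father_posterior = fpost,
      tree = tree_id, mode = ctx$mode, ids = g$info$id, loci = g$loci,
      species = unique(g$info$species)[1L], search = search
    ),
    class = "sibship_config"
  )
}

#' @export
print.sibship_config <- function(x, ...) {
  cat(sprintf(
    "sibship_config (%s, %s search): %d workers -> %d mother(s), %d father(s); log-likelihood %.2f\n",
    x$tree, x$search, length(x$ids), x$n_mothers, x$n_fathers, x$loglik
  ))
  invisible(x)
}

#' Reconstruct sibships tree by tree
#'
#' Applies [reconstruct()] separately to each tree of a genotype matrix
#' (workers from different trees cannot share a parent in this mode,
#' mirroring the per-colony reconstruction used for maternal-genotype
#' recovery). A candidate queen is offered only to her own tree.
#'
#' @inheritParams reconstruct
#' @param candidates optional named list of [candidate_queen] objects,
#'   names matching tree ids.
#' @return a named list of `sibship_config` objects, one per tree.
#' @export
reconstruct_colonies <- function(g, freqs = NULL, err = error_model(),
                                 candidates = NULL,
                                 mode = c("haplodiploid", "diplodiploid"),
                                 search = c("auto", "exhaustive", "anneal"),
                                 seed = NULL, cap = 7L, control = list()) {
  stopifnot(inherits(g, "geno_matrix"))
  mode <- match.arg(mode)
  search <- match.arg(search)
  freqs <- freqs %||% sample_allele_frequencies(g)
  trees <- unique(g$info$tree)
  out <- vector("list", length(trees))
  names(out) <- trees
  for (i in seq_along(trees)) {
    sub <- subset_geno(g, which(g$info$tree == trees[i] &
                                  g$info$caste == "worker"))
    out[[i]] <- reconstruct(
      sub, freqs, err,
      candidate = if (!is.null(candidates)) candidates[[trees[i]]] else NULL,
      mode = mode, search = search, seed = child_seed(seed, i), cap = cap,
      control = control
    )
  }
  out
}

#' Recover maternal genotypes from a reconstruction
#'
#' For each inferred mother the maximum-posterior diploid genotype is
#' emitted per locus; any allele whose marginal posterior support falls
#' below `threshold` renders the call missing (half-calls are not
#' representable in the biallelic matrix). `threshold = 0` disables
#' masking.
#'
#' @param config a `sibship_config` from [reconstruct()], or a list of
#'   them (one per tree) as returned by [reconstruct_colonies()].
#' @param threshold posterior mass an allele must reach (default 0.90).
#' @return a [geno_matrix] of inferred mothers (caste `"queen"`), labeled
#'   with each mother's tree.
#' @export
infer_maternal_genotypes <- function(config, threshold = 0.9) {
  if (inherits(config, "sibship_config")) config <- list(config)
  stopifnot(all(vapply(config, inherits, logical(1), "sibship_config")))
  if (threshold < 0 || threshold > 1) stop_arg("'threshold' must lie in [0, 1]")
  rows <- list()
  info <- list()
  for (cfg in config) {
    for (m in seq_along(cfg$mother_posterior)) {
      post <- cfg$mother_posterior[[m]]
      map <- max.col(t(post), ties.method = "first") - 1L
      # allele support: copies of each allele the posterior can vouch for
      p_ge1_ref <- post[1L, ] + post[2L, ] # >= 1 reference allele
      p_ge1_alt <- post[3L, ] + post[2L, ] # >= 1 alternate allele
      supp1 <- ifelse(map == 0L, p_ge1_ref, ifelse(map == 2L, p_ge1_alt, p_ge1_ref))
      supp2 <- ifelse(map == 0L, post[1L, ], ifelse(map == 2L, post[3L, ], p_ge1_alt))
      masked <- threshold > 0 & (pmin(supp1, supp2) < threshold)
      calls <- ifelse(masked, NA_integer_, map)
      rows[[length(rows) + 1L]] <- as.integer(calls)
      info[[length(info) + 1L]] <- data.frame(
        id = cfg$mother_ids[m], species = cfg$species, tree = cfg$tree,
        caste = "queen", stringsAsFactors = FALSE
      )
    }
  }
  calls <- do.call(rbind, rows)
  geno_matrix(calls, info = do.call(rbind, info), loci = config[[1L]]$loci)
}
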