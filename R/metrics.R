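#' Colony-structure indices from a sibship reconstruction
#'
#' Computes, for one tree's reconstructed brood: the Polygyny Index
#' (number of inferred mothers among the sampled workers), the Polyandry
#' Index (number of distinct inferred fathers across the tree), queen and
#' male dominance (the proportion of sampled workers descending from the
#' most prolific mother, respectively father), and the number of male
#' mates per queen, the latter restricted to queens with at least
#' `min_offspring` sampled offspring. These are relative, sample-dependent
#' indices: families absent from the sample are invisible to them.
#'
#' @param config a `sibship_config` from [reconstruct()].
#' @param min_offspring minimum sampled offspring a queen needs for her
#'   mate count to be reported (default 4).
#' @return a list of class `colony_metrics`: `tree`, `n_workers`,
#'   `polygyny`, `polyandry`, `queen_dominance`, `male_dominance`,
#'   `males_per_queen` (numeric vector, possibly empty).
#' @export
polygyny_polyandry <- function(config, min_offspring = 4L) {
  stopifnot(inherits(config, "sibship_config"))
  fam_sizes <- vapply(config$families, function(fam) sum(lengths(fam)),
                      integer(1))
  n_w <- sum(fam_sizes)
  if (n_w == 0L) stop_arg("empty configuration")
  mates <- vapply(config$families, length, integer(1))
  pat_fam_sizes <- unlist(lapply(config$families, function(fam) lengths(fam)))
  structure(
    list(
      tree = config$tree, n_workers = n_w,
      polygyny = length(config$families),
      polyandry = sum(mates),
      queen_dominance = max(fam_sizes) / n_w,
      male_dominance = max(pat_fam_sizes) / n_w,
      males_per_queen = mates[fam_sizes >= min_offspring],
      min_offspring = as.integer(min_offspring)
    ),
    class = "colony_metrics"
  )
}

#' @export
print.colony_metrics <- function(x, ...) {
  cat(sprintf(
    "colony_metrics %s: %d workers; Polygyny %d, Polyandry %d, queen dominance %.2f, male dominance %.2f; males/queen: %s\n",
    x$tree, x$n_workers, x$polygyny, x$polyandry, x$queen_dominance,
    x$male_dominance,
    if (length(x$males_per_queen)) paste(x$males_per_queen, collapse = ",") else "-"
  ))
  invisible(x)
}

#' Tabulate colony metrics across trees
#'
#' @param configs list of `sibship_config` objects (one per tree).
#' @param min_offspring passed to [polygyny_polyandry()].
#' @return a data frame with one row per tree and columns `tree`,
#'   `n_workers`, `polygyny`, `polyandry`, `queen_dominance`,
#'   `male_dominance`, `males_per_queen` (comma-separated string).
#' @export
colony_metrics_table <- function(configs, min_offspring = 4L) {
  rows <- lapply(configs, function(cfg) {
    m <- polygyny_polyandry(cfg, min_offspring)
    data.frame(
      tree = m$tree, n_workers = m$n_workers, polygyny = m$polygyny,
      polyandry = m$polyandry, queen_dominance = m$queen_dominance,
      male_dominance = m$male_dominance,
      males_per_queen = paste(m$males_per_queen, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Classify kinship among inferred queens
#'
#' Runs a sibship reconstruction on the inferred maternal genotypes
#' themselves, treating the queens as a single set of diploid offspring
#' of unknown (diplodiploid) parents, and classifies every queen pair as
#' full siblings (same maternal and paternal family), half siblings
#' (same maternal family only) or unrelated. "Related" pairs (full or
#' half siblings) are tabulated separately for queens from the same tree
#' and queens from different trees.
#'
#' @param mothers a [geno_matrix] of inferred queens (from
#'   [infer_maternal_genotypes()]); the `tree` labels define the strata.
#' @param freqs reference [allele_freqs] (defaults to worker-derived
#'   frequencies are recommended; sample frequencies of the mothers
#'   otherwise).
#' @param err an [error_model].
#' @param search,seed,cap,control passed to [reconstruct()].
#' @return a list of class `queen_kinship_table`: `pairs` (data frame
#'   with `id1`, `id2`, `tree1`, `tree2`, `relation`, `related`),
#'   `counts` (2 x 2 matrix: rows within/between tree, columns
#'   related/unrelated), `proportions` (named numeric), and `config` (the
#'   underlying reconstruction).
#' @export
queen_kinship <- function(mothers, freqs = NULL, err = error_model(),
                          search = c("auto", "exhaustive", "anneal"),
                          seed = NULL, cap = 7L, control = list()) {
  stopifnot(inherits(mothers, "geno_matrix"))
  search <- match.arg(search)
  if (nrow(mothers$calls) < 2L) {
    return(structure(
      list(pairs = data.frame(), counts = matrix(0L, 2L, 2L,
        dimnames = list(c("within", "between"), c("related", "unrelated"))),
        proportions = c(within = NA_real_, between = NA_real_), config = NULL),
      class = "queen_kinship_table"
    ))
  }
  freqs <- freqs %||% sample_allele_frequencies(mothers)
  cfg <- reconstruct(mothers, freqs, err, mode = "diplodiploid",
                     search = search, seed = seed, cap = cap, control = control)
  # map each queen to (maternal family, paternal family)
  ids <- mothers$info$id
  mat_f <- integer(length(ids)); pat_f <- integer(length(ids))
  pf_counter <- 0L
  for (m in seq_along(cfg$families)) {
    for (f in seq_along(cfg$families[[m]])) {
      pf_counter <- pf_counter + 1L
      idx <- match(cfg$families[[m]][[f]], ids)
      mat_f[idx] <- m
      pat_f[idx] <- pf_counter
    }
  }
  cmb <- utils::combn(length(ids), 2L)
  i <- cmb[1L, ]; j <- cmb[2L, ]
  relation <- ifelse(
    mat_f[i] == mat_f[j],
    ifelse(pat_f[i] == pat_f[j], "full-sib", "half-sib"),
    "unrelated"
  )
  pairs <- data.frame(
    id1 = ids[i], id2 = ids[j],
    tree1 = mothers$info$tree[i], tree2 = mothers$info$tree[j],
    relation = relation, related = relation != "unrelated",
    stringsAsFactors = FALSE
  )
  within <- pairs$tree1 == pairs$tree2
  counts <- matrix(
    c(sum(pairs$related[within]), sum(!pairs$related[within]),
      sum(pairs$related[!within]), sum(!pairs$related[!within])),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("within", "between"), c("related", "unrelated"))
  )
  proportions <- c(
    within = if (sum(within)) mean(pairs$related[within]) else NA_real_,
    between = if (sum(!within)) mean(pairs$related[!within]) else NA_real_
  )
  structure(
    list(pairs = pairs, counts = counts, proportions = proportions,
         config = cfg),
    class = "queen_kinship_table"
  )
}

#' @export
print.queen_kinship_table <- function(x, ...) {
  cw <- x$counts["within", ]; cb <- x$counts["between", ]
  cat(sprintf(
    "queen kinship: same-tree related %.2f (%d/%d); different-tree related %.2f (%d/%d)\n",
    x$proportions["within"], cw["related"], sum(cw),
    x$proportions["between"], cb["related"], sum(cb)
  ))
  invisible(x)
}
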