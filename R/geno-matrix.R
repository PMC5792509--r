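#' Genotype matrix for biallelic SNP panels
#'
#' The central container of the package: a rectangular matrix of biallelic
#' genotype calls, individuals in rows and loci in columns, with per-individual
#' labels (species, tree/colony, caste). Calls are coded as the count of the
#' alternate allele: `0` = homozygous reference, `1` = heterozygous,
#' `2` = homozygous alternate, `NA` = missing.
#'
#' @param calls integer matrix of 0/1/2/`NA` calls; row names are taken as
#'   individual ids when `info` is omitted.
#' @param info data frame with columns `id`, `species`, `tree`, `caste`
#'   (caste one of `"worker"`, `"queen"`), one row per row of `calls`.
#'   Missing columns are filled with defaults (one species, one tree,
#'   all workers).
#' @param loci character vector of locus ids; defaults to the column names
#'   of `calls` or `L1..Ln`.
#' @return an object of class `geno_matrix`: a list with elements `calls`
#'   (integer matrix), `info` (data frame) and `loci` (character).
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'   dimnames = list(c("w1", "w2"), c("s1", "s2"))
#' ))
#' n_ind(g)
#' n_loci(g)
#' @export
geno_matrix <- function(calls, info = NULL, loci = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) == 0L) {
    stop_arg("genotype matrix has no individuals")
  }
  if (ncol(calls) == 0L) {
    stop_arg("genotype matrix has no loci")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop_arg("genotype calls must be 0, 1, 2 or NA")
  }
  if (is.null(loci)) {
    loci <- colnames(calls) %||% paste0("L", seq_len(ncol(calls)))
  }
  if (length(loci) != ncol(calls)) {
    stop_arg("length of 'loci' must equal the number of columns")
  }
  if (anyDuplicated(loci)) {
    stop_arg("duplicated locus ids")
  }
  if (is.null(info)) {
    ids <- rownames(calls) %||% paste0("ind", seq_len(nrow(calls)))
    info <- data.frame(
      id = ids, species = "sp1", tree = "t1", caste = "worker",
      stringsAsFactors = FALSE
    )
  } else {
    info <- as.data.frame(info, stringsAsFactors = FALSE)
    if (is.null(info$id)) stop_arg("'info' must have an 'id' column")
    info$id <- as.character(info$id)
    if (is.null(info$species)) info$species <- "sp1"
    if (is.null(info$tree)) info$tree <- "t1"
    if (is.null(info$caste)) info$caste <- "worker"
    info$species <- as.character(info$species)
    info$tree <- as.character(info$tree)
    info$caste <- as.character(info$caste)
  }
  if (nrow(info) != nrow(calls)) {
    stop_arg("'info' must have one row per individual")
  }
  if (anyDuplicated(info$id)) {
    stop_arg("duplicated individual ids")
  }
  if (!all(info$caste %in% c("worker", "queen"))) {
    stop_arg("caste must be 'worker' or 'queen'")
  }
  dimnames(calls) <- list(info$id, loci)
  structure(
    list(calls = calls, info = info[, c("id", "species", "tree", "caste")], loci = loci),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(
    "geno_matrix:", nrow(x$calls), "individuals x", ncol(x$calls), "loci\n",
    " species:", paste(unique(x$info$species), collapse = ", "), "\n",
    " trees:", length(unique(x$info$tree)),
    " queens:", sum(x$info$caste == "queen"), "\n",
    " completeness:", sprintf("%.3f", matrix_completeness(x)), "\n"
  )
  invisible(x)
}

#' @rdname geno_matrix
#' @param g a `geno_matrix`.
#' @export
n_ind <- function(g) nrow(g$calls)

#' @rdname geno_matrix
#' @export
n_loci <- function(g) ncol(g$calls)

#' Subset a genotype matrix
#'
#' @param g a `geno_matrix`.
#' @param individuals individual ids or row indices (optional).
#' @param loci locus ids or column indices (optional).
#' @return the subset `geno_matrix`.
#' @export
subset_geno <- function(g, individuals = NULL, loci = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  ri <- seq_len(nrow(g$calls))
  ci <- seq_len(ncol(g$calls))
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, g$info$id) else individuals
    if (anyNA(ri)) stop_arg("unknown individual id(s)")
  }
  if (!is.null(loci)) {
    ci <- if (is.character(loci)) match(loci, g$loci) else loci
    if (anyNA(ci)) stop_arg("unknown locus id(s)")
  }
  geno_matrix(g$calls[ri, ci, drop = FALSE], info = g$info[ri, , drop = FALSE],
              loci = g$loci[ci])
}

#' Matrix completeness
#'
#' Proportion of individual-by-locus cells with a determined genotype,
#' the quantity reported as "matrix completeness" for a SNP panel.
#'
#' @param g a `geno_matrix`.
#' @return a single fraction in \[0, 1\].
#' @export
matrix_completeness <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  mean(!is.na(g$calls))
}

#' Per-locus observed heterozygosity
#'
#' The proportion of individuals carrying two different alleles at a locus,
#' among individuals with a non-missing call there.
#'
#' @param g a `geno_matrix`.
#' @return named numeric vector, one value per locus; `NA` (with the locus
#'   flagged by name in a warning) where every call is missing, since the
#'   proportion is then undefined rather than zero.
#' @export
observed_heterozygosity <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  nonmiss <- colSums(!is.na(g$calls))
  het <- colSums(g$calls == 1L, na.rm = TRUE)
  out <- ifelse(nonmiss > 0L, het / nonmiss, NA_real_)
  names(out) <- g$loci
  if (anyNA(out)) {
    warning(
      "observed heterozygosity undefined (all calls missing) at ",
      sum(is.na(out)), " locus/loci", call. = FALSE
    )
  }
  out
}

# Genotype codes <-> two-character strings used by the TSV dialect.
GENO_CODES <- c("AA", "AB", "BB")

calls_to_strings <- function(calls) {
  out <- matrix("--", nrow(calls), ncol(calls), dimnames = dimnames(calls))
  ok <- !is.na(calls)
  out[ok] <- GENO_CODES[calls[ok] + 1L]
  out
}

strings_to_calls <- function(strs) {
  m <- match(toupper(as.matrix(strs)), GENO_CODES) - 1L
  bad <- is.na(m) & !(as.matrix(strs) %in% c("--", "", NA))
  if (any(bad)) {
    stop_arg(
      "unrecognised genotype string(s): ",
      paste(utils::head(unique(as.matrix(strs)[bad]), 3), collapse = ", ")
    )
  }
  matrix(m, nrow(strs), ncol(strs), dimnames = dimnames(as.matrix(strs)))
}
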