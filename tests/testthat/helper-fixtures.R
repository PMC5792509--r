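# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# A tiny genotype matrix from a plain integer matrix (rows = individuals).
make_geno <- function(m, species = "sp1", tree = "t1", caste = "worker",
                      ids = NULL) {
  m <- as.matrix(m)
  ids <- ids %||% paste0("w", seq_len(nrow(m)))
  info <- data.frame(
    id = ids,
    species = rep_len(species, nrow(m)),
    tree = rep_len(tree, nrow(m)),
    caste = rep_len(caste, nrow(m)),
    stringsAsFactors = FALSE
  )
  geno_matrix(m, info = info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent nested-partition count: sum over set partitions of the
# product of Bell numbers of the block sizes (recursive, no shared code
# with the enumeration under test).
bell_number <- function(n) {
  if (n <= 1L) {
    return(1L)
  }
  b <- c(1, 1) # B0, B1
  for (k in 2:n) {
    b <- c(b, sum(choose(k - 1L, 0:(k - 1L)) * b))
  }
  b[n + 1L]
}

nested_partition_count <- function(n) {
  # a(n) = sum_{k=1}^{n} C(n-1, k-1) * Bell(k) * a(n-k): place element 1
  # in a maternal block of size k, sub-partition it, recurse on the rest.
  if (n == 0L) {
    return(1)
  }
  total <- 0
  for (k in 1:n) {
    total <- total + choose(n - 1L, k - 1L) * bell_number(k) *
      nested_partition_count(n - k)
  }
  total
}
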