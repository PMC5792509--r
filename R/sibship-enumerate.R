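# Exhaustive enumeration of nested sibship configurations: every set
# partition of the workers into maternal families, sub-partitioned into
# paternal families. Feasible only for small broods; used as the exact
# oracle that the annealing search is validated against.

#' All set partitions of 1..n
#'
#' @param n number of elements (>= 0).
#' @return a list of partitions; each partition is a list of strictly
#'   increasing integer vectors (blocks) in canonical order.
#' @keywords internal
set_partitions <- function(n) {
  if (n == 0L) {
    return(list(list()))
  }
  if (n == 1L) {
    return(list(list(1L)))
  }
  smaller <- set_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Relabel a partition of 1..k onto arbitrary element ids.
map_partition <- function(p, elements) {
  lapply(p, function(b) elements[b])
}

#' Enumerate all nested sibship configurations
#'
#' Yields every partition of `n_workers` into maternal families together
#' with every sub-partition of each maternal family into paternal
#' families, each configuration exactly once. The count grows as the
#' Bell-number composition (1, 3, 12, 60, 358, 2471, ... for n = 1..7),
#' so enumeration is refused above `cap`.
#'
#' @param n_workers number of workers.
#' @param cap refusal threshold (default 8).
#' @return a list of configurations; each configuration is a list of
#'   maternal families, each maternal family a list of integer vectors
#'   (paternal families).
#' @export
enumerate_configs <- function(n_workers, cap = 8L) {
  if (n_workers < 1L) stop_arg("'n_workers' must be >= 1")
  if (n_workers > cap) {
    stop_arg("refusing to enumerate ", n_workers,
             " workers (cap ", cap, "); use the annealing search instead")
  }
  maternal <- set_partitions(as.integer(n_workers))
  out <- list()
  for (mp in maternal) {
    subparts <- lapply(mp, function(block) {
      lapply(set_partitions(length(block)), map_partition, elements = block)
    })
    # cartesian product of per-block sub-partitions
    combos <- expand_grid_list(lapply(subparts, seq_along))
    for (row in combos) {
      cfg <- lapply(seq_along(mp), function(b) subparts[[b]][[row[b]]])
      out[[length(out) + 1L]] <- cfg
    }
  }
  out
}

# All combinations of one index from each list element, as integer vectors.
expand_grid_list <- function(index_lists) {
  if (length(index_lists) == 0L) {
    return(list(integer()))
  }
  grid <- do.call(expand.grid, c(index_lists, KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}
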