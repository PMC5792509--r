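#' Evaluate relatedness estimators on simulated dyads
#'
#' Runs the simulation experiment used to choose a relatedness estimator:
#' for each of the four relationship classes (parent-offspring, full-sib,
#' half-sib, unrelated) it draws `n_pairs` dyads from the supplied allele
#' frequencies, estimates each dyad's relatedness with each candidate
#' estimator (using the same frequencies as reference), and scores each
#' estimator by the Pearson correlation between true and estimated
#' relatedness pooled over all `4 * n_pairs` dyads.
#'
#' @param freqs an [allele_freqs] panel.
#' @param n_pairs dyads per relationship class (>= 2).
#' @param mode inheritance mode for the dyad simulation; diplodiploid by
#'   default (the convention of the evaluation experiment, even for
#'   haplodiploid study taxa).
#' @param estimators character subset of `c("lr", "qg")`.
#' @param seed optional integer seed.
#' @return an object of class `estimator_evaluation`: a list with
#'   `correlations` (named numeric), `per_class` (data frame of
#'   per-relationship mean/SD per estimator), `table` (the pooled
#'   true-vs-estimated data frame), `n_pairs`, `mode` and `seed`.
#' @examples
#' f <- draw_allele_frequencies(150, 0.1, 0.5, seed = 1)
#' ev <- evaluate_estimators(f, n_pairs = 25, seed = 2)
#' ev$correlations
#' @export
evaluate_estimators <- function(freqs, n_pairs = 100,
                                mode = c("diplodiploid", "haplodiploid"),
                                estimators = c("lr", "qg"), seed = NULL) {
  stopifnot(inherits(freqs, "allele_freqs"))
  mode <- match.arg(mode)
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (n_pairs < 2) stop_arg("'n_pairs' must be >= 2 for a defined correlation")
  rels <- c("parent-offspring", "full-sib", "half-sib", "unrelated")
  rows <- list()
  for (i in seq_along(rels)) {
    sim <- simulate_relationship_pairs(rels[i], n_pairs, freqs, mode = mode,
                                       seed = child_seed(seed, i))
    calls <- sim$genotypes$calls
    for (est in estimators) {
      r_hat <- vapply(seq_len(n_pairs), function(k) {
        pair_estimate(calls[2L * k - 1L, ], calls[2L * k, ], freqs$p, est)$r
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        relationship = rels[i], estimator = est, pair = seq_len(n_pairs),
        true_r = sim$pairs$true_r, est_r = r_hat, stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$est_r))) stop_arg("all estimates undefined")
  cors <- vapply(estimators, function(est) {
    d <- tab[tab$estimator == est & !is.na(tab$est_r), ]
    if (stats::var(d$true_r) == 0) {
      stop_arg("true relatedness has no variance; supply multiple relationship classes")
    }
    stats::cor(d$true_r, d$est_r)
  }, numeric(1))
  per_class <- do.call(rbind, lapply(estimators, function(est) {
    d <- tab[tab$estimator == est, ]
    agg <- stats::aggregate(est_r ~ relationship, data = d, FUN = function(x) {
      c(mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE), sum(!is.na(x)))
    })
    data.frame(estimator = est, relationship = agg$relationship,
               mean = agg$est_r[, 1L], sd = agg$est_r[, 2L],
               n = as.integer(agg$est_r[, 3L]), stringsAsFactors = FALSE)
  }))
  structure(
    list(correlations = cors, per_class = per_class, table = tab,
         n_pairs = as.integer(n_pairs), mode = mode, seed = seed),
    class = "estimator_evaluation"
  )
}

#' @export
print.estimator_evaluation <- function(x, ...) {
  cat("estimator evaluation (", x$mode, ", ", x$n_pairs,
      " pairs/relationship):\n", sep = "")
  for (e in names(x$correlations)) {
    cat(sprintf("  %s: pooled true-vs-estimated r = %.4f\n", e,
                x$correlations[[e]]))
  }
  invisible(x)
}

#' Select the best-scoring estimator
#'
#' @param evaluation an `estimator_evaluation` (or a named numeric vector
#'   of correlations).
#' @return the name of the estimator with the highest pooled correlation;
#'   ties are broken by name order with a warning.
#' @export
select_estimator <- function(evaluation) {
  cors <- if (inherits(evaluation, "estimator_evaluation")) {
    evaluation$correlations
  } else {
    evaluation
  }
  cors <- cors[!is.na(cors)]
  if (length(cors) == 0L) stop_arg("no defined correlations to select from")
  best <- max(cors)
  winners <- sort(names(cors)[cors == best])
  if (length(winners) > 1L) {
    warning("correlation tie between ", paste(winners, collapse = ", "),
            "; selecting '", winners[1L], "' by name order", call. = FALSE)
  }
  winners[1L]
}
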