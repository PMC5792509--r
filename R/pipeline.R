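#' Pipeline configuration
#'
#' Assembles the configuration for an end-to-end synthetic run: one
#' colony design per (pseudo-)species, locus panels, filter settings,
#' estimator policy, sibship settings and the statistical plan. The
#' default mirrors the scale of the four-species acacia-ant study
#' (13-18 trees per species, about six workers per tree, 309-764 SNPs,
#' species-specific queen numbers and mate counts).
#'
#' @param species named list; each element a list with `design`
#'   (arguments for [colony_design()]) and `n_loci`. Defaults to four
#'   pseudo-species spanning monogynous to strongly polygynous.
#' @param maf_range length-2 minor-allele-frequency range for the
#'   simulated panels.
#' @param filters arguments for [filter_settings()].
#' @param estimator `"lr"`, `"qg"`, or `"by_simeval"` (run the evaluation
#'   experiment and use the winner).
#' @param simeval_pairs dyads per relationship class for the estimator
#'   evaluation.
#' @param err_dropout,err_miscall error rates assumed by the sibship
#'   likelihood.
#' @param min_offspring queen mate counts reported only for queens with
#'   at least this many sampled offspring.
#' @param mask_threshold posterior mass below which inferred maternal
#'   alleles are recorded as missing.
#' @param seed top-level seed; all stage seeds are derived from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(species = NULL,
                            maf_range = c(0.1, 0.5),
                            filters = list(),
                            estimator = c("lr", "qg", "by_simeval"),
                            simeval_pairs = 100L,
                            err_dropout = 1e-4, err_miscall = 2.5e-3,
                            min_offspring = 4L, mask_threshold = 0.9,
                            seed = 1L) {
  estimator <- match.arg(estimator)
  if (is.null(species)) {
    species <- list(
      spA = list(design = list(n_trees = 16, workers_per_tree = 6,
                               queens_per_tree = 1.4, males_per_queen = 3.7,
                               p_missing = 0.44), n_loci = 746),
      spB = list(design = list(n_trees = 14, workers_per_tree = 6,
                               queens_per_tree = 2.9, males_per_queen = 3.7,
                               p_sister_queens = 0.2, p_missing = 0.41),
                 n_loci = 669),
      spC = list(design = list(n_trees = 18, workers_per_tree = 7,
                               queens_per_tree = 1.3, males_per_queen = 2.4,
                               p_missing = 0.16), n_loci = 764),
      spD = list(design = list(n_trees = 13, workers_per_tree = 6,
                               queens_per_tree = 3.5, males_per_queen = 3.0,
                               p_missing = 0.42), n_loci = 309)
    )
  }
  structure(
    list(species = species, maf_range = maf_range, filters = filters,
         estimator = estimator, simeval_pairs = as.integer(simeval_pairs),
         err_dropout = err_dropout, err_miscall = err_miscall,
         min_offspring = as.integer(min_offspring),
         mask_threshold = mask_threshold, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate -> filter -> (optionally) evaluate estimators -> pairwise
#' relatedness with within/between-tree aggregation -> per-tree sibship
#' reconstruction -> colony metrics -> inferred-queen kinship ->
#' statistical comparisons. All randomness derives from the config seed,
#' so identical configurations yield identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, tables are written as
#'   TSV and the manifest as JSON.
#' @return a manifest list: per-species `freqs`, `genotypes`, `truth`,
#'   `filtered`, `relatedness` summary, `sibship` configs, `metrics`
#'   table, `queen_kinship`; cross-species `simeval`, `estimator`,
#'   `tests`; and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  err <- error_model(config$err_dropout, config$err_miscall)
  per_species <- list()
  stage_seed <- function(tag, i) child_seed(config$seed, 1000L * i + tag)
  sp_names <- names(config$species)
  # estimator policy (one evaluation at the first species' panel size)
  simeval_res <- NULL
  estimator <- config$estimator
  if (estimator == "by_simeval") {
    f_eval <- draw_allele_frequencies(
      config$species[[1L]]$n_loci, config$maf_range[1L], config$maf_range[2L],
      seed = child_seed(config$seed, 17L)
    )
    simeval_res <- evaluate_estimators(f_eval, config$simeval_pairs,
                                       seed = child_seed(config$seed, 18L))
    estimator <- select_estimator(simeval_res)
  }
  for (i in seq_along(config$species)) {
    sp <- sp_names[i]
    spec <- config$species[[i]]
    freqs <- draw_allele_frequencies(spec$n_loci, config$maf_range[1L],
                                     config$maf_range[2L],
                                     seed = stage_seed(1L, i))
    design <- do.call(colony_design, c(spec$design, list(species = sp)))
    sim <- simulate_colonies(design, freqs, seed = stage_seed(2L, i))
    filtered <- filter_genotypes(sim$genotypes,
                                 do.call(filter_settings, config$filters))
    obs_freqs <- sample_allele_frequencies(filtered)
    pr <- pairwise_relatedness(filtered, obs_freqs, estimator)
    rel <- aggregate_within_between(pr)
    sib <- reconstruct_colonies(filtered, obs_freqs, err,
                                seed = stage_seed(3L, i))
    metrics <- colony_metrics_table(sib, config$min_offspring)
    mothers <- infer_maternal_genotypes(sib, config$mask_threshold)
    qk <- if (nrow(mothers$calls) >= 2L) {
      queen_kinship(mothers, obs_freqs, err, seed = stage_seed(4L, i))
    } else {
      NULL
    }
    heights <- with_seed(stage_seed(5L, i),
                         stats::rlnorm(design$n_trees, log(2), 0.3))
    per_species[[sp]] <- list(
      freqs = freqs, genotypes = sim$genotypes, truth = sim$truth,
      filtered = filtered, pairs = pr, relatedness = rel, sibship = sib,
      metrics = metrics, mothers = mothers, queen_kinship = qk,
      tree_heights = stats::setNames(heights, sprintf("t%02d", seq_len(design$n_trees)))
    )
  }
  tests <- pipeline_tests(per_species)
  manifest <- list(config = config, estimator = estimator,
                   simeval = simeval_res, species = per_species,
                   tests = tests)
  if (!is.null(out_dir)) write_manifest(manifest, out_dir)
  manifest
}

# The statistical battery over the per-species results.
pipeline_tests <- function(per_species) {
  sp <- names(per_species)
  metric_long <- do.call(rbind, lapply(sp, function(s) {
    m <- per_species[[s]]$metrics
    heights <- per_species[[s]]$tree_heights
    cbind(species = s, m, height = unname(heights[m$tree]))
  }))
  within_long <- do.call(rbind, lapply(sp, function(s) {
    w <- per_species[[s]]$relatedness$within_tree
    if (nrow(w)) data.frame(species = s, value = w$mean_r) else NULL
  }))
  between_long <- do.call(rbind, lapply(sp, function(s) {
    b <- per_species[[s]]$relatedness$between_tree
    if (nrow(b)) data.frame(species = s, value = b$mean_r) else NULL
  }))
  mpq_long <- do.call(rbind, lapply(sp, function(s) {
    v <- unlist(lapply(per_species[[s]]$sibship, function(cfg) {
      polygyny_polyandry(cfg)$males_per_queen
    }))
    if (length(v)) data.frame(species = s, value = as.numeric(v)) else NULL
  }))
  tests <- list(
    within_relatedness = compare_species(within_long$value,
                                         within_long$species, "anova"),
    between_relatedness = compare_species(between_long$value,
                                          between_long$species, "kwt"),
    polygyny = compare_species(metric_long$polygyny, metric_long$species, "kwt"),
    polyandry = compare_species(metric_long$polyandry, metric_long$species, "kwt"),
    between_vs_zero = lapply(stats::setNames(sp, sp), function(s) {
      v <- between_long$value[between_long$species == s]
      if (length(v) >= 2L) ttest_vs_zero(v) else NULL
    }),
    polygyny_vs_height = tree_size_effects(metric_long$polygyny,
                                           metric_long$height,
                                           metric_long$species, "spearman"),
    queen_sibship = lapply(stats::setNames(sp, sp), function(s) {
      qk <- per_species[[s]]$queen_kinship
      if (!is.null(qk) && sum(qk$counts) > 0 &&
          sum(qk$counts["within", ]) > 0) {
        fisher_queen_sibship(qk)
      } else {
        NULL
      }
    })
  )
  if (!is.null(mpq_long) && length(unique(mpq_long$species)) >= 2L &&
      all(table(mpq_long$species) >= 2L) && stats::var(mpq_long$value) > 0) {
    tests$males_per_queen <- compare_species(mpq_long$value,
                                             mpq_long$species, "anova")
  }
  tests
}

write_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_rows <- list()
  for (sp in names(manifest$species)) {
    d <- file.path(out_dir, sp)
    dir.create(d, showWarnings = FALSE)
    x <- manifest$species[[sp]]
    write_genotypes(x$genotypes, file.path(d, "genotypes.tsv"))
    write_pedigree_truth(x$truth, d)
    utils::write.table(x$pairs, file.path(d, "pairwise_relatedness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(x$metrics, file.path(d, "colony_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    s <- x$relatedness$species
    qk <- x$queen_kinship
    summary_rows[[sp]] <- data.frame(
      species = sp, trees = nrow(x$metrics),
      within_r = s$within_mean, within_se = s$within_se,
      between_r = s$between_mean, between_se = s$between_se,
      polygyny = mean(x$metrics$polygyny),
      polyandry = mean(x$metrics$polyandry),
      queen_dominance = mean(x$metrics$queen_dominance),
      related_within = if (!is.null(qk)) qk$proportions[["within"]] else NA,
      related_between = if (!is.null(qk)) qk$proportions[["between"]] else NA
    )
  }
  utils::write.table(do.call(rbind, summary_rows),
                     file.path(out_dir, "species_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  test_summary <- lapply(manifest$tests, function(t) {
    if (inherits(t, "test_report")) {
      list(test = t$test, statistic = t$statistic, p = t$p_value)
    } else if (is.list(t)) {
      lapply(t, function(u) {
        if (inherits(u, "test_report")) {
          list(test = u$test, statistic = u$statistic, p = u$p_value)
        } else {
          NULL
        }
      })
    }
  })
  jsonlite::write_json(
    list(seed = manifest$config$seed, estimator = manifest$estimator,
         tests = test_summary),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
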