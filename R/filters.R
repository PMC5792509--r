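#' Filter settings for post-calling genotype QC
#'
#' Bundles the locus- and individual-level filters applied to a called SNP
#' matrix before relatedness and sibship analysis: a per-species locus
#' presence cutoff, an observed-heterozygosity ceiling (loci with excess
#' heterozygosity are typically collapsed paralogs), a minor-allele-frequency
#' floor, and the culling of individuals whose genotyping largely failed.
#'
#' @param species_r named numeric vector of per-species presence cutoffs;
#'   the `"default"` entry applies to species not named explicitly. Each
#'   value is the minimum fraction of a species' individuals in which a
#'   locus must be called.
#' @param max_het maximum observed heterozygosity for a locus; loci
#'   strictly above it are removed.
#' @param min_maf minimum minor allele frequency.
#' @param min_cov minimum fraction of (pre-screened) loci an individual
#'   must be genotyped at to be retained.
#' @param r_prelim presence cutoff used to pre-screen loci before
#'   individual coverage is assessed.
#' @return an object of class `filter_settings`.
#' @export
filter_settings <- function(species_r = c(default = 0.5),
                            max_het = 0.5,
                            min_maf = 0.02,
                            min_cov = 0.2,
                            r_prelim = 0.5) {
  if (is.null(names(species_r))) {
    if (length(species_r) != 1L) stop_arg("'species_r' must be named")
    names(species_r) <- "default"
  }
  vals <- c(unname(species_r), max_het, min_maf, min_cov, r_prelim)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop_arg("all filter thresholds must lie in [0, 1]")
  }
  if (any(species_r <= 0)) stop_arg("presence cutoffs must be positive")
  structure(
    list(species_r = species_r, max_het = max_het, min_maf = min_maf,
         min_cov = min_cov, r_prelim = r_prelim),
    class = "filter_settings"
  )
}

presence_cutoff_for <- function(settings, species) {
  r <- settings$species_r
  if (species %in% names(r)) unname(r[[species]]) else {
    if (!"default" %in% names(r)) {
      stop_arg("no presence cutoff for species '", species, "' and no default")
    }
    unname(r[["default"]])
  }
}

require_single_species <- function(g, what) {
  sp <- unique(g$info$species)
  if (length(sp) > 1L) {
    stop_arg(what, " operates on one species at a time; split the matrix ",
             "with split_by_species() first")
  }
  sp
}

#' Split a genotype matrix by species
#'
#' @param g a [geno_matrix].
#' @return a named list of single-species `geno_matrix` objects.
#' @export
split_by_species <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  sp <- unique(g$info$species)
  out <- lapply(sp, function(s) subset_geno(g, which(g$info$species == s)))
  names(out) <- sp
  out
}

# Fraction of individuals with a call, per locus.
locus_presence <- function(g) colMeans(!is.na(g$calls))

# Pooled minor allele frequency per locus from non-missing calls.
minor_allele_frequency <- function(g) {
  alt <- colSums(g$calls, na.rm = TRUE)
  nonmiss <- colSums(!is.na(g$calls))
  p_alt <- ifelse(nonmiss > 0L, alt / (2 * nonmiss), NA_real_)
  pmin(p_alt, 1 - p_alt)
}

#' Remove individuals with insufficient genotyping coverage
#'
#' Loci are first screened at the preliminary presence cutoff
#' (`r_prelim`); individuals genotyped at fewer than `min_cov` of the
#' screened loci are removed. This mirrors the usual practice of culling
#' failed libraries before locus-level filtering.
#'
#' @param g a single-species [geno_matrix].
#' @param settings a [filter_settings] object.
#' @return the filtered `geno_matrix`, with a `filter_log` attribute
#'   (data frame of rule, number removed, and removed ids).
#' @export
filter_individuals <- function(g, settings = filter_settings()) {
  stopifnot(inherits(g, "geno_matrix"), inherits(settings, "filter_settings"))
  require_single_species(g, "filter_individuals")
  screened <- locus_presence(g) >= settings$r_prelim
  if (!any(screened)) {
    # nothing survives the screen: assess coverage over all loci instead
    screened <- rep(TRUE, ncol(g$calls))
  }
  cov <- rowMeans(!is.na(g$calls[, screened, drop = FALSE]))
  drop <- cov < settings$min_cov
  if (all(drop)) stop_arg("all individuals removed by the coverage filter")
  out <- if (any(drop)) subset_geno(g, which(!drop)) else g
  attr(out, "filter_log") <- data.frame(
    rule = "individual_coverage",
    removed = sum(drop),
    ids = paste(g$info$id[drop], collapse = ","),
    stringsAsFactors = FALSE
  )
  out
}

#' Apply locus-level filters
#'
#' Keeps loci that (i) are called in at least the species' presence
#' fraction `r` of retained individuals, (ii) have observed heterozygosity
#' not exceeding `max_het` (strict `>` removes), and (iii) have minor
#' allele frequency at least `min_maf`. Locus order is preserved and the
#' number of loci failing each rule is recorded in the `filter_log`
#' attribute (a locus may fail several rules; it is counted under each).
#'
#' @inheritParams filter_individuals
#' @return the filtered `geno_matrix` with a `filter_log` attribute.
#' @export
filter_loci <- function(g, settings = filter_settings()) {
  stopifnot(inherits(g, "geno_matrix"), inherits(settings, "filter_settings"))
  sp <- require_single_species(g, "filter_loci")
  r <- presence_cutoff_for(settings, sp)
  pres <- locus_presence(g)
  het <- suppressWarnings(observed_heterozygosity(g))
  maf <- minor_allele_frequency(g)
  fail_pres <- pres < r
  fail_het <- !is.na(het) & het > settings$max_het
  fail_maf <- is.na(maf) | maf < settings$min_maf
  keep <- !(fail_pres | fail_het | fail_maf) & !is.na(het)
  if (!any(keep)) stop_arg("no loci survive the locus filters")
  out <- subset_geno(g, loci = which(keep))
  attr(out, "filter_log") <- data.frame(
    rule = c("presence", "max_het", "min_maf"),
    removed = c(sum(fail_pres), sum(fail_het), sum(fail_maf)),
    stringsAsFactors = FALSE
  )
  out
}

#' Run the full individual-then-locus filter pipeline
#'
#' Individuals are culled first (coverage screen), then locus filters are
#' applied to the retained individuals — the order used throughout the
#' package.
#'
#' @inheritParams filter_individuals
#' @return filtered `geno_matrix`; the `filter_log` attribute stacks the
#'   logs of both stages.
#' @export
filter_genotypes <- function(g, settings = filter_settings()) {
  g1 <- filter_individuals(g, settings)
  log1 <- attr(g1, "filter_log")
  g2 <- filter_loci(g1, settings)
  attr(g2, "filter_log") <- rbind(
    log1[, c("rule", "removed")],
    attr(g2, "filter_log")
  )
  g2
}
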