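---
title: "Inferring colony genetic structure from SNP panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring colony genetic structure from SNP panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antcolonykin)
```

`antcolonykin` estimates the genetic structure of social-insect colonies
— how many queens and males produced a sampled brood, how dominant the
most prolific of each is, and whether co-resident queens are kin — from
a few hundred biallelic SNPs genotyped in a handful of workers per
colony. This vignette is the package's own account of the models it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The data model

A `geno_matrix` holds unphased biallelic calls (0/1/2 alternate-allele
counts, `NA` missing), one row per individual, with species, tree
(colony) and caste labels. Trees are treated as colonies: the analyses
assume one colony per tree and free mixing of workers within it, and
they are blind to polydomy (one colony spanning several trees) except
insofar as reconstruction can be run on pooled trees.

Filtering reflects standard post-calling QC for RAD-derived SNP
matrices, in this order: individuals genotyped at fewer than `min_cov =
0.2` of loci (after pre-screening loci at presence `r_prelim = 0.5`)
are culled; then loci must be present in at least a per-species fraction
`r` of individuals (defaults configurable; heavily duplicated genomes
warrant higher `r`), have observed heterozygosity at most 0.5 (a strict
`>` removes; excess heterozygosity flags collapsed paralogs), and minor
allele frequency at least 0.02. Whether the original workflow culled
individuals before or after the locus filters is not something the
filters themselves record; the package fixes the order above and reports
per-rule removal counts so the reconciliation (dropped + kept = input)
can always be checked.

## Pairwise relatedness

Two moment estimators are implemented, both referenced to per-locus
allele frequencies $p_a$ estimated from the pooled non-missing calls of
the species (including the focal pair; exclusion is offered but off by
default, as the induced bias at $n \gtrsim 50$ individuals is far inside
the estimators' sampling noise). With reference individual carrying
alleles $a, b$ and proband $c, d$, and $S_{xy}$ the identity indicator:

* Lynch–Ritland: per-locus numerator
  $p_a(S_{bc}+S_{bd}) + p_b(S_{ac}+S_{ad}) - 4p_ap_b$, denominator
  $(1+S_{ab})(p_a+p_b) - 4p_ap_b$;
* Queller–Goodnight: numerator
  $\tfrac12(S_{ac}+S_{ad}+S_{bc}+S_{bd}) - p_a - p_b$, denominator
  $1 + S_{ab} - p_a - p_b$.

Loci are combined as a ratio of summed numerators over summed
denominators (equivalently, denominator-weighted), separately per
reference direction, and the two directions are averaged — making the
estimate exactly symmetric in the pair. Loci missing in either member
are skipped; a pair with no usable loci, or a degenerate denominator
sum, yields `NA` and is excluded from aggregation rather than zeroed.
These conventions are validated by the unbiasedness property: at 100
dyads × 500 loci, each estimator's mean is within 3 standard errors of
the pedigree value for all four relationship classes.

Aggregation respects the sampling design: pair values are averaged
within each tree (or within each unordered tree pair), and species-level
means and standard errors are taken over those per-tree (per-tree-pair)
means, never over raw pairs. Between-tree means referenced to sample
frequencies are slightly negative by construction (the average pair in
the sample is the frequency reference); the one-tailed *t* test against
zero therefore uses tree-pair means as its sampling unit, which is also
the unit exposed to the species comparisons.

### Choosing an estimator by simulation

`evaluate_estimators()` reruns the standard selection experiment: 100
dyads per relationship class — parent–offspring, full siblings, half
siblings, unrelated, with pedigree relatedness 0.5, 0.5, 0.25, 0 —
simulated as diplodiploid pairs at the panel's allele frequencies, each
estimator scored by the Pearson correlation between true and estimated
values pooled over all 4 × 100 dyads. Dyads are diplodiploid by default
even for haplodiploid study taxa, preserving the convention of the
original experiment; a haplodiploid mode (full sisters at 0.75) is
available for sensitivity analysis, and which mode *should* drive
estimator choice for haplodiploid workers is left to the user. Selection
is the argmax of the pooled correlation, ties broken by estimator name
with a warning.

## Sibship reconstruction

The centrepiece is a maximum-likelihood reconstruction of maternity and
paternity within one brood, the computation usually delegated to
pedigree software, implemented natively so that it can be enumerated,
audited and tested.

**State space.** A configuration is a nested partition: maternal
families (workers sharing a mother) sub-partitioned into paternal
families (workers additionally sharing a father). Polygamy for both
sexes means the partition is unconstrained. The count of nested
partitions grows as 1, 3, 12, 60, 358, 2471 for 1–6 workers.

**Likelihood.** Loci are independent, and parental genotypes are
independent across loci given the partition, so everything factorises
per locus. For one maternal family at one locus:

$$P(\text{obs}) = \sum_{G_m} \pi(G_m) \prod_{\text{paternal fam } j}
  \Big[ \sum_{a_f} p(a_f) \prod_{w \in j} P(x_w \mid G_m, a_f) \Big]$$

where $\pi(G_m)$ is the Hardy–Weinberg prior over the mother's diploid
genotype, $p(a_f)$ the population frequency of the father's allele
(haplodiploid mode; in diplodiploid mode the father's diploid genotype
is integrated and transmits one uniform allele), and the offspring's
true genotype is one uniform maternal allele plus the paternal
contribution. Full integration keeps the per-locus computation exact
and makes exhaustive enumeration feasible; nothing is sampled.

**Error kernel.** Observations pass through a two-class model: a true
heterozygote is observed as either homozygote with probability
$\varepsilon_d/2$ each (allelic dropout, default $10^{-4}$), then every
allele of the resulting call is flipped independently with probability
$\varepsilon_o$ (default $2.5\times10^{-3}$). Missing calls contribute
likelihood 1. The synthetic-data generator applies the same kernel, so
simulator and likelihood agree by construction. A worker genotype
impossible under every parental state with zero error rates drives the
configuration's log-likelihood to $-\infty$, which the search treats as
an ordinary (infinitely bad) value.

**Candidate queens.** A genotyped putative mother enters each maternal
family's likelihood as a two-component mixture: with prior $\pi$ her
(point-mass) genotype replaces the Hardy–Weinberg prior, with $1-\pi$
the mother stays latent. The conventional prior is $0.5/T$ for $T$ trees
in the data set. She is reported as the family's mother when her mixture
component carries posterior mass above one half. The candidate is
offered to every family independently; the constraint that she can be
only one family's mother is not enforced, which in practice is harmless
because a genotype that matches one family is overwhelmingly rejected by
the others.

**Search.** For broods of up to 7 workers the exact optimum is found by
enumerating, for every maternal block (subset of workers), the best
paternal sub-partition — block results are cached, so the work is
bounded by the number of (block, sub-partition) pairs rather than full
configurations — and then maximising over maternal partitions. Ties are
broken toward fewer mothers, then fewer fathers, with a $10^{-9}$
log-likelihood tolerance defining a tie. Larger broods use simulated
annealing over five proposal kinds (move a worker; split/merge paternal
families; split/merge maternal families) with geometric cooling from
$T_0 = 2$ to $0.02$ over `max(2000, 400 n)` iterations, a mandatory
seed, and family-level likelihood caching. The annealer is validated
against the exhaustive oracle: across seeded runs on broods of 4–6
workers it attains the exact maximum in at least 95% of runs and can
never exceed it.

**Maternal genotypes.** Each mother's per-locus genotype posterior falls
out of the same integration. The maximum-posterior genotype is emitted;
each of its two alleles is kept only if the posterior mass of genotypes
supporting that allele count reaches the masking threshold (default
0.90). Because the biallelic matrix cannot represent half-calls, a
genotype with either allele masked becomes missing — slightly more
conservative than masking single alleles.

## Colony metrics and queen kinship

From the most likely configuration: the Polygyny Index is the number of
maternal families, the Polyandry Index the number of paternal families
across the tree, and queen (male) dominance the largest maternal
(paternal) family's share of the sampled workers. Males per queen is
reported only for queens with at least `min_offspring = 4` sampled
offspring (a parameter, not a constant), since mate counts from two or
three offspring are mostly sampling noise. All indices count families
*among the sampled workers*: they are relative measures that
underestimate the colony's true diversity, and they are used only for
comparisons across groups sampled the same way.

Queen kinship reruns the reconstruction on the inferred maternal
genotypes themselves, as a single set of *diplodiploid* offspring of
unknown parents (queens have diploid fathers). Pairs in the same
maternal and paternal family are full siblings, same maternal family
only are half siblings, and "related" means either — the union is the
quantity tabulated within trees versus between trees and tested with
Fisher's exact test (two-sided, sum-of-small-probabilities convention,
as in the statistical environment this analysis is conventionally run
in). All between-tree queen pairs within a species form the comparison
stratum.

## The synthetic-data generator

`simulate_colonies()` is first-class, tested code, and its defaults are
the study conditions: queens drawn from Hardy–Weinberg proportions at
the panel frequencies; sister queens (probability `p_sister_queens` per
additional queen) generated as daughters of one auxiliary mother–father
pair per tree, matching the daughter-queens-stay-home interpretation of
related co-resident queens; haploid fathers; workers allocated to queens
by a symmetric Dirichlet over queen shares and uniformly to the queen's
males. The Dirichlet concentration defaults to 1, which puts the
dominant queen's expected share near 0.6 in two- and three-queen
colonies — the 0.54–0.68 range observed in polygynous field colonies —
without assuming a parametric skew model the field data do not provide.
Missingness is genotype-wise i.i.d., matching observed matrix
completeness in expectation but not in structure (real missingness is
locus- and library-correlated). Minor allele frequencies are uniform on
[0.1, 0.5] by default; empirical RAD panels have more low-frequency
loci and correspondingly lower per-locus information, so passing tests
on these panels demonstrate correctness of the machinery, not field
power. No read-level process is simulated.

All randomness flows from a single integer seed per call; identical
seeds give byte-identical outputs, and derived stage seeds keep the
pipeline deterministic end to end.

## Problem sizes used by the test suite

The suite validates properties at the smallest sizes at which they are
statistically decisive: estimator calibration at 100 dyads × 500 loci;
estimator evaluation at the 309-locus panel size with 100 dyads per
class; annealer-vs-oracle on broods of 4–6 workers across 51 seeded
runs; parameter recovery over 50 simulated trees (queens 1–3, males
1–3 per queen, 300 loci, default error rates, 15% missingness); and the
end-to-end pipeline property over 20 seeded runs of a three-species
design with 6 trees per species. The designed queen numbers there (1,
2, 4) are spaced so that the *sampled* number of distinct mothers — the
quantity a six-worker sample can expose — differs between species by
clearly more than its sampling noise; with adjacent queen numbers the
designed ordering is genuinely not identifiable from samples this size,
which is itself the central caveat of sample-based polygyny indices.

## Known limitations

* No inbreeding, no diploid males, no multi-generation pedigrees, no
  sibship-size priors; paternal half-sibs across maternal families are
  not representable in the nested partition.
* The candidate-queen mixture treats families independently (see above).
* Moment-estimator aggregation assumes the frequency reference is
  shared; mixing panels across species is refused rather than
  reconciled.
* The Wang, Li and Ritland comparator estimators are out of scope; the
  selection experiment runs on the two implemented estimators.
* Queen-kinship classification degrades with missingness twice over:
  matrix missingness first thins the workers' information, and the
  posterior masking then blanks further maternal loci. At 40%+
  missingness the between-tree sibship false-positive rate rises well
  above the ~2% seen on mostly complete matrices, so Fisher contrasts
  on heavily masked panels should be read with that inflation in mind.
* Real RAD data carry linked loci within tags and batch-structured
  missingness; both violate the independence assumptions here and
  should temper interpretation on empirical matrices.
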