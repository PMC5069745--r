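---
title: "Quantifying isotope assimilation from SIP metaproteomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying isotope assimilation from SIP metaproteomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoSIP)
```

## The measurement and the two metrics

In proteomic stable isotope probing (SIP), a microbial community is
incubated with an isotopically heavy substrate — here ¹³C-labeled dissolved
free amino acids (DFAAs) added to coastal seawater — and the proteins
synthesized during the incubation are measured by tandem mass spectrometry.
The database search is repeated over a grid of candidate ¹³C atom
enrichments (0–100% in 1% steps), so every peptide-spectrum match (PSM)
arrives annotated with the percent ¹³C that best explains its isotopic
envelope. Natural carbon is 1.109% ¹³C; a PSM assigned 0–1% is an
unlabeled, pre-existing or newly-made-from-unlabeled-carbon protein, while
anything clearly above natural abundance was synthesized at least partly
from the labeled substrate.

Two metrics summarize labeling for any subset of PSMs (a whole sample, one
taxon's proteins, one COG functional category within a taxon):

* **label frequency** — the percent of PSMs at or above the labeling
  threshold. It measures how *widespread* de novo synthesis from labeled
  carbon is, but cannot distinguish direct substrate uptake from
  cross-feeding or recycling of labeled biomass;
* **average enrichment** — the mean percent ¹³C among the *labeled* PSMs
  only. High values indicate direct assimilation of the substrate's carbon
  into new protein.

The labeling threshold defaults to 2%, inclusive. It sits just above
natural abundance so that grid values of 0 and 1% are never called
labeled; it is exposed as a parameter (`threshold`) because the
appropriate cutoff depends on the false-discovery behaviour of the
search engine on unlabeled controls, which is outside this package's
scope. Both metrics accept per-PSM weights; with the default unit weights
they are the per-spectrum proportions.

The labeled-enrichment *histogram* (`enrichment_histogram()`) bins labeled
PSMs into half-open 3%-wide bins [4, 7), …, [97, 100). The denominator is
the total labeled weight, including labeled mass in [2, 4) that falls
below the first bin, so bin proportions may sum to less than 1. Whether
the bins should instead be centred on multiples of 3 is not determined by
the convention we emulate; the chosen edges are recorded here and in the
output metadata. A value of exactly 100% (possible after grid clipping in
the generator) is likewise outside the last half-open bin; it still counts
in the denominator.

## Protein inference: two-peptide rule and balanced spectral counts

Protein-level outputs use the *two-peptide rule*: a protein is reported
only with at least one unique peptide (a peptide mapping to no other
protein) plus at least one additional peptide, shared or unique. PSMs
whose entire protein group fails the rule are flagged *orphaned*: they are
excluded from protein tables but **retained in sample-level labeling
metrics**, because per-sample PSM totals are counts over all spectra, not
only spectra of confidently identified proteins. This choice (rather than
dropping orphans everywhere) is deliberate and configurable downstream by
filtering on the `orphaned` flag.

Relative protein abundances use *balanced spectral counting*: each PSM
carries unit count, given entirely to its protein when the peptide has a
single identified candidate, and otherwise split across candidates
proportionally to their unique-peptide PSM counts (equally if no candidate
has unique evidence). The term names the balancing scheme rather than a
single published formula; proportional allocation is the standard variant
and degrades gracefully to an equal split. Conservation holds exactly:
summed balanced counts plus the unassigned (orphaned) bucket equal the PSM
count, and relative abundances sum to 1 per sample.

A protein group whose PSMs disagree on taxonomy gets `NA` taxonomy (the
conflict is counted in the sample metadata); its PSMs consequently drop
out of taxon-level tests rather than being assigned arbitrarily.

## The permutation null and significance calls

To ask whether a taxon assimilated the substrate differently from the
community, the observed label frequency and average enrichment of the
taxon's PSMs are compared with a null distribution built by resampling:
each of `n_perm` (default 1000) permutations draws PSMs uniformly without
replacement from the *whole sample's* spectra, stopping when the
cumulative weight first reaches the taxon's weight, and evaluates the
metric on the draw. With unit weights this is exact size matching; with
balanced weights it matches on balanced spectral counts (both phrasings
are in circulation for this design, so `weight_mode` supports either; the
default is unit weights). Matching on spectral counts is what makes
labeled-PSM proportions comparable between groups of very different
sampling depth.

COG-category tests within a taxon use the same machinery with the pool
restricted to the taxon's own spectra: the null hypothesis is that
enrichment within a taxon is independent of functional category. A PSM
carrying several COG letters is counted once per category (membership,
not partition).

Significance is two-sided and empirical: an observation is called `high`
or `low` when it is *at or beyond* the 2.5th/97.5th percentiles of the
null (inclusive comparisons implement "as extreme or more extreme";
percentiles use the linear-interpolation definition, `quantile` type 7).
Z-scores against the null mean and sd are reported for display on a
common scale. Design choices worth making explicit:

* draws of the average-enrichment null that contain no labeled PSM are
  undefined; they are recorded, excluded from the moments, and their count
  reported (`n_undefined`) rather than being imputed as zero;
* a null sd of zero yields an `NA` Z-score, never a fabricated value;
* no multiple-testing correction is applied by default, matching common
  practice for these exploratory per-sample panels; `adjust_p = TRUE`
  adds Benjamini–Hochberg-adjusted empirical p-values (computed with the
  add-one correction) for users who want it;
* groups below `min_weight` (default 13 PSM-equivalents) are skipped:
  below roughly a dozen spectra the permutation percentiles are too
  coarse for a two-sided 5% call to be meaningful;
* a group that *is* the whole pool has no null (the target weight must be
  strictly below the pool weight) and raises an error; the assembled
  pipeline logs and skips such cases;
* each group's permutations are seeded by hashing the (sample, grouping,
  group) context into a master seed, so results are reproducible
  bit-for-bit and adding or removing one group never shifts another
  group's draws.

## Cross-sample statistics

Replicate agreement of protein relative-abundance profiles uses **Lin's
concordance correlation coefficient**,
ρ_c = 2·cov(x, y) / (var(x) + var(y) + (mean(x) − mean(y))²) with
population (n-denominator) moments — the original estimator; unlike
Pearson's r it penalizes location and scale shifts, which matters when
comparing abundance profiles. It is computed pairwise over the union of
identified proteins with absent proteins at abundance zero. Time-point
contrasts of replicate metrics use the pooled-variance Student t-test
(two-tailed by default; Welch is deliberately not the default because the
replicate groups are tiny and the pooled test is the convention for this
design). Growth summaries are plain arithmetic on cell counts
(`fold_change`, `percent_increase`), with the exact identity
100·(fold − 1) = percent.

## The synthetic-data generator

`generate_experiment()` emulates the statistical structure this analysis
consumes, with the true parameters recorded for recovery tests. The
default design is eight samples: two locations ("MB" with three
replicates per time point, "OR" with one) at incubations of 15 h and
32 h, 20,000 PSMs per sample. The default community has eight marine
bacterioplankton taxa whose proportions and labeling probabilities give a
community label frequency near 2.4% at the first MB time point, roughly
doubling by the second; the OR community is labeled about four times more
heavily. Labeled enrichments are drawn from truncated-normal mixtures
snapped to the 1% search grid and clipped to [threshold, 100]: unimodal
with mode 35% (sd 8) at the first MB time point, and bimodal with modes
17% (sd 4) and 60% (sd 8) at the second time point and at OR — the
characteristic shift from a single moderately-labeled population to
coexisting moderately- and highly-labeled populations as incubation
lengthens. Unlabeled PSMs sit at natural abundance (1.109%) with ±0.5%
uniform jitter, always below the threshold; since the labeling metrics
only ask whether a PSM clears the threshold, any sub-threshold model is
observationally equivalent.

Protein and peptide structure: each taxon has a fixed repertoire of
proteins (default 60) with three unique peptides each, a configurable
fraction of shared peptides mapping to protein pairs within the taxon,
one COG letter (or none) per protein, and long-tailed (log-normal)
per-protein abundance propensities. The repertoire is generated once per
design seed and shared by all samples, so replicates overlap in protein
identifications and their abundance profiles agree — without this,
replicate concordance would be pure noise. Everything is deterministic
given the design seed: per-sample streams are derived by the same context
hashing as the permutation seeds, and written TSVs are byte-identical
across runs.

What the generator does *not* emulate — and hence what green tests on it
do not demonstrate about real data: search-engine errors and FDR
structure (enrichment values here are exact draws from the configured
mixtures, never misassigned), chimeric spectra, peptide detectability
biases, protein-inference ambiguity across taxa (shared peptides stay
within a taxon), compositional differences between locations (the OR
community differs from MB only in labeling parameters), and dynamic range
beyond the log-normal propensity model.

## Problem sizes and numerical choices

The bundled checks run the permutation machinery at the scales the method
is meant for: nulls of 1000 permutations per group; exhaustive-enumeration
cross-checks on pools of ≤ 8 PSMs (where all C(n, k) subsets can be listed)
against 10,000-permutation Monte-Carlo nulls; type-I calibration with 200
replicates of an exchangeable pool of 2000 PSMs at 8% labeling with test
groups of 300; power checks with 100 replicates of a two-taxon community
(2000 PSMs, one taxon at five times the background labeling probability);
and a full default experiment (8 × 20,000 PSMs) through the assembled
pipeline. Percentile estimates use linear interpolation (`quantile`
type 7); empirical p-values use the add-one correction so they are never
exactly zero; ties at the critical values are significant by the inclusive
comparison.

## Known limitations

* Taxonomy is taken from the PSM annotations as given; the package does
  not re-resolve conflicting protein-group taxonomy beyond voiding it.
* The permutation test conditions on the observed pool; it does not model
  between-replicate variance (that is what the replicate aggregation and
  t-tests are for).
* `min_weight` trades sensitivity for call stability and its default of 13
  is a pragmatic floor, not an estimate.
* With `n_perm` below 2/α the empirical percentiles cannot resolve a
  two-sided α call; the configuration warns rather than fails.
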