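---
title: "Fold-change normalisation analysis of three-condition proteomes"
author: "ProteoRenorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold-change normalisation analysis of three-condition proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoRenorm)
```

## The question the pipeline answers

A disease cell line (for instance a high-grade bladder carcinoma line) is
quantified by label-free LC-MS/MS alongside a normal reference line and a
treated derivative of the disease line (for instance after partial
reprogramming with pluripotency factors). For every protein the analysis asks
two categorical questions:

1. **Regulation** — is the protein's abundance in the disease line
   substantially different from the reference?
2. **Normalisation** — if it is, did the treatment return its abundance to
   the reference range, move it towards that range, or not?

Everything downstream — clustering, enrichment, biomarker triage — consumes
these two calls. The calculus is deliberately simple: label-free abundances
from pooled samples with technical (injection) replicates carry no
biological-replicate error structure, so fold-change thresholds with an
evidence filter, not inferential tests, define the verdicts.

## The regulation and normalisation calculus

Let $r_D = a_\text{disease}/a_\text{reference}$ and
$r_T = a_\text{treated}/a_\text{reference}$ be a protein's abundance ratios,
and $\mathrm{UP}$ its unique-peptide count. With thresholds
$(f_\text{high}, f_\text{low}) = (2, 0.5)$ and evidence tiers
$\mathrm{UP} \ge 2$ (standard) and $\mathrm{UP} \ge 5$ (strict):

* `insufficient_evidence` if $\mathrm{UP}$ is below the active tier minimum;
* `exclusive_disease` / `exclusive_reference` / `undetected` when one or
  both of the numerator and denominator are not detected — these proteins
  never receive a ratio (no pseudo-counts, no imputation) and are carried as
  categories of their own;
* `regulated_up` if $r_D > f_\text{high}$, `regulated_down` if
  $r_D < f_\text{low}$, else `unregulated`.

For a regulated protein with a treated ratio:

* `normalised` iff $f_\text{low} \le r_T \le f_\text{high}$;
* `trend` iff $r_T$ is still outside the band but
  $\operatorname{sign}(\log r_T) = \operatorname{sign}(\log r_D)$ and
  $|\log r_T| < |\log r_D|$ — the abundance kept its direction of
  dysregulation but moved strictly closer to the reference in log space;
* `not_normalised` otherwise, which covers both worsening and overshoot
  past the opposite cut-off.

The headline quantity is the percentage of regulated proteins (with an
applicable call) that are normalised. With 348 upregulated and 281
downregulated proteins of which 295 normalise, that fraction is
$295/629 = 46.9\%$, i.e. 47% after integer rounding.

### Boundary conventions

Two boundary decisions are easy to get silently wrong, so they are pinned by
tests:

* The fold-change cut-offs are **strict** inequalities: $r_D = 2.0$ exactly
  is *unregulated*. The unique-peptide minima are **inclusive**:
  $\mathrm{UP} = 5$ passes the strict tier.
* The normalised band is **inclusive** at both edges, and the biomarker
  triage bound ("at least 5-fold") is **inclusive**, deliberately unlike
  the regulation bound.

All log operations use base 2; reported fold changes are raw ratios.

## Preprocessing

`scaleTotalIntensity()` multiplies each sample by one scalar so all samples
share a total intensity. It is a stand-in for the staged amount
normalisation done at the bench (equal protein load, equal peptide load,
spectral-intensity normalisation), which cannot be replayed from an
exported table. It is **off by default** in `pipelineConfig()`: exported
abundance tables are usually already normalised, and total-intensity
scaling is only appropriate when most proteins are unchanged between
samples — in a comparison where a majority of the proteome is dysregulated
it would systematically shift every ratio. Enable it
(`scaling$enabled = TRUE`) for raw, unnormalised exports; the
scale-invariance property (any per-sample rescaling of the input leaves
every downstream ratio unchanged) is then guaranteed and tested.

`aggregateReplicates()` collapses technical injections to one abundance per
pool (mean by default, median by configuration). A protein counts as
detected in a pool if detected in at least `min_detected` injections
(default 1). Whether published ratio tables were computed from pooled or
replicate-averaged abundances is generally not stated by such studies; both
are reachable through the configuration.

## Clustering

Profiles are row z-scored (mean 0, sample standard deviation 1; constant
rows map to zeros rather than erroring, since a constant profile carries no
clustering signal) and clustered by unweighted average linkage (UPGMA) under
Euclidean or Pearson ($1 - r$) distance. Both metrics are first-class
because published heatmap methods and figure captions frequently disagree
about which was used; the default is Euclidean and the dendrogram panels of
the study's heatmaps use Pearson.

The linkage is implemented in the package rather than delegated to
`stats::hclust` for one reason: deterministic tie-breaking. When several
cluster pairs tie at the minimal mean distance, the pair with the lowest
(row, column) index in the current ordering is merged, so reruns and
platforms agree bit-for-bit. `hclust` with `method = "average"` serves as an
independent reference in the test suite (cophenetic distances agree to
1e-9 on 200 random instances with distinct distances); permutation
invariance of the tree shape is only guaranteed when all pairwise distances
are distinct, which is the documented caveat of any deterministic tie rule.

`firstMergePartner()` turns qualitative dendrogram statements ("the treated
line groups with the reference") into testable assertions.

## Enrichment and triage

`ora()` is a local hypergeometric over-representation test with
Benjamini-Hochberg correction, replacing web-service enrichment so results
are reproducible offline. Conventions:

* The universe defaults to **all quantified proteins at the active
  unique-peptide filter**, not the whole annotation space — the defensible
  background for a selection drawn from a quantified proteome. Gene-set
  members are intersected with the universe before the set size $K$ is
  computed.
* Sets overlapping the selection below `min_overlap` (default 2) are
  excluded *before* correction, and the number of tests $m$ counts only
  tested sets.
* One-sided over-representation only; depletion is out of scope.

`selectCandidates()` triages biomarker candidates: membership in at least
one configured GO cellular-component category (defaults in the
study-reproduction profile: extracellular matrix GO:0031012, plasma
membrane GO:0005886, cell junction GO:0030054), at least `biomarker_fold`
(default 5) fold dysregulation in either direction, and — switchable,
because the published selection is ambiguous on this point — the
`normalised` call. Identifier matching is on accession with gene-symbol
fallback. Cross-validation against expression atlases is left to the user:
the report carries blank concordance columns instead of scraping a
version-dependent web service.

## The synthetic-data generator

`simulateProteomes()` emulates the statistical structure of a three-line
label-free experiment so every stage is testable without the original
export:

* Reference abundances are log-normal (meanlog 13, sdlog 1.2 — a typical
  4–5 orders-of-magnitude LFQ dynamic range).
* A Bernoulli draw with probability `frac_dysregulated` (default 0.6,
  matching roughly two-thirds of a cancer-versus-normal proteome changing)
  plants dysregulation; planted $|\log_2 r_D|$ sits strictly beyond the
  cut-off by $\max(|N(1.0, 0.5)|, 0.1)$ log2 units so truth labels are
  well-defined under the strict-inequality boundary rule. Background
  proteins are drawn strictly inside the band.
* Among dysregulated proteins the normalised / trend / not-normalised
  outcomes are allocated at **exactly** the configured fractions (defaults
  0.47 / 0.05, the study's summary partition), randomly assigned. The
  planted fraction is the benchmark constant the recovery tests compare
  against; making it exact keeps binomial assignment noise out of a
  comparison whose tolerance (3 percentage points) is of the same order as
  that noise would be.
* Trend proteins are placed strictly between the band edge and the disease
  ratio (margin floor 0.3 log2 units, so the interval is never empty; a
  configuration that plants trends with no room beyond the cut-off is
  rejected). Not-normalised proteins sit at or beyond the disease ratio.
* Technical replicates multiply each abundance by independent log-normal
  noise with the configured CV (default 0.1, typical for replicate
  injections on one instrument); exclusive proteins (default 5%) have one
  condition blanked.
* Unique-peptide counts default to 5% below the standard tier and 20% below
  the strict tier, so both filters are exercised.

Truth labels are derived by applying the classification rules to the
noise-free planted ratios and the drawn unique-peptide counts. Truth is
therefore consistent with the thresholds by construction, and the
noise-free equivalence test (CV 0, no exclusives, every pipeline call equal
to its truth label) validates the *plumbing* — scaling, aggregation, ratio
computation — rather than restating the rules.

What the generator does **not** emulate: intensity-dependent
(missing-not-at-random) dropout, batch effects, peptide-level roll-up,
correlated noise across proteins, biological replication. Recovery results
therefore bound what the pipeline can do under well-behaved technical
noise; they do not certify performance on real data with structured
missingness.

## Problem sizes and numerical choices

The test suite runs the recovery benchmark at 2000 proteins, CV 0.1, 3
replicates over 100 seeds — the size at which the planted 47% is recovered
within 3 percentage points in well over 95% of runs — and checks oracle
equivalence on small instances (classification tables up to 50 rows,
clustering up to 10 leaves on 200 seeded instances, hypergeometric grids up
to a universe of 30 where exact binomial-coefficient sums are
representable). The hypergeometric tail is computed by `stats::phyper`
(log-factorial implementation, exact to better than 1e-12 against
enumeration); BH adjustment by `stats::p.adjust`. Result tables round-trip
through TSV at 12+ significant digits; parsing is locale-independent, and
comma-decimal input fails loudly rather than being silently misread.
Degenerate inputs error with typed conditions (`prn_*_error`) naming the
offending sample, column or line.

## Known limitations

* The calculus has no error model: a protein at fold change 2.05 and one at
  20 are equally "regulated". That mirrors the descriptive design of the
  studies this pipeline serves, and is why the strict evidence tier exists.
* Exclusive proteins are categorised but never enter the percentage
  denominators; a treatment that rescues detection (absent → present) is
  visible only in the categorical tallies.
* Published counts derived from vendor exports can differ by one or two
  proteins purely through boundary conventions; the boundary decisions
  above are the package's fixed, documented reading.
* With only three conditions, row z-scoring makes column profiles linearly
  dependent; condition-level grouping assertions are best made on raw or
  log abundances, as the grouping tests here do.
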