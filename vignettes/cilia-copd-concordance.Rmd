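---
title: "Cross-cohort concordance of cilia gene expression in COPD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort concordance of cilia gene expression in COPD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cilicopd)
```

## The analysis model

`cilicopd` asks a deliberately narrow question: among a curated set of cilia-
and ciliopathy-associated genes, which are deregulated in COPD consistently
across independent transcriptomic cohorts? The unit of evidence is not a
pooled effect size but a per-cohort significance call, combined by counting.
This "vote counting" design has a clear rationale for heterogeneous public
data: the cohorts mix microarray and RNA-seq platforms with incompatible
preprocessing, so effect sizes are not directly poolable, while a within-cohort
two-group comparison is always well defined. The cost is that the package
deliberately performs no meta-analytic pooling or heterogeneity modelling, and
none should be read into its outputs.

The workflow is staged:

1. **Curation.** Labelled source lists are merged into one geneset keyed by
   the normalized gene symbol (trimmed, uppercased). Symbols, not accessions,
   are the dedup key, because the contributing sources mix identifier types
   while downstream expression matrices are symbol-indexed. A gene is flagged
   ciliopathy-associated exactly when at least one of its sources is a
   ciliopathy-labelled source; the flag is therefore provenance-derived, not
   an independent annotation. Symbol aliases are *not* resolved: no aliasing
   procedure is part of the design, and a network lookup would make runs
   irreproducible. Conflicting accessions keep the first seen and warn.
2. **Per-cohort differential expression.** Each cohort is analysed
   independently, on the log2 scale, restricted to the geneset genes its
   platform measures. The test is a two-sample t test, Welch by default.
   The groups being compared (COPD vs non-COPD subjects) are independent and
   of unequal size, so a paired design is not possible; the Student (pooled)
   variant is available as an option. Multiple testing is corrected with the
   Benjamini–Hochberg step-up over exactly the tested genes of that cohort —
   not the whole transcriptome — because the analysis is geneset-restricted
   by construction.
3. **Concordance.** Significant-gene sets are combined per compartment (whole
   lung or SAEC, never mixed) into tier counts ("deregulated in ≥ k
   cohorts"), an exact Venn partition, and percentages of the compartment
   geneset. A cross-compartment rule (defaults: ≥ 2 lung and ≥ 1 SAEC
   cohorts) produces the candidate list, and a common-gene table (defaults:
   ≥ 3 lung or ≥ 2 SAEC) mirrors the published table layout.
4. **Single-cell annotation.** Candidates are annotated with the fraction of
   cells expressing the transcript, overall and per cell population, using
   pre-existing cluster labels; the package does no clustering of its own.

## Definitions that matter

- **"Deregulated"** means significant in that cohort — no fold-change cutoff
  and no cross-cohort direction requirement. The stricter direction-consistent
  variant can be obtained by filtering the per-cohort tables on `sign(log2fc)`
  before `tier_summary()`, but it is not the default: commonly deregulated
  genes can genuinely flip sign between platforms and tissues, and the tier
  analysis is about *any* perturbation of the cilia program.
- **Significance rule.** The default is raw `p < alpha` (`alpha = 0.05`) with
  BH q-values reported alongside; `sig_rule = "fdr_q"` switches the call to
  `q < alpha`. Both are exposed because "p < 0.05 with FDR correction applied"
  admits either reading; reporting q next to p keeps the choice auditable.
- **Two fold-change statistics.** `log2fc` is the difference of log2 group
  means (positive = up in COPD). `log10_ratio` is the log10 ratio of *linear*
  group means with non-COPD in the numerator — the dot-plot convention — so
  the two run in opposite directions. Because one averages logs and the other
  averages linear values, their magnitudes are not interchangeable, and for
  near-zero differences Jensen-gap effects can even make the signs agree;
  they reliably oppose only where group separation is substantial.
- **Tier percentages** use half-up rounding (`percent_of_geneset()`), with 0
  decimals for lung and 1 for SAEC by default, matching the printed formats
  of the source analyses; both are overridable.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `alpha` | 0.05 | per-cohort significance threshold |
| `sig_rule` | `raw_p` | `raw_p` or `fdr_q` |
| `variant` | `welch` | t-test variant |
| `pseudocount` | 1 | added before log2 of linear data |
| cross thresholds | 2 lung, 1 SAEC | tier minima for cross-compartment hits |
| common-table thresholds | 3 lung, 2 SAEC | inclusion minima for the common-gene table |
| `min_value` (single cell) | 0 | a cell "expresses" a gene when value > this |
| `dominance_ratio` | 1.5 | principal-population rule, see below |

Scale handling: when a manifest does not state a cohort's scale, a matrix
maximum above 50 is treated as linear (log2 data from expression platforms
rarely exceed ~20), and `ensure_log2()` applies `log2(x + 1)`. The heuristic
is always overridable per cohort, and the linear copy is retained so the
log10-ratio statistic uses exact linear means. Missing cells are an error,
not imputed; duplicate gene rows (multiple probes per symbol) collapse to the
highest-mean row, the common microarray convention.

## Single-cell binning and the principal population

The fraction-expressing bins are `+` below 25%, `++` from 25% to 50%
inclusive, `+++` above 50%: the intermediate interval is printed as a closed
range in the published footnote, so both boundaries belong to `++`. The
principal-population rule is this package's own construction (the source
analyses do not state one): the top population is called principal when its
fraction is at least `dominance_ratio` (default 1.5) times the size-weighted
pooled fraction of the remaining populations, otherwise expression is called
broad (`All`). The default ratio was chosen so that a population expressing a
gene half again as often as everything else pooled counts as dominant; it is
a reporting heuristic, not an inferential statement, and published
principal-population labels should not be expected to reproduce under it.

## The synthetic study generator

`simulate_study()` emulates the seven-cohort design so every stage is
exercised on data of realistic shape: 4 lung cohorts totalling 238 non-COPD
and 391 COPD subjects (split ~evenly, (60, 98) per cohort), 3 SAEC cohorts of
(100, 39) totalling 300/117, and a 495-gene universe in which 447 genes form
the cilia list and 189 the ciliopathy set, overlapping in 141 by
inclusion–exclusion. Within the synthetic fixture the UniProt-style
ciliopathy list carries 171 of the 189 and the 100,000-Genomes-style list
completes the remainder (their real per-source composition is not public, so
the fixture fixes one deterministic realization and labels both as
ciliopathy sources).

The expression model: per gene a log2 baseline `mu_g ~ N(7, 2)` and noise
s.d. `sigma_g ~ U(0.3, 1.0)` — spanning tightly and loosely measured
transcripts on log2 microarray-like scales; 25% of genes carry a planted
effect of `delta = 0.4` log2 units with random sign, active in any given
cohort with concordance probability `rho = 0.5`; each gene drops out of each
cohort with probability 0.1, emulating platform coverage. These defaults
were chosen once as a realistic mid-power regime — per-cohort detection of an
active gene is likely but not certain, so tier counts exercise the whole
range — and give per-cohort significant fractions in the tens of percent of
the geneset, comparable to the motivating analyses. A single seed drives
gene-level draws (shared by both compartments, so planted genes and
directions agree across tissues) and compartment-offset streams drive
cohort-level draws; identical seeds give bit-identical output.

What the generator does *not* emulate: probe-level effects, batch structure,
library-size variation, covariate structure (age, sex, smoking), or
correlated genes. Passing recovery tests on this generator therefore
demonstrates the correctness of the pipeline's bookkeeping and statistics
under an idealized independence model — not robustness to the artifacts of
real public cohorts.

## Numerical and degenerate-input conventions

- Welch df by Welch–Satterthwaite; two constant equal groups give `t = 0, p =
  1`, constant unequal groups give `p = 0` with a warning.
- BH q-values are clamped to `max(q, p)` to keep the `q >= p` invariant exact
  under floating-point rounding of `p·m/j`.
- All emitted gene and dataset lists are sorted with locale-independent radix
  order; Venn regions are keyed by "&"-joined sorted dataset-id tuples.
- Report JSON serializes floats at 6 significant digits, making reruns
  byte-identical.
- Percent rounding is half-up (`floor(x·10^d + 0.5)/10^d`), not banker's.

## Verification strategy and problem sizes

The test suite checks every statistic against an independent oracle:
`stats::t.test` and `stats::p.adjust` for the t and BH implementations (which
are written from first principles, those library routines being reserved for
cross-checking), explicit brute-force enumeration for tier/Venn counts,
symbol-union counting for the merge, and binomial bounds for single-cell
fractions. Calibration tests use 200 genes × 50 null cohorts for the type-I
error (within 3 Monte-Carlo standard errors of alpha), 20 seeds for the
binomial tier model, and a 120-gene, 7-cohort high-power configuration
(`delta = 2, sigma = 0.25`, 30/30 per group, `alpha = 1e-6`) where
significance provably coincides with planted activity intersected with
platform detection, making tier recovery exact. These sizes keep the full
suite under half a minute on one core while leaving each check's standard
error far below its tolerance.

## Known limitations

- Vote counting ignores effect-size information and treats a cohort of 36 and
  a cohort of 580 as equal voters.
- Per-cohort percentages use that cohort's tested-gene denominator, which
  differs across platforms; compartment-level percentages use the compartment
  geneset.
- The ciliopathy flag inherits any curation errors of the source lists; no
  alias resolution is attempted.
- Clinical covariates are out of scope: the public cohorts lack harmonized
  clinical data, so no severity or smoking adjustment is offered.
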