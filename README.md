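# cilicopd

Multi-cohort concordance analysis of cilia and ciliopathy gene expression in
chronic obstructive pulmonary disease (COPD).

Altered mucociliary clearance is a hallmark of COPD, driven by structural and
functional abnormalities of airway cilia. `cilicopd` implements a geneset-first
comparative transcriptomics workflow for asking whether cilia-associated and
ciliopathy-associated genes are consistently deregulated in COPD across
independent public cohorts, separately in two tissue compartments: whole lung
tissue and bronchoscopically sampled small airway epithelial cells (SAEC). It
is written for respiratory transcriptomics researchers who have per-cohort
expression matrices (GEO-style, already preprocessed) and a curated gene list,
and want reproducible cross-cohort concordance calls rather than single-cohort
hit lists.

## What it computes

- **Geneset curation** — merges labelled gene lists from up to seven
  annotation sources (UniProtKB cilia and ciliopathy queries, 100,000 Genomes
  panels, CentrosomeDB, CilDB, SysCilia, CiliaCarta) into one deduplicated
  geneset keyed by normalized symbol, with per-gene source provenance and a
  source-derived ciliopathy flag.
- **Per-dataset differential expression** — for each cohort and each geneset
  gene measured on its platform, a two-sample t test (Welch by default) on
  log2 data of COPD vs non-COPD:

  ```
  log2FC(g) = mean(log2 x_COPD) − mean(log2 x_nonCOPD)
  t(g)      = log2FC(g) / sqrt(s²_COPD/n_COPD + s²_nonCOPD/n_nonCOPD)
  ```

  with Benjamini–Hochberg step-up q-values, `q_(i) = min_{j≥i} p_(j)·m/j`,
  computed over exactly the tested geneset genes. The dot-plot statistic
  `log10( mean_linear(nonCOPD) / mean_linear(COPD) )` is reported alongside
  (note its opposite orientation).
- **Concordance tiers** — per compartment: the number of genes significant in
  ≥ k datasets, the full Venn partition over datasets, and tier percentages of
  the compartment geneset; cross-compartment hits (significant in ≥ 2 lung
  and ≥ 1 SAEC cohorts) and ciliopathy-subset summaries; a common-gene table
  mirroring the published layout, with a "fully concordant" flag for genes
  significant in every cohort of their compartment.
- **Single-cell annotation** — fraction of cells expressing each candidate
  gene, overall and per cell population, binned `+` (< 25%), `++` (25–50%),
  `+++` (> 50%), plus a dominance-based principal-population call.
- **Synthetic study generator** — a seeded simulator of the seven-cohort
  design (4 lung cohorts, 238 non-COPD / 391 COPD; 3 SAEC cohorts, 300
  non-COPD / 117 COPD; 495-gene geneset with 189 ciliopathy-flagged genes)
  with planted, partially concordant effects and platform dropout, so the
  entire pipeline is testable end to end without any downloads.

## Worked example

Simulate a full study, write it to disk as pipeline-ready TSVs, and run the
curation → validation → DE → concordance pipeline:

```r
library(cilicopd)

study <- simulate_study(sim_config(seed = 7))
study$geneset
#> gene_set 'cilia geneset': 495 genes (189 ciliopathy-flagged)

de <- run_diffexp(study$lung$datasets[[1]], study$geneset)
de
#> dataset_de_result LUNG1 (lung): 71/437 genes significant (p < 0.05)

manifest <- write_study(study, "study7")
report <- run_pipeline(manifest, out_dir = "out7")
unlist(report$compartments$lung$tier_counts)
#>   1   2   3   4
#> 173  66  23   5
report$cross_compartment$n_hits
#> [1] 51
```

Reading the output: of the 437 geneset genes detected on the first simulated
lung platform, 71 are deregulated in COPD at p < 0.05; across the four lung
cohorts 173 genes are deregulated in at least one, 66 in at least two, 23 in
at least three and 5 in all four; 51 genes meet the cross-compartment rule
(≥ 2 lung and ≥ 1 SAEC cohorts). `out7/` then holds the merged geneset,
per-dataset DE tables, tier and Venn summaries, the cross-compartment and
common-gene tables, and a machine-readable `report.json` whose reruns are
byte-identical.

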