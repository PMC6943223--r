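# difnet

Differential expression and differential co-expression network analysis
for two-condition replicated RNA-seq, with a synthetic-data generator
that makes every stage verifiable offline.

## The problem

Given a gene × sample matrix of read counts from a two-condition
experiment (e.g. control vs overexpression, n = 3 each), a common
systems-biology workflow asks four questions in sequence:

1. **Which genes respond?** A negative-binomial screen: counts are
   modelled as NB with variance μ + αμ², samples are normalized by
   median-of-ratios size factors, and each gene's condition sums are
   compared with an exact conditional test. Genes are called at the
   dual threshold |log₂FC| ≥ 0.585 with BH FDR ≤ 0.05.
2. **What are they enriched for?** One-sided Fisher (hypergeometric
   upper-tail) enrichment of the up- and downregulated lists against
   GO-like collections (significant at P ≤ 0.01) and pathway-like
   collections (FDR ≤ 0.05), over the tested genes as background.
3. **How do they interact?** Induced subgraphs of KEGG-style typed
   relation tables (act/inh/bin/com/exp/dissociation) on the DEGs and
   on the significant pathways, ranked by degree centrality.
4. **Whose wiring changes?** Per-condition Pearson co-expression
   networks over the DEGs (edge iff |r| ≥ 0.9 and correlation-test
   p ≤ 0.05, on one shared node set), per-gene degree and k-core in
   each network, and **core regulatory factors** called by
   DifDegree = |degree_A − degree_B| ≥ 12 and
   DifKcore = |kcore_A − kcore_B| ≥ 8.

Because real runs of this workflow hinge on annotation snapshots and
unavailable raw data, difnet ships a generator that plants DEGs,
enriched sets and condition-specific co-expression modules with known
ground truth, so calibration and recovery are measurable.

## Worked example

The `analysis/` directory is a numbered workflow over the package;
run from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_enrichment.R
Rscript analysis/04_interaction_networks.R
Rscript analysis/05_coexpression.R
Rscript analysis/06_recovery_benchmarks.R
```

Stage 1 simulates 2000 genes × 6 samples with 200 planted DEGs at
|log₂FC| = 2 and two 15-gene co-expression modules, writing inputs and
truth under `results/data/`. The later stages print, for that dataset:

```
Tested 2000 genes; 104 up and 79 down at |log2FC| >= 0.585, FDR <= 0.05
Sensitivity vs planted truth: 0.825; realized FDP: 0.098
go_like      up  :  2 significant sets; top hit set001 (p = 9.20e-05)
Gene network: 183 nodes, 28 typed edges
Network A: 182 nodes, 825 connections (393 positive, 432 negative)
Network B: 182 nodes, 822 connections (397 positive, 425 negative)
Core regulatory factors (DifDegree >= 12 & DifKcore >= 8): 1
```

Reading those numbers: the screen recovers ~83% of planted DEGs; its
realized false-discovery proportion on this run (0.098) exceeds the
nominal 0.05 because the planted co-expression modules make gene means
co-fluctuate across only three replicates — a real small-n failure mode
the methods vignette discusses (the module-free benchmark in stage 6
measures FDP ≈ 0.02). The planted enriched sets (`set001`–`set003`)
top the Fisher ranking, and the two co-expression networks report their
positive/negative edge split, whose sum always equals the connection
total.

The same pipeline runs as one call — `run_pipeline(pipeline_config())`
— which also writes a provenance record and, in synthetic mode, a
truth-scored recovery scorecard; `mode = "user-data"` ingests your own
counts TSV, condition map, GMT collections and relation tables with the
identical stages and thresholds.

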