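# oscarrest

Cell-cycle transcriptional oscillations under checkpoint and CDK arrest.

## The problem

In budding yeast, a network of serially activating transcription factors
(SBF/MBF at G1/S, SFF at G2/M, Swi5/Ace2 at M/G1) drives genome-wide periodic
transcription. When the cell cycle is arrested — by depleting the APC
activator Cdc20 (persistent mitotic CDK activity, "CDK on"), by deleting
cyclins ("CDK off"), or by triggering the DNA-replication or spindle-assembly
checkpoints — individual regulons halt with very different behaviors: some
transcripts keep oscillating, some stay persistently high, some are repressed
after one pulse, some are never induced. Analyzing this requires calling
periodic genes reliably from short, noisy, desynchronizing bulk time courses
and then classifying each gene's arrest behavior.

`oscarrest` provides, as a tested pipeline:

* **synthgen** — a generative model of elutriation-synchronized populations:
  each gene is a von Mises-shaped single-cell pulse
  `b + a·exp(κ(cos2π(θ−φ) − 1))` averaged over a wrapped-normal phase
  distribution whose sd grows as `σ(t) = √(σ₀² + (c·t/p)²)` (progressive
  desynchronization damps bulk amplitude), with per-regulon arrest programs,
  multiplicative lognormal noise, and matching budding-index curves.
* **periodicity** — three independent rhythmicity statistics (Lomb–Scargle
  maximum power, maximum lagged autocorrelation, maximum Kendall rank
  correlation against a cosine/damped-cosine template bank), seeded
  permutation p-values `(1 + #[perm ≥ obs])/(n_perm + 1)`, per-algorithm
  Benjamini–Hochberg FDR, and a high-confidence periodic set defined as the
  **intersection** of the three significant sets.
* **arrest_dynamics** — log2 fold change relative to each gene's mean,
  temporal alignment at the 50%-budded anchor (t50), per-gene behavior
  classification (`oscillating / damped / persistent_high / repressed /
  low_flat`), persistence overlaps between condition consensus sets,
  replicate concordance (r²), and period comparison across conditions.
* **enrichment** — one-sided hypergeometric overrepresentation of TF target
  sets within behavior clusters, BH-corrected jointly.
* **io_cli** — TSV/GMT/config readers and writers, deterministic report
  tables, and a CLI (`simulate`, `detect`, `classify`, `enrich`, `report`,
  `all`).

## Worked example

```r
library(oscarrest)
models <- scenario_gene_models(n_genes = 200, seed = 1)
sync   <- synchrony_model()            # 100-min cycle, sigma0 = 0.05, c = 0.08
wt     <- simulate_experiment(models, sync, experiment_design("WT", seed = 11))
cdk_on <- simulate_experiment(models, sync, experiment_design("CDK_ON", seed = 12))

res_wt <- call_periodic(wt, n_perm = 199, seed = 2)
res_on <- call_periodic(cdk_on, n_perm = 199, seed = 2)
persistence_overlap(res_wt$consensus$gene_ids, res_on$consensus$gene_ids)

shared <- intersect(res_wt$consensus$gene_ids, res_on$consensus$gene_ids)
compare_periods(estimate_periods(wt, shared), estimate_periods(cdk_on, shared))

lab <- classify_matrix(cdk_on, wt_period = 100, n_perm = 199, seed = 3)
table(lab$label)
t50_budded(simulate_budding(sync, experiment_design("CDK_ON", seed = 12)))
```

Output (exactly as printed by the code above):

```
consensus_set: 140 genes (alpha = 0.05; per algorithm: periodogram=143, autocorr=142, template_rank=143)
overlap: 34 / 140 of reference shared (24.3%); comparison set 34
median period WT 99.9 min, CDK-on 99.9 min, median |diff| 0.8 min

         damped        low_flat     oscillating persistent_high       repressed
              3              78              42              40              37
CDK-on t50 (50% budded): 28.0 min
```

Reading: 140 of the 200 simulated genes (the 140 with a periodic program)
form the WT consensus periodic set; only 24.3% of them remain periodic under
Cdc20-depletion arrest — the SBF-like regulon is repressed after its first
pulse, the SFF-like regulon plateaus high, Swi5/Ace2-like genes are never
induced, and the MBF-like branch keeps oscillating with a period essentially
identical to WT (0.8 min median difference). The population is 50% budded at
28 min, the anchor used to align conditions.

## Command line

```sh
Rscript inst/cli/oscarrest all --out-dir demo_out --n-genes 100 --seed 7
```

writes simulated matrices, budding curves, periodicity calls, the consensus
set, behavior labels, overlap/period tables, enrichment results, the
peak-time row ordering, normalized matrices, heat maps, and a provenance log.

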