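# seednet

Seed-gene co-expression network discovery and upstream-regulator
prioritization for bulk and single-cell transcriptomics.

Many genes of interest — the motivating case is *ACBP/DBI*, a tissue hormone
involved in lipo-anabolism and autophagy control — are embedded in a
co-regulated transcriptional module whose membership, cross-species
conservation and upstream control are the actual biological question.
`seednet` turns that question into a reproducible pipeline for analysts
working with many expression cohorts at once (pan-cancer panels,
tissue atlases, perturbation compendia):

1. **Network discovery.** In each condition *c*, samples are split at the
   median of the seed gene *s* (strict upper half = High). A gene *g* joins
   the per-condition hit list when, on log2(x+1) values,

   - log2FC(g) = mean(High) − mean(Low) > 0 with Welch-test *P* < 0.05, and
   - Spearman ρ(g, s) > 0.3 with *P* < 0.05,

   and joins the network when it passes in ≥ 20 of the screened conditions
   (all four thresholds are parameters). Validation in independent datasets
   re-tests ρ > 0, *P* < 0.05 per member; annotation summaries report
   mitochondrial / metabolism fractions with hypergeometric enrichment.
2. **Regulator consensus.** Transcription factors predicted by multiple
   databases are kept by the two-branch rule
   (h ≥ 3 ∧ m ≥ 3) ∨ (h ≥ 4 ∧ m ≥ 2) over the human (h) and mouse (m)
   panels; miRNAs by a cross-species Venn plus a negative-correlation screen
   (ρ < 0, *P* < 0.01).
3. **Net-effect scoring.** Each regulator knockdown/knockout dataset yields
   per-gene effects (log2FC, test chosen per gene among Student / Welch /
   Wilcoxon by a deterministic rule). A dataset is *coherent* when the seed
   responds significantly, a strict sign-majority of network genes agrees,
   and a one-sample Wilcoxon on the network effects confirms the joint
   response; only then is the total-network score (mean effect) reported
   and the regulator called an activator or repressor.
4. **Conservation tools.** Cross-species organ/cell-type Spearman profiles,
   single-cell dot-plot summaries (mean ln(CPTT+1), % expressing), and
   immunoblot densitometry (Ponceau + LC2 normalization) with BH-corrected
   sex-dimorphism tests.

A seeded synthetic-data generator plants a latent-factor module, regulator
signs and cross-species correlations, so every stage is benchmarked as a
recovery problem without downloading TCGA/GTEx/GEO/CELLxGENE.

## Worked example

```r
library(seednet)

cfg    <- sim_config(seed = 42, n_conditions = 12, n_samples_per_condition = 50,
                     n_genes = 400, module_size = 20)
panel  <- simulate_panel(cfg)
screens <- lapply(panel$matrices, condition_screen,
                  seed_gene = panel$truth$seed_gene)
net    <- build_network(screens, min_conditions = 8)
print(net)
#> co-expression network of g0001: 7 members (support >= 8 of 12 conditions)
#>   gene_id support
#> 1   g0005      11
#> 2   g0018      11
#> 3   g0011      10
#> ...
```

Seven of the 19 planted partners clear 8 of 12 conditions at these sizes
(the strongest-loading ones; precision is 1). Validating in an independent
panel that shares the module:

```r
val <- validate_network(net, simulate_panel(cfg, truth = panel$truth,
                                            n_conditions = 1,
                                            seed_offset = 99)$matrices[[1]])
sum(val$replicated)   # 6 of 7 members replicate (rho > 0, p < 0.05)
```

Annotating the published 44-gene DBI network fixture (34 printed symbols,
10 synthetic placeholders) against a 20,000-gene background:

```r
ann <- read.delim(system.file("extdata", "dbi_network_annotation.tsv",
                              package = "seednet"), comment.char = "#")
annotate_network(network_from_genes("DBI", ann$gene_id), ann,
                 c(ann$gene_id, sprintf("BG%05d", 1:19956)))
#> network of 44 genes: 22 mitochondrial (50%, enrichment p = 5.7e-62),
#>                      29 metabolism (66%, enrichment p = 3.86e-83)
```

Half the network is mitochondrial and two thirds metabolism-annotated —
massive overrepresentation against the background. Scoring the simulated
perturbation compendium and aggregating:

```r
pred  <- simulate_prediction_tables(cfg, panel$truth)
perts <- simulate_perturbations(cfg, pred$truth)
nets  <- lapply(perts, function(ds)
  network_net_effect(perturbation_effects(ds, pred$truth$module_gene_ids),
                     pred$truth$seed_gene, pred$truth$module_gene_ids))
aggregate_regulators(nets)$calls
#> all 8 planted regulators called with their planted sign; all 4 nulls NS
```

`run_pipeline(pipeline_config(...))` chains the whole thing and writes every
table plus a JSON manifest (config echo, row counts, md5 hashes, recovery
block); reruns with the same seed are byte-identical.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package's default synthetic pipeline end to end
(generator → screens → network → validation → consensus → perturbation
scoring) and writes the JSON report to `--out`.

## Design notes

The methods vignette (`vignettes/seednet-methods.Rmd`) documents the model
behind the generator, the reasoning for every statistical choice (Welch in
the screen, the median tie rule, the network-side coherence gate, raw vs
adjusted p), and what the synthetic benchmarks do and do not establish.
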