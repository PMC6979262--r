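# rdrbench

Benchmarking two-group differential-expression (DE) analysis of single-cell
RNA-seq matrices by **rediscovery rate**: how many of the top-ranked DE
isoforms found in one sample of cells are found again, at p < 0.05, in an
independent sample of cells from the same populations?

Single-cell expression matrices are noisy, zero-inflated and heavy-tailed,
and DE methods built for bulk RNA-seq can behave very differently on them —
especially on lowly expressed genes. `rdrbench` is for methodologists and
analysts who want to measure that behaviour under controlled conditions: it
bundles a generative count simulator with known ground truth, seven natively
implemented DE tests spanning the main model families, and an evaluation
engine for type-I error, rediscovery rates and ROC/AUC, everything
stratified by expression level and reproducible from a single seed.

## The model and the metrics

**Simulator.** Counts are drawn from a four-parameter beta-Poisson
distribution,

```
BP4(x | α, β, λ1, λ2) = λ2 · Poisson(x | λ1 · Beta(α, β))
```

whose closed-form moments are, with φ1 = α/(α+β) and φ2 = β/(α(α+β+1)),

```
μ = E(X) = λ1 λ2 φ1,        Var(X) = μ λ2 + μ² φ2 .
```

The Beta-distributed rate captures transcriptional bursting; zero inflation
and overdispersion fall out of the mixture instead of being bolted on.
Per-isoform parameters are drawn from configurable priors, a chosen fraction
of isoforms (default 5%) receives a ±1 log2 fold change on λ1 in the
treated group (direction random with equal probability), per-cell library
sizes are uniform on 1–3 million, and all-zero rows are filtered. A
method-of-moments fitter (`fit_bp4`) lets you replace the priors with a
population fitted to your own matrix.

**Tests.** `ttest` (Welch on log2(CPM+1)), `wilcoxon` (rank-sum,
exact/tie-corrected), `limmatrend` (empirical-Bayes moderated t with a
mean-variance trend), `nbwald` (negative-binomial Wald with trended
dispersion shrinkage), `zinb` (zero-inflated NB likelihood-ratio test),
`hurdle` (two-part detection + expression LRT), `bp4` (beta-Poisson GLM
z-test). All share one interface and documented degenerate rules.

**Metrics.** For disjoint, equally sized training and validation cell sets:

- `FPR` — fraction of isoforms with p < α on null data;
- `RDR` — fraction of the training set's top-k isoforms (k = 5%, 10%, 20%
  or 100%, ranked by p) with validation p < α; under a global null a
  calibrated test gives RDR ≈ α;
- `TrueRDR` — rediscoveries that are also truly DE by simulation truth;
- `RDR_ratio` — TrueRDR / RDR, a specificity summary;
- `AUC` — tie-corrected Mann–Whitney AUC of −log10 p against the truth.

All metrics are reported separately for highly and lowly expressed isoforms
(normalised expression > 1 in strictly more than 25% of cells, or not).

## Worked example

```r
library(rdrbench)
sim <- simulate_dataset(sim_config(n_isoforms = 2000, n_cells_per_group = 40,
                                   seed = 1))
print(sim$matrix)
#> count_matrix: 2000 isoforms x 80 cells
#> groups: control=40, treated=40
#> library sizes: [ 1034313 , 2969679 ]

res <- wilcoxon_test(sim$matrix)
head(res[order(res$pvalue), c("isoform_id", "statistic", "effect", "pvalue")], 5)
#>      isoform_id statistic     effect       pvalue
#> 472    iso00472    1599.5 -1.0754645 1.452754e-14
#> 539    iso00539      87.0  0.9890875 6.798515e-12
#> 1586   iso01586      90.5  1.0867398 8.824703e-12
#> 951    iso00951      95.5  1.0501747 1.222388e-11
#> 527    iso00527      97.0  1.0761504 1.374949e-11
```

The top hits carry effects near ±1 on the log2 scale — the injected fold
change. A small benchmark sweep, with two methods and five
simulate/split replicates, summarised for the top 5% of highly expressed
isoforms:

```r
cfg <- benchmark_config(methods = c("ttest", "wilcoxon"),
                        n_replicates = 5,
                        sim = sim_config(n_isoforms = 2000,
                                         n_cells_per_group = 40, seed = 1),
                        n_per_set_per_group = 20, seed = 1)
out <- run_benchmark(cfg)
s <- summarize_benchmark(out$table)
subset(s, stratum == "high" & top_fraction == 0.05 & metric %in% c("RDR", "TrueRDR"))
#>      method stratum top_fraction  metric n       q25    median       q75
#> 23    ttest    high         0.05     RDR 5 0.4000000 0.4105263 0.4468085
#> 25    ttest    high         0.05 TrueRDR 5 0.3789474 0.3936170 0.4000000
#> 83 wilcoxon    high         0.05     RDR 5 0.5000000 0.5052632 0.5263158
#> 85 wilcoxon    high         0.05 TrueRDR 5 0.4680851 0.4947368 0.5157895
```

Roughly half of the rank test's top-5% training discoveries validate at 20
cells per group, and nearly all validated discoveries are truly DE
(TrueRDR close to RDR).

## Command line

```sh
Rscript inst/cli/rdrbench.R simulate  --config cfg.yaml --out-dir out/
Rscript inst/cli/rdrbench.R test      --method wilcoxon --matrix out/matrix.tsv \
                                      --labels out/labels.tsv --out res.tsv
Rscript inst/cli/rdrbench.R benchmark --config cfg.yaml --out-dir out/
Rscript inst/cli/rdrbench.R report    --table out/eval_table.tsv --out summary.tsv
```

Every subcommand writes a JSON manifest (config, seed, package version,
timings, outputs), so each result file is regenerable from its manifest.

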