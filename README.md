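# sidefxnet

Which properties of a drug's protein targets predict how many side effects
the drug causes? `sidefxnet` implements a network-pharmacology analysis
battery around that question, for computational biologists studying drug
safety from interactome data. It relates per-drug side-effect counts to:

* **target essentiality** — how many targets are encoded by essential
  genes;
* **target centrality** — degree and betweenness in a quality-filtered
  protein–protein interactome, including *bottleneck* targets (betweenness
  in the top 20%, with a 5/10/20/40% sensitivity sweep);
* **interface sharing** — on a structurally resolved sub-network, the mean
  Jaccard similarity of the interacting-domain sets a target uses for its
  partners (single-interface targets score 1: one bound drug can disrupt
  all of their interactions);
* **target-to-disease distance** — the average shortest distance between a
  drug's targets and its indicated-disease genes, splitting drugs into
  *near* (< 3) and *far* (≥ 3) classes.

## The model

Side-effect counts are overdispersed, so each analysis fits a negative
binomial GLM with log link on median-binned responses:

```
log μ = β₀ + β·x,   Var(Y) = μ + μ²/θ,   H₀: β = 0 (two-sided Wald test)
```

with the shape θ estimated by profile maximum likelihood alternating with
IRLS, and automatic fallback to Poisson when a Pearson χ²/df diagnostic
shows no overdispersion. Group contrasts use Wilcoxon rank-sum tests; the
near/far class medians are compared by a bootstrap (1000 resamples of size
10 per class) because the classes are very unequal in size; and three
randomization nulls (degree-preserving edge swaps, drug–target shuffles,
disease–gene shuffles) check that the distance-class gap is
association-driven. A synthetic-data generator emulates all six input
tables at study scale (996 drugs, 3,000-protein scale-free interactome)
with known injected effect sizes, so the entire pipeline is testable
offline. See `vignette("sidefxnet-methods")` for assumptions, parameter
defaults, and design rationale.

## Worked example

```r
library(sidefxnet)

study  <- simulate_study(generator_config(seed = 42, n_proteins = 1000,
                                          n_drugs = 500, n_diseases = 80))
report <- run_pipeline(study, pipeline_config(seed = 7, null_trials = 20))

r <- report$regressions$essential_targets
sprintf("essential-target regression: beta = %.3f (se %.3f), p = %.2g",
        r$beta, r$se, r$p)
#> "essential-target regression: beta = 0.320 (se 0.009), p = 5.7e-259"

d <- report$distance
sprintf("distance classes: %d near / %d far; medians %g vs %g; bootstrap p = %.2g",
        d$n_near, d$n_far, d$median_near, d$median_far, d$bootstrap$p)
#> "distance classes: 23 near / 298 far; medians 35 vs 88; bootstrap p = 2.4e-189"

sprintf("edge-swap null gap: %.1f (observed %.1f)",
        report$null_models$edge_swap$mean_gap, report$null_models$observed_gap)
#> "edge-swap null gap: -42.5 (observed 53.0)"
```

Reading the output: drugs with more essential targets have a higher
side-effect burden (each essential target multiplies the expected count by
exp(0.32) ≈ 1.4 in this simulated study); drugs whose targets sit far from
their indicated-disease genes have a much higher median burden (88 vs 35);
and the far-minus-near gap vanishes (here, inverts) once the interactome
is rewired degree-preservingly, so the gap is carried by the actual wiring,
not by degree structure alone. `write_report(report, "out/")` saves the
report as JSON plus per-analysis TSVs.

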