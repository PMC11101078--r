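# ppptracer

Analysis of ¹³C stable-isotope tracing through glycolysis and the pentose
phosphate pathway (PPP), built for LC-HRMS experiments in which cells are
fed fully labeled glucose (¹³C₆) or trehalose (¹³C₁₂) and the mass
isotopologue distributions (MIDs) of sugar phosphates are read out — the
kind of experiment used to show that immune cells run the *cyclic* PPP
(re-oxidizing recycled glucose-6P for extra NADPH) alongside glycolysis and
the nonoxidative PPP.

The package is aimed at metabolomics analysts who start from exported peak
areas (one row per sample, metabolite and mass shift) and want a fully
scripted, testable route from raw areas to pathway attribution.

## What it computes

**Exact carbon-atom labeling simulation.** The trehalose/glycolysis/PPP
network ships with explicit substrate-carbon → product-carbon maps
(transketolase transfers the C1–C2 ketose unit, transaldolase the C1–C3
unit; the oxidative lump removes C1 as CO₂). All label propagation is exact
enumeration of positional states — no sampling. This reproduces the
scheme-level arithmetic of cyclic-PPP tracing: one round recycles 6
pentoses into 4 hexoses + 2 trioses; the first round admits 7
tracer-placement combinations of which 3 regenerate an m+2 hexose;
sedoheptulose-7P comes out m+4 from labeled fructose-6P + unlabeled
glyceraldehyde-3P but m+5 from labeled ribose-5P.

**Measurement model.** Natural-abundance correction by
nonnegativity-constrained least squares against the binomial correction
matrix `A[i,j] = C(n−j, i−j) p₁₃^(i−j) (1−p₁₃)^(n−i)`;
reference-sample peak-area normalization (mean of per-metabolite m+0
ratios); isotopologue fractions.

**Statistics.** Welch's *t* test (1- or 2-tailed, optionally paired) with
Holm–Šidák step-down adjustment per metabolite family.

**Pathway attribution.** The central estimator, `fit_pathway_mixture()`,
models observed corrected MIDs as a convex combination of simulated regime
templates (direct glycolysis, single-pass oxidative PPP, cyclic PPP,
nonoxidative PPP): minimize ‖Tw − y‖² subject to w ≥ 0, Σw = 1. It returns
a fitted-model object with `coef`, `summary`, `predict`, `residuals` and
`plot` methods.

**Synthetic data.** `generate_experiment()` produces ground-truthed
LC-HRMS-like tables (5 replicates/group, log-normal per-sample scale
factors and per-peak noise, natural-abundance convolution), so the entire
pipeline is testable offline.

## Worked example

```r
library(ppptracer)
net <- default_network()

# the 7 first-round tracer placements of one TKT/TAL set
enumerate_first_round(net)[, c("tkt1_donor", "acceptor", "tkt2_donor",
                               "hexose_tal", "hexose_tkt2")]
#>   tkt1_donor acceptor tkt2_donor hexose_tal hexose_tkt2
#> 1       TRUE    FALSE      FALSE          2           0
#> 2      FALSE     TRUE      FALSE          1           4
#> 3       TRUE     TRUE      FALSE          3           4
#> 4      FALSE    FALSE       TRUE          0           2
#> 5       TRUE    FALSE       TRUE          2           2
#> 6      FALSE     TRUE       TRUE          1           6
#> 7       TRUE     TRUE       TRUE          3           6
```

Three of the seven placements (rows 1, 4, 5) regenerate an m+2 hexose — the
late-phase cyclic-PPP signature. Early, with a mostly unlabeled pentose
pool, the m+3 hexose dominates instead, formed by coupling labeled
glyceraldehyde-3P with unlabeled sedoheptulose-7P:

```r
mids <- simulate_regime(net, regime_spec("cyclic_ppp", rounds = 1,
                                         enrichment = 0.5))
round(mids$G6P, 4)
#>     m0     m1     m2     m3     m4     m5     m6
#> 0.1875 0.0625 0.1875 0.1250 0.1875 0.0625 0.1875
```

A full synthetic experiment, pushed through normalization, correction and
mixture deconvolution:

```r
cfg <- synthetic_config(seed = 20)   # 2 groups x 5 replicates, 10% CV noise
end_to_end_recovery(cfg)
#> End-to-end mixture recovery
#>   uninfected: max |error| 0.0052
#>           direct_glycolysis oxppp_single_pass cyclic_ppp nonox_ppp
#> recovered            0.5478            0.2052     0.0979    0.1491
#> truth                0.5500            0.2000     0.1000    0.1500
#>   infected: max |error| 0.0133
#>           direct_glycolysis oxppp_single_pass cyclic_ppp nonox_ppp
#> recovered            0.3605            0.1883     0.2879    0.1633
#> truth                0.3500            0.2000     0.3000    0.1500
#> overall max error: 0.01327
```

The recovered weights are the estimated share of each labeling route in
each group's MIDs; here the infected group's raised cyclic-PPP share
(0.29 vs 0.10) is recovered to within ~0.01 despite 10% measurement noise.

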