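---
title: "Tracing the pentose phosphate pathway: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the pentose phosphate pathway: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppptracer)
```

## The problem

Cells choose among routes of glucose catabolism according to need: direct
glycolysis for ATP, the nonoxidative pentose phosphate pathway (PPP) for
ribose-5P, the oxidative PPP for NADPH — and, when NADPH demand is high
(as in activated immune cells mounting an oxidative burst), the *cyclic*
PPP, in which the ribulose-5P made by oxidation is recombined back to
glucose-6P by transketolase (TKT) and transaldolase (TAL) and re-enters
oxidation. Feeding cells fully labeled ¹³C₆-glucose or ¹³C₁₂-trehalose and
measuring mass isotopologue distributions (MIDs) of sugar phosphates by
LC-HRMS distinguishes these routes, because each route moves carbon atoms
differently: the mass shift (m+k = k heavy carbons) of each intermediate is
a fingerprint of the path taken.

`ppptracer` implements that fingerprinting end to end: an exact
carbon-transition simulator, the measurement model (natural abundance,
normalization), the statistics applied to measured fractions, and a
deconvolution that turns observed MIDs into route shares.

## The carbon-transition model

The shipped network (`default_network()`) covers trehalose cleavage, upper
glycolysis, the oxidative-PPP lump, pentose interconversion, TKT/TAL, the
aldolase/TPI lump and lower glycolysis to lactate. Each reaction carries an
explicit bijective substrate-carbon → product-carbon map. Carbons are
numbered by the standard biochemical convention (C1 at the most oxidized
end); the published tracing schemes draw carbons as colored balls without
indices, and this convention pins them down. The key maps are:

* **Oxidative lump (G6P → CO₂ + Ru5P)**: C1 leaves as CO₂; C2–C6 become
  Ru5P C1–C5. Fully labeled G6P therefore yields m+5 pentose plus labeled
  CO₂.
* **Transketolase** transfers the C1–C2 unit of its ketose donor (Xu5P or
  F6P) onto the C1 end of the acceptor; **transaldolase** transfers the
  C1–C3 dihydroxyacetone unit (textbook mechanisms). These choices
  reproduce the published worked examples: S7P is m+5 when built from fully
  labeled ribose-5P + unlabeled Xu5P, m+4 when built by reversing TKT/TAL
  from fully labeled fructose-6P + unlabeled glyceraldehyde-3P, and TAL
  places a labeled triose at F6P C4–C6, giving the m+3 hexose signature.
* **Aldolase/TPI lump (F6P → 2 GAP)**: C4–C6 map onto one GAP unchanged;
  C1–C3 onto the second GAP with order inverted (C1→C3) to account for
  triose-phosphate isomerase. Only positional states are affected, not mass
  shifts.
* **Reversibility**: PGI, RPI, RPE, TKT1, TKT2, TAL are reversible
  (the nonoxidative PPP and the m+4 S7P route require it); trehalase,
  hexokinase, the oxidative decarboxylation and lower glycolysis are not.

Label propagation is *exact*: molecules are bitmask positional states, and
pool-level computations enumerate full joint distributions over the 2ⁿ
states (n ≤ 12 carbons), so no Monte-Carlo error enters the templates.

## Labeling regimes

`simulate_regime()` produces template MIDs for four idealized routes. All
share an entry hexose pool: tracer-derived molecules (per-carbon labeling
probability = tracer purity) mixed with unlabeled hexose at fraction
`enrichment` (the share of the pool that is tracer-derived; real
experiments dilute tracer with unlabeled sugar taken up in parallel, which
this single scalar summarizes).

* **direct_glycolysis**: identity transport to G6P/F6P, cleavage to
  trioses; pentose pools stay unlabeled.
* **oxppp_single_pass**: one oxidation; pentoses are m+5 (probability =
  enrichment) or m+0; S7P is formed by TKT1 from two independent pentose
  draws.
* **cyclic_ppp**: per round, the hexose pool is oxidized, TKT1/TAL/TKT2
  recombine pentoses into hexoses, and the recycled hexoses re-enter the
  next round diluted by unlabeled influx at the enrichment scalar. The TAL
  triose partner is drawn from the *glycolytic* triose pool at the same
  enrichment: early in labeling this pool is the dominant source of fully
  labeled GAP, and it is exactly the coupling of labeled GAP with unlabeled
  S7P that makes m+3 the modal labeled hexose after round one. Reported
  pools are those of the final round. Default `rounds = 2`: one round
  expresses the early m+3 signature, the second the late m+2 signature that
  emerges once labeled pentoses enter TKT/TAL; the number of rounds real
  cells run is unknown and is never fitted here.
* **nonox_ppp**: the TKT/TAL sequence run in reverse from F6P and GAP
  (2 F6P + GAP → 2 Xu5P + R5P), enumerated jointly over the three input
  draws so within-lineage carbon correlations are exact. The S7P
  intermediate can be m+4 but never m+5 under a glucose tracer, and the
  pentose pool acquires the m+2 marker — the mirror image of the oxidative
  signatures.

Species the instrument cannot resolve are reported combined: ribulose-5P /
ribose-5P as one pentose pool (taken as the RPI/RPE-equilibrated mix of the
pentoses each regime produces) and fructose-6P / glucose-1P as one hexose
signal (modeled by F6P; the network does not produce G1P).

The marker structure — m+3/m+5 pentose and m+5 S7P from oxidative routes,
m+2 pentose and m+4 S7P from the nonoxidative route — holds *exactly* (zero
cross-terms) for a pure tracer pool (enrichment 1), which is how the
package's marker tests state it. At partial enrichment a second cyclic
round can re-oxidize a TAL-formed hexose carrying labels at C1–C3 into m+2
pentose, so the exact-zero property is a property of the pure-tracer limit,
not of all mixtures; the markers remain strongly regime-enriched either
way.

## Measurement model

**Natural abundance.** Each carbon not labeled by the tracer carries ¹³C
with probability `p13` (default 0.0107, the standard natural abundance —
the source experiments do not print their value, so it is configurable).
The correction matrix is the binomial
`A[i,j] = C(n−j, i−j) p13^(i−j) (1−p13)^(n−i)`; `correct_mid()` solves
`A x ≈ y, x ≥ 0` by nonnegative least squares and renormalizes. Constrained
least squares rather than sequential satellite stripping: identical in the
noise-free case, but it cannot be driven negative by noise. Only ¹³C is
corrected; at the resolving power of the targeted assays the extracted
isotopologues are the carbon satellites. Tracer purity (stated ≥ 99 atom %
for the commercial tracers; default 1.0) enters the *forward* model as the
per-carbon labeling probability of tracer molecules.

**Normalization.** For each sample, every screened metabolite's unlabeled
(m+0) peak area is divided by the same metabolite's m+0 area in a selected
reference sample; the arithmetic mean of these ratios is the sample's
normalization factor, and all of the sample's areas are divided by it.
Labeled satellites never enter the factor; internal standards
(4-fluorophenylalanine by default) are excluded; metabolites with zero or
missing reference area are dropped from the mean and counted. The reference
defaults to the first control-group sample and is configurable. The
procedure is idempotent and removes per-sample global scale exactly.

**Fractions.** `fraction(m+k) = area(m+k) / Σ areas` per (sample,
metabolite) block; missing shifts are zero; all-zero blocks are a contract
violation rather than silent NaNs.

## Statistics

Fractions are compared on the raw simplex (no logit/arcsine transform),
matching how such data are plotted and tested in practice, with Welch's
*t* test (Satterthwaite df; one-tailed and paired variants included because
the targeted experiments use both). Multiple-testing adjustment is
Holm–Šidák step-down, applied within one metabolite's mass shifts by
default — the published panels adjust per panel, and the family definition
is configurable because the original family choices are not stated.

## Mixture deconvolution

`fit_pathway_mixture()` stacks the corrected MIDs of G6P, F6P/G1P,
Ru5P/R5P, S7P and lactate (≈ 32 fractions) and solves

> minimize ‖T w − y‖² subject to w ≥ 0, Σ w = 1

with the sum constraint imposed by an augmented row of weight 10³ followed
by exact renormalization. The nonnegative solve is exact active-set
enumeration for the small template sets used here (global optimum; immune
to iterative-solver cycling on zero-residual systems), falling back to
Lawson–Hanson beyond 10 templates. Identical templates are reported with a
collinearity flag rather than an error, since the weights between them are
then arbitrary but their sum is still meaningful. Templates must be
simulated at the experiment's enrichment; enrichment is an input, not a
fitted parameter.

On noise-free mixtures across the whole weight simplex (step 0.1) the fit
recovers weights to ≤ 10⁻³; the test suite verifies this grid exhaustively.

## The synthetic-data generator

`generate_experiment()` emulates the targeted experiment class: two groups
(default labels uninfected/infected) × 5 biological replicates; tracer
media of 0.5 mM glucose-¹³C₆ or 5 mM trehalose-¹³C₁₂ (a half-labeled
trehalose option models hemolymph exchanged at one glucosyl unit); true
MIDs from the exact simulator under a known regime mixture;
natural-abundance convolution; a per-sample global log-normal scale factor
(σ = 0.2) emulating loading/instrument drift; and per-peak multiplicative
log-normal noise (CV 10% by default — chromatographic areas are positive
and heteroscedastic, which is why additive Gaussian noise was rejected).
The default group contrast raises the cyclic share (0.10 → 0.30) and
enrichment (0.6 → 0.7) in the "infected" group, mirroring the direction of
published changes without asserting their magnitudes. Baseline pool areas
are order-of-magnitude placeholders (10⁴–10⁶ instrument units); no
published values exist for them.

What the generator does *not* emulate: chromatographic peak shape and
integration error, retention-time drift, co-elution beyond the two declared
unresolvable pairs, feeding-time kinetics, and any TCA-cycle labeling.
Passing recovery tests therefore demonstrate correctness of the analysis
pipeline under its own measurement model, not robustness to every artifact
of real chromatography.

Determinism: the generator seeds R's Mersenne-Twister and records the
algorithm and seed in the ground-truth object; equal seeds give identical
tables.

## Numerical choices and problem sizes

* MID normalization is asserted to 10⁻⁹; natural-abundance round trips to
  10⁻⁶; normalization idempotence to 10⁻⁹.
* The label-conservation property is exercised on ~10⁴ randomized states
  across all reactions; the noise-recovery suites use 20 seeded synthetic
  experiments at CV 10% and 5 replicates per group, and 25–100 seeded
  repeats for modal-regime and noise-robustness checks — sizes chosen to
  make sampling error negligible relative to the asserted tolerances while
  keeping the default test run fast.
* Degenerate inputs fail loudly: all-zero measurement vectors, zero-variance
  t tests, missing reference samples, malformed tables and broken carbon
  maps are contract violations with named offenders.

## Known limitations

* Route shares are defined relative to the four idealized regime templates;
  real cells interleave routes molecule by molecule, and mixtures of
  regimes are identified only up to the information in the measured MIDs
  (at enrichment 1 the direct and cyclic G6P templates coincide, so fits
  should use the experimentally realistic partial enrichment).
* The cyclic template reports the final round's pools; a time-resolved
  model of round mixing is out of scope.
* Enrichment and rounds are user inputs. Fitting them jointly with the
  weights would require richer data (time courses) than the targeted
  experiments provide.
* No flux magnitudes, kinetics or thermodynamics are estimated — the
  package quantifies labeling-route composition, not absolute fluxes.
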