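# aggkinetics

Kinetic analysis of amyloid self-assembly for people who run aggregation
assays: thioflavin-T (ThT) plate-reader concentration series, ¹⁹F-NMR
signal-decay experiments, and circular-dichroism (CD) kinetic series. The
package grew out of quality control for recombinantly produced amyloid-β
peptides — deciding whether a purified monomer preparation aggregates with
the kinetic signature expected of pure, seed-free Aβ42 — but the machinery
is generic to nucleation-elongation systems. A small sequence toolbox
(charge profiles, pairwise identity, Poisson-corrected distances,
Neighbor-Joining trees) supports the engineering of spidroin-derived
solubility tags used in such production work.

## The model

Unseeded aggregation is described by the standard moment equations for
fibril number *P* and fibril mass *M* (free monomer *m = m₀ − M*):

    dP/dt = kₙ m^(n_c) + k₂ m^(n₂) M / (1 + m^(n₂)/K_M)
    dM/dt = 2 k₊ m P,        P(0) = M(0) = 0

with primary nucleation (kₙ, n_c), elongation (k₊) and secondary
nucleation (k₂, n₂) that may saturate through the Michaelis-type constant
K_M (K_M = ∞ is the single-step model). The package provides

* the integrated rate law (`mass_fraction_closed`) and a stiff-safe ODE
  reference (`mass_fraction_ode`), with the effective rates
  λ = √(2k₊kₙm₀^n_c) and κ = √(2k₊k₂m₀^(n₂+1)/(1+m₀^(n₂)/K_M));
* sigmoidal half-time extraction (`fit_sigmoid`), normalization and
  replicate averaging, the scaling exponent γ in τ½ ∝ m₀^γ
  (`scaling_exponent`), and final-intensity linearity (`plateau_linearity`);
* global multi-concentration fitting with shared parameters and χ² model
  comparison between the single-step and saturating models (`global_fit`,
  `compare_models`);
* seeded synthetic-data generators for all three modalities
  (`generate_tht_dataset`, `generate_f19_trace`, `generate_cd_series`)
  that write the trace CSV + JSON metadata dialect and always record their
  ground truth;
* sequence utilities (`charge_profile`, `pairwise_identity`,
  `poisson_distance`, `nj_tree`).

## Worked example

Generate a six-replicate 1–9 µM ThT series from the default saturating
model, extract half times, the scaling exponent, and compare models:

```r
library(aggkinetics)

spec <- synthetic_spec(seed = 42)          # 1-9 uM, 6 replicates, 2% noise
ds   <- generate_tht_dataset(spec)

ht <- halftimes_by_concentration(ds$traces)
head(ht[, c("m0", "tau_half", "tau_half_se")], 3)
#>   m0 tau_half tau_half_se
#> 1  1    9.155    0.015281
#> 2  2    3.938    0.007836
#> 3  3    2.560    0.005273

scaling_exponent(ht)
#> gamma = -0.999 +/- 0.034 (R^2 = 0.9920, n = 9)

avg <- lapply(split(ds$traces, sapply(ds$traces, function(x) x$m0)),
              function(g) average_replicates(lapply(g, normalize_trace)))
cmp <- compare_models(unname(avg), seed = 1)
cmp
#> chi2 single = 9.247, multi = 0.2234 (ratio 41.4) -> preferred: multi_step
cmp$multi$params
#> Aggregation kinetic parameters (multi_step)
#>   k+*kn = 0.001421, k+*k2 = 0.2504 (uM, per-time^2 units)
#>   n_c = 2, n_2 = 2, K_M = 7.72116 uM^n_2
```

Half times are in hours (the fixture's time unit). The extracted γ ≈ −1.0
is the partially saturated signature; the χ² comparison prefers the
multi-step model, and the recovered K_M ≈ 7.7 µM² sits close to the
generator's 8.24 µM². A declining ¹⁹F-NMR trace works the same way through
`fit_sigmoid`:

```r
f19 <- generate_f19_trace(seed = 7)        # 50 uM, 3% noise, minutes
fit_sigmoid(f19$trace)
#> tau_1/2 = 258.2 +/- 0.73 (width 33.1, base 1055, plateau 47.69, rss 2.66e+05)
```

A thin command-line wrapper covering simulate / halftimes / scaling / fit /
seqprops / njtree ships as `inst/exec/aggkin` (see `?run_cli`).

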