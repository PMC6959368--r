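---
title: "Modelling amyloid aggregation kinetics with aggkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling amyloid aggregation kinetics with aggkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggkinetics)
```

## The kinetic model

Unseeded amyloid self-assembly from monomeric peptide is described by the
standard two-moment system for the fibril number concentration $P$ and the
fibril mass concentration $M$, with free monomer $m = m_0 - M$:

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 \frac{m^{n_2}}{1 + m^{n_2}/K_M}\, M,
\qquad
\frac{dM}{dt} = 2 k_+ m P, \qquad P(0) = M(0) = 0 .$$

The three processes are primary nucleation (rate constant $k_n$, reaction
order $n_c$), fibril-end elongation ($k_+$), and fibril-surface-catalyzed
secondary nucleation ($k_2$, order $n_2$). Secondary nucleation may saturate:
the Michaelis-type factor $1/(1 + m^{n_2}/K_M)$ caps the rate when the
monomer concentration is large compared to $K_M^{1/n_2}$. $K_M = \infty$
recovers the *single-step* model; finite $K_M$ is the *multi-step*
(saturating) model. The two effective proliferation rates are

$$\lambda = \sqrt{2 k_+ k_n m_0^{n_c}}, \qquad
\kappa = \sqrt{\frac{2 k_+ k_2 m_0^{n_2+1}}{1 + m_0^{n_2}/K_M}} .$$

`mass_fraction_ode()` integrates the moment system with `deSolve` (lsoda,
default tolerances `rtol = 1e-8`, `atol = 1e-10`) and is the package's
numerical reference. `mass_fraction_closed()` evaluates the first-order
self-consistent integrated rate law

$$\frac{M(t)}{m_0} = 1 -
\left(\frac{(B_+ + C_+)(B_- + C_+ e^{\kappa t})}
           {(B_- + C_+)(B_+ + C_+ e^{\kappa t})}\right)^{k_\infty^2/(\kappa\,\tilde k_\infty)}
e^{-k_\infty t},$$

with $C_\pm = \pm\lambda^2/(2\kappa^2)$,
$\tilde k_\infty = \sqrt{k_\infty^2 + \lambda^4/\kappa^2}$ and
$B_\pm = (k_\infty \pm \tilde k_\infty)/(2\kappa)$. The late-time relaxation
rate $k_\infty = 2 k_+ P(\infty)$ is computed from

$$k_\infty^2 = 4 k_+ k_2 \int_0^{m_0}
\frac{m^{n_2-1}(m_0 - m)}{1 + m^{n_2}/K_M}\, dm \;+\; \frac{2\lambda^2}{n_c},$$

which reduces to the familiar
$2\kappa^2/\bigl(n_2(n_2+1)\bigr) + 2\lambda^2/n_c$ when $K_M = \infty$ and,
unlike the naive substitution of the saturated $\kappa$, tracks the true
(ODE) late-time rate to about 0.1% under saturation. The integral is done by
deterministic adaptive quadrature; for $n_c = n_2 = 2$ it also has an
elementary antiderivative, but the quadrature keeps the orders general.

### Accuracy of the closed form

The integrated rate law is a perturbative solution built for the
secondary-nucleation-dominated regime. Its accuracy was mapped against the
ODE reference (and against the exact Oosawa solution
$M/m_0 = 1-\operatorname{sech}(\lambda t)$ for $n_c = 2$ in the
primary-only limit):

* single-step, $\kappa/\lambda \ge 20$: maximum absolute deviation of
  $M/m_0$ below $10^{-2}$ everywhere on $\kappa t \in [0, 15]$;
* saturation up to $m_0^{n_2}/K_M = 10$: a few-percent approximation
  (deviations up to about $6\times 10^{-2}$);
* near the crossover $\kappa \approx \lambda$ the deviation grows to about
  0.12, the known cost of the single-bridge ansatz.

The property tests assert exactly these measured domains. Because the
synthetic-data generators and the global fit both use the closed form, the
approximation error cancels in all recovery tests; it matters only when the
closed form is interpreted against independently simulated (ODE) data.

### Identifiability and units

Normalized unseeded curves constrain only the products $k_+ k_n$ and
$k_+ k_2$ (plus $K_M$): rescaling $k_+ \to c\,k_+$, $k_n \to k_n/c$,
$k_2 \to k_2/c$ leaves every normalized curve unchanged. `kinetic_params()`
therefore stores the products; raw constants are accepted and folded in
immediately. Concentrations are micromolar throughout ($K_M$ in
$\mu M^{n_2}$); the time unit is whatever the data use — the shipped ThT
fixture uses hours, the ¹⁹F fixture minutes, each declared in its docs.

## Trace analysis

`fit_sigmoid()` fits the four-parameter logistic
$F(t) = b + (p - b)/(1 + e^{-(t - t_{1/2})/w})$ by bounded
Levenberg–Marquardt and defines the aggregation half time $\tau_{1/2}$ on
the *fitted* curve (equal to $t_{1/2}$ for this form), which is robust to
noise in a way a raw-data crossing is not. A sloping-baseline variant was
considered and left out: the logistic without drift terms is the common
default, and drift correction is explicitly out of scope. Initialization is
multi-start — $t_{1/2}$ seeded at the raw half-crossing, $w$ at 5% of the
time span with 2%, 10% and 20% alternatives — and converged local optima
whose midpoint falls outside the observed time range are discarded. The
logistic is an approximation to the true (asymmetric) kinetic curve; on
noiseless model curves the fitted $\tau_{1/2}$ agrees with the exact
`model_halftime()` to well within 2% across the fixture grid.

Normalization (`normalize_trace()`) maps the fitted baseline to 0 and the
fitted plateau to 1, flipping declining traces (¹⁹F decay, the 218 nm CD
extreme) to aggregation extent; the original orientation is kept as an
attribute. Replicates are averaged *after* per-trace normalization, by
linear interpolation onto the first trace's grid restricted to the
intersection of time ranges (never extrapolating).

The scaling exponent $\gamma$ in $\tau_{1/2} \propto m_0^{\gamma}$ is the
slope of an ordinary least-squares fit of $\log\tau_{1/2}$ on $\log m_0$
(`scaling_exponent()`, at least three distinct concentrations). For
$n_2 = 2$ the mechanistic limits are $\gamma = -3/2$ (no saturation) and
$\gamma = -1/2$ (full saturation); intermediate $K_M$ interpolates
monotonically, which the property tests verify by simulation.

## Global fitting and model comparison

`global_fit()` minimizes the unweighted
$\chi^2 = \sum_{\text{traces}}\sum_t (y - M(t)/m_0)^2$ over normalized
traces with shared rate parameters, fitting
$\log_{10}(k_+k_n), \log_{10}(k_+k_2)$ and, for the multi-step model,
$\log_{10}K_M$, inside wide documented boxes
($[10^{-10}, 10^2]$, $[10^{-4}, 10^8]$, $[10^{-4}, 10^8]$ in $\mu M$/h
units). No per-point weighting is applied by default (a weighting hook
exists) because the noise model of plate-reader data is rarely known;
reaction orders are fixed at $n_c = n_2 = 2$, the standard choice for this
peptide family, and are configurable rather than fitted. Optimization is
multi-start (default 20: one heuristic start derived from the
mid-concentration half time via $\kappa\tau_{1/2}\approx 7$, the rest drawn
uniformly in the log-space box from a caller-supplied seed), each refined by
bounded Levenberg–Marquardt; results are deterministic given the seed.
Parameters finishing on a box edge raise a warning and are flagged
(`at_bounds`) — this is the identifiability guard that catches, e.g.,
secondary-nucleation constants driven to the lower bound by pure-primary
data.

`compare_models()` fits both models and prefers the saturating one only if
it lowers $\chi^2$ by more than 5% (relative) — a parsimony threshold chosen
here, since nested models guarantee $\chi^2_{multi} \le \chi^2_{single}$ up
to optimizer noise. That inequality is enforced in practice by injecting the
single-step optimum (with $K_M$ at its upper bound) as an extra start of the
multi-step fit. On single-step data $K_M$ is unidentifiable and lands on its
upper bound; `compare_models()` resolves that by parsimony and silences the
corresponding boundary warning.

## Synthetic data: what it emulates, and what it does not

`generate_tht_dataset()` emulates a quiescent plate-reader experiment: a
1–9 µM concentration series, six replicate wells per concentration, signal
$= \text{baseline} + \text{gain}\cdot m_0 \cdot M(t)/m_0$ with gain
500 a.u./µM and baseline 100 a.u., sampled every 5 min for 25 h, plus
i.i.d. Gaussian noise with standard deviation 2% of each trace's amplitude.
All randomness flows from the single mandatory seed, so any output is
bit-reproducible. Ground truth (parameters, per-concentration model half
times, the designed $\gamma$ and plateau slope) is always written alongside;
tests read it rather than reverse-engineering outputs.

Two design anchors are fixed at design time and never revisited:

* the default multi-step parameters ($k_+k_n = 1.26\times10^{-3}$,
  $k_+k_2 = 0.252$ in µM/h units) give realistic Aβ42-like half times
  (about 2.5 h at 3 µM, $\kappa/\lambda \approx 17$), and $K_M = 8.24$ µM²
  was solved by root-finding so that the designed series-average scaling
  exponent is exactly $\gamma = -1.0$, the partially saturated regime;
* the ¹⁹F fixture (`default_f19_params()`) rescales both rate products by
  the time-rescaling symmetry so that the model half time at 50 µM is
  exactly 258 min; the declining trace is generated with 3% noise.

The noise model is deliberately plain: i.i.d., amplitude-proportional
Gaussian (a heteroscedastic option is off by default). The generator does
*not* emulate plate-edge effects, evaporation or drift, ThT photophysics or
photobleaching, NMR baseline roll, or replicate-to-replicate half-time
scatter beyond what the noise induces. Tests passing on these data therefore
demonstrate the correctness of the estimators and fitting machinery under
the stated statistical assumptions — not robustness to the instrumental
artifacts real plates show.

`generate_cd_series()` builds a strict two-state spectral series: each
spectrum is $\alpha(t)\,\text{coil} + (1-\alpha(t))\,\beta$ with
$\alpha = 1 - M/m_0$. The basis spectra are smooth synthetic Gaussian-band
parameterizations of the canonical coil (minimum near 198 nm) and
beta-sheet (positive band near 196 nm, minimum near 218 nm) shapes — not
digitized from any measured figure. The beta basis is offset by a constant
solved at construction so the two bases cross exactly once, at 208 nm, in
the 200–215 nm window; every two-state mixture then passes through that
isodichroic point, and the time courses at the 198/218 nm extremes are
monotone images of $\alpha(t)$.

## Sequence tools

`charge_profile()` counts D/E as $-1$ and K/R as $+1$ with histidine
neutral and termini ignored — the convention used when comparing
solubility tags at neutral storage pH; the residue sets are arguments, a
pKa-based model is out of scope. `pairwise_identity()` aligns globally with
BLOSUM62 and affine gaps (open 10, extend 0.5) via `Biostrings` and reports
matches over all alignment columns; identity percentages are
method-sensitive, so the settings travel with the result.
`poisson_distance()` is the multiple-hit correction $d = -\ln(1-p)$;
`poisson_dist_matrix()` computes $p$ from an alignment under pairwise
(default) or complete gap deletion. `nj_tree()` is classical Saitou–Nei
Neighbor-Joining written in-package with deterministic lowest-index
tie-breaking and branch lengths clamped at zero; on additive matrices it is
an exact reconstructor, which the tests verify against random trees and
against `ape::nj` as an independent cross-check.

The shipped FASTA (`inst/extdata/synthetic_nt_domains.fasta`) contains two
*synthetic stand-in* sequences, generated once with a fixed seed and frozen.
They are designed to reproduce the published contrast between the
charge-reversed flagelliform and major-ampullate N-terminal-domain tags —
25 charged residues with net charge $-7$ versus 11 with $-5$, and global
identity well below 35% — but they are not natural spidroin sequences, and
results on them say nothing about the real domains beyond the arithmetic of
the designed properties.

## Numerical choices and degenerate inputs

* Overflow guard: the closed form's power term is evaluated in log space;
  for $\kappa t > 500$ the converged asymptotic branch returns the plateau.
* `model_halftime()` brackets from $1/\kappa$ by doubling (default horizon
  $10^6/\kappa$) and solves with `uniroot` at relative tolerance $10^{-6}$;
  a curve that cannot reach 0.5 raises an error rather than returning the
  horizon.
* Constant or non-crossing traces, mixed concentrations in a replicate
  group, non-overlapping time grids, fewer than three concentrations for
  scaling, non-symmetric distance matrices and saturated $p \ge 1$ all
  raise immediate, named errors; nothing degrades to silent `NaN`.
* Problem sizes: tests and the acceptance script use 301-point grids, six
  replicates, 20 starts per fit, 20 recovery datasets and 200 oracle draws —
  sizes at which every stage is fast while estimator variance is still
  representative.

## Known limitations

Unseeded kinetics only ($P(0)=M(0)=0$); no fragmentation-dominated model,
no length distributions, no spatial effects. The closed form degrades near
the primary/secondary crossover and under strong saturation as quantified
above — fits in those regimes inherit the rate law's bias even when the
optimizer is exact. Model comparison is by relative $\chi^2$ with a fixed
parsimony threshold; no information criteria or bootstrap uncertainty are
provided. The sequence fixtures are synthetic stand-ins, and identity values
depend on the alignment settings reported alongside them.
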