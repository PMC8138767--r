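---
title: "Models and methods behind spopbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spopbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spopbind)
```

spopbind quantifies how a multivalent disordered substrate engages the
SPOP ubiquitin-ligase adaptor, from three complementary kinds of tabular
data: fluorescence anisotropy titrations (binding affinities), NMR
titration peak lists (which residues bind), and per-cell
fluorescence/localization tables (whether the interaction redistributes
SPOP in cells). This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Binding equilibria

**Direct mode.** A trace of fluorescently labeled peptide probe (total
$A_T$) is titrated with receptor (total $R_T$). Because the probe is not
in vast excess over its dissociation constant, the hyperbolic isotherm is
wrong; the fraction of probe bound uses the exact ligand-depletion
(quadratic) solution

$$
FB = \frac{A_T + R_T + K_D - \sqrt{(A_T + R_T + K_D)^2 - 4 A_T R_T}}{2 A_T},
$$

evaluated internally as $2R_T/(S + \sqrt{S^2 - 4A_TR_T})$ with
$S = A_T + R_T + K_D$ to avoid catastrophic cancellation when $A_T$ is
tiny (`direct_fraction_bound()`).

**Competition mode.** Unlabeled competitor (total $B_T$, dissociation
constant $K_B$) displaces the probe from a fixed probe/receptor mixture.
The model is the complete competitive binding equilibrium — one receptor,
two mutually exclusive ligands — solved exactly, with no excess-ligand or
IC50-to-$K_i$ approximation. Free receptor $[R]$ is the physical root of

$$[R]^3 + a[R]^2 + b[R] + c = 0,$$

with $a = K_A + K_B + A_T + B_T - R_T$,
$b = K_B(A_T - R_T) + K_A(B_T - R_T) + K_AK_B$, $c = -K_AK_BR_T$,
obtained trigonometrically and converted to the fraction of probe bound,
$FSB = [R]/(K_A + [R])$ (`competitive_free_receptor()`,
`competitive_fraction_bound()`).

Predicted anisotropy mixes the free and bound endpoint anisotropies
weighted by fluorescence intensity:
$r = \big(r_f(1-FB) + g\,r_bFB\big)/\big((1-FB) + gFB\big)$, where $g$ is
the bound/free intensity ratio. The default is $g = 1$ (pure anisotropy
mixing, no intensity change on binding), with $g$ exposed as a fixed or
free fit parameter because published protocols differ on whether the
correction is applied and a wrong fixed $g$ biases $K_D$.

**Numerical choices.** All internal concentrations are molar; file
readers require an explicit unit column (`nM`/`uM`/`mM`/`M`) because
these assays legitimately span 40 nM probe to 2 mM competitor and silent
unit guessing is the classic failure mode. The arccos argument of the
trigonometric root is clamped to $[-1, 1]$. Because the trig form loses
relative precision to cancellation when $[R] \ll a$ (tight binding with
large totals), the root is polished with four Newton steps on the
strictly increasing mass-balance residual
$f([R]) = [R](1 + A_T/(K_A+[R]) + B_T/(K_B+[R])) - R_T$, restoring full
double accuracy across the nine-decade parameter sweep used in the
tests. Degeneracy of the cubic ($a^2 - 3b$ not safely positive) is
detected *relative to the coefficient scale*,
$a^2 - 3b \le \varepsilon(a^2 + 3|b|)$: an absolute threshold would
misclassify every nanomolar-scale system. Degenerate inputs — a
measure-zero set — fall back, with a warning, to the independent
bisection solver `solve_equilibrium()`, which brackets the unique root of
$f$ in $[0, R_T]$ and converges relative to the root itself (free
receptor can sit many orders of magnitude below $R_T$ under tight
binding). The bisection solver is otherwise used only as the verification
oracle in the test suite, never in the fitting hot path.

## Affinity fitting

`fit_direct()` and `fit_competition()` minimize unweighted squared
anisotropy residuals per replicate, then aggregate per-replicate $K$
estimates as mean ± SEM (sample sd/$\sqrt{n}$) — the convention for
reporting affinities from repeated titrations, and the reason the result
object keeps the per-replicate table (`tidy()`) alongside the summary
(`glance()`).

Because competitor affinities span at least five orders of magnitude
across constructs, $K$ is optimized in $\log_{10}$ space with a
grid-search initialization over $[10^{-9}, 10^{-1}]$ M: at each grid $K$
the endpoints $(r_f, r_b)$ enter the model linearly and are profiled out
by linear least squares, and Levenberg–Marquardt (minpack.lm) refines
from the best grid point. Endpoints are fitted jointly with $K$ by
default and can instead be fixed from control wells. A replicate whose
optimizer lands on the $\log_{10}K$ bounds is flagged not-converged; if
that happens in every replicate the fitted value is still reported but
the result is forcibly classified as a bound, not a point estimate.

**Lower-bound classification.** A competitor too weak (or too insoluble)
to approach saturation within the accessible concentration range cannot
pin down $K_D$; only "$K_D >$ value" is defensible.
`classify_bound_estimate()` codifies this: the fitted model is evaluated
at the highest titrant concentration, and if the achieved fraction of
the fitted dynamic range (probe displacement in competition mode, probe
saturation in direct mode) falls below `saturation_threshold` the status
is `lower_bound_only`. The default threshold of 0.8 is a policy choice
— the underlying judgment in the literature is qualitative — and 0 turns
classification off. Note that under the standard design (2 mM ceiling,
6 µM receptor, 2.6 µM probe $K_A$) a competitor at $K_B \approx 140$ µM
achieves displacement $\approx 0.805$, i.e. sits essentially on the 0.8
boundary; its classification under noise is genuinely marginal, which is
faithful to how such intermediate cases read in practice.

Uncertainty in the fixed probe $K_A$ is *not* propagated into $K_B$;
fit reports carry that caveat explicitly.

## NMR titration mapping

For an intrinsically disordered region in intermediate exchange, binding
manifests as per-residue peak intensity *loss*. The statistic is
$1 - I_\mathrm{bound}/I_\mathrm{unbound}$ after normalizing each dataset
internally: values near 1 mark strong attenuation, near 0 no
perturbation, negative values (gains) are retained. The default
normalization scales each dataset so the median intensity of the 20% of
shared residues with the smallest provisional change equals 1 — using the
*least*-perturbed residues as the reference keeps the binding signal from
biasing the scale; total- and max-intensity alternatives are available.
Any per-dataset multiplicative factor cancels exactly (a property test
asserts this).

Changes are binned on the percent scale by ordered
lower-exclusive/upper-inclusive intervals. Two built-in schemes cover
the common cases: a four-bin scheme (>90, 80–90, 70–80, <70, lightest to
darkest) for strong titrations and a three-bin scheme (>70, 40–70, <40)
for weaker ones. Residues lost to overlap or left unassigned are placed
in the darkest catch-all bin — on a structure surface, absence of
evidence is drawn as absence of perturbation.

`detect_binding_regions()` reduces a profile to contiguous motif
footprints: maximal runs of residues with change ≥ `change_threshold`
(default 0.5), spanning ≥ `min_run` residues (default 4, roughly the
shortest meaningful linear-motif footprint), tolerating up to `max_gap`
consecutive interior below-threshold *or missing* residues (default 1,
since single-residue overlap holes inside real binding regions are
routine). Boundaries are always above-threshold residues. These defaults
reproduce the two planted motifs (residues 220–235 and 265–275 of the
Pdx1 C-terminus window 204–283) exactly on clean synthetic profiles; the
published regions themselves were delimited by inspection, so the
detector is a reproducible proxy, not a claim about the original
delineation rule. In the Monte-Carlo recovery study (10% missing
residues, 10% multiplicative noise) the analysis uses `max_gap = 3`:
gap tolerance must cover the plausible missing-run length, and at 10%
independent missingness adjacent missing pairs occur in roughly a fifth
of profiles and would otherwise split a true region.

## Cell localization statistics

The unit of analysis is the cell: mean nuclear GFP intensity with a
binary SPOP localization class (cells with any punctate signal count as
`speckled`; cells lacking either marker are excluded upstream).
`summarize_by_class()` gives violin-ready summaries with per-replicate
provenance counts; `compare_classes()` runs the two-tailed two-sample
t test of intensity, diffuse vs speckled, pooled-variance (Student's) by
default to match the conventional wording, Welch by flag. Degenerate
structures — one class, fewer than two cells in a class, zero pooled
variance — return a not-applicable result rather than an error, because
variants that abolish binding legitimately produce single-class tables.
Cells are pooled across biological replicates (no hierarchical model);
this mirrors common practice but understates replicate-level
correlation, a known limitation.

## Synthetic data

Generators take an explicit seed (no hidden global state; the caller's
RNG stream is untouched) and return ground truth alongside the data for
closed-loop tests.

- Titrations: model curves plus additive Gaussian anisotropy noise
  (instrument-like; default sd 0.005, a plausible plate-reader figure).
  Defaults are the study design: 40 nM probe; direct-mode receptor
  log-spaced over 0.001–300 µM; competition at 6 µM receptor with twelve
  3-fold serial dilutions from 2 mM (reaching ~0.01 µM); three technical
  replicates. Endpoints default to $r_f = 0.08$, $r_b = 0.20$ — typical
  fluorescein-peptide values; only relative displacement matters.
- NMR peak lists: log-normal apo intensities (meanlog $\log 100$, sdlog
  0.3), per-region attenuation depths (defaults 0.9 and 0.8 for the two
  planted motifs, within the 0.7–0.95 range typical of strong
  intermediate-exchange attenuation), independent multiplicative
  log-normal noise on each measurement, and per-residue Bernoulli
  missingness emulating overlap.
- Cell tables: log-normal per-cell intensities; $P(\mathrm{diffuse})$ is
  a logistic function of log-intensity with configurable midpoint and
  slope. Slope 0 is the exact null for type-I-error calibration;
  `binding_deficient = TRUE` forces all-speckled tables.

What the generators do *not* emulate: pipetting error structure and
plate-position effects in titrations; exchange-regime-dependent
lineshape changes, chemical-shift movement, or spatially correlated
overlap in NMR; segmentation error, replicate-level batch effects, and
intensity-dependent misclassification in cell tables. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated noise models, not robustness to every artifact of real data.

## Problem sizes used in the automated studies

The test suite and the acceptance script run: a 1000-system log-uniform
sweep ($10^{-9}$–$10^{-2}$ M) for oracle equivalence and conservation;
100 noisy competition simulations per affinity level
($K_B \in \{1, 10, 100\}$ µM) for recovery and 100 each for
lower-bound/point-estimate classification; 200 noisy NMR profiles for
region recovery; and 2000 null cell tables (60 cells each) for t-test
calibration. These sizes give Monte-Carlo standard errors comfortably
inside the property margins being checked.

## Worked example

```{r example, eval = FALSE}
sim <- gen_competition_titration(kb = 1.4e-4, seed = 1)
fit <- fit_competition(sim, probe_kd = 2.6e-6, probe_total = 4e-8,
                       receptor_total = 6e-6)
glance(fit)
autoplot(fit)
```
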