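# spopbind

Quantitative analysis of multivalent substrate binding to the SPOP
ubiquitin-ligase adaptor — for structural biologists and biochemists who
measure protein–peptide interactions by fluorescence anisotropy,
carbon-detected NMR titrations of disordered regions, and per-cell
localization imaging, and want the downstream numbers to come from one
tested, reproducible pipeline instead of one-off scripts.

The package covers three analysis stages, each fed by plain CSV tables,
plus seeded synthetic-data generators so every stage is testable without
any experimental download.

## Binding models

**Direct titrations** (receptor titrated into a trace of labeled probe)
use the exact ligand-depletion isotherm

    FB = (A_T + R_T + K_D − sqrt((A_T + R_T + K_D)² − 4·A_T·R_T)) / (2·A_T)

rather than the hyperbolic approximation. **Competition titrations**
(unlabeled competitor displacing the probe from a probe/receptor mix) use
the complete competitive binding model: free receptor [R] is the physical
root of the cubic

    [R]³ + a[R]² + b[R] + c = 0
    a = K_A + K_B + A_T + B_T − R_T
    b = K_B(A_T − R_T) + K_A(B_T − R_T) + K_A·K_B
    c = −K_A·K_B·R_T

solved in closed form (and verified in the test suite against an
independent bisection mass-balance solver to ≤1e−8 relative over a
1000-system parameter sweep). Predicted anisotropy is intensity-weighted
two-state mixing with an optional bound/free intensity ratio *g*
(default 1). Fits are per replicate with Levenberg–Marquardt after a
log-spaced grid search in K, aggregated as mean ± SEM; titrations that
never approach saturation are reported as "K_D > value" rather than a
sham point estimate.

**NMR titration mapping** computes per-residue intensity attenuation
1 − I_bound/I_unbound between apo and ligand-added peak lists (Sparky or
CSV), bins it by configurable threshold schemes (built-ins: >90/80–90/
70–80/<70 and >70/40–70/<40, missing residues to the darkest bin),
detects contiguous binding motifs, and exports structure-coloring
attribute files. **Cell localization statistics** summarize per-cell
nuclear GFP intensity by SPOP localization class (violin-ready) and run
the two-tailed Student's t test, with a not-applicable pathway for
single-class variants.

## Worked example

```r
library(spopbind)

# a competition titration at the standard design: 40 nM probe, 6 uM
# receptor, 12-point 3-fold dilution series from 2 mM, 3 replicates
sim <- gen_competition_titration(kb = 1e-5, seed = 1)
fit <- fit_competition(sim, probe_kd = 2.6e-6, probe_total = 4e-8,
                       receptor_total = 6e-6)
fit
#> Anisotropy titration fit (competition mode)
#>   K_D = 13.4 +/- 1.75 uM (mean +/- SEM, n = 3)
#>   replicates: 3 fitted, 3 converged
#>   endpoints: r_free = 0.0773, r_bound = 0.2004, g = 1
#>   residual RMS: 3.82e-03 anisotropy units
```

The generating K_B was 10 µM; the fit recovers 13.4 ± 1.75 µM from noisy
data (sd 0.005 anisotropy units) with its replicate spread, and `tidy(fit)`
/ `glance(fit)` expose the per-replicate and summary tables. Mapping a
simulated NMR titration with 10% overlap-missing residues and 10%
intensity noise:

```r
nmr <- gen_nmr_titration(seed = 1, missing_frac = 0.1, noise_sd = 0.1)
prof <- intensity_change(nmr$apo, nmr$bound, window = 204:283)
detect_binding_regions(prof, max_gap = 3)
#> # A tibble: 2 × 4
#>   start_residue end_residue n_scored mean_percent_change
#> 1           220         235       15               0.880
#> 2           266         275        9               0.766
```

recovering the two planted motifs (truth: 220–235 and 265–275; one
boundary off by one where the edge residue was lost to overlap). And a
cell table whose diffuse-localization probability rises with expression:

```r
cells <- gen_cell_table(seed = 1, n_cells = 120, slope = 3)
compare_classes(cells)
#> Diffuse vs speckled SPOP localization: GFP intensity comparison
#>   n: 62 diffuse, 58 speckled
#>   Student's t = 6.9153, df = 118, two-tailed p = 2.563e-10
#>   mean difference (diffuse - speckled): 59.06
```

File-based pipelines (`run_fit_direct()`, `run_fit_compete()`,
`run_nmr_map()`, `run_cells()`, `run_simulate()`) read the documented CSV
dialects and write JSON + text reports with a provenance manifest; a thin
command-line dispatcher ships in `inst/cli/spopbind.R`. Plots:
`autoplot(fit)`, `plot_intensity_profile()`, `plot_cell_violin()`.

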