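---
title: "Models and methods behind cochleaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cochleaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleaging)
```

cochleaging quantifies age-related change in cochlear hair cells across
four experimental modalities: bulk RNA-seq of isolated inner (IHC) and
outer (OHC) hair cells and stria vascularis cells (SVC); whole-cell
nonlinear capacitance (NLC) of OHCs; OHC axial stiffness from
calibrated-fiber loading; and cochleogram / fluorescence quantification.
Every modality has a synthetic-data generator with known ground truth, so
each analysis stage can be validated end to end without any external
data. This vignette documents the models, the defaults and why they were
chosen, and the numerical decisions that matter.

## Transcriptomics

### The generator

`simulate_expression_study()` draws, per gene, a baseline abundance from
a lognormal (default `meanlog = 1`, `sdlog = 2`, spanning roughly five
orders of magnitude as bulk RNA-seq does), a transcript length uniform on
500–10,000 bp, and replicate counts from a negative binomial with
dispersion 0.05 (variance $\mu + \phi\mu^2$), a mid-range value for
biological replicates of a sorted cell population. A planted aging
signature multiplies the aged-group means of a random `frac_up` fraction
of genes by $2^{+\Delta}$ and a `frac_down` fraction by $2^{-\Delta}$
(default $\Delta = 2$, i.e. four-fold), identically in every cell type —
emulating a shared aging program. RPKM is *derived* from the counts, the
drawn lengths and the realized library sizes rather than generated
directly, so the RPKM arithmetic is exercised honestly:
$\mathrm{RPKM} = 10^9 \cdot c / (L \cdot N)$.

The generator does not emulate several features of real data: gene-gene
correlation, length-coupled expression biases, batch effects,
cell-type-specific expression programs, or mean-dependent dispersion
trends. Passing tests therefore demonstrate the correctness of the
pipeline's arithmetic and its statistical calibration under a clean
negative-binomial world, not robustness to those artefacts.

### Filtering and the DEG rule

A gene is *expressed* in a (cell type, age) group when its mean replicate
RPKM exceeds 0.1 (`deg_thresholds()`). The cutoff is applied strictly
(`> 0.1`); the convention is exposed as configuration because boundary
inclusivity is not standardized. The mean-of-replicates rule is the
default, with an any-replicate variant behind `rule = "any"`, since
either reading is defensible; the choice only moves genes sitting exactly
at background.

Differential expression follows the rule: a gene expressed in at least
one age is tested by a one-way fixed-effects ANOVA on
$\log_2(\mathrm{RPKM} + 0.01)$ (for two groups, $F = t^2$ of the
pooled-variance t), the p values are Benjamini–Hochberg adjusted *within
the family of tested genes for that cell type* (matching the
above-background precondition), and the gene is called `up` when
$\log_2\mathrm{FC} \ge 1$ and $\mathrm{FDR} \le 0.10$, `down`
symmetrically — both thresholds inclusive. The pseudocount 0.01 (a tenth
of the background cutoff) keeps zero-RPKM replicates finite without
materially moving genes that pass background. The log transform is a
design decision: only "ANOVA" is specified by the upstream analysis
convention, and variance on the log scale is far closer to constant for
RPKM-type data.

### Gene lists

The "top-N" rankings behind common, exclusive and concordant lists have
no canonical metric, so the package defines them explicitly and
configurably: common lists rank by $\min(|\mathrm{l2fc}_A|,
|\mathrm{l2fc}_B|)$ (a gene must change strongly in *both* cell types),
single-cell-type lists by $|\mathrm{l2fc}|$, with lexicographic
tie-breaks for determinism. Over-representation of annotation categories
uses the upper-tail hypergeometric test, BH-adjusted across categories —
a deliberate, dependency-free stand-in for ontology-based enrichment
tooling, which is out of scope.

## Nonlinear capacitance

### Model

OHC membrane capacitance is the linear (cell-size) term plus the
derivative of a two-state Boltzmann charge:

$$C_m(v) = C_{lin} + \frac{Q_{max}}{\alpha}\frac{e^x}{(1+e^x)^2},
\qquad x = \frac{v - V_{pk}}{\alpha}.$$

The peak height above $C_{lin}$ is $Q_{max}/(4\alpha)$, the curve is
symmetric about $V_{pk}$, and its integral over voltage is $Q_{max}$ —
all three identities are regression-tested. Charge density is
$Q_{max}/C_{lin}$. The slope factor $\alpha$ is in mV ($\alpha = kT/ze$);
defaults ($Q_{max} = 800$ fC, $\alpha = 33$ mV, $V_{pk} = -70$ mV,
$C_{lin} = 7$ pF) are typical for a healthy adult mouse OHC.

### Simulator

`simulate_voltage_clamp()` integrates the single-compartment patch
circuit $C(V_m)\dot V_m = (V_c - V_m)/R_s - V_m/R_m$ with fixed-step
fourth-order Runge–Kutta at the 50 kHz sample rate, evaluating the
command analytically at half-steps (an endpoint-averaged command would
degrade the integrator to third order, which is measurable at these
tolerances). Internal units are mV, MΩ, pF, nA, ms; because
pF·mV/ms = pA, the ODE carries an explicit 10³ factor. The dual-sine
command superimposes 10 mV peaks at $f_1 = 390.625$ Hz and
$f_2 = 2f_1 = 781.25$ Hz — the exact hardware rates that print as 390.6
and 781.2 — on each holding level; at 50 kHz these give exactly 128 and
64 samples per period, so every analysis window holds an integer period
count and the Fourier projections are leakage-free. Each dc level gets 2
settle periods (the circuit time constant is ~70 µs, orders of magnitude
shorter) plus 10 analysed periods.

### Estimator

Per dc segment the complex admittance is measured at both frequencies and
the three-element circuit $Y(\omega) = (R_s + R_m/(1 + j\omega R_m
C_m))^{-1}$ is solved: root-find $R_s$ on the frequency-independence of
$\mathrm{Re}\{1/(Z - R_s)\}$, recover $R_m, C_m$ in closed form, then
polish by Levenberg–Marquardt. The reported membrane potential is
series-resistance corrected to first order, $v = V_{dc} - I_{dc}\hat
R_s$; the correction ignores ac-drop rectification, a documented
limitation.

Two systematic errors of the dual-sine method on a *voltage-dependent*
capacitance are dealt with explicitly:

1. **Intermodulation.** Because $f_2 = 2f_1$, the quadratic term
   $C'(V)\,v\,\dot v$ of the capacitive current lands back on the two
   measurement frequencies with opposite signs. The protocol therefore
   *phase-cycles*: every dc level is recorded twice with the $f_2$ tone
   inverted, and the admittances are averaged — every product odd in the
   $f_2$ tone cancels identically. (Estimator-side, the circuit solve
   also offers a `resym` mode that fits only the symmetric part of the
   real admittance.)
2. **Stimulus smoothing.** A finite excursion averages the bell over
   ~±20 mV, biasing the fitted slope factor wide by roughly
   $3\kappa/(\pi^2\alpha^2)$ where $\kappa$ is the second moment of the
   membrane-level stimulus. For equal command amplitudes $a$ at both
   tones the leading-order effective curve is $C(v) + \kappa C''(v)$ with
   $\kappa = 3a^2/8$, attenuated per segment through the fitted pipette
   divider. `cm_voltage_series()` reports this per-point $\kappa$ and
   `fit_boltzmann()` fits the corrected model by default (`kappa =
   "auto"`), recovering the underlying parameters; `kappa = NULL` gives
   the uncorrected fit.

The Boltzmann fit is multi-start (slope factors 20, 33, 50 mV;
$C_{lin,0} = \min C_m$; $V_{pk,0} = \arg\max C_m$; $Q_{max,0} =
4\alpha_0(\max - \min)$), keeping the lowest-RSS converged start. A
fitted peak outside the sampled voltage range triggers a warning and a
`peak_bracketed = FALSE` flag rather than an error. With the default
13-level sweep (−150 to +90 mV in 20 mV steps) the full noise-free
simulate–estimate–fit loop recovers all four parameters to a few tenths
of a percent, which the test suite asserts at the 0.5 % level; Qmax
recovery under 5 pA RMS noise is asserted at the 10 % level (median over
10 seeds).

## Axial stiffness

A calibrated fiber (stiffness $k_f$) driven against the cell apex shares
displacement with the cell as two springs in series: the cell stiffness
is $k_c = k_f (L_f - L_c)/L_c$ from the free and loaded tip amplitudes.
Amplitudes are extracted at the drive frequency only
(`trace_amplitude()`, $2|X(f)|/N$ on the detrended trace), which rejects
DC offset and broadband noise; the extraction method is a package choice,
as none is prescribed by the measurement convention. Stiffness units are
treated as opaque-but-consistent: published values for OHCs appear
variously in nN/m and mN/m, and the package does not silently rescale.
The generator inverts the same relation ($L_c = k_f L_f/(k_f + k_c)$), so
the round trip is an identity at zero noise — asserted to <1 % over 100
random parameter draws.

## Cytology

Cochleogram survival is `100 * aged / baseline` per location and cell
type, from fixed 400 µm counting areas; zero baselines yield `NA`
(reported, never dropped) and unmatched locations are an error — no
interpolation along the cochlea. The generator draws aged counts
binomially from the baseline, so the expected survival percentage equals
the survival probability; the suite checks the mean over seeds against
the binomial standard error. Fluorescence quantification uses integrated
density = mean gray × area, per cell, averaged within age before the
log2 ratio (the per-cell average is a package decision; per-section
averaging would differ only by weighting). Group statistics are the
classical pooled-variance Student t (Welch behind a flag) and the
step-down Holm–Šidák adjustment
$\tilde p_{(k)} = \max_{j\le k}[1 - (1-p_{(j)})^{m-j+1}]$, implemented
directly since standard adjustment menus offer Holm–Bonferroni but not
the Šidák step-down. A full two-way ANOVA is deliberately omitted: the
reported quantities are the pairwise comparisons with Holm–Šidák
correction, and the factorial decomposition would contribute none.

## Pipeline

`run_pipeline()` executes the enabled stages in dependency order from a
single validated configuration (`pipeline_config()` /
`read_pipeline_config()`; unknown keys are rejected before anything
runs). Every stage writes plain-text artifacts (TSV/CSV/JSON) plus a
JSON report carrying the package version, a configuration hash and the
seed; identical configuration and seed give byte-identical reports. Each
top-level generator runs its own RNG stream and restores the caller's
RNG state, so stages cannot perturb each other's draws. A failed stage is
recorded in the report and later independent stages still run.

## Problem sizes and limitations

The shipped tests and the acceptance script run synthetic studies at
2,000 genes × 3 replicates, 13-level capacitance sweeps (two phase passes
each), 100-draw stiffness round trips and a few hundred cochleogram
seeds — sizes chosen so the whole suite completes in about a minute while
keeping Monte-Carlo standard errors well inside the asserted tolerances.

Known limitations: the series-resistance correction is dc-only; the
stimulus-smoothing correction is second-order (fourth-order residuals of
order $(a/\alpha)^4$ remain); the expression generator's variance
structure is not calibrated to any particular deposited dataset, so
absolute expressed-gene or DEG counts from real data are not reproduction
targets; and gene identity is by case-sensitive official symbol, with no
alias resolution.
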