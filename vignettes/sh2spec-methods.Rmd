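---
title: "Methods: models, estimators and design choices in sh2spec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in sh2spec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sh2spec)
```

# Scope

`sh2spec` re-implements, as tested reusable code, the quantitative analyses
by which one can dissect how tandem-SH2 phosphatases (SHP1, SHP2) are
discriminated by dual-phosphotyrosine inhibitory receptors (PD-1, BTLA):
equilibrium SPR affinity estimation, avidity-based ranking of tandem-SH2
binding modes, single-molecule trajectory analysis, microcluster enrichment
quantification, and ITIM/ITSM motif arithmetic. Every estimator is paired
with a synthetic-data generator with known ground truth, so the test suite
can verify parameter recovery end-to-end rather than trusting any single
implementation.

# Equilibrium SPR fitting

The binding of an individual SH2 domain to an immobilized phosphopeptide is
modeled as a 1:1 interaction at equilibrium,

$$R_{eq}(C) = \frac{R_{max} \, C}{K_d + C},$$

fitted by unweighted nonlinear least squares over the injection series
(default grid 20, 50, 100, 200, 500, 1000 nM). Only plateau responses are
used — this is an EC50-style equilibrium evaluation, not a kinetic fit;
`simulate_sensorgram()` exists purely as a forward model for the
association/dissociation phases and is never inverted.

Choices that matter:

* **Initialization.** $R_{max}^{(0)} = 1.1\max R_{eq}$ and $K_d^{(0)}$ the
  concentration whose response is nearest half of that. On monotone
  saturating data this lands close enough that the `port` optimizer
  converges essentially always; the tests also cross-check the optimum
  against a brute-force lattice search.
* **Not-detected rule.** The source data report "no detectable binding"
  without a numeric cutoff. We classify a series as not detected when its
  maximal response stays below 3 times the response-noise scale (estimated
  robustly from first differences). Not-detected affinities are carried as
  censored records (`NA`), never as a floor $K_d$.
* **Units.** Concentrations in nM on input, $K_d$ reported in µM, matching
  how such affinities are printed.

Free energies use $\Delta G = RT\ln(K_d/c^\circ)$ with $c^\circ = 1$ M,
$R = 1.987\times10^{-3}$ kcal/(mol·K) and a default temperature of 298 K
(the SPR temperature is not reported in the source; room temperature is
assumed). A censored $K_d$ yields a censored free energy with a lower
bound, never a number.

# Binding-mode thermodynamics

A tandem-SH2 protein on a receptor with two phosphotyrosines has six
candidate modes: four monovalent and two bivalent — *parallel*
(nSH2:ITIM + cSH2:ITSM) and *antiparallel* (nSH2:ITSM + cSH2:ITIM).
Bivalent modes use the standard effective-concentration avidity cycle:

$$\Delta G_{biv} = \Delta G_1 + \Delta G_2 - RT\ln(C_{eff}/c^\circ).$$

Once one arm is docked, the second binds pseudo-intramolecularly at local
concentration $C_{eff}$. The exact formalism used in the original
supplementary calculations is not recoverable from the main text, so this
package commits to the effective-concentration treatment explicitly and
documents which conclusions depend on it:

* The parallel-vs-antiparallel ordering is **independent of $C_{eff}$**
  (the $RT\ln C_{eff}$ term cancels); it equals the ordering of the
  products of constituent $K_d$'s.
* Bivalent-vs-monovalent comparisons **do** depend on $C_{eff}$.
  `min_ceff_for_bivalent_advantage()` reports the closed-form threshold
  $C_{eff}^* = K_{d,1}K_{d,2}/K_{d,\text{best mono}}$; for the weakest
  case in the bundled table (PD-1:SHP1) this is ≈ 5.5 µM, far below the
  1 mM default, so the parallel-over-monovalent conclusion is robust
  across any plausible effective concentration.
* A mode containing a not-detected constituent is **infeasible**, mirroring
  the categorical exclusion of the antiparallel PD-1:SHP1 mode, rather
  than being assigned a floor affinity.

`mode_occupancy()` adds a Boltzmann partition over the unbound state and
all feasible modes at a given free phosphatase concentration, each bound
mode weighted by $(c/c^\circ)e^{-\Delta G/RT}$. Absolute occupancies are
not invariant under a uniform shift of all mode energies (the unbound
reference is fixed); occupancies *conditional on being bound* are, and that
is the invariance the tests assert.

The bundled affinity table (`affinity_fixture()`) carries a `source`
column: PD-1 records and two BTLA records are measured values printed in
the source results; the six remaining BTLA records are clearly labelled
synthetic stand-ins chosen once to respect the qualitatively reported
domain preferences (nSH2 prefers BTLA-ITIM, cSH2 prefers BTLA-ITSM, for
both phosphatases). Conclusions that rest on those stand-ins are therefore
tests of the stated inequalities, not of printed numbers. Cross-linking of
two receptors by one phosphatase (a 2:1 mode) is out of model scope.

# Single-molecule trajectory analysis

## Generator

`gen_trajectory()` simulates an exact continuous-time two-state Markov
chain (pseudo-first-order on-rate $k_{on}^{eff}$, off-rate $k_{off}$) and
samples it at the camera frame rate (default 20 Hz). The state recorded
for a frame is the state occupying the **majority of the frame interval**,
emulating camera integration rather than instantaneous sampling. The
consequence — dwells shorter than half a frame are missed, and rates are
biased when dwell times approach the frame interval — is deliberate and
predictable; rate-recovery tests use rates well below the frame rate, as
the real experiments do. Emission is the state mean plus Gaussian noise;
an optional exponential photobleaching clock (running on bound time)
darkens the fluorophore permanently.

Every generator consumes one pseudorandom stream derived from its
config seed via the published splitting rule (`split_seed()`), restores the
caller's RNG state afterwards, and emits byte-identical output for a fixed
seed.

## HMM

The bound/unbound segmentation is a two-state Gaussian-emission hidden
Markov model fitted by Baum–Welch (scaled forward–backward in compiled
code; M-step in R). Two states are fixed — the physics is binary — and no
model-order selection is performed. Initialization is a deterministic
2-means split of the pooled intensities, so fits are reproducible without
a random seed and EM never starts from a seed-dependent point. Emission
variances are untied (bound spots may be noisier). Convergence is a
relative log-likelihood change below 1e-8 or 500 iterations; the EM
monotonicity of the log-likelihood is asserted in the tests. Viterbi
decoding breaks ties toward UNBOUND and is verified against exhaustive
path enumeration on short traces.

## Dwell times and rates

Decoded state runs are converted to dwell times; the first and last dwell
of each trajectory are censored and **excluded** from rate estimation,
which uses the exponential maximum-likelihood estimator
$\hat k = 1/\bar t$ with standard error $\hat k/\sqrt n$. Interior
complete dwells in a finite observation window are themselves slightly
length-biased (long dwells are more likely to touch a window edge); for a
window $T \gg 1/k$ the bias is $O(1/(kT))$ and the tests choose window
lengths that keep it below the asserted tolerances.

## Spots, bleaching, colocalization

The spot detector replaces an external localization plugin with an
in-repo equivalent: difference-of-Gaussians band-pass ($\sigma$,
$1.6\sigma$), strict 3×3 local maxima above 5 robust noise SDs (1.4826
MAD), then least-squares refinement of a 2-D Gaussian plus offset.
Coordinates are 0-based with the origin at the center of the top-left
pixel; localization is translation-equivariant by construction and tested.

Photobleaching steps are counted by greedy binary-segmentation
change-point fitting with a BIC-style penalty ($2\hat\sigma^2\log n$ per
change-point, $\hat\sigma$ from first differences) and a minimum step
depth of 3 noise SDs; downward jumps between segment means are the steps.
This is deterministic and needs no per-trace tuning.

Colocalization counts a receptor spot as positive when at least one
ligand-channel detection falls within the matching radius (default 2 px;
no radius is stated in the source) during the observation window. The
source phrase "within 0.5 s of image acquisitions" is ambiguous — and its
printed quotient is inverted relative to a rate in [0, 1] — so the rate is
implemented as colocalized/total with a `window_mode` switch: `"any"`
(default; any sliding 0.5-s window, which for a detection-existence
criterion equals the whole acquisition) or `"first"` (the first 0.5 s).
Both channels are assumed registered.

# Microcluster enrichment

Background subtraction is grayscale morphological opening with a flat
disk (default radius 50 px, the common default of interactive tools;
idempotent, output non-negative). The cluster mask thresholds the
subtracted receptor image at 3 robust noise SDs and keeps 4-connected
components of ≥ 4 px (both unstated in the source Methods; these are this
package's choices). When a cell-footprint mask is supplied, it is eroded
by the ball radius first, because the rolling-ball background is
systematically underestimated within one radius of the footprint rim and
would otherwise leave a spurious bright ring; the noise scale is then
estimated inside the footprint so the clamped zero background outside the
cell cannot collapse the MAD.

The per-cell statistic is the ratio of summed background-subtracted
effector to summed background-subtracted receptor fluorescence over the
mask — the intensity-weighted mean of per-cluster ratios, matching the
"effector FI normalized to receptor FI" convention (`statistic = "mean"`
switches to unweighted means). The ratio is invariant to common gain and
to any background the subtraction removes. `compare_groups()` reports
Welch t statistics between conditions.

The generator (`gen_cluster_image()`) emulates a circular cell footprint
with Gaussian microclusters and an effector channel carrying
`enrichment × blob` signal plus diffuse background. It does **not**
emulate irregular cell outlines, cluster size distributions, staining
nonlinearity, or chromatic offset — a green enrichment-recovery test
establishes that the estimator is unbiased on this stated world, not that
those real-world effects are handled.

# Motif arithmetic

ITIM (`[SIVL]xYxx[IVL]`) and ITSM (`TxYxx[VI]`) consensus classes are
encoded exactly as printed, matched as character classes with no scoring.
Positions are 1-based full-protein numbering. The bundled sequence fixture
is *synthetic*: motif windows (VDYGEL, TEYATI; IVYASL, TEYASI) are placed
at the printed tyrosine positions (Y223/Y248; Y257/Y282) inside
tyrosine-free filler, avoiding the risk of silently corrupted full-length
sequences; scanning real FASTA input is the supported path for real use.
Residue volumes for the pY+1 analysis come from the standard Zamyatnin
(1972) compilation, embedded as data because the original figure does not
name its table; the bell-shape fit is a least-squares quadratic in volume
whose vertex is reported along with the nearest residues (ties within
1 Å³, so the Leu/Ile pair is reported together). A concave-up fit is a
no-peak result, not an error.

# Degenerate inputs and numerical conventions

* Isotherms need ≥ 4 strictly positive, distinct concentrations; fits that
  do not converge are flagged, not thrown.
* `fit_hmm()` refuses single-level (zero-variance) data; an emission-SD
  floor (1e-3) keeps the likelihood bounded.
* `colocalization_rate()` on an empty receptor table is an error (the rate
  is undefined), while an empty ligand table is a valid 0.
* `enrichment_ratio()` on an empty mask or zero receptor signal is an
  error naming the condition.
* All randomness flows through explicit seeds; generators restore the
  caller's RNG state.

# Known limitations

* Optical realism is out of scope: no EMCCD gain model, no drift, no
  bilayer diffusion, no astigmatism. Shot noise is available but off by
  default (the camera model is unstated in the source).
* Kinetic constants are never estimated from sensorgrams (equilibrium
  analysis only).
* The effective-concentration value for bivalent modes is a model input;
  only $C_{eff}$-independent conclusions are reported as unconditional.
* Dwell-time estimates are biased upward once true dwells approach two
  frame intervals; the documentation of `estimate_rates()` flags this.
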