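---
title: "Phase dynamics of BOLD signals and whole-brain Hopf network models"
author: "hopfbrain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase dynamics of BOLD signals and whole-brain Hopf network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopfbrain)
```

## Scope

`hopfbrain` analyses region-wise BOLD time series through the lens of
instantaneous phase synchronization, and interprets the resulting
statistics with a generative whole-brain model: a network of noisy
Stuart–Landau oscillators coupled through a weighted structural
connectome. The package covers four layers:

1. **Phase dynamics** — band-pass filtering, Hilbert phases,
   phase-interaction matrices, global synchrony and its fluctuations,
   phase-randomized surrogates, and the derived statistics *integration*,
   *segregation* and *functional connectivity dynamics* (FCD).
2. **Generative model** — simulation of the coupled Hopf normal form on a
   structural connectome; fitting of the global coupling $g$ by
   Kolmogorov–Smirnov (KS) distance between FCD distributions, and of
   node-wise bifurcation parameters $a_j$ from spectral power
   proportions; the effective-parameter decomposition
   $a^{\mathrm{eff}}_j = a_j - g S_j$.
3. **Linear stability** — the Jacobian of the coupled system at the
   silent fixed point and the relation between its most stable
   eigenvectors and the structural hubs.
4. **Structural graph analysis** — node strengths, hub detection,
   weighted k-density (rich-club) curves, and hub-lesion models, plus
   synthetic connectome/BOLD generators that give every estimator a known
   ground truth.

Everything operates on plain matrices wrapped in small S4 containers
(`SCMatrix`, `BoldMatrix`, `PhaseInteractionSeries`, `FCDMatrix`,
`HopfModelSpec`, …) with validity checks, so malformed inputs fail early
and loudly.

## The phase-dynamics statistics

BOLD signals are band-passed to 0.04–0.07 Hz — the band where resting
fMRI carries most functionally relevant oscillatory power — with a
second-order Butterworth applied forward and backward
(`bandpassFilter()`). Zero-phase filtering matters because the phases
*are* the downstream signal; a causal filter would rotate them. The
instantaneous phase $\phi_j(t)$ of each region is the argument of the
analytic signal $z(t) = s(t) + i\,H[s(t)]$ (`instantaneousPhases()`).

The phase-interaction matrix at each volume is
$P_{jk}(t) = \cos(|\phi_j(t) - \phi_k(t)|)$: 1 in phase, 0 orthogonal,
−1 anti-phase. Because cosine is even this equals
$\cos(\phi_j - \phi_k)$; the absolute difference is used so symmetry is
exact in floating point. The first and last 10 volumes are discarded by
default (`settle`) to protect the statistics from filter and Hilbert edge
transients.

From $P(t)$ the package derives:

* **Global synchrony** $r(t)$, the mean over distinct pairs, and the
  **phase-interaction fluctuations** $m = \mathrm{sd}(r)$ (population
  convention, divide by $T$ — any consistent convention works; this one
  is documented and frozen). A fully synchronized network gives
  $r \equiv 1$, $m = 0$ exactly.
* **Integration**: the time-averaged matrix $\langle P \rangle$
  (bias-corrected, see below) is binarized at every threshold on the grid
  $0, 0.01, \dots, 0.99$; integration is the mean over thresholds of the
  largest connected component's relative size. The grid stops one step
  short of 1 so the fully coherent matrix scores exactly 1 under the
  strict `>` binarization; the fully incoherent one scores $1/N$.
* **Segregation**: pairs whose raw $\langle P \rangle$ exceeds the
  $1-\alpha$ quantile ($\alpha = 0.01$) of their own phase-randomized
  surrogate distribution form a binary graph; Louvain community
  detection (best of 10 seeded restarts) gives the Newman modularity
  $Q$. At least $1/\alpha$ surrogates are required so the quantile is
  resolvable.
* **FCD**: sliding windows of 30 volumes shifted by 1 TR; each window's
  mean $P$ is vectorized (strict upper triangle) and all window pairs are
  compared by cosine similarity. The window mean is normalized by the
  window length, making each entry a true average. The mean FCD
  summarizes pattern recurrence; by default all off-diagonal window pairs
  enter the mean (overlapping windows included), with
  `excludeOverlap = TRUE` available — overlapping pairs keep a small
  positive offset (~0.1 on white noise) purely from shared samples, which
  is worth knowing when comparing absolute values across window settings.

**Surrogate bias correction.** Time averages of $P$ are positively biased
at finite $T$ even for unrelated signals. `phaseRandomizedSurrogate()`
replaces Fourier phases with i.i.d. uniform draws while preserving each
row's amplitude spectrum exactly (random phases are assigned on the half
spectrum and mirrored conjugate-symmetrically, DC and Nyquist bins kept
real, so the surrogate is exactly real-valued — the naive independent
randomization of all bins would not be). `biasCorrectMeanInteraction()`
subtracts the surrogate-ensemble mean of $\langle P \rangle$, removing
the bias; per-pair sampling noise of order $T^{-1/2}$ necessarily
remains.

## The whole-brain Hopf model

Each region follows the normal form of a supercritical Hopf bifurcation
with added noise, coupled diffusively through the connectome $C$:

$$\dot z_j = z_j\left[(a_j + i\omega_j) - |z_j|^2\right]
  + g \sum_k C_{jk} (z_k - z_j) + \beta \eta_j(t).$$

For $a_j < 0$ the node is a stable spiral (noisy fluctuations); for
$a_j > 0$ a limit cycle of amplitude $\sqrt{a_j}$; near zero the node is
maximally susceptible to its neighbours. BOLD is modelled as
$\mathrm{Re}(z_j)$. Parameters and defaults:

| parameter | meaning | default |
|---|---|---|
| $a_j$ | bifurcation / growth rate (1/s) | 0 (homogeneous fit) |
| $\omega_j$ | intrinsic frequency (rad/s) | spectral peak in 0.04–0.07 Hz |
| $g$ | global coupling (scales $C$) | fitted on a 0–3 grid |
| $C$ | structural weights | max-scaled to 0.2 |
| $\beta$ | noise sd per component | 0.02 |
| `dt` | Euler–Maruyama step (s) | 0.1 |

The 0.2 scaling of $C$ prevents full synchronization; $\beta = 0.02$
enters each complex component as an independent Gaussian increment
scaled by $\sqrt{dt}$ (the noise is specified only as Gaussian; the
per-component convention is frozen here). Integration uses
Euler–Maruyama with `dt` = 0.1 s and a discarded 60 s transient, which
passes stationarity checks at the default parameters; the trajectory is
sampled every TR without averaging. At `dt` = 0.1 the scheme inflates
the noise-free limit-cycle amplitude by roughly $dt\,\omega^2/2$
(≈1–3 %); the closed-form amplitude tests therefore run at `dt` = 0.025
together with a step-halving convergence check, while the stochastic
fitting keeps `dt` = 0.1 where this bias is immaterial.

Internally the drift is always evaluated in the strength-absorbed form
$(a_j - g S_j + i\omega_j) z_j + g \sum_k C_{jk} z_k$, so the bare
parameterization and the effective one
($a^{\mathrm{eff}}_j = a_j - g S_j$, `effectiveMode = TRUE`) are not
merely algebraically but bit-for-bit identical trajectories under the
same seed — a tested contract.

### Fitting

**Global coupling.** For each $g$ on a grid (default 0–3, step 0.1, 10
trials; the recovery experiments use step 0.25 with 5 trials), the
homogeneous model ($a_j = 0$) is simulated with deterministic sub-seeds,
pushed through the *same* analysis chain as the data, and the pooled FCD
values are compared to the empirical FCD distribution by the two-sample
KS distance. $g_{\mathrm{opt}}$ minimizes the trial-mean KS, ties going
to the smallest $g$. A single 300-volume realization's FCD distribution
fluctuates between realizations by about as much as a 0.25 change in
$g$ shifts it, so recovery experiments pool the FCD values of a small
synthetic group (4 subjects) on the empirical side — matching how the
statistic is accumulated over participants in practice.

**Local parameters.** With $g$ fixed, each iteration simulates the
network, measures each node's proportion of spectral power in
0.04–0.07 Hz relative to 0.04–0.25 Hz, and updates all nodes in
parallel: $a_j \leftarrow a_j + \eta\,(p^{\mathrm{emp}}_j -
p^{\mathrm{sim}}_j)$ with $\eta = 0.1$. Power proportions integrate a
single Welch spectrum (Hann taper, 50 % overlap, segment length
$\min(128, T/4)$) over both bands — identical estimator settings on the
empirical and simulated side by construction, and no band-edge filter
shaping enters the ratio (a flat spectrum yields the bandwidth ratio
0.143 exactly in expectation). The stopping rule is
$\max_j |p^{\mathrm{emp}}_j - p^{\mathrm{sim}}_j| < 0.01$ or 100
iterations; because $p^{\mathrm{sim}}$ is re-estimated from one
stochastic simulation per iteration, the mismatch typically plateaus
near 0.1 rather than reaching the tolerance, so `converged = FALSE`
with a plateaued trace is normal and the estimates are still reported —
the recovery tests show the ground-truth ordering is recovered (Spearman
above 0.7) regardless. Each iteration draws a fresh deterministic
sub-seed so the fit cannot lock onto one noise path.

**Effective parameters and residuals.** `fitEffectiveParameters()` runs
the same loop in effective parameterization, estimating
$a^{\mathrm{eff}}_j$ directly. In a homogeneous network
$a^{\mathrm{eff}}_j$ is an exact linear function of strength, so the
node-wise absolute residuals of the OLS line
$a^{\mathrm{eff}} \sim S$ (`strengthResidualAnalysis()`) measure how
much local heterogeneity exceeds what the structure dictates.

### Linear stability

At the silent fixed point $z = 0$ the linearized dynamics are governed by
$A = \mathrm{diag}(a - gS + i\omega) + gC$ (the conjugate sector
decouples at $z=0$ because the cubic term contributes nothing linear, so
the $N\times N$ complex matrix is the full story).
`eigendecomposeSorted()` returns eigenpairs sorted ascending by real
part, unit-norm and phase-fixed (largest component real-positive) for
reproducible reporting, and verifies $\|Av - \lambda v\| < 10^{-8}$. By
Gershgorin's theorem every eigenvalue satisfies
$\mathrm{Re}(\lambda) \le \max_j a_j$, an exact tested bound.
`hubStabilitySummary()` correlates component magnitudes of the most
stable eigenvectors with node strength: on core–periphery connectomes
the hubs dominate the most stable directions, and reducing $g$ makes the
stability depth $\min \mathrm{Re}(\lambda)$ shallower.

## Synthetic data: what it emulates and what it does not

`generateCorePeripherySC()` builds a weighted stochastic-block
connectome: hub-incident links are always present (hubs connect
broadly), periphery links appear with probability `density`, weights are
log-normal with hub-incident links boosted by `hubFactor` (hub–hub by
`hubFactor`²), and the matrix is symmetrized and max-scaled to 0.2. The
log-scale spread defaults to 1.2, giving the long-tailed weight and
strength distributions characteristic of probabilistic-tractography
connectomes. That tail is not cosmetic: with near-homogeneous strengths
the coupled model has a near-critical collective mode at every coupling
and collapses into full synchronization across most of the $g$ range,
whereas a heavy-tailed strength profile spreads the effective damping
$-gS_j$ across nodes and keeps the FCD informative about $g$ — the
regime the empirical statistics occupy. `degradeHubs()` models lesions
as multiplicative attenuation of hub-incident links, keeping $N$ fixed
so intact and lesioned connectomes share a parcellation.

The desk-scale study conditions are: $N = 40$ regions (6 hubs, hub
factor 5, density 0.2), 300 volumes at TR = 2 s, band 0.04–0.07 Hz,
$\beta = 0.02$ — a 10-minute scan per synthetic subject. The generators
emulate the *dynamical* regime of resting BOLD, not its physiology:
there is no haemodynamic convolution (the model equates
$\mathrm{Re}(z)$ with BOLD), no measurement noise floor, no motion or
physiological confounds, and the connectome is a statistical
caricature. Passing recovery tests therefore demonstrate that the
estimators invert the model faithfully at realistic signal lengths; they
do not certify performance on empirical fMRI.

## Numerical choices and degenerate inputs

* Threshold grids: integration scans $[0, 1)$ in steps of 0.01 with
  strict binarization; k-density scans $S' = 0 \dots S_{\max}$ in steps
  of 0.2 (defaults 10 and 0.2), computing strengths once on the full
  matrix (single pass, no re-pruning). The $S' = 0$ point includes all
  nodes, so it equals the global mean off-diagonal weight; the curve is
  cut off (NA, with the cutoff recorded) once fewer than 2 nodes
  survive. k-density averages all surviving pairs including zero
  weights; `existingOnly = TRUE` averages only present links.
* Ties in the $g$ scan go to the smallest candidate; Louvain partitions
  use best-of-10 seeded restarts.
* All-zero signal rows make the phase undefined and raise an error
  rather than propagating NaNs; zero-variance rows in `pearsonFC()` are
  flagged and masked; correlations at ±1 are capped before the Fisher
  transform.
* Every stochastic routine takes an explicit seed and derives sub-seeds
  deterministically; callers' RNG state is saved and restored, and
  identical inputs and seeds reproduce results bit-for-bit.
* The hub threshold default 4.5 is meaningful on the strength scale of
  fibre-density connectomes; synthetic fixtures pass thresholds on their
  own scale (tests use the midpoint between designated hub and non-hub
  strengths).

## Known limitations

* Euler–Maruyama is first-order; the documented amplitude bias at
  `dt` = 0.1 is visible in noise-free closed-form checks (and absent at
  finer steps) but negligible relative to stochastic variability in the
  fitting pipeline.
* The local-parameter fit's stopping tolerance is rarely reached at
  realistic scan lengths (single-simulation gradient noise); treat the
  trace, not the `converged` flag, as the diagnostic.
* The pooled FCD-value distribution is nearly invariant under
  permutation of the $a_j$ across nodes at desk scale, so the shuffle
  control is evaluated on the node-wise spectral statistic the fit
  targets rather than on the FCD-KS.
* Group outputs of `runFullPipeline()` are descriptive (means ± SE);
  inferential statistics are deliberately out of scope.

## A small worked example

```{r example, eval = FALSE}
sc <- generateCorePeripherySC(40, 6, hubFactor = 5, density = 0.2,
                              seed = 1)
gt <- makeGroundTruthDataset(sc, g = 1.5,
                             list(mode = "homogeneous", value = 0),
                             seed = 7)
dynamicsSummary(gt$bold, seed = 3)

spec <- hopfModelSpec(a = 0, omega = gt$groundTruth$omega, g = 1.5,
                      C = sc)
stab <- eigendecomposeSorted(buildJacobian(spec))
hubStabilitySummary(stab, nodeStrengths(sc))
```

The problem sizes used throughout the package's own validation — 40
regions, 300 volumes, grids of 13 coupling values with 3–5 trials — keep
every experiment reproducible on a laptop while staying inside the
dynamical regime the statistics are designed for.
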