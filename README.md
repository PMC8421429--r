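# hopfbrain

Phase-synchronization analysis of resting-state BOLD signals and
whole-brain modelling with networks of coupled Stuart–Landau (Hopf)
oscillators.

## What problem this addresses

Resting fMRI dynamics can be summarized by how the instantaneous phases
of regional BOLD signals interact: how *integrated* the network is, how
*segregated* into modules, how much the global synchrony *fluctuates*,
and how *recurrent* the synchronization patterns are over time
(functional connectivity dynamics, FCD). Altered states of
consciousness — anaesthesia, disorders of consciousness after brain
injury — shift all four statistics. Whole-brain models built on the
structural connectome can interpret those shifts mechanistically: a
global coupling `g` scaling the anatomical weights, node-wise
bifurcation parameters `a_j` controlling local dynamics, and the
spectrum of the linearized system relating network stability to the
structural hub regions.

`hopfbrain` is for computational neuroscientists who want that entire
chain — statistics, generative model, fitting, stability and graph
analysis — as tested, seed-reproducible R functions operating on plain
delimited matrices, with synthetic ground-truth generators so every
estimator can be validated end to end without any empirical data.

## The model

Each region j follows the Hopf normal form with noise, coupled
diffusively through the weighted connectome `C` (max-scaled to 0.2):

    dz_j/dt = z_j [ (a_j + i w_j) - |z_j|^2 ]
              + g * sum_k C_jk (z_k - z_j) + beta eta_j(t)

BOLD is Re(z_j). For `a_j < 0` a node shows noisy damped oscillations,
for `a_j > 0` a limit cycle of amplitude `sqrt(a_j)`. The global
coupling is fitted by minimizing the Kolmogorov–Smirnov distance between
empirical and simulated FCD value distributions; node-wise parameters by
matching each node's proportion of spectral power in 0.04–0.07 Hz
relative to 0.04–0.25 Hz via parallel updates
`a_j <- a_j + 0.1 (p_emp_j - p_sim_j)`. The effective parameter
`a_eff_j = a_j - g S_j` (strength `S_j = sum_k C_jk`) separates local
dynamics from the coupling leak, and the Jacobian at the silent fixed
point, `A = diag(a - gS + iw) + gC`, links hub strength to the most
stable eigenmodes.

## Worked example

```r
library(hopfbrain)

# synthetic core-periphery connectome, 40 regions with 6 hubs
sc <- generateCorePeripherySC(40, 6, hubFactor = 5, density = 0.2,
                              seed = 1)
sc
#> SCMatrix with 40 regions
#>   max weight: 0.2  mean strength: 0.1743
#>   designated hubs: 1, 2, 3, 4, 5, 6

# ground-truth BOLD from the model itself (300 volumes, TR 2 s)
gt <- makeGroundTruthDataset(sc, g = 1.5,
                             list(mode = "homogeneous", value = 0),
                             seed = 7)
unlist(dynamicsSummary(gt$bold, seed = 3))
#>  integration  segregation fluctuations      meanFCD
#>    0.6160000    0.1276298    0.1749633    0.4306309

# linear stability of the fitted model at the silent fixed point
spec <- hopfModelSpec(a = 0, omega = gt$groundTruth$omega, g = 1.5,
                      C = sc)
stab <- eigendecomposeSorted(buildJacobian(spec))
stab
#> StabilityResult: 40 eigenvalues; stable
#>   Re(lambda) in [ -1.513 , -0.02567 ]
round(hubStabilitySummary(stab, nodeStrengths(sc))$correlations, 2)
#> [1] 0.67 0.68 0.71 0.66 0.75
```

Reading the output: the synthetic resting-state run is moderately
integrated (0.62 on a 0–1 scale), weakly modular (Q = 0.13), with
clearly fluctuating global synchrony (m = 0.17) and recurrent
synchronization patterns (mean FCD = 0.43). The linearized network is
stable (all eigenvalue real parts negative down to −1.51), and the
positive correlations (~0.7) between hub strength and the component
magnitudes of the five most stable eigenvectors show the structural hubs
anchoring the most stable directions of the dynamics.

`runFullPipeline()` chains the same stages — per-group dynamics
summaries, homogeneous `g` fit, heterogeneous `a` and `a_eff` fits,
strength–residual regression, stability, and rich-club graph analysis —
from a single config (`defaultRunConfig()`), and
`writeRunReport()` serializes the results with a reproducibility
manifest.

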