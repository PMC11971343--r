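---
title: "Models and methods in polybind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in polybind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`polybind` analyzes dynamic complexes between a disordered polyanionic
chain and a folded cationic domain. This vignette explains the models
behind each stage, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical choices made where
the design was genuinely open. No empirical result is quoted here that
the package's tests and acceptance script do not themselves compute.

## Units and conventions

Internally: lengths in nm, times in ns (trajectory intervals supplied in
ps), rates in 1/s, concentrations in mol/L, temperatures in K, chemical
shifts in ppm, energies in kJ/mol (PMFs in kT). Residue numbering is
1-based; trajectory frames are 0-based with time = index × interval.
Converters live at the I/O boundary only.

## Binding models

The 1:1 stage uses the closed-form bound fraction from total
concentrations (`predict_mean_E_1to1()`). We evaluate the quadratic root
in its conjugate form, `2 g / (s + sqrt(s^2 - 4 g p))`, because the
textbook difference form loses ~4 significant digits by cancellation
when the chain concentration is picomolar — relevant precisely for
excess titrations, where the labeled chain is at 50–100 pM.

The sequential 1:N model (`solve_sequential_populations()`) treats
macroscopic stepwise dissociation constants: populations are geometric
in free ligand, p_i ∝ Π_{j≤i} [G]/K_Dj, and free ligand solves the mass
balance by bisection on [0, [G]_tot]. Bisection is retained over faster
root finders because the bracket is guaranteed and the residual is
monotone; we iterate to machine precision (~200 halvings cost nothing at
this problem size).

The multistate transfer-efficiency model weights per-stoichiometry
efficiencies E_i = α_i Δ⟨E⟩_sat + ⟨E⟩₀. The default α profile
(0, 0.80, 0.91, 0.98, 1) encodes the coarse-grained-simulation result
that the first bound ligand contributes ~80% of the chain's total
compaction and later ligands progressively less; α is fixed during
fitting, mirroring how the profile is obtained independently of the
titration being fitted. Parameters whose standard error exceeds their
estimate are flagged `overparameterized` — with typical titration data
the 1:4 model identifies only K_D1, ⟨E⟩₀ and Δ⟨E⟩_sat, which is the
expected and informative outcome, not a failure.

Weighted least squares uses Levenberg–Marquardt (`minpack.lm`), with
dissociation constants log-parameterized to enforce positivity; standard
errors on K_D are delta-method transforms of the log-scale errors.

### Salt dependence

`fit_salt_dependence()` fits log₁₀K_D against log₁₀(ionic strength); the
slope (positive convention) counts counterions released. Base-10 logs
are a presentation choice — the slope is base-invariant. Errors on K_D
enter as symmetric errors in log space (SE/K_D/ln 10), and the 90%
confidence interval is a linear-regression t-interval; a profile
likelihood would be asymptotically identical for these small, nearly
balanced designs. Ionic strengths are totals including the buffer
contribution (8 mM for the standard Tris buffer).

## Polymer model and efficiency inversion

`saw_nu_distribution()` implements the modified self-avoiding-walk
distance distribution with scaling exponent ν, universal exponent
γ = 1.1615 and segment length b = 0.55 nm. The normalization and
second-moment constants have closed-form moment integrals in terms of
Γ-functions, so the pair (A, α) is solved with a single 1-D root find;
both integral conditions are then verified by quadrature in the tests.
The support is truncated where the analytic tail mass falls below
1e-10.

`mean_efficiency()` integrates P(r)E(r) adaptively; for arbitrary
user-supplied densities the domain is partitioned into 20 panels first,
which makes the quadrature robust to densities much narrower than the
domain (a delta-like test density had been integrated to zero by a
single adaptive pass). `infer_rms_end_to_end()` inverts the map by
bisection on √⟨R²⟩ ∈ [0.1 nm, 3bN]; the map is strictly monotone, so
the root is unique. The scaling exponent for bound chains is a required
argument with no default: a chain compacted by a bound ligand is not in
the free-chain scaling regime, and silently reusing ν ≈ 0.6 would be
wrong more often than helpful.

`interdye_distance_from_backbone()` applies r = d((N+9)/N)^ν with
ν = 0.6, approximating dye linkers as nine effective residues.

## nsFCS and the reconfiguration time

`fit_nsfcs()` fits the three channel-pair correlations globally. In the
short model (lags ≤ 1 μs) each curve carries amplitude, antibunching,
chain-dynamics and triplet terms; τ_cd is shared. The full model adds a
second triplet component and a translational-diffusion denominator with
shared τ_D and aspect ratio s. Chain-dynamics amplitudes are
unconstrained in sign so that the diagnostic pattern — positive in the
autocorrelations, negative in the cross-correlation — is an outcome,
not an assumption. Start values are heuristic (curve amplitudes from
the data, antibunching at −0.8/3 ns, triplet at microseconds) and can
be overridden; the stochastic recovery tests exercise the short model,
which is the one fitted to nanosecond-window data in practice, while
the full model is validated noiselessly (a ~20-parameter global fit
from heuristic starts on noisy data is not reliably convergent, and the
full model's role is extracting triplet times from log-spaced
correlations).

`reconfiguration_time()` converts τ_cd to the chain reconfiguration
time τ_rec by modelling the inter-dye distance as 1-D diffusion in
U(r) = −kT ln P(r) with reflecting boundaries. P(r) from the SAW-ν
model already contains the radial measure, so no extra Jacobian is
applied. The default solver discretizes the Smoluchowski operator with
detailed-balance hopping rates, symmetrizes it, and computes
correlation times spectrally: τ = Σ c_k/λ_k / Σ c_k over the non-trivial
eigenmodes. Both the efficiency-signal and distance correlation times
scale exactly as 1/D, so matching the measured τ_cd is a single
rescaling, and the procedure is deterministic. A seeded
Brownian-dynamics simulation (100 independent walkers, Euler–Maruyama,
index-lookup forces) is provided as an independent cross-check; the two
agree within 3% in the tests. For the sampled BD autocorrelation the
integral is cut at 0.1 with an exponential-tail completion, because the
long-lag tail of a sampled ACF is noise-dominated and integrating it
directly biases τ downward.

The package-wide correlation-time definition for sampled series
(`integrated_correlation_time()`) integrates the normalized ACF by
trapezoid to the first crossing of 0.01 and adds an exponential tail
estimated from a log-linear fit over the last decade of decay; the
cutoff lag and tail correction are recorded as attributes.

## NMR observables

CSPs use the standard ¹H/¹⁵N weighted distance with nitrogen weight
0.154. The normalized CSP sum is a plain ratio of sums over the shared
residue set; its error applies the relative standard error of the
wild-type sum over replicate titrations (sd/mean/√n) to the ratio.

Back-calculation from bond-vector trajectories computes
C(t) = ⟨P₂(μ(t′+t)·μ(t′))⟩ exactly over all time origins via FFT
cross-correlations of the dyadic products μ_aμ_b. A constrained
triple-exponential fit (amplitudes and timescales log-parameterized)
gives the analytic spectral density J(ω) = 2Σ a_kτ_k/(1+(ωτ_k)²). The
amplitude sum is left free below C(0) to absorb librational decay
faster than the sampling interval. Components whose timescales converge
within 5% are merged after fitting — an overparameterized fit on
mono-exponential data otherwise splits one amplitude across twin
components. The default fit window is one tenth of the trajectory
length; plateaued correlation functions (incompletely averaged slow
tumbling) should be refit with an explicit window, which is why it is
exposed.

Rates use the standard dipolar + CSA expressions with CODATA constants,
γ_N negative, r_NH = 0.1041 nm and Δσ = −170 ppm; 600 and 750 MHz
presets are provided. J is treated as even. Uncertainties use block
averaging over N = 10 equal windows, σ_M = √((⟨O²⟩−⟨O⟩²)/N).

The tumbling generator evolves unit vectors by small-step isotropic
rotational diffusion with per-axis kick variance 2D_rot·dt, the kick
projected perpendicular to the current orientation; dt ≤ τ_c/50 is
enforced so discretization error stays below statistical error. The
acceptance-grade check uses 8 independent vectors × 2×10⁵ steps at 5 ps
(1 μs each, τ_c = 5 ns), which brings the combined statistical and fit
error of the back-calculated rates under 5% at both fields.

## Contact kinetics

`detect_contacts()` runs a per-pair hysteresis state machine: formed
below 0.38 nm (minimum heavy-atom distance), broken only above 0.8 nm.
The sequence-separation exclusion (< 4 residues) applies to intra-chain
pairs only — inter-chain pairs have no sequence separation. Events open
at either trajectory end are censored and excluded from lifetime
statistics by default (configurable); mean lifetimes carry a
10-temporal-block error. Minimum-image distances are used when box
dimensions are present. Lifetimes shorter than one frame are not
representable at the sampling interval; this is a resolution limit of
the input, not of the method.

## Stability fits

Chemical denaturation uses the linear-extrapolation two-state form with
sloping baselines; thermal melts use the van 't Hoff two-state form
with ΔH defined at T_m. R = 8.314 J/mol/K; enthalpies in kJ/mol. ΔΔG
from T_m shifts assumes temperature-independent ΔC_p with negligible
change between variants and is evaluated at 298 K; errors propagate
from the T_m and ΔH standard errors to first order.

## Umbrella sampling and free energies

`wham_pmf()` iterates the standard self-consistent weighted-histogram
equations on binned samples until the window free energies change by
less than 1e-8 kT. Default histogram breaks trim the pooled samples at
the 0.1%/99.9% quantiles so edge bins are populated; a genuinely
uncovered interior bin is an error naming the gap. The PMF is zeroed on
the outer 20% of the grid (the unbound plateau), which also makes the
dissociation constant invariant to the additive constant.

`kd_from_pmf()` integrates 4πr²e^(−W/kT) to the bound-region cutoff
with the 1 M standard state. The spherical volume element reflects an
isotropic unbound state for a center-of-mass separation coordinate. The
default cutoff is where W first returns within 0.5 kT of the plateau —
the bound/unbound partition is exposed as a parameter because it is a
modelling choice; for well-depths of several kT the result is
insensitive to it. Uncertainty comes from resampling the per-bin PMF
errors. The umbrella generator presets the window layout (centers every
0.5 nm to 2.5 nm, then every 1 nm to 24.5 nm; k = 10 kJ/mol/nm²) used
for coarse-grained binding runs and samples each biased window by
Metropolis random walk with step size √(kT/k).

`vant_hoff_decomposition()` fits ln K_D versus 1/T: ΔH = R·slope,
ΔS = −R·intercept (dissociation direction, 1 M standard state). No
extrapolation beyond the input temperature range is performed.

## What the generators emulate — and what they do not

The generators reproduce the *statistical structure* each stage
assumes: Gaussian noise on mean efficiencies and CD signals, log-normal
noise on dissociation constants, exact-discretization
Ornstein–Uhlenbeck dynamics for relaxation traces (no Euler error, so
distributional checks are exact), isotropic rotational diffusion for
bond vectors, scripted square-pulse contact episodes with a ramp
through the hysteresis band, and Boltzmann-distributed umbrella
windows. They do not emulate force-field physics, photophysics beyond
the fitted model forms, exchange broadening, or correlated noise;
passing recovery tests therefore demonstrates the correctness and
calibration of the estimators, not the realism of any force field.
Trajectory stand-ins are statistical surrogates and are labelled as
synthetic throughout.

## Problem sizes and determinism

Test and acceptance runs use: 12-point titrations with 30 replicate
fits, 6-point salt series, 8 × 2×10⁵-step tumbling trajectories,
8×10⁵-step Rg traces at 0.5 ns, 600 scripted contact episodes, 3000
samples per umbrella window, and 4–8×10⁶ Brownian-dynamics steps split
over 100 walkers. These sizes put sampling error comfortably inside
each check's tolerance while keeping a full run in tens of seconds.
Every stochastic stage takes an explicit integer seed, and identical
seeds reproduce outputs bit-identically.

## Known limitations

- XTC trajectories are not readable (no installed reader); use DCD or
  multi-model PDB.
- Burst corrections are configurable linear factors; a full
  correction chain (per-channel backgrounds from laser duty cycles,
  γ calibration from stoichiometry fits) is out of scope, as is photon
  time-tag processing.
- The sequential binding model is macroscopic: it does not resolve
  site-level binding or explicit cooperativity mechanisms.
- WHAM per-bin uncertainties are Poisson-count based and ignore sample
  autocorrelation within windows; for strongly correlated samplers they
  underestimate the error.
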