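# polybind

Analysis toolkit for **dynamic, charge-driven protein complexes** between an
intrinsically disordered polyelectrolyte chain (such as the polyanionic
prothymosin α, net charge ≈ −44) and a folded, positively charged domain
(such as the globular domain of linker histone H1.0, net charge +9). Such
complexes bind with well-defined affinity yet without a fixed binding
interface, and their characterization combines single-molecule FRET, NMR,
circular dichroism and molecular simulation. `polybind` implements the full
quantitative chain for users of those experiments:

- **smFRET titrations** — burst transfer efficiencies
  E = n_A/(n_A + n_D) with configurable corrections and stoichiometry-window
  selection; Gaussian decomposition of efficiency histograms; fitting of
  ⟨E⟩ versus ligand concentration with the 1:1 closed-form binding isotherm

  ⟨E⟩ = Δ⟨E⟩_sat · ([G]ₜ + K_D + [P]ₜ − √(([G]ₜ + K_D + [P]ₜ)² − 4[G]ₜ[P]ₜ)) / (2[P]ₜ) + ⟨E⟩₀

  or with a sequential 1:N model, ⟨E⟩ = Σᵢ pᵢ (αᵢ Δ⟨E⟩_sat + ⟨E⟩₀), whose
  populations pᵢ solve the coupled stepwise equilibria
  K_Dᵢ = p₍ᵢ₋₁₎[G]/pᵢ under ligand mass balance.
- **Counterion release** — Lohman–Record analysis: the slope of
  log₁₀ K_D versus log₁₀ ionic strength counts the ions released on binding.
- **Polymer-model inversion** — the SAW-ν end-to-end distance distribution
  P(r) ∝ (r/√⟨R²⟩)^(2+(γ−1)/ν) exp(−α (r/√⟨R²⟩)^(1/(1−ν))), combined with the
  Förster relation E(r) = 1/(1+(r/R₀)⁶), maps measured ⟨E⟩ to chain
  dimensions √⟨R²⟩ and back.
- **nsFCS** — global fits of donor/acceptor auto- and cross-correlations
  with a shared chain-dynamics time τ_cd, and its conversion to the chain
  reconfiguration time τ_rec by diffusive dynamics in the potential of mean
  force U(r) = −k_BT ln P(r).
- **NMR** — chemical shift perturbations
  Δδ_NH = √(ΔδH² + (0.154·ΔδN)²) and normalized CSP sums; single-exponential
  relaxation-decay fits; and back-calculation of ¹⁵N R₁, R₂ and hetNOE from
  amide bond-vector trajectories via the P₂ orientation correlation, a
  triple-exponential spectral-density model and the standard dipolar + CSA
  expressions (r_NH = 0.1041 nm, Δσ = −170 ppm), with block-averaged errors.
- **Contact kinetics** — dual-cutoff (0.38 / 0.8 nm) hysteresis detection of
  residue–residue contacts in trajectories, lifetime distributions,
  per-residue contact profiles, bound-ligand counting (1.3 nm criterion) and
  the correlation time of radius-of-gyration fluctuations.
- **Protein stability** — mean-residue-weight ellipticity conversion,
  two-state chemical and thermal (van 't Hoff) denaturation fits, and ΔΔG
  from melting-temperature shifts.
- **Free energies** — WHAM reconstruction of umbrella-sampling PMFs,
  dissociation constants by K_D⁻¹ = N_A ∫ 4πr² e^(−W(r)/k_BT) dr, and van 't
  Hoff ΔH/ΔS decomposition of K_D(T).

Every analysis stage has a seeded synthetic-data generator
(`make_titration()`, `make_tumbling_vectors()`, `make_ou_trace()`,
`make_contact_frames()`, `make_umbrella_samples()`, ...) that produces data
with the statistical structure the stage assumes and records its true
parameters, so the whole pipeline is testable end to end without external
data.

## Worked example

Fit a synthetic excess titration (trace-labeled chain, ligand to 100 μM)
generated at a true K_D of 17 μM, then invert the free-chain transfer
efficiency into chain dimensions and quantify the salt dependence:

```r
library(polybind)

g_tot <- 10^seq(-7, -4, length.out = 12)
tit <- make_titration(17e-6, E0 = 0.334, dE_sat = 0.21,
                      g_tot_M = g_tot, p_tot_M = rep(1e-10, 12),
                      noise_sd = 0.005, seed = 1)
fit_titration(tit, model = "1to1")
#> binding_fit (1to1 model)
#>  parameter     estimate           se overparameterized
#>     kd_app 1.663689e-05 1.532836e-06             FALSE
#>         E0 3.338143e-01 2.053939e-03             FALSE
#>     dE_sat 2.133827e-01 5.692657e-03             FALSE

infer_rms_end_to_end(0.334, nu = 0.598, N = 54, R0 = 5.4)
#> [1] 7.432026

ss <- make_salt_series(1e-6, 4.6, c(0.06, 0.09, 0.13, 0.18, 0.24, 0.30),
                       noise_sd_log = 0.05, seed = 2)
fit_salt_dependence(ss)$ions_released
#> [1] 4.619476
```

The fitted `kd_app` of 16.6 ± 1.5 μM recovers the 17 μM truth within one
standard error; a free-chain ⟨E⟩ of 0.334 corresponds to a root-mean-square
end-to-end distance of 7.4 nm for the 54-residue inter-dye segment at
ν = 0.598; and the log–log salt fit returns ≈ 4.6 counterions released.

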