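# cortexshape

Quantitative image analysis of actomyosin cortices reconstituted inside
giant unilamellar vesicles (GUVs).  Starting from two-channel (membrane,
actin) timelapse stacks of the liposome mid-plane, the package measures how
the architecture of the actin cortex — Arp2/3-nucleated branched networks,
mDia1-nucleated linear filaments, or composites of the two — controls force
generation and membrane deformation, and it estimates the cortex tension
from a closed-form mechanical model.  A synthetic scene generator renders
ground-truth liposomes so every analysis stage can be validated without any
microscopy data.

## What it measures

* **Network contraction** — multi-pass cross-correlation PIV on the actin
  channel, and the cumulative compressive strain
  ε(t) = −Σ<sub>t′≤t</sub> ∫ min(∇·u, 0) dA / ∫ dA over the liposome
  interior, plus the cortical flow speed v<sub>act</sub> near the membrane.
* **Cortex architecture** — structure-tensor director fields and the
  nematic order parameter S = ⟨cos 2θ⟩ (1 = aligned linear filaments,
  0 = disordered branched mesh).
* **Membrane shape** — sub-pixel contour extraction; circularity
  C = 4πA/L², membrane strain ε<sub>memb</sub> = 1 − C; actin polarity
  P<sub>act</sub> = |r<sub>act</sub> − r<sub>c</sub>|/R, the normalized
  offset of the intensity-weighted cortical actin centroid.
* **Deformation spectra** — the angular deformation amplitude
  u(θ,t) = R(θ,t) − ⟨R⟩<sub>θ</sub>, its power spectrum
  ⟨|u(q)|²⟩<sub>t</sub> ∼ (κq⁴ + γq²)⁻¹ with the scaling exponent α
  (q⁻⁴: bending/elasticity-dominated; q⁻²: tension-dominated), the
  characteristic deformation size θ<sub>c</sub> (first zero of the angular
  autocorrelation), and Pratt circle-fit local curvature.
* **Cortex thickness** — the sub-resolution estimator
  h = 2(Δ − δ) with δ = (σ²/h) ln[(I<sub>out</sub> − I<sub>S</sub>)/(I<sub>V</sub> − I<sub>S</sub>)],
  solved exactly as h = Δ + √(Δ² − 2σ² ln r), from averaged membrane/actin
  line profiles and the bead-calibrated PSF width σ.
* **Cortex mechanics** — order-of-magnitude energies
  F<sub>bend</sub> = Eh³δ²/ξ<sub>c</sub>²,
  F<sub>stretch</sub> = Ehξ<sub>c</sub>²δ²/R² (1 + ξ<sub>c</sub>²/R²),
  F<sub>memb</sub> = γ<sub>m</sub>ξ<sub>c</sub>²δ/R; cortex tension
  γ<sub>c</sub> = hσ<sub>act</sub> from the work balance
  W ∼ hσ<sub>act</sub>ξ<sub>c</sub>²δ/R and, independently, from the
  flow-friction balance f<sub>fric</sub> = ζv<sub>act</sub> with
  ζ = η<sub>m</sub>N<sub>link</sub>/(4πR²); and membrane binding-site
  budgets for His-tagged nucleators.

## Worked example

```r
library(cortexshape)

# a mixed-architecture liposome cohort with known ground truth
coh <- synthesize_cohort("mixed", n = 2, seed = 42, n_frames = 4)
res <- run_timelapse_analysis(analysis_config(), coh$scenes)
merge(res$per_liposome, coh$truth, by = "id")[,
  c("id", "eps_memb_max", "eps_memb_max_true", "P_act_max",
    "polarity_true", "alpha", "h_um", "h_true_um")]
```

```
        id eps_memb_max eps_memb_max_true P_act_max polarity_true    alpha      h_um h_true_um
1 mixed_01   0.01806185             0.018 0.3002365           0.3 3.444446 0.3082526 0.3092736
2 mixed_02   0.01797871             0.018 0.3005745           0.3 3.203355 0.2574303 0.2622179
```

Each row is one rendered liposome: the maximum membrane strain recovered
from the extracted contours (0.0181 and 0.0180) matches the generated
strain of 0.018 to three decimals, the measured actin polarity matches the
painted 0.30 pattern, the spectral exponent sits in the bending-dominated
regime the scenes were drawn from, and the two-peak thickness estimator
recovers the per-scene cortex thickness within a few percent.

The closed-form mechanics on typical inputs (R = 20 µm, h = 0.29 µm,
δ = 1.1 µm, ξ<sub>c</sub> = 9.7 µm, E = 4×10³ Pa):

```r
en <- deformation_energies(mechanics_inputs(xi_c_m = 9.7e-6))
en$F_bend_J
#> [1] 1.254573e-18
cortex_tension_from_flow()$gamma_c_N_per_m
#> [1] 6.394381e-05
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/cortex-shape.R simulate --preset mixed --n 5 --out scenes
Rscript inst/cli/cortex-shape.R run --scenes scenes --out cohort
Rscript inst/cli/cortex-shape.R shape --membrane ch0.tif --actin ch1.tif
```

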