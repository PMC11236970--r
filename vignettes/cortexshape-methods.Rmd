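---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cortexshape)
```

This vignette is the package's account of its science: the measurement
models behind each module, the conventions and defaults that matter, what
the synthetic scenes do and do not emulate, and the choices made where the
design was genuinely open.

## The system

A giant unilamellar vesicle (GUV, radius 10–30 µm) encapsulates purified
actin, myosin II and nucleators anchored to the inner leaflet through
His-tag–Ni-NTA lipid links.  Arp2/3 plus a membrane-bound VCA fragment
nucleates a branched, membrane-linked cortex; mDia1 nucleates linear,
weakly linked filaments; mixtures produce composite architectures.  When
myosin is activated, contractile stresses in the cortex deform the
membrane — or fail to, depending on whether the architecture can generate
force (linear filaments) and transmit it to the membrane (branches and
links).  The analysis reduces two-channel timelapse images (membrane dye,
fluorescent actin; 0.0938 µm/px and 6 s frame interval by default) to a
small set of per-liposome readouts: compressive strain of the actin
network, nematic order of the cortex texture, membrane strain and actin
polarity, deformation spectra and sizes, cortex thickness, and closed-form
tension estimates.

## Coordinates and containers

Images are base-R matrices `[row, col]` with the origin at the top-left;
physical coordinates are `x = col * pixel_size`, `y = row * pixel_size`,
and angles are measured counter-clockwise from +x in that frame.  Contours
(`membrane_contour`) are closed counter-clockwise polygons in µm whose
centre of mass is the plain vertex average \(r_c = N^{-1}\sum r_i\); area
comes from the shoelace formula and the perimeter from the segment sum.

## Synthetic scenes

The generator provides ground truth for every stage; its defaults are the
conditions the analyses are validated under.

**Contours.** `sample_contour_series()` draws
\(r(\theta) = R + \sum_{q\ge2} \mathrm{Re}[a_q e^{iq\theta}]\) with
independent complex amplitudes of variance \(\propto (\kappa q^4 + \gamma
q^2)^{-1}\) — the Helfrich form, so \(\kappa\)-dominated ensembles have a
\(q^{-4}\) spectrum and \(\gamma\)-dominated ensembles \(q^{-2}\).  Modes
q = 0 (area) and q = 1 (translation) are excluded: the analysis measures
shape, not size or position.  The overall scale is set by `u_rms_um`
(default 2% of R, the scale of cortex-driven deformations on ~20 µm
liposomes).  Self-intersection cannot occur while \(r > 0\); draws
violating \(r > 0.2R\) are rejected and resampled with a bounded budget.

**Rendering.** `render_two_channel_frame()` builds both channels from the
signed radial distance s to the contour (positive outside).  The membrane
is a PSF-blurred thin shell; the actin channel is the step profile
I<sub>out</sub> (s > 0), I<sub>S</sub> (−h < s ≤ 0), I<sub>V</sub>
(s ≤ −h) convolved analytically with a Gaussian of width σ along the
normal.  This 1D blur is exact for a straight edge; curvature corrections
are O(σ/R) ≈ 0.6% and neglected.  Poisson shot noise (camera gain 0.01)
plus Gaussian read noise gives SNR ≈ 20 at the cortex peak, typical of
spinning-disk confocal data.  The default surface-to-volume intensity
ratio is I<sub>S</sub>/I<sub>V</sub> = 4, the mid-range of well-formed
cortices (reported ratios span roughly 1.8–7.7); cohort scenes use 7.7,
the well-localised-cortex regime to which deformation analysis is
restricted.  The ratio is configurable.

**Speckles, filaments, polarity, beads.**  Speckle pairs advect Gaussian
particles exactly under translation, radial contraction (u<sub>r</sub> =
−kr, divergence −2k) or rigid rotation, and return the analytic
displacement truth on a PIV grid.  Filament textures draw segment
orientations from a wrapped-normal distribution on the doubled angle whose
mean resultant equals the target order; the realized per-draw mean of
cos 2θ is recorded as truth.  Polarized cortex patterns solve a profile
contrast (cosine or lit-arc family) so the intensity-weighted centroid
offset over the actual polygon equals the requested polarity to 1e-6.
Bead images place Gaussian spots with ≥ 6σ separation for PSF calibration.

## PIV and strain

`piv_displacement()` is classical multi-pass normalized cross-correlation:
interrogation windows of a decreasing cascade (defaults 100/200, 60/120,
48/96 px; 16 or 32 px final windows for cortical flow) matched within
search windows, FFT correlation normalised by integral-image local sums,
and three-point Gaussian sub-pixel peak interpolation.  Coarse passes seed
the search offsets of finer passes.  Quality control: peak correlation
≥ 0.6; the secondary correlation peak must stay below 80% of the primary
(`noise = 0.20`); neighbourhood-median outliers beyond 5 robust residuals
are rejected.  These mirror the nominal parameter values used with the
common plugin implementations, whose exact semantics are plugin-specific;
failing vectors are marked invalid, never zero.

`divergence_field()` fits a local least-squares plane to each velocity
component over a 3×3 node neighbourhood and sums the fitted slopes.  The
plane fit is exact for affine flows on any neighbourhood (including
asymmetric edge neighbourhoods), exact for quadratics on symmetric ones
(so convergence is second order), and pools the sub-pixel noise that raw
differencing amplifies.  Invalid vectors are neighbour-interpolated for
differencing only, never for reporting, so dropouts do not bias the
strain.

`cumulative_compressive_strain()` integrates only the negative part of the
divergence over the liposome interior,
\(\epsilon(t) = -\sum_{t'\le t} \overline{\min(\nabla\cdot u, 0)}\),
summing per-frame-pair displacement fields on the fixed Eulerian grid.
Clipping (rather than discarding frames) keeps ε non-decreasing under
expansion noise, matching its meaning as a *compressive* strain; Eulerian
summation is adequate because frame-to-frame motion is at most a few
pixels.  The strain rate is the forward difference over the frame
interval.

## Orientation and nematic order

`orientation_field()` computes the structure tensor from
Gaussian-derivative gradients smoothed at `tensor_sigma_px` (default 2 px).
The director is the eigenvector of the smaller eigenvalue (along ridges),
wrapped to [−π/2, π/2); coherence is the normalised eigenvalue anisotropy,
and directors below `coherence_cutoff = 0.2` are invalid.

`nematic_order()` averages \(S = \cos 2\theta\) over the four axial
neighbours at a configurable lattice spacing (default: the tensor window;
analyses here use 4 px).  The reference axis required by
\(S = \langle\cos 2\theta\rangle\) is a genuine design choice:

* measuring θ against the *central point's own director* ("pairwise")
  looks natural but squares the order parameter for uncorrelated
  neighbours — \(E[\cos 2(\theta_i - \theta_j)] = S^2\) for independent
  draws — so a disordered texture would not read 0 against a realized
  order of 0, and a texture of order 0.3 would read ~0.09;
* measuring θ against the *mean director axis of the analysed region*
  (the principal axis of the average nematic tensor) is equally
  frame-independent — rotating the image rotates the reference with it —
  and reproduces the aligned-vs-disordered interpretation exactly: an
  aligned field reads 1, a disordered one 0 in expectation, a fraction-f
  aligned mixture reads f, and synthetic textures read their realized
  order.

The mean-axis reference is therefore the default and the headline
statistic; the pairwise variant remains available (`reference =
"pairwise"`) for sensitivity.  Estimator biases at the extremes are known
and documented by the tests: filament end-caps contribute perpendicular
directors (−0.05 to −0.09 at S = 1) and mean-axis overfitting inflates
S ≈ 0 textures by up to ~+0.1; in the 0.25–0.45 range where cortex
architectures are compared, recovery is within ±0.05.  Whether all pixels
or only high-coherence pixels enter the average is configurable via the
mask; raising the coherence cutoff preferentially retains isolated
(aligned) filaments and biases mixtures upward, so the default keeps the
cutoff low.

## Contour extraction and shape metrics

`extract_contour()` traces the membrane ring by radial ray casting: a
threshold/largest-component initialisation, then per-angle intensity peaks
localised by three-point Gaussian fits, a centre re-estimate, and a second
ray cast about the updated centre.  Gaps longer than 25° abort with the
gap location; shorter gaps are interpolated periodically.  An optional
angular low-pass (`smooth_modes`; the pipeline keeps modes ≤ 60) removes
per-vertex localisation noise, which otherwise inflates the perimeter and
hence the membrane strain by ~1×10⁻³; the analysed deformation band
(q ≤ 24) is untouched.  The default N = 360 vertices (1° resolution) keeps
the polygonal circularity error of a circle below 1e-4.

Membrane strain is ε_memb = 1 − C with C = 4πA/L²; the maximum radial
deformation R_max/⟨R⟩ and ⟨R⟩ come from the radial decomposition
u(θ) = R(θ) − ⟨R⟩ on a uniform angular grid (ray casting from the centre
of mass; non-star-shaped contours are refused rather than silently
re-parameterised).  Actin polarity samples the cortical intensity in a
±3 px band along the inward normal at each vertex.  Because the volume
and exterior signals add a θ-independent term that dilutes the centroid
offset, the band mean is background-corrected by the average of two
reference bands just inside and just outside the cortex; with this
correction the painted polarity is recovered within ±0.003.  The
normalising radius is the initial-frame mean radius, held fixed per
liposome.  Cohort summaries exclude liposomes with ⟨R⟩ below 17.5 µm
(configurable): small liposomes pay a relative bending cost h²/R² too
high for measurable deformation, and the analysed size class is ~35–55 µm
diameter.

## Spectra, deformation size, curvature

The power spectrum is the squared FFT of u(θ) per frame, averaged over the
first 20 post-activation frames by default, one-sided and normalised as
P(q) = 2|U_q|²/N so that Parseval reads \(\sum_{q\ge1} P(q) = N\,
\mathrm{var}_\theta(u)\).  Only the q-dependence matters for the scaling
exponent, which is the negative log–log least-squares slope over q ≥ 2
(q = 0, 1 are removed at decomposition).  For synthetic scenes the
pipeline fits q = 2..24, the generated band; higher modes of extracted
contours sit on the vertex-noise floor.  The Helfrich-form fit
\(P(q) = 1/(\kappa' q^4 + \gamma' q^2)\) is nonlinear least squares in log
space with non-negativity bounds; the amplitude is absorbed (only the
two-parameter family is identifiable), one-parameter degenerate fits are
flagged, and the crossover mode \(\sqrt{\gamma'/\kappa'}\) is reported.

The angular autocorrelation is computed circularly per frame; the first
zero crossing (sign change, linearly interpolated) gives that frame's
deformation size, and θ_c is the minimum over frames with t′ its frame
index.  Normalisation by the variance cannot move a zero crossing; the
normalised ACF is returned so both conventions are available.

Local curvature fits a circle through each vertex and its ±`separation`
neighbours with the Pratt algebraic fit and signs it by the local turning
direction.  The spacing of the "three separated points" is not canonical;
the default separation of 5 vertices (≈5° at N = 360) is exposed, and the
total-turning invariant \(\oint \kappa\, ds = 2\pi\) (within 1%) holds
across separations.  Collinear triplets return curvature 0 and are
flagged.

## Cortex thickness

The estimator follows the established two-peak linescan method for
sub-resolution cortices.  Averaged membrane/actin profiles along inward
normals (bilinear sampling, per-ray alignment at the Gaussian-fitted
membrane peak) give the peak distance Δ, the cortex peak I_S and the
plateaus I_V (interior) and I_out (exterior).  The textbook relations
δ = (σ²/h) ln r with r = (I_out − I_S)/(I_V − I_S) and h = 2(Δ − δ) are
mutually dependent; substituting gives the quadratic
h² − 2Δh + 2σ² ln r = 0, solved exactly with the root
h = Δ + √(Δ² − 2σ² ln r) — the branch with h → 2Δ as σ → 0.  Two
practical points:

* the *observed* peak height of a sub-resolution shell underestimates the
  true plateau I_S, which would corrupt ln r; `estimate_cortex_thickness()`
  inverts the step-profile convolution at the peak and iterates h and I_S
  to joint consistency (a few iterations);
* the sign convention asserts an interior actin peak (Δ > 0); violations
  are reported, never silently flipped.

σ comes from 2D Gaussian fits to isolated sub-resolution beads
(`psf_sigma_from_beads()`, with separation and saturation filters); the
default σ = 0.119 µm matches a typical spinning-disk PSF SD.  Round-trip
accuracy is within 10% for h between 0.15 and 0.6 µm at SNR ≥ 20.

## Mechanics

All scaling formulas are evaluated in SI with unit prefactors, as
order-of-magnitude estimates — that is how they are used.  On the typical
inputs (R = 20 µm, h = 0.29 µm, δ = 1.1 µm, ξ_c = 9.7 µm from θ_c = 28°,
E = 4×10³ Pa, γ_m = 10⁻⁷ N/m) the bending energy evaluates to
1.25×10⁻¹⁸ J and the membrane term to ~5×10⁻¹⁹ J.  The stretching term is
ambiguous as printed: with a unit prefactor the multiplicative reading of
the geometric factor gives ≈4×10⁻¹⁶ J and the divisive reading
≈2.7×10⁻¹⁶ J, an order above the quoted ≈8×10⁻¹⁷ J; both readings are
implemented behind `stretch_geom_factor`, and tension work that needs the
component energies takes them as explicit inputs rather than deriving them.
The energy-route tension is γ_c = W·R/(ξ_c²δ) (h cancels); the flow route
is γ_c = h·ζ·v_act with ζ = η_m N_link/(4πR²).  On the typical inputs the
two routes give 1.6×10⁻⁵ and 6.4×10⁻⁵ N/m — consistent within an order of
magnitude, which is the claim the model supports.  Binding budgets count
lipids (head group 0.55 nm²), Ni-NTA anchors, encapsulated protein copies
and footprint-limited bound protein (4R²/r_prot²).

## Cohort presets and what passing tests show

`synthesize_cohort()` builds three regimes: `arp23` (κ-dominated spectrum,
order 0.29, polarity 0.10, strain 0.006), `mdia1` (γ-dominated, order
0.39, polarity 0.20, strain 0.009) and `mixed` (κ-dominated with crossover
mode 5, order 0.43, polarity 0.30, strain 0.018).  Per scene, independent
per-frame mode draws grow under a linear contraction ramp whose final
scale is solved so the realized maximum membrane strain equals the preset;
polarity is painted on the cortex and the surface texture is a filament
image at the preset order.  The analytic regime truths (fitted α of the
sampling law; first zero of its expected ACF) give the preset orderings
θ_c: mdia1 < mixed < arp23 and α: mdia1 < mixed < arp23, which the
pipeline must reproduce with zero rank inversions on a 30-scene cohort
(n = 10 per condition, 8 frames — sizes chosen so the full cohort runs in
about two minutes).

The scenes emulate near-circular liposomes with low-mode Helfrich
deformations, a uniform sub-resolution cortex with an angular intensity
modulation, and Poisson–Gaussian camera noise.  They do not emulate:
out-of-plane (3D) deformation, z-drift or defocus, photobleaching,
cortex coarsening into discrete asters/aggregates, volume network
textures, membrane tubes, or liposome-to-liposome variation in imaging
background.  Passing recovery tests therefore demonstrates estimator
correctness under the stated image-formation model, not robustness to
every pathology of real microscopy; the quality filters (contour gap
tolerance, PIV vector validation, ray dropouts) are the mechanisms real
data would exercise harder.

## Numerical conventions and degenerate inputs

Sub-pixel peaks use three-point Gaussian (log-parabolic) interpolation
with a parabolic fallback; featureless PIV windows yield invalid vectors,
not zeros; flat images yield zero-coherence orientation fields; blank
channels, broken rings, non-star-shaped contours, empty masks, too-coarse
grids, unreachable polarity targets and inconsistent thickness profiles
all raise informative errors rather than returning numbers.  All
randomness flows from explicit per-call seeds (restored afterwards), so
identical configurations produce byte-identical outputs; cohort outputs
carry the configuration hash.

## Known limitations

* PIV assumes conserved speckle texture between frames; strong
  polymerisation/depolymerisation between frames violates it.
* The radial-distance renderer and ray-cast contour extraction assume
  star-shaped liposomes; strongly budded or tubulated shapes need a
  different parameterisation (arc length), which the API signals
  explicitly rather than substituting silently.
* The thickness model assumes a single uniform shell; double cortices or
  strong volume gradients break the three-plateau profile.
* Fitted κ′ and γ′ are in arbitrary units unless the spectrum is
  calibrated; only α and the crossover are interpreted.
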