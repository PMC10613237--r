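---
title: "Tracing multiple scattering with reflection matrices: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing multiple scattering with reflection matrices: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mstrace)
```

## The problem

An object buried a few scattering mean free paths deep inside tissue-like
media is essentially invisible to confocal imaging: the ballistic waves that
carry undistorted object information decay as `exp(-z/l_s)`, and the
time-gated backscattered field is dominated by multiply scattered light.
`mstrace` implements a matrix method that *uses* that multiply scattered
light instead of filtering it out. The medium above the object is modelled
as a discrete stack of thin phase plates; identifying the per-plate phase
functions from a measured (or simulated) reflection matrix is equivalent to
identifying the medium's transmission matrix, whose structural inverse
converts the multiply scattered contributions back into ballistic signal and
yields a diffraction-limited object image.

## Forward model

All fields live on an `n x n` lateral grid with pitch at most half a
wavelength (`make_grid()`). The medium is an ordered stack of plates at
depths `z_1 < ... < z_N` above the object plane `z_0 = 0`; plate `k` applies
the diagonal unit-modulus factor `exp(i phi_k(rho))` and the wave then
propagates to the adjacent plane by the exact angular-spectrum transfer
function `exp(i k_z d)`, `k_z = sqrt(k0^2 - k_par^2)`. The one-way operator
is `T = T_1 T_2 ... T_N` with `T_k = P_k Phi_k`, and the time-gated
reflection matrix of an object with diagonal amplitude reflectance `O` is

    R = T^T O T,

symmetric by reciprocity. Columns index illumination points, rows detection
points. Time gating enters as the modelling assumption that intra-medium
back-reflections and absorption are negligible, not as a temporal
simulation.

Two representation choices matter and are deliberate:

* **Unit-modulus propagation.** The transfer function is `exp(i k_z d)` on
  the propagating band and exactly `1` (zero phase advance) on the
  non-propagating remainder of the discrete frequency square. Free space
  does not absorb: with this convention every propagation operator is
  exactly unitary, symmetric and invertible, so correcting a synthetic
  matrix with its ground-truth stack recovers the object diagonal to
  machine precision — the identity the whole method rests on. The
  objective's circular pupil (`NA * k0`) is kept as grid metadata and used
  where a measurement aperture, passband projection or probe basis is
  meant; it is never part of free space.
* **Measurement aperture as an explicit step.** Because free space leaves
  non-propagating content in place under the unit-modulus convention, a
  focused probe keeps a non-defocusing component that would return to the
  confocal pixel regardless of scattering — something a real objective
  never records. `reflection_from_medium(aperture = "pupil")` therefore
  band-limits both matrix sides (`Pi R Pi`) to the objective's angular
  coverage, and all measurement-emulation studies (including the phantom
  below) use it. The default `aperture = "none"` keeps the bare model,
  for which `diag(R) = O` without a medium and the structural inversion
  are exact identities.
* **Periodic, same-lattice operators.** Propagation is carried out on the
  periodic grid without zero-padding. Padding plus cropping would lose
  energy and break unitarity, composition and reciprocity at the `1e-9`
  level the rest of the package relies on; the periodic operator satisfies
  them exactly. `angular_spectrum_propagate(..., pad = TRUE)` remains
  available for one-off field propagation where wrap-around suppression
  matters more than exact invariants. A consequence of the same-lattice
  choice is that plates are sampled on the object grid: recovered phase
  maps live on the region-of-interest window, and the circular
  field-of-view masks of diameter `L_k = L0 + 2 z_k tan(asin(NA_eff))` are
  clipped to it.

## The reconstruction loop

`mst_iterate()` starts from `R` referenced to the object plane. For each
layer `k` the matrix is re-referenced so its columns index virtual sources
in the plate plane (`transform_to_layer()`), the spherical-wave curvature of
each column is removed against the band-limited free-space Green's function
(`normalize_by_greens()`), and the resulting matrix `S` is fit by a rank-1
phase model `S ~ o %o% exp(i phi)`: the phase of the dominant right singular
vector, found by power iteration, is the phase-function increment. The
increment (piston-pinned at the grid origin, confined to the layer's
circular field of view) is compensated on the input side; after all layers,
the output path is processed identically through the matrix transpose, and
the cycle repeats until the increments' RMS falls below tolerance.
Accumulated increments per layer are the identified phase functions
`phi_k^c`; the identified stack corrects the original matrix by structural
inversion (`corrected_reflection()` — the reversed product of conjugated
unitary factors, never a dense numerical inverse), and the diagonal of the
corrected matrix is the reconstructed object.

### Green's normalisation: phase-only default

The normalisation's purpose is to remove the spherical curvature so that
column-to-column phase differences reveal the plate. The literal entrywise
division by `G` also *rescales amplitudes* by `1/|G|`, which near the nulls
of the band-limited point response amplifies the unmodelled
multiple-scattering term by orders of magnitude; measured on the four-plate
phantom below, the first-visit phase estimates then correlate with truth at
only ~0.2 and the loop diverges. The package therefore defaults to
multiplying by `conj(G)/|G|`: curvature is cancelled, `|G|` stays in place
as an entry weight. Because the unmodelled term has roughly uniform variance
per entry, this is the matched filter for the rank-1 fit; the phase of the
dominant singular vector is unbiased (the per-column weights are real and
positive), and noiseless single-plate recovery remains exact. The literal
division (with a configurable amplitude mask, default: drop entries with
`|G|` below half its median) is available as `normalization = "amplitude"`.

### Loop controls and defaults

| parameter | default | why |
|---|---|---|
| power iteration start | all-ones vector | unbiased; converges to the dominant singular pair |
| power iteration stop | rel. change `1e-6`, max 30 steps | the estimate's phase stabilises well before the amplitude |
| cycle stop | max RMS increment `< 0.01` rad, max 20 cycles | increments are pure noise below this level |
| layer order | nearest-to-object outward | near layers have the finest mapping resolution and stabilise early cycles |
| piston reference | grid origin; fallback to strongest column | the reference must carry object signal |
| FOV masking | on, during estimation | pixels outside the illumination cone are unconstrained |

The input and output passes accumulate per-side estimates of the same
physical plates; the reported `phi_k^c` is their mean (the two coincide at
convergence for a reciprocal matrix).

## Diagnostics

* `ballistic_fraction()` (`eta_T`): diagonal power fraction of the
  transmission matrix in the spatial-frequency basis;
  `optical_thickness() = -log(eta_T)` is the one-way thickness in
  scattering mean free paths, and `xi1 = eta_T^-2` the roundtrip ballistic
  enhancement delivered by rectifying the identified stack.
  `ballistic_fraction_probe()` estimates the same ratio from a strided
  subset of plane-wave probes when the dense matrix is too expensive.
* `confocal_enhancement()` (`eta_c`): corrected-to-uncorrected confocal
  diagonal power ratio. Because the uncorrected diagonal contains
  substantial multiple scattering, `eta_c` underestimates the ballistic
  enhancement; `xi2 = eta_c / alpha` rescales it by the ballistic
  contribution `alpha` of the uncorrected diagonal.
* `ballistic_contribution_alpha()`: `alpha` is estimated by restricting a
  reference transmission matrix to its frequency-diagonal
  (direction-preserving) component `T_b` and predicting the ballistic
  confocal diagonal as `diag(T_b^T O T_b)`. This is a strict
  ballistic-only construction: scattered light that happens to return to
  the confocal pixel is excluded. Published analyses of this quantity
  acknowledge the estimator is ambiguous when the ballistic signal is
  weak; different defensible constructions move `alpha` (and hence `xi2`)
  by tens of percent, which is why `xi2` carries a much wider tolerance
  than `xi1` in our own tests.
* `angular_spread_function()`: the spatial-frequency intensity of a
  normally incident plane wave at depth; its central pixel is the
  ballistic component, and the corrected-to-uncorrected central ratio at
  the object plane measures the one-way ballistic gain.
* `pearson_score()`: intensity-mode Pearson correlation, or the magnitude
  of the normalised complex covariance of `exp(i phi)` maps
  (piston-invariant) for phase functions.

## The synthetic phantom

The generator emulates the numerical study the package is validated
against: four Gaussian-correlated random phase plates at
`{35, 50, 70, 100}` um above a Siemens-star reflectance target,
`lambda = 0.9` um, `NA = 1.0`, the stack calibrated to a one-way optical
thickness of `3.3 l_s` as measured from its own transmission matrix
(`calibrate_plate_strength()`, a bracketed root find on the probe-measured
`eta_T`).

Two generator choices are fixed a priori and deserve justification:

* **Grid `64^2` at half-wavelength pitch** (`L0 = 28.8` um). Dense
  reflection matrices scale as `N0^6` in compute; `64^2` is the scale at
  which the full study runs on a single CPU in minutes while keeping the
  deepest plate resolvable (see below).
* **Correlation length 2 um.** The plate maps stand in for subcellular
  refractive-index texture; at this strength (about `0.9` rad per plate)
  and correlation length, four plates produce the stated `3.3 l_s` with
  phase features several pixels wide — well clear of both the lattice
  scale and the region-of-interest scale. In the physical cone geometry
  the region of interest also acts as the aperture for quantifying a
  plate at depth `z_k` (effective aperture `L0/(2 z_k)`, the
  [mapping_resolution()] relations); on the periodic same-lattice
  representation the re-referenced point sources are exact, so the
  practical recovery limit is instead fidelity, discussed next.

What the phantom does **not** emulate: volumetric (continuous) scattering
between plates, absorption, intra-medium back-reflections, detection noise
of the interferometric chain, and plates larger than the periodic cell.
Passing tests therefore demonstrate correctness of the operators and the
estimator on media that truly are discrete phase-plate stacks, plus
robustness to object-uncorrelated clutter (`add_background_scattering()`);
they do not by themselves certify performance on real tissue.

## Numerical choices and degenerate inputs

* All dense kernels run through compiled per-column 2D FFTs; `32^2`-grid
  results agree with explicit dense-operator products to `1e-10`.
* Fourier conventions are unitary throughout, so Parseval-type identities
  and basis invariance of the metrics are exact.
* Wrapped phases are stored in `(-pi, pi]`; accumulated phase maps are
  additionally kept unwrapped for visualisation.
* A scattering-free matrix converges in one cycle with `xi1 ~ 1`; an
  all-masked normalised matrix, constant-map correlations, zero matrices
  and off-lattice scan positions raise errors rather than returning
  numbers.
* Problem sizes used by the test-suite: unit tests run at `16^2`/`32^2`;
  the full-scale study (one seed in the test suite, three in the
  acceptance script) at `64^2` with at most 5 cycles, which is past the
  observed saturation of `xi1` (within 1% of its 10-cycle value).

### What the reduced scale can and cannot recover

Each phase estimate correlates the unmodelled multiple-scattering term
against the rank-1 object structure over the `N0^2` detection pixels of
the region of interest, so its error variance — and hence the residual
scattering left at the converged fixed point — scales inversely with the
pixel count. The per-plate phase error feeds back as unmodelled
scattering for every other estimate, which is why the loop settles at a
self-consistent noise floor rather than at zero. Concretely: at `64^2`
(4096 pixels) the runs performed by the package's tests and acceptance
script on the `3.3 l_s` phantom leave a residual close to `1 l_s`
(`xi1` just above 100, deepest-plate phase correlation ~0.75, image
correlation ~0.98); rescaling that residual by the pixel-count ratio to a
`100^2` region of interest predicts ~`0.4 l_s` — several hundred-fold
`xi1` — so quantities that depend exponentially on the residual
(`xi1`, the residual thickness itself) change several-fold between the
two scales, while fidelity-insensitive quantities (image correlation,
`xi2`, the consistency `ln xi1 ~ 2 (OD - OD_residual)`) transfer well.
The `64^2` size is the package's choice of problem scale; the full-scale
matrix is ~15x the compute (the matrix pipeline scales as `N0^6`).

## Known limitations

* The identified phase maps are limited to the region-of-interest window;
  the full cone-geometry field of view of shallow, large plates is not
  represented on the periodic lattice.
* `alpha` (and so `xi2`) is estimator-dependent, as discussed above.
* Depth positions of the plates are inputs; only the single-plate depth
  scan (`sweep_depth()`) is provided for localisation.
* The per-cycle `xi1` trace uses the probe estimator (192 modes by
  default) and can differ from the dense value by a few percent;
  final reported values should use the dense matrix or a large probe set.
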