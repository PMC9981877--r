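---
title: "Models and methods behind uvqdpc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uvqdpc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(uvqdpc)
```

# The imaging model

`uvqdpc` models a reflection-geometry microscope for the UVC band built
around a mirror-based (Cassegrain-type) objective. Two features of that
design drive everything else in the package:

* the secondary mirror obscures the center of the pupil, so the pupil is an
  **annulus** between an inner NA (`naObs`, default 0.27) and the full NA
  (default 0.65);
* the sample is probed in **reflection**, so light passes through the
  specimen twice and the effective optical path is doubled.

A thin specimen is described by its complex refractive index: a real
increment $\Delta n$ over the medium and an extinction coefficient $k$ (the
imaginary part). Over a local thickness $t$ the double pass imprints

$$\phi = 2\,\frac{2\pi}{\lambda}\,\Delta n\,t, \qquad
  \mu = 2\,\frac{2\pi}{\lambda}\,k\,t,$$

a phase delay in radians and an amplitude-attenuation exponent. In the UVC
($\lambda$ = 275 nm) protein and nucleic-acid absorption make $k$ values of
order $10^{-4}$ measurable, which is the whole point of working there.

## Partially coherent image formation

Oblique, partially coherent illumination is produced by a rotatable
half-ring mask in a pupil plane: the source $S(u)$ occupies the half of the
annulus with $u \cdot d \ge 0$, where $d = (\cos\theta, \sin\theta)$ is the
mean illumination direction. For a weak object ($\mu$, $|\phi|$ well below
1) the recorded intensity linearizes to

$$\hat I(u) = B\,\delta(u) + h_{abs}(u)\,\hat\mu(u) + h_{ph}(u)\,\hat\phi(u),$$

with $B = \sum_u S|P|^2$ and the weak-object transfer functions

$$h_{abs}(u) = -\bigl[C_1(u) + C_2(u)\bigr], \qquad
  h_{ph}(u) = i\bigl[C_1(u) - C_2(u)\bigr],$$

where $C_1(u) = \sum_{u'} S P^* (u')P(u'+u)$ and
$C_2(u) = \sum_{u'} S P (u')P^*(u'-u)$ are pupil cross-correlations
(`computeWOTF()`). The signs are fixed so that a weak pure absorber darkens
the image: $h_{abs}(0) = -2B$ and $h_{ph}(0) = 0$. For a real source and
binary pupil $h_{abs}$ is real and even and $h_{ph}$ purely imaginary and
odd — both therefore Hermitian-symmetric, as any transfer function of a
real-valued intensity must be. A symmetric (full-ring) source gives
$h_{ph} \equiv 0$: phase is invisible without asymmetric illumination, which
is why four half-ring orientations (0°, 90°, 180°, 270°) are acquired.

`forwardWOTF()` implements this linearized model. `forwardAbbe()` is its
deliberately independent check: a brute-force partially coherent sum of
coherent images $I = \sum_s w_s\,|\mathcal F^{-1}[P\,\hat T(\cdot-u_s)]|^2$
with the exact transmission $T = e^{i\phi - \mu}$ and no linearization. On
weak objects the two agree to a fraction of a percent, and their discrepancy
shrinks quadratically as the object weakens — the signature of the neglected
second-order term. When the Abbe source is subsampled, the points are
stratified uniformly in ring angle; picking every $k$-th pixel in array
order instead subtly biases the effective source shape and tilts the
transfer anisotropy by several degrees (this mattered for the direction
calibration below).

## Grid conventions and numerics

Images are row-major with the origin at the top left; angles are
counter-clockwise from +x (east), i.e. $y$ points up. Frequency arrays are
kept in centered layout with the DC term at `floor(n/2)+1` and a step of
$1/(N\,\Delta x)$ cycles/nm. Both pupil edges are closed
($na_{obs}/\lambda \le |u| \le na/\lambda$) and the half-ring includes its
dividing line, so pixel counts are deterministic. All pupil
cross-correlations are evaluated with 2x zero padding so no lag wraps.
Simulations warn when the pixel pitch exceeds the intensity Nyquist bound
$\lambda/(4\,NA)$ (105.8 nm for the default optics); the default pitch is
100 nm.

# Inversion

`flatfieldCorrect()` forms $d_j = (I_j - B_j)/B_j$ per orientation from the
matching sample-free background frames. `solveQDPC()` then solves, at every
spatial frequency independently, the 2x2 Tikhonov-regularized least squares
problem over the orientations

$$\min_{\hat\mu,\hat\phi}\ \sum_j \|h_{abs,j}\hat\mu + h_{ph,j}\hat\phi -
  B_j\hat d_j\|^2 + \tau_{abs}\|\hat\mu\|^2 + \tau_{ph}\|\hat\phi\|^2$$

in closed form. Frequencies beyond the incoherent support $2NA/\lambda$ are
zeroed before the inverse transform.

**Units of $\tau$.** The transfer functions are kept in "source-sum" units:
the source is a per-pixel binary (or radially weighted) mask, so $B$ is of
the order of the number of illuminated pupil pixels and $|h|$ scales with
$B$. Under this convention $\tau$ competes with $\sum_j |h|^2$, which is
very large where the object is well transferred and tends to zero at
transfer nulls and the band edge. Values of $\tau$ in the hundreds therefore
act almost exclusively near the band edge: they suppress the noise
amplification of the deconvolution there at a small cost in nominal
resolution, while leaving the quantitative scale of the retrieved maps
untouched. The package default is $\tau_{abs} = \tau_{ph} = 300$; a sweep
from 100 to 1000 monotonically decreases the high-frequency energy of the
reconstruction (this is asserted in the test suite). Separate weights for
the absorption and phase channels are allowed because their transfer
strengths differ; the defaults are equal.

**Phase sign.** Positive $\phi$ means optically thicker than the
background.

## From attenuation to extinction coefficients

Amplitude attenuation over a single geometric pass of length $\ell$ is
$e^{-2\pi k \ell/\lambda}$; the reflection geometry doubles the path, so the
retrieved exponent is $\mu = 2\pi k L/\lambda$ with $L$ the **total**
(double-pass) optical path. `muToK()` inverts this:

$$k = \frac{\mu\,\lambda}{2\pi L}.$$

The default $L$ is twice the depth of field, because the objective
integrates over an axial slice of that extent and the double pass traverses
it twice. The depth of field itself follows from modeling the generalized
pupil as a *truncated* Ewald-sphere cap (the obscuration removes the low-NA
part):

$$\Delta z = \frac{\lambda_0}{n}\left(\sqrt{1 - NA_{obs}^2/n^2}
  - \sqrt{1 - NA^2/n^2}\right)^{-1} = 1.355\ \mu m$$

for the default optics in air. Structures thinner than $\Delta z$ (sieve
plates are 0.1–0.2 µm thick against $\Delta z$ = 1.355 µm) therefore come
out with **underestimated** extinction coefficients, by roughly the ratio of
their thickness to the depth of field. This is a property of the method, not
a bug; the synthetic tests account for it by scaling expectations with the
known phantom thickness. Exact recovery of $k$ holds exactly where the
sample thickness matches the assumed path ($2t = L$), which the unit tests
exercise.

**Band-limit ringing and apodization.** A hard cutoff at $2NA/\lambda$
leaves Gibbs oscillations around strong sharp structures (most visibly the
nucleus edge) whose amplitude can rival genuine faint peaks on the membrane.
`reconstructStack(..., apodizeTaper = f)` optionally replaces the hard edge
by a half-cosine roll-off over the outer fraction `f` of the passband. The
fenestration analyses in this package run on reconstructions with
`apodizeTaper = 0.4`; quantitative round-trip tests use the hard cutoff.

# The synthetic-data generator

`makeLsecPhantom()` emulates the morphology that matters for liver
sinusoidal endothelial cell (LSEC) imaging: a wobbled-ellipse cell body, a
thicker nucleus ($k$ = 8e-4), a thin plasma-membrane region with a single
drawn thickness in 100–200 nm (the expected sieve-plate thickness) and
$k$ = 2.7e-4 (the reported membrane mean), and planted sieve-plate sites:
patches perforated by sub-diffraction fenestrations (holes of radius 50–300
nm with $k = 0$) each ringed by an elevated-extinction rim, standing in for
the denser cytoskeleton around fenestrations. Each patch is rescaled so its
mean extinction is exactly `clusterK` (default 3.4e-4, the reported cluster
mean). The real-index increment defaults to $\Delta n = 0.02$ and the
nucleus thickness to 500 nm; no measured values exist for either, so they
were chosen once to keep the object safely inside the weak regime
($\max\mu, \max|\phi| < 0.5$). All randomness flows from one integer seed
through an isolated RNG stream, so phantoms are bit-reproducible and the
caller's RNG state is untouched.

What the generator does **not** emulate: organelle texture, 3-D structure,
thin-film interference in the sieve plates (the "darker than background"
inversion seen in raw reflection images is reproduced qualitatively by the
coherent Abbe oracle for thin structures, but no explicit interference model
is added), autofluorescence background, or live-cell dynamics. Passing tests
on these phantoms therefore validates the computational chain, not the
biology.

`makeBarTarget()` renders USAF-style absorbing bars with anti-aliased edges
(error below a period of 2 pixels), and `makeBeadPhantom()` scatters
non-overlapping discs for the calibration fixtures.

# Calibration

## Illumination direction

The retrieval needs the mean illumination direction of each half-ring
position. `estimateIlluminationDirection()` exploits the anisotropy the
half-ring imprints on the spectrum of an image of small scatterers. The
pipeline follows the robust recipe: smooth circular crop (Gaussian edge,
$\sigma$ = 20 px), periodic–smooth decomposition (both suppress the spectral
cross of the non-periodic image boundary), log magnitude of the FFT, a
smooth mask at the nominal support, Radon center-projections at 1° steps
(realized as image rotation plus a central-column sum), and a 3-sample
circular median filter. A naive variant that skips the masking and
decomposition steps is kept for comparison and is measurably worse on
edge-heavy images — the regression test asserts exactly that.

Two implementation details were found necessary on synthetic data. First,
the masked log-spectrum is Gaussian-smoothed ($\sigma$ = 2 px) before the
Radon step: speckle-scale roughness otherwise interacts with the bilinear
rotation so that grid-aligned projection angles are favored, biasing the
estimate by several degrees. Second, the axis is located at the sharp
*minimum* of the angular profile — the nodal line of the odd phase transfer,
which sits 90° from the broad maximum the physical argument refers to — with
parabolic sub-degree refinement, because the maximum is nearly flat over
tens of degrees while the minimum is well conditioned. The stored profile is
indexed so the maximum is orthogonal to the returned axis. The remaining
180° ambiguity cannot be resolved by any quadratic statistic of the image
(magnitude spectra are blind to the sign of the odd component), so the
estimator uses a third-order moment, $\sum f^2 (D_d * f)$ with a
derivative-of-Gaussian filter along the candidate axis, and calibrates its
sign convention at run time by pushing a single positive model blob through
the same optics. This assumes phase and absorption are positively
co-located (optically thicker regions absorb more), which holds for cells in
medium; a rotationally symmetric spectrum instead triggers a low-confidence
warning. On 256-px bead fields the estimator stays within 5° over a full
0–345° sweep.

## Pupil function

With an off-center pinhole source at pupil position $u_p$, the intensity
spectrum contains two decentered copies of the pupil centered at $\pm u_p$.
`estimatePupil()` finds them by cross-correlating the log-magnitude spectrum
with a zero-mean annulus template built from the nominal geometry (a
classical matched filter in place of a learned detector), re-centers and
averages the copies over all supplied images, subtracts the spectral floor,
and binarizes. The object's spectral envelope dims the outer annulus edge,
so the binarization threshold is 0.4 of the 99th percentile (followed by a
3-px closing) rather than one half; the factor is exposed as a parameter.
Coinciding copies (a centered pinhole) are reported as a degenerate
geometry. Four simulated pinhole images recover the true annulus with a
Jaccard index above 0.95.

# Contrast metrics and fenestration analysis

`contrastSigmaMedian()` is the population standard deviation over the median
of the ROI pixels; `contrastMichelson()` is $(I_{max}-I_{min})/(I_{max}+I_{min})$
with optional robust percentile extrema. Both are invariant under
multiplicative rescaling. `improvementRatio()` is a plain quotient; applied
to the published sieve-plate $\sigma/M$ values it reproduces the 12x/7x/293x
improvement factors of qDPC-processed UVC over brightfield, DIC and
holotomography. `barTargetVisibility()` measures Michelson visibility of a
reconstructed bar target along the bar normal; it stays high up to the
incoherent cutoff ($2NA/\lambda$, i.e. 4727 lp/mm for the default optics)
and collapses beyond it.

The sieve-plate analysis (`analyzeFenestrations()`) chains: 3-class
segmentation of the extinction map (smoothed thresholding with a
deterministic 1-D k-means split plus morphological cleanup — a pluggable
replacement for a trainable pixel classifier), sliding-paraboloid background
removal on the membrane, prominence-based maxima detection, and statistics.
Conventions:

* **Sliding paraboloid** (`slidingParaboloidBackground()`): grayscale
  opening by a separable paraboloid $z = d^2/(2\,\mathrm{radius})$ in units
  where the image's robust (0.1–99.9 percentile) range is 100, matching the
  classical background-removal semantics where the radius parameter sets the
  curvature. The opening is exact on affine ramps (away from the image
  boundary, where the element is one-sided) and idempotent.
* **Prominence** (`detectClusters()`): topographic prominence by flood
  ordering with union-find, 8-connected, plateaus counted once; the global
  maximum takes its height over the image minimum. The implementation is
  tested for exact agreement against a brute-force per-level
  connected-component oracle. The reference prominence for LSEC maps is
  0.00015 in extinction units; on synthetic phantoms the planted contrast is
  known, so tests derive their threshold from it (a fixed fraction of the
  planted cluster-minus-membrane contrast scaled by thickness over depth of
  field).
* Detection runs on the background-subtracted residual by default
  (switchable), restricted to the membrane mask eroded by a few pixels —
  band-limit ringing concentrates along the segment boundaries and would
  otherwise dominate the false-positive budget. Optional non-maximum
  suppression (`minDistancePx`) collapses the multiple maxima a rim-like
  cluster can produce.
* Per-cluster extinction is read from the **un-subtracted** map at the
  detected peak (disc mean, radius 1 px), since the quantity of interest is
  the cluster's extinction coefficient, not its residual height.

# Problem sizes and test design

The test suite runs phantoms of 128–256 px and one 384-px fenestration
pipeline; the Abbe oracle uses the full half-ring source (about 1200 points
at 128 px) where it serves as ground truth and 64 stratified points
elsewhere. These sizes were chosen so each property is measured comfortably
above its tolerance; all tolerances in the tests come from the model
properties themselves (linearization error, grid quantization, statistical
spread at the chosen sizes), not from fitted constants. Quantities measured
on real cells — decorrelation resolutions, the ~650 detected clusters and
the absolute contrast table — require the original raw data and are replaced
by the property-based synthetic checks described above.

# Known limitations

* The model is strictly 2-D and weak-object; thick or strongly scattering
  samples violate the linearization (the Abbe oracle quantifies, but the
  inversion does not correct, that error).
* Extinction coefficients are lower bounds for structures thinner than the
  depth of field, with the thickness/depth-of-field scaling described above.
* The coherence-length convention $L_c = \lambda^2/\Delta\lambda$ reproduces
  the quoted 6.8 µm only for a bandwidth of ~11.1 nm; the nominal 10 nm
  bandwidth gives 7.56 µm. Both values are exposed and documented rather
  than silently reconciled.
* Illumination-direction sign resolution assumes positively correlated
  phase and absorption; samples that are optically thicker but less
  absorbing than their surroundings would flip it.
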