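---
title: "Determining map handedness by Ewald-sphere factorization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining map handedness by Ewald-sphere factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewaldhand)
```

## The problem

A single-particle cryoEM reconstruction and its mirror image explain the
projection data equally well under the usual flat-sphere (planar)
approximation: every per-shell statistic of the real-space map — histogram,
half-map FSC — is identical for the map and its inversion. The physical
record of handedness lives in the *curvature* of the Ewald sphere. Elastic
scattering places the data on a sphere of radius $1/\lambda$ tangent to the
zero-frequency plane, and its Friedel mate (the inversion of that sphere
through the origin) carries the complex conjugate of the exit wave. The
separation between the two spheres at in-plane frequency $k$ is $2 z_0(k)$
with

$$z_0(k) = \tfrac{1}{2}\lambda k^2 ,$$

the paraboloidal (small-angle) form used throughout; the exact spherical
form $(1-\sqrt{1-\lambda^2k^2})/\lambda$ is available behind the
`exact_sphere` switch and differs by $O(\lambda^3k^4)$, under one part in
$10^4$ at the frequencies of interest.

`ewaldhand` splits each phase-corrected particle transform into its Hermite
component $H(k) = \tfrac12\left(F(k) + \overline{F(-k)}\right)$ and
anti-Hermite component $A(k) = \tfrac12\left(F(k) - \overline{F(-k)}\right)$
— equivalently the real and imaginary parts of the corrected image — and
reconstructs a separate 3D map from each: `MapR` from $H$, `MapI` from $A$.
Under inversion of the solution (re-projecting every particle with
$\gamma + 180^\circ$) `MapR` simply inverts, while `MapI` inverts *and
changes sign*. The sign of the shell correlation between `MapI` and the
$R^2$-modulated `MapR` (the **I-R FSC**) therefore reports whether the map
or its mirror is the hand consistent with the data, and the two candidate
curves are exact mirror images of one another by construction.

## Forward model

The simulator and the reconstruction engine share one linear weak-contrast
model. With a real scattering density $\rho$ and its 3D transform $F_{3D}$,
the recorded image transform of a particle at pose $R$ and defocus $z$ is

$$M(k) = \tfrac12\left[e^{-i\varphi(k)}\,F_{3D}\!\big(R\,(k, +z_0)\big)
       + e^{+i\varphi(k)}\,F_{3D}\!\big(R\,(k, -z_0)\big)\right],
\qquad \varphi(k) = 2\pi W(k) = -\pi z \lambda k^2 ,$$

which is Hermitian (the image is real), reduces to the straight projection
at $z = 0$, $\lambda \to 0$, and drops the quadratic $|F_e|^2$ term so that
the image is linear in the density and reconstructions have an exact ground
truth. Positive defocus means underfocus; spherical aberration and
amplitude contrast are carried in metadata but not modelled. Phase
correction multiplies by $e^{+i\varphi}$, the conjugate of the phase the
microscope applied to the Ewald-sphere term, so that term comes out
aberration-free.

A consequence of this convention worth stating explicitly: after phase
correction, the Hermite component carries the symmetric sphere sum with an
effective planar CTF of $\cos^2\varphi$, and the anti-Hermite component
carries the antisymmetric difference with $\sin^2\varphi$. These are the
interference amplitudes used in the gather weights. They are non-negative,
so the sign structure of the method comes entirely from the kernel algebra:
for the real component the two spheres' kernel contributions *add*; for the
imaginary component they *subtract*, cancelling exactly at the inter-sphere
midplane — which is why the planar approximation has no imaginary signal
and why the imaginary map's information grows with resolution.

## Gather reconstruction

For every reconstruction grid point $\bar R$ inside the resolution sphere,
each particle contributes

$$F_{3D}(\bar R) \;\leftarrow\; \sum w \cdot \text{data}, \qquad
  \text{with } w = \big[K(d_E) \pm K(d_M)\big]\cdot
  \{\cos^2\varphi\ \text{or}\ \sin^2\varphi\},$$

where $d_E, d_M$ are the signed distances from the rotated grid point to
the Ewald sphere and its mate, and $K$ is a truncated Gaussian kernel
(default $\sigma = 0.75$ reciprocal voxels, support $3\sigma$ — narrow, to
keep the real-space apodization mild). Two running sums are kept per
component: $\sum w\,\text{data}$ and $\sum w^2$. Finalization divides the
signal sum by the squared-weight sum with a per-shell relative floor
($10^{-3}$ of the shell median of the positive weights); voxels that never
rise above the floor are zeroed.

Numerical choices that matter:

* **Centred transforms.** All Fourier grids are centred in *both* domains:
  the DC term at index $n/2$ and the real-space phase origin at the centre
  voxel. With the phase origin at index 0 a centred particle rides a
  $(-1)^k$ checkerboard ramp and interpolation between Fourier samples is
  meaningless.
* **Twofold Fourier oversampling.** Images (and the simulator's truth
  volume) are zero-padded by 2 before transforming, so bilinear (trilinear)
  interpolation acts on a twice-oversampled transform. This is the standard
  gridding accuracy measure; without it the interpolation error visibly
  depresses map-versus-truth shell correlations.
* **Mean subtraction.** Each image's mean is removed before transforming:
  the DC term carries no structural information and its large peak
  otherwise leaks into the lowest shells through interpolation.
* **Friedel handling.** On even grids the $-k$ partner of index $i$ is
  $(n - i) \bmod n$; the Nyquist row is its own partner. The gather stops
  two voxels short of Nyquist so interpolation stencils stay in bounds.
  Real-space inversion is the circular index flip about the centre voxel,
  which makes `invert_volume` an exact involution and makes the $R^2$
  modulation commute with inversion voxel-exactly.
* **Half sets.** Half maps split particles by even/odd index:
  deterministic and seed-free.

## The verdict and its calibration

The as-given I-R FSC is $\mathrm{FSC}(R^2 \cdot \mathrm{MapR},
\mathrm{MapI})$ per one-voxel shell, after both maps are Wiener-filtered
with $\mathrm{SNR}/(\mathrm{SNR}+1)$, the per-shell SNR coming from each
component's half-map FSC via $\mathrm{SNR} = 2f/(1-f)$. The inverted-hand
curve is the exact negation and is asserted, not recomputed. The $R^2$
modulation (squared voxel distance from the map centre) mirrors the
$\Delta z^2$ weighting inherent to the imaginary reconstruction — only
out-of-focus density contributes to it — and, being inversion-invariant,
cannot change the correlation's sign.

Shells are combined by Fisher-transforming each shell's correlation and
weighting by its effective number of independent samples. The raw voxel
count overstates independence: Friedel symmetry halves it, the Gaussian
kernel correlates neighbours along the sphere normal by
$\sum_d e^{-d^2/4\sigma^2} \approx 2.66$ at $\sigma = 0.75$, and bilinear
interpolation contributes $\approx 1.25$ per in-plane dimension, so
$n_\text{eff} = n_\text{vox}/8.3$. When a predicted curve is available it
also serves as a matched filter (shell weight
$n_\text{eff} \times \text{prediction}$): the prediction is built from
half-map FSCs and kernel weights only, never from the observed correlation
sign, so the null calibration is untouched while empty shells stop diluting
the score. The verdict follows the sign of the summed score when it exceeds
3 null standard deviations; otherwise the hand is *indeterminate*.

The predicted I-R FSC itself converts the real component's half-map FSC to
a full-map SNR, scales by the per-shell ratio of accumulated squared
imaginary/real kernel weights and a scalar compensation factor (default 1;
it absorbs the deliberately narrow kernel and shape assumptions), and takes
the geometric mean of the two normalized SNRs. An indeterminate verdict in
the face of a clearly above-noise prediction is flagged
`inconsistent-with-prediction` — the signature of a reconstruction that
failed even though its half-map FSC looked healthy.

## What the verdict means — and what it cannot mean

The method reads the *consistency between the reconstruction's hand and
the data's curvature*, not absolute chirality. A mirror-image molecule,
imaged and reconstructed self-consistently, also yields a positive I-R FSC
for its own (correct) map. What flips the verdict is a wrong-hand
*reconstruction*: the same data rebuilt with the inverted pose set
($\gamma + 180^\circ$), whose real map is precisely the mirrored solution.
Equivalently, conjugating every particle transform inverts the solution;
doing both returns the original. This also delimits a failure mode the
package cannot detect by construction: an axis flip introduced during
image-format conversion, *followed by* pose refinement against the flipped
images, produces a self-consistent mirror experiment and a confidently
wrong hand. (With stale metadata the flip merely scrambles pose
assignments and the verdict degrades to indeterminate.) Detector
handedness must be calibrated upstream; the readers here never reorder or
flip axes and refuse files whose axis order is not the identity.

## The synthetic-data generator

`make_dataset` emulates the parts of a cryoEM experiment this method
exercises: a chiral ground truth (Gaussian blobs on a helical path, with
an exactly inversion-symmetric achiral control), uniform SO(3) poses (or a
preferred-orientation mode with a single viewing direction and random
in-plane angle), defoci uniform over a range, curved-sphere projection
with CTF phase, and additive white Gaussian noise — uncorrelated between
particles, as the correlation analysis requires.

Desk-scale experiments cannot reach the particle counts (hundreds of
thousands) at which the physical $\lambda$ gives a measurable imaginary
component, so the generator exposes `lambda_scale`: curvature is
exaggerated (default in the examples: 50-fold) until the particle diameter
exceeds the depth of focus $L = 2d^2/\lambda$ at Nyquist, while defoci are
scaled down (150-450 Å) to keep $z\lambda$ — hence the number of CTF rings
— in the physical range. The code path is identical to the physical-λ one;
only the magnitude of the curvature signal changes. The test-suite study
conditions are a 48-voxel box at 3 Å/pixel with 1000 particles at image
SNR 0.5 for handedness recovery, and 32-voxel boxes for the smaller
property checks; null calibration uses preferred-orientation (β = 45°) and
pure-noise datasets.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: structural heterogeneity, per-particle defocus
error, detector MTF and non-Gaussian noise, amplitude contrast, higher-
order aberrations, and pose-refinement errors (poses are known exactly).
The paper-scale claim that the method works at physical λ with refined
poses rests on the algebra being λ-independent, not on these tests.

## Degenerate inputs and edge behaviour

Zero-power shells (e.g. beyond the gathered band, or Wiener-zeroed) are
reported as correlation 0 with a `zero_power` flag; a relative threshold
($10^{-24}$ of the strongest shell's power) keeps floating-point residue
from masquerading as signal. An all-zero accumulator refuses to finalize.
`lambda_scale = 0` selects the planar limit exactly: both spheres collapse
onto the tangent plane, the imaginary weights vanish identically, and the
real-component pipeline reproduces central-slice insertion (a regression
test holds it to the independent oracle at $10^{-10}$).

## Known limitations

* The interference amplitudes ($\cos^2\varphi$, $\sin^2\varphi$) are tied
  to this package's amplitude-like weak-contrast convention; they are
  isolated in one function (`dual_sphere_weights`) so an alternative
  convention can be swapped in.
* The effective-sample correction is analytic, not estimated per dataset;
  it is deliberately conservative, and the 3σ threshold inherits that
  conservatism (the null tests in the suite run well inside it).
* Wiener SNR for the imaginary component comes from its half-map FSC,
  which is itself noisy at desk scale; shells whose half-map FSC is
  non-positive are zeroed rather than smoothed.
* Maps reconstructed here carry an $O(\text{kernel})$ real-space
  apodization that is not back-compensated; it cancels in all shell
  correlations, which is what the method consumes.
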