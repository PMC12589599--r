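---
title: "Stacking polytypes, planar disorder and their diffraction signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacking polytypes, planar disorder and their diffraction signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polystack)
```

## The model

Many hydrogen-bonded molecular crystals — the purine nucleobases
xanthine, guanine and hypoxanthine are the motivating family — are built
from strongly bound 2D molecular layers held together by weak van der
Waals contacts.  Such crystals are prone to *polytypism* (polymorphs
differing only in the stacking sequence of identical layers) and to
*stacking faults* (isolated wrong interlayer steps).

`polystack` models this with a deliberately minimal algebra.  The
translation relating one layer to the next takes one of four values
sharing a common magnitude.  In fractional coordinates of the reference
(Form II-like) orthorhombic cell, with **b** the stacking axis:

$$\mathbf A = (+u, v, +w), \quad \mathbf B = (-u, v, +w), \quad
  \mathbf C = (-u, v, -w), \quad \mathbf D = (+u, v, -w),$$

with defaults $u = 0.377$, $v = 0.250$, $w = 0.041$.  The in-plane
parts obey $\mathbf C = -\mathbf A$ and $\mathbf D = -\mathbf B$, and
**A**/**B** (likewise **C**/**D**) are related by the mirror that flips
the *a* component.  Only those relations are physically fixed; the
explicit sign assignment above is a convention of this package, chosen
so that the four relations hold simultaneously and the **A B C D**
cycle closes.  Under it:

* **A B A B …** (the Form I-like polytype) never returns a layer to a
  lattice point of this frame — the *c*-component accumulates by $2w$
  per **AB** pair — consistent with a monoclinic native cell for that
  polytype, which this package deliberately does not re-index;
* **A B C D** closes exactly after four layers, giving the orthorhombic
  cell whose **b** repeat contains four layers
  ($b = 4 \times 3.135\,\mathrm{\AA} = 12.54\,\mathrm{\AA}$).

`detect_period()` finds the closure order by direct enumeration of
cumulative sums; `extract_interlayer_vectors()` inverts a built
structure back to its vectors under the rigid-layer assumption, always
reporting the minimum-magnitude in-plane representative (that is the
convention under which the four vectors are defined; magnitude ties
within 1e-9 are broken towards non-negative *a*, then non-negative *c*
components).

## The synthetic generator

Real layer motifs (Z' = 4 hydrogen-bonded molecules on a
10.10 × 17.91 Å footprint) are replaced by rigid planar rings placed
at seeded random positions with a minimum-separation constraint, flat
in the layer plane.  This reproduces everything the stacking analysis
is sensitive to — rigid 2D motifs, translational stacking, interface
statistics — and nothing it is not: there is no hydrogen-bond
geometry, no molecular tilt, no thermal motion, and the molecules sit
exactly at zero height within their layer.  Consequently passing tests
demonstrate correctness of the stacking/diffraction machinery, not
fidelity to any real nucleobase structure; with real atomic layers the
(0*k*0) row would carry intra-layer structure that the flat toy layers
do not have.

Fault insertion (`faulted_sequence()`) substitutes, independently at
each interface with probability `p_fault` (default 0.1), the expected
label by a uniformly chosen different label.  Whether real faults are
substitutions, insertions or sign flips is not established; the
substitution protocol is this package's definition, and statements
about real fault statistics should not be read into it.  A sequence of
$n$ labels builds $n$ layers, so the last label is never consumed;
fault positions therefore run over interfaces $0 \dots n-2$.

## Diffraction

All scattering is kinematic, with constant scattering factors
$f_j = Z_j$ by default: systematic absences and streaking are phase
effects, indifferent to the $f(s)$ falloff (Cromer–Mann 4-Gaussian
factors for H/C/N/O are available behind the `form_factors` switch).
Dynamical effects, which matter for absolute electron-diffraction
intensities, are out of scope.

Reciprocal *rods* are computed along the stacking direction at fixed
in-plane indices $(h, l)$, in reciprocal units of the reference cell:

$$I(k) = \bigl|F_{\text{layer}}(h, l)\bigr|^2\,
  \Bigl|\sum_{n=0}^{N-1} e^{2\pi i (h u_n + k n v + l w_n)}\Bigr|^2 / N .$$

Two regimes matter.  On rods with $h = l = 0$ the in-plane
displacements contribute zero phase, so the profile is exactly
independent of faulting — the "strong systematic row" stays sharp.
Because the toy layers are identical and equally spaced, that row peaks
at the layer repeat, $k = 4m$ in Form II units; tests and the
acceptance checks therefore sample it around $k = 4$, while in-plane
rods are sampled around $k = 1$.  On rods with $h \ne 0$ faults
scramble the phase $h u_n$ and the Bragg comb broadens into streaks;
the `streak_metric()` is the FWHM ratio of the strongest peak against
the ordered reference.

The Monte-Carlo supercell route is validated against an independent
closed form: for labels following a Markov chain with transition matrix
$P$, stationary distribution $\pi$ and per-step phase factors collected
in $D = \operatorname{diag}(\phi_s)$, the finite-$N$ ensemble mean is
the Hendricks–Teller-type expression

$$I/N = |F|^2 \Bigl(1 + 2\,\mathrm{Re} \sum_{m=1}^{N-1}
  \bigl(1 - m/N\bigr)\, \pi^T D (P D)^{m-1} \mathbf 1\Bigr).$$

The substitution fault protocol is independent per interface, not
Markov in the label, so the two routes coincide exactly only where the
substitution process is label-independent: at `p_fault = 0.75` every
interface is i.i.d. uniform over {A, B, C, D}, identical to the
all-rows-equal transition model.  The oracle-equivalence check is run
at that point (200 layers, 500-member ensemble), demanding pointwise
agreement within three standard errors; on a ~200-point grid a
fraction of order 0.3% of points is expected beyond three standard
errors by chance, so the assertion is "at least 99% of points within
3 se and none beyond 6", not a literal all-points bound.

Powder patterns enumerate the Friedel half-sphere to the d-limit of
the 2θ window, apply multiplicity 2 (P1 setting) and the Lorentz
factor $1/(\sin^2\theta\cos\theta)$ (polarization is omitted: the
default wavelength, 0.82408 Å, is a synchrotron setting and the
package never fits absolute intensities of real data), and convolve
with an area-normalized pseudo-Voigt (default FWHM 0.05° 2θ,
η = 0.5).  Ensembles of faulted supercells are averaged at the
stick-intensity level.

## Twin operators

`relate_orientations()` forms $T = \mathrm{UB}_{\text{parent}}^{-1}
\mathrm{UB}_{\text{twin}}$ and characterizes its Cartesian image:
rotation angle from the trace, axis from the $+1$ eigenvector, and for
improper operators both the mirror description and the proper
equivalent obtained by composing with inversion — the two descriptions
a centrosymmetric structure cannot distinguish.  Axes are direct-space
(contravariant) triples, plane normals reciprocal-space (covariant)
triples; keeping the two transformation rules separate avoids the
classic indexing bug.  Axis indices are rationalized by exhaustive
search over primitive integer triples with components up to 12, scored
by angular deviation — and reported *with* that deviation, because
physically interesting twin axes need not be rational (a near-integer
axis like [1 0.1 1] should surface as a best fit plus residual, never
be forced to integers).  Tolerances: metric preservation 1e-4
relative (beyond it the pair is flagged as misoriented crystals rather
than a twin), plane parallelism 0.5°, isometry of the Cartesian image
1e-6.  The Form I-like monoclinic cell used in tests
(a = 7.1, b = 8.7, c = 6.3 Å, β = 115°) is synthetic: the package
validates the 180° twin law and (10-1) plane invariance, not any
literal published axis value.

## Profile comparison

"Rietveld-style" fitting here means fixed atomic models: refined are
per-phase scales, one zero shift, a Chebyshev background (default
degree 3) and one global peak width.  At every trial of the nonlinear
pair (zero, width) the linear parameters are solved exactly by weighted
least squares — stick intensities are max-normalized per phase first so
the normal equations stay well conditioned — with negative scales
pinned at zero; L-BFGS-B drives the outer pair within bounds
(|zero| ≤ 0.5°).  Weights default to 1/max(y, 1), the counting
statistics convention under which

$$R_{wp} = 100\sqrt{\frac{\sum w (y_o - y_c)^2}{\sum w y_o^2}}, \qquad
  R_{exp} = 100\sqrt{\frac{N - P}{\sum w y_o^2}}, \qquad
  \mathrm{GooF} = R_{wp}/R_{exp}$$

make GooF → 1 for a true model at high counts.  Noise fixtures are
Poisson (not Gaussian) for the same reason.  The package targets
*relative* model comparison — ordered versus faulted-ensemble
supercells on the same observation — not absolute residuals of any
published refinement, which depend on the beamline data and on
refinement conventions (background, weighting, profile) that are not
recomputable from desk inputs.

## Problem sizes and numerical choices

The shipped tests and acceptance checks use: 8–20-layer stacks for
geometry round trips (up to 200 layers in the sequence-recovery
property test), 100–200-layer supercells with 100–500-member ensembles
for rod statistics, and 24-member ensembles of 20-layer (five-cell)
supercells for the powder-model comparison — the point at which both
ensemble means are converged enough for the faulted model to win on
faulted data.  Fractional coordinates live in the half-open interval
[0, 1) throughout; molecule centroids are computed after per-molecule
unwrapping so molecules straddling a cell edge do not corrupt layer
matching; layer extraction demands matched-displacement scatter below
0.01 fractional (the rigid-body assumption) and errors otherwise.
Symmetry expansion refuses colliding images within 0.1 Å rather than
merging special positions — the generators here only ever need general
positions.

## Limitations

No intra-layer relaxation, molecular canting, or stacking energetics;
no dynamical scattering, tilt-series geometry or detector models; no
atomic-coordinate refinement, texture or instrument profiles; Form
I-like polytypes are represented in the orthorhombic frame only.  The
space-group machinery is the hard-coded operator set for P1, P2₁/c and
P2₁2₁2₁ — enough for the absence logic, not a general engine.
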