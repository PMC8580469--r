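---
title: "Quantifying approximate symmetry with Transformation Information"
author: "symscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying approximate symmetry with Transformation Information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symscan)
```

## The measure

Biological symmetry is almost never exact. `symscan` quantifies how far
an image is from being symmetric under a candidate transformation
$T_a$ with the Transformation Information

$$\mathrm{TI} \;=\; \frac{1}{|\tilde D|}\int_{\tilde D}
  \mu(x)\,\ln\!\frac{\mu(x)}{T_a\mu(x)}\,dA ,$$

where $\mu$ is a strictly positive intensity field and $\tilde D$ is the
overlap domain — the intersection of the original image region with the
region onto which the transformed image falls. TI has the structure of a
Kullback–Leibler divergence between the field and its transform: it is
zero exactly when $T_a\mu = \mu$ on $\tilde D$, and it grows with the
mass-weighted log-ratio mismatch. It is not symmetric in $\mu$ and
$T_a\mu$ in general (the overlap rule breaks the exchange), is not
sign-definite when the transform changes the total mass on $\tilde D$,
and scales covariantly with intensity:
$\mathrm{TI}(c\mu) = c\,\mathrm{TI}(\mu)$ for constant $c>0$, since the
constant cancels inside the logarithm. On a periodic domain, where a
translation preserves total mass exactly, the log-sum inequality forces
$\mathrm{TI}\ge 0$.

Scanning TI over a transformation family — rotation angle, reflection
axis, translation vector, or rotation combined with isotropic rescaling —
and locating *local minima* yields the approximate symmetries of the
image; the TI value at a minimum measures its deviation from perfection,
and the values at local maxima (the least symmetric transforms) give the
scale against which those minima should be read.

### Assumptions and conventions

* $\mu$ must be strictly positive. Raw images are clamped by
  `ensurePositive()` with a floor of 1 on the 0–255 intensity scale; the
  relative-greenness construction $2g-r-b+1$ can reach $-510$, so
  clamping is a real decision, not a formality. A floor of 1 is the
  minimal completion of the $+1$ in that formula.
* Pixel centres sit at integer coordinates, $x$ rightward, $y$ upward
  (files are flipped on load), angles in degrees counterclockwise.
  Nothing in the measure depends on this choice, but reflection axes and
  rotation centres are only reproducible against a stated convention.
* The discrete quadrature is the midpoint rule — pixel sum times pixel
  area — which reduces TI to the mean of $\mu\ln(\mu/T_a\mu)$ over
  overlap pixels.
* Transforms are resampled by bilinear interpolation of the inverse map.
  A pixel belongs to $\tilde D$ only if every interpolation neighbour of
  its pre-image is defined, so interpolated values never draw on
  undefined data; out-of-domain samples are NA, never zero-filled (a
  zero would poison the logarithm). Coordinates within $10^{-9}$ px of
  the lattice are snapped, making 90° rotations and integer shifts
  bit-exact.
* Raw (unnormalized) $\mu$ enters the integrand. An optional flag in
  `transformationInformation()` divides by the mean of $\mu$ on
  $\tilde D$ for cross-specimen comparability; it is off by default.
* Curves are reported as TI, so symmetries are minima; plotting $-$TI is
  a display choice only.

## Detection choices

`findSymmetries()` needs a reproducible notion of "a clear minimum": it
keeps interior local minima whose topographic prominence is at least 2%
of the curve's TI range (by default). Angular grids spanning a full
period are treated as rings, so minima at the wrap point are found;
the identity transformation is always excluded. For 2-D scans
(rotation–rescale, translation) a minimum must undercut all eight grid
neighbours and its prominence is approximated by the smaller of the two
1-D prominences along its row and column — a conservative bound that
avoids a full watershed analysis. No sub-grid refinement is applied: the
grid resolution is the precision contract, which keeps detection
deterministic.

Three automatic centre estimators are provided:

* **Rotational (`estimateCenterRotational`)** evaluates TI at the
  $k\cdot 360/n$ rotations ($k=1..n-1$, default $n=12$) about each
  candidate centre after block-downsampling (default factor 16), and
  scores the centre by the Euclidean norm of consecutive TI differences.
  A true rotation centre makes TI swing between deep minima and high
  antiphase values; off-centre the curve flattens. The identity rotation
  is deliberately excluded from the ring: TI(0°) is zero for *every*
  candidate centre, so differences taken against it scale with the
  overall TI level rather than its angular variation, and a badly
  centred, highly asymmetric configuration can out-score the true centre
  (we observed exactly this on an off-centre rosette before excluding
  it). For the same reason the search window should stay inside the
  object's core.
* **Reflection (`estimateCenterReflection`)** takes the $x$ minimizing
  TI for reflections about vertical axes and the $y$ minimizing TI for
  horizontal axes. This recovers the coordinate transverse to a true
  mirror axis well, but the other coordinate is systematically biased
  for objects that are asymmetric along their axis (a leaf with a
  pointed tip) — a genuine limitation of reflection-based centring that
  the tests assert rather than hide.
* **Area balance (`estimateCenterArea`)** equalizes foreground mask
  areas left/right and above/below. Split lines run between pixels or
  through a pixel line (whose pixels then count on neither side), and
  ties resolve to the median tied position, so a single-pixel mask
  yields that pixel and a centred disc its exact centre.

## Baseline measures

The Simple Indicator partitions the mask into $n$ equal-width bands
orthogonal to a reflection axis and averages $|A_i-B_i|/(A_i+B_i)$ over
bands with foreground; it is 0 for mirror-perfect masks, 1 for
one-sided ones. The band count and geometry are not canonical; we use
equal-width bands over the object's extent with $n=20$ by default.
Pixels exactly on the axis belong to neither side. Note one discrete
artefact: if band edges fall exactly on pixel coordinates, knife-edge
pixels can change bands under rigid motions; choose $n$ so edges avoid
pixel centres when exact invariance matters.

The landmark measure ZI rotates a point set about a centre and sums
squared distances from each rotated point to its *nearest* original
point (first-index tie-break, no optimal assignment). It vanishes
exactly at the rotations of a regular polygon and is invariant to
relabelling — but uses only the landmarks, which is precisely the
limitation TI avoids.

## The reaction–diffusion test bed

To exercise translation symmetry on a field with a known physics,
the package integrates a two-species Turing model on an $L\times L$
periodic square ($L=10$ by default):

$$u_t = D\,\delta\,\nabla^2 u + \alpha u(1-r_1v^2) + v(1-r_2u)
       + c\,\delta\,u_y, \qquad
  v_t = \delta\,\nabla^2 v + \beta v\!\left(1+\tfrac{\alpha r_1}{\beta}uv\right)
       + u(\gamma + r_2 v).$$

The default coefficients ($\delta=5\times10^{-3}$, $D=0.5$, $\alpha=1$,
$\beta=-1$, $\gamma=-1$, $r_1=1$, $r_2=0$, $c=0$) put the system in a
stripe-forming regime: the quadratic terms vanish and the homogeneous
zero state sits exactly at onset at $k=0$ (trace and determinant of the
linearization both vanish there). Linear stability about zero gives the
per-mode growth matrix
$\begin{pmatrix}\alpha-D\delta k^2 & 1\\ \gamma & \beta-\delta k^2
\end{pmatrix}$; at these coefficients the fastest-growing mode solves
$\delta k^2 = \sqrt{72}/2-4$, i.e. $k_{\max}\approx 6.97$ (wavelength
$2\pi/k_{\max}\approx 0.90$), which `fastestMode()` reproduces and the
test suite checks against a brute-force scan of the closed-form rate.
All wavenumbers use the $2\pi$ convention.

The advection term $c\,\delta\,u_y$ breaks rotational isotropy: as $c$
grows the stripes align along $x$, the deviation spectrum concentrates
near the $k_y$ axis, and the translation-TI map becomes anisotropic.
`anisotropyRatio()` summarizes this as the ratio of mean TI in a ±15°
sector about the $y$ shift axis to the matching $x$ sector. Shift
magnitudes are capped at the least-symmetric-annulus radius by default:
at larger radii the sector admits transverse shift components beyond
half a pattern wavelength, TI saturates in every direction, and the
contrast washes out (a pure $y$ plane wave would read ≈1.6 instead of
≫1 without the cap).

### Numerics

The integrator is the fourth-order exponential time-differencing
Runge–Kutta scheme in Fourier space. The per-mode linear operator holds
diffusion and advection only (diagonal per species, complex for
$c\neq 0$); all reaction terms, including their linear parts, are
treated in the nonlinear stage, evaluated in real space with two-thirds
dealiasing of the cubic products. The $\varphi$-function coefficients
are evaluated by averaging over a unit complex contour around each
$h\lambda$, the standard remedy for cancellation at small arguments.
Defaults $N=128$, $dt=0.05$: the unstable band (growth positive up to
$k\approx 14$) is resolved with more than nine grid points per shortest
unstable wavelength, and halving $dt$ changes the $t=10$ state by less
than $10^{-10}$ RMS. Initial conditions are independent uniform noise in
$[-0.05, 0.05]$ for both species, drawn from the stated seed; runs are
bit-reproducible. The integrator reports a blow-up error naming the
step if the state leaves the finite range, with $dt\le 0.05$ stable at
the default stiffness.

At $t=100$ the $c=0$ field $u+v$ is a disordered labyrinth of stripes.
Its radially averaged deviation spectrum peaks near $k\approx 5.7$
(median over seeds), consistent with selection inside the linear band,
and the radially averaged translation-TI profile peaks at a shift
radius of ≈0.62 — about half the characteristic stripe wavelength,
the least symmetric displacement.

## What the fixtures emulate — and what they do not

The synthetic generator reproduces the geometric *structure* of the
specimen classes the measure targets: $n$-fold rosettes (with an
optional one-sided petal lobe that destroys reflections while keeping
rotations — chirality without landmarks), a leaf-like bilateral blob
with a single mirror axis at a chosen angle (round base, tapered tip,
so no spurious 180° rotation survives), a regular-pentagon landmark
set, a decussate whorl whose level-to-level rotation and shrinkage make
it self-similar under a rotation–rescale map, and plane waves. Shapes
are rendered with smooth Gaussian edges deliberately: near an exact
symmetry the TI of a hard-edged shape is dominated by interpolation
error at the edge, which would obscure the quantity under test.

Fixtures do not emulate photographic nuisance structure — uneven
illumination, background clutter, perspective and petal curvature,
sensor noise beyond i.i.d. pixel noise. Passing tests therefore
demonstrate the correctness and resolution of the measure and its
detectors on known ground truth, not robustness to field photography.

Two boundary effects are inherent and documented rather than hidden:

* The whorl has finitely many levels, so its self-similarity is
  truncated: the outermost pair has no outer partner (its position
  leaves the overlap domain) and the image of the innermost pair lands
  on background. The truth transforms are deep minima of the TI
  landscape, but their difference maps are only near-zero on the middle
  annulus; tests assert exactly that region.
* Detected 2-D minima are reported at grid resolution; with the default
  scan grids the whorl recovery is asserted to one grid step
  (5° in angle, 0.02 in scale).

## Problem sizes

The shipped tests run rosette/blob scans at 128² with 1–2° angle grids,
the whorl at 160² on a 49×46 rotation–rescale grid, and three
stripe-pattern integrations at 128² to $t=100$ (plus two short ones for
the convergence and advection checks); the acceptance script repeats
the three long integrations. These sizes were chosen so the full
evidence chain — simulate, scan, detect — reruns comfortably on a
single CPU while keeping every detection at least one grid step away
from its tolerance.

## Known limitations

* Straight axes only: curved bilateral axes (a bent midvein) are out of
  scope, as are shears and non-rigid warps.
* TI compares intensities pointwise after interpolation; minima
  positions can shift by a fraction of the grid spacing under a
  different interpolation scheme.
* The rotational centre criterion assumes the search window lies within
  the object; it is not a global object detector.
* No background masking beyond the overlap rule is applied; strongly
  textured backgrounds will contribute to TI.
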