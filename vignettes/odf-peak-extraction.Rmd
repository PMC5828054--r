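---
title: "Extracting fiber orientations from diffusion ODFs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting fiber orientations from diffusion ODFs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odfpeaks)
```

## The model

A diffusion ODF is a nonnegative, antipodally symmetric function
$\psi(\mathbf u)$ on the unit sphere whose local maxima align with the
fiber populations crossing an imaging voxel. `odfpeaks` treats peak
extraction as multimodal maximization of $\psi$ over the sphere,
parameterized by azimuth $\theta$ (measured in the x–y plane from $+x$)
and elevation $\varphi$ (from the plane toward $+z$). The frame is chosen
so that $(\theta,\varphi)=(0,0)$ is the $+x$ axis; angles outside the
canonical ranges still address the right point because the trigonometric
map is periodic, which lets the local optimizer work in an unconstrained
plane.

### The hybrid optimizer

The extractor combines a global and a local stage.

**Derandomized PSO.** Particle velocities update as
$V \leftarrow \omega(k)\,V + c_1 (P - X)$ with the social term $c_2 = 0$
and no random factors; positions advance by $X \leftarrow X + V$ and are
wrapped (pole crossings reflect $\varphi$ and shift $\theta$ by $\pi$;
azimuth differences are taken as shortest wrapped differences). Each
particle therefore climbs toward its *own* best position: the swarm keeps
covering all basins instead of collapsing onto the global optimum. The
inertia weight decays linearly from $\omega_{\max}$ to $\omega_{\min}$
over $t_{\max}$ iterations. The stage stops when the mean per-iteration
improvement of the personal bests (the transfer tolerance) drops below
the threshold $P$, or at $t_{\max}$.

Because the update has no stochastic term and personal bests start at the
particle positions, a swarm started at rest would be at a fixed point and
never move. Initial velocities are therefore drawn uniformly within
$\pm\sqrt{4\pi/N}$ (the mean inter-particle spacing) per component, from
the run's seed; reinitialization between hybrid rounds redraws both
positions and velocities. This is the one place the published update rule
needed an explicit completion, and it is what makes the derandomized
swarm function as a basin-covering sweep.

**Modified Powell.** From each personal best (deduplicated at
`start_dedup_angle`, default 2°, since near-identical starts converge to
the same extremum), a direction-set search runs sequential line searches
along $\theta$- and $\varphi$-axes, measures the cycle displacement
$d^D = x^D - x^0$, and either keeps the direction set (when the printed
extrapolation inequality on the negated objective holds) or replaces the
maximum-drop direction with the unit-normalized $d^D$. Convergence is
declared when $\lVert d^D\rVert \le \varepsilon$ — but only after a
confirming cycle with the axis direction set, which guards against the
replacement set losing a coordinate and stalling on a ridge. A classical
Powell retention rule is available via `powell_criterion = "classical"`.

**Line search.** Each 1-D maximization brackets outward from the current
point (initial probe 0.05 rad, doubling, capped at $\pi$) and refines
with Brent's method (`stats::optimize`, tolerance $10^{-6}$ rad). The
bracketing is deliberately *local*: an ODF slice is multimodal, and a
global line maximization repeatedly drained weaker basins (in three-fiber
tests the faintest fiber was lost); locality preserves the division of
labor in which the swarm covers and Powell refines. If no probe improves
on the current point the step is zero, which also makes the Powell trace
provably non-decreasing.

**Extreme set and filtering.** Converged extrema accumulate across up to
$M$ rounds with antipodal deduplication at `merge_angle` (default 10°,
keeping the higher value; the published text does not state a radius).
Finally, peaks below the spherical mean of the ODF samples and peaks with
min–max normalized value below $P$ are discarded — the two published
rules against noise-driven ripples. Normalized values are capped at 1
because a continuous optimum can slightly top the discrete mesh samples
that define the scaling. Early exit fires when three consecutive rounds
add no extremum that would survive filtering (sub-threshold ripples keep
being collected but no longer prolong the schedule); set
`early_exit = FALSE` for the strict fixed-round schedule.

Defaults are the published operating point: $N = 100$, $t_{\max} = 120$,
$P = 0.02$, $M = 20$, $c_1 = 0.5$, $\omega \in [0.1, 0.2]$. The transfer
tolerance itself is not defined in print; the mean personal-best
improvement per iteration (in normalized ODF units, matching the scale of
$P$) is this package's operationalization. Powell's $\varepsilon$
likewise has no printed value; the default $10^{-4}$ rad resolves
orientations far below a degree while keeping cycles short.

## Synthetic data

The quantitative test bed is the Gaussian multi-tensor phantom: a voxel
is a mixture of diffusion tensors $D_i$ with volume fractions $f_i$, and
the single-shell signal is
$S(\mathbf g, b) = S_0 \sum_i f_i \exp(-b\, \mathbf g^\top D_i \mathbf g)$
at $b = 3000\ \mathrm{s/mm^2}$ over 64 quasi-uniform gradient directions
plus one $b=0$ volume. The standard configurations are one fiber at
$(0,0)$; two at $(0,0)$ and $(1.22, 0)$ rad (a 69.9° crossing) with equal
fractions; and three at $(0,0)$, $(1.22,0)$, $(0.52,1.05)$ with fractions
renormalized from 0.33 each. Eigenvalues are not stated in the source
experiments; the default $(1.7, 0.3, 0.3)\times10^{-3}\ \mathrm{mm^2/s}$
is the standard coherent white-matter choice and gives realistic
attenuation at $b=3000$; it is a parameter, not a constant. The exact
solid-angle ODF of the mixture has the closed form
$$\psi(\mathbf u) = \sum_i \frac{f_i}{4\pi \sqrt{\det D_i}\,
  (\mathbf u^\top D_i^{-1} \mathbf u)^{3/2}},$$
which integrates to 1 analytically — the package uses this exact constant
rather than renormalizing by quadrature, so the quadrature-consistency
checks in the test suite are informative rather than tautological.

Rician noise follows the magnitude-MRI convention
$\sqrt{(S+n_1)^2 + n_2^2}$ with independent Gaussians of standard
deviation $\sigma = S_0/\mathrm{SNR}$ per channel (SNR 20 in the noisy
conditions), deterministically seeded.

What the phantoms do *not* emulate: spatial correlation of noise, partial
volume with CSF or gray matter, non-Gaussian restriction (no ball, stick
or kurtosis compartments), eddy-current or motion artifacts, and
gradient-scheme imperfections. Passing the synthetic suites therefore
demonstrates correctness of the optimizer and reconstructions under the
stated model, not robustness to everything an in-vivo acquisition can
produce; the NIfTI pathway exists so users can apply the tool to real
data where those effects are present.

## ODF reconstruction

Signals are represented in the real symmetric spherical-harmonic basis
(even orders, $l_{\max} = 8$, 45 coefficients — high enough to resolve
small crossing angles, at the cost of noise sensitivity), fit by least
squares with Laplace–Beltrami regularization
$\lambda\,\mathrm{diag}(l(l+1))^2$, default $\lambda = 0.006$ (the
standard analytic-QBI value; the source is silent on regularization).
QBI applies the Funk–Radon transform diagonally,
$c_{lm} \mapsto 2\pi P_l(0)\, c_{lm}$; CSA-QBI fits
$\log(-\log E)$ with the attenuation clamped into
$[\delta, 1-\delta]$ ($\delta = 10^{-3}$) and forms
$\tfrac{1}{4\pi} + \tfrac{1}{16\pi^2} \mathrm{FRT}\{\Delta_b \cdot\}$.
A third published constructor (the diffusion orientation transform) is
not implemented; analytic, QBI and CSA surfaces already exercise every
downstream contract. Whether ODFs should be min–max normalized or
unit-integral before thresholding is unstated in print; min–max is the
default because the threshold $P = 0.02$ only makes sense on a
normalized scale.

## Sphere geometry and numerics

Evaluation meshes are deterministic spherical Fibonacci lattices
(default 724 vertices, matching the published evaluation set size, whose
provenance is otherwise unknown) triangulated by their 3-D convex hull —
for points on a sphere, exactly the spherical Delaunay triangulation.
The hull is built by a hand-written incremental algorithm because no
installed computational-geometry package provides one; the mesh is
validated by Euler's formula and nearest-neighbor spacing tests.
Per-vertex quadrature weights start from one third of the incident
spherical triangle areas and are then corrected by least squares to
integrate spherical harmonics exactly up to a mesh-dependent order
(16 at the default sizes): the raw vertex rule converges too slowly for
sharply peaked ODFs, while the corrected rule reaches $\sim 10^{-6}$
relative error on the mixture ODFs at 724 vertices with all weights
positive.

Interpolation of sampled ODFs locates the triangle whose
central-projection cone contains the query (brute force over triangles
with precomputed solve matrices — adequate at a few thousand triangles)
and returns either the nearest vertex value, reproducing the published
sample-snapped scheme, or the barycentric average. Nearest-neighbor
surfaces are piecewise constant, so line searches stall on their
plateaus; the continuous objectives (analytic closed form, SH evaluation,
or barycentric samples) are the default whenever available, with nearest
mode kept for fidelity experiments. For the optimizer's hot path the SH
evaluation is collapsed once per ODF into per-order polynomials in
$z = \sin\varphi$ (Horner evaluation plus trigonometric recurrences),
bit-identical to the basis-matrix route up to roundoff.

Degenerate inputs: an isotropic signal reconstructs to a constant ODF,
which min–max normalization cannot scale — the objective constructor
raises a *degenerate objective* error and the pipeline records an empty
peak set with a warning. Ties in the grid-peak oracle (plateaus) produce
no strict maximum and are flagged. Pole queries define azimuth 0 by
convention.

## Evaluation harness

Recovered peaks are matched one-to-one to planted directions by
exhaustive assignment minimizing total antipodal arc (exact up to 7
peaks), with pairs beyond `max_arc` (default 20°, unstated in print)
counted as missed or spurious. Azimuth and elevation deviations are
reported after mapping each found direction to the antipodal
representative nearest its matched truth, so grouped bar summaries can be
regenerated in the published style; success means correct count *and*
all matched arcs within the gate. `run_experiment()` crosses phantoms ×
reconstructions × SNR × repetitions with per-cell derived seeds, and
reports both per-repetition rows and aggregates, since single-run versus
averaged reporting is ambiguous in the source.

Problem sizes used by the shipped validation suites: the three standard
phantoms on the 724-vertex mesh; a 50-phantom random-crossing study
(1–3 tensors, pairwise separation ≥ 40°) checked against a 2562-vertex
1-ring grid oracle; and a 100-seed SNR-20 robustness study on the
two-fiber QBI reconstruction. These sizes keep the full suite in the
tens of minutes on a single core while leaving the statistical
conclusions stable across seeds.

## Known limitations

- Peak *locations* on crossing phantoms are biased by lobe overlap
  (≈0.3–0.7° on the noiseless analytic ODFs; several degrees for QBI at
  a 69.9° crossing) — a property of the mixture and the reconstruction,
  not of the optimizer, and within the tolerances used throughout.
- The derandomized swarm's coverage guarantee is statistical: a basin
  that receives no particle in any round cannot be found. With
  $N = 100$ and the default round schedule this was never observed for
  up to three fibers separated by ≥ 40°.
- Volume fractions are not estimated (stated future work in the source);
  no tractography, no multi-shell models, no deconvolution.
- The voxel-wise CLI pipeline is serial; large volumes are out of scope
  for this reference implementation.
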