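---
title: "Methods: dimer determination from pulsed-EPR distance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimer determination from pulsed-EPR distance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerdock)
```

# Scope and model

`deerdock` determines the architecture of a C2-symmetric membrane-protein
dimer from PELDOR/DEER distance measurements between spin labels placed at
symmetry-equivalent sites of the two protomers, and models the functional
consequences of dimerization with a stochastic heterodimer-mixing model.
The pipeline is: spin-label ensemble modelling, forward simulation of
dipolar time traces, Tikhonov inversion of measured traces into distance
distributions, exhaustive rigid-body docking of two protomer copies under
a two-fold symmetry constraint, maximum-entropy reweighting of the label
rotamers against the traces, and initial-rate analysis of transport by
protomer mixtures.

## Dipolar signal model

For an isolated pair of nitroxide spins at distance $r$ (nm), the
orientation-averaged dipolar evolution is

$$K(t, r) = \int_0^1 \cos\!\big[(3u^2 - 1)\,\omega_{dd}\,t\big]\,du,
\qquad \omega_{dd} = \frac{2\pi \cdot 52.04\ \mathrm{MHz\,nm^3}}{r^3},$$

with $t$ in µs. The constant 52.04 MHz nm³ is the standard nitroxide
value. $K$ is evaluated through its Fresnel-integral closed form
(power series below $x = 1.5$, a modified Lentz continued fraction above,
accurate to ~1e-14 against SciPy's implementation); a brute-force
quadrature fallback exists and the equivalence of the two routes is a
tested property. Note that a *midpoint* rule with 2001 nodes is itself
only accurate to ~1e-5 at the highest phases in the working range
($r = 1.5$ nm, $t = 3$ µs); the test oracle therefore uses 2001-node
Gauss–Legendre quadrature, which is exact to machine precision there.

A distance distribution $P(r)$ and modulation depth $\lambda$ give the
form factor $F(t) = 1 - \lambda + \lambda \int P(r) K(t, r)\,dr$, and the
primary trace is $V(t) = F(t)\,B(t)$ with a homogeneous 3-dimensional
intermolecular background $B(t) = e^{-kt}$ (stretched-exponential
$d \ne 3$ available). The background rate is fitted by log-linear least
squares on the final 75% of the trace by default. For a dimer with
labelling efficiency $f$ and pump inversion efficiency $\lambda_B$, the
expected depth is $\lambda = f \lambda_B$.

Orientation selection, multi-spin effects and exchange coupling are
neglected: each dimer carries at most two coupled labels and the labels
are conformationally disordered.

## Spin-label model

The crystallographic rotamer libraries used by established labelling
software are not redistributable, so the default label model is a
documented stand-in: `n = 200` candidate positions drawn uniformly in a
spherical shell of 0.4–0.9 nm around the side-chain anchor (Cβ when
present, an ideal pseudo-Cβ built from the N/Cα/C triad otherwise, and
the Cα itself for Cα-trace models), rejecting candidates within 0.25 nm
of any protein heavy atom. The shell radii approximate the Cβ–nitroxide
tether length; they are defaults, not measured values. A file-based hook
(`attach_label(model = "table")`) accepts real rotamer tables given as
displacements in the local backbone frame. This stand-in is *much
broader* than a real MTSSL rotamer cloud; consequences for the synthetic
scenarios are discussed below.

## Tikhonov inversion

Distance recovery solves
$\min_{p \ge 0} \|K_\lambda p - s\|^2 + \alpha^2 \|L_2 p\|^2$
on a uniform $r$-grid, where $K_\lambda$ is the depth-scaled kernel
matrix with trapezoidal quadrature weights folded in, $s$ the
depth-adjusted signal, and $L_2$ the interior second-difference operator.
Non-negativity is enforced by Lawson–Hanson active-set least squares
implemented on the normal equations (the stacked Tikhonov block keeps
them well conditioned; a QR fallback guards rank deficiency). The
regularization parameter is chosen at the corner (maximum Menger
curvature) of the (log residual, log seminorm) L-curve over at least 8
log-spaced candidates. When the modulation depth is unknown it is fitted
by a 1-D scan over 0.05–0.95 in steps of 0.01, minimizing the residual.
Moments are trapezoidal; no error bars are attached.

## Rigid-body C2 docking

A dimer pose has four parameters: rotation $\alpha \in [0, 360)$ about
the membrane normal (z), tilt $\beta \in [0, 180]$ about y, and in-plane
translation $(x, y)$. Rotations are active and right-handed, applied
$\alpha$ about z first, then $\beta$ about y, then the translation; the
second protomer is the 180° z-rotation of the first, which freezes the
third Euler angle and the z-translation at 0. The default search grid is
$\alpha$ in 10° steps, $\beta$ in 5° steps, $x, y$ within ±7.5 nm in
0.25 nm steps (≈5.1 M nodes).

Nodes are excluded unless the dimer is clash-free (no inter-protomer
Cα–Cα pair below 0.4 nm) and in contact (some pair within 1.0 nm); these
two cutoffs are documented defaults, not measured values. Surviving
nodes are scored by the RMSD between simulated mean inter-label distances
and the restraint means (unweighted by default; inverse-variance
weighting behind a flag). The compiled search marks clash/contact per
(x, y) node by exact per-pair disc tests, so the full default grid on a
~100-residue Cα toy completes in seconds. Per-site ensembles above 64
positions are deterministically thinned for grid scoring only; local
refinement (Nelder–Mead, initial step one grid cell, stopping at score
changes below 1e-4) re-scores with full ensembles and never returns a
score above its start.

Two identifiability facts matter when interpreting results:

* **Membrane-flip gauge.** The pose
  $(\alpha + 180°,\ 180° - \beta,\ x,\ -y)$ generates *the same dimer*
  as $(\alpha, \beta, x, y)$ up to a global rotation, so no distance
  data can distinguish them. Recovery tests accept either
  representative.
* **Three restraints, four parameters.** With only three restrained
  sites the level set of a perfect fit is generically a curve in pose
  space; the contact shell breaks the degeneracy only partially. The
  recovery property tests therefore use toys with six labelled sites,
  while the shipped three-site default scenario is verified end-to-end
  for its fixed pose. Small $\beta$ is particularly degenerate: at
  $\beta = 0$ a global z-rotation maps poses within the family.

The time-domain route (`contact_sweep`) instead spins the second
protomer about its own axis ($\varphi_2$, 10° steps), revolves it about
the first protomer's axis ($\varphi_1$, 5° steps; the reported "polar
plane angle" by convention), translates it radially inward to the first
clash-free touching position (step scan plus bisection to 1e-3 nm), and
scores the summed per-site chi-squared between forward-calculated and
experimental form factors. This literal construction is exactly
C2-symmetric only at $\varphi_2 = 180°$; symmetry is enforced by the
distance-restraint route.

## Maximum-entropy rotamer reweighting

Per labelled site, rotamer-pair weights $w$ minimize
$\theta\, S_{KL}(w \| w^0) + \chi^2(w)/2$ over the simplex, with the
pair-trace matrix as forward model. The optimizer works in softmax
(log-weight) coordinates with analytic gradients (L-BFGS-B restarts,
plus an exact damped Newton polish with the full softmax-chain Hessian
for problems up to 400 weights). Convergence is declared at a gradient
sup-norm of 1e-8 *relative to the gradient magnitude at the reference
weights*: the chi-squared gradient carries $1/\sigma^2$, so an absolute
1e-8 would exceed double precision on small-noise problems; on
O(1)-scaled toys the two criteria coincide. The noise sd defaults to the
standard deviation of the final 20% of the trace.

$\theta$ is selected at the corner of the $(\log\chi^2, \log S_{KL})$
curve over a 13-point log grid ($10^{-2}$–$10^4$). The curvature is
taken on log–log axes: on the literal $(\log\chi^2, S_{KL})$ curve the
Menger curvature peaks degenerately among the nearly collinear points at
the prior-dominated end. Monotonicity of the trade-off
($\chi^2$ non-increasing, $S_{KL}$ non-decreasing as $\theta$ falls) is
checked and a violation raises an error; a zero-misfit problem
degenerates and falls back to the largest candidate $\theta$. Conformer
selection runs the reweighting per site — at a fixed shared $\theta$
(e.g. 10) or with per-site L-curve selection, both policies being
defensible readings of the published procedure — and returns the
conformer with minimal total chi-squared.

## Heterodimer mixing model

Stochastic assembly of dimers from a pool with wild-type fraction $f$
gives class fractions $(f^2,\ 2f(1-f),\ (1-f)^2)$. With homodimer
specific activities $a_{WT} = 32.3$ and $a_{IL} = 6.8$ nmol mg⁻¹ min⁻¹
and heterodimer activity $c_{het} \cdot a_{WT}$,

$$\mathrm{rate}(f) = f^2 a_{WT} + 2f(1-f)\,c_{het}\,a_{WT} + (1-f)^2 a_{IL},$$

exactly quadratic in $f$ with the homodimer activities at the endpoints.
Given fixed activities the model is linear in $c_{het}$, so the
least-squares estimate is closed-form (clipped to [0, 1]); the three
reference models $c_{het} \in \{0, 0.5, 1\}$ are compared by SSE with
ties broken toward fewer active species. One point of care: the
independent-protomer expectation (each protomer contributing half its
homodimer activity, the straight line between the endpoint activities)
corresponds to $c_{het} = (a_{WT} + a_{IL})/(2a_{WT}) \approx 0.605$,
not to the $c_{het} = 0.5$ reference model, unless the mutant homodimer
is fully inactive.

Initial rates are ordinary least-squares slopes over the early window,
defined by default as points with uptake at or below 30% of the fitted
saturation plateau (minimum three points; a fixed-first-k policy is
available), averaged over technical replicates. This window estimator
carries a known downward bias of order $k\bar t$ on saturating data
(about 10% when the window reaches 30% of the plateau); assays intended
for initial rates should sample the early linear phase densely, and the
synthetic uptake generator does.

# The synthetic world

All tests run against generated data; nothing is downloaded.

* **Toy protomers** are Cα traces of ideal helices (rise 0.15 nm,
  100°/residue, Cα ring radius 0.23 nm) standing parallel to the
  membrane normal on a ring; the seed sets helix phases. They reproduce
  backbone geometry (consecutive Cα–Cα ≈ 0.38 nm) but have no side
  chains, no sequence and no membrane.
* **The default truth scenario** is a 4-helix × 24-residue toy with
  three labelled sites and the fixed contact pose
  (α = 30°, β = 10°, x = 1.5 nm, y = 0.5 nm), giving inter-protomer mean
  distances of roughly 4.2, 3.6 and 2.9 nm, modulation depth 0.4,
  background rate 0.2 µs⁻¹, 2.5 µs traces at 8 ns steps, Gaussian noise
  sd 0.01 — the conditioning regime of real dimer measurements. The
  published site distances (4.4/3.9/1.8 nm) cannot all be imitated: the
  uniform-shell label stand-in is so broad that a 1.8 nm mean would put
  pair-distance density below the ~1 nm resolvable floor, so sites were
  chosen with all pair distances inside 1–8 nm. The acceptance round
  trips use the printed Gaussians directly and are unaffected by this
  choice.
* **Uptake datasets** follow
  $u(t) = A\,(1 - e^{-\mathrm{rate}(f)\,t/A})$ with plateau
  $A = 1000$ nmol/mg and sampling at 0.5–4 min: an assay designed so the
  sampled window is close to linear (curvature < 15%), as initial-rate
  assays are in practice. Noise sd 0.5 nmol/mg, three technical
  replicates, f from 0 to 1 in steps of 0.2.

A green test therefore establishes internal consistency of the pipeline
under realistic conditioning — pose recovery to one grid step,
distance-mean recovery to 0.05–0.1 nm, $c_{het}$ recovery to 0.1 — not
agreement with any particular measured protein.

# Numerical choices and degenerate inputs

* Internal unit is nm everywhere; Å appears only at PDB boundaries and
  in reported buried-surface areas. Buried surface uses Shrake–Rupley
  sampling (golden-spiral points, 960 per atom by default, Bondi radii,
  probe 0.14 nm) and converges within 1% when the sampling doubles.
* Distance histograms assign each weighted pair to the nearest grid
  point and renormalize to unit trapezoidal integral; the *exact*
  weighted pair mean/sd are carried as attributes and used for docking
  restraints, so binning never biases a score. Zero-distance pairs
  (labels on the symmetry axis) are dropped with a warning.
* Grid vectors are sorted and deduplicated before the search; ranking
  ties break lexicographically by (α, β, x, y), making every search
  deterministic.
* `make_c2_dimer` centres the protomer's geometric centre first;
  `center = FALSE` supports coordinates already in the docking frame.
* All generators and label sampling use private, restorable RNG streams:
  the same seed gives byte-identical bundles and the caller's RNG state
  is untouched.

# Known limitations

* The uniform-shell label model reproduces neither rotamer energetics
  nor the anisotropy of real MTSSL clouds; simulated means at buried or
  tether-constrained sites will differ from rotamer-library predictions.
* No uncertainty quantification: Tikhonov moments, docking poses and
  BioEn weights carry no error bars.
* The docking treats protomers as rigid and the membrane as an implicit
  z-convention; no lipids, no flexibility, no symmetry detection.
* Background correction assumes a homogeneous 3-D spin distribution by
  default; the fit window and dimensionality are user-visible knobs, and
  misspecifying them propagates directly into the form factor.
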