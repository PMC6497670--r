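# deerdock

Determining how two copies of a membrane transporter pack into a dimer —
when the dimer only forms in a lipid bilayer and resists crystallography —
is a classic use case for pulsed EPR. PELDOR/DEER measures nanometre
distances between nitroxide spin labels placed at symmetry-equivalent
sites of the two protomers; a handful of such distance distributions,
plus the two-fold symmetry of the dimer, can pin down the interface.
`deerdock` implements that computation as a tested R pipeline, together
with the functional counterpart: a stochastic heterodimer-mixing model
that asks whether the two protomers in a dimer work independently or
cooperate.

The package is aimed at spectroscopists and structural modellers who have
(or simulate) DEER time traces and want to go from traces to a docked
C2 dimer and from uptake time courses to a heterodimer activity model,
fully offline.

## What it computes

* **Dipolar forward model.** The powder-averaged two-spin kernel
  `K(t, r) = ∫₀¹ cos[(3u² − 1) ω t] du`, `ω = 2π·52.04 MHz·nm³/r³`,
  via its Fresnel closed form; form factors
  `F(t) = 1 − λ + λ ∫ P(r) K(t, r) dr`; exponential intermolecular
  background `B(t) = e^(−kt)` with tail fitting.
* **Inversion.** Non-negative Tikhonov regularization
  `min ‖Kp − s‖² + α²‖L₂p‖²`, `p ≥ 0` (Lawson–Hanson), with L-curve
  selection of `α` and optional modulation-depth fitting.
* **Spin labels.** A uniform-shell rotamer stand-in (0.4–0.9 nm around
  Cβ, clash-rejected) plus a hook for real rotamer tables; weighted
  pair-distance distributions, including the C2-symmetric case.
* **Docking.** Exhaustive grid search over the C2 pose
  `(α, β, x, y)` — default grid α: 0–360° by 10°, β: 0–180° by 5°,
  x, y: ±7.5 nm by 0.25 nm — with clash/contact filtering in compiled
  code, distance-RMSD scoring against per-site mean restraints,
  Nelder–Mead refinement, and a time-domain contact-sweep alternative.
* **Ensemble reweighting.** BioEn-style maximum-entropy reweighting of
  rotamer-pair weights, `min θ·S_KL(w‖w⁰) + χ²(w)/2`, with L-curve
  selection of θ and minimum-total-χ² conformer selection.
* **Transport mixing.** Binomial dimer assembly
  `(f², 2f(1−f), (1−f)²)`, the quadratic activity model
  `rate(f) = f²·a_WT + 2f(1−f)·c_het·a_WT + (1−f)²·a_IL`, initial-rate
  estimation from uptake time courses, and closed-form fitting of the
  heterodimer activity fraction `c_het`.
* **Synthetic data.** Seeded toy protomers, ground-truth dimer bundles
  (PDB + traces + restraints + manifest) and uptake datasets, so the
  whole pipeline is testable without downloads.

## Worked example

```r
library(deerdock)

# 1. simulate a ground-truth dimer scenario (Cα toy, 3 labelled sites)
sc <- default_scenario(seed = 1, dir = file.path(tempdir(), "bundle"))
sc$restraints$entries
#>   site     mean        sd
#> 1    2 4.244510 0.6087046
#> 2   32 3.482751 0.6395321
#> 3   29 2.727508 0.5940363

# 2. process one site's noisy primary trace: background + inversion
tr <- read_deer_trace(file.path(sc$dir, "trace_site2.dat"), kind = "primary")
ff <- remove_background(tr, fit_background(tr))
inv <- tikhonov_invert(ff, seq(1, 7.5, 0.025), reg_param = 1e-2, depth = 0.4)
distribution_moments(inv$distribution)
#>      mean        sd
#> 4.2343314 0.7692896

# 3. dock two protomer copies against the bundled restraints
ctr <- colMeans(coords(sc$protomer))
centred <- apply_transform(translation(-ctr), sc$protomer)
ens <- setNames(lapply(sc$spec$label_sites, function(s)
  attach_label(centred, list("A", s), seed = sc$spec$seed + s)),
  as.character(sc$spec$label_sites))
ranked <- grid_search(sc$protomer, ens, sc$restraints,
                      grid = dock_grid(x = seq(-4, 4, 0.25),
                                       y = seq(-4, 4, 0.25)),
                      max_ensemble = 200)
head(ranked[, 1:6], 3)
#>   alpha beta    x     y     rmsd min_dist
#> 1   210  170 1.50 -0.50 2.21e-12    0.404
#> 2    30   10 1.50  0.50 2.21e-12    0.404
#> 3   250  130 1.75 -1.25 3.35e-02    0.480
```

The simulated truth pose was (30°, 10°, 1.5 nm, 0.5 nm): the mean
distance recovered from the noisy trace (4.23 nm) matches the bundled
restraint (4.24 nm), and the top two grid nodes are the truth pose and
its membrane-flip partner (α+180°, 180°−β, x, −y), which generates the
identical dimer and is indistinguishable by any distance data — both at
rmsd ≈ 0.

```r
# 4. heterodimer mixing with the published homodimer activities
dimer_fractions(0.5)
#>      f_ww f_wi f_ii
#> [1,] 0.25  0.5 0.25
ds <- make_uptake_dataset(mixing_model(32.3, 6.8, c_het = 0.5), seed = 1)
rates <- do.call(rbind, lapply(split(ds, ds$f_wt), function(g) {
  class(g) <- c("uptake_time_course", "data.frame")
  data.frame(f_wt = g$f_wt[1], rate = initial_rate(g)$rate)
}))
fit_mixing(rates, a_wt = 32.3, a_il = 6.8)[c("c_het", "best_model")]
#> c_het estimate: 0.433; best discrete model: 0.5
```

A 50:50 protomer mix gives 25/50/25% dimer classes; with activities
32.3 and 6.8 nmol·mg⁻¹·min⁻¹ the fitted heterodimer fraction (0.43)
identifies the planted half-active model against the 0% and 100%
alternatives.

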