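#' Toy protomer specification
#'
#' Cα-trace protomers built from ideal helices (rise 0.15 nm per
#' residue, 100 degree turn) standing parallel to z (the membrane
#' normal) on a circle. Deterministic per seed (the seed sets the helix
#' phase angles).
#'
#' @param n_helices number of helices (>= 1).
#' @param helix_len residues per helix.
#' @param ring_radius circle radius for helix placement (nm).
#' @param label_sites residue numbers to label (within range).
#' @param seed integer seed.
#' @return object of class `toy_spec`.
#' @export
toy_spec <- function(n_helices = 3L, helix_len = 20L, ring_radius = 1.0,
                     label_sites = integer(), seed = 1L) {
  stopifnot(n_helices >= 1L, helix_len >= 2L)
  n_res <- n_helices * helix_len
  if (length(label_sites) && (any(label_sites < 1) ||
                              any(label_sites > n_res)))
    stop("toy_spec: label sites outside residue range 1..", n_res)
  structure(list(n_helices = as.integer(n_helices),
                 helix_len = as.integer(helix_len),
                 ring_radius = ring_radius,
                 label_sites = as.integer(label_sites),
                 seed = as.integer(seed)),
            class = "toy_spec")
}

.helix_radius <- 0.23   # Calpha helix radius, nm
.helix_rise <- 0.15     # rise per residue, nm
.helix_turn <- 100      # degrees per residue

#' Build a toy Cα-trace protomer
#'
#' @param spec a [toy_spec()].
#' @return a `structure3d` with one CA atom per residue, chain "A".
#' @export
make_toy_protomer <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  nh <- spec$n_helices; hl <- spec$helix_len
  if (nh > 1L) {
    axis_sep <- 2 * spec$ring_radius * sin(pi / nh)
    if (axis_sep < 2 * .helix_radius + 0.3)
      stop("make_toy_protomer: helix placement overlaps (axis separation ",
           signif(axis_sep, 3), " nm)")
  }
  phases <- with_private_seed(spec$seed, stats::runif(nh, 0, 360))
  height <- (hl - 1) * .helix_rise
  rows <- vector("list", nh * hl)
  res <- 0L
  for (h in seq_len(nh)) {
    ang <- 2 * pi * (h - 1) / nh
    cx <- if (nh > 1L) spec$ring_radius * cos(ang) else 0
    cy <- if (nh > 1L) spec$ring_radius * sin(ang) else 0
    for (j in seq_len(hl)) {
      res <- res + 1L
      th <- (phases[h] + .helix_turn * (j - 1)) * pi / 180
      rows[[res]] <- data.frame(
        chain = "A", resno = res, resname = "ALA", atom = "CA",
        element = "C",
        x = cx + .helix_radius * cos(th),
        y = cy + .helix_radius * sin(th),
        z = -height / 2 + .helix_rise * (j - 1))
    }
  }
  structure3d(do.call(rbind, rows),
              label = sprintf("toy-%dx%d-seed%d", nh, hl, spec$seed))
}

#' Ground-truth dimer scenario with file bundle
#'
#' Builds the toy protomer, attaches uniform-shell labels at the spec's
#' sites, constructs the C2 dimer at the ground-truth pose, computes the
#' true per-site distance distributions, forward-simulates noisy primary
#' PELDOR traces (intramolecular form factor times exponential
#' background, Gaussian noise), and writes a self-contained bundle:
#' `protomer.pdb`, `pr_site<r>.csv`, `trace_site<r>.dat`,
#' `restraints.csv` and `manifest.json`. Byte-identical for identical
#' seeds.
#'
#' @param spec a [toy_spec()] with at least one label site.
#' @param pose ground-truth [c2_pose()]; must be clash-free and in
#'   contact for the toy.
#' @param dir output directory (created if needed).
#' @param depth modulation depth lambda (default 0.4, dimer regime).
#' @param bg_rate intermolecular background rate k in 1/us (default 0.2).
#' @param noise_sd Gaussian noise sd on the primary trace (default 0.01).
#' @param t_max,dt time grid (us), defaults 2.5 us at 8 ns steps.
#' @param label_n shell candidates per site.
#' @param r_grid distance grid for the truth distributions.
#' @return invisible list `(spec, pose, protomer, ensembles, truth_pr,
#'   traces, restraints, params, dir, manifest)`.
#' @export
make_truth_scenario <- function(spec, pose, dir = tempfile("scenario"),
                                depth = 0.4, bg_rate = 0.2,
                                noise_sd = 0.01, t_max = 2.5, dt = 0.008,
                                label_n = 200L,
                                r_grid = seq(0.5, 10, by = 0.02)) {
  stopifnot(inherits(spec, "toy_spec"), length(spec$label_sites) >= 1L)
  pose <- as_c2_pose(pose)
  protomer <- make_toy_protomer(spec)
  dimer <- make_c2_dimer(protomer, pose)
  cc <- clash_and_contact(dimer$A, dimer$B)
  if (cc$is_clashing) stop("make_truth_scenario: ground-truth pose clashes")
  if (!cc$is_in_contact)
    stop("make_truth_scenario: ground-truth pose is not in contact")
  # ensembles in the centred protomer frame (toy is built centred already
  # up to its geometric centre)
  ctr <- colMeans(coords(protomer))
  centred <- apply_transform(translation(-ctr), protomer)
  ensembles <- list()
  for (s2 in spec$label_sites) {
    ensembles[[as.character(s2)]] <-
      attach_label(centred, list("A", s2), seed = spec$seed + s2,
                   n = label_n)
  }
  tgrid <- seq(0, t_max, by = dt)
  truth_pr <- list(); traces <- list(); noisy <- list()
  noise <- with_private_seed(spec$seed + 99991L,
                             lapply(seq_along(ensembles), function(i)
                               stats::rnorm(length(tgrid), 0, noise_sd)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  restr <- data.frame(site = character(), mean = numeric(), sd = numeric())
  for (i in seq_along(ensembles)) {
    s2 <- names(ensembles)[i]
    pd <- c2_pair_distribution(ensembles[[s2]], pose, r_grid)
    truth_pr[[s2]] <- pd
    ff <- form_factor(pd, tgrid, depth)
    prim <- apply_background(ff, background_model(bg_rate))
    v <- prim$v + noise[[i]]
    v[1] <- 1
    noisy[[s2]] <- deer_trace(tgrid, v, kind = "primary", depth = depth)
    traces[[s2]] <- ff
    # exact weighted pair moments (attributes), not the binned histogram's
    restr <- rbind(restr, data.frame(site = s2, mean = attr(pd, "mean"),
                                     sd = attr(pd, "sd")))
    utils::write.csv(data.frame(r = pd$r, p = pd$p),
                     file.path(dir, sprintf("pr_site%s.csv", s2)),
                     row.names = FALSE)
    write_deer_trace(noisy[[s2]], file.path(dir,
                                            sprintf("trace_site%s.dat", s2)),
                     meta = list(k = bg_rate, noise_sd = noise_sd,
                                 seed = spec$seed, site = s2))
  }
  write_pdb(protomer, file.path(dir, "protomer.pdb"))
  utils::write.csv(restr, file.path(dir, "restraints.csv"),
                   row.names = FALSE)
  manifest <- list(
    kind = "deerdock-truth-scenario",
    seed = spec$seed,
    toy = list(n_helices = spec$n_helices, helix_len = spec$helix_len,
               ring_radius = spec$ring_radius,
               label_sites = spec$label_sites),
    pose = list(alpha = pose$alpha, beta = pose$beta, x = pose$x,
                y = pose$y),
    trace = list(depth = depth, bg_rate = bg_rate, noise_sd = noise_sd,
                 t_max = t_max, dt = dt),
    files = list(protomer = "protomer.pdb", restraints = "restraints.csv",
                 traces = sprintf("trace_site%s.dat", names(ensembles)),
                 pr = sprintf("pr_site%s.csv", names(ensembles))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(spec = spec, pose = pose, protomer = protomer,
                 ensembles = ensembles, truth_pr = truth_pr,
                 form_factors = traces, primary_traces = noisy,
                 restraints = restraint_set(restr),
                 params = list(depth = depth, bg_rate = bg_rate,
                               noise_sd = noise_sd),
                 dir = dir, manifest = manifest))
}

#' Default ground-truth scenario
#'
#' A 4-helix, 24-residue-per-helix Cα toy with three labelled sites and
#' a fixed contact pose, emulating the measured regime: inter-protomer
#' mean distances of roughly 1.5-5 nm, modulation depth 0.4, 2.5 us
#' traces.
#'
#' @param seed integer seed.
#' @param dir bundle directory.
#' @param ... passed to [make_truth_scenario()].
#' @return see [make_truth_scenario()].
#' @export
default_scenario <- function(seed = 1L, dir = tempfile("scenario"), ...) {
  spec <- toy_spec(n_helices = 4L, helix_len = 24L, ring_radius = 1.0,
                   label_sites = c(2L, 32L, 29L), seed = seed)
  make_truth_scenario(spec, c2_pose(30, 10, 1.5, 0.5), dir = dir, ...)
}

#' Simulated proteoliposome uptake dataset
#'
#' uptake(t) = plateau * (1 - exp(-rate(f) t / plateau)) (initial slope
#' rate(f), saturating), plus seeded Gaussian noise; `plateau = Inf`
#' gives a pure line. One series per mixing fraction with the requested
#' number of technical replicates.
#'
#' @param model a [mixing_model()] (planted truth).
#' @param f_grid mixing fractions (default 0 to 1 by 0.2, mirroring a
#'   WT/mutant titration).
#' @param times sampling times in minutes.
#' @param noise_sd Gaussian noise sd on uptake (nmol/mg).
#' @param replicates technical replicates per fraction (default 3).
#' @param plateau saturation level (nmol/mg); Inf for no saturation.
#' @param seed integer seed.
#' @return an [uptake_time_course()] covering all fractions/replicates.
#' @export
make_uptake_dataset <- function(model, f_grid = seq(0, 1, by = 0.2),
                                times = c(0.5, 1, 1.5, 2, 3, 4),
                                noise_sd = 0.5, replicates = 3L,
                                plateau = 1000, seed = 1L) {
  stopifnot(inherits(model, "mixing_model"))
  rows <- with_private_seed(seed, {
    out <- list(); k <- 0L
    for (f in f_grid) {
      rate <- predicted_rate(f, model)
      for (rep in seq_len(replicates)) {
        mu <- if (is.finite(plateau))
          plateau * (1 - exp(-rate * times / plateau)) else rate * times
        k <- k + 1L
        out[[k]] <- data.frame(
          time_min = times,
          uptake_nmol_per_mg = mu + stats::rnorm(length(times), 0, noise_sd),
          replicate = rep, f_wt = f)
      }
    }
    out
  })
  df <- do.call(rbind, rows)
  class(df) <- c("uptake_time_course", "data.frame")
  df
}
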