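#' Distance restraints for docking
#'
#' A restraint set maps labelled sites to target (mean, sd) inter-protomer
#' distances in nm, as obtained from Tikhonov inversion of PELDOR data.
#'
#' @param entries data.frame with columns `site` (character key matching
#'   the names of the ensemble list), `mean` (nm, > 0), `sd` (nm, >= 0).
#' @return object of class `restraint_set`.
#' @export
restraint_set <- function(entries) {
  entries <- as.data.frame(entries)
  stopifnot(all(c("site", "mean", "sd") %in% names(entries)))
  if (any(entries$mean <= 0)) stop("restraint_set: means must be positive")
  if (any(entries$sd < 0)) stop("restraint_set: sds must be non-negative")
  structure(list(entries = entries), class = "restraint_set")
}

#' Distance-RMSD score of a pose
#'
#' Simulates the mean inter-protomer spin-spin distance for every
#' restrained site at the given pose and returns the root mean square
#' deviation from the restraint means:
#' `rmsd = sqrt(mean_s (simulated_s - target_s)^2)`. Restraint sds are
#' carried but unweighted by default; `weighted = TRUE` applies
#' inverse-variance weights.
#'
#' @param pose a [c2_pose()].
#' @param ensembles named list of `spin_site_ensemble` objects (centred
#'   protomer frame), names matching `restraints$entries$site`.
#' @param restraints a [restraint_set()].
#' @param weighted inverse-variance weighting flag.
#' @return list `(rmsd, means)` with per-site simulated mean distances.
#' @export
score_distance <- function(pose, ensembles, restraints, weighted = FALSE) {
  pose <- as_c2_pose(pose)
  ent <- restraints$entries
  missing <- setdiff(ent$site, names(ensembles))
  if (length(missing))
    stop("score_distance: no ensemble for site(s): ",
         paste(missing, collapse = ", "))
  means <- vapply(ent$site, function(s2) {
    e <- ensembles[[s2]]
    tr <- c2_placement(pose)
    pa <- apply_transform(tr, e$positions)
    pb <- apply_transform(rot_z(180), pa)
    dw <- cpp_pair_distances(pa, e$weights, pb, e$weights)
    keep <- dw$d >= 1e-9
    sum(dw$d[keep] * dw$w[keep]) / sum(dw$w[keep])
  }, 0)
  dev2 <- (means - ent$mean)^2
  w <- if (weighted) {
    iv <- 1 / pmax(ent$sd, 1e-6)^2
    iv / sum(iv)
  } else rep(1 / nrow(ent), nrow(ent))
  list(rmsd = sqrt(sum(w * dev2)), means = means)
}

#' Docking grid specification
#'
#' Defaults reproduce the exhaustive search grid used for the
#' distance-restrained docking: alpha 0-360 degrees in 10 degree steps,
#' beta 0-180 degrees in 5 degree steps, x and y within +/- 7.5 nm in
#' 0.25 nm steps (about 5.1 million nodes).
#'
#' @param alpha,beta,x,y grid vectors (degrees, degrees, nm, nm).
#' @return list of grid vectors.
#' @export
dock_grid <- function(alpha = seq(0, 360, by = 10),
                      beta = seq(0, 180, by = 5),
                      x = seq(-7.5, 7.5, by = 0.25),
                      y = seq(-7.5, 7.5, by = 0.25)) {
  list(alpha = alpha, beta = beta, x = x, y = y)
}

#' Exhaustive C2 docking grid search against distance restraints
#'
#' Evaluates every grid node: nodes whose dimer clashes (any
#' inter-protomer Calpha pair closer than `clash_cut`) or is out of
#' contact (no pair within `contact_cut`) are excluded; surviving nodes
#' are scored by [score_distance()] and returned sorted by ascending
#' RMSD, ties broken lexicographically by (alpha, beta, x, y). A
#' centre-distance cull skips (x, y) nodes that cannot possibly be in
#' contact before any pair computation. To keep the full default grid
#' tractable, per-site ensembles larger than `max_ensemble` positions
#' are deterministically thinned (evenly spaced indices) for grid
#' scoring; refinement re-scores with full ensembles.
#'
#' @param protomer a `structure3d` (Calpha atoms are used for
#'   clash/contact).
#' @param ensembles named list of `spin_site_ensemble`s in the centred
#'   protomer frame.
#' @param restraints a [restraint_set()].
#' @param grid a [dock_grid()].
#' @param clash_cut,contact_cut distances in nm.
#' @param max_ensemble ensemble thinning bound for grid scoring.
#' @param top number of best nodes to return.
#' @return data.frame of ranked `dock_result` rows: pose parameters,
#'   `rmsd`, `min_dist`, per-site simulated means, `clash_free = TRUE`.
#' @export
grid_search <- function(protomer, ensembles, restraints,
                        grid = dock_grid(), clash_cut = 0.4,
                        contact_cut = 1.0, max_ensemble = 64L,
                        top = 100L) {
  stopifnot(inherits(protomer, "structure3d"))
  ca <- coords(protomer, "CA")
  if (nrow(ca) == 0L) stop("grid_search: protomer lacks CA atoms")
  ctr <- colMeans(coords(protomer))
  ca <- sweep(ca, 2, ctr)
  ent <- restraints$entries
  missing <- setdiff(ent$site, names(ensembles))
  if (length(missing))
    stop("grid_search: no ensemble for site(s): ",
         paste(missing, collapse = ", "))
  ens <- lapply(ent$site, function(s2) {
    e <- ensembles[[s2]]
    k <- nrow(e$positions)
    idx <- if (k > max_ensemble)
      unique(round(seq(1, k, length.out = max_ensemble))) else seq_len(k)
    list(positions = e$positions[idx, , drop = FALSE],
         weights = e$weights[idx] / sum(e$weights[idx]))
  })
  grid <- lapply(grid, function(g) sort(unique(g)))  # traversal order fixed
  res <- cpp_grid_search(ca, ens, ent$mean,
                         grid$alpha, grid$beta, grid$x, grid$y,
                         clash_cut, contact_cut)
  if (nrow(res) == 0L)
    stop("grid_search: no clash-free node in contact on this grid")
  df <- as.data.frame(res)
  names(df) <- c("alpha", "beta", "x", "y", "rmsd", "min_dist",
                 paste0("mean_", ent$site))
  ord <- order(df$rmsd, df$alpha, df$beta, df$x, df$y)
  df <- df[ord, , drop = FALSE][seq_len(min(top, nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df$clash_free <- TRUE
  df
}

#' Local refinement of a docking pose
#'
#' Derivative-free Nelder-Mead minimization of the docking score
#' starting from a grid node. The initial simplex step is one grid cell
#' per parameter; poses that clash, leave contact or leave `bounds`
#' are penalized. Stops when the score improvement falls below `tol`;
#' the returned score never exceeds the start score. Deterministic for a
#' fixed start.
#'
#' @param start a [c2_pose()] (or coercible).
#' @param score_fn function(pose) -> non-negative score; defaults to the
#'   distance RMSD built from `ensembles`/`restraints` when those are
#'   supplied.
#' @param protomer,ensembles,restraints as in [grid_search()]; used to
#'   build the default score and the clash test.
#' @param step initial step per parameter `(alpha, beta, x, y)`.
#' @param bounds list with `lower`/`upper` length-4 numeric bounds.
#' @param tol convergence tolerance on the score (default 1e-4).
#' @param clash_cut,contact_cut clash/contact distances (nm).
#' @return list `(pose, score, means, clash_free)`.
#' @export
refine <- function(start, score_fn = NULL, protomer = NULL,
                   ensembles = NULL, restraints = NULL,
                   step = c(10, 5, 0.25, 0.25),
                   bounds = list(lower = c(-360, 0, -7.5, -7.5),
                                 upper = c(720, 180, 7.5, 7.5)),
                   tol = 1e-4, clash_cut = 0.4, contact_cut = 1.0) {
  start <- as_c2_pose(start)
  ca <- NULL
  if (!is.null(protomer)) {
    ca0 <- coords(protomer, "CA")
    ca <- sweep(ca0, 2, colMeans(coords(protomer)))
  }
  pose_ok <- function(p) {
    all(p >= bounds$lower) && all(p <= bounds$upper)
  }
  clashes <- function(pose) {
    if (is.null(ca)) return(FALSE)
    pa <- apply_transform(c2_placement(pose), ca)
    pb <- apply_transform(rot_z(180), pa)
    d <- cpp_min_pair_dist(pa, pb)
    d < clash_cut || d > contact_cut
  }
  if (is.null(score_fn)) {
    if (is.null(ensembles) || is.null(restraints))
      stop("refine: supply score_fn or ensembles + restraints")
    score_fn <- function(pose) score_distance(pose, ensembles,
                                              restraints)$rmsd
  }
  obj <- function(par) {
    if (!pose_ok(par)) return(1e6 + sum(pmax(0, bounds$lower - par)) +
                                sum(pmax(0, par - bounds$upper)))
    pose <- c2_pose(par[1], min(max(par[2], 0), 180), par[3], par[4])
    if (clashes(pose)) return(1e5)
    s <- score_fn(pose)
    if (!is.finite(s))
      stop("refine: non-finite score at pose (",
           paste(signif(par, 6), collapse = ", "), ")")
    s
  }
  par0 <- c(start$alpha, start$beta, start$x, start$y)
  s0 <- obj(par0)
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(parscale = step / 0.1,
                                     abstol = tol, reltol = 0,
                                     maxit = 2000L))
  if (opt$value < s0) {
    best <- opt$par; sc <- opt$value
  } else {
    best <- par0; sc <- s0
  }
  pose <- c2_pose(best[1], min(max(best[2], 0), 180), best[3], best[4])
  means <- if (!is.null(ensembles) && !is.null(restraints))
    score_distance(pose, ensembles, restraints)$means else NULL
  list(pose = pose, score = sc, means = means,
       clash_free = !clashes(pose))
}

#' Chi-squared between two traces on a common time grid
#'
#' @param a,b `deer_trace` objects on identical grids.
#' @param noise_sd noise standard deviation (default 1: unweighted SSD).
#' @return scalar chi-squared.
#' @export
trace_chi2 <- function(a, b, noise_sd = 1) {
  stopifnot(length(a$t) == length(b$t), max(abs(a$t - b$t)) < 1e-9)
  sum((a$v - b$v)^2) / noise_sd^2
}

#' Contact-sweep docking scored in the time domain
#'
#' The first docking route: protomer 1 stays fixed at the origin;
#' protomer 2 is spun about its own membrane-normal (z) axis by `phi2`,
#' revolved about protomer 1's z axis by `phi1` (the reported "polar
#' plane angle"), and translated radially inward until the first
#' clash-free touching position (minimum Calpha distance within
#' (`clash_cut`, `contact_cut`]). Each reachable node is scored by the
#' summed per-site chi-squared between forward-calculated (uniform
#' rotamer weight) and supplied experimental form factors. Nodes with no
#' reachable clash-free contact are skipped.
#'
#' @param protomer a `structure3d`.
#' @param ensembles named list of `spin_site_ensemble`s (centred frame).
#' @param traces named list of experimental form-factor [deer_trace()]s,
#'   names matching `ensembles`; each must carry its modulation depth.
#' @param phi1_step,phi2_step sweep steps in degrees (defaults 5 and 10).
#' @param clash_cut,contact_cut distances in nm.
#' @param r_grid distance grid for forward calculation.
#' @return data.frame ranked by ascending chi2 with columns phi1, phi2,
#'   d (centre separation, nm), chi2, min_dist.
#' @export
contact_sweep <- function(protomer, ensembles, traces,
                          phi1_step = 5, phi2_step = 10,
                          clash_cut = 0.4, contact_cut = 1.0,
                          r_grid = seq(0.01, 12, by = 0.02)) {
  stopifnot(inherits(protomer, "structure3d"))
  sites <- names(traces)
  missing <- setdiff(sites, names(ensembles))
  if (length(missing))
    stop("contact_sweep: no ensemble for site(s): ",
         paste(missing, collapse = ", "))
  ctr <- colMeans(coords(protomer))
  ca <- sweep(coords(protomer, "CA"), 2, ctr)
  if (nrow(ca) == 0L) stop("contact_sweep: protomer lacks CA atoms")
  rg <- max(sqrt(rowSums(ca^2)))
  phi1s <- seq(0, 360 - phi1_step, by = phi1_step)
  phi2s <- seq(0, 360 - phi2_step, by = phi2_step)
  # kernel matrices are pose-independent; precompute once per site
  Kmats <- lapply(sites, function(s2)
    dipolar_kernel_matrix(traces[[s2]]$t, r_grid) %*%
      diag(trapz_weights(r_grid)))
  names(Kmats) <- sites
  rows <- list(); ri <- 0L
  skipped <- 0L
  for (p2 in phi2s) {
    ca2 <- apply_transform(rot_z(p2), ca)
    for (p1 in phi1s) {
      u <- c(cos(p1 * pi / 180), sin(p1 * pi / 180), 0)
      mind <- function(d) cpp_min_pair_dist(ca, sweep(ca2, 2, d * u, `+`))
      d_touch <- find_touch(mind, d_hi = 2 * rg + contact_cut + 0.5,
                            clash_cut = clash_cut,
                            contact_cut = contact_cut)
      if (is.na(d_touch)) { skipped <- skipped + 1L; next }
      chi2 <- 0
      for (s2 in sites) {
        e <- ensembles[[s2]]
        tr_exp <- traces[[s2]]
        dp <- tr_exp$depth
        if (is.na(dp)) stop("contact_sweep: trace for ", s2,
                            " lacks a modulation depth")
        e1 <- spin_site_ensemble(e$site, e$positions, e$weights)
        p2pos <- sweep(apply_transform(rot_z(p2), e$positions), 2,
                       d_touch * u, `+`)
        e2 <- spin_site_ensemble(e$site, p2pos, e$weights)
        pd <- pair_distance_distribution(e1, e2, r_grid)
        sv <- 1 - dp + dp * as.numeric(Kmats[[s2]] %*% pd$p)
        sim <- deer_trace(tr_exp$t, sv / sv[1], kind = "form_factor",
                          depth = dp)
        chi2 <- chi2 + trace_chi2(sim, tr_exp)
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(phi1 = p1, phi2 = p2, d = d_touch,
                               chi2 = chi2, min_dist = mind(d_touch))
    }
  }
  if (ri == 0L)
    stop("contact_sweep: no reachable clash-free contact at any node (",
         skipped, " skipped)")
  out <- do.call(rbind, rows)
  out[order(out$chi2, out$phi1, out$phi2), , drop = FALSE]
}

# innermost clash-free centre separation with contact; NA if unreachable
find_touch <- function(mind, d_hi, clash_cut, contact_cut,
                       step = 0.1, tol = 1e-3) {
  d <- d_hi
  prev <- d
  while (d > 0) {
    m <- mind(d)
    if (m < clash_cut) break
    if (m <= contact_cut) {
      # walk further in while clash-free, bisect against the clash front
      lo <- d - step
      while (lo > 0 && mind(lo) >= clash_cut) { d <- lo; lo <- lo - step }
      hi <- d; lo <- max(lo, 0)
      while (hi - lo > tol) {
        mid <- (hi + lo) / 2
        if (mind(mid) >= clash_cut) hi <- mid else lo <- mid
      }
      return(hi)
    }
    prev <- d
    d <- d - step
  }
  # clashed before ever entering the contact window: try bisecting between
  # the last clash-free separation and the clash point
  if (prev > d) {
    hi <- prev; lo <- d
    while (hi - lo > tol) {
      mid <- (hi + lo) / 2
      if (mind(mid) >= clash_cut) hi <- mid else lo <- mid
    }
    if (mind(hi) <= contact_cut && mind(hi) >= clash_cut) return(hi)
  }
  NA_real_
}
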