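# docking fixtures: the shared scenario plus its self-consistent restraints
dock_fixture <- function() {
  if (is.null(.fixture_env$dock)) {
    sc <- shared_scenario()
    .fixture_env$dock <- list(sc = sc, prot = sc$protomer,
                              ens = sc$ensembles,
                              restr = sc$restraints)
  }
  .fixture_env$dock
}

test_that("score_distance matches hand arithmetic and is order-invariant", {
  fx <- dock_fixture()
  # restraints generated from the pose itself score zero
  self <- score_distance(fx$sc$pose, fx$ens, fx$restr)
  expect_lt(self$rmsd, 1e-9)
  # one site, simulated 2.0 vs target 1.8 -> rmsd 0.2
  e <- point_ensemble(c(1, 0, 0))
  r1 <- restraint_set(data.frame(site = "s", mean = 1.8, sd = 0.1))
  sc1 <- score_distance(c2_pose(0, 0, 0, 0), list(s = e), r1)
  expect_equal(sc1$rmsd, 0.2, tolerance = 1e-9)
  # restraint-entry ordering does not matter
  ent <- fx$restr$entries
  shuffled <- restraint_set(ent[rev(seq_len(nrow(ent))), ])
  pose <- c2_pose(100, 20, 1.2, 0.3)
  expect_equal(score_distance(pose, fx$ens, fx$restr)$rmsd,
               score_distance(pose, fx$ens, shuffled)$rmsd,
               tolerance = 1e-12)
  expect_error(score_distance(pose, fx$ens["2"], fx$restr), "site")
  # alpha + 360 gauge
  p2 <- c2_pose(100 + 360, 20, 1.2, 0.3)
  expect_equal(score_distance(p2, fx$ens, fx$restr)$rmsd,
               score_distance(pose, fx$ens, fx$restr)$rmsd,
               tolerance = 1e-12)
})

test_that("grid_search finds the truth node and is resolution-monotone", {
  fx <- dock_fixture()
  # coarse 4-node grid containing the truth node: it ranks first, rmsd ~ 0
  g4 <- dock_grid(alpha = fx$sc$pose$alpha, beta = fx$sc$pose$beta,
                  x = c(fx$sc$pose$x, fx$sc$pose$x + 0.25),
                  y = c(fx$sc$pose$y - 0.25, fx$sc$pose$y))
  rk4 <- grid_search(fx$prot, fx$ens, fx$restr, grid = g4,
                     max_ensemble = 1000L)
  expect_equal(rk4$alpha[1], fx$sc$pose$alpha)
  expect_equal(rk4$x[1], fx$sc$pose$x)
  expect_equal(rk4$y[1], fx$sc$pose$y)
  expect_lt(rk4$rmsd[1], 1e-9)
  expect_true(all(diff(rk4$rmsd) >= -1e-12))
  # doubling grid resolution never increases the best score
  coarse <- dock_grid(alpha = seq(0, 350, 20), beta = seq(0, 180, 10),
                      x = seq(-2, 2, 0.5), y = seq(-2, 2, 0.5))
  fine <- dock_grid(alpha = seq(0, 350, 10), beta = seq(0, 180, 5),
                    x = seq(-2, 2, 0.25), y = seq(-2, 2, 0.25))
  b_coarse <- grid_search(fx$prot, fx$ens, fx$restr, grid = coarse)$rmsd[1]
  b_fine <- grid_search(fx$prot, fx$ens, fx$restr, grid = fine)$rmsd[1]
  expect_lte(b_fine, b_coarse + 1e-12)
  # empty clash-free set errors
  expect_error(grid_search(fx$prot, fx$ens, fx$restr,
                           grid = dock_grid(alpha = 0, beta = 0,
                                            x = 7.5, y = 7.5)),
               "clash-free")
})

test_that("refine improves the score and stays at optima", {
  fx <- dock_fixture()
  # the documented refinement start from a global search
  start <- c2_pose(360, 5, 5, 1)
  score_fn <- function(pose) score_distance(pose, fx$ens, fx$restr)$rmsd
  ref <- refine(start, score_fn = score_fn)
  expect_lte(ref$score, score_fn(start) + 1e-12)
  # an exact optimum is returned unchanged
  opt <- refine(fx$sc$pose, score_fn = score_fn, protomer = fx$prot,
                ensembles = fx$ens, restraints = fx$restr)
  expect_lt(abs(opt$score), 1e-9)
  expect_lt(abs(opt$pose$alpha - fx$sc$pose$alpha), 1e-6)
  # refinement from the best grid node reaches rmsd < 0.02 nm
  g <- dock_grid(x = seq(-2.5, 2.5, 0.25), y = seq(-2.5, 2.5, 0.25))
  best <- grid_search(fx$prot, fx$ens, fx$restr, grid = g,
                      max_ensemble = 1000L)[1, ]
  ref2 <- refine(c2_pose(best$alpha, best$beta, best$x, best$y),
                 protomer = fx$prot, ensembles = fx$ens,
                 restraints = fx$restr)
  expect_lt(ref2$score, 0.02)
  expect_true(ref2$clash_free)
})

test_that("contact_sweep scores the time domain and finds planted geometry", {
  fx <- dock_fixture()
  tg <- seq(0, 1.2, by = 0.024)
  # plant traces from a sweep-constructed geometry (phi1 = 150, phi2 = 120)
  sw0 <- contact_sweep(fx$prot, fx$ens,
                       traces = lapply(fx$ens, function(e) {
                         tr <- trace_from_pose(e, fx$sc$pose, tg, 0.4)
                         deer_trace(tg, tr$v, "form_factor", depth = 0.4)
                       }),
                       phi1_step = 30, phi2_step = 60)
  planted <- sw0[1, ]
  ctr <- colMeans(coords(fx$prot))
  ca <- sweep(coords(fx$prot, "CA"), 2, ctr)
  u <- c(cos(planted$phi1 * pi / 180), sin(planted$phi1 * pi / 180), 0)
  traces <- lapply(fx$ens, function(e) {
    p2 <- sweep(apply_transform(rot_z(planted$phi2), e$positions), 2,
                planted$d * u, `+`)
    pd <- pair_distance_distribution(
      e, spin_site_ensemble(e$site, p2, e$weights), seq(0.01, 12, 0.02))
    form_factor(pd, tg, 0.4)
  })
  sw <- contact_sweep(fx$prot, fx$ens, traces, phi1_step = 30,
                      phi2_step = 60)
  expect_lt(sw$chi2[1], 1e-12)      # chi2 of a trace against itself
  expect_equal(sw$phi1[1], planted$phi1)
  expect_equal(sw$phi2[1], planted$phi2)
  # flat traces (lambda = 0): all nodes score equally
  flat <- lapply(fx$ens, function(e)
    deer_trace(tg, rep(1, length(tg)), "form_factor", depth = 0))
  swf <- contact_sweep(fx$prot, fx$ens, flat, phi1_step = 90,
                       phi2_step = 120)
  expect_lt(diff(range(swf$chi2)), 1e-12)
})
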