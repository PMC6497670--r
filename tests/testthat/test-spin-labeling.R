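test_that("attach_label samples the shell deterministically", {
  s <- single_residue()
  e1 <- attach_label(s, list("A", 1L), seed = 7)
  e2 <- attach_label(s, list("A", 1L), seed = 7)
  expect_identical(e1$positions, e2$positions)
  # no clash rejection for an isolated residue: all 200 candidates survive
  expect_equal(nrow(e1$positions), 200L)
  expect_true(all(abs(e1$weights - 1 / 200) < 1e-12))
  rad <- sqrt(rowSums(e1$positions^2))
  expect_true(all(rad >= 0.4 - 1e-9 & rad <= 0.9 + 1e-9))
  expect_lt(sqrt(sum(colMeans(e1$positions)^2)), 0.9)
  e3 <- attach_label(s, list("A", 1L), seed = 8)
  expect_false(identical(e1$positions, e3$positions))
})

test_that("attach_label errors for buried sites and missing residues", {
  # dense atom cage filling the whole shell volume: grid spacing 0.25 nm
  # leaves no point further than 0.22 nm from an atom, below the 0.25 nm
  # clearance, so every candidate is rejected
  g <- seq(-1.2, 1.2, by = 0.25)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  rad <- sqrt(rowSums(pts^2))
  cage <- point_structure(rbind(c(0, 0, 0), pts[rad > 0.2 & rad < 1.2, ]))
  expect_error(attach_label(cage, list("A", 1L), seed = 1), "buried")
  expect_error(attach_label(single_residue(), list("A", 99L)), "not found")
})

test_that("label anchor prefers CB, then pseudo-CB, then CA", {
  # residue with backbone triad: shell centres on the pseudo-CB, not CA
  bb <- structure3d(data.frame(
    chain = "A", resno = 1, resname = "GLY",
    atom = c("N", "CA", "C"), element = c("N", "C", "C"),
    x = c(0.1459, 0, -0.0520), y = c(0, 0, 0.1420), z = c(0, 0, 0)))
  anchor <- deerdock:::label_anchor(bb, "A", 1L)
  expect_equal(sqrt(sum(anchor^2)), 0.153, tolerance = 1e-6)
  e <- attach_label(bb, list("A", 1L), seed = 3)
  ctr <- colMeans(e$positions)
  expect_lt(sqrt(sum((ctr - anchor)^2)), sqrt(sum((ctr - c(0, 0, 0))^2)) + 0.3)
  # explicit CB wins over construction
  cb <- structure3d(data.frame(
    chain = "A", resno = 1, resname = "ALA", atom = c("CA", "CB"),
    element = "C", x = c(0, 0.3), y = 0, z = 0))
  expect_equal(deerdock:::label_anchor(cb, "A", 1L), c(0.3, 0, 0))
})

test_that("rotamer tables place positions in the backbone frame", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# dx dy dz weight",
               "0.50 0.00 0.00 2",
               "0.00 0.40 0.10 1"), path)
  tab <- read_rotamer_table(path)
  bb <- structure3d(data.frame(
    chain = "A", resno = 1, resname = "CYS",
    atom = c("N", "CA", "C"), element = c("N", "C", "C"),
    x = c(0.15, 0, 0), y = c(0, 0, 0.15), z = c(0, 0, 0)))
  e <- attach_label(bb, list("A", 1L), model = "table", rotamers = tab)
  # x axis of the local frame is CA->N = +x here
  expect_equal(as.numeric(e$positions[1, ]), c(0.5, 0, 0), tolerance = 1e-9)
  expect_equal(e$weights, c(2, 1) / 3)
})

test_that("pair distance distributions match hand enumeration", {
  r_grid <- seq(1, 4, by = 0.02)
  a <- point_ensemble(c(0, 0, 0))
  b <- point_ensemble(c(1.8, 0, 0))
  pd <- pair_distance_distribution(a, b, r_grid)
  expect_equal(attr(pd, "mean"), 1.8, tolerance = 1e-12)
  expect_equal(attr(pd, "sd"), 0)
  # all mass in the bin containing 1.8 nm
  expect_equal(sum(pd$p > 0), 1L)
  expect_equal(pd$r[which(pd$p > 0)], 1.8)

  # shifted copy: mean d exactly
  a2 <- spin_site_ensemble(list("A", 1), rbind(c(0, 0, 0), c(0, 0.3, 0)),
                           c(0.5, 0.5))
  b2 <- spin_site_ensemble(list("A", 1),
                           sweep(a2$positions, 2, c(2.5, 0, 0), `+`),
                           c(0.5, 0.5))
  pd2 <- pair_distance_distribution(a2, b2, r_grid)
  d4 <- c(2.5, sqrt(2.5^2 + 0.3^2), sqrt(2.5^2 + 0.3^2), 2.5)
  expect_equal(attr(pd2, "mean"), mean(d4), tolerance = 1e-12)

  # two 2-point ensembles with non-uniform weights: 4-pair enumeration
  p1 <- rbind(c(0, 0, 0), c(0.5, 0, 0)); w1 <- c(0.3, 0.7)
  p2 <- rbind(c(2, 0, 0), c(2, 1, 0)); w2 <- c(0.6, 0.4)
  e1 <- spin_site_ensemble(list("A", 1), p1, w1)
  e2 <- spin_site_ensemble(list("A", 2), p2, w2)
  pd3 <- pair_distance_distribution(e1, e2, r_grid)
  dd <- as.matrix(stats::dist(rbind(p1, p2)))[1:2, 3:4]
  ww <- outer(w1, w2)
  expect_equal(attr(pd3, "mean"), sum(dd * ww), tolerance = 1e-12)
  # symmetry in the arguments
  pd3b <- pair_distance_distribution(e2, e1, r_grid)
  expect_equal(pd3$p, pd3b$p)
  expect_error(pair_distance_distribution(
    a, point_ensemble(c(10, 0, 0)), r_grid), "coverage")
})

test_that("distributions normalize and match a Monte-Carlo oracle", {
  set.seed(5)
  r_grid <- seq(0.1, 6, by = 0.02)
  for (i in 1:3) {
    e1 <- spin_site_ensemble(list("A", 1), matrix(rnorm(30, 0, 0.3), 10, 3),
                             runif(10))
    e2 <- spin_site_ensemble(list("A", 2),
                             matrix(rnorm(24, 0, 0.3), 8, 3) +
                               matrix(rep(c(2.5, 0, 0), each = 8), 8, 3),
                             runif(8))
    pd <- pair_distance_distribution(e1, e2, r_grid)
    expect_equal(trapz(pd$r, pd$p), 1, tolerance = 1e-9)
    # MC resampling oracle: 1e5 weighted pair draws
    n <- 1e5
    i1 <- sample(10, n, TRUE, e1$weights)
    i2 <- sample(8, n, TRUE, e2$weights)
    d <- sqrt(rowSums((e1$positions[i1, ] - e2$positions[i2, ])^2))
    se <- sd(d) / sqrt(n)
    expect_lt(abs(mean(d) - attr(pd, "mean")), 3 * se + 1e-6)
  }
})

test_that("c2 pair distribution handles symmetry and degeneracy", {
  r_grid <- seq(1, 4, by = 0.02)
  e <- point_ensemble(c(1, 0, 0))
  pd <- c2_pair_distribution(e, c2_pose(0, 0, 0, 0), r_grid)
  expect_equal(attr(pd, "mean"), 2.0, tolerance = 1e-12)
  # point on the z axis: zero-distance pair is dropped -> nothing left
  on_axis <- point_ensemble(c(0, 0, 1.3))
  expect_error(suppressWarnings(
    c2_pair_distribution(on_axis, c2_pose(0, 0, 0, 0), r_grid)),
    "zero distance")
  # mean invariant under alpha -> alpha + 180 for an untranslated,
  # untilted placement (the only case where the half-turn is a gauge;
  # with a translation the two dimers genuinely differ)
  m1 <- attr(c2_pair_distribution(e, c2_pose(40, 0, 0, 0), r_grid), "mean")
  m2 <- attr(c2_pair_distribution(e, c2_pose(220, 0, 0, 0), r_grid), "mean")
  expect_equal(m1, m2, tolerance = 1e-9)
  # the full-turn gauge holds unconditionally
  wide <- seq(1, 6, by = 0.02)
  m3 <- attr(c2_pair_distribution(e, c2_pose(40 - 360, 15, 1, 0.5), wide),
             "mean")
  m4 <- attr(c2_pair_distribution(e, c2_pose(40, 15, 1, 0.5), wide), "mean")
  expect_equal(m3, m4, tolerance = 1e-9)
})

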