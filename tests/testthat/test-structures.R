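test_that("rigid transforms are proper and preserve geometry", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  set.seed(11)
  for (i in 1:5) {
    tr <- compose_transforms(rot_z(runif(1, 0, 360)),
                             compose_transforms(rot_y(runif(1, 0, 180)),
                                                translation(rnorm(3))))
    x <- matrix(rnorm(30), 10, 3)
    y <- apply_transform(tr, x)
    expect_lt(max(abs(dist(x) - dist(y))), 1e-9)
  }
  # associativity
  a <- rot_z(33); b <- rot_y(71); cc <- translation(c(1, -2, 3))
  p <- matrix(rnorm(9), 3, 3)
  lhs <- apply_transform(compose_transforms(compose_transforms(a, b), cc), p)
  rhs <- apply_transform(compose_transforms(a, compose_transforms(b, cc)), p)
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("read_pdb parses, filters and converts units", {
  path <- three_atom_pdb(tempfile(fileext = ".pdb"))
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$atoms$x[1], 1.1104, tolerance = 1e-10)  # Angstrom -> nm
  expect_equal(s$atoms$atom, c("N", "CA", "C"))

  # hydrogens, waters and altloc B are skipped
  path2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   ALA A   1       1.000   1.000   0.000  1.00  0.00           H",
    "ATOM      3  CA BALA A   2       2.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101       9.000   0.000   0.000  1.00  0.00           O",
    "END"), path2)
  expect_equal(nrow(read_pdb(path2)$atoms), 1L)

  # duplicate key is an invariant violation
  path3 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   1       2.000   0.000   0.000  1.00  0.00           C"),
    path3)
  expect_error(read_pdb(path3), "duplicate")

  # unparseable record names its line
  path4 <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM  garbage"), path4)
  expect_error(read_pdb(path4), "line 1")
  expect_error(read_pdb(tempfile()), "not found")
})

test_that("pdb round trip preserves coordinates to PDB precision", {
  sc <- shared_scenario()
  path <- tempfile(fileext = ".pdb")
  write_pdb(sc$protomer, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$atoms), nrow(sc$protomer$atoms))
  expect_lt(max(abs(coords(back) - coords(sc$protomer))), 1e-4 + 1e-12)
})

test_that("make_c2_dimer builds an exactly C2-symmetric dimer", {
  sc <- shared_scenario()
  prot <- sc$protomer
  # identity pose: B' is the 180 degree z-rotation of the centred protomer
  d0 <- make_c2_dimer(prot, c2_pose(0, 0, 0, 0))
  ctr <- colMeans(coords(prot))
  centred <- sweep(coords(prot), 2, ctr)
  expect_lt(max(abs(coords(d0$A) - centred)), 1e-12)
  expect_lt(max(abs(coords(d0$B) -
                      apply_transform(rot_z(180), centred))), 1e-12)
  # symmetry closure at a generic pose
  d <- make_c2_dimer(prot, c2_pose(137, 42, 1.7, -0.9))
  rotA <- apply_transform(rot_z(180), coords(d$A))
  rotB <- apply_transform(rot_z(180), coords(d$B))
  expect_lt(max(abs(rotA - coords(d$B))), 1e-9)
  expect_lt(max(abs(rotB - coords(d$A))), 1e-9)
})

test_that("single-atom pose arithmetic matches hand calculation", {
  s <- single_residue(c(1, 0, 0))
  d <- make_c2_dimer(s, c2_pose(90, 0, 3, 0), center = FALSE)
  expect_equal(as.numeric(coords(d$A)), c(3, 1, 0), tolerance = 1e-12)
  expect_equal(as.numeric(coords(d$B)), c(-3, -1, 0), tolerance = 1e-12)
})

test_that("c2 construction is gauge-invariant under input z-rotation", {
  sc <- shared_scenario()
  prot <- sc$protomer
  delta <- 77
  rotated <- apply_transform(rot_z(delta), prot)
  d1 <- make_c2_dimer(prot, c2_pose(130, 25, 1.2, 0.4))
  d2 <- make_c2_dimer(rotated, c2_pose(130 - delta, 25, 1.2, 0.4))
  expect_lt(max(abs(coords(d1$A) - coords(d2$A))), 1e-9)
  expect_lt(max(abs(coords(d1$B) - coords(d2$B))), 1e-9)
})

test_that("clash_and_contact classifies distances correctly", {
  sc <- shared_scenario()
  prot <- sc$protomer
  expect_true(clash_and_contact(prot, prot)$is_clashing)
  far <- apply_transform(translation(c(50, 0, 0)), prot)
  cc <- clash_and_contact(prot, far)
  expect_false(cc$is_clashing)
  expect_false(cc$is_in_contact)
  expect_equal(cc$min_distance, 50, tolerance = 0.1)
  # single-CA pair at 0.7 nm with defaults
  cc2 <- clash_and_contact(single_residue(), single_residue(c(0.7, 0, 0)))
  expect_equal(unname(unlist(cc2)), c(0, 1, 0.7), tolerance = 1e-12)
  expect_error(clash_and_contact(single_residue(), single_residue(),
                                 clash_cut = 1, contact_cut = 0.5))
  no_ca <- point_structure(rbind(c(0, 0, 0)), atom = "CB")
  expect_error(clash_and_contact(no_ca, single_residue()), "CA")
})

test_that("buried_surface matches the two-sphere closed form", {
  a <- single_residue()
  b <- single_residue(c(0.3, 0, 0))
  got <- buried_surface(a, b, probe = 0, n_points = 4000)
  # carbon radius 0.17 nm: two spherical caps of height R - d/2
  R <- 0.17; h <- R - 0.3 / 2
  analytic <- 2 * (2 * pi * R * h) * 100  # A^2
  expect_lt(abs(got - analytic) / analytic, 0.02)
  # separated protomers bury nothing
  sc <- shared_scenario()
  far <- apply_transform(translation(c(50, 0, 0)), sc$protomer)
  expect_lt(abs(buried_surface(sc$protomer, far)), 1e-6)
  expect_error(buried_surface(
    point_structure(rbind(c(0, 0, 0))),
    structure3d(data.frame(chain = "B", resno = 1, resname = "UNK",
                           atom = "XX", element = "XX",
                           x = 0.3, y = 0, z = 0))), "XX")
})

test_that("buried_surface is symmetric and converges with sampling", {
  sc <- shared_scenario()
  dm <- make_c2_dimer(sc$protomer, sc$pose)
  b1 <- buried_surface(dm$A, dm$B, n_points = 960)
  b2 <- buried_surface(dm$B, dm$A, n_points = 960)
  expect_equal(b1, b2, tolerance = 1e-9)
  b4 <- buried_surface(dm$A, dm$B, n_points = 1920)
  expect_lt(abs(b4 - b1) / b4, 0.01)
  expect_gt(b1, 0)
})
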