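# shared fixtures, built in code (no binary data)

# minimal structure with arbitrary points, all carbons
point_structure <- function(xyz, chain = "A", atom = "CA") {
  xyz <- rbind(xyz)
  structure3d(data.frame(
    chain = chain, resno = seq_len(nrow(xyz)), resname = "ALA",
    atom = atom, element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# single-residue structure with one CA at the origin
single_residue <- function(at = c(0, 0, 0)) point_structure(rbind(at))

# one-point spin ensemble
point_ensemble <- function(p, site = list("A", 1L)) {
  spin_site_ensemble(site, rbind(p), 1)
}

# hand-written 3-atom PDB text (Angstrom)
three_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.672   6.603  -4.093  1.00  0.00           C",
    "END"), path)
  path
}

# Gauss-Legendre nodes/weights on [0, 1] by Newton iteration on the
# Legendre recurrence (vectorized); the independent quadrature oracle
# for the dipolar kernel. Memoized: the rule is reused across checks.
gauss_legendre_01 <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  m <- ceiling(n / 2)
  x <- cos(pi * (seq_len(m) - 0.25) / (n + 0.5))
  legendre_pair <- function(x) {
    p1 <- rep(1, length(x)); p2 <- rep(0, length(x))
    for (j in seq_len(n)) {
      p3 <- p2; p2 <- p1
      p1 <- ((2 * j - 1) * x * p2 - (j - 1) * p3) / j
    }
    list(p = p1, dp = n * (x * p1 - p2) / (x^2 - 1))
  }
  for (it in 1:100) {
    lp <- legendre_pair(x)
    dx <- lp$p / lp$dp
    x <- x - dx
    if (max(abs(dx)) < 1e-15) break
  }
  lp <- legendre_pair(x)
  w <- 2 / ((1 - x^2) * lp$dp^2)
  keep <- if (n %% 2 == 1) seq_len(m - 1) else seq_len(m)
  xs <- c(-x, rev(x[keep]))
  ws <- c(w, rev(w[keep]))
  out <- list(x = (xs + 1) / 2, w = ws / 2)
  .fixture_env[[key]] <- out
  out
}

kernel_oracle_gl <- function(t, r, n = 2001L) {
  gl <- gauss_legendre_01(n)
  w_dd <- 2 * pi * 52.04 / r^3
  sum(gl$w * cos((3 * gl$x^2 - 1) * w_dd * t))
}

# memoized small default scenario shared across test files
.fixture_env <- new.env(parent = emptyenv())
shared_scenario <- function() {
  if (is.null(.fixture_env$scenario)) {
    .fixture_env$scenario <- default_scenario(
      seed = 1L, dir = file.path(tempdir(), "deerdock-shared-scenario"),
      label_n = 64L)
  }
  .fixture_env$scenario
}

# pose deviation against truth or its membrane-flip gauge partner
# (alpha + 180, 180 - beta, x, -y), which yields the identical dimer
pose_recovered <- function(found, truth, tol = c(10, 5, 0.25, 0.25)) {
  ang <- function(a, b) {
    d <- abs(a - b) %% 360
    min(d, 360 - d)
  }
  dev <- function(a0, b0, x0, y0)
    c(ang(found$alpha, a0), abs(found$beta - b0),
      abs(found$x - x0), abs(found$y - y0))
  d1 <- dev(truth$alpha, truth$beta, truth$x, truth$y)
  d2 <- dev((truth$alpha + 180) %% 360, 180 - truth$beta, truth$x, -truth$y)
  all(d1 <= tol + 1e-9) || all(d2 <= tol + 1e-9)
}

trapz <- deerdock:::trapz
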