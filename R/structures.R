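#' Protein structures as atom tables
#'
#' A `structure3d` holds heavy-atom coordinates in nm together with chain,
#' residue and atom-name addressing. The membrane normal is the +z axis by
#' convention throughout the package. Coordinates are stored in nm; PDB
#' files (Angstrom) are converted at the file boundary.
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer),
#'   `resname`, `atom`, `element`, `x`, `y`, `z` (nm).
#' @param label free-text label carried along with the structure.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, label = "") {
  req <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    stop("structure3d: atoms must have columns ", paste(req, collapse = ", "))
  atoms <- as.data.frame(atoms)[req]
  atoms$resno <- as.integer(atoms$resno)
  if (nrow(atoms) == 0L) stop("structure3d: empty atom selection")
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("structure3d: non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("structure3d: duplicate (chain, resno, atom) records: ",
         key[duplicated(key)][1])
  structure(list(atoms = atoms, label = label), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms, %d residues, chains: %s%s\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ","),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param s a `structure3d`.
#' @param atom_name optional atom-name filter (e.g. `"CA"`).
#' @return n x 3 matrix in nm.
#' @export
coords <- function(s, atom_name = NULL) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  if (!is.null(atom_name)) a <- a[a$atom %in% atom_name, , drop = FALSE]
  as.matrix(a[c("x", "y", "z")])
}

n_atoms <- function(s) nrow(s$atoms)

# Water residue names skipped on read
.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

#' Read a PDB file (ATOM/HETATM subset)
#'
#' Reads all protein heavy atoms from a PDB file. Hydrogens, waters and
#' alternate locations other than blank/'A' are skipped. Coordinates are
#' converted from Angstrom to nm.
#'
#' @param path path to a PDB file.
#' @param label optional label; defaults to the file name.
#' @return A `structure3d`.
#' @export
read_pdb <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("read_pdb: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(idx) == 0L) stop("read_pdb: no ATOM/HETATM records in ", path)
  parse_one <- function(i) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("read_pdb: unparseable record at line ", i, " (too short)")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (any(is.na(xyz)) || is.na(resno))
      stop("read_pdb: unparseable record at line ", i)
    elem <- trimws(substr(ln, 77, 78))
    atom <- trimws(substr(ln, 13, 16))
    if (!nzchar(elem)) elem <- toupper(substr(gsub("[0-9]", "", atom), 1, 1))
    list(chain = substr(ln, 22, 22), resno = resno,
         resname = trimws(substr(ln, 18, 20)), atom = atom,
         altloc = substr(ln, 17, 17), element = elem,
         x = xyz[1] / 10, y = xyz[2] / 10, z = xyz[3] / 10)
  }
  parsed <- lapply(idx, parse_one)
  df <- do.call(rbind.data.frame, c(parsed, stringsAsFactors = FALSE))
  keep <- !(df$element %in% c("H", "D")) &
    !(df$resname %in% .water_resnames) &
    df$altloc %in% c(" ", "A", "")
  df <- df[keep, setdiff(names(df), "altloc"), drop = FALSE]
  if (nrow(df) == 0L) stop("read_pdb: empty selection after filtering in ", path)
  structure3d(df, label = label)
}

#' Write a structure to a PDB file
#'
#' Coordinates are converted from nm back to Angstrom. Chains longer than
#' one character are truncated to their first character.
#'
#' @param s a `structure3d` (or a list of them, written as separate chains).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  if (inherits(s, "structure3d")) s <- list(s)
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (st in s) {
    a <- st$atoms
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$atom[i]
      # PDB atom-name column convention: element right-justified in 13-14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else substr(nm, 1, 4)
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm_fmt, substr(a$resname[i], 1, 3),
        substr(a$chain[i], 1, 1), a$resno[i],
        a$x[i] * 10, a$y[i] * 10, a$z[i] * 10, 1, 0, a$element[i]), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Construct a C2-symmetric dimer from a protomer and a pose
#'
#' The protomer is centred at its geometric centre, rotated about z by
#' `alpha` then about y by `beta` (active, right-handed), translated by
#' (x, y, 0), giving protomer A'. Protomer B' is the 180 degree z-rotation
#' of A', so the dimer is exactly C2-symmetric about the z axis through
#' the origin (the membrane normal). The third Euler angle and the z
#' translation are frozen at 0 by the symmetry/parallel-orientation
#' constraint.
#'
#' @param protomer a `structure3d`.
#' @param pose a [c2_pose()].
#' @param center centre the protomer's geometric centre at the origin
#'   before applying the pose (default TRUE); set FALSE when coordinates
#'   are already expressed in the docking frame.
#' @return list with elements `A` and `B`, both `structure3d`.
#' @export
make_c2_dimer <- function(protomer, pose, center = TRUE) {
  stopifnot(inherits(protomer, "structure3d"))
  pose <- as_c2_pose(pose)
  tr <- c2_placement(pose)
  centered <- if (center) {
    ctr <- colMeans(coords(protomer))
    apply_transform(translation(-ctr), protomer)
  } else protomer
  A <- apply_transform(tr, centered)
  B <- apply_transform(rot_z(180), A)
  A$label <- paste0(protomer$label, ":A")
  B$label <- paste0(protomer$label, ":B")
  list(A = A, B = B)
}

# transform placing the centred protomer at pose: translate(x,y,0) o Ry(beta) o Rz(alpha)
c2_placement <- function(pose) {
  compose_transforms(translation(c(pose$x, pose$y, 0)),
                     compose_transforms(rot_y(pose$beta), rot_z(pose$alpha)))
}

#' Clash and contact test between two structures
#'
#' By default distances are measured between Cα atoms only (adequate for
#' rigid docking grids); `use_all_atoms = TRUE` switches to all heavy
#' atoms.
#'
#' @param a,b `structure3d` objects.
#' @param clash_cut distance (nm) below which a pair counts as a steric
#'   clash; default 0.4 nm.
#' @param contact_cut distance (nm) at or below which the structures count
#'   as in contact; default 1.0 nm. Must exceed `clash_cut`.
#' @param use_all_atoms use all heavy atoms instead of Cα only.
#' @return list `(is_clashing, is_in_contact, min_distance)`.
#' @export
clash_and_contact <- function(a, b, clash_cut = 0.4, contact_cut = 1.0,
                              use_all_atoms = FALSE) {
  stopifnot(clash_cut < contact_cut)
  sel <- if (use_all_atoms) NULL else "CA"
  xa <- coords(a, sel); xb <- coords(b, sel)
  if (nrow(xa) == 0L || nrow(xb) == 0L)
    stop("clash_and_contact: structure lacks ",
         if (use_all_atoms) "atoms" else "CA atoms")
  d <- cpp_min_pair_dist(xa, xb)
  list(is_clashing = d < clash_cut, is_in_contact = d <= contact_cut,
       min_distance = d)
}

# Bondi van der Waals radii, nm
.vdw_radii <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                P = 0.180, H = 0.120, SE = 0.190, FE = 0.160)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  if (any(is.na(r)))
    stop("unknown element radius for: ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley solvent-accessible surface area, nm^2
sasa <- function(xyz, radii, probe, n_points) {
  rr <- radii + probe
  pts <- sphere_points(n_points)
  cpp_sasa(xyz, rr, pts)
}

#' Buried surface area of a dimer interface
#'
#' Computes SASA(a) + SASA(b) - SASA(a+b) by Shrake-Rupley sphere
#' sampling. Reported in Angstrom squared to match the convention of the
#' structural literature; all inputs are in nm.
#'
#' @param a,b `structure3d` objects.
#' @param probe probe radius in nm (default 0.14, a water molecule).
#' @param n_points sphere sample points per atom (>= 100; default 960).
#' @return buried area in Angstrom squared (non-negative up to sampling noise).
#' @export
buried_surface <- function(a, b, probe = 0.14, n_points = 960L) {
  stopifnot(n_points >= 100L)
  xa <- coords(a); xb <- coords(b)
  ra <- vdw_radius(a$atoms$element); rb <- vdw_radius(b$atoms$element)
  sa <- sasa(xa, ra, probe, n_points)
  sb <- sasa(xb, rb, probe, n_points)
  sab <- sasa(rbind(xa, xb), c(ra, rb), probe, n_points)
  (sa + sb - sab) * 100  # nm^2 -> A^2
}
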