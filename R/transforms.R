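#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) followed by a translation, acting on coordinates in nm.
#' Transforms compose associatively; `apply_transform(tr, X)` computes
#' `X %*% t(R) + t` row-wise.
#'
#' @param rotation 3x3 orthonormal matrix, det = +1 (within 1e-9).
#' @param translation numeric length-3 translation in nm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite components")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rigid_transform: rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rigid_transform: rotation determinant is not +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @describeIn rigid_transform Rotation by `angle_deg` degrees about the z axis.
#' @param angle_deg rotation angle in degrees (active, right-handed).
#' @export
rot_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rigid_transform(matrix(c(cos(a), sin(a), 0,
                           -sin(a), cos(a), 0,
                           0, 0, 1), 3, 3, byrow = FALSE))
}

#' @describeIn rigid_transform Rotation by `angle_deg` degrees about the y axis.
#' @export
rot_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  rigid_transform(matrix(c(cos(a), 0, -sin(a),
                           0, 1, 0,
                           sin(a), 0, cos(a)), 3, 3, byrow = FALSE))
}

#' @describeIn rigid_transform Pure translation by `v` (nm).
#' @param v numeric length-3 translation in nm.
#' @export
translation <- function(v) rigid_transform(diag(3), v)

#' Compose two rigid transforms
#'
#' `compose_transforms(f, g)` returns the transform "f after g", i.e. the
#' result applies `g` first, then `f`.
#'
#' @param f,g `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(f, g) {
  stopifnot(inherits(f, "rigid_transform"), inherits(g, "rigid_transform"))
  rigid_transform(f$rotation %*% g$rotation,
                  as.numeric(f$rotation %*% g$translation) + f$translation)
}

#' Apply a rigid transform to coordinates
#'
#' @param tr a `rigid_transform`.
#' @param x either an n x 3 coordinate matrix (nm) or a `structure3d`.
#' @return Object of the same kind as `x`, transformed.
#' @export
apply_transform <- function(tr, x) {
  stopifnot(inherits(tr, "rigid_transform"))
  if (inherits(x, "structure3d")) {
    xyz <- coords(x)
    xyz <- apply_transform(tr, xyz)
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  x <- rbind(x)  # promote a bare 3-vector to 1 x 3
  sweep(x %*% t(tr$rotation), 2, tr$translation, `+`)
}
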