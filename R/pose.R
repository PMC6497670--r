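#' C2 dimer pose
#'
#' Four parameters place one protomer of a C2-symmetric dimer: rotation
#' `alpha` about z (degrees, [0, 360)), rotation `beta` about y (degrees,
#' [0, 180]), and in-plane translation `x`, `y` (nm). The second protomer
#' is generated by the two-fold axis (z); the remaining Euler angle and
#' the z translation are 0 by construction.
#'
#' @param alpha,beta angles in degrees.
#' @param x,y translations in nm.
#' @return An object of class `c2_pose`.
#' @export
c2_pose <- function(alpha, beta, x, y) {
  alpha <- alpha %% 360
  if (!is.finite(alpha) || !is.finite(beta) || !is.finite(x) || !is.finite(y))
    stop("c2_pose: non-finite parameters")
  if (beta < 0 || beta > 180)
    stop("c2_pose: beta must lie in [0, 180] degrees, got ", beta)
  structure(list(alpha = alpha, beta = beta, x = x, y = y),
            class = "c2_pose")
}

as_c2_pose <- function(p) {
  if (inherits(p, "c2_pose")) return(p)
  p <- as.list(p)
  if (all(c("alpha", "beta", "x", "y") %in% names(p)))
    return(c2_pose(p$alpha, p$beta, p$x, p$y))
  if (length(p) == 4L) return(c2_pose(p[[1]], p[[2]], p[[3]], p[[4]]))
  stop("cannot interpret as c2_pose")
}

#' @export
print.c2_pose <- function(x, ...) {
  cat(sprintf("<c2_pose> alpha=%.2f deg, beta=%.2f deg, x=%.3f nm, y=%.3f nm\n",
              x$alpha, x$beta, x$x, x$y))
  invisible(x)
}

#' @export
as.data.frame.c2_pose <- function(x, ...) {
  data.frame(alpha = x$alpha, beta = x$beta, x = x$x, y = x$y)
}
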