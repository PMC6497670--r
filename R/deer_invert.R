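#' Lawson-Hanson non-negative least squares
#'
#' Minimizes ||A x - b||_2 subject to x >= 0 by the active-set algorithm.
#' Used by the Tikhonov inversion; exposed because the oracle tests
#' compare it against dense unconstrained solves.
#'
#' @param A design matrix.
#' @param b response vector.
#' @param tol dual-feasibility tolerance (default 1e-12 scaled by the
#'   problem).
#' @return list `(x, residual_norm)`.
#' @export
nnls_solve <- function(A, b, tol = 1e-12) {
  n <- ncol(A)
  AtA <- crossprod(A)
  Atb <- as.numeric(crossprod(A, b))
  ls_sub <- function(passive) {
    # normal-equations solve on the passive set (fast; A carries a
    # Tikhonov block so AtA is well conditioned), QR fallback if singular
    z <- numeric(n)
    sub <- AtA[passive, passive, drop = FALSE]
    zi <- tryCatch(solve(sub, Atb[passive]), error = function(e) {
      zz <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      zz[is.na(zz)] <- 0
      zz
    })
    z[passive] <- zi
    z
  }
  x <- numeric(n)
  passive <- logical(n)
  wvec <- Atb - as.numeric(AtA %*% x)
  scale <- max(abs(wvec), 1)
  it <- 0L; maxit <- 10L * n
  while (any(!passive) && max(wvec[!passive]) > tol * scale) {
    it <- it + 1L
    if (it > maxit) break
    j <- which(!passive)[which.max(wvec[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- ls_sub(passive)
      if (all(z[passive] > 0)) { x <- z; break }
      neg <- passive & (z <= 0)
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    wvec <- Atb - as.numeric(AtA %*% x)
  }
  list(x = x, residual_norm = sqrt(sum((A %*% x - b)^2)))
}

# second-difference operator, (n-2) x n, scaled by 1/dr^2
second_difference <- function(n, dr = 1) {
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L / dr^2
}

#' Non-negative Tikhonov inversion of a form factor
#'
#' Recovers a distance distribution from a background-corrected DEER
#' form factor by minimizing
#' `||K p - s||^2 + reg_param^2 ||L2 p||^2` subject to `p >= 0`, where
#' `K` is the dipolar kernel matrix scaled by the modulation depth and
#' the trapezoidal grid weights, `s` the depth-adjusted signal, and `L2`
#' the second-difference operator. The returned distribution is
#' renormalized to unit integral. Deterministic.
#'
#' @param f a [deer_trace()] of kind `form_factor`.
#' @param r_grid uniform distance grid (nm).
#' @param reg_param regularization parameter (> 0), or `"auto"` for
#'   L-curve selection via [select_reg_param()].
#' @param depth modulation depth; `"auto"` scans 0.05-0.95 in steps of
#'   0.01 and keeps the depth minimizing the residual.
#' @param reg_grid candidate grid for `reg_param = "auto"`.
#' @return An object of class `tikhonov_result`: list with
#'   `distribution`, `reg_param`, `depth`, `residual_norm`, `seminorm`
#'   and `fit` (a form-factor [deer_trace()]).
#' @export
tikhonov_invert <- function(f, r_grid = seq(1, 6, by = 0.02),
                            reg_param = "auto", depth = "auto",
                            reg_grid = 10^seq(-4, 2, length.out = 13)) {
  stopifnot(inherits(f, "deer_trace"))
  if (f$kind != "form_factor")
    stop("tikhonov_invert: remove the background first (need a form factor)")
  check_uniform_grid(f$t, "t"); check_uniform_grid(r_grid, "r_grid")
  if (identical(depth, "auto")) {
    depths <- seq(0.05, 0.95, by = 0.01)
    K <- dipolar_kernel_matrix(f$t, r_grid)
    Kw <- K %*% diag(trapz_weights(r_grid))
    rp <- if (identical(reg_param, "auto")) 1e-2 else reg_param
    res <- vapply(depths, function(dp)
      tikhonov_core(Kw, f$v, dp, rp, r_grid)$residual_norm, 0)
    depth <- depths[which.min(res)]
  }
  stopifnot(is.numeric(depth), depth > 0, depth <= 1)
  if (identical(reg_param, "auto"))
    reg_param <- select_reg_param(f, r_grid, reg_grid, depth = depth)
  stopifnot(is.numeric(reg_param), reg_param > 0)
  K <- dipolar_kernel_matrix(f$t, r_grid)
  Kw <- K %*% diag(trapz_weights(r_grid))
  sol <- tikhonov_core(Kw, f$v, depth, reg_param, r_grid)
  if (all(sol$p <= 0))
    stop("tikhonov_invert: all-zero solution; check depth or r_grid coverage")
  fitv <- 1 - depth + depth * as.numeric(Kw %*% sol$p)
  structure(list(
    distribution = distance_distribution(r_grid, sol$p),
    reg_param = reg_param, depth = depth,
    residual_norm = sol$residual_norm, seminorm = sol$seminorm,
    fit = deer_trace(f$t, fitv / fitv[1], kind = "form_factor",
                     depth = depth)),
    class = "tikhonov_result")
}

# core solve at fixed depth and reg_param; returns raw (unnormalized) p
tikhonov_core <- function(Kw, v, depth, reg_param, r_grid) {
  s <- (v - (1 - depth)) / depth  # dipolar part, in [.,1]
  n <- length(r_grid)
  L <- second_difference(n, dr = 1)  # unit spacing scaling absorbed in reg
  A <- rbind(depth * Kw, reg_param * L)
  b <- c(depth * s, numeric(nrow(L)))
  fit <- nnls_solve(A, b)
  p <- fit$x
  list(p = p,
       residual_norm = sqrt(sum((depth * Kw %*% p - depth * s)^2)),
       seminorm = sqrt(sum((L %*% p)^2)))
}

#' @export
print.tikhonov_result <- function(x, ...) {
  m <- distribution_moments(x$distribution)
  cat(sprintf(
    "<tikhonov_result> reg=%.3g depth=%.2f mean=%.3f nm sd=%.3f nm resid=%.3g\n",
    x$reg_param, x$depth, m[["mean"]], m[["sd"]], x$residual_norm))
  invisible(x)
}

#' L-curve selection of the Tikhonov regularization parameter
#'
#' Solves the inversion for every candidate and returns the candidate at
#' the corner (maximum Menger curvature) of the
#' (log residual norm, log seminorm) curve. Deterministic.
#'
#' @param f form-factor [deer_trace()].
#' @param r_grid distance grid.
#' @param candidates >= 8 log-spaced candidates.
#' @param depth modulation depth (numeric).
#' @return the selected reg_param (numeric scalar), with the full
#'   (reg_param, residual, seminorm) table as attribute `lcurve`.
#' @export
select_reg_param <- function(f, r_grid, candidates = 10^seq(-4, 2,
                                                            length.out = 13),
                             depth) {
  candidates <- sort(unique(candidates))
  if (length(candidates) < 8L)
    stop("select_reg_param: need at least 8 distinct candidates")
  K <- dipolar_kernel_matrix(f$t, r_grid)
  Kw <- K %*% diag(trapz_weights(r_grid))
  tab <- t(vapply(candidates, function(rp) {
    sol <- tikhonov_core(Kw, f$v, depth, rp, r_grid)
    c(rp, sol$residual_norm, sol$seminorm)
  }, numeric(3)))
  colnames(tab) <- c("reg_param", "residual_norm", "seminorm")
  lx <- log10(pmax(tab[, 2], 1e-15))
  ly <- log10(pmax(tab[, 3], 1e-15))
  if (max(lx) - min(lx) < 1e-6 && max(ly) - min(ly) < 1e-6)
    stop("select_reg_param: degenerate flat L-curve; choose reg_param manually")
  curv <- menger_curvature(lx, ly)
  best <- which.max(curv)
  structure(tab[best, 1], lcurve = tab)
}

# signed-magnitude Menger curvature at interior points; endpoints get -Inf
menger_curvature <- function(x, y) {
  n <- length(x)
  k <- rep(-Inf, n)
  for (i in 2:(n - 1)) {
    a <- c(x[i - 1], y[i - 1]); b <- c(x[i], y[i]); cc <- c(x[i + 1], y[i + 1])
    num <- 2 * abs((b[1] - a[1]) * (cc[2] - a[2]) -
                     (b[2] - a[2]) * (cc[1] - a[1]))
    den <- sqrt(sum((b - a)^2)) * sqrt(sum((cc - b)^2)) * sqrt(sum((cc - a)^2))
    k[i] <- if (den < 1e-300) -Inf else num / den
  }
  k
}
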