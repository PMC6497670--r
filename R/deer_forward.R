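#' Distance distributions
#'
#' `distance_distribution(r, p)` stores a probability density P(r) on a
#' uniform distance grid (nm, nm^-1), normalized to unit trapezoidal
#' integral.
#'
#' @param r uniform, strictly increasing grid in nm.
#' @param p non-negative densities in nm^-1; renormalized on construction.
#' @return An object of class `distance_distribution`.
#' @export
distance_distribution <- function(r, p) {
  check_uniform_grid(r, "r")
  if (length(p) != length(r)) stop("distance_distribution: length mismatch")
  if (any(!is.finite(p)) || any(p < -1e-12))
    stop("distance_distribution: densities must be finite and non-negative")
  p <- pmax(p, 0)
  z <- trapz(r, p)
  if (z <= 0) stop("distance_distribution: zero total mass")
  structure(list(r = r, p = p / z), class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  m <- distribution_moments(x)
  cat(sprintf(
    "<distance_distribution> r in [%.2f, %.2f] nm (%d pts), mean %.2f nm, sd %.2f nm\n",
    min(x$r), max(x$r), length(x$r), m[["mean"]], m[["sd"]]))
  invisible(x)
}

#' Gaussian distance distribution on a grid
#'
#' @param mean,sd Gaussian parameters in nm.
#' @param r_grid distance grid.
#' @return A [distance_distribution()].
#' @export
gaussian_distribution <- function(mean, sd, r_grid = default_r_grid()) {
  distance_distribution(r_grid, stats::dnorm(r_grid, mean, sd))
}

#' Mean and standard deviation of a distance distribution
#'
#' Trapezoidal first and central second moments over the grid.
#'
#' @param p a `distance_distribution`.
#' @return named numeric `c(mean =, sd =)` in nm.
#' @export
distribution_moments <- function(p) {
  stopifnot(inherits(p, "distance_distribution"))
  m <- trapz(p$r, p$r * p$p)
  v <- trapz(p$r, (p$r - m)^2 * p$p)
  c(mean = m, sd = sqrt(max(v, 0)))
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2; w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

check_uniform_grid <- function(g, name) {
  if (length(g) < 2L) stop(name, ": need at least 2 grid points")
  d <- diff(g)
  if (any(d <= 0)) stop(name, ": grid must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * max(abs(g)))
    stop(name, ": grid must be uniform")
  invisible(g)
}

#' DEER/PELDOR time traces
#'
#' Two kinds are distinguished: `"primary"` traces V(t)/V(0) (carrying
#' the intermolecular background) and background-corrected
#' `"form_factor"` traces F(t)/F(0). Both are normalized to 1 at t = 0.
#'
#' @param t uniform time grid in microseconds starting at 0.
#' @param v normalized intensities, v[1] = 1.
#' @param kind `"form_factor"` or `"primary"`.
#' @param depth modulation depth attribute carried for downstream use
#'   (optional, may be NA).
#' @return An object of class `deer_trace`.
#' @export
deer_trace <- function(t, v, kind = c("form_factor", "primary"), depth = NA) {
  kind <- match.arg(kind)
  check_uniform_grid(t, "t")
  if (abs(t[1]) > 1e-12) stop("deer_trace: time grid must start at 0")
  if (length(v) != length(t)) stop("deer_trace: length mismatch")
  if (abs(v[1] - 1) > 1e-9) stop("deer_trace: v[1] must be 1 (normalize first)")
  structure(list(t = t, v = v, kind = kind, depth = depth),
            class = "deer_trace")
}

#' @export
print.deer_trace <- function(x, ...) {
  cat(sprintf("<deer_trace:%s> %d points, t up to %.2f us\n",
              x$kind, length(x$t), max(x$t)))
  invisible(x)
}

# dipolar frequency constant for a nitroxide pair, MHz nm^3
.dipolar_const_mhz_nm3 <- 52.04

#' Angle-averaged dipolar kernel
#'
#' K(t, r) = integral_0^1 cos[(3u^2 - 1) w t] du with w = 2 pi * 52.04
#' MHz nm^3 / r^3, the powder-averaged two-spin dipolar evolution for a
#' nitroxide pair. Evaluated by the Fresnel-integral closed form;
#' `method = "quadrature"` provides a brute-force fallback used for
#' equivalence testing.
#'
#' @param t time(s) in microseconds, t >= 0.
#' @param r distance(s) in nm, r > 0. `t` and `r` are recycled against
#'   each other elementwise; use [dipolar_kernel_matrix()] for the outer
#'   product.
#' @param method `"fresnel"` (closed form, default) or `"quadrature"`.
#' @param n_quad number of midpoint quadrature nodes for the fallback.
#' @return kernel values in [-1, 1]; K(0, r) = 1.
#' @export
dipolar_kernel <- function(t, r, method = c("fresnel", "quadrature"),
                           n_quad = 2001L) {
  method <- match.arg(method)
  if (any(r <= 0)) stop("dipolar_kernel: r must be positive")
  if (any(t < 0)) stop("dipolar_kernel: t must be non-negative")
  w <- 2 * pi * .dipolar_const_mhz_nm3 / r^3  # rad/us
  phi <- w * t
  if (method == "quadrature") {
    u <- (seq_len(n_quad) - 0.5) / n_quad
    return(vapply(phi, function(ph) mean(cos((3 * u^2 - 1) * ph)), 0))
  }
  out <- numeric(length(phi))
  phi <- rep_len(phi, length(out))
  small <- phi < 1e-8
  out[small] <- 1
  if (any(!small)) {
    ph <- phi[!small]
    k <- sqrt(6 * ph / pi)
    fr <- fresnel_cs(k)
    out[!small] <- sqrt(pi / (6 * ph)) *
      (cos(ph) * fr$C + sin(ph) * fr$S)
  }
  out
}

# Fresnel integrals C(x), S(x) (normalization: C(x) = int_0^x cos(pi t^2/2) dt);
# evaluated in compiled code (power series / continued fraction).
fresnel_cs <- function(x) cpp_fresnel_cs(as.numeric(x))

#' Kernel matrix over a time and distance grid
#'
#' @param t time grid (us); @param r distance grid (nm).
#' @return length(t) x length(r) matrix of kernel values.
#' @export
dipolar_kernel_matrix <- function(t, r) {
  outer(t, r, function(tt, rr) dipolar_kernel(tt, rr))
}

#' Form factor from a distance distribution
#'
#' F(t) = 1 - lambda + lambda * integral p(r) K(t, r) dr; F(0) = 1.
#'
#' @param p a [distance_distribution()].
#' @param t time grid in us.
#' @param depth modulation depth lambda in [0, 1].
#' @return A [deer_trace()] of kind `form_factor`.
#' @export
form_factor <- function(p, t, depth) {
  stopifnot(inherits(p, "distance_distribution"), depth >= 0, depth <= 1)
  K <- dipolar_kernel_matrix(t, p$r)
  s <- as.numeric(K %*% (p$p * trapz_weights(p$r)))
  deer_trace(t, 1 - depth + depth * s, kind = "form_factor", depth = depth)
}

#' Intermolecular background model
#'
#' Homogeneous 3-dimensional background B(t) = exp(-k t) by default; a
#' stretched exponential exp(-k t^(d/3)) for d != 3.
#'
#' @param k decay rate in us^-1, k >= 0.
#' @param d background dimensionality (default 3).
#' @return object of class `background_model`.
#' @export
background_model <- function(k, d = 3) {
  if (k < 0) stop("background_model: k must be >= 0")
  structure(list(k = k, d = d), class = "background_model")
}

background_values <- function(bg, t) exp(-bg$k * t^(bg$d / 3))

#' Apply or remove an intermolecular background
#'
#' `apply_background` turns a form factor into a primary trace
#' V(t) = F(t) B(t) (renormalized to V(0) = 1); `remove_background`
#' divides it out again. Removing after applying is the identity.
#'
#' @param trace a [deer_trace()].
#' @param bg a [background_model()].
#' @return A [deer_trace()] of the other kind.
#' @export
apply_background <- function(trace, bg) {
  stopifnot(inherits(trace, "deer_trace"), inherits(bg, "background_model"))
  v <- trace$v * background_values(bg, trace$t)
  deer_trace(trace$t, v / v[1], kind = "primary", depth = trace$depth)
}

#' @rdname apply_background
#' @export
remove_background <- function(trace, bg) {
  stopifnot(inherits(trace, "deer_trace"), inherits(bg, "background_model"))
  b <- background_values(bg, trace$t)
  if (any(b <= 0)) stop("remove_background: background reaches zero")
  v <- trace$v / b
  deer_trace(trace$t, v / v[1], kind = "form_factor", depth = trace$depth)
}

#' Fit an intermolecular background to the trace tail
#'
#' Log-linear least squares of log V(t) on t over the tail window
#' t >= `tail_from` * max(t) (default: the final 75% of the trace),
#' where the intramolecular oscillations have decayed.
#'
#' @param trace a primary [deer_trace()].
#' @param tail_from fraction of the trace length at which the fit window
#'   starts (default 0.25).
#' @param d background dimensionality.
#' @return A [background_model()] with the fitted rate.
#' @export
fit_background <- function(trace, tail_from = 0.25, d = 3) {
  stopifnot(inherits(trace, "deer_trace"))
  sel <- trace$t >= tail_from * max(trace$t)
  if (sum(sel) < 3L) stop("fit_background: tail window has < 3 points")
  if (any(trace$v[sel] <= 0)) stop("fit_background: non-positive tail values")
  ts <- trace$t[sel]^(d / 3)
  fit <- stats::lm.fit(cbind(1, ts), log(trace$v[sel]))
  background_model(max(0, -fit$coefficients[2]), d = d)
}

#' Expected modulation depth of a dimer
#'
#' lambda = f * lambda_B: the probability that the partner protomer both
#' carries a label (labeling efficiency f) and is flipped by the pump
#' pulse (inversion efficiency lambda_B).
#'
#' @param label_fraction f in [0, 1].
#' @param inversion_efficiency lambda_B in [0, 1].
#' @return modulation depth in [0, 1].
#' @export
dimer_modulation_depth <- function(label_fraction, inversion_efficiency) {
  stopifnot(label_fraction >= 0, label_fraction <= 1,
            inversion_efficiency >= 0, inversion_efficiency <= 1)
  label_fraction * inversion_efficiency
}

#' Forward-calculate a PELDOR trace from a dimer pose
#'
#' Composes [c2_pair_distribution()] and [form_factor()]. The returned
#' trace carries, as attribute `kernel_matrix`, the per-rotamer-pair
#' form-factor matrix (pairs x timepoints, each row 1 - lambda +
#' lambda K(t, r_pair)) and `pair_weights`, as needed for maximum-entropy
#' reweighting.
#'
#' @param ensemble a `spin_site_ensemble` in the centred protomer frame.
#' @param pose a [c2_pose()].
#' @param t time grid (us).
#' @param depth modulation depth lambda.
#' @param r_grid distance grid for the intermediate distribution.
#' @return A [deer_trace()] with attributes `kernel_matrix`, `pair_weights`
#'   and `distribution`.
#' @export
trace_from_pose <- function(ensemble, pose, t, depth,
                            r_grid = default_r_grid()) {
  pose <- as_c2_pose(pose)
  tr <- c2_placement(pose)
  pa <- apply_transform(tr, ensemble$positions)
  pb <- apply_transform(rot_z(180), pa)
  dw <- cpp_pair_distances(pa, ensemble$weights, pb, ensemble$weights)
  keep <- dw$d >= 1e-9
  if (!any(keep)) stop("trace_from_pose: all pairs at zero distance")
  d <- dw$d[keep]; w <- dw$w[keep] / sum(dw$w[keep])
  Kp <- t(vapply(d, function(ri) 1 - depth + depth * dipolar_kernel(t, ri),
                 numeric(length(t))))
  v <- as.numeric(crossprod(Kp, w))
  dist <- c2_pair_distribution(ensemble, pose, r_grid)
  out <- deer_trace(t, v / v[1], kind = "form_factor", depth = depth)
  attr(out, "kernel_matrix") <- Kp
  attr(out, "pair_weights") <- w
  attr(out, "distribution") <- dist
  out
}

#' Read / write DEER traces as two-column ASCII
#'
#' Format: '#' comment lines, then two whitespace-separated columns
#' (time in us, normalized signal). The writer emits a provenance header
#' with kind, depth and any extra fields supplied.
#'
#' @param path file path.
#' @param kind trace kind for the reader (default `"primary"`).
#' @return A [deer_trace()] (reader); `path` invisibly (writer).
#' @export
read_deer_trace <- function(path, kind = c("primary", "form_factor")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("t", "v"))
  deer_trace(df$t, df$v / df$v[1], kind = kind)
}

#' @rdname read_deer_trace
#' @param trace a [deer_trace()] to write.
#' @param meta named list of extra provenance fields for the header.
#' @export
write_deer_trace <- function(trace, path, meta = list()) {
  stopifnot(inherits(trace, "deer_trace"))
  hdr <- c(sprintf("# deerdock trace kind=%s depth=%s", trace$kind,
                   format(trace$depth)),
           vapply(names(meta), function(nm)
             sprintf("# %s=%s", nm, format(meta[[nm]])), ""))
  writeLines(c(hdr, sprintf("%.6f %.10f", trace$t, trace$v)), path)
  invisible(path)
}
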