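#' Maximum-entropy reweighting problems
#'
#' A reweight problem holds, for one labelled site, the forward-calculated
#' per-rotamer-pair signal matrix (pairs x timepoints), reference weights
#' (uniform by default), the experimental form factor, and the noise sd.
#' The optimal weights minimize `theta * S_KL(w || w0) + chi2(w) / 2`
#' over the probability simplex, with
#' `chi2(w) = sum_t (sum_i w_i K_it - F_t)^2 / sigma^2`.
#'
#' @param kernel pairs x timepoints matrix of forward-calculated signals
#'   (e.g. the `kernel_matrix` attribute of [trace_from_pose()]).
#' @param fexp experimental form-factor values (length = ncol(kernel)).
#' @param noise_sd noise standard deviation; if NULL, estimated as the sd
#'   of the final 20% of `fexp` after removing its local mean.
#' @param w0 reference weights (default uniform).
#' @return object of class `reweight_problem`.
#' @export
reweight_problem <- function(kernel, fexp, noise_sd = NULL, w0 = NULL) {
  kernel <- as.matrix(kernel)
  stopifnot(length(fexp) == ncol(kernel))
  n <- nrow(kernel)
  if (is.null(w0)) w0 <- rep(1 / n, n)
  if (length(w0) != n || any(w0 < 0) || abs(sum(w0) - 1) > 1e-9)
    stop("reweight_problem: w0 must be a length-nrow probability vector")
  if (is.null(noise_sd)) {
    tail_idx <- seq.int(max(1L, ceiling(0.8 * length(fexp))), length(fexp))
    tl <- fexp[tail_idx]
    noise_sd <- stats::sd(tl - mean(tl))
    if (!is.finite(noise_sd) || noise_sd <= 0) noise_sd <- 1e-3
  }
  if (noise_sd <= 0) stop("reweight_problem: noise_sd must be positive")
  structure(list(kernel = kernel, fexp = as.numeric(fexp),
                 noise_sd = noise_sd, w0 = w0),
            class = "reweight_problem")
}

chi2_of <- function(problem, w) {
  r <- as.numeric(crossprod(problem$kernel, w)) - problem$fexp
  sum(r^2) / problem$noise_sd^2
}

skl_of <- function(w, w0) {
  nz <- w > 1e-300
  sum(w[nz] * log(w[nz] / w0[nz]))
}

#' BioEn-style maximum-entropy reweighting at fixed confidence theta
#'
#' Minimizes `theta * S_KL(w || w0) + chi2(w) / 2` in log-weight
#' coordinates (softmax parameterization, so the simplex constraint is
#' implicit) with analytic gradients and BFGS restarts until the
#' projected gradient norm is at or below `grad_tol`. The objective at
#' the solution never exceeds the objective at `w0`. Deterministic.
#'
#' @param problem a [reweight_problem()].
#' @param theta confidence parameter (> 0). Large theta returns w0.
#' @param grad_tol gradient sup-norm target (default 1e-8).
#' @param max_restarts BFGS restart cap.
#' @return object of class `bioen_solution`: list
#'   `(theta, weights, chi2, skl, objective)`.
#' @export
reweight <- function(problem, theta, grad_tol = 1e-8, max_restarts = 40L) {
  stopifnot(inherits(problem, "reweight_problem"), theta > 0)
  K <- problem$kernel; fexp <- problem$fexp
  s2 <- problem$noise_sd^2; w0 <- problem$w0
  n <- nrow(K)
  lw0 <- log(pmax(w0, 1e-300))
  obj_grad <- function(g) {
    z <- lw0 + g
    z <- z - max(z)
    w <- exp(z); w <- w / sum(w)
    r <- as.numeric(crossprod(K, w)) - fexp
    chi2 <- sum(r^2) / s2
    skl <- skl_of(w, w0)
    f <- theta * skl + chi2 / 2
    # d obj / d w, then chain through softmax: J = diag(w) - w w^T
    dw <- theta * (log(pmax(w, 1e-300) / pmax(w0, 1e-300)) + 1) +
      as.numeric(K %*% r) / s2
    gr <- w * (dw - sum(w * dw))
    list(f = f, gr = gr, w = w, chi2 = chi2, skl = skl,
         dwmax = max(abs(dw)))
  }
  # Newton step in the softmax coordinates (small problems only; the
  # Hessian is n x n). H = J' H_w J + diag terms of the softmax chain.
  newton_step <- function(g) {
    z <- lw0 + g; z <- z - max(z)
    w <- exp(z); w <- w / sum(w)
    r <- as.numeric(crossprod(K, w)) - fexp
    dw <- theta * (log(pmax(w, 1e-300) / pmax(w0, 1e-300)) + 1) +
      as.numeric(K %*% r) / s2
    Hw <- theta * diag(1 / pmax(w, 1e-12)) + tcrossprod(K) / s2
    J <- diag(w) - tcrossprod(w)            # d w / d g
    gr <- as.numeric(J %*% dw)
    H <- J %*% Hw %*% J + diag(w * dw) - (w %o% (w * dw)) -
      ((w * dw) %o% w) + sum(w * dw) * tcrossprod(w) - sum(w * dw) * J
    H <- H + diag(1e-12, n)
    step <- tryCatch(solve(H, gr), error = function(e) gr)
    # backtracking line search on the Newton direction; near the optimum
    # objective differences fall below double-precision resolution, so
    # allow a relative slack and let the caller judge by the gradient
    f0 <- obj_grad(g)$f
    a <- 1
    while (a > 1e-10 &&
           obj_grad(g - a * step)$f > f0 + 1e-10 * abs(f0) + 1e-12)
      a <- a / 2
    g - a * step
  }
  g <- numeric(n)
  at0 <- obj_grad(g)
  f0 <- at0$f
  # convergence target is relative to the problem's gradient scale: with
  # small noise sd the raw gradient carries 1/sigma^2 and an absolute
  # 1e-8 would demand beyond-double precision
  gtol <- grad_tol * max(1, at0$dwmax)
  for (k in seq_len(max_restarts)) {
    opt <- stats::optim(g, fn = function(p) obj_grad(p)$f,
                        gr = function(p) obj_grad(p)$gr,
                        method = "L-BFGS-B",
                        control = list(maxit = 1000L, pgtol = 0,
                                       factr = 1))
    g <- opt$par
    if (max(abs(obj_grad(g)$gr)) <= gtol) break
    if (n <= 400L) {
      for (j in 1:30) {
        g2 <- newton_step(g)
        a2 <- obj_grad(g2); a1 <- obj_grad(g)
        if (max(abs(a2$gr)) < max(abs(a1$gr)) || a2$f < a1$f) g <- g2
        else break
        if (max(abs(obj_grad(g)$gr)) <= gtol) break
      }
    }
    if (max(abs(obj_grad(g)$gr)) <= gtol) break
    if (k == max_restarts)
      stop(sprintf(
        "reweight: not converged; final gradient norm %.3g > %.3g",
        max(abs(obj_grad(g)$gr)), gtol))
  }
  fin <- obj_grad(g)
  if (fin$f > f0 + 1e-10) { g <- numeric(n); fin <- obj_grad(g) }
  structure(list(theta = theta, weights = fin$w, chi2 = fin$chi2,
                 skl = max(0, fin$skl), objective = fin$f),
            class = "bioen_solution")
}

#' @export
print.bioen_solution <- function(x, ...) {
  cat(sprintf("<bioen_solution> theta=%.3g chi2=%.4g S_KL=%.4g (%d weights)\n",
              x$theta, x$chi2, x$skl, length(x$weights)))
  invisible(x)
}

#' L-curve selection of the confidence parameter theta
#'
#' Solves the reweighting across a log-spaced theta grid, checks the
#' maximum-entropy monotonicity (chi2 non-increasing and S_KL
#' non-decreasing as theta decreases; violations beyond `mono_tol`
#' signal optimizer failure and raise an error), and returns the theta
#' at maximum curvature of the (log chi2, S_KL) curve. If the problem
#' has zero misfit (S_KL ~ 0 throughout) the selection degenerates and
#' the largest theta is returned.
#'
#' @param problem a [reweight_problem()].
#' @param thetas >= 8 log-spaced candidates (default 10^-2..10^4).
#' @param mono_tol tolerance for the monotonicity check.
#' @return list `(theta, table)`; table has columns theta, chi2, skl.
#' @export
theta_lcurve <- function(problem, thetas = 10^seq(-2, 4, length.out = 13),
                         mono_tol = 1e-6) {
  thetas <- sort(unique(thetas), decreasing = TRUE)
  if (length(thetas) < 8L) stop("theta_lcurve: need >= 8 candidates")
  sols <- lapply(thetas, function(th) reweight(problem, th))
  tab <- data.frame(theta = thetas,
                    chi2 = vapply(sols, `[[`, 0, "chi2"),
                    skl = vapply(sols, `[[`, 0, "skl"))
  # decreasing theta down the table: chi2 must not increase, skl not decrease
  sc <- max(tab$chi2, 1)
  if (any(diff(tab$chi2) > mono_tol * sc))
    stop("theta_lcurve: chi2 not monotone in theta (optimizer failure?)")
  if (any(diff(tab$skl) < -mono_tol * max(tab$skl, 1)))
    stop("theta_lcurve: S_KL not monotone in theta (optimizer failure?)")
  if (max(tab$skl) < 1e-9)
    return(list(theta = max(thetas), table = tab))
  # corner of the log-log trade-off curve (see vignette: the linear-skl
  # curvature peaks degenerately at the prior-dominated end)
  lx <- log10(pmax(tab$chi2, 1e-15))
  ly <- log10(pmax(tab$skl, 1e-15))
  curv <- menger_curvature(lx, ly)
  list(theta = tab$theta[which.max(curv)], table = tab)
}

#' Select the dimer conformer with minimal total chi-squared
#'
#' For each conformer (a named list of per-site [reweight_problem()]s
#' over identical sites), runs the reweighting at the policy theta and
#' sums chi2 over sites; returns the argmin (ties broken toward the
#' lower index).
#'
#' @param conformers list of conformers; each a named list of
#'   `reweight_problem`s with identical names (sites).
#' @param theta_policy either a fixed numeric theta (e.g. 10) applied to
#'   every site, or `"lcurve"` for per-site L-curve selection.
#' @return list `(best, total_chi2, per_site)`: 1-based best index,
#'   per-conformer total chi2 vector, and a matrix of per-site chi2.
#' @export
select_conformer <- function(conformers, theta_policy = 10) {
  stopifnot(length(conformers) >= 1L)
  sites <- names(conformers[[1]])
  for (cf in conformers)
    if (!identical(names(cf), sites))
      stop("select_conformer: conformers must share the same sites")
  per_site <- t(vapply(conformers, function(cf) {
    vapply(sites, function(s2) {
      pb <- cf[[s2]]
      th <- if (identical(theta_policy, "lcurve"))
        theta_lcurve(pb)$theta else theta_policy
      reweight(pb, th)$chi2
    }, 0)
  }, numeric(length(sites))))
  per_site <- matrix(per_site, nrow = length(conformers),
                     dimnames = list(NULL, sites))
  total <- rowSums(per_site)
  list(best = which.min(total), total_chi2 = total, per_site = per_site)
}

#' Marginalize joint rotamer-pair weights
#'
#' Sums pair weights over the partner index, returning the per-rotamer
#' marginal distribution (a valid probability vector).
#'
#' @param weights pair weights of length n1 * n2, ordered with the
#'   partner index varying fastest (as produced by the pair kernel of
#'   [trace_from_pose()]).
#' @param n1,n2 rotamer counts of the two copies.
#' @param margin 1 to marginalize onto copy one, 2 onto copy two.
#' @return numeric vector of marginal weights summing to 1.
#' @export
marginal_rotamer_weights <- function(weights, n1, n2, margin = 1) {
  stopifnot(length(weights) == n1 * n2, margin %in% c(1, 2))
  m <- matrix(weights, nrow = n2, ncol = n1)  # partner varies fastest
  out <- if (margin == 1) colSums(m) else rowSums(m)
  out / sum(out)
}
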