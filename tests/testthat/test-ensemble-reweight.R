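# small reweighting problem with a planted non-uniform truth
planted_problem <- function(n = 6, nt = 25, seed = 21, noise = 0.002) {
  set.seed(seed)
  rs <- runif(n, 1.8, 4.5)
  tg <- seq(0, 1.5, length.out = nt)
  K <- t(vapply(rs, function(r) 1 - 0.4 + 0.4 * dipolar_kernel(tg, r),
                numeric(nt)))
  w_true <- runif(n); w_true <- w_true / sum(w_true)
  fexp <- as.numeric(crossprod(K, w_true)) + rnorm(nt, 0, noise)
  list(problem = reweight_problem(K, fexp, noise_sd = max(noise, 1e-3)),
       w_true = w_true, K = K)
}

test_that("reweight hits the prior-dominated and zero-misfit limits", {
  # theta -> infinity returns the reference weights (O(1)-scaled toy; on
  # a small-noise problem the optimum at theta = 1e6 genuinely deviates
  # by ~|grad chi2|/theta, so the 1e-4 bound applies to the toy scale)
  K3 <- matrix(c(1.0, 0.2, 1.0, -0.1, 1.0, 0.5), nrow = 3, byrow = TRUE)
  pb3 <- reweight_problem(K3, c(1.0, 0.25), noise_sd = 0.05)
  s_inf <- reweight(pb3, 1e6)
  expect_lt(max(abs(s_inf$weights - 1 / 3)), 1e-4)
  pp <- planted_problem()
  n <- length(pp$w_true)
  s_inf2 <- reweight(pp$problem, 1e8)
  expect_lt(max(abs(s_inf2$weights - 1 / n)), 1e-4)
  # data generated exactly from w0: w = w0 for every theta
  fexp0 <- as.numeric(crossprod(pp$K, rep(1 / n, n)))
  pb0 <- reweight_problem(pp$K, fexp0, noise_sd = 0.01)
  for (th in c(0.1, 10, 1000)) {
    s <- reweight(pb0, th)
    expect_lt(max(abs(s$weights - 1 / n)), 1e-6)
    expect_lt(s$skl, 1e-9)
  }
})

test_that("reweight matches a brute-force simplex-grid oracle", {
  K <- matrix(c(1.0, 0.2,
                1.0, -0.1,
                1.0, 0.5), nrow = 3, byrow = TRUE)
  fexp <- c(1.0, 0.25)
  sig <- 0.05
  pb <- reweight_problem(K, fexp, noise_sd = sig)
  th <- 2
  sol <- reweight(pb, th)
  # dense 1e-3-spaced simplex enumeration (vectorized)
  g <- seq(0, 1, by = 1e-3)
  grid <- expand.grid(w1 = g, w2 = g)
  grid <- grid[grid$w1 + grid$w2 <= 1, ]
  W <- cbind(grid$w1, grid$w2, pmax(1 - grid$w1 - grid$w2, 0))
  xlogx <- function(w) { o <- w * log(w * 3); o[w == 0] <- 0; o }
  skl <- rowSums(xlogx(W))
  R <- W %*% K - matrix(fexp, nrow(W), 2, byrow = TRUE)
  fval <- th * skl + rowSums(R^2) / sig^2 / 2
  w_star <- W[which.min(fval), ]
  expect_lt(max(abs(sol$weights - w_star)), 2e-3)
  # objective at the solution does not exceed the objective at w0
  expect_lte(sol$objective, th * 0 + sum((crossprod(K, rep(1 / 3, 3)) -
                                            fexp)^2) / sig^2 / 2 + 1e-12)
})

test_that("chi2/S_KL trade-off is monotone in theta", {
  for (seed in c(21, 22)) {
    pp <- planted_problem(seed = seed)
    lc <- theta_lcurve(pp$problem, 10^seq(-2, 4, length.out = 13))
    tab <- lc$table  # descending theta
    expect_true(all(diff(tab$chi2) <= 1e-6 * max(tab$chi2, 1)))
    expect_true(all(diff(tab$skl) >= -1e-6 * max(tab$skl, 1)))
  }
})

test_that("L-curve theta lands between the grid endpoints (planted truth)", {
  pp <- planted_problem(noise = 0.004)
  thetas <- 10^seq(-2, 4, length.out = 13)
  lc <- theta_lcurve(pp$problem, thetas)
  l1 <- function(th) sum(abs(reweight(pp$problem, th)$weights - pp$w_true))
  expect_lt(l1(lc$theta), l1(max(thetas)))
  expect_lt(l1(lc$theta), l1(min(thetas)))
  # zero-misfit degeneracy falls back to the largest theta
  n <- length(pp$w_true)
  fexp0 <- as.numeric(crossprod(pp$K, rep(1 / n, n)))
  pb0 <- reweight_problem(pp$K, fexp0, noise_sd = 0.01)
  lc0 <- theta_lcurve(pb0, thetas)
  expect_equal(lc0$theta, max(thetas))
})

test_that("select_conformer picks the generator with minimal total chi2", {
  pp <- planted_problem(seed = 31, noise = 0)
  n <- length(pp$w_true)
  # conformer A generated the data; conformer B is shuffled columns
  K_b <- pp$K[, c(2:ncol(pp$K), 1)]
  fexp <- as.numeric(crossprod(pp$K, rep(1 / n, n)))
  make_cf <- function(K) list(
    site1 = reweight_problem(K, fexp, noise_sd = 0.01),
    site2 = reweight_problem(K + 0.01, fexp, noise_sd = 0.01))
  cfA <- make_cf(pp$K); cfB <- make_cf(K_b)
  expect_equal(select_conformer(list(cfA), theta_policy = 10)$best, 1L)
  selAB <- select_conformer(list(cfA, cfB), theta_policy = 10)
  selBA <- select_conformer(list(cfB, cfA), theta_policy = 10)
  expect_equal(selAB$best, 1L)
  expect_equal(selBA$best, 2L)
  expect_equal(selAB$total_chi2[1], selBA$total_chi2[2], tolerance = 1e-6)
})

test_that("marginalized pair weights form a valid distribution", {
  sc <- shared_scenario()
  big <- sc$ensembles[[1]]
  ens <- spin_site_ensemble(big$site, big$positions[1:8, , drop = FALSE])
  tg <- seq(0, 0.4, by = 0.02)
  tr <- trace_from_pose(ens, sc$pose, tg, 0.4)
  K <- attr(tr, "kernel_matrix")
  n1 <- nrow(ens$positions)
  pb <- reweight_problem(K, tr$v * (1 + 0.002 * sin(8 * tg)),
                         noise_sd = 0.002)
  sol <- reweight(pb, 10)
  for (m in 1:2) {
    marg <- marginal_rotamer_weights(sol$weights, n1, n1, margin = m)
    expect_equal(sum(marg), 1, tolerance = 1e-9)
    expect_true(all(marg >= 0))
    expect_length(marg, n1)
  }
})
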