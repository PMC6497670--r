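#' Stochastic dimer-class fractions
#'
#' Under stochastic (binomial) dimer assembly from a protomer pool with
#' wildtype fraction `f_wt`, the dimer classes occur with fractions
#' (f^2, 2 f (1 - f), (1 - f)^2) for WT-WT, WT-mutant and
#' mutant-mutant dimers; mixing 50:50 gives 25/50/25%.
#'
#' @param f_wt wildtype protomer fraction in [0, 1] (vectorized).
#' @return matrix with columns `f_ww`, `f_wi`, `f_ii`; rows sum to 1.
#' @export
dimer_fractions <- function(f_wt) {
  if (any(!is.finite(f_wt)) || any(f_wt < 0) || any(f_wt > 1))
    stop("dimer_fractions: f_wt must lie in [0, 1]")
  cbind(f_ww = f_wt^2, f_wi = 2 * f_wt * (1 - f_wt), f_ii = (1 - f_wt)^2)
}

#' Heterodimer-mixing activity model
#'
#' Specific activities of the homodimers plus the heterodimer activity
#' expressed as a fraction `c_het` of the wildtype homodimer activity.
#' The three reference models use c_het = 0, 0.5 and 1. The
#' independent-protomer expectation (each protomer contributes half its
#' homodimer activity, giving the straight line between the endpoint
#' activities) corresponds to c_het = (a_wt + a_il) / (2 a_wt), not to
#' c_het = 0.5 unless the mutant homodimer is fully inactive.
#'
#' @param a_wt,a_il homodimer specific activities (nmol per mg per min).
#' @param c_het heterodimer activity as a fraction of `a_wt`, in [0, 1].
#' @return object of class `mixing_model`.
#' @export
mixing_model <- function(a_wt = 32.3, a_il = 6.8, c_het = 1) {
  if (a_wt < 0 || a_il < 0) stop("mixing_model: activities must be >= 0")
  if (c_het < 0 || c_het > 1) stop("mixing_model: c_het must lie in [0, 1]")
  structure(list(a_wt = a_wt, a_il = a_il, c_het = c_het),
            class = "mixing_model")
}

#' Predicted ensemble transport rate of a protomer mixture
#'
#' rate(f) = f^2 a_WT + 2 f (1 - f) c_het a_WT + (1 - f)^2 a_IL:
#' exactly quadratic in the wildtype fraction, with the homodimer
#' activities at the endpoints.
#'
#' @param f_wt wildtype protomer fraction(s) in [0, 1].
#' @param model a [mixing_model()].
#' @return rate(s) in nmol per mg per min.
#' @export
predicted_rate <- function(f_wt, model) {
  stopifnot(inherits(model, "mixing_model"))
  fr <- dimer_fractions(f_wt)
  as.numeric(fr %*% c(model$a_wt, model$c_het * model$a_wt, model$a_il))
}

#' Uptake time courses
#'
#' @param times minutes, non-negative increasing within each replicate.
#' @param uptake nmol substrate per mg protein.
#' @param replicate replicate identifier.
#' @param f_wt wildtype mixing fraction of the sample.
#' @return data.frame of class `uptake_time_course`.
#' @export
uptake_time_course <- function(times, uptake, replicate = 1L, f_wt = 1) {
  df <- data.frame(time_min = times, uptake_nmol_per_mg = uptake,
                   replicate = replicate, f_wt = f_wt)
  sp <- split(df, list(df$replicate, df$f_wt), drop = TRUE)
  for (g in sp) {
    if (nrow(g) < 3L)
      stop("uptake_time_course: each replicate needs >= 3 points")
    if (any(g$time_min < 0) || any(diff(g$time_min) <= 0))
      stop("uptake_time_course: times must be non-negative increasing")
  }
  class(df) <- c("uptake_time_course", "data.frame")
  df
}

# per-replicate linear-window slope
replicate_slope <- function(tt, up, window, k_points) {
  if (window == "fraction_of_plateau") {
    plateau <- tryCatch(suppressWarnings({
      fit <- stats::nls(up ~ A * (1 - exp(-k * tt)),
                        start = list(A = max(up), k = 1 / max(tt)),
                        control = stats::nls.control(warnOnly = TRUE))
      stats::coef(fit)[["A"]]
    }), error = function(e) Inf)
    sel <- up <= 0.3 * plateau
    if (sum(sel) < 3L) sel <- seq_along(tt) <= 3L  # fall back to first 3
  } else {
    sel <- seq_along(tt) <= k_points
  }
  if (sum(sel) < 3L) stop("initial_rate: fewer than 3 linear-window points")
  stats::lm.fit(cbind(1, tt[sel]), up[sel])$coefficients[2]
}

#' Initial transport rate from an uptake time course
#'
#' Ordinary least-squares slope of uptake versus time over the early
#' linear window, per replicate; the default window keeps points with
#' uptake at or below 30% of the fitted saturation plateau (minimum 3
#' points). Returns the mean and sd across replicates.
#'
#' @param tc an [uptake_time_course()] for a single mixing fraction.
#' @param window `"fraction_of_plateau"` (default) or `"first_k"`.
#' @param k_points number of points for the `"first_k"` policy.
#' @return list `(rate, sd, n_replicates)` in nmol per mg per min.
#' @export
initial_rate <- function(tc, window = c("fraction_of_plateau", "first_k"),
                         k_points = 3L) {
  window <- match.arg(window)
  stopifnot(inherits(tc, "uptake_time_course"))
  if (length(unique(tc$f_wt)) != 1L)
    stop("initial_rate: time course mixes f_wt values; split first")
  slopes <- vapply(split(tc, tc$replicate), function(g)
    replicate_slope(g$time_min, g$uptake_nmol_per_mg, window, k_points), 0)
  list(rate = mean(slopes),
       sd = if (length(slopes) > 1L) stats::sd(slopes) else 0,
       n_replicates = length(slopes))
}

#' Fit the heterodimer activity fraction to a rate table
#'
#' With the homodimer activities fixed, the mixing model is linear in
#' `c_het`: `rate - f^2 a_WT - (1-f)^2 a_IL = c_het * 2 f (1-f) a_WT`.
#' The closed-form least-squares estimate is clipped to [0, 1]. The SSE
#' of the three reference models (c_het = 0, 0.5, 1) is reported; the
#' best discrete model is the SSE argmin, ties broken toward the
#' smaller c_het (fewer active species).
#'
#' @param rates data.frame with columns `f_wt` and `rate` (>= 3 distinct
#'   f values).
#' @param a_wt,a_il fixed homodimer activities.
#' @return list `(c_het, sse, best_model)`; `sse` is a named vector for
#'   c(0, 0.5, 1), `best_model` the winning c_het value.
#' @export
fit_mixing <- function(rates, a_wt = 32.3, a_il = 6.8) {
  stopifnot(all(c("f_wt", "rate") %in% names(rates)))
  if (length(unique(rates$f_wt)) < 3L)
    stop("fit_mixing: need >= 3 distinct mixing fractions")
  f <- rates$f_wt; r <- rates$rate
  y <- r - f^2 * a_wt - (1 - f)^2 * a_il
  x <- 2 * f * (1 - f) * a_wt
  c_hat <- if (sum(x^2) > 0) sum(x * y) / sum(x^2) else NA_real_
  c_hat <- min(max(c_hat, 0), 1)
  cands <- c(`0` = 0, `0.5` = 0.5, `1` = 1)
  sse <- vapply(cands, function(cc)
    sum((r - predicted_rate(f, mixing_model(a_wt, a_il, cc)))^2), 0)
  best <- cands[order(sse, cands)][1]
  list(c_het = c_hat, sse = sse, best_model = unname(best))
}
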