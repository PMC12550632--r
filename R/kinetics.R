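# Kinetics: stretched-exponential lifetime fits per trial, the Poisson
# bond-number universal curve across trials, and off-rate vs force.
#
# Model family:
#   survival under a ramp      f(t) = 1 - g + g * exp(-(t/tau)^beta)
#   adhesion frequency         AF(lambda) = 1 - exp(-lambda)
#   population lifetime        tau(lambda) = k * lambda + x0
# Varying lambda (mean bonds per cell) traces the parametric "universal
# curve" (AF(lambda), tau(lambda)) that a single receptor type follows
# across surface concentrations.

#' Adhesion frequency implied by a Poisson bond number
#'
#' If the number of bonds per cell is Poisson(\eqn{\lambda}), the
#' probability of at least one bond — i.e. of surviving the gravity
#' interval — is \eqn{AF(\lambda) = 1 - e^{-\lambda}}, the complement of
#' the Poisson CDF at zero.
#'
#' @param lam Expected number of bonds per cell, >= 0 (vectorized).
#' @return Adhesion frequency in `[0, 1)`.
#' @export
af_from_lambda <- function(lam) {
  if (any(lam < 0)) stop("lambda must be >= 0", call. = FALSE)
  -expm1(-lam)
}

#' Mean bond number implied by an adhesion frequency
#'
#' Exact inverse of [af_from_lambda()]: \eqn{\lambda = -\ln(1 - AF)}. Values
#' of AF at or above `af_cap` are capped before inversion so that AF = 1
#' (which would send \eqn{\lambda \to \infty}) maps to a finite bond number.
#'
#' @param af Adhesion frequency in `[0, 1]` (vectorized).
#' @param af_cap Cap applied before inversion (default 0.999,
#'   \eqn{\lambda \approx 6.9}).
#' @return Expected bonds per cell.
#' @export
lambda_from_af <- function(af, af_cap = 0.999) {
  if (any(af < 0 | af > 1))
    stop("adhesion frequency must lie in [0, 1]", call. = FALSE)
  -log1p(-pmin(af, af_cap))
}

#' Stretched-exponential survival function
#'
#' \eqn{f(t) = 1 - g + g \exp(-(t/\tau)^\beta)}: the fraction of cells
#' still bound at time `t` after the force ramp starts. `g` is the
#' detachable fraction (`1 - g` never detaches within the protocol),
#' `tau` the population lifetime, and `beta` the stretching exponent
#' (`beta > 1` compresses the decay, as a ramping force accelerating the
#' off-rate does).
#'
#' @param t Times (s), >= 0.
#' @param g Detachable fraction in `[0, 1]`.
#' @param tau Population lifetime (s), > 0.
#' @param beta Stretching exponent, > 0.
#' @return Survival fraction, in `[1 - g, 1]`.
#' @export
stretched_exp <- function(t, g, tau, beta) {
  1 - g + g * exp(-(t / tau)^beta)
}

#' Fit the stretched-exponential lifetime model to a detachment curve
#'
#' Bounded nonlinear least squares (Levenberg–Marquardt via
#' \pkg{minpack.lm}) of [stretched_exp()] to `fraction_bound` vs `time_s`.
#' The fit is deterministic: initialization is rule-based (`g` from the
#' final plateau, `tau` from the half-decay time, `beta = 1`) with no
#' random restarts.
#'
#' @param curve A [build_detachment_curve()] object (time origin at
#'   centrifuge start), or any data.frame with `time_s` and
#'   `fraction_bound`; needs >= 10 points.
#' @param lower,upper Named bounds for `g`, `tau`, `beta`. Defaults:
#'   `g` in `[0, 1]`, `tau` in `(0, 10 x span]`, `beta` in `[0.2, 5]`.
#' @param flat_tol A curve whose total drop is below `flat_tol` is treated
#'   as degenerate: `g` is pinned at its lower bound and the result flagged
#'   rather than fit.
#' @return An object of class `stretched_exp_fit`: list with `g`, `tau`,
#'   `beta`, `rmse`, `n_points`, `converged`, `flags`.
#' @examples
#' tt <- seq(0, 120, by = 0.5)
#' cv <- data.frame(time_s = tt, fraction_bound = stretched_exp(tt, 0.9, 40, 1.5))
#' fit_stretched_exponential(cv)
#' @export
fit_stretched_exponential <- function(curve, lower = NULL, upper = NULL,
                                      flat_tol = 0.02) {
  t <- curve$time_s
  y <- curve$fraction_bound
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 10)
    stop("need at least 10 points spanning the decay", call. = FALSE)
  span <- max(t) - min(t)
  lo <- c(g = 0, tau = 1e-6, beta = 0.2)
  hi <- c(g = 1, tau = 10 * span, beta = 5)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)

  drop_total <- y[1] - min(y)
  if (drop_total < flat_tol) {
    return(structure(list(
      g = lo[["g"]], tau = NA_real_, beta = NA_real_,
      rmse = sd(y), n_points = length(t), converged = FALSE,
      flags = "degenerate flat curve: no measurable detachment; g pinned at lower bound"),
      class = "stretched_exp_fit"))
  }

  g0 <- min(max(1 - min(y), 0.05), 1)
  # time at which the detachable fraction has half-decayed
  y_half <- 1 - g0 / 2
  below <- which(y <= y_half)
  tau0 <- if (length(below)) max(t[below[1]], 1e-3) else span / 2
  start <- c(g = g0, tau = tau0, beta = 1)
  start <- pmin(pmax(start, lo + 1e-9), hi - 1e-9)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 - g + g * exp(-(t / tau)^beta),
      start = as.list(start), lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(list(
      g = NA_real_, tau = NA_real_, beta = NA_real_, rmse = NA_real_,
      n_points = length(t), converged = FALSE,
      flags = paste("fit failed:", conditionMessage(fit))),
      class = "stretched_exp_fit"))
  }
  cf <- coef(fit)
  res <- y - stretched_exp(t, cf[["g"]], cf[["tau"]], cf[["beta"]])
  structure(list(
    g = cf[["g"]], tau = cf[["tau"]], beta = cf[["beta"]],
    rmse = sqrt(mean(res^2)), n_points = length(t), converged = TRUE,
    flags = character(0)),
    class = "stretched_exp_fit")
}

#' @export
print.stretched_exp_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<stretched_exp_fit> g = %.3f, tau = %.2f s, beta = %.3f (rmse %.4f, n = %d)\n",
      x$g, x$tau, x$beta, x$rmse, x$n_points))
  else
    cat("<stretched_exp_fit> not converged:", x$flags, "\n")
  invisible(x)
}

#' Per-trial (adhesion frequency, lifetime) points
#'
#' Assembles the table on which the universal curve is fit: one row per
#' trial with its measured adhesion frequency and fitted population
#' lifetime.
#'
#' @param adhesion_frequency Adhesion frequencies in `[0, 1]`.
#' @param tau Fitted population lifetimes (s), > 0.
#' @param condition Optional condition labels.
#' @param n_cells Optional cells observed per trial.
#' @return A data.frame of class `trial_points`.
#' @export
trial_points <- function(adhesion_frequency, tau, condition = NA_character_,
                         n_cells = NA_integer_) {
  if (any(adhesion_frequency < 0 | adhesion_frequency > 1))
    stop("adhesion_frequency must lie in [0, 1]", call. = FALSE)
  if (any(tau <= 0, na.rm = TRUE)) stop("tau must be > 0", call. = FALSE)
  structure(data.frame(adhesion_frequency = adhesion_frequency, tau = tau,
                       condition = condition, n_cells = n_cells),
            class = c("trial_points", "data.frame"))
}

# RMSE of points to the parametric curve (AF(lambda), tau(lambda)) measured
# as orthogonal distance in the plane (AF, tau / sd(tau)). This scaling is a
# local convention that makes the two axes comparable.
universal_rmse <- function(af, tau, k, x0, af_cap = 0.999) {
  s <- sd(tau)
  if (!is.finite(s) || s == 0) s <- 1
  d2 <- vapply(seq_along(af), function(i) {
    obj <- function(lam)
      (af_from_lambda(lam) - af[i])^2 + ((k * lam + x0 - tau[i]) / s)^2
    optimize(obj, c(0, lambda_from_af(af_cap, af_cap) + 2),
             tol = 1e-9)$objective
  }, numeric(1))
  sqrt(mean(d2))
}

#' Fit the Poisson universal curve across trials
#'
#' Each trial's adhesion frequency is mapped to its implied mean bond number
#' \eqn{\lambda_i = -\ln(1 - AF_i)} (exact inverse of the Poisson closure),
#' and \eqn{\tau_i = k\lambda_i + x_0} is then fit by ordinary least
#' squares — `k` measures per-bond strength (s of lifetime per unit
#' \eqn{\lambda}) and `x0` the lifetime offset as AF approaches 0.
#' An orthogonal-distance variant in the (AF, tau) plane is available via
#' `method = "orthogonal"` for sensitivity analysis. RMSE is reported as the
#' orthogonal distance to the parametric curve in the (AF, tau / sd(tau))
#' plane in both cases.
#'
#' @param points A [trial_points()] data.frame (or any data.frame with
#'   `adhesion_frequency` and `tau`); >= 5 trials spanning a nontrivial AF
#'   range.
#' @param method `"ols"` (default) or `"orthogonal"`.
#' @param weight_by_cells If `TRUE`, OLS weights trials by `n_cells`;
#'   default `FALSE` (each trial counts once).
#' @param af_cap Passed to [lambda_from_af()].
#' @return An object of class `universal_curve_fit`: list with `k`, `x0`,
#'   `rmse`, `n_trials`, `method`, `flags`.
#' @export
fit_universal_curve <- function(points, method = c("ols", "orthogonal"),
                                weight_by_cells = FALSE, af_cap = 0.999) {
  method <- match.arg(method)
  af <- points$adhesion_frequency
  tau <- points$tau
  keep <- is.finite(af) & is.finite(tau)
  af <- af[keep]; tau <- tau[keep]
  if (length(af) < 5)
    stop("need at least 5 trials with finite AF and tau", call. = FALSE)
  if (diff(range(af)) < 1e-6)
    stop("all adhesion frequencies identical: lambda not identifiable",
         call. = FALSE)
  flags <- character(0)
  if (any(af >= af_cap))
    flags <- c(flags, sprintf("%d trial(s) at AF >= %g capped before inversion",
                              sum(af >= af_cap), af_cap))
  lam <- lambda_from_af(af, af_cap)
  w <- if (weight_by_cells && !is.null(points$n_cells) &&
           all(is.finite(points$n_cells[keep])))
    points$n_cells[keep] else rep(1, length(af))
  ols <- lm(tau ~ lam, weights = w)
  k <- unname(coef(ols)[2]); x0 <- unname(coef(ols)[1])
  if (method == "orthogonal") {
    s <- sd(tau); if (!is.finite(s) || s == 0) s <- 1
    obj <- function(p) {
      d2 <- vapply(seq_along(af), function(i) {
        f <- function(l) (af_from_lambda(l) - af[i])^2 +
          ((p[1] * l + p[2] - tau[i]) / s)^2
        optimize(f, c(0, lambda_from_af(af_cap, af_cap) + 2))$objective
      }, numeric(1))
      sum(w * d2)
    }
    opt <- stats::optim(c(k, x0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    k <- opt$par[1]; x0 <- opt$par[2]
  }
  structure(list(k = k, x0 = x0,
                 rmse = universal_rmse(af, tau, k, x0, af_cap),
                 n_trials = length(af), method = method, flags = flags),
            class = "universal_curve_fit")
}

#' @export
print.universal_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<universal_curve_fit> k = %.2f s/bond, x0 = %.2f s (rmse %.3f, %d trials, %s)\n",
    x$k, x$x0, x$rmse, x$n_trials, x$method))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Off-rate versus force from a detachment curve
#'
#' Bins the force axis and, per bin, estimates the population off-rate as
#' the number of cells that detached in the bin divided by the number of
#' cells available at the bin start and by the bin's duration:
#' \eqn{k_{off} = \Delta N_{det} / (N_{avail} \, \Delta t)}. Bins in which
#' fewer than `n_floor` cells remain available are masked (rate `NA`), as
#' the estimate there is dominated by counting noise.
#'
#' @param curve A [build_detachment_curve()] object (origin at centrifuge
#'   start).
#' @param force A [force_trace()] sampled on the same clock as `curve`
#'   (times in seconds since centrifuge start); force must be
#'   non-decreasing.
#' @param bin_width Force bin width in pN (default 20).
#' @param n_floor Minimum available cells for a bin to be reported
#'   (default 5).
#' @return A data.frame of class `off_rate_series` with columns
#'   `force_pN` (bin centers), `off_rate_per_s`, `n_detached`,
#'   `n_available`, `dt_s`.
#' @export
off_rate_vs_force <- function(curve, force, bin_width = 20, n_floor = 5) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  tspan <- range(curve$time_s)
  fspan <- range(force$time_s)
  if (fspan[1] > tspan[1] + 1e-9 || fspan[2] < tspan[2] - 1e-9)
    stop("force trace does not cover the curve's time span: align the time bases",
         call. = FALSE)
  if (any(diff(force$force_pN) < -1e-9))
    stop("force must be non-decreasing for force binning", call. = FALSE)
  n0 <- attr(curve, "normalization_count")
  if (is.null(n0)) n0 <- 1
  # count remaining vs time on the curve's own samples
  n_t <- curve$fraction_bound * n0
  f_t <- approx(force$time_s, force$force_pN, xout = curve$time_s,
                method = "constant", rule = 2)$y
  edges <- seq(floor(min(f_t) / bin_width) * bin_width,
               ceiling(max(f_t) / bin_width) * bin_width, by = bin_width)
  if (length(edges) < 2) edges <- c(edges, edges + bin_width)
  res <- lapply(seq_len(length(edges) - 1), function(k) {
    lo <- edges[k]; hi <- edges[k + 1]
    idx <- which(f_t >= lo & f_t < hi)
    if (length(idx) < 2) return(NULL)
    i0 <- idx[1]; i1 <- idx[length(idx)]
    dt <- curve$time_s[i1] - curve$time_s[i0]
    if (dt <= 0) return(NULL)
    n_avail <- n_t[i0]
    n_det <- max(n_t[i0] - n_t[i1], 0)
    rate <- if (n_avail >= n_floor) n_det / (n_avail * dt) else NA_real_
    data.frame(force_pN = (lo + hi) / 2, off_rate_per_s = rate,
               n_detached = n_det, n_available = n_avail, dt_s = dt)
  })
  out <- do.call(rbind, res)
  structure(out, class = c("off_rate_series", "data.frame"))
}
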