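#' Ex-Gaussian parameter set
#'
#' Parameters of the exponentially modified Gaussian used to model
#' non-decision time: a Gaussian component (mean `mu`, sd `sigma_g`) convolved
#' with an exponential of mean `tau_e`.
#'
#' @param mu Gaussian mean (ms).
#' @param sigma_g Gaussian standard deviation (ms), > 0.
#' @param tau_e Exponential mean (ms), >= 0.
#' @return An `exgauss_params` list.
#' @export
exgauss_params <- function(mu, sigma_g, tau_e) {
  if (!is.finite(mu) || !is.finite(sigma_g) || !is.finite(tau_e) ||
      sigma_g <= 0 || tau_e < 0)
    stop("invalid ex-Gaussian parameters: need sigma_g > 0, tau_e >= 0")
  structure(list(mu = mu, sigma_g = sigma_g, tau_e = tau_e),
            class = "exgauss_params")
}

#' Ex-Gaussian density and sampler
#'
#' Density of the sum of a Gaussian(`mu`, `sigma_g`) and an independent
#' Exponential(mean `tau_e`) variable, evaluated with log-space stabilization.
#' For `tau_e` negligible relative to `sigma_g` the density reduces to the
#' Gaussian limit.
#'
#' @param x Evaluation points (ms).
#' @param params An [exgauss_params()] object.
#' @return `exgauss_density`: densities; `exgauss_sample`: `n` samples.
#' @export
exgauss_density <- function(x, params) {
  mu <- params$mu; s <- params$sigma_g; tau <- params$tau_e
  if (tau < 1e-4 * s)
    return(stats::dnorm(x, mu + tau, sqrt(s^2 + tau^2)))
  lf <- -log(tau) + s^2 / (2 * tau^2) - (x - mu) / tau +
    stats::pnorm((x - mu) / s - s / tau, log.p = TRUE)
  exp(lf)
}

#' @rdname exgauss_density
#' @param n Number of samples.
#' @export
exgauss_sample <- function(params, n) {
  g <- stats::rnorm(n, params$mu, params$sigma_g)
  if (params$tau_e > 0) g <- g + stats::rexp(n, rate = 1 / params$tau_e)
  g
}

#' Ex-Gaussian cumulative distribution
#'
#' @rdname exgauss_density
#' @export
exgauss_cdf <- function(x, params) {
  mu <- params$mu; s <- params$sigma_g; tau <- params$tau_e
  if (tau < 1e-4 * s)
    return(stats::pnorm(x, mu + tau, sqrt(s^2 + tau^2)))
  u <- (x - mu) / s
  lterm <- -log(1) + s^2 / (2 * tau^2) - (x - mu) / tau +
    stats::pnorm(u - s / tau, log.p = TRUE)
  stats::pnorm(u) - exp(lterm)
}

#' Maximum-likelihood ex-Gaussian fit
#'
#' Fits (`mu`, `sigma_g`, `tau_e`) by maximizing the log-likelihood, starting
#' from moment estimates (the exponential component carries all the skew).
#'
#' @param x Samples (ms).
#' @return An `exgauss_params` object with attributes `loglik` and
#'   `convergence` (0 = converged).
#' @export
fit_exgauss <- function(x) {
  stopifnot(length(x) >= 10)
  m <- mean(x); sdev <- stats::sd(x)
  sk <- mean((x - m)^3) / sdev^3
  tau0 <- sdev * (max(sk, 0.01) / 2)^(1 / 3)
  sig0 <- sqrt(max(sdev^2 - tau0^2, (0.1 * sdev)^2))
  mu0 <- m - tau0
  nll <- function(p) {
    pars <- list(mu = p[1], sigma_g = exp(p[2]), tau_e = exp(p[3]))
    class(pars) <- "exgauss_params"
    -sum(log(pmax(exgauss_density(x, pars), 1e-300)))
  }
  opt <- stats::optim(c(mu0, log(sig0), log(tau0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  out <- exgauss_params(opt$par[1], exp(opt$par[2]), exp(opt$par[3]))
  attr(out, "loglik") <- -opt$value
  attr(out, "convergence") <- opt$convergence
  out
}

#' Estimate the non-decision-time distribution by deconvolution
#'
#' Exploits the near-Gaussianity of the model's decision times: the observed
#' response time is RT = DT + NDT with DT approximately Gaussian and NDT
#' ex-Gaussian, so RT is itself ex-Gaussian. The RT sample is fitted by
#' maximum likelihood and the Gaussian moments of the decision-time sample are
#' subtracted: `mu = mu_RT - mean(DT)`,
#' `sigma_g = sqrt(max(sigma_RT^2 - var(DT), eps))`, `tau_e = tau_RT`.
#'
#' @param rt_samples Observed response times (ms).
#' @param decision_time_samples Simulated decision times (ms), assumed
#'   independent of NDT.
#' @return An `exgauss_params` object with attributes `truncated` (`TRUE` when
#'   the variance subtraction hit its floor) and `negative_support` (`TRUE`
#'   when P(NDT < 0) >= 0.01 at the fitted parameters).
#' @export
deconvolve_ndt <- function(rt_samples, decision_time_samples) {
  stopifnot(length(rt_samples) >= 200, length(decision_time_samples) >= 200)
  fit <- fit_exgauss(rt_samples)
  v_dt <- stats::var(decision_time_samples)
  v_g <- fit$sigma_g^2 - v_dt
  truncated <- v_g <= 0
  eps <- (1e-3 * fit$sigma_g)^2
  out <- exgauss_params(mu = fit$mu - mean(decision_time_samples),
                        sigma_g = sqrt(max(v_g, eps)),
                        tau_e = fit$tau_e)
  attr(out, "truncated") <- truncated
  attr(out, "negative_support") <- exgauss_cdf(0, out) >= 0.01
  out
}

#' Reconstruct the response-time density
#'
#' Numerical convolution of the decision-time density (Gaussian with the
#' sample moments of the simulated decision times) with a fitted ex-Gaussian
#' non-decision-time density, on a user grid.
#'
#' @param decision_time_samples Simulated decision times (ms).
#' @param ndt An [exgauss_params()] object.
#' @param grid Equally spaced evaluation grid (ms) covering the RT support.
#' @return Data frame `t` (the grid) and `density`; the density integrates to
#'   1 up to grid truncation.
#' @export
reconstruct_rt_density <- function(decision_time_samples, ndt, grid) {
  h <- diff(grid[1:2])
  stopifnot(all(abs(diff(grid) - h) < 1e-9))
  m_dt <- mean(decision_time_samples)
  s_dt <- stats::sd(decision_time_samples)
  # support grid for the NDT factor, wide enough for the exponential tail and
  # fine enough to resolve a near-point-mass Gaussian component
  u_lo <- ndt$mu - 6 * ndt$sigma_g
  u_hi <- ndt$mu + 6 * ndt$sigma_g + 12 * max(ndt$tau_e, ndt$sigma_g)
  du <- min(h, ndt$sigma_g / 4, if (ndt$tau_e > 0) ndt$tau_e / 4 else h)
  u <- seq(u_lo, u_hi, by = du)
  fu <- exgauss_density(u, ndt)
  fu <- fu / (sum(fu) * du) # renormalize the truncated factor
  dens <- vapply(grid, function(t)
    sum(fu * stats::dnorm(t - u, m_dt, s_dt)) * du, numeric(1))
  data.frame(t = grid, density = dens)
}
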