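#' Network parameters for the reduced two-pool attractor model
#'
#' Constructs and validates the full parameter set of the reduced two-variable
#' attractor network used to simulate sequences of two-alternative decisions.
#' Defaults are the published constants of the reduced mean-field model
#' (input-output gain `a`, offset `b`, curvature `d`, rate-to-gating factor
#' `gamma`, synaptic time constant `tau_S`, noise parameters, background
#' current `I0`, stimulus and recurrent couplings) together with the shared
#' corollary-discharge parameters. The decision threshold `z` and the
#' stimulus-strength coefficients `alpha1`, `alpha2` (so that
#' `c_theta = alpha1 * |theta| + alpha2 * theta^2`) are participant-specific
#' free parameters and default to a representative calibrated regime.
#'
#' @param a Input-output gain (Hz/nA).
#' @param b Input-output offset (Hz).
#' @param d Input-output curvature (s).
#' @param gamma Rate-to-gating conversion factor (dimensionless).
#' @param tau_S Synaptic gating time constant (ms).
#' @param sigma_noise Noise current amplitude (nA).
#' @param tau_noise Noise filter time constant (ms).
#' @param I0 Mean background current (nA).
#' @param J_ext Stimulus coupling (nA).
#' @param J_self Self-excitation coupling (nA).
#' @param J_cross Mutual-inhibition coupling (nA).
#' @param z Decision threshold on the firing rate (Hz).
#' @param I_CD_max Corollary-discharge peak amplitude (nA).
#' @param tau_CD Corollary-discharge decay time constant (ms).
#' @param alpha1 Linear coefficient of the stimulus strength (per degree).
#' @param alpha2 Quadratic coefficient of the stimulus strength (per degree^2).
#' @param dt Integration step (ms).
#' @param t_max Decision deadline (ms); trials with no threshold crossing by
#'   `t_max` are timeouts.
#' @param exact_ou Logical; if `TRUE` (default) the noise current uses the
#'   exact Ornstein-Uhlenbeck update, whose stationary standard deviation
#'   `sigma_noise / sqrt(2)` is independent of `dt`, so simulations at
#'   different integration steps see identical noise statistics. `FALSE`
#'   selects the plain Euler-Maruyama noise update (stationary sd
#'   `sigma_noise / sqrt(2 - dt/tau_noise)`).
#'
#' @return An object of class `network_params` (a named list).
#' @export
#' @examples
#' p <- network_params()
#' transfer_rate(0.4, p)
network_params <- function(a = 270, b = 108, d = 0.154, gamma = 0.641,
                           tau_S = 100, sigma_noise = 0.02, tau_noise = 2,
                           I0 = 0.3255, J_ext = 0.0182, J_self = 0.2609,
                           J_cross = 0.0497, z = 15, I_CD_max = 0.033,
                           tau_CD = 150, alpha1 = 0.1, alpha2 = 0,
                           dt = 0.5, t_max = 1500, exact_ou = TRUE) {
  p <- list(a = a, b = b, d = d, gamma = gamma, tau_S = tau_S,
            sigma_noise = sigma_noise, tau_noise = tau_noise, I0 = I0,
            J_ext = J_ext, J_self = J_self, J_cross = J_cross, z = z,
            I_CD_max = I_CD_max, tau_CD = tau_CD, alpha1 = alpha1,
            alpha2 = alpha2, dt = dt, t_max = t_max, exact_ou = exact_ou)
  class(p) <- "network_params"
  validate_network_params(p)
  p
}

#' Validate attractor-network parameters
#'
#' Checks positivity of time constants, non-negativity of couplings, the
#' integration-step constraint `dt < min(tau_S, tau_noise)` and that the
#' stimulus strength stays in `[0, 1]` over the protocol orientations.
#'
#' @param p A `network_params` object.
#' @param orientations Orientation magnitudes (degrees) at which the stimulus
#'   strength must lie in `[0, 1]`.
#' @return `p`, invisibly; errors if any invariant is violated.
#' @export
validate_network_params <- function(p, orientations = c(0.2, 0.5, 0.8, 1.6)) {
  stopifnot(inherits(p, "network_params") || is.list(p))
  num <- vapply(p[setdiff(names(p), "exact_ou")], is.numeric, logical(1))
  if (!all(num)) stop("all network parameters except 'exact_ou' must be numeric")
  with(p, {
    if (any(c(tau_S, tau_noise, tau_CD, dt, t_max) <= 0))
      stop("time constants, dt and t_max must be positive")
    if (dt >= min(tau_S, tau_noise))
      stop("dt must be smaller than min(tau_S, tau_noise)")
    if (any(c(J_self, J_cross, J_ext, I_CD_max) < 0))
      stop("couplings and I_CD_max must be non-negative")
    if (z <= 0) stop("decision threshold z must be positive")
    if (sigma_noise < 0) stop("sigma_noise must be non-negative")
  })
  cth <- stim_strength(orientations, p)
  if (any(cth < 0 | cth > 1))
    stop("c_theta outside [0, 1] at protocol orientations")
  invisible(p)
}

#' Stimulus strength as a function of orientation
#'
#' Maps an orientation magnitude (degrees) onto the dimensionless stimulus
#' strength `c_theta = alpha1 * |theta| + alpha2 * theta^2`.
#'
#' @param theta Orientation in degrees (signed or absolute; the magnitude is
#'   used).
#' @param p A `network_params` object (fields `alpha1`, `alpha2`).
#' @return Numeric vector of strengths.
#' @export
stim_strength <- function(theta, p) {
  p$alpha1 * abs(theta) + p$alpha2 * theta^2
}

#' @export
print.network_params <- function(x, ...) {
  cat("Two-pool attractor network parameters\n")
  flat <- unlist(x[setdiff(names(x), "exact_ou")])
  print(flat)
  cat("exact_ou:", x$exact_ou, "\n")
  invisible(x)
}

#' Read and write a network configuration file
#'
#' The configuration is a flat key-value text file (YAML) whose keys mirror
#' the model parameter names (`a`, `b`, `d`, `gamma`, `tau_S`, `sigma_noise`,
#' `tau_noise`, `I0`, `J_ext`, `J_self`, `J_cross`, `z`, `I_CD_max`,
#' `tau_CD`, `alpha1`, `alpha2`, `dt`, `t_max`).
#'
#' @param path File path.
#' @return `read_network_config` returns a `network_params` object;
#'   `write_network_config` returns `path` invisibly.
#' @export
read_network_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(network_params, vals)
}

#' @rdname read_network_config
#' @param p A `network_params` object to serialize.
#' @export
write_network_config <- function(p, path) {
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}
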