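#' Effective single-cell input-output relation
#'
#' Firing rate of a pool as a function of its total input current,
#' `f(I) = (a I - b) / (1 - exp(-d (a I - b)))`, with the removable
#' singularity at `a I = b` evaluated as its limit `1/d`. The function is
#' continuous, non-negative and strictly increasing.
#'
#' @param I_tot Total input current (nA); vectorized.
#' @param params A [network_params()] object.
#' @return Firing rate(s) in Hz.
#' @export
#' @examples
#' transfer_rate(0.4, network_params()) # = 1/d at a*I = b
transfer_rate <- function(I_tot, params) {
  if (any(!is.finite(I_tot))) stop("input current must be finite")
  x <- params$a * I_tot - params$b
  dx <- params$d * x
  out <- ifelse(abs(dx) < 1e-8, 1 / params$d + x / 2, x / (1 - exp(-dx)))
  pmax(out, 0)
}

#' Stimulus-selective input currents
#'
#' The pool favored by the stimulus receives `J_ext * (1 + c)` and the other
#' pool `J_ext * (1 - c)`, so the summed drive is `2 * J_ext` independent of
#' the stimulus strength.
#'
#' @param c_theta Stimulus strength in `[0, 1]`.
#' @param favored `"C"` or `"AC"`, the category the stimulus supports.
#' @param J_ext Stimulus coupling (nA).
#' @return Named numeric vector `c(C = ..., AC = ...)` in nA.
#' @export
stimulus_current <- function(c_theta, favored = c("C", "AC"), J_ext = 0.182) {
  favored <- match.arg(favored)
  if (!is.finite(c_theta) || c_theta < 0 || c_theta > 1)
    stop("c_theta must lie in [0, 1]")
  if (favored == "C")
    c(C = J_ext * (1 + c_theta), AC = J_ext * (1 - c_theta))
  else
    c(C = J_ext * (1 - c_theta), AC = J_ext * (1 + c_theta))
}

#' Corollary-discharge current
#'
#' Non-specific inhibitory current injected into both pools after a decision:
#' zero before the decision (and during stimulus presentation), and
#' `-I_CD_max * exp(-(t - t_D) / tau_CD)` from the decision time `t_D` until
#' the next stimulus onset.
#'
#' @param t Time (ms), vectorized.
#' @param t_D Decision time (ms) on the same clock as `t`.
#' @param params A [network_params()] object.
#' @return Current(s) in nA (non-positive).
#' @export
corollary_discharge <- function(t, t_D, params) {
  ifelse(t < t_D, 0, -params$I_CD_max * exp(-(t - t_D) / params$tau_CD))
}

#' Create a network state
#'
#' @param S_C,S_AC Synaptic gating variables in `[0, 1]`.
#' @param I_noise_C,I_noise_AC Filtered noise currents (nA).
#' @param t Elapsed time (ms).
#' @return A `network_state` list.
#' @export
network_state <- function(S_C = 0, S_AC = 0, I_noise_C = 0.3255,
                          I_noise_AC = 0.3255, t = 0) {
  stopifnot(S_C >= 0, S_C <= 1, S_AC >= 0, S_AC <= 1)
  structure(list(S_C = S_C, S_AC = S_AC, I_noise_C = I_noise_C,
                 I_noise_AC = I_noise_AC, t = t),
            class = "network_state")
}

#' Advance the network state by one integration step
#'
#' Reference (R-level) Euler-Maruyama step of the gating equations and of the
#' Ornstein-Uhlenbeck noise currents. The gating variables are clamped to
#' `[0, 1]` after the step; discretization can overshoot the interval that the
#' continuous-time dynamics preserves. The compiled session simulator performs
#' the identical update.
#'
#' @param state A [network_state()].
#' @param I_stim Named currents `c(C=, AC=)` in nA (0 outside stimulation).
#' @param params A [network_params()] object.
#' @param eta Pair of standard-normal noise draws for the two pools; `c(0, 0)`
#'   gives the noiseless update of the noise currents.
#' @param I_CD Corollary-discharge current (nA) at this instant.
#' @return A list with the advanced `state` and the firing rates `r` (Hz,
#'   named `C`/`AC`) evaluated at the pre-step currents.
#' @export
step_state <- function(state, I_stim = c(C = 0, AC = 0), params,
                       eta = c(0, 0), I_CD = 0) {
  I_C <- params$J_self * state$S_C - params$J_cross * state$S_AC +
    I_stim[["C"]] + state$I_noise_C + I_CD
  I_AC <- params$J_self * state$S_AC - params$J_cross * state$S_C +
    I_stim[["AC"]] + state$I_noise_AC + I_CD
  r <- transfer_rate(c(I_C, I_AC), params)
  dt_s <- params$dt / 1000
  tau_s <- params$tau_S / 1000
  S_C <- state$S_C + dt_s * (-state$S_C / tau_s + (1 - state$S_C) * params$gamma * r[1])
  S_AC <- state$S_AC + dt_s * (-state$S_AC / tau_s + (1 - state$S_AC) * params$gamma * r[2])
  if (isTRUE(params$exact_ou)) {
    dec <- exp(-params$dt / params$tau_noise)
    sd_ou <- params$sigma_noise * sqrt((1 - dec^2) / 2)
  } else {
    dec <- 1 - params$dt / params$tau_noise
    sd_ou <- params$sigma_noise * sqrt(params$dt / params$tau_noise)
  }
  In_C <- params$I0 + (state$I_noise_C - params$I0) * dec + sd_ou * eta[1]
  In_AC <- params$I0 + (state$I_noise_AC - params$I0) * dec + sd_ou * eta[2]
  new_state <- network_state(min(max(S_C, 0), 1), min(max(S_AC, 0), 1),
                             In_C, In_AC, state$t + params$dt)
  list(state = new_state, r = c(C = r[1], AC = r[2]))
}

#' Simulate a single decision trial (reference implementation)
#'
#' Integrates the network from a starting state under a stimulus applied from
#' onset until the first firing rate crosses the decision threshold `z`, then
#' applies the corollary-discharge relaxation up to the next stimulus onset.
#' This R-level implementation mirrors the compiled session simulator and is
#' intended for inspection, traces and cross-checks; bulk simulation goes
#' through [run_session()].
#'
#' @param state0 Starting [network_state()] at stimulus onset; `NULL` settles
#'   from `S = (0, 0)` under background input for 1000 ms first.
#' @param theta Signed orientation (degrees); `theta > 0` is category `C`.
#' @param params A [network_params()] object.
#' @param gap_ms Interval from the decision to the next stimulus onset (ms).
#' @param trace If `TRUE`, attach a data frame with columns `time_ms`, `S_C`,
#'   `S_AC`, `r_C`, `r_AC`, `I_CD`, `phase` (`pre`/`stim`/`post`).
#' @param c_theta Optional explicit stimulus strength overriding
#'   `stim_strength(theta, params)`.
#' @return A `trial_outcome` list: `choice` (`"C"`, `"AC"` or `"timeout"`),
#'   `decision_time` (ms from onset), `delta_r` (Hz), `correct`, `end_state`
#'   (state at the next onset), and optionally `trace`.
#' @export
run_trial <- function(state0 = NULL, theta, params, gap_ms = 500,
                      trace = FALSE, c_theta = NULL) {
  if (is.null(c_theta)) c_theta <- stim_strength(theta, params)
  favored <- if (theta > 0) "C" else "AC"
  I_stim <- stimulus_current(c_theta, favored, params$J_ext)
  if (is.null(state0)) {
    state0 <- network_state(0, 0, params$I0, params$I0, 0)
    for (k in seq_len(floor(1000 / params$dt)))
      state0 <- step_state(state0, c(C = 0, AC = 0), params,
                           eta = stats::rnorm(2))$state
    state0$t <- 0
  }
  state <- state0
  onset <- state$t
  tr <- list()
  choice <- "timeout"; t_D <- NA_real_; dr <- NA_real_
  n_max <- floor(params$t_max / params$dt)
  for (k in seq_len(n_max)) {
    st <- step_state(state, I_stim, params, eta = stats::rnorm(2))
    state <- st$state
    if (trace) tr[[length(tr) + 1]] <- c(state$t, state$S_C, state$S_AC,
                                         st$r[1], st$r[2], 0, 1)
    if (max(st$r) >= params$z) {
      if (st$r[1] > st$r[2]) choice <- "C"
      else if (st$r[2] > st$r[1]) choice <- "AC"
      else choice <- sample(c("C", "AC"), 1)
      t_D <- state$t - onset
      dr <- abs(st$r[1] - st$r[2])
      break
    }
  }
  if (choice == "timeout") {
    t_D <- params$t_max
    st_last <- step_state(state, I_stim, params, eta = c(0, 0))
    dr <- abs(st_last$r[1] - st_last$r[2])
  }
  t_dec_abs <- state$t
  for (k in seq_len(floor(gap_ms / params$dt))) {
    icd <- corollary_discharge(state$t, t_dec_abs, params)
    st <- step_state(state, c(C = 0, AC = 0), params,
                     eta = stats::rnorm(2), I_CD = icd)
    state <- st$state
    if (trace) tr[[length(tr) + 1]] <- c(state$t, state$S_C, state$S_AC,
                                         st$r[1], st$r[2], icd, 2)
  }
  out <- list(choice = choice, decision_time = t_D, delta_r = dr,
              correct = identical(choice, favored), end_state = state)
  if (trace) {
    m <- do.call(rbind, tr)
    trd <- data.frame(time_ms = m[, 1], S_C = m[, 2], S_AC = m[, 3],
                      r_C = m[, 4], r_AC = m[, 5], I_CD = m[, 6],
                      phase = c("pre", "stim", "post")[m[, 7] + 1])
    out$trace <- trd
  }
  class(out) <- "trial_outcome"
  out
}

#' Simulate a session: a sequence of trials with state carry-over
#'
#' Runs the compiled simulator over a stimulus schedule. The network settles
#' from `S = (0, 0)` under background input for `pre_ms` before the first
#' stimulus; between trials the corollary discharge and the noise currents
#' stay active, and relaxation is generally incomplete at the next onset,
#' which is what produces sequential effects.
#'
#' @param params A [network_params()] object.
#' @param schedule Data frame with one row per trial: column `theta` (signed
#'   orientation, degrees) and column `gap_ms` (interval from the decision to
#'   the next stimulus onset, ms). An optional column `c_signed` overrides the
#'   strength computed from `theta`.
#' @param seed Integer seed for the simulator's random stream; if `NULL`, one
#'   is drawn from R's RNG (so `set.seed()` makes the session reproducible).
#' @param pre_ms Settling time before the first stimulus (ms).
#' @return A data frame with one row per trial: `theta`, `choice` (`"C"`,
#'   `"AC"`, `"timeout"`), `correct`, `decision_time` (ms), `delta_r` (Hz),
#'   and the gating variables at stimulus onset, at decision and at the next
#'   onset (`S_C_onset`, ..., `S_AC_next`).
#' @export
run_session <- function(params, schedule, seed = NULL, pre_ms = 1000) {
  stopifnot(is.data.frame(schedule), "theta" %in% names(schedule) ||
              "c_signed" %in% names(schedule), "gap_ms" %in% names(schedule))
  if (any(schedule$gap_ms < 0)) stop("schedule error: negative inter-trial gap")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  if (!is.null(schedule$c_signed)) {
    c_signed <- schedule$c_signed
  } else {
    c_signed <- sign(schedule$theta) * stim_strength(schedule$theta, params)
  }
  if (any(abs(c_signed) > 1)) stop("stimulus strength outside [-1, 1]")
  res <- .cpp_simulate_session(unclass(params), as.numeric(c_signed),
                               as.numeric(schedule$gap_ms), pre_ms,
                               as.numeric(seed))
  theta <- if (!is.null(schedule$theta)) schedule$theta else sign(c_signed)
  ch <- c("AC", "timeout", "C")[res$choice + 2]
  out <- data.frame(theta = theta, choice = ch,
                    correct = (res$choice == sign(c_signed)) & res$choice != 0,
                    res[, setdiff(names(res), "choice")])
  attr(out, "seed") <- seed
  out
}

#' Simulate independent batches of trials at given stimulus strengths
#'
#' Convenience wrapper around [run_session()]: `n` trials per strength, with
#' the favored category randomized, using the standard inter-trial gap.
#'
#' @param params A [network_params()] object.
#' @param c_theta Vector of stimulus strengths in `[0, 1]`.
#' @param n Trials per strength.
#' @param gap_ms Decision-to-onset gap (ms).
#' @param seed Integer seed (see [run_session()]).
#' @return Data frame of outcomes with a `c_theta` column.
#' @export
simulate_trials <- function(params, c_theta, n, gap_ms = 500, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  out <- lapply(seq_along(c_theta), function(i) {
    sgn <- rep(c(1, -1), length.out = n)[sample.int(n)]
    sched <- data.frame(theta = sgn, c_signed = sgn * c_theta[i],
                        gap_ms = gap_ms)
    r <- run_session(params, sched, seed = seed + i - 1)
    r$c_theta <- c_theta[i]
    r
  })
  do.call(rbind, out)
}

#' Noiseless mean-field trajectory
#'
#' Integrates the deterministic flow (noise currents pinned at their mean
#' `I0`) from a starting point, e.g. for phase-plane plots and basin
#' classification, "as if there were no decision threshold".
#'
#' @param S0 Length-2 vector `(S_C, S_AC)` at the start.
#' @param c_signed Signed stimulus strength (`0` for background-only flow;
#'   positive favors `C`).
#' @param duration_ms Duration (ms).
#' @param params A [network_params()] object.
#' @param stimulus If `FALSE`, no stimulus current at all (inter-trial flow);
#'   if `TRUE`, `J_ext (1 +/- c)` is applied to the two pools.
#' @return Data frame `time_ms`, `S_C`, `S_AC`, `r_C`, `r_AC` sampled at `dt`.
#' @export
noiseless_flow <- function(S0, c_signed = 0, duration_ms = 1000, params,
                           stimulus = c_signed != 0) {
  if (stimulus) {
    I_C <- params$J_ext * (1 + c_signed)
    I_AC <- params$J_ext * (1 - c_signed)
  } else {
    I_C <- 0; I_AC <- 0
  }
  m <- .cpp_noiseless_flow(unclass(params), S0[1], S0[2], I_C, I_AC,
                           duration_ms)
  as.data.frame(m)
}

#' Classify the basin of attraction of a state
#'
#' Runs the noiseless flow from `S0` for `t_settle` ms and classifies the
#' endpoint by the sign of `S_C - S_AC`. Under background-only input the flow
#' has three attractors - the two decision states and the symmetric
#' low-activity state - so a state can legitimately settle on the diagonal;
#' under a stimulus the symmetric branch is confined to the exact diagonal
#' and generic states end in `"C"` or `"AC"`.
#'
#' @inheritParams noiseless_flow
#' @param t_settle Settling horizon (ms).
#' @param tol Symmetry tolerance on `S_C - S_AC` at the endpoint.
#' @return `"C"`, `"AC"` or `"symmetric"`.
#' @export
basin_of <- function(S0, c_signed = 0, params, t_settle = 3000, tol = 1e-4,
                     stimulus = c_signed != 0) {
  fl <- noiseless_flow(S0, c_signed, t_settle, params, stimulus = stimulus)
  dS <- fl$S_C[nrow(fl)] - fl$S_AC[nrow(fl)]
  if (dS > tol) "C" else if (dS < -tol) "AC" else "symmetric"
}

#' Locate the basin boundary along a segment by bisection
#'
#' @param S_a,S_b Endpoints (length-2 `(S_C, S_AC)`) lying in different basins.
#' @inheritParams basin_of
#' @param tol_bisect Termination tolerance on the segment parameter.
#' @return List with the boundary point `S`, the segment parameter `lambda`
#'   (`0` at `S_a`), and the basins of the two endpoints.
#' @export
basin_boundary <- function(S_a, S_b, c_signed = 0, params,
                           t_settle = 3000, tol_bisect = 1e-4,
                           stimulus = c_signed != 0) {
  ba <- basin_of(S_a, c_signed, params, t_settle, stimulus = stimulus)
  bb <- basin_of(S_b, c_signed, params, t_settle, stimulus = stimulus)
  if (ba == bb) stop("segment endpoints lie in the same basin")
  lo <- 0; hi <- 1
  while (hi - lo > tol_bisect) {
    mid <- (lo + hi) / 2
    Sm <- S_a + mid * (S_b - S_a)
    bm <- basin_of(Sm, c_signed, params, t_settle, stimulus = stimulus)
    if (bm == ba) lo <- mid else hi <- mid
  }
  lam <- (lo + hi) / 2
  list(S = S_a + lam * (S_b - S_a), lambda = lam,
       basin_a = ba, basin_b = bb)
}

#' Export a simulation trace to delimited text
#'
#' @param trace Trace data frame as produced by `run_trial(trace = TRUE)`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
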