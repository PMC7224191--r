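#' Parameters of the extended independent race model
#'
#' Two uncoupled accumulators race from 0 to a positive threshold; the first
#' to reach it gives the choice, and confidence is proxied by the balance of
#' evidence, the distance of the losing race to the threshold. Between trials
#' both activities relax exponentially toward baseline (time constant
#' `relax_tau`) with the diffusion noise still active; the default keeps the
#' relaxation visibly incomplete at protocol-length gaps, the regime in which
#' a race model makes a sequential prediction at all (a race that decays
#' fully to baseline before the next onset trivially predicts no sequential
#' effect). Accuracy and decision-time defaults were tuned on a coarse grid so
#' that accuracies and mean decision times across the protocol strengths match
#' the attractor model's defaults to within about 10%, making the sequential
#' contrasts of the two models comparable.
#'
#' @param I0_drift Base drift (units/ms); the favored race drifts at
#'   `I0_drift * (1 + c)`, the other at `I0_drift * (1 - c)`.
#' @param sigma Diffusion coefficient (units/sqrt(ms)).
#' @param z_thr Decision threshold (units).
#' @param relax_tau Inter-trial relaxation time constant (ms).
#' @param dt Integration step (ms).
#' @param t_max Decision deadline (ms).
#' @return An `irm_params` list.
#' @export
irm_params <- function(I0_drift = 0.0033, sigma = 0.008, z_thr = 1,
                       relax_tau = 500, dt = 0.5, t_max = 1500) {
  if (sigma <= 0 || z_thr <= 0 || relax_tau <= 0 || dt <= 0 || t_max <= 0)
    stop("sigma, z_thr, relax_tau, dt and t_max must be positive")
  structure(list(I0_drift = I0_drift, sigma = sigma, z_thr = z_thr,
                 relax_tau = relax_tau, dt = dt, t_max = t_max),
            class = "irm_params")
}

#' Simulate an IRM session
#'
#' Euler-Maruyama integration of the two races over a stimulus schedule, with
#' exponential relaxation (noise active) between trials. Activities start at 0
#' and carry over across trials.
#'
#' @param params An [irm_params()] object.
#' @param schedule Data frame with columns `c_signed` (signed strength;
#'   positive favors `C`) and `gap_ms` (decision-to-onset gap).
#' @param seed Integer seed (drawn from R's RNG when `NULL`).
#' @param collapse_rate Optional linear collapse of the threshold
#'   (units/ms); 0 keeps the bound constant. The bound is floored at 10% of
#'   `z_thr`.
#' @return Data frame per trial: `choice` (`"C"`/`"AC"`/`"timeout"`),
#'   `correct`, `decision_time` (ms), `balance` (units), activities at onset
#'   and at the next onset.
#' @export
run_irm_session <- function(params, schedule, seed = NULL,
                            collapse_rate = 0) {
  stopifnot(is.data.frame(schedule),
            all(c("c_signed", "gap_ms") %in% names(schedule)))
  if (collapse_rate < 0) stop("collapse schedule must be non-increasing")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  res <- .cpp_simulate_irm_session(unclass(params),
                                   as.numeric(schedule$c_signed),
                                   as.numeric(schedule$gap_ms),
                                   as.numeric(seed), collapse_rate)
  ch <- c("AC", "timeout", "C")[res$choice + 2]
  out <- data.frame(choice = ch,
                    correct = (res$choice == sign(schedule$c_signed)) &
                      res$choice != 0,
                    res[, setdiff(names(res), "choice")],
                    c_signed = schedule$c_signed)
  attr(out, "seed") <- seed
  out
}

#' Simulate a single race trial
#'
#' @param state0 Starting activities `(x_C, x_AC)` (below threshold).
#' @param c_signed Signed strength (positive favors `C`).
#' @param params An [irm_params()] object.
#' @param seed Integer seed.
#' @return A list: `choice`, `decision_time`, `balance`, `end` (activities at
#'   the decision; no relaxation applied).
#' @export
run_irm_trial <- function(state0 = c(0, 0), c_signed, params, seed = NULL) {
  if (any(state0 >= params$z_thr))
    stop("activities must be below threshold at onset")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  # a single-trial session with zero gap; shift the start by folding the
  # offset into the first step is unnecessary: the compiled core starts at 0,
  # so for nonzero starts integrate in R
  if (all(state0 == 0)) {
    r <- run_irm_session(params, data.frame(c_signed = c_signed, gap_ms = 0),
                         seed = seed)
    return(list(choice = r$choice, decision_time = r$decision_time,
                balance = r$balance, end = c(r$x_C_next, r$x_AC_next)))
  }
  set.seed(seed)
  x <- state0
  mu <- params$I0_drift * c(1 + c_signed, 1 - c_signed) * params$dt
  sq <- params$sigma * sqrt(params$dt)
  n_max <- floor(params$t_max / params$dt)
  for (k in seq_len(n_max)) {
    x <- x + mu + sq * stats::rnorm(2)
    if (any(x >= params$z_thr)) {
      w <- which.max(x)
      return(list(choice = c("C", "AC")[w],
                  decision_time = k * params$dt,
                  balance = abs(params$z_thr - x[-w][1]), end = x))
    }
  }
  list(choice = "timeout", decision_time = params$t_max,
       balance = abs(params$z_thr - min(x)), end = x)
}

#' Relax race activities between trials
#'
#' Exponential decay of both activities toward 0 with `relax_tau`, with the
#' diffusion noise active (set `noise = FALSE` for the deterministic decay).
#'
#' @param state Activities `(x_C, x_AC)` at the decision.
#' @param gap_ms Relaxation duration (ms).
#' @param params An [irm_params()] object.
#' @param noise Keep the diffusion noise on during relaxation?
#' @return Activities at the next onset.
#' @export
relax_between_trials <- function(state, gap_ms, params, noise = TRUE) {
  stopifnot(gap_ms >= 0)
  n <- floor(gap_ms / params$dt)
  if (n == 0) return(state)
  x <- state
  sq <- params$sigma * sqrt(params$dt)
  for (k in seq_len(n)) {
    eta <- if (noise) stats::rnorm(2) else c(0, 0)
    x <- x - x / params$relax_tau * params$dt + sq * eta
  }
  x
}

#' Post-confidence sequential contrast in the race model
#'
#' Simulates a session of trials at a single strength with randomized favored
#' category, median-splits the balance of evidence as the confidence proxy,
#' and contrasts post-low versus post-high confidence mean decision times in
#' the repeated and alternated bins, with bootstrap confidence intervals on
#' the signed differences. The race model predicts post-LOW-confidence
#' speeding in the alternated bin and no difference in the repeated bin —
#' the opposite pattern to the attractor network's.
#'
#' @param params An [irm_params()] object.
#' @param c_theta Stimulus strength used for every trial.
#' @param n Number of trials (>= 2000 recommended).
#' @param gap_ms Decision-to-onset gap (ms).
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples for the CI on each difference.
#' @param collapse_rate Optional collapsing-bound rate (units/ms).
#' @return Data frame per bin (`repeated`, `alternated`): mean decision time
#'   after low and high confidence, `diff` (`post_low - post_high`; negative
#'   means post-low speeding), bootstrap 95% CI, and counts.
#' @export
irm_sequential_contrast <- function(params, c_theta = 0.05, n = 4000,
                                    gap_ms = 700, seed = 1, n_boot = 500,
                                    collapse_rate = 0) {
  set.seed(seed)
  sgn <- sample(c(1, -1), n, replace = TRUE)
  sched <- data.frame(c_signed = sgn * c_theta, gap_ms = gap_ms)
  sim <- run_irm_session(params, sched, seed = seed,
                         collapse_rate = collapse_rate)
  contrast_from_session(decision_time = sim$decision_time,
                        conf_proxy = sim$balance,
                        choice = sim$choice,
                        favored = ifelse(sgn > 0, "C", "AC"),
                        n_boot = n_boot)
}

#' Post-confidence sequential contrast in the attractor network
#'
#' The attractor-side analogue of [irm_sequential_contrast()] on a matched
#' protocol: same single-strength randomized schedule, confidence proxied by
#' the median-split evidence balance `delta_r`.
#'
#' @param params A [network_params()] object.
#' @inheritParams irm_sequential_contrast
#' @return Same table as [irm_sequential_contrast()].
#' @export
attractor_sequential_contrast <- function(params, c_theta = 0.05, n = 4000,
                                          gap_ms = 700, seed = 1,
                                          n_boot = 500) {
  set.seed(seed)
  sgn <- sample(c(1, -1), n, replace = TRUE)
  sched <- data.frame(theta = sgn, c_signed = sgn * c_theta, gap_ms = gap_ms)
  sim <- run_session(params, sched, seed = seed)
  contrast_from_session(decision_time = sim$decision_time,
                        conf_proxy = sim$delta_r,
                        choice = sim$choice,
                        favored = ifelse(sgn > 0, "C", "AC"),
                        n_boot = n_boot)
}

# shared binning + bootstrap for the two models
contrast_from_session <- function(decision_time, conf_proxy, choice, favored,
                                  n_boot = 500) {
  n <- length(decision_time)
  prev <- seq_len(n - 1); cur <- prev + 1
  ok <- choice[prev] != "timeout" & choice[cur] != "timeout"
  hi <- conf_proxy[prev] > stats::median(conf_proxy[choice != "timeout"])
  repeated <- favored[cur] == choice[prev]
  dt <- decision_time[cur]
  out <- list()
  for (b in c("repeated", "alternated")) {
    sel <- ok & (repeated == (b == "repeated"))
    lo <- dt[sel & !hi]; hg <- dt[sel & hi]
    if (length(lo) < 10 || length(hg) < 10) next
    d0 <- mean(lo) - mean(hg)
    boot <- replicate(n_boot, mean(sample(lo, replace = TRUE)) -
                        mean(sample(hg, replace = TRUE)))
    ci <- stats::quantile(boot, c(0.025, 0.975))
    out[[b]] <- data.frame(bin = b, mean_post_low = mean(lo),
                           mean_post_high = mean(hg), diff = d0,
                           ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                           n_low = length(lo), n_high = length(hg))
  }
  do.call(rbind, out)
}

#' Joint model-discrimination report
#'
#' Runs the attractor and race contrasts on matched protocols and returns the
#' signed differences side by side; the two models predict opposite-signed
#' post-confidence effects.
#'
#' @param net_params A [network_params()] object.
#' @param race_params An [irm_params()] object.
#' @inheritParams irm_sequential_contrast
#' @return Data frame with one row per model x bin.
#' @export
compare_model_contrasts <- function(net_params, race_params, c_theta = 0.05,
                                    n = 4000, gap_ms = 700, seed = 1,
                                    n_boot = 500) {
  att <- attractor_sequential_contrast(net_params, c_theta, n, gap_ms, seed,
                                       n_boot)
  irm <- irm_sequential_contrast(race_params, c_theta, n, gap_ms, seed,
                                 n_boot)
  att$model <- "attractor"; irm$model <- "irm"
  rbind(att, irm)[, c("model", "bin", "mean_post_low", "mean_post_high",
                      "diff", "ci_low", "ci_high", "n_low", "n_high")]
}
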