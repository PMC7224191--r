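#' Summarize a block of trials per orientation magnitude
#'
#' Pools trials at orientations `+theta` and `-theta`, excluding timeouts and
#' motor mistakes, and computes the mean response time, accuracy and trial
#' count per magnitude, plus the centered mean RTs (per-orientation mean minus
#' the grand mean over orientation means). Centering removes the mean
#' non-decision time, which is independent of orientation.
#'
#' @param trials Trial table with columns `theta` (or `abs_theta`), `correct`,
#'   a response-time column, and optionally `choice` and `motor_mistake`.
#' @param rt_col Name of the response-time column (`"rt_ms"` for behavioral
#'   data, `"decision_time"` for simulated outcomes).
#' @param orientations Optional orientation magnitudes that must all be
#'   present; a missing one raises an error naming the gap.
#' @return A `block_summary`: data frame (`abs_theta`, `mean_rt`,
#'   `centered_rt`, `accuracy`, `n`) with attribute `grand_mean_rt`.
#' @export
summarize_block <- function(trials, rt_col = "rt_ms", orientations = NULL) {
  stopifnot(rt_col %in% names(trials))
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(trials$choice)) keep <- keep & trials$choice != "timeout"
  if (!is.null(trials$motor_mistake)) keep <- keep & !trials$motor_mistake
  trials <- trials[keep, , drop = FALSE]
  ath <- if (!is.null(trials$abs_theta)) trials$abs_theta else abs(trials$theta)
  if (!is.null(orientations)) {
    miss <- setdiff(orientations, unique(ath))
    if (length(miss) > 0)
      stop("summary error: no trials at orientation(s) ",
           paste(miss, collapse = ", "))
  }
  rt <- trials[[rt_col]]
  agg <- stats::aggregate(cbind(rt = rt, correct = as.numeric(trials$correct)),
                          by = list(abs_theta = ath), FUN = mean)
  sds <- stats::aggregate(rt, by = list(abs_theta = ath),
                          FUN = stats::sd)$x
  cnt <- as.vector(table(factor(ath, levels = agg$abs_theta)))
  out <- data.frame(abs_theta = agg$abs_theta, mean_rt = agg$rt,
                    centered_rt = agg$rt - mean(agg$rt),
                    accuracy = agg$correct, n = cnt, sd_rt = sds)
  if (!is.null(orientations))
    out <- out[out$abs_theta %in% orientations, , drop = FALSE]
  attr(out, "grand_mean_rt") <- mean(agg$rt)
  class(out) <- c("block_summary", "data.frame")
  out
}

#' Calibration cost between data and simulation summaries
#'
#' The cost is `lambda * (1/m) * sum_theta [centered-RT difference]^2 +
#' (1/n) * sum_theta [accuracy difference]^2`, where `m` and `n` are the
#' maxima over orientations of the respective squared differences. A term
#' whose maximum is zero contributes zero (0/0 convention), so a simulation
#' identical to the data has cost 0. The normalization makes each term
#' scale-free, and the RT centering makes the cost invariant to adding a
#' constant to all response times.
#'
#' When used as the objective of an iterative fit, the per-evaluation
#' renormalization destroys the magnitude of the mismatch (the cost is bounded
#' by `(lambda + 1) * K` for `K` orientations no matter how poor the fit), so
#' [fit_participant()] freezes the normalizers at their values on the first
#' iterate and passes them through `normalizers`; the frozen cost coincides
#' with the displayed expression at that first iterate.
#'
#' @param data,sim `block_summary` objects on the same orientation set.
#' @param lambda Relative weight of the response-time term (default 2).
#' @param normalizers Optional list with fixed `m` (ms^2) and `n` used instead
#'   of the per-evaluation maxima.
#' @return Scalar cost.
#' @export
calib_cost <- function(data, sim, lambda = 2, normalizers = NULL) {
  if (!setequal(data$abs_theta, sim$abs_theta))
    stop("orientation sets differ between data and simulation summaries")
  sim <- sim[match(data$abs_theta, sim$abs_theta), ]
  d_rt <- (sim$centered_rt - data$centered_rt)^2
  d_ac <- (sim$accuracy - data$accuracy)^2
  if (is.null(normalizers)) {
    m <- max(d_rt); n <- max(d_ac)
  } else {
    m <- normalizers$m; n <- normalizers$n
  }
  t_rt <- if (m > 0) sum(d_rt) / m else 0
  t_ac <- if (n > 0) sum(d_ac) / n else 0
  lambda * t_rt + t_ac
}

#' Per-evaluation normalizers of the calibration cost
#'
#' The maxima over orientations of the squared centered-RT and accuracy
#' differences between two summaries.
#'
#' @inheritParams calib_cost
#' @return List with `m` and `n`.
#' @export
calib_normalizers <- function(data, sim) {
  sim <- sim[match(data$abs_theta, sim$abs_theta), ]
  list(m = max((sim$centered_rt - data$centered_rt)^2),
       n = max((sim$accuracy - data$accuracy)^2))
}

# Gaussian negative log-likelihood (up to a constant) of the data summary
# given the simulation summary: each squared difference divided by twice its
# sampling variance (data + Monte-Carlo), so exp(-cost) is an actual Gaussian
# likelihood. Used for the profile confidence intervals, not as the fit
# objective.
likelihood_cost <- function(data, sim) {
  sim <- sim[match(data$abs_theta, sim$abs_theta), ]
  v_rt <- data$sd_rt^2 / data$n + sim$sd_rt^2 / sim$n
  p_d <- pmin(pmax(data$accuracy, 1e-3), 1 - 1e-3)
  p_s <- pmin(pmax(sim$accuracy, 1e-3), 1 - 1e-3)
  v_ac <- p_d * (1 - p_d) / data$n + p_s * (1 - p_s) / sim$n
  sum((sim$centered_rt - data$centered_rt)^2 / (2 * v_rt)) +
    sum((sim$accuracy - data$accuracy)^2 / (2 * v_ac))
}

#' Simulate a block and summarize it
#'
#' Samples a schedule from the protocol (restricted to the orientations being
#' fitted), runs the network over it as one continuous session, and summarizes
#' the decision times and accuracies per orientation. Stimulus strengths can
#' be supplied directly per orientation magnitude, bypassing
#' `alpha1`/`alpha2`.
#'
#' @param params A [network_params()] object.
#' @param protocol A [protocol_spec()].
#' @param n_trials Number of simulated trials.
#' @param c_by_theta Optional named vector of stimulus strengths keyed by
#'   orientation magnitude (e.g. `c("0.2" = 0.01, ...)`).
#' @param seed Simulator seed (also used to freeze the schedule).
#' @return A `block_summary` of the simulated block.
#' @export
simulate_block_summary <- function(params, protocol, n_trials,
                                   c_by_theta = NULL, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed %% .Machine$integer.max)
  sched <- sample_schedule(protocol, n_trials)
  if (!is.null(c_by_theta)) {
    key <- as.character(abs(sched$theta))
    if (!all(key %in% names(c_by_theta)))
      stop("c_by_theta must cover all scheduled orientations")
    sched$c_signed <- sign(sched$theta) * unname(c_by_theta[key])
  }
  sim <- run_session(params, sched, seed = seed)
  summarize_block(sim, rt_col = "decision_time")
}

#' Default calibration control settings
#'
#' @param n_sim Simulated trials per cost evaluation.
#' @param mcmc_iter Metropolis iterations.
#' @param prop_frac Proposal standard deviation as a fraction of each
#'   parameter range.
#' @param nm_maxit Nelder-Mead refinement iterations after the chain.
#' @param z_bounds,c_bounds Box bounds for the threshold (Hz) and the
#'   stimulus strengths.
#' @param lambda Cost weight (see [calib_cost()]).
#' @param temperature Metropolis temperature on the cost scale.
#' @param sim_dt Integration step (ms) used inside cost evaluations; the
#'   default coarsens the generator's step to halve the simulation cost (mean
#'   decision times shift by under 2%, well inside the fit tolerances).
#' @param ridge_prob Probability of a joint multiplicative proposal that
#'   rescales the threshold and all strengths together, improving mixing
#'   along the z-c trade-off ridge of the cost surface.
#' @return A list of control settings.
#' @export
calib_control <- function(n_sim = 1200, mcmc_iter = 400, prop_frac = 0.05,
                          nm_maxit = 60, z_bounds = c(10, 60),
                          c_bounds = c(0, 1), lambda = 2, temperature = 1,
                          sim_dt = 1, ridge_prob = 0.25) {
  list(n_sim = n_sim, mcmc_iter = mcmc_iter, prop_frac = prop_frac,
       nm_maxit = nm_maxit, z_bounds = z_bounds, c_bounds = c_bounds,
       lambda = lambda, temperature = temperature, sim_dt = sim_dt,
       ridge_prob = ridge_prob)
}

#' Fit the participant-specific free parameters
#'
#' Calibrates the decision threshold `z` and one stimulus strength per
#' orientation magnitude against a behavioral block summary, by Metropolis
#' exploration of `exp(-cost / T)` followed by a Nelder-Mead simplex
#' refinement of the best visited point. Every cost evaluation uses the same
#' simulation seed (common random numbers), so the optimized surface is
#' deterministic and the fit is reproducible given the seed.
#'
#' @param data A `block_summary` of the participant's behavioral block.
#' @param base_params A [network_params()] object carrying the fixed network
#'   constants; `z` and the strengths are overridden during the fit.
#' @param shared Named vector with the shared corollary-discharge parameters
#'   `I_CD_max` (nA) and `tau_CD` (ms).
#' @param protocol The [protocol_spec()] of the block being fitted.
#' @param control A [calib_control()] list.
#' @param seed Integer seed for the whole fit.
#' @param init Optional named starting point (`z` plus one strength per
#'   orientation); defaults to mid-bounds heuristics.
#' @param fix_c_theta Optional named vector of stimulus strengths (keyed by
#'   orientation magnitude) held fixed during the fit, leaving only `z` free —
#'   e.g. for threshold-recovery and interval-coverage experiments where the
#'   strength law is known.
#' @param fix_z Optional fixed decision threshold (Hz), leaving only the
#'   strengths free. The full joint fit is available but weakly identified
#'   along the threshold-strength ridge (see the methods vignette); the two
#'   fixed-direction modes recover each parameter group where the data
#'   actually constrain it.
#' @return A `calibration_result`: `z`, `c_theta` (named by orientation),
#'   `alpha1`, `alpha2`, `c_model` (`"linear"`/`"quadratic"`), `aic` (both
#'   forms), `cost`, `ci` (70% intervals per parameter), `chain` (visited
#'   points and costs), `shared`, and `flagged` (`TRUE` when the chain never
#'   improved over its patience window).
#' @export
fit_participant <- function(data, base_params, shared = c(I_CD_max = 0.033,
                                                          tau_CD = 150),
                            protocol, control = calib_control(), seed = 1,
                            init = NULL, fix_c_theta = NULL, fix_z = NULL) {
  set.seed(seed)
  sim_seed <- sample.int(.Machine$integer.max, 1)
  thetas <- sort(data$abs_theta)
  fixed_c <- !is.null(fix_c_theta)
  fixed_z <- !is.null(fix_z)
  if (fixed_c && fixed_z) stop("nothing left to fit")
  if (fixed_c) stopifnot(all(as.character(thetas) %in% names(fix_c_theta)))
  n_c <- if (fixed_c) 0 else length(thetas)
  par_names <- c(if (!fixed_z) "z", if (!fixed_c) paste0("c_", thetas))
  lo <- c(if (!fixed_z) control$z_bounds[1], rep(control$c_bounds[1], n_c))
  hi <- c(if (!fixed_z) control$z_bounds[2], rep(control$c_bounds[2], n_c))
  k <- length(par_names) - 1 # legacy: moves draw k + 1 normals
  pars <- base_params
  pars$I_CD_max <- unname(shared[["I_CD_max"]])
  pars$tau_CD <- unname(shared[["tau_CD"]])
  if (!is.null(control$sim_dt)) pars$dt <- control$sim_dt

  norm <- NULL # frozen at the first evaluation (see calib_cost)
  last_cost <- Inf # displayed-equation cost of the latest evaluation
  # negative log-likelihood scale objective; exp(-lik_of) is a Gaussian
  # likelihood of the summaries, which is what the Metropolis chain samples.
  # eval_seed governs the simulation noise: held fixed (common random
  # numbers) for the deterministic pre-scan and simplex refinement, but
  # refreshed every chain iteration so that the Monte-Carlo evaluation noise
  # itself widens the sampled posterior (the chain then covers the extra
  # estimator scatter that a frozen noise realization hides)
  eval_seed <- NULL
  lik_of <- function(x) {
    if (any(x < lo | x > hi)) {
      last_cost <<- Inf
      return(1e6 + sum(pmax(lo - x, 0) + pmax(x - hi, 0)))
    }
    p <- pars; p$z <- if (fixed_z) fix_z else x[1]
    if (fixed_c) {
      cth <- fix_c_theta
    } else {
      cth <- if (fixed_z) x else x[-1]
      names(cth) <- as.character(thetas)
    }
    # a candidate can push every trial to timeout; treat as infeasible
    sim <- tryCatch(
      simulate_block_summary(p, protocol, control$n_sim, c_by_theta = cth,
                             seed = if (is.null(eval_seed)) sim_seed
                                    else eval_seed),
      error = function(e) NULL)
    if (is.null(sim) || !setequal(sim$abs_theta, data$abs_theta)) {
      last_cost <<- Inf
      return(1e6)
    }
    if (is.null(norm)) {
      nn <- calib_normalizers(data, sim)
      if (nn$m > 0 && nn$n > 0) norm <<- nn
    }
    last_cost <<- calib_cost(data, sim, lambda = control$lambda,
                             normalizers = norm)
    likelihood_cost(data, sim)
  }

  if (is.null(init)) {
    z0 <- control$z_bounds[1] + 0.2 * diff(control$z_bounds)
    if (fixed_c) {
      # coarse scan over the threshold: the deterministic surface has a wide
      # infeasible plateau (all-timeout) that can strand a local chain
      z_grid <- seq(max(control$z_bounds[1] + 0.5, 11),
                    min(control$z_bounds[2], 27), length.out = 9)
      vals <- vapply(z_grid, lik_of, numeric(1))
      init <- z_grid[which.min(vals)]
    } else if (fixed_z) {
      c0 <- 0.08 * stats::qnorm(pmin(pmax(data$accuracy, 0.55), 0.995)) /
        stats::qnorm(0.75)
      c0 <- pmin(pmax(c0, 0.005), 0.9)
      best <- NULL; best_v <- Inf
      for (sg in c(0.5, 0.7, 0.85, 1.0, 1.2, 1.5, 2.0)) {
        cand <- pmin(pmax(c0 * sg, 0.005), 0.95)
        v <- lik_of(cand)
        if (v < best_v) { best_v <- v; best <- cand }
      }
      init <- best
    } else {
      # strengths read off the data accuracies through a probit-scale
      # heuristic, then a coarse global scan over the threshold and a common
      # rescaling of the strengths: the cost surface has a long ridge along
      # this pair, and a local chain started on its far side can stall there
      c0 <- 0.08 * stats::qnorm(pmin(pmax(data$accuracy, 0.55), 0.995)) /
        stats::qnorm(0.75)
      c0 <- pmin(pmax(c0, 0.005), 0.9)
      z_grid <- seq(max(control$z_bounds[1] + 0.5, 11),
                    min(control$z_bounds[2], 27), length.out = 6)
      s_grid <- c(0.6, 0.85, 1.0, 1.2, 1.5)
      best <- NULL; best_v <- Inf
      for (zg in z_grid) for (sg in s_grid) {
        cand <- c(zg, pmin(pmax(c0 * sg, 0.005), 0.95))
        v <- lik_of(cand)
        if (v < best_v) { best_v <- v; best <- cand }
      }
      init <- best
    }
  }
  x <- pmin(pmax(init, lo + 1e-6), hi - 1e-6)
  cur <- lik_of(x); cur_cost <- last_cost
  n_it <- control$mcmc_iter
  chain <- matrix(NA_real_, n_it + 1, k + 3,
                  dimnames = list(NULL, c(par_names, "cost", "cost_lik")))
  chain[1, ] <- c(x, cur_cost, cur)
  best_x <- x; best_lik <- cur; best_cost <- cur_cost; last_improve <- 0
  prop_sd <- control$prop_frac * (hi - lo)
  n_burn <- floor(n_it / 3)
  acc_win <- 0
  for (it in seq_len(n_it)) {
    eval_seed <- (sim_seed + 7919 * it) %% 2147483647
    if (stats::runif(1) < control$ridge_prob) {
      # joint rescaling of (z, c_theta); Hastings correction exp((k+1) s)
      # accounts for the asymmetric multiplicative proposal
      s_mv <- stats::rnorm(1, 0, 0.06)
      cand <- x * exp(s_mv)
      log_corr <- (k + 1) * s_mv
    } else {
      cand <- x + stats::rnorm(k + 1, 0, prop_sd)
      log_corr <- 0
    }
    cc <- lik_of(cand); cc_cost <- last_cost
    if (stats::runif(1) < exp((cur - cc) / control$temperature + log_corr)) {
      x <- cand; cur <- cc; cur_cost <- cc_cost
      acc_win <- acc_win + 1
      if (cc < best_lik) {
        best_lik <- cc; best_x <- cand; best_cost <- cc_cost
        last_improve <- it
      }
    }
    # adapt the proposal scale toward ~30% acceptance during burn-in only,
    # so the post-burn-in chain is a valid (fixed-kernel) Metropolis sample
    if (it <= n_burn && it %% 10 == 0) {
      prop_sd <- prop_sd * exp((acc_win / 10 - 0.3))
      acc_win <- 0
    }
    chain[it + 1, ] <- c(x, cur_cost, cur)
  }
  flagged <- (n_it - last_improve) > max(0.9 * n_it, 50)

  # refinement under common random numbers: re-baseline the chain's best
  # point on the deterministic surface first
  eval_seed <- NULL
  best_lik <- lik_of(best_x); best_cost <- last_cost

  nm <- if (k == 0) {
    # local 1-d refinement inside the region the chain actually supports
    post_z <- chain[seq.int(n_burn + 1, n_it + 1), 1]
    w <- max(stats::sd(post_z), 0.02 * diff(control$z_bounds))
    stats::optim(best_x, lik_of, method = "Brent",
                 lower = max(lo, min(post_z) - w),
                 upper = min(hi, max(post_z) + w),
                 control = list(maxit = control$nm_maxit))
  } else
    stats::optim(best_x, lik_of, method = "Nelder-Mead",
                 control = list(maxit = control$nm_maxit, reltol = 1e-4))
  if (nm$value < best_lik) {
    best_lik <- nm$value; best_x <- nm$par
    best_lik <- lik_of(best_x); best_cost <- last_cost
  }

  if (fixed_c) {
    cth <- fix_c_theta[as.character(thetas)]
  } else {
    cth <- if (fixed_z) best_x else best_x[-1]
    names(cth) <- as.character(thetas)
  }
  sel <- select_c_model(cth, thetas)
  ci <- param_confidence_intervals(chain, estimate = best_x)

  structure(list(z = if (fixed_z) fix_z else best_x[1],
                 c_theta = cth, alpha1 = sel$alpha1,
                 alpha2 = sel$alpha2, c_model = sel$model, aic = sel$aic,
                 cost = best_cost, cost_lik = best_lik, ci = ci,
                 chain = chain, shared = shared, flagged = flagged,
                 seed = seed),
            class = "calibration_result")
}

#' Choose between linear and quadratic stimulus-strength laws
#'
#' Regresses the fitted per-orientation strengths on `alpha1 * theta` versus
#' `alpha1 * theta + alpha2 * theta^2` (no intercept: zero orientation carries
#' no evidence) and selects the form with the lower AIC, computed as
#' `2k + n log(RSS / n)`.
#'
#' @param c_theta_by_orientation Fitted strengths (named or in the order of
#'   `thetas`).
#' @param thetas Orientation magnitudes (degrees).
#' @return List with `model` (`"linear"` or `"quadratic"`), `alpha1`,
#'   `alpha2` (0 for linear), `aic` (named pair), and `flagged` (`TRUE` when
#'   fewer than 3 orientations forced the linear default).
#' @export
select_c_model <- function(c_theta_by_orientation, thetas) {
  cc <- unname(c_theta_by_orientation)
  n <- length(cc)
  if (n < 3) {
    a1 <- sum(cc * thetas) / sum(thetas^2)
    return(list(model = "linear", alpha1 = a1, alpha2 = 0,
                aic = c(linear = NA_real_, quadratic = NA_real_),
                flagged = TRUE))
  }
  f_lin <- stats::lm(cc ~ 0 + thetas)
  f_quad <- stats::lm(cc ~ 0 + thetas + I(thetas^2))
  aic_of <- function(fit, kpar) {
    rss <- sum(stats::residuals(fit)^2)
    2 * kpar + n * log(max(rss, 1e-300) / n)
  }
  aic <- c(linear = aic_of(f_lin, 1), quadratic = aic_of(f_quad, 2))
  if (aic["quadratic"] < aic["linear"]) {
    co <- stats::coef(f_quad)
    list(model = "quadratic", alpha1 = unname(co[1]), alpha2 = unname(co[2]),
         aic = aic, flagged = FALSE)
  } else {
    list(model = "linear", alpha1 = unname(stats::coef(f_lin)[1]), alpha2 = 0,
         aic = aic, flagged = FALSE)
  }
}

#' 70% confidence intervals from the Metropolis chain
#'
#' The chain of [fit_participant()] samples `exp(-cost_lik)`, a Gaussian
#' likelihood of the block summaries, so after burn-in the visited states are
#' a posterior sample (flat prior over the bounds) and the level-`p` interval
#' for each parameter is the central `p` quantile range of its marginal. For
#' an exactly quadratic cost this reproduces the closed-form Gaussian interval
#' `estimate +/- qnorm((1 + level) / 2) * sigma`.
#'
#' @param chain Matrix of visited states with a `cost_lik` (or `cost`) column;
#'   one row per iteration.
#' @param level Coverage level (default 0.70).
#' @param burn_in Fraction of initial iterations discarded.
#' @param estimate Optional named vector of point estimates to report
#'   alongside the intervals (defaults to the minimum-cost visited state).
#' @return Data frame (`parameter`, `estimate`, `ci_low`, `ci_high`,
#'   `unbounded`); `unbounded` flags a degenerate marginal (the chain never
#'   moved in that coordinate).
#' @export
param_confidence_intervals <- function(chain, level = 0.70, burn_in = 1 / 3,
                                       estimate = NULL) {
  stopifnot(nrow(chain) >= 100)
  cost_col <- if ("cost_lik" %in% colnames(chain)) "cost_lik" else "cost"
  pn <- setdiff(colnames(chain), c("cost", "cost_lik"))
  keep <- seq.int(floor(burn_in * nrow(chain)) + 1, nrow(chain))
  post <- chain[keep, , drop = FALSE]
  ib <- which.min(ifelse(is.finite(chain[, cost_col]),
                         chain[, cost_col], Inf))
  alpha <- (1 - level) / 2
  out <- lapply(pn, function(p) {
    v <- post[, p]
    q <- stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
    est <- if (!is.null(estimate)) unname(estimate[match(p, pn)])
           else chain[ib, p]
    data.frame(parameter = p, estimate = est, ci_low = q[1], ci_high = q[2],
               unbounded = stats::sd(v) == 0)
  })
  do.call(rbind, out)
}

#' Grid search over the shared corollary-discharge parameters
#'
#' For each point of a grid over (`I_CD_max`, `tau_CD`), fits every
#' participant with [fit_participant()] and sums the best costs; returns the
#' grid point with the lowest summed cost and the per-participant results at
#' that point.
#'
#' @param data_list List of `block_summary` objects, one per participant.
#' @param grid Data frame with columns `I_CD_max` and `tau_CD`; the default
#'   grid is centered on 0.033 nA and 150 ms.
#' @param base_params,protocol,control,seed Passed to [fit_participant()].
#' @return List with `I_CD_max`, `tau_CD`, `total_cost`, `fits` (list of
#'   `calibration_result`), and `grid_costs`.
#' @export
fit_shared <- function(data_list, grid = expand.grid(
                         I_CD_max = c(0.023, 0.033, 0.043),
                         tau_CD = c(100, 150, 200)),
                       base_params = network_params(),
                       protocol = protocol_spec("confidence"),
                       control = calib_control(), seed = 1) {
  stopifnot(nrow(grid) >= 1)
  totals <- numeric(nrow(grid))
  fits_by_point <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    shared <- c(I_CD_max = grid$I_CD_max[g], tau_CD = grid$tau_CD[g])
    fits <- lapply(seq_along(data_list), function(i)
      fit_participant(data_list[[i]], base_params, shared, protocol,
                      control, seed = seed + i))
    totals[g] <- sum(vapply(fits, function(f) f$cost, numeric(1)))
    fits_by_point[[g]] <- fits
  }
  best <- which.min(totals)
  list(I_CD_max = grid$I_CD_max[best], tau_CD = grid$tau_CD[best],
       total_cost = totals[best], fits = fits_by_point[[best]],
       grid_costs = cbind(grid, total_cost = totals))
}

#' Write a calibration report as delimited text
#'
#' @param result A `calibration_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(result, path) {
  utils::write.table(result$ci, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result\n")
  cat(sprintf("  z = %.2f Hz, cost = %.4g%s\n", x$z, x$cost,
              if (x$flagged) " [flagged: no recent improvement]" else ""))
  cat("  c_theta:", paste(sprintf("%s=%.4f", names(x$c_theta), x$c_theta),
                          collapse = ", "), "\n")
  cat(sprintf("  strength law: %s (alpha1 = %.4f, alpha2 = %.4f)\n",
              x$c_model, x$alpha1, x$alpha2))
  invisible(x)
}
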