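test_that("transfer function is continuous at its removable singularity", {
  p <- fast_params()
  # a*I = b at I = 0.4 nA with the published constants; limit is 1/d
  expect_equal(transfer_rate(0.4, p), 1 / p$d, tolerance = 1e-10)
  # continuity: values just around the singular point straddle 1/d smoothly
  eps <- 1e-9
  expect_equal(transfer_rate(0.4 + eps, p), 1 / p$d, tolerance = 1e-5)
  expect_equal(transfer_rate(0.4 - eps, p), 1 / p$d, tolerance = 1e-5)
})

test_that("transfer function matches an independent high-precision oracle", {
  # f(0.5255 nA) evaluated with 40-digit arithmetic (mpmath), frozen:
  expect_equal(transfer_rate(0.5255, fast_params()),
               34.06954051336651, tolerance = 1e-10)
})

test_that("transfer function is increasing, vanishes at -Inf, rejects NaN", {
  p <- fast_params()
  I <- seq(-1, 2, by = 0.01)
  r <- transfer_rate(I, p)
  expect_true(all(diff(r) > 0))
  expect_lt(transfer_rate(-50, p), 1e-10)
  expect_true(all(r >= 0))
  expect_error(transfer_rate(NaN, p), "finite")
  expect_error(transfer_rate(Inf, p), "finite")
})

test_that("stimulus currents split J_ext by the signed strength", {
  # symmetric case, published coupling value
  expect_equal(unname(stimulus_current(0, "C", 0.182)), c(0.182, 0.182))
  # extreme case
  expect_equal(unname(stimulus_current(1, "C", 0.182)), c(0.364, 0))
  # direct arithmetic at c = 0.05
  expect_equal(unname(stimulus_current(0.05, "C", 0.182)),
               c(0.1911, 0.1729), tolerance = 1e-12)
  # the summed drive is strength-independent
  for (cc in c(0.1, 0.37, 0.9))
    expect_equal(sum(stimulus_current(cc, "AC", 0.02)), 0.04)
  expect_error(stimulus_current(1.2, "C"), "\\[0, 1\\]")
  expect_error(stimulus_current(-0.1, "C"), "\\[0, 1\\]")
})

test_that("corollary discharge is zero before the decision, then decays", {
  p <- fast_params()
  expect_equal(corollary_discharge(400, 400, p), -0.033)
  expect_equal(corollary_discharge(400 + p$tau_CD, 400, p),
               -0.033 * exp(-1))
  expect_equal(corollary_discharge(c(0, 100, 399.9), 400, p), rep(0, 3))
})

test_that("a symmetric state under identical noise stays exactly symmetric", {
  p <- fast_params()
  st <- network_state(0.3, 0.3, p$I0, p$I0)
  for (k in 1:50) {
    eta <- rnorm(1)
    st <- step_state(st, c(C = 0, AC = 0), p, eta = c(eta, eta))$state
    expect_identical(st$S_C, st$S_AC)
    expect_identical(st$I_noise_C, st$I_noise_AC)
  }
})

test_that("noiseless Euler trajectory agrees with a dt/100 refinement", {
  p <- fast_params(sigma_noise = 0)
  run_flow <- function(dt, t_end) {
    pp <- p; pp$dt <- dt
    st <- network_state(0, 0, p$I0, p$I0)
    for (k in seq_len(round(t_end / dt)))
      st <- step_state(st, c(C = 0, AC = 0), pp, eta = c(0, 0))$state
    c(st$S_C, st$S_AC)
  }
  coarse <- run_flow(0.5, 200)
  fine <- run_flow(0.005, 200)
  expect_lt(max(abs(coarse - fine)), 1e-4)
})

test_that("noise current has mean I0 and the documented stationary sd", {
  p <- fast_params(exact_ou = FALSE)
  # Euler-Maruyama OU: stationary sd = sigma / sqrt(2 - dt/tau)
  n <- 40000
  rho <- 1 - p$dt / p$tau_noise
  innov_sd <- p$sigma_noise * sqrt(p$dt / p$tau_noise)
  set.seed(5)
  x <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), rho,
                                method = "recursive"))
  x <- x[-(1:200)]
  doc_sd <- p$sigma_noise / sqrt(2 - p$dt / p$tau_noise)
  expect_lt(abs(sd(x) / doc_sd - 1), 0.03)
  # the package stepper realizes the same process around I0
  st <- network_state(0, 0, p$I0, p$I0)
  set.seed(6)
  vals <- numeric(20000)
  for (k in seq_along(vals)) {
    st <- step_state(st, c(C = 0, AC = 0), p, eta = rnorm(2))$state
    vals[k] <- st$I_noise_C
  }
  expect_lt(abs(mean(vals[-(1:500)]) - p$I0), 4 * doc_sd / sqrt(1000))
  expect_lt(abs(sd(vals[-(1:500)]) / doc_sd - 1), 0.03)
})

test_that("exact OU updates reproduce the continuous-time stationary law", {
  p <- fast_params(exact_ou = TRUE)
  st <- network_state(0, 0, p$I0, p$I0)
  set.seed(7)
  vals <- numeric(20000)
  for (k in seq_along(vals)) {
    st <- step_state(st, c(C = 0, AC = 0), p, eta = rnorm(2))$state
    vals[k] <- st$I_noise_AC
  }
  expect_lt(abs(sd(vals[-(1:500)]) / (p$sigma_noise / sqrt(2)) - 1), 0.03)
})

test_that("noiseless symmetric trials never decide; strong bias always wins", {
  p <- fast_params(sigma_noise = 0)
  S0 <- settled_state(p)
  st <- network_state(S0[1], S0[2], p$I0, p$I0)
  out <- run_trial(st, theta = 1, p, gap_ms = 0, c_theta = 0)
  expect_identical(out$choice, "timeout")
  # deterministic dominant drive at c = 0.5 with the spec's z = 20 Hz
  p2 <- fast_params(sigma_noise = 0, z = 20)
  for (k in 1:3) {
    st <- network_state(S0[1], S0[2] + 1e-6 * k, p2$I0, p2$I0)
    out <- run_trial(st, theta = 1, p2, gap_ms = 0, c_theta = 0.5)
    expect_identical(out$choice, "C")
  }
})

test_that("trial outcomes satisfy their invariants and traces are phased", {
  p <- fast_params()
  set.seed(11)
  out <- run_trial(NULL, theta = -0.8, p, gap_ms = 300, trace = TRUE)
  expect_true(out$choice %in% c("C", "AC", "timeout"))
  expect_gt(out$decision_time, 0)
  expect_lte(out$decision_time, p$t_max)
  expect_gte(out$delta_r, 0)
  expect_true(all(out$trace$S_C >= 0 & out$trace$S_C <= 1))
  expect_identical(unique(out$trace$phase), c("stim", "post"))
  # corollary discharge is active only after the decision
  expect_true(all(out$trace$I_CD[out$trace$phase == "stim"] == 0))
  expect_true(all(out$trace$I_CD[out$trace$phase == "post"] < 0))
  tmp <- tempfile(fileext = ".tsv")
  write_trace(out$trace, tmp)
  rt <- utils::read.delim(tmp)
  expect_equal(nrow(rt), nrow(out$trace))
  expect_named(rt, c("time_ms", "S_C", "S_AC", "r_C", "r_AC", "I_CD", "phase"))
})

test_that("sessions replay identically under the same seed", {
  p <- fast_params()
  set.seed(3)
  sched <- rand_schedule(40, 0.05)
  a <- run_session(p, sched, seed = 99)
  b <- run_session(p, sched, seed = 99)
  expect_identical(a, b)
  # and differ under another seed
  d <- run_session(p, sched, seed = 100)
  expect_false(identical(a$decision_time, d$decision_time))
})

test_that("gating variables stay in [0, 1] across a session", {
  p <- fast_params()
  set.seed(4)
  s <- run_session(p, rand_schedule(80, 0.1, gap_ms = 300), seed = 5)
  sc <- unlist(s[, c("S_C_onset", "S_AC_onset", "S_C_decision",
                     "S_AC_decision", "S_C_next", "S_AC_next")])
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("after a very long gap the next trial forgets the previous one", {
  p <- fast_params()
  set.seed(8)
  s <- run_session(p, rand_schedule(1200, 0.05, gap_ms = 6000), seed = 21)
  ok <- s$choice != "timeout"
  prev <- 1:(nrow(s) - 1); cur <- prev + 1
  keep <- ok[prev] & ok[cur]
  rep_prev <- (s$choice[cur] == s$choice[prev])[keep]
  # previous choice does not bias the current one
  expect_gt(binom.test(sum(rep_prev), length(rep_prev), 0.5)$p.value, 0.01)
  # previous choice does not shift the current decision time
  dt_cur <- s$decision_time[cur][keep]
  expect_gt(t.test(dt_cur[rep_prev], dt_cur[!rep_prev])$p.value, 0.01)
})

test_that("protocol-length gaps leave a repetition bias (state carry-over)", {
  p <- fast_params()
  set.seed(9)
  s <- run_session(p, rand_schedule(800, 0.05, gap_ms = 500), seed = 22)
  ok <- s$choice != "timeout"
  prev <- 1:(nrow(s) - 1); cur <- prev + 1
  keep <- ok[prev] & ok[cur]
  rep_prev <- (s$choice[cur] == s$choice[prev])[keep]
  expect_lt(binom.test(sum(rep_prev), length(rep_prev), 0.5)$p.value, 0.01)
  expect_gt(mean(rep_prev), 0.5)
})

test_that("Euler step halving changes mean decision times by under 2%", {
  # the Euler-Maruyama scheme: its step-dependent noise amplitude offsets the
  # finer first-passage sampling, keeping the decision-time scale stable
  mean_dt <- function(dt) {
    p <- fast_params(dt = dt, exact_ou = FALSE)
    set.seed(12)
    s <- simulate_trials(p, 0.05, 2500, gap_ms = 500, seed = 13)
    mean(s$decision_time[s$choice != "timeout"])
  }
  m1 <- mean_dt(0.5)
  m2 <- mean_dt(0.05)
  expect_lt(abs(m1 / m2 - 1), 0.02)
})

test_that("noiseless flow finds fixed points, symmetry and basin boundaries", {
  p <- fast_params()
  # background-only flow from a decision-like state converges to an attractor
  fl <- noiseless_flow(c(0.6, 0.1), 0, 4000, p, stimulus = FALSE)
  nn <- nrow(fl)
  expect_lt(sqrt(sum((fl[nn, 2:3] - fl[nn - 1, 2:3])^2)), 1e-6)
  expect_identical(basin_of(c(0.6, 0.1), 0, p), "C")
  # under background input the symmetric low state is itself an attractor
  expect_identical(basin_of(c(0.12, 0.1), 0, p, t_settle = 8000),
                   "symmetric")
  # the symmetry diagonal is invariant under the c = 0 flow
  fd <- noiseless_flow(c(0.25, 0.25), 0, 500, p, stimulus = TRUE)
  expect_true(all(abs(fd$S_C - fd$S_AC) < 1e-12))
  # bisection brackets the separatrix of the stimulus-driven flow: points
  # just either side converge to the two different decision attractors
  bb <- basin_boundary(c(0.35, 0.1), c(0.1, 0.35), 0.05, p,
                       t_settle = 6000, tol_bisect = 1e-4, stimulus = TRUE)
  dirn <- (c(0.1, 0.35) - c(0.35, 0.1))
  lo <- bb$S - 1e-3 * dirn
  hi <- bb$S + 1e-3 * dirn
  expect_identical(basin_of(lo, 0.05, p, t_settle = 6000, stimulus = TRUE),
                   "C")
  expect_identical(basin_of(hi, 0.05, p, t_settle = 6000, stimulus = TRUE),
                   "AC")
})

test_that("network parameter validation enforces the documented invariants", {
  expect_error(network_params(dt = 5), "dt")
  expect_error(network_params(z = -1), "z")
  expect_error(network_params(tau_CD = 0), "positive")
  expect_error(network_params(J_cross = -0.1), "non-negative")
  expect_error(network_params(alpha1 = 1), "c_theta")
  # config round trip preserves every field
  p <- network_params(z = 17.5, alpha1 = 0.08)
  tmp <- tempfile(fileext = ".yaml")
  write_network_config(p, tmp)
  q <- read_network_config(tmp)
  expect_equal(unclass(p), unclass(q))
})
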