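make_raw <- function(participant, block, theta, choice, rt, conf = NA,
                     motor = FALSE) {
  data.frame(participant = participant, block = block,
             trial = seq_along(theta), theta = theta, choice = choice,
             correct = ifelse(theta > 0, choice == "C", choice == "AC"),
             rt_ms = rt, confidence = conf, motor_mistake = motor)
}

test_that("preprocessing computes the hand-checked covariates on 6 rows", {
  raw <- make_raw(1, "confidence",
                  theta = c(0.8, -0.8, 0.8, 0.8, -1.6, 0.2),
                  choice = c("C", "C", "AC", "C", "AC", "C"),
                  rt = c(700, 650, 720, 600, 550, 800),
                  conf = c(2, 5, 4, 8, 7, 3))
  out <- preprocess_trials(raw)
  expect_equal(out$ln_rt, log(raw$rt_ms))
  expect_equal(out$ln_rt_prev, c(NA, log(c(700, 650, 720, 600, 550))))
  # repetition: current correct category vs previous response
  # categories: C, AC, C, C, AC, C ; previous responses: -, C, C, AC, C, AC
  expect_equal(out$x_repetition, c(NA, 0, 1, 0, 0, 0))
  # median confidence is 4.5: conf > median is high
  expect_equal(out$conf_prev, c(NA, 0, 1, 0, 1, 1))
  expect_equal(attr(out, "n_rejected"), 0)
})

test_that("z-scores are per participant and degenerate RTs give zeros", {
  raw <- rbind(make_raw(1, "pure", c(0.2, -0.2, 0.8), c("C", "AC", "C"),
                        c(500, 600, 700)),
               make_raw(2, "pure", c(0.2, -0.2, 0.8), c("C", "AC", "C"),
                        c(900, 900, 900)))
  out <- preprocess_trials(raw)
  expect_equal(mean(out$rt_z[out$participant == 1]), 0, tolerance = 1e-12)
  expect_equal(sd(out$rt_z[out$participant == 1]), 1, tolerance = 1e-12)
  expect_equal(out$rt_z[out$participant == 2], rep(0, 3))
})

test_that("preprocessing drops bad rows and breaks lags across blocks", {
  raw <- rbind(make_raw(1, "pure", c(0.2, -0.2), c("C", "timeout"),
                        c(500, 1500)),
               make_raw(1, "confidence", c(0.8, 0.8), c("C", "C"),
                        c(-10, 700), conf = c(3, 6)))
  out <- preprocess_trials(raw)
  expect_equal(nrow(out), 2) # timeout and negative RT removed
  expect_equal(attr(out, "n_rejected"), 2)
  # the confidence-block row that starts its block has no lagged covariates
  expect_true(all(is.na(out$ln_rt_prev[c(1, 2)])))
  expect_error(preprocess_trials(raw[, -3]), "missing column")
})

test_that("a confidence report exactly at the median counts as low", {
  raw <- make_raw(1, "confidence", theta = rep(c(0.8, -0.8), 3),
                  choice = rep(c("C", "AC"), 3), rt = rep(600, 6),
                  conf = c(2, 4, 4, 6, 8, 4))
  out <- preprocess_trials(raw)
  # median is 4; trials following a report of 4 are post-LOW
  expect_equal(out$conf_prev[c(3, 4)], c(0, 0))
  expect_equal(out$conf_prev[6], 1) # after the 8
})

test_that("LMM recovers generating coefficients and nulls out white noise", {
  gen <- function(a4, seed) {
    set.seed(seed)
    rows <- list()
    for (p in 1:6) {
      n <- 800
      a0 <- 5.4 + rnorm(1, 0, 0.05)
      a1 <- -0.1 + rnorm(1, 0, 0.01)
      a3 <- 0.15 + rnorm(1, 0, 0.02)
      th <- sample(c(0.2, 0.8, 1.6), n, replace = TRUE)
      xr <- rbinom(n, 1, 0.5)
      cf <- rbinom(n, 1, 0.5)
      ln_rt <- numeric(n); ln_prev <- 6.4
      for (i in 1:n) {
        ln_rt[i] <- a0 + a1 * th[i] - 0.03 * xr[i] + a3 * ln_prev +
          a4 * cf[i] + rnorm(1, 0, 0.15)
        ln_prev <- ln_rt[i]
      }
      rows[[p]] <- data.frame(participant = p, ln_rt = ln_rt, abs_theta = th,
                              x_repetition = xr,
                              ln_rt_prev = c(6.4, ln_rt[-n]),
                              conf_prev = cf)
    }
    do.call(rbind, rows)
  }
  tbl <- gen(a4 = -0.02, seed = 40)
  fit <- fit_rt_lmm(tbl)
  est <- fit$fixed
  truth <- c("(Intercept)" = NA, abs_theta = -0.1, x_repetition = -0.03,
             ln_rt_prev = 0.15, conf_prev = -0.02)
  for (term in c("abs_theta", "x_repetition", "ln_rt_prev", "conf_prev")) {
    row <- est[est$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 2 * row$se)
  }
  # white-noise response: no spurious sequential structure (a systematic
  # covariate leak would give vanishing p-values; single 3-sigma flukes at a
  # fixed seed are tolerated)
  set.seed(43)
  tbl0 <- tbl
  noise <- rnorm(nrow(tbl0), 6.4, 0.15)
  tbl0$ln_rt <- noise
  tbl0$ln_rt_prev <- ave(noise, tbl0$participant,
                         FUN = function(v) c(6.4, v[-length(v)]))
  fit0 <- fit_rt_lmm(tbl0)
  p0 <- fit0$fixed$p[fit0$fixed$term %in%
                       c("x_repetition", "ln_rt_prev", "conf_prev")]
  expect_true(all(p0 > 0.001))
  # model comparison: AIC picks the full model when a4 matters; without the
  # effect the stiffer BIC penalty drops the confidence term
  cmp <- compare_rt_lmm(tbl)
  expect_identical(cmp$model[1], "full")
  tbl_no4 <- gen(a4 = 0, seed = 2)
  cmp0 <- compare_rt_lmm(tbl_no4)
  expect_identical(cmp0$model[which.min(cmp0$bic)], "no_conf")
  # the reported criteria match the fitted objects
  expect_equal(fit$aic, AIC(fit$model))
  expect_equal(fit$bic, BIC(fit$model))
})

test_that("post-confidence contrasts: nulls, power, and empty bins", {
  set.seed(42)
  base <- data.frame(
    participant = 1,
    conf_prev = rep(c(0, 1), each = 600),
    x_repetition = rep(c(0, 1), 600),
    abs_theta = sample(c(0.2, 0.8, 1.6), 1200, replace = TRUE),
    rt_z = rnorm(1200))
  out0 <- post_confidence_contrasts(base)
  expect_true(all(out0$p > 0.001)) # identical populations: no effect
  # identical groups give t = 0 exactly
  same <- data.frame(participant = 1, conf_prev = rep(c(0, 1), each = 30),
                     x_repetition = 1, abs_theta = 0.2,
                     rt_z = rep(seq(-1, 1, length.out = 30), 2))
  t0 <- post_confidence_contrasts(same)
  expect_lt(max(abs(t0$t)), 1e-12)
  # a 0.2-sd shift in one bin at n = 600/600 is detected at alpha = 0.05
  pow <- 0
  for (r in 1:20) {
    shifted <- data.frame(participant = 1,
                          conf_prev = rep(c(0, 1), each = 600),
                          x_repetition = 1,
                          abs_theta = 0.2,
                          rt_z = rnorm(1200))
    shifted$rt_z[shifted$conf_prev == 1] <-
      shifted$rt_z[shifted$conf_prev == 1] - 0.2
    res <- post_confidence_contrasts(shifted)
    row <- res[res$repetition == "repeated" & res$strength == "low", ]
    pow <- pow + (row$p < 0.05 && row$diff > 0)
  }
  expect_gt(pow / 20, 0.8) # theoretical power ~0.93
  # bins with no trials are skipped, not errors
  small <- base[base$x_repetition == 1, ]
  res <- post_confidence_contrasts(small)
  expect_false(any(res$repetition == "alternated"))
})

test_that("phase-plane report orders basin depth and speed by confidence", {
  p <- network_params()
  rep_ <- phase_plane_report(p, protocol_spec("confidence", report_ms = 0),
                             n_trials = 3000, seed = 77)
  b <- rep_$bins
  expect_true(all(c("conf", "repetition", "strength", "S_winner", "S_loser",
                    "basin_depth", "noiseless_tth_ms", "mean_decision_time",
                    "n") %in% names(b)))
  lw <- b[b$repetition == "repeated" & b$strength == "low", ]
  hi <- lw[lw$conf == "high", ]; lo <- lw[lw$conf == "low", ]
  # post-high states sit deeper toward the previous winner ...
  expect_gt(hi$S_winner, lo$S_winner)
  expect_lt(hi$S_loser, lo$S_loser)
  # ... so the deterministic flow from them reaches threshold sooner
  expect_lt(hi$noiseless_tth_ms, lo$noiseless_tth_ms)
  # and the stochastic repeated low-strength decisions are faster
  expect_lt(hi$mean_decision_time, lo$mean_decision_time)
  # trajectories are exported for the populated bins
  expect_true(length(rep_$trajectories) >= nrow(b))
})
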