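#' Preprocess a trial table for sequential analyses
#'
#' Adds the derived covariates used by the response-time mixed model and the
#' post-confidence contrasts: log RT, per-participant z-scored RT, the lagged
#' log RT, the previous-trial confidence dichotomized at the participant's
#' median (a report exactly at the median counts as low), and the repetition
#' indicator (1 when the correct category of the current trial repeats the
#' previous response; switchable to the previous correct category). Motor
#' mistakes, timeouts and non-positive RTs are dropped (the rejected row count
#' is recorded), lagged covariates are missing on the first trial of each
#' block instance, and trials following a missing confidence report carry a
#' missing `conf_prev`.
#'
#' @param raw Trial table with columns `participant`, `block`, `trial`,
#'   `theta`, `choice`, `correct`, `rt_ms`, `confidence`, `motor_mistake`, and
#'   optionally `session` and `run`.
#' @param repetition `"response"` (default) or `"category"`: what the current
#'   correct category must repeat for `x_repetition = 1`.
#' @return The augmented table (columns `abs_theta`, `ln_rt`, `rt_z`,
#'   `ln_rt_prev`, `conf_prev`, `x_repetition`), with attribute `n_rejected`.
#' @export
preprocess_trials <- function(raw, repetition = c("response", "category")) {
  repetition <- match.arg(repetition)
  req <- c("participant", "block", "trial", "theta", "choice", "correct",
           "rt_ms")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(raw$confidence)) raw$confidence <- NA_integer_
  if (is.null(raw$motor_mistake)) raw$motor_mistake <- FALSE

  bad <- raw$motor_mistake | raw$choice == "timeout" |
    !is.finite(raw$rt_ms) | raw$rt_ms <= 0
  tbl <- raw[!bad, , drop = FALSE]
  n_rejected <- sum(bad)

  grp_cols <- intersect(c("participant", "session", "run", "block"),
                        names(tbl))
  blk <- interaction(tbl[grp_cols], drop = TRUE)
  ord <- order(blk, tbl$trial)
  tbl <- tbl[ord, , drop = FALSE]
  blk <- blk[ord]

  tbl$abs_theta <- abs(tbl$theta)
  tbl$ln_rt <- log(tbl$rt_ms)
  # per-participant z-score (all identical RTs give z = 0, not NaN)
  zs <- stats::ave(tbl$rt_ms, tbl$participant, FUN = function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  tbl$rt_z <- zs

  lag_in <- function(x) stats::ave(x, blk, FUN = function(v)
    c(NA, v[-length(v)]))
  tbl$ln_rt_prev <- lag_in(tbl$ln_rt)
  prev_choice <- lag_in_chr(tbl$choice, blk)
  prev_conf <- lag_in(tbl$confidence)

  med <- stats::ave(tbl$confidence, tbl$participant, FUN = function(x)
    rep(stats::median(x, na.rm = TRUE), length(x)))
  tbl$conf_prev <- ifelse(is.na(prev_conf), NA_real_,
                          as.numeric(prev_conf > med))

  cur_cat <- ifelse(tbl$theta > 0, "C", "AC")
  prev_ref <- if (repetition == "response") prev_choice
              else lag_in_chr(cur_cat, blk)
  tbl$x_repetition <- ifelse(is.na(prev_ref), NA_real_,
                             as.numeric(cur_cat == prev_ref))
  attr(tbl, "n_rejected") <- n_rejected
  tbl
}

# lag a character vector within groups
lag_in_chr <- function(x, g) {
  out <- rep(NA_character_, length(x))
  for (lv in levels(g)) {
    i <- which(g == lv)
    if (length(i) > 1) out[i[-1]] <- x[i[-length(i)]]
  }
  out
}

#' Fit the sequential-effects linear mixed model
#'
#' Fits `ln(RT_n) ~ a0 + a1 |theta| + a2 x_repetition + a3 ln(RT_{n-1}) +
#' a4 Conf_{n-1}` with per-participant random slopes on the intercept,
#' `|theta|` and the lagged log RT. Singular fits are refitted with the
#' offending random slopes dropped (recorded in the result).
#'
#' @param tbl A preprocessed table from [preprocess_trials()] (rows with
#'   missing lagged covariates are dropped here).
#' @param use_confidence If `FALSE`, fit without the previous-confidence term
#'   (for blocks with no reports).
#' @return An `lmm_result`: `fixed` (term, estimate, se, df, t, p),
#'   `random_variances`, `aic`, `bic`, the `model` object, and
#'   `simplified` (`TRUE` if random terms were dropped).
#' @export
fit_rt_lmm <- function(tbl, use_confidence = TRUE) {
  keep <- stats::complete.cases(tbl[, c("ln_rt", "abs_theta", "x_repetition",
                                        "ln_rt_prev")])
  if (use_confidence) keep <- keep & !is.na(tbl$conf_prev)
  d <- tbl[keep, , drop = FALSE]
  if (length(unique(d$participant)) < 2)
    stop("need at least 2 participants for the mixed model")
  fe <- if (use_confidence)
    "ln_rt ~ abs_theta + x_repetition + ln_rt_prev + conf_prev"
  else
    "ln_rt ~ abs_theta + x_repetition + ln_rt_prev"
  res <- c("(1 + abs_theta + ln_rt_prev || participant)",
           "(1 + abs_theta || participant)",
           "(1 | participant)")
  fit <- NULL; simplified <- FALSE
  for (i in seq_along(res)) {
    f <- stats::as.formula(paste(fe, "+", res[i]))
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(f, data = d, REML = FALSE)))
    if (!lme4::isSingular(fit, tol = 1e-5)) break
    simplified <- TRUE
  }
  co <- summary(fit)$coefficients
  fixed <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], df = co[, "df"],
                      t = co[, "t value"], p = co[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fixed = fixed, random_variances = vc,
                 aic = stats::AIC(fit), bic = stats::BIC(fit),
                 model = fit, simplified = simplified, n = nrow(d)),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Sequential-effects LMM (", x$n, " trials)\n", sep = "")
  print(x$fixed, digits = 4)
  if (x$simplified) cat("note: random-effect structure was simplified\n")
  invisible(x)
}

#' Compare the full sequential LMM with nested reductions
#'
#' Fits the full model and reductions without the previous-confidence and/or
#' repetition terms on the same rows, and ranks them by AIC and BIC.
#'
#' @param tbl A preprocessed table from [preprocess_trials()].
#' @return Data frame (`model`, `df`, `aic`, `bic`, `logLik`) sorted by AIC.
#' @export
compare_rt_lmm <- function(tbl) {
  keep <- stats::complete.cases(tbl[, c("ln_rt", "abs_theta", "x_repetition",
                                        "ln_rt_prev", "conf_prev")])
  d <- tbl[keep, , drop = FALSE]
  forms <- list(
    full = ln_rt ~ abs_theta + x_repetition + ln_rt_prev + conf_prev +
      (1 | participant),
    no_conf = ln_rt ~ abs_theta + x_repetition + ln_rt_prev +
      (1 | participant),
    no_seq = ln_rt ~ abs_theta + (1 | participant))
  fits <- lapply(forms, function(f) suppressWarnings(suppressMessages(
    lme4::lmer(f, data = d, REML = FALSE))))
  out <- data.frame(model = names(forms),
                    df = vapply(fits, function(m) attr(stats::logLik(m), "df"),
                                numeric(1)),
                    aic = vapply(fits, stats::AIC, numeric(1)),
                    bic = vapply(fits, stats::BIC, numeric(1)),
                    logLik = vapply(fits, function(m)
                      as.numeric(stats::logLik(m)), numeric(1)))
  out[order(out$aic), ]
}

#' Post-confidence response-time contrasts
#'
#' Bins trials by repetition (repeated/alternated relative to the previous
#' response) and stimulus strength (low/high orientation), and within each bin
#' compares the z-scored RTs of post-low versus post-high confidence trials
#' with a Welch t-test.
#'
#' @param tbl A preprocessed table from [preprocess_trials()] (confidence
#'   block rows).
#' @param low_orient,high_orient Orientation magnitudes counted as low/high
#'   strength.
#' @param rt_col Column to contrast (default the z-scored RT).
#' @return Data frame with one row per non-empty bin: mean RT after low and
#'   high confidence, their difference (`post_low - post_high`; positive means
#'   post-high speeding), Welch `t`, fractional `df`, `p`, and bin counts.
#' @export
post_confidence_contrasts <- function(tbl, low_orient = c(0.2, 0.8),
                                      high_orient = 1.6, rt_col = "rt_z") {
  d <- tbl[!is.na(tbl$conf_prev) & !is.na(tbl$x_repetition), , drop = FALSE]
  d$strength <- ifelse(d$abs_theta %in% high_orient, "high",
                       ifelse(d$abs_theta %in% low_orient, "low", NA))
  d <- d[!is.na(d$strength), , drop = FALSE]
  bins <- expand.grid(repetition = c("repeated", "alternated"),
                      strength = c("low", "high"),
                      stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(bins))) {
    rep_flag <- as.numeric(bins$repetition[i] == "repeated")
    sel <- d$x_repetition == rep_flag & d$strength == bins$strength[i]
    lo <- d[[rt_col]][sel & d$conf_prev == 0]
    hi <- d[[rt_col]][sel & d$conf_prev == 1]
    if (length(lo) < 2 || length(hi) < 2) next
    tt <- stats::t.test(lo, hi)
    out[[length(out) + 1]] <- data.frame(
      repetition = bins$repetition[i], strength = bins$strength[i],
      mean_post_low = mean(lo), mean_post_high = mean(hi),
      diff = mean(lo) - mean(hi), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value,
      n_low = length(lo), n_high = length(hi))
  }
  do.call(rbind, out)
}

#' Phase-plane account of the post-confidence sequential effect
#'
#' Simulates a confidence-block session, classifies each trial by the previous
#' trial's confidence (median split of the evidence balance), by repetition
#' (current category versus previous response) and by stimulus strength, and
#' reports per bin: the mean network state at stimulus onset (oriented as
#' previous-winner / previous-loser coordinates), the mean decision time, and
#' a 200 ms noiseless continuation of the flow from the mean onset state under
#' the bin's stimulus, as if there were no decision threshold. Also reports
#' the basin depth of the mean onset state: the distance (along the segment to
#' its mirror image) from the state to the basin boundary of the
#' background-input flow.
#'
#' @param params A [network_params()] object.
#' @param protocol A confidence-block [protocol_spec()].
#' @param n_trials Session length.
#' @param seed Simulator seed.
#' @param low_orient,high_orient Strength split (orientation magnitudes).
#' @param follow_ms Duration of the thresholdless continuation (ms).
#' @return List with `bins` (per-bin table: mean onset state in
#'   winner/loser coordinates, bisection basin depth where the stimulus flow
#'   defines one (`NA` when the whole segment lies in one basin, as happens
#'   at weak strengths), the deterministic time-to-threshold of the mean
#'   state `noiseless_tth_ms`, mean decision time, counts) and
#'   `trajectories` (named list of noiseless continuations).
#' @export
phase_plane_report <- function(params, protocol = protocol_spec("confidence"),
                               n_trials = 4000, seed = 1,
                               low_orient = c(0.2, 0.8), high_orient = 1.6,
                               follow_ms = 200) {
  set.seed(seed)
  sched <- sample_schedule(protocol, n_trials)
  sim <- run_session(params, sched, seed = seed)
  n <- nrow(sim)
  prev <- seq_len(n - 1); cur <- prev + 1
  ok <- sim$choice[prev] != "timeout" & sim$choice[cur] != "timeout"
  conf_hi <- sim$delta_r[prev] > stats::median(sim$delta_r[sim$choice != "timeout"])
  repeated <- ifelse(sim$theta[cur] > 0, "C", "AC") == sim$choice[prev]
  strength <- ifelse(abs(sim$theta[cur]) %in% high_orient, "high", "low")
  # orient states as (previous winner, previous loser)
  win_C <- sim$choice[prev] == "C"
  S_w <- ifelse(win_C, sim$S_C_onset[cur], sim$S_AC_onset[cur])
  S_l <- ifelse(win_C, sim$S_AC_onset[cur], sim$S_C_onset[cur])
  dt_cur <- sim$decision_time[cur]
  c_cur <- stim_strength(sim$theta[cur], params)

  bins <- expand.grid(conf = c("low", "high"),
                      repetition = c("repeated", "alternated"),
                      strength = c("low", "high"), stringsAsFactors = FALSE)
  rows <- list(); trajs <- list()
  for (i in seq_len(nrow(bins))) {
    sel <- ok & (conf_hi == (bins$conf[i] == "high")) &
      (repeated == (bins$repetition[i] == "repeated")) &
      (strength == bins$strength[i])
    if (sum(sel) < 5) next
    mS <- c(mean(S_w[sel]), mean(S_l[sel]))
    # stimulus favors the previous winner if repeated, the loser otherwise
    c_sgn <- mean(c_cur[sel]) * ifelse(bins$repetition[i] == "repeated", 1, -1)
    # depth of the onset state in the previous winner's basin under the
    # upcoming stimulus flow: fraction of the segment to the mirrored state
    # that still converges to the winner
    depth <- tryCatch({
      if (basin_of(mS, c_sgn, params, t_settle = 6000,
                   stimulus = TRUE) != "C") 0
      else basin_boundary(mS, rev(mS), c_signed = c_sgn, params,
                          t_settle = 6000, stimulus = TRUE)$lambda
    }, error = function(e) NA_real_)
    key <- paste(bins$conf[i], bins$repetition[i], bins$strength[i], sep = "_")
    trajs[[key]] <- noiseless_flow(mS, c_signed = c_sgn, follow_ms, params,
                                   stimulus = TRUE)
    # deterministic time-to-threshold of the mean state under the bin's
    # stimulus: the direct dynamical expression of "lying deeper"
    long <- noiseless_flow(mS, c_signed = c_sgn, params$t_max, params,
                           stimulus = TRUE)
    cross <- which(pmax(long$r_C, long$r_AC) >= params$z)[1]
    tth <- if (is.na(cross)) NA_real_ else long$time_ms[cross]
    rows[[length(rows) + 1]] <- data.frame(
      conf = bins$conf[i], repetition = bins$repetition[i],
      strength = bins$strength[i], S_winner = mS[1], S_loser = mS[2],
      basin_depth = depth, noiseless_tth_ms = tth,
      mean_decision_time = mean(dt_cur[sel]), n = sum(sel))
  }
  list(bins = do.call(rbind, rows), trajectories = trajs)
}
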