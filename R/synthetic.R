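#' Protocol specification for one block type
#'
#' Encodes the behavioral protocol: per-block orientation sets and sampling
#' weights, and the inter-event delays that determine the decision-to-onset
#' gap seen by the network. Pure blocks use eight orientations
#' `[-1.6, -0.8, -0.5, -0.2, 0.2, 0.5, 0.8, 1.6]` with weights
#' `[0.05, 0.1, 0.15, 0.2, 0.2, 0.15, 0.1, 0.05]`; feedback and confidence
#' blocks use `[-1.6, -0.8, -0.2, 0.2, 0.8, 1.6]` with weights
#' `[0.12, 0.18, 0.2, 0.2, 0.18, 0.12]`.
#'
#' The gap from a decision to the next stimulus onset is: pure, 300 ms
#' post-decision wait + 200 ms fixation = 500 ms; feedback, 200 ms wait +
#' 200 ms auditory feedback + 100 ms + 200 ms fixation = 700 ms; confidence,
#' 200 ms wait + the confidence-report period (`report_ms`, not specified by
#' the protocol text, default 2000 ms) + 300 ms wait + 200 ms fixation.
#'
#' @param block `"pure"`, `"feedback"` or `"confidence"`.
#' @param trials Trials per block.
#' @param report_ms Duration of the confidence report period (ms), confidence
#'   blocks only.
#' @return A `protocol_spec` list with `block`, `trials`, `orientations`,
#'   `weights`, `gap_ms`.
#' @export
protocol_spec <- function(block = c("pure", "feedback", "confidence"),
                          trials = 100, report_ms = 2000) {
  block <- match.arg(block)
  if (block == "pure") {
    orientations <- c(-1.6, -0.8, -0.5, -0.2, 0.2, 0.5, 0.8, 1.6)
    weights <- c(0.05, 0.1, 0.15, 0.2, 0.2, 0.15, 0.1, 0.05)
    gap_ms <- 300 + 200
  } else {
    orientations <- c(-1.6, -0.8, -0.2, 0.2, 0.8, 1.6)
    weights <- c(0.12, 0.18, 0.2, 0.2, 0.18, 0.12)
    gap_ms <- if (block == "feedback") 200 + 200 + 100 + 200
              else 200 + report_ms + 300 + 200
  }
  stopifnot(abs(sum(weights) - 1) < 1e-12)
  structure(list(block = block, trials = trials, orientations = orientations,
                 weights = weights, gap_ms = gap_ms), class = "protocol_spec")
}

#' Sample a stimulus schedule from a protocol
#'
#' @param protocol A [protocol_spec()].
#' @param n Number of trials (defaults to `protocol$trials`).
#' @return Data frame with columns `theta` and `gap_ms`, suitable for
#'   [run_session()]. Uses R's RNG (seed with `set.seed()`).
#' @export
sample_schedule <- function(protocol, n = protocol$trials) {
  theta <- sample(protocol$orientations, n, replace = TRUE,
                  prob = protocol$weights)
  data.frame(theta = theta, gap_ms = protocol$gap_ms)
}

#' Ground truth for a synthetic participant
#'
#' Draws participant-specific free parameters from configured ranges, keeping
#' the published network constants fixed. Non-decision time is ex-Gaussian.
#'
#' @param z_range,alpha1_range Ranges for the decision threshold (Hz) and the
#'   linear stimulus-strength coefficient (per degree).
#' @param alpha2 Quadratic strength coefficient (per degree^2; 0 = linear).
#' @param ndt_mu_range,ndt_sigma_range,ndt_tau_range Ranges (ms) for the
#'   ex-Gaussian non-decision-time parameters.
#' @return A list with a `network_params` object and an `exgauss_params`
#'   list. Uses R's RNG.
#' @export
draw_ground_truth <- function(z_range = c(13.5, 16.5),
                              alpha1_range = c(0.08, 0.13),
                              alpha2 = 0,
                              ndt_mu_range = c(250, 350),
                              ndt_sigma_range = c(30, 50),
                              ndt_tau_range = c(50, 100)) {
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  list(params = network_params(z = runif1(z_range),
                               alpha1 = runif1(alpha1_range),
                               alpha2 = alpha2),
       ndt = exgauss_params(mu = runif1(ndt_mu_range),
                            sigma_g = runif1(ndt_sigma_range),
                            tau_e = runif1(ndt_tau_range)))
}

#' Generate a synthetic behavioral cohort
#'
#' Simulates every block trial-by-trial with the attractor network (state
#' carried across trials within a block; each block starts from the settled
#' neutral state), adds ex-Gaussian non-decision time to the decision times,
#' and, in confidence blocks, maps the evidence balance `delta_r` onto the
#' 10-level scale through a participant-specific confidence map built by
#' histogram matching against a target histogram.
#'
#' @param n_participants Number of simulated participants.
#' @param sessions,runs Protocol repetitions: each session holds `runs` runs,
#'   each run one block of each requested type.
#' @param blocks Character vector of block types to include.
#' @param trials_per_block Trials per block instance.
#' @param truth Optional list of per-participant ground truths (as returned by
#'   [draw_ground_truth()]); drawn if `NULL`.
#' @param conf_target_counts Target confidence histogram (10 counts) used to
#'   build each participant's ground-truth confidence map.
#' @param report_ms Confidence-report duration (ms).
#' @param seed Master seed; all randomness in the generator flows from it.
#' @return A list: `trials` (tidy trial table: participant, session, run,
#'   block, trial, theta, abs_theta, choice, correct, decision_time, rt_ms,
#'   delta_r, confidence, motor_mistake) and `truth` (per-participant
#'   generating parameters, including the confidence-map thresholds).
#' @export
generate_cohort <- function(n_participants = 6, sessions = 1, runs = 1,
                            blocks = c("pure", "confidence"),
                            trials_per_block = 100, truth = NULL,
                            conf_target_counts = rep(10, 10),
                            report_ms = 2000, seed = 1) {
  set.seed(seed)
  if (is.null(truth)) truth <- replicate(n_participants, draw_ground_truth(),
                                         simplify = FALSE)
  stopifnot(length(truth) == n_participants)
  protos <- lapply(blocks, protocol_spec, trials = trials_per_block,
                   report_ms = report_ms)
  names(protos) <- blocks
  all <- list()
  for (p in seq_len(n_participants)) {
    tp <- truth[[p]]
    rows <- list()
    for (s in seq_len(sessions)) for (r in seq_len(runs)) for (b in blocks) {
      sched <- sample_schedule(protos[[b]])
      sim <- run_session(tp$params, sched,
                         seed = sample.int(.Machine$integer.max, 1))
      ndt <- exgauss_sample(tp$ndt, nrow(sim))
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, session = s, run = r, block = b,
        trial = seq_len(nrow(sim)), theta = sim$theta,
        abs_theta = abs(sim$theta), choice = sim$choice,
        correct = sim$correct, decision_time = sim$decision_time,
        rt_ms = sim$decision_time + ndt, delta_r = sim$delta_r,
        confidence = NA_integer_, motor_mistake = FALSE)
    }
    tab <- do.call(rbind, rows)
    if ("confidence" %in% blocks) {
      idx <- tab$block == "confidence"
      cmap <- histogram_match(tab$delta_r[idx], conf_target_counts,
                              participant = p)
      tab$confidence[idx] <- map_confidence(tab$delta_r[idx], cmap)
      truth[[p]]$confidence_map <- cmap
    }
    all[[p]] <- tab
  }
  trials <- do.call(rbind, all)
  attr(trials, "seed") <- seed
  list(trials = trials, truth = truth)
}

#' Inject pathological rows into a trial table
#'
#' Adds motor-mistake flags, missing confidence reports and timeout rows at
#' configured rates, for robustness testing of the preprocessing stage.
#'
#' @param trials Trial table from [generate_cohort()].
#' @param motor_rate,missing_conf_rate,timeout_rate Rates in `[0, 1]`.
#' @return The modified table. Uses R's RNG.
#' @export
inject_pathologies <- function(trials, motor_rate = 0,
                               missing_conf_rate = 0, timeout_rate = 0) {
  rates <- c(motor_rate, missing_conf_rate, timeout_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  n <- nrow(trials)
  if (motor_rate > 0) {
    k <- round(motor_rate * n)
    trials$motor_mistake[sample.int(n, k)] <- TRUE
  }
  if (missing_conf_rate > 0) {
    idx <- which(trials$block == "confidence" & !is.na(trials$confidence))
    k <- round(missing_conf_rate * length(idx))
    trials$confidence[sample(idx, k)] <- NA_integer_
  }
  if (timeout_rate > 0) {
    k <- round(timeout_rate * n)
    i <- sample.int(n, k)
    trials$choice[i] <- "timeout"
    trials$correct[i] <- FALSE
  }
  trials
}

#' Write a cohort to delimited text with a ground-truth sidecar
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab_path <- file.path(dir, "trials.tsv")
  utils::write.table(cohort$trials, tab_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  truth <- lapply(cohort$truth, function(tp) {
    out <- list(params = unclass(tp$params), ndt = unclass(tp$ndt))
    if (!is.null(tp$confidence_map))
      out$confidence_map <- list(thresholds = tp$confidence_map$thresholds,
                                 level_props = tp$confidence_map$level_props)
    out
  })
  truth_path <- file.path(dir, "truth.yaml")
  yaml::write_yaml(list(seed = attr(cohort$trials, "seed"),
                        participants = truth), truth_path)
  invisible(c(tab_path, truth_path))
}
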