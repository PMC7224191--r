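#' Run the full analysis pipeline
#'
#' Orchestrates generate -> map-confidence -> fit-ndt -> calibrate ->
#' analyze -> irm-contrast -> report over a single flat configuration. All
#' randomness flows from one master seed through named per-stage substreams,
#' so a rerun with the same configuration reproduces every table. Each stage
#' writes delimited text into the run directory, plus a provenance record
#' (`run_meta.json`) with the seed, the configuration and the stage list.
#'
#' @param config A named list (or path to a YAML file) with entries: `seed`
#'   (master seed), `n_participants`, `trials_per_block`, `blocks`, `stages`
#'   (character vector among `generate`, `map-confidence`, `fit-ndt`,
#'   `calibrate`, `analyze`, `irm-contrast`, `report`), and optional
#'   `calib_control` overrides (list) and `report_ms`.
#' @param out_dir Output directory for the run.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1, n_participants = 2, trials_per_block = 100,
                   blocks = c("pure", "confidence"),
                   stages = c("generate", "map-confidence", "fit-ndt",
                              "calibrate", "analyze", "irm-contrast",
                              "report"),
                   report_ms = 2000, calib_control = list())
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(k) (config$seed * 101 + k * 9973) %% 2147483647
  res <- list()
  log_path <- file.path(out_dir, "pipeline.log")
  logln <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                             "\n", file = log_path, append = TRUE)

  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop("stage-dependency error: '", stage, "' requires stage '", what,
           "' output")
  }

  if ("generate" %in% config$stages) {
    logln("generate")
    res$cohort <- generate_cohort(
      n_participants = config$n_participants,
      trials_per_block = config$trials_per_block,
      blocks = config$blocks, report_ms = config$report_ms,
      seed = stage_seed(1))
    write_cohort(res$cohort, out_dir)
    validate_trial_table(res$cohort$trials)
  }

  if ("map-confidence" %in% config$stages) {
    need("cohort", "map-confidence")
    logln("map-confidence")
    tr <- res$cohort$trials
    res$maps <- lapply(unique(tr$participant), function(p) {
      d <- tr[tr$participant == p & tr$block == "confidence" &
                !is.na(tr$confidence), ]
      counts <- as.vector(table(factor(d$confidence, levels = 0:9)))
      m <- histogram_match(d$delta_r, counts, participant = p)
      write_confidence_map(m, file.path(out_dir,
                                        sprintf("confidence_map_p%d.tsv", p)))
      m
    })
  }

  if ("fit-ndt" %in% config$stages) {
    need("cohort", "fit-ndt")
    logln("fit-ndt")
    tr <- res$cohort$trials
    res$ndt <- lapply(unique(tr$participant), function(p) {
      d <- tr[tr$participant == p & tr$choice != "timeout", ]
      fit <- deconvolve_ndt(d$rt_ms, d$decision_time)
      data.frame(participant = p, mu = fit$mu, sigma_g = fit$sigma_g,
                 tau_e = fit$tau_e,
                 truncated = isTRUE(attr(fit, "truncated")),
                 negative_support = isTRUE(attr(fit, "negative_support")))
    })
    ndt_tab <- do.call(rbind, res$ndt)
    utils::write.table(ndt_tab, file.path(out_dir, "ndt_fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if ("calibrate" %in% config$stages) {
    need("cohort", "calibrate")
    logln("calibrate")
    tr <- res$cohort$trials
    ctrl <- do.call(calib_control, config$calib_control)
    proto <- protocol_spec("confidence",
                           trials = config$trials_per_block,
                           report_ms = config$report_ms)
    res$calibration <- lapply(unique(tr$participant), function(p) {
      d <- tr[tr$participant == p & tr$block == "confidence", ]
      summ <- summarize_block(d, rt_col = "rt_ms")
      fit <- fit_participant(summ, network_params(), protocol = proto,
                             control = ctrl, seed = stage_seed(4) + p)
      write_calibration_report(fit, file.path(
        out_dir, sprintf("calibration_p%d.tsv", p)))
      fit
    })
  }

  if ("analyze" %in% config$stages) {
    need("cohort", "analyze")
    logln("analyze")
    pre <- preprocess_trials(res$cohort$trials)
    conf_rows <- pre[pre$block == "confidence", ]
    res$lmm <- tryCatch(fit_rt_lmm(conf_rows), error = function(e) e)
    if (!inherits(res$lmm, "error"))
      utils::write.table(res$lmm$fixed, file.path(out_dir, "lmm_fixed.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    res$contrasts <- post_confidence_contrasts(conf_rows)
    if (!is.null(res$contrasts))
      utils::write.table(res$contrasts,
                         file.path(out_dir, "post_confidence_contrasts.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if ("irm-contrast" %in% config$stages) {
    logln("irm-contrast")
    res$irm_contrast <- compare_model_contrasts(
      network_params(), irm_params(), n = max(2000, config$trials_per_block),
      seed = stage_seed(6))
    utils::write.table(res$irm_contrast,
                       file.path(out_dir, "model_contrasts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if ("report" %in% config$stages) {
    logln("report")
    cfg_path <- file.path(out_dir, "config_used.yaml")
    yaml::write_yaml(config, cfg_path)
    meta <- list(seed = config$seed, stages = config$stages,
                 config_md5 = unname(tools::md5sum(cfg_path)),
                 package_version = as.character(
                   utils::packageVersion("dynconf")))
    jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}

#' Validate the trial-table schema
#'
#' @param trials A trial table.
#' @return `trials`, invisibly; errors naming the first offending column.
#' @export
validate_trial_table <- function(trials) {
  req <- c(participant = "numeric", block = "character", trial = "numeric",
           theta = "numeric", choice = "character", correct = "logical",
           rt_ms = "numeric")
  for (col in names(req)) {
    if (is.null(trials[[col]]))
      stop("schema-validation error: missing column '", col, "'")
    ok <- switch(req[[col]],
                 numeric = is.numeric(trials[[col]]),
                 character = is.character(trials[[col]]) ||
                   is.factor(trials[[col]]),
                 logical = is.logical(trials[[col]]))
    if (!ok)
      stop("schema-validation error: column '", col, "' has type ",
           class(trials[[col]])[1], ", expected ", req[[col]])
  }
  invisible(trials)
}
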