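#' Build a confidence map by histogram matching
#'
#' Matches the distribution of the neural evidence balance (the firing-rate
#' difference `delta_r` at decision time) onto an empirical histogram of
#' reported confidence levels (0-9). The nine thresholds are the order
#' statistics of the `delta_r` samples at the cumulative proportions of the
#' empirical counts, so that mapping the samples through the resulting map
#' reproduces the empirical histogram (exactly when the counts divide the
#' sample size). Empty empirical levels yield coincident thresholds
#' (zero-width bins), which preserves exact matching.
#'
#' @param delta_r_samples Numeric vector of `delta_r` values (Hz), non-empty.
#' @param empirical_counts Ten non-negative integers, counts of reported
#'   confidence levels 0-9; not all zero.
#' @param participant Optional participant identifier stored in the map.
#' @return A `confidence_map`: list with `thresholds` (9 non-decreasing Hz
#'   cut-points delimiting levels 0-9), `level_props` (10 proportions summing
#'   to 1), `participant`, and `degenerate` (`TRUE` when all mass sits in one
#'   level).
#' @export
histogram_match <- function(delta_r_samples, empirical_counts,
                            participant = NA) {
  if (length(delta_r_samples) == 0) stop("delta_r_samples must be non-empty")
  if (length(empirical_counts) != 10 || any(empirical_counts < 0) ||
      sum(empirical_counts) == 0)
    stop("empirical_counts must be 10 non-negative values, not all zero")
  n <- length(delta_r_samples)
  s <- sort(delta_r_samples)
  props <- empirical_counts / sum(empirical_counts)
  cum <- cumsum(props)[1:9]
  # number of samples that belong to levels strictly below each threshold
  m <- round(cum * n)
  thr <- s[pmin(m + 1, n)]
  structure(list(thresholds = thr, level_props = props,
                 participant = participant,
                 degenerate = sum(props > 0) == 1),
            class = "confidence_map")
}

#' Map evidence balances to discrete confidence levels
#'
#' Monotone non-decreasing in `delta_r`; a value exactly equal to a threshold
#' is assigned to the upper level (the map is right-continuous).
#'
#' @param delta_r Numeric vector of balances (Hz).
#' @param map A `confidence_map` from [histogram_match()].
#' @return Integer confidence levels in 0-9.
#' @export
map_confidence <- function(delta_r, map) {
  stopifnot(inherits(map, "confidence_map"))
  findInterval(delta_r, map$thresholds)
}

#' Fit a sigmoid to the confidence map
#'
#' Least-squares fit of `1 / (1 + exp(-beta (delta_r - kappa)))` to the
#' empirical CDF points of `delta_r` at the map thresholds, summarizing the
#' quantile map by a slope `beta` and midpoint `kappa`.
#'
#' @param map A `confidence_map`.
#' @param delta_r_samples The samples from which the map was built (used for
#'   the empirical CDF values at the thresholds).
#' @return A `sigmoid_fit`: list with `beta` (per Hz, > 0), `kappa` (Hz) and
#'   `rms_error` of the fit.
#' @export
fit_sigmoid <- function(map, delta_r_samples) {
  stopifnot(inherits(map, "confidence_map"))
  thr <- map$thresholds
  keep <- !duplicated(thr)
  x <- thr[keep]
  ecdf_fun <- stats::ecdf(delta_r_samples)
  y <- ecdf_fun(x)
  if (length(unique(x)) < 3)
    stop("fit not possible: fewer than 3 distinct threshold points")
  # logit-space linear fit as starting values, then nonlinear least squares
  yc <- pmin(pmax(y, 1e-4), 1 - 1e-4)
  lf <- stats::lm(stats::qlogis(yc) ~ x)
  beta0 <- max(unname(stats::coef(lf)[2]), 1e-3)
  kappa0 <- -unname(stats::coef(lf)[1]) / beta0
  obj <- function(p) sum((y - stats::plogis(p[1] * (x - p[2])))^2)
  opt <- stats::optim(c(beta0, kappa0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  beta <- opt$par[1]; kappa <- opt$par[2]
  if (beta <= 0) stop("fit not possible: non-increasing CDF points")
  structure(list(beta = beta, kappa = kappa,
                 rms_error = sqrt(opt$value / length(x))),
            class = "sigmoid_fit")
}

#' @export
print.confidence_map <- function(x, ...) {
  cat("Confidence map (levels 0-9)\n")
  cat("thresholds (Hz):", format(x$thresholds, digits = 4), "\n")
  cat("level proportions:", format(x$level_props, digits = 3), "\n")
  if (x$degenerate) cat("note: degenerate map (all mass in one level)\n")
  invisible(x)
}

#' Read and write a confidence map as delimited text
#'
#' The serialization has one row per level with its lower `delta_r` threshold
#' (Hz; `-Inf` for level 0) and its empirical proportion.
#'
#' @param map A `confidence_map`.
#' @param path File path.
#' @return `write_confidence_map` returns `path` invisibly;
#'   `read_confidence_map` returns a `confidence_map`.
#' @export
write_confidence_map <- function(map, path) {
  df <- data.frame(level = 0:9,
                   lower_threshold_Hz = c(-Inf, map$thresholds),
                   proportion = map$level_props)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_confidence_map
#' @export
read_confidence_map <- function(path) {
  df <- utils::read.delim(path)
  structure(list(thresholds = df$lower_threshold_Hz[-1],
                 level_props = df$proportion, participant = NA,
                 degenerate = sum(df$proportion > 0) == 1),
            class = "confidence_map")
}
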