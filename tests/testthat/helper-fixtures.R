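# shared fixtures: small parameter sets and schedules used across test files

fast_params <- function(...) {
  # default network constants; override via ...
  network_params(...)
}

# a settled symmetric state under background input (deterministic)
settled_state <- function(params, t_settle = 1000) {
  fl <- noiseless_flow(c(0, 0), 0, t_settle, params, stimulus = FALSE)
  c(fl$S_C[nrow(fl)], fl$S_AC[nrow(fl)])
}

# quick single-strength schedule with randomized favored category
rand_schedule <- function(n, c_theta, gap_ms = 500) {
  sgn <- rep(c(1, -1), length.out = n)[sample.int(n)]
  data.frame(theta = sgn, c_signed = sgn * c_theta, gap_ms = gap_ms)
}

skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
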