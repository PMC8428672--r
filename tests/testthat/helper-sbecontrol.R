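# Shared fixtures (built in code, memoised per test run).

baseline_params <- sbe_parameters()
baseline_init <- sbe_initial_state()

# clean 21-month model-implied report curves at the baseline fit
clean_curves <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- model_report_curves(baseline_params,
                                                      baseline_init, 21)
    cache
  }
})

# per-series gaussian noise scale: small relative to each series' range so
# the monotone-restoration step of the generator almost never triggers
series_sd <- function(curves) {
  vapply(curves[, -1], function(v) max(0.0025 * (max(v) - min(v)), 0.5),
         numeric(1))
}

# published strategy outcomes (deaths averted, cost) used by the ICER tests
table9_outcomes <- data.frame(
  strategy = c("A", "B", "C"),
  effect = c(5857, 4316.1, 7225.4),
  cost = c(6461500, 3003000, 7310000)
)

# 4th-order central difference of f at x
fd_deriv <- function(f, x, h) {
  (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
}

random_state11 <- function() {
  c(runif(9, 0, 1e6), runif(1, 0, 7e4), runif(1, 0, 1e4))
}
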