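# Small designs and fixtures shared across tests.

tiny_design <- function(seed = 42L, tasks = "normal", repetitions = 1L,
                        n_control = 2L, n_csvd = 2L) {
  d <- calibrated_design(n_control = n_control, n_csvd = n_csvd,
                         repetitions = repetitions, seed = seed)
  d$tasks <- tasks
  # shorter recordings keep disk round-trip tests quick
  d$groups$control$gait$duration <- c(15, 0)
  d$groups$csvd$gait$duration <- c(15, 0)
  d
}

# a design in which both groups share the control distributions (null case)
null_design <- function(seed = 1L, tasks = c("normal", "dual", "fast"),
                        n_control = 10L, n_csvd = 19L) {
  d <- calibrated_design(n_control = n_control, n_csvd = n_csvd,
                         repetitions = 1L, seed = seed)
  d$groups$csvd <- d$groups$control
  d$task_offsets$csvd <- d$task_offsets$control
  d$tasks <- tasks
  d
}

# brute-force unbiased autocorrelation, O(N^2), independent of the package
# implementation
acf_bruteforce <- function(x, rate, max_lag) {
  n <- length(x)
  kmax <- floor(max_lag * rate)
  c0 <- sum(x^2) / n
  sapply(0:kmax, function(k) {
    acc <- 0
    for (i in seq_len(n - k)) acc <- acc + x[i] * x[i + k]
    (acc / (n - k)) / c0
  })
}
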