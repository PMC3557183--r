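# Independent reference solvers and fixture builders used across the suite.

# Exact non-negative least squares by exhaustive active-set enumeration:
# the optimum of min ||Ax - y||, x >= 0 lies on some face of the positive
# orthant, so trying every subset of active (zeroed) coordinates and keeping
# the best feasible unconstrained solution is exact. Exponential in ncol(A),
# fine for the <= 5-column problems here; independent of pracma.
enum_nnls <- function(A, y) {
  p <- ncol(A)
  best <- NULL
  for (bits in 0:(2^p - 1)) {
    free <- which(bitwAnd(bits, 2^(seq_len(p) - 1)) > 0)
    x <- numeric(p)
    if (length(free) > 0) {
      sol <- tryCatch(qr.solve(A[, free, drop = FALSE], y),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[free] <- sol
    }
    if (any(x < -1e-9)) next
    x <- pmax(x, 0)
    sse <- sum((y - A %*% x)^2)
    if (is.null(best) || sse < best$sse - 1e-15) best <- list(x = x, sse = sse)
  }
  best
}

default_sched <- function() acquisition_schedule()

# Frame-averaged noiseless curve for given amplitudes/half-lives.
make_clean_tac <- function(amplitudes, half_lives, constant = 0,
                           schedule = default_sched(), label = "synthetic") {
  predicted_tac(multiexp_model(amplitudes, half_lives, constant),
                schedule, voi_label = label)
}

# Random multi-exponential TAC with well-separated half-lives, optional
# truncated Gaussian noise; used for optimizer-vs-oracle comparisons.
random_tac <- function(noise_sd = 0) {
  amps <- runif(3, 0.05, 1)
  hls <- c(runif(1, 15, 25), runif(1, 1.5, 3), runif(1, 8, 12))
  y <- make_clean_tac(amps, hls)
  if (noise_sd > 0) {
    y <- tac(y$frame_bounds, pmax(y$values + rnorm(length(y$values),
                                                   0, noise_sd), 0),
             voi_label = y$voi_label)
  }
  list(tac = y, amplitudes = amps, half_lives = hls)
}
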