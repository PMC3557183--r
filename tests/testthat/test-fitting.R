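test_that("fixed-mode fit recovers amplitudes from noiseless curves", {
  y <- make_clean_tac(c(0.32, 0.65, 0.03), c(20.39, 2.04, 9.97))
  r <- fit_fixed(y)
  expect_equal(r$normalized_fractions, c(0.32, 0.65, 0.03), tolerance = 1e-9)
  expect_equal(r$constant, 0, tolerance = 1e-9)
  expect_equal(r$labels, c("C11", "O15", "N13"))
  expect_lt(r$sse, 1e-20)
})

test_that("fixed-mode fit handles degenerate curves", {
  sched <- default_sched()
  zero <- tac(sched$frame_bounds, rep(0, 15))
  r0 <- fit_fixed(zero)
  expect_equal(r0$amplitudes, c(0, 0, 0))
  expect_equal(r0$constant, 0)
  expect_equal(r0$sse, 0)
  expect_false(r0$fractions_defined)
  # pure-background curve: constant column absorbs everything
  rk <- fit_fixed(tac(sched$frame_bounds, rep(0.37, 15)))
  expect_equal(rk$amplitudes, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(rk$constant, 0.37, tolerance = 1e-10)
  short <- tac(sched$frame_bounds[1:4, ], rep(1, 4))
  expect_error(fit_fixed(short), "frames", class = "photopet_input_error")
})

test_that("fixed-mode fit is scale-equivariant in the amplitudes", {
  set.seed(21)
  for (i in 1:10) {
    r <- random_tac(noise_sd = 0.01)
    base <- fit_fixed(r$tac)
    s <- runif(1, 0.1, 50)
    scaled <- fit_fixed(tac(r$tac$frame_bounds, r$tac$values * s))
    expect_equal(scaled$amplitudes, base$amplitudes * s, tolerance = 1e-6)
    expect_equal(scaled$normalized_fractions, base$normalized_fractions,
                 tolerance = 1e-8)
  }
})

test_that("fixed-mode fit equals the enumeration NNLS optimum", {
  set.seed(31)
  sched <- default_sched()
  A <- cbind(photopet:::frame_basis(c(20.39, 2.04, 9.97),
                                    sched$frame_bounds), 1)
  for (i in 1:20) {
    r <- random_tac(noise_sd = 0.02)
    fit <- fit_fixed(r$tac)
    oracle <- enum_nnls(A, r$tac$values)
    expect_equal(fit$sse, oracle$sse, tolerance = 1e-10)
    expect_equal(c(fit$amplitudes, fit$constant), oracle$x, tolerance = 1e-7)
  }
})

test_that("fixed-mode objective dominates random feasible points", {
  set.seed(41)
  sched <- default_sched()
  A <- cbind(photopet:::frame_basis(c(20.39, 2.04, 9.97),
                                    sched$frame_bounds), 1)
  for (i in 1:5) {
    r <- random_tac(noise_sd = 0.05)
    fit <- fit_fixed(r$tac)
    for (j in 1:40) {
      x <- runif(4, 0, 1.5)
      expect_lte(fit$sse, sum((r$tac$values - A %*% x)^2) + 1e-12)
    }
  }
})

test_that("free fit recovers a single exponential exactly", {
  y <- make_clean_tac(1, 5)
  r <- fit_free(y)
  on <- r$identified
  expect_equal(sum(on), 1)
  expect_equal(r$amplitudes[on], 1, tolerance = 1e-4)
  expect_equal(r$half_lives[on], 5, tolerance = 1e-4)
  expect_equal(r$amplitudes[!on], rep(0, sum(!on)))
  expect_equal(r$constant, 0, tolerance = 1e-6)
})

test_that("free fit recovers two distinct physical half-lives", {
  y <- make_clean_tac(c(0.08, 0.92), c(20.39, 2.04))
  r <- fit_free(y)
  on <- which(r$identified)
  expect_equal(length(on), 2)
  # sorted by descending half-life, so slow (11C-like) first
  expect_equal(r$half_lives[on[1]], 20.39, tolerance = 1e-3)
  expect_equal(r$half_lives[on[2]], 2.04, tolerance = 1e-3)
  expect_equal(r$amplitudes[on], c(0.08, 0.92), tolerance = 1e-3)
})

test_that("free fit identifies random three-component models from noiseless data", {
  set.seed(51)
  for (i in 1:5) {
    truth <- random_tac()
    r <- fit_free(truth$tac)
    expect_lt(r$sse / sum(truth$tac$values^2), 1e-12)
    ord <- order(truth$half_lives, decreasing = TRUE)
    expect_equal(r$half_lives[r$identified], truth$half_lives[ord],
                 tolerance = 1e-4)
    expect_equal(r$amplitudes[r$identified], truth$amplitudes[ord],
                 tolerance = 1e-4)
  }
})

test_that("free fit reports components sorted and flags empty ones", {
  y <- make_clean_tac(c(0.08, 0.92), c(20.39, 2.04))
  r <- fit_free(y)
  expect_true(all(diff(r$half_lives) <= 0))
  expect_true(any(!r$identified))
  expect_equal(r$amplitudes[!r$identified], rep(0, sum(!r$identified)))
  zero <- tac(default_sched()$frame_bounds, rep(0, 15))
  rz <- fit_free(zero)
  expect_equal(rz$amplitudes, c(0, 0, 0))
  expect_equal(rz$constant, 0)
})

test_that("free fit never loses to the coarse grid oracle", {
  set.seed(61)
  grid <- c(0.5, 1, 2.04, 4, 9.97, 15, 20.39, 30)
  for (i in 1:8) {
    r <- random_tac(noise_sd = 0.02)
    fit <- fit_free(r$tac)
    oracle <- grid_search_oracle(r$tac, half_life_grid = grid)
    expect_lte(fit$sse, oracle$sse + 1e-9)
  }
})

test_that("grid oracle is exact when the truth lies on the grid", {
  y <- make_clean_tac(1, 5)
  oracle <- grid_search_oracle(y, half_life_grid = c(2, 5, 11, 20),
                               n_components = 1)
  expect_equal(oracle$half_lives, 5)
  expect_lt(oracle$sse, 1e-25)
  expect_error(grid_search_oracle(y, half_life_grid = 1:200, max_evals = 100),
               class = "photopet_input_error")
})

test_that("amplitude normalization excludes K and flags the zero case", {
  y <- make_clean_tac(c(2, 2, 1e-15), c(20.39, 2.04, 9.97), constant = 0.5)
  r <- fit_fixed(y)
  r$amplitudes <- c(2, 2, 0)
  r <- normalize_amplitudes(r)
  expect_equal(r$normalized_fractions, c(0.5, 0.5, 0))
  r$amplitudes <- c(0, 0, 0)
  r <- normalize_amplitudes(r)
  expect_false(r$fractions_defined)
  expect_true(all(is.na(r$normalized_fractions)))
})

test_that("linearized intervals collapse on noiseless data", {
  y <- make_clean_tac(c(0.32, 0.65, 0.03), c(20.39, 2.04, 9.97))
  r <- confidence_intervals(fit_fixed(y), y)
  widths <- r$ci95[, "upper"] - r$ci95[, "lower"]
  expect_true(all(widths < 1e-8))
  expect_equal(r$ci_method, "linearized")
})

test_that("bootstrap intervals are seed-reproducible", {
  set.seed(71)
  r0 <- random_tac(noise_sd = 0.02)
  fit <- fit_fixed(r0$tac)
  a <- confidence_intervals(fit, r0$tac, method = "bootstrap", n_boot = 50,
                            seed = 99)
  b <- confidence_intervals(fit, r0$tac, method = "bootstrap", n_boot = 50,
                            seed = 99)
  expect_identical(a$ci95, b$ci95)
  c2 <- confidence_intervals(fit, r0$tac, method = "bootstrap", n_boot = 50,
                             seed = 100)
  expect_false(identical(a$ci95, c2$ci95))
})

test_that("interval estimation degrades gracefully, never errors", {
  # 7 frames, 7 free parameters: zero residual degrees of freedom
  sched <- acquisition_schedule(n_frames = 7)
  y <- predicted_tac(multiexp_model(c(0.3, 0.5, 0.2), c(20.39, 2.04, 9.97)),
                     sched)
  r <- fit_free(y)
  r <- confidence_intervals(r, y)
  expect_false(isTRUE(r$ci_reliable))
})
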