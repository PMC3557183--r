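test_that("a tissue composition implies the expected decay model", {
  m <- composition_to_model(simulation_spec(tissue = "urinary_bladder_filled"))
  expect_equal(m$labels, c("C11", "O15", "N13"))
  expect_equal(m$half_lives, c(20.39, 2.04, 9.97))
  cno <- c(0.04, 0.94, 0.017)
  expect_equal(m$amplitudes, cno / sum(cno), tolerance = 2e-3)
  expect_equal(sum(m$amplitudes), 1, tolerance = 1e-12)

  single <- composition_to_model(simulation_spec(composition = c(O = 1)))
  expect_equal(single$amplitudes, 1)
  expect_equal(single$half_lives, 2.04)

  contaminated <- composition_to_model(simulation_spec(
    tissue = "urinary_bladder_filled",
    contaminants = list(list(amplitude = 0.05, half_life = 2.5, label = "P30"))))
  expect_equal(length(contaminated$amplitudes), 4)
  expect_equal(contaminated$half_lives[4], 2.5)
})

test_that("simulation specs validate their inputs", {
  expect_error(simulation_spec(), class = "photopet_input_error")
  expect_error(simulation_spec(composition = c(O = 0.5)),
               class = "photopet_input_error")
  expect_error(simulation_spec(composition = c(Fe = 1)),
               class = "photopet_input_error")
  expect_error(simulation_spec(tissue = "urinary_bladder_filled",
                               noise = "poisson"),
               "seed", class = "photopet_input_error")
  bad <- simulation_spec(composition = c(O = 0.5, C = 0.3, N = 0.2))
  bad$composition <- c(Fe = 1)
  expect_error(composition_to_model(bad), "Fe", class = "photopet_input_error")
})

test_that("noiseless simulation equals the frame-averaged prediction", {
  spec <- simulation_spec(tissue = "adipose_adult2", background_K = 0.01)
  y <- simulate_tac(spec)
  expect_equal(y$values,
               predicted_tac(composition_to_model(spec), spec$schedule)$values,
               tolerance = 1e-15)
})

test_that("Poisson simulation is seeded and reproducible", {
  spec <- simulation_spec(tissue = "urinary_bladder_filled",
                          amplitude_scale = 500, noise = "poisson", seed = 42)
  a <- simulate_tac(spec)
  b <- simulate_tac(spec)
  expect_identical(a$values, b$values)
  spec2 <- simulation_spec(tissue = "urinary_bladder_filled",
                           amplitude_scale = 500, noise = "poisson", seed = 43)
  expect_false(identical(a$values, simulate_tac(spec2)$values))
})

test_that("Poisson frame rates are unbiased for the noiseless curve", {
  n_rep <- 2000
  scale <- 200
  clean <- simulate_tac(simulation_spec(tissue = "urinary_bladder_filled"))
  draws <- vapply(seq_len(n_rep), function(i) {
    simulate_tac(simulation_spec(tissue = "urinary_bladder_filled",
                                 amplitude_scale = scale, noise = "poisson",
                                 seed = 100000 + i))$values
  }, numeric(15))
  dur <- clean$frame_bounds[, 2] - clean$frame_bounds[, 1]
  # frame rate = Poisson(mu)/ (dur*scale), mu = scale*rate*dur
  se <- sqrt(clean$values / (dur * scale)) / sqrt(n_rep)
  dev <- abs(rowMeans(draws) - clean$values)
  expect_true(all(dev <= 3 * pmax(se, 1e-12)))
})

test_that("noiseless generate-and-refit recovers the fractions exactly", {
  set.seed(81)
  for (i in 1:6) {
    comp <- runif(3); comp <- comp / sum(comp)
    names(comp) <- c("C", "O", "N")
    spec <- simulation_spec(composition = comp, background_K = runif(1, 0, 0.1))
    truth <- composition_to_model(spec)
    r <- fit_fixed(simulate_tac(spec))
    expect_equal(r$normalized_fractions, truth$amplitudes, tolerance = 1e-6)
    expect_equal(r$constant, spec$background_K, tolerance = 1e-6)
  }
})

test_that("fraction RMSE under high-count Poisson noise stays small", {
  # ~1.4e4 expected first-frame counts at this scale for a bladder-like VOI
  n_rep <- 200
  spec0 <- simulation_spec(tissue = "urinary_bladder_filled")
  truth <- composition_to_model(spec0)$amplitudes
  err2 <- matrix(0, n_rep, 3)
  for (i in seq_len(n_rep)) {
    spec <- simulation_spec(tissue = "urinary_bladder_filled",
                            amplitude_scale = 5e4, noise = "poisson",
                            seed = 7000 + i)
    r <- fit_fixed(simulate_tac(spec))
    err2[i, ] <- (r$normalized_fractions - truth)^2
  }
  rmse <- sqrt(colMeans(err2))
  expect_true(all(rmse <= 0.02))
})

test_that("a 30P contaminant is absorbed into the 15O label", {
  spec <- simulation_spec(tissue = "urinary_bladder_filled",
                          contaminants = list(list(amplitude = 0.1,
                                                   half_life = 2.5,
                                                   label = "P30")))
  r <- fit_free(simulate_tac(spec))
  comp <- fractions_to_composition(r)
  # the fast activity, 15O plus the 2.5-min contaminant, reads as oxygen;
  # only the small 13N share can end up between the label windows
  expect_gt(comp[["O"]], 0.9)
  expect_lt(attr(comp, "unassigned"), 0.05)
})

test_that("phantom regions carry their models and a silent background", {
  spec_f <- simulation_spec(tissue = "adipose_adult2")
  spec_b <- simulation_spec(tissue = "urinary_bladder_filled")
  ph <- simulate_phantom(spec_f, spec_b, grid = c(12, 12, 12))
  pred_b <- predicted_tac(composition_to_model(spec_b), spec_b$schedule)
  expect_equal(extract_tac(ph$volume, ph$mask_bladder)$values, pred_b$values,
               tolerance = 1e-12)
  pred_f <- predicted_tac(composition_to_model(spec_f), spec_f$schedule)
  expect_equal(extract_tac(ph$volume, ph$mask_fat)$values, pred_f$values,
               tolerance = 1e-12)
  # background voxel is identically zero
  bg <- array(FALSE, dim = c(12, 12, 12)); bg[1, 1, 1] <- TRUE
  expect_equal(extract_tac(ph$volume, voi_mask(bg))$values, rep(0, 15))
  expect_false(any(ph$mask_fat$mask & ph$mask_bladder$mask))
  expect_error(simulate_phantom(spec_f, spec_b, grid = c(100, 12, 12)),
               class = "photopet_input_error")
})
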