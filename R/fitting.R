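#' Constraints for a multi-exponential fit
#'
#' Two regimes are supported. In `"fixed"` mode the half-lives are held at
#' the physical values of the activation products (default 11C 20.39 min,
#' 15O 2.04 min, 13N 9.97 min) and only the non-negative amplitudes and the
#' constant are estimated -- a convex problem solved exactly by non-negative
#' linear least squares. In `"free"` mode the half-lives are estimated too,
#' subject to a strictly positive lower bound that excludes the degenerate
#' spike solution (anything faster than ~0.1 min has decayed away before the
#' patient reaches the scanner).
#'
#' @param mode `"fixed"` or `"free"`.
#' @param fixed_half_lives Half-lives (minutes) used in fixed mode, and as
#'   multi-start anchors in free mode. Must have length `n_components`.
#' @param n_components Number of exponential components (default 3).
#' @param labels Nuclide symbols per component in fixed mode.
#' @param amplitude_lower Lower bound on amplitudes (0).
#' @param half_life_lower Lower bound on free half-lives, minutes (0.1).
#' @return An object of class `fit_constraints`.
#' @export
fit_constraints <- function(mode = c("fixed", "free"),
                            fixed_half_lives = c(20.39, 2.04, 9.97),
                            n_components = length(fixed_half_lives),
                            labels = c("C11", "O15", "N13"),
                            amplitude_lower = 0,
                            half_life_lower = 0.1) {
  mode <- match.arg(mode)
  if (length(fixed_half_lives) != n_components) {
    stop_input("mode=%s needs exactly %d half-lives, got %d", mode,
               n_components, length(fixed_half_lives))
  }
  if (any(fixed_half_lives <= 0)) stop_input("half-lives must be > 0")
  if (half_life_lower <= 0) stop_input("half_life_lower must be > 0")
  if (length(labels) != n_components) labels <- rep(NA_character_, n_components)
  structure(list(mode = mode, fixed_half_lives = fixed_half_lives,
                 n_components = n_components, labels = labels,
                 amplitude_lower = amplitude_lower,
                 half_life_lower = half_life_lower),
            class = "fit_constraints")
}

# Frame bounds used for fitting: the TAC's own, checked against an optional
# schedule, and shifted to the model's reference time (end of irradiation).
fit_frame_bounds <- function(tac, schedule) {
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "acquisition_schedule"))
    if (!isTRUE(all.equal(unname(schedule$frame_bounds),
                          unname(tac$frame_bounds), tolerance = 1e-9))) {
      stop_input("schedule frame bounds disagree with the TAC's")
    }
  }
  tac$frame_bounds
}

resolve_weights <- function(weights, y) {
  if (is.null(weights)) return(rep(1, length(y)))
  if (identical(weights, "poisson")) {
    # inverse-variance weights for counting noise; floor avoids 1/0
    return(1 / pmax(y, max(y, 1e-12) * 1e-3))
  }
  if (length(weights) != length(y) || any(weights < 0)) {
    stop_input("weights must be 'poisson' or a non-negative vector per frame")
  }
  weights
}

new_fit_result <- function(amplitudes, half_lives, constant, labels,
                           identified, residuals, fitted, sse, mode,
                           n_starts_used, n_frames) {
  amplitudes <- unname(as.numeric(amplitudes))
  half_lives <- unname(as.numeric(half_lives))
  constant <- unname(as.numeric(constant))
  total <- sum(amplitudes)
  res <- list(amplitudes = amplitudes, half_lives = half_lives,
              constant = constant, labels = labels, identified = identified,
              normalized_fractions = if (total > 0) amplitudes / total else
                rep(NA_real_, length(amplitudes)),
              fractions_defined = total > 0,
              residuals = residuals, fitted = fitted, sse = sse, mode = mode,
              n_starts_used = n_starts_used, n_frames = n_frames,
              ci95 = NULL, ci_method = NULL, ci_reliable = NA)
  structure(res, class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s-half-life fit, %d frames, sse = %.4g\n",
              x$mode, x$n_frames, x$sse))
  tab <- data.frame(
    label = ifelse(is.na(x$labels), "?", x$labels),
    S = signif(x$amplitudes, 4),
    half_life_min = ifelse(x$identified, signif(x$half_lives, 4), NA),
    fraction = signif(x$normalized_fractions, 4))
  print(tab)
  cat(sprintf("  K = %.4g%s\n", x$constant,
              if (!x$fractions_defined) "  (fractions undefined: sum S = 0)" else ""))
  if (!is.null(x$ci95)) {
    cat(sprintf("  95%% CI (%s%s):\n", x$ci_method,
                if (isFALSE(x$ci_reliable)) ", flagged unreliable" else ""))
    print(signif(x$ci95, 4))
  }
  invisible(x)
}

# Solve min ||A x - y|| with x >= 0; returns the exact optimum of the
# convex problem (active-set NNLS). Columns are normalized first: a
# short-half-life basis column can have a norm of 1e-11 or less, which
# defeats the solver's internal tolerance; scaling is exact to undo.
nnls_solve <- function(A, y) {
  if (all(y == 0)) return(rep(0, ncol(A)))
  cn <- sqrt(colSums(A^2))
  live <- cn > max(cn) * 1e-14
  x <- rep(0, ncol(A))
  if (any(live)) {
    As <- sweep(A[, live, drop = FALSE], 2, cn[live], `/`)
    sol <- pracma::lsqnonneg(As, y)
    x[live] <- sol$x / cn[live]
  }
  x
}

#' Fixed-half-life fit of a time-activity curve
#'
#' Estimates the non-negative component amplitudes `S_k` (at the end of
#' irradiation) and the non-negative constant `K` with the half-lives held
#' at their physical values. The objective is the unweighted sum of squared
#' differences between the measured frame means and the frame-averaged model;
#' because the model is linear in `(S, K)`, the constrained global optimum is
#' found exactly by non-negative linear least squares over the precomputed
#' frame-basis matrix -- no starting values, no local minima.
#'
#' @param tac A [tac()] with at least 5 frames.
#' @param schedule Optional [acquisition_schedule()]; checked for consistency
#'   with the TAC's own frame bounds.
#' @param constraints A [fit_constraints()] with `mode = "fixed"`.
#' @param weights `NULL` (unweighted, the default), `"poisson"`
#'   (inverse-variance weights for counting noise), or a numeric vector.
#' @return A `fit_result`.
#' @export
#' @examples
#' m <- multiexp_model(c(0.32, 0.65, 0.03), c(20.39, 2.04, 9.97))
#' y <- predicted_tac(m, acquisition_schedule())
#' fit_fixed(y)$normalized_fractions
fit_fixed <- function(tac, schedule = NULL,
                      constraints = fit_constraints("fixed"),
                      weights = NULL) {
  stopifnot(inherits(tac, "tac"), inherits(constraints, "fit_constraints"))
  if (constraints$mode != "fixed") stop_input("constraints must have mode='fixed'")
  fb <- fit_frame_bounds(tac, schedule)
  n <- nrow(fb)
  if (n < 5) stop_input("fixed-mode fit needs >= 5 frames, got %d", n)
  y <- tac$values
  w <- resolve_weights(weights, y)
  k <- constraints$n_components
  Tk <- constraints$fixed_half_lives
  A <- cbind(frame_basis(Tk, fb), 1)
  sw <- sqrt(w)
  x <- nnls_solve(A * sw, y * sw)
  fitted <- as.numeric(A %*% x)
  resid <- y - fitted
  new_fit_result(amplitudes = x[seq_len(k)], half_lives = Tk,
                 constant = x[k + 1], labels = constraints$labels,
                 identified = rep(TRUE, k),
                 residuals = resid, fitted = fitted,
                 sse = sum(w * resid^2), mode = "fixed",
                 n_starts_used = 1L, n_frames = n)
}

# Weighted residual vector for a free-mode parameter vector
# theta = (S_1..S_k, T_1..T_k, K).
free_resid_fn <- function(theta, k, fb, y, sw) {
  S <- theta[seq_len(k)]
  Tk <- theta[k + seq_len(k)]
  K <- theta[2 * k + 1]
  (as.numeric(frame_basis(Tk, fb) %*% S) + K - y) * sw
}

# Peak contribution of each component to the frame-averaged signal.
component_contrib <- function(theta, k, fb) {
  B <- frame_basis(theta[k + seq_len(k)], fb)
  theta[seq_len(k)] * apply(B, 2, max)
}

# Analytic Jacobian of the weighted residuals; the exact derivative keeps
# Levenberg-Marquardt converging to machine precision where the
# finite-difference default stalls on this ill-conditioned problem.
free_jac_fn <- function(theta, k, fb, y, sw) {
  S <- theta[seq_len(k)]
  Tk <- theta[k + seq_len(k)]
  a <- fb[, 1]; b <- fb[, 2]; d <- b - a
  B <- frame_basis(Tk, fb)
  dB <- sapply(seq_len(k), function(j) {
    T <- Tk[j]
    ea <- 2^(-a / T); eb <- 2^(-b / T)
    (ea - eb) / (log(2) * d) + (a * ea - b * eb) / (T * d)
  })
  cbind(B, sweep(dB, 2, S, `*`), 1) * sw
}

#' Free-half-life fit of a time-activity curve
#'
#' Estimates amplitudes, half-lives and the constant jointly, all
#' non-negative, by bounded Levenberg-Marquardt least squares. Because a
#' three-exponential fit is ill-conditioned, a multi-start grid is used: the
#' half-lives are initialised at the physical values of the activation
#' products and at 0.5x and 2x each (all combinations), with amplitudes
#' warm-started by a fixed-half-life solve at each grid point; the lowest
#' objective wins, ties broken in favour of fewer non-zero components. After
#' each local fit the amplitudes are re-solved exactly at the final
#' half-lives. Components are returned sorted by descending half-life;
#' components with amplitude 0 carry no half-life information and are
#' flagged unidentified.
#'
#' @inheritParams fit_fixed
#' @param constraints A [fit_constraints()] with `mode = "free"`.
#' @param extra_starts Optional matrix of additional half-life start vectors
#'   (rows of length `n_components`).
#' @return A `fit_result`.
#' @export
fit_free <- function(tac, schedule = NULL,
                     constraints = fit_constraints("free"),
                     weights = NULL, extra_starts = NULL) {
  stopifnot(inherits(tac, "tac"), inherits(constraints, "fit_constraints"))
  if (constraints$mode != "free") stop_input("constraints must have mode='free'")
  fb <- fit_frame_bounds(tac, schedule)
  n <- nrow(fb)
  k <- constraints$n_components
  if (n < 2 * k + 1) {
    stop_input("free-mode fit needs >= %d frames for %d components, got %d",
               2 * k + 1, k, n)
  }
  y <- tac$values
  w <- resolve_weights(weights, y)
  sw <- sqrt(w)

  if (all(y == 0)) {
    return(new_fit_result(amplitudes = rep(0, k),
                          half_lives = constraints$fixed_half_lives,
                          constant = 0, labels = rep(NA_character_, k),
                          identified = rep(FALSE, k),
                          residuals = y, fitted = y, sse = 0, mode = "free",
                          n_starts_used = 0L, n_frames = n))
  }

  anchors <- constraints$fixed_half_lives
  grids <- lapply(anchors, function(a) a * c(0.5, 1, 2))
  starts <- as.matrix(expand.grid(grids))
  # global screen: score a wider coarse half-life grid by its exact NNLS
  # objective and promote the best combinations to full local fits, so the
  # optimiser cannot be trapped away from, e.g., a sub-minute component
  g <- sort(unique(as.numeric(outer(anchors, c(0.25, 0.5, 1, 2, 4)))))
  g <- unique(pmax(g, constraints$half_life_lower))
  if (length(g) >= k) {
    combos <- utils::combn(g, k)
    screen <- apply(combos, 2, function(Tk) {
      A <- cbind(frame_basis(Tk, fb), 1) * sw
      x <- nnls_solve(A, y * sw)
      sum((y * sw - A %*% x)^2)
    })
    top <- combos[, order(screen)[seq_len(min(5, ncol(combos)))], drop = FALSE]
    starts <- rbind(starts, t(top))
  }
  if (!is.null(extra_starts)) starts <- rbind(starts, as.matrix(extra_starts))

  lower <- c(rep(constraints$amplitude_lower, k),
             rep(constraints$half_life_lower, k), 0)
  upper <- c(rep(Inf, k), rep(1e4, k), Inf)

  best <- NULL
  n_ok <- 0L
  diag_msgs <- character(0)
  # variable-projection residual: amplitudes and K are solved exactly by
  # NNLS at each candidate half-life vector, so the nonlinear search runs
  # over the k half-lives only -- far better conditioned than the joint
  # (S, T, K) surface
  vp_resid <- function(Tk) {
    A <- cbind(frame_basis(Tk, fb), 1) * sw
    x <- nnls_solve(A, y * sw)
    as.numeric(A %*% x) - y * sw
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  for (s in seq_len(nrow(starts))) {
    T0 <- pmax(starts[s, ], constraints$half_life_lower)
    # warnings about exhausted iterations in individual exploratory starts
    # are expected; convergence is judged on the pooled objective instead
    fit <- tryCatch(suppressWarnings({
      vp <- minpack.lm::nls.lm(par = T0, lower = lower[k + seq_len(k)],
                               upper = upper[k + seq_len(k)],
                               fn = vp_resid, control = ctrl)
      # full-parameter polish from the projected solution, with the
      # analytic Jacobian, to finish off the last digits
      A0 <- cbind(frame_basis(vp$par, fb), 1)
      x0 <- nnls_solve(A0 * sw, y * sw)
      theta0 <- c(x0[seq_len(k)], vp$par, x0[k + 1])
      minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                         fn = free_resid_fn, jac = free_jac_fn,
                         k = k, fb = fb, y = y, sw = sw, control = ctrl)
    }), error = function(e) e)
    if (inherits(fit, "error")) {
      diag_msgs <- c(diag_msgs, conditionMessage(fit))
      next
    }
    theta <- fit$par
    sse <- sum(free_resid_fn(theta, k, fb, y, sw)^2)
    # amplitude polish: re-solve (S, K) exactly at the converged half-lives,
    # kept only if it does not worsen the objective
    Tk <- theta[k + seq_len(k)]
    A1 <- cbind(frame_basis(Tk, fb), 1)
    x1 <- nnls_solve(A1 * sw, y * sw)
    theta1 <- c(x1[seq_len(k)], Tk, x1[k + 1])
    sse1 <- sum(free_resid_fn(theta1, k, fb, y, sw)^2)
    if (sse1 <= sse) {
      theta <- theta1
      sse <- sse1
    }
    n_ok <- n_ok + 1L
    nz <- sum(component_contrib(theta, k, fb) > 1e-9 * max(y))
    cand <- list(theta = theta, sse = sse, nz = nz)
    if (is.null(best) || sse < best$sse * (1 - 1e-9) ||
        (abs(sse - best$sse) <= 1e-9 * max(best$sse, 1e-300) && nz < best$nz)) {
      best <- cand
    }
  }
  if (n_ok == 0L) {
    stop_fit("no free-fit start converged (%d starts); first error: %s",
             nrow(starts), if (length(diag_msgs)) diag_msgs[1] else "none")
  }

  S <- best$theta[seq_len(k)]
  Tk <- best$theta[k + seq_len(k)]
  K <- best$theta[2 * k + 1]
  # components contributing a negligible share of the measured signal are
  # unidentified: amplitude reported as exactly 0, half-life is noise.
  # The test is on the contribution (amplitude x basis column), not the raw
  # amplitude: a short-half-life component can carry an enormous amplitude
  # at the reference time yet add almost nothing inside the scan window
  zero <- component_contrib(best$theta, k, fb) <= 1e-6 * max(y)
  S[zero] <- 0
  ord <- order(Tk, decreasing = TRUE)
  S <- S[ord]; Tk <- Tk[ord]; zero <- zero[ord]
  fitted <- as.numeric(frame_basis(Tk, fb) %*% S) + K
  resid <- y - fitted
  new_fit_result(amplitudes = S, half_lives = Tk, constant = K,
                 labels = rep(NA_character_, k), identified = !zero,
                 residuals = resid, fitted = fitted,
                 sse = sum(w * resid^2), mode = "free",
                 n_starts_used = n_ok, n_frames = n)
}

#' Recompute normalized count-rate fractions
#'
#' The fractions are `S_k / sum(S)`; the constant `K` is excluded from the
#' denominator. When all amplitudes are zero the fractions are undefined and
#' flagged as such (`fractions_defined = FALSE`), not an error.
#'
#' @param result A `fit_result`.
#' @return The result with `normalized_fractions` and `fractions_defined`
#'   refreshed.
#' @export
normalize_amplitudes <- function(result) {
  stopifnot(inherits(result, "fit_result"))
  total <- sum(result$amplitudes)
  if (total > 0) {
    result$normalized_fractions <- result$amplitudes / total
    result$fractions_defined <- TRUE
  } else {
    result$normalized_fractions <- rep(NA_real_, length(result$amplitudes))
    result$fractions_defined <- FALSE
  }
  result
}

# Free parameters of a fit, as (values, residual function, names).
fit_parameterization <- function(result, fb, y, sw) {
  k <- length(result$amplitudes)
  if (result$mode == "fixed") {
    list(par = c(result$amplitudes, result$constant),
         names = c(paste0("S", seq_len(k)), "K"),
         fn = function(p) {
           (as.numeric(frame_basis(result$half_lives, fb) %*% p[seq_len(k)]) +
              p[k + 1] - y) * sw
         })
  } else {
    idf <- which(result$identified)
    list(par = c(result$amplitudes, result$half_lives[idf], result$constant),
         names = c(paste0("S", seq_len(k)), paste0("T", idf), "K"),
         fn = function(p) {
           Tk <- result$half_lives
           Tk[idf] <- p[k + seq_along(idf)]
           (as.numeric(frame_basis(Tk, fb) %*% p[seq_len(k)]) +
              p[k + length(idf) + 1] - y) * sw
         })
  }
}

num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

#' 95% confidence intervals for fitted parameters
#'
#' Two methods. `"linearized"` (default): the covariance of the estimates is
#' approximated by `sigma^2 (J'J)^-1` with `J` the Jacobian of the model at
#' the optimum and `sigma^2` the residual variance; intervals use the t
#' quantile with `n - p` degrees of freedom. `"bootstrap"`: parametric
#' resampling -- synthetic curves are drawn from the fitted model with
#' Gaussian noise at the estimated residual standard deviation, refit, and
#' the percentile interval taken; reproducible for a fixed `seed`.
#' A singular Jacobian (e.g. a component pinned at zero) flags the intervals
#' unreliable rather than raising an error.
#'
#' @param result A converged `fit_result`.
#' @param tac,schedule The data the result was fitted to.
#' @param method `"linearized"` or `"bootstrap"`.
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param seed RNG seed for the bootstrap.
#' @param level Confidence level (default 0.95).
#' @return The result with `ci95` (matrix with columns `lower`, `upper`),
#'   `ci_method` and `ci_reliable` filled in.
#' @export
confidence_intervals <- function(result, tac, schedule = NULL,
                                 method = c("linearized", "bootstrap"),
                                 n_boot = 200, seed = NULL, level = 0.95) {
  stopifnot(inherits(result, "fit_result"), inherits(tac, "tac"))
  method <- match.arg(method)
  fb <- fit_frame_bounds(tac, schedule)
  y <- tac$values
  sw <- rep(1, length(y))
  par <- fit_parameterization(result, fb, y, sw)
  n <- length(y)
  p <- length(par$par)
  dof <- n - p
  if (method == "linearized") {
    if (dof <= 0) {
      result$ci95 <- matrix(NA_real_, p, 2,
                            dimnames = list(par$names, c("lower", "upper")))
      result$ci_method <- method
      result$ci_reliable <- FALSE
      return(result)
    }
    sigma2 <- result$sse / dof
    J <- num_jacobian(par$fn, par$par)
    JtJ <- crossprod(J)
    reliable <- TRUE
    cv <- tryCatch(solve(JtJ), error = function(e) NULL)
    if (is.null(cv) || !all(is.finite(cv))) {
      reliable <- FALSE
      sv <- svd(JtJ)
      pos <- sv$d > max(sv$d) * 1e-12
      cv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    }
    se <- sqrt(pmax(diag(cv), 0) * sigma2)
    tq <- qt((1 + level) / 2, dof)
    ci <- cbind(lower = par$par - tq * se, upper = par$par + tq * se)
    rownames(ci) <- par$names
    result$ci95 <- ci
    result$ci_method <- method
    result$ci_reliable <- reliable
    return(result)
  }
  # parametric bootstrap
  if (dof <= 0) dof <- 1
  sigma <- sqrt(result$sse / dof)
  refit <- function(yb) {
    tb <- tac(fb, pmax(yb, 0), voi_label = tac$voi_label)
    if (result$mode == "fixed") {
      r <- fit_fixed(tb, constraints = fit_constraints(
        "fixed", fixed_half_lives = result$half_lives))
      c(r$amplitudes, r$constant)
    } else {
      r <- fit_free(tb, constraints = fit_constraints(
        "free", fixed_half_lives = ifelse(result$identified,
                                          result$half_lives, 2)),
        extra_starts = matrix(result$half_lives, nrow = 1))
      idf <- which(result$identified)
      c(r$amplitudes, r$half_lives[idf], r$constant)
    }
  }
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      refit(result$fitted + rnorm(n, 0, sigma))
    }, numeric(p))
  })
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  dimnames(ci) <- list(par$names, c("lower", "upper"))
  result$ci95 <- ci
  result$ci_method <- method
  result$ci_reliable <- TRUE
  result
}

#' Coarse grid-search reference optimum
#'
#' Exhaustively evaluates the constrained objective on a user-supplied grid
#' of half-life combinations, solving the amplitudes and constant exactly by
#' non-negative linear least squares at every grid point, and returns the
#' grid optimum. This is a slow, transparent reference against which the
#' nonlinear optimiser can be checked: the optimiser's objective must never
#' exceed the grid's.
#'
#' @param tac A [tac()].
#' @param schedule Optional [acquisition_schedule()].
#' @param half_life_grid Numeric vector of candidate half-lives (minutes).
#' @param n_components Components per combination (default 3).
#' @param max_evals Refuse grids with more combinations than this.
#' @return A list with `amplitudes`, `half_lives`, `constant`, `sse`.
#' @export
grid_search_oracle <- function(tac, schedule = NULL, half_life_grid,
                               n_components = 3, max_evals = 2e5) {
  stopifnot(inherits(tac, "tac"))
  fb <- fit_frame_bounds(tac, schedule)
  g <- sort(unique(half_life_grid))
  if (any(g <= 0)) stop_input("half-life grid values must be > 0")
  n_comb <- choose(length(g), n_components)
  if (n_comb > max_evals) {
    stop_input("grid has %g combinations, above the %g limit; coarsen it",
               n_comb, max_evals)
  }
  if (n_comb < 1) stop_input("grid smaller than n_components")
  y <- tac$values
  combos <- utils::combn(g, n_components)
  best <- NULL
  for (i in seq_len(ncol(combos))) {
    Tk <- combos[, i]
    A <- cbind(frame_basis(Tk, fb), 1)
    x <- nnls_solve(A, y)
    sse <- sum((y - as.numeric(A %*% x))^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(amplitudes = x[seq_len(n_components)], half_lives = Tk,
                   constant = x[n_components + 1], sse = sse)
    }
  }
  best
}
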