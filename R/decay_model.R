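#' Multi-exponential decay model of an activated-tissue count rate
#'
#' The measured count rate in an irradiated volume, with biological washout
#' neglected, is a sum of exponentially decaying components plus a constant:
#' \deqn{S(t) = \sum_k S_k \, 2^{-t/T_{1/2,k}} + K}
#' where each amplitude `S_k` is the component's count rate at the reference
#' time (end of irradiation) and `T_(1/2,k)` its physical half-life in
#' minutes. `K` absorbs any non-decaying background.
#'
#' @param amplitudes Numeric vector of component amplitudes, all >= 0.
#' @param half_lives Numeric vector of half-lives (minutes), all > 0, same
#'   length as `amplitudes`.
#' @param constant Constant background K (>= 0, same units as the rate).
#' @param reference_time Time (minutes since end of irradiation) at which the
#'   amplitudes are defined; 0 = beam-off, the package-wide convention.
#' @param labels Optional character vector of nuclide symbols per component.
#' @return An object of class `multiexp_model`.
#' @export
#' @examples
#' m <- multiexp_model(c(0.32, 0.65, 0.03), c(20.39, 2.04, 9.97))
#' model_rate(m, 7)
multiexp_model <- function(amplitudes, half_lives, constant = 0,
                           reference_time = 0, labels = NULL) {
  if (length(amplitudes) == 0) stop_input("model needs at least one component")
  if (length(amplitudes) != length(half_lives)) {
    stop_input("amplitudes and half_lives differ in length (%d vs %d)",
               length(amplitudes), length(half_lives))
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    stop_input("amplitudes must be finite and >= 0")
  }
  if (any(!is.finite(half_lives)) || any(half_lives <= 0)) {
    stop_input("half-lives must be finite and > 0")
  }
  if (!is.finite(constant) || constant < 0) {
    stop_input("constant K must be finite and >= 0")
  }
  if (!is.null(labels) && length(labels) != length(amplitudes)) {
    stop_input("labels must match the number of components")
  }
  structure(list(amplitudes = as.numeric(amplitudes),
                 half_lives = as.numeric(half_lives),
                 constant = as.numeric(constant),
                 reference_time = as.numeric(reference_time),
                 labels = labels),
            class = "multiexp_model")
}

#' @export
print.multiexp_model <- function(x, ...) {
  lab <- if (is.null(x$labels)) rep("", length(x$amplitudes)) else x$labels
  cat("<multiexp_model> S(t) = sum_k S_k 2^(-t/T_k) + K\n")
  for (k in seq_along(x$amplitudes)) {
    cat(sprintf("  S=%.6g  T1/2=%.4g min  %s\n",
                x$amplitudes[k], x$half_lives[k], lab[k]))
  }
  cat(sprintf("  K=%.6g, reference time %.3g min\n", x$constant, x$reference_time))
  invisible(x)
}

#' Acquisition schedule of a dynamic PET scan
#'
#' Frame boundaries are expressed in minutes since the end of irradiation.
#' The default replicates a 15-frame, 2-minute-frame protocol starting after
#' a 7-minute patient transport from the treatment unit to the scanner.
#'
#' @param transport_delay Minutes between end of irradiation and the first
#'   frame start (default 7).
#' @param n_frames Number of frames (default 15); ignored when `frame_bounds`
#'   is given.
#' @param frame_length Frame duration in minutes (default 2); ignored when
#'   `frame_bounds` is given.
#' @param frame_bounds Optional n x 2 matrix of explicit `[start, end]`
#'   frame boundaries (minutes since end of irradiation).
#' @return An object of class `acquisition_schedule`.
#' @export
acquisition_schedule <- function(transport_delay = 7, n_frames = 15,
                                 frame_length = 2, frame_bounds = NULL) {
  if (is.null(frame_bounds)) {
    starts <- transport_delay + frame_length * (seq_len(n_frames) - 1)
    frame_bounds <- cbind(start = starts, end = starts + frame_length)
  } else {
    frame_bounds <- as.matrix(frame_bounds)
    if (ncol(frame_bounds) != 2) stop_input("frame_bounds must have 2 columns")
    colnames(frame_bounds) <- c("start", "end")
    transport_delay <- frame_bounds[1, 1]
  }
  validate_frame_bounds(frame_bounds)
  structure(list(transport_delay = transport_delay,
                 frame_bounds = frame_bounds),
            class = "acquisition_schedule")
}

validate_frame_bounds <- function(fb) {
  if (nrow(fb) == 0) stop_input("schedule needs at least one frame")
  if (any(!is.finite(fb))) stop_input("frame bounds must be finite")
  if (any(fb[, 2] <= fb[, 1])) {
    stop_input("every frame must end strictly after it starts")
  }
  if (nrow(fb) > 1 && any(fb[-1, 1] < fb[-nrow(fb), 2] - 1e-12)) {
    stop_input("frames must be non-overlapping and strictly increasing")
  }
  if (any(fb < 0)) stop_input("frame bounds must be non-negative")
  invisible(fb)
}

#' Decay constant from a half-life
#'
#' @param half_life Half-life in minutes (> 0).
#' @return lambda = ln(2) / half_life, in 1/min.
#' @export
decay_constant <- function(half_life) {
  if (any(!is.finite(half_life)) || any(half_life <= 0)) {
    stop_input("half-life must be finite and > 0")
  }
  log(2) / half_life
}

#' Decay-correct a rate across a time offset
#'
#' Maps a rate measured `delta_t` minutes after the reference time back to
#' the reference time: multiply by `2^(delta_t / half_life)`. A negative
#' `delta_t` decays the value forward instead. Used to express amplitudes at
#' beam-off when the scan starts only after the patient transport.
#'
#' @param amplitude Measured rate.
#' @param half_life Half-life in minutes (> 0).
#' @param delta_t Offset in minutes between measurement and reference time.
#' @export
#' @examples
#' decay_correct(1, 2.04, 7)  # 15O decays ~10.8-fold over a 7-min transport
decay_correct <- function(amplitude, half_life, delta_t) {
  if (any(!is.finite(half_life)) || any(half_life <= 0)) {
    stop_input("half-life must be finite and > 0")
  }
  amplitude * 2^(delta_t / half_life)
}

#' Instantaneous model count rate
#'
#' @param model A [multiexp_model()].
#' @param t Time(s) in minutes since the model's reference time; must be
#'   >= 0 (the model describes decay after beam-off only).
#' @return Numeric vector of rates.
#' @export
model_rate <- function(model, t) {
  stopifnot(inherits(model, "multiexp_model"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop_input("t must be finite and >= 0 (minutes after the reference time)")
  }
  expo <- outer(t, model$half_lives, function(tt, T) 2^(-tt / T))
  drop(expo %*% model$amplitudes) + model$constant
}

#' Frame-averaged model count rate
#'
#' PET frame values are time integrals of the count rate divided by the
#' frame duration, not midpoint samples; with a 2.04-min component and 2-min
#' frames the two differ materially, so the whole package uses the integral
#' convention. Closed form per component:
#' `S_k * T_k / (ln2 * dur) * (2^(-start/T_k) - 2^(-end/T_k))`.
#'
#' @param model A [multiexp_model()].
#' @param frame Either a length-2 vector `[start, end]` or an n x 2 matrix of
#'   frame bounds (minutes since the reference time), with `end > start >= 0`.
#' @return One mean rate per frame.
#' @export
frame_mean_rate <- function(model, frame) {
  stopifnot(inherits(model, "multiexp_model"))
  fb <- if (is.matrix(frame)) frame else matrix(frame, ncol = 2)
  if (any(!is.finite(fb)) || any(fb < 0)) {
    stop_input("frame bounds must be finite and >= 0")
  }
  if (any(fb[, 2] <= fb[, 1])) {
    stop_input("frame must have end > start (zero-length frames are undefined)")
  }
  frame_basis(model$half_lives, fb) %*% model$amplitudes + model$constant
}

# Basis matrix of frame-averaged unit-amplitude exponentials: one column per
# half-life, rows are frames. Shared by the forward model and the fitter so
# both sides use the same frame-integral convention.
frame_basis <- function(half_lives, frame_bounds) {
  dur <- frame_bounds[, 2] - frame_bounds[, 1]
  sapply(half_lives, function(T) {
    T / (log(2) * dur) * (2^(-frame_bounds[, 1] / T) - 2^(-frame_bounds[, 2] / T))
  })
}

#' Noiseless predicted time-activity curve
#'
#' @param model A [multiexp_model()].
#' @param schedule An [acquisition_schedule()].
#' @param voi_label Label carried on the returned curve.
#' @return A [tac()] with one frame-averaged rate per frame.
#' @export
predicted_tac <- function(model, schedule, voi_label = "predicted") {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  fb <- schedule$frame_bounds - model$reference_time
  tac(schedule$frame_bounds, as.numeric(frame_mean_rate(model, fb)),
      voi_label = voi_label)
}
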