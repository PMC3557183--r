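#' Specification of a synthetic activated-tissue acquisition
#'
#' Describes everything needed to generate a time-activity curve (or a small
#' 4-D phantom) with the statistical structure the analysis assumes: a tissue
#' composition that sets the component amplitudes, the acquisition schedule,
#' an optional non-decaying background, optional contaminant components
#' (e.g. 30P from bone at 2.5 min), and Poisson counting noise at a
#' configurable count level. The induced activity seen minutes after a
#' photon treatment is very low -- on the order of a twentieth of a standard
#' FDG scan's -- so the Poisson regime, not a Gaussian approximation, is
#' what the generator reproduces.
#'
#' @param tissue Bundled tissue name (amplitudes from its H-omitted
#'   composition), or `NULL` when `composition` is given.
#' @param composition Named numeric of element fractions over C/N/O (unit
#'   fractions), used instead of `tissue`.
#' @param yield_weights Optional named per-element weights; component
#'   amplitude is fraction x weight, renormalized. Default all 1.
#' @param amplitude_scale Expected total counts per unit (rate x minutes);
#'   higher means lower relative Poisson noise. Must be > 0 under Poisson
#'   noise.
#' @param background_K Constant background rate (default 0).
#' @param schedule An [acquisition_schedule()] (default: 7-min transport,
#'   15 x 2-min frames).
#' @param contaminants Optional list of `list(amplitude=, half_life=,
#'   label=)` extra components appended to the model.
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed; mandatory when `noise != "none"`.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(tissue = NULL, composition = NULL,
                            yield_weights = NULL, amplitude_scale = 1e4,
                            background_K = 0,
                            schedule = acquisition_schedule(),
                            contaminants = NULL,
                            noise = c("none", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  if (is.null(tissue) && is.null(composition)) {
    stop_input("give either a bundled tissue name or an explicit composition")
  }
  if (!is.null(composition)) {
    if (is.null(names(composition)) ||
        !all(names(composition) %in% c("C", "N", "O"))) {
      stop_input("explicit composition must be named over C, N, O")
    }
    if (abs(sum(composition) - 1) > 0.01) {
      stop_input("composition fractions must sum to 1 (got %.4f)",
                 sum(composition))
    }
  }
  if (noise != "none") {
    if (is.null(seed)) stop_input("a seed is mandatory when noise != 'none'")
    if (!is.finite(amplitude_scale) || amplitude_scale <= 0) {
      stop_input("amplitude_scale must be > 0 under Poisson noise")
    }
  }
  if (!is.finite(background_K) || background_K < 0) {
    stop_input("background_K must be >= 0")
  }
  stopifnot(inherits(schedule, "acquisition_schedule"))
  structure(list(tissue = tissue, composition = composition,
                 yield_weights = yield_weights,
                 amplitude_scale = amplitude_scale,
                 background_K = background_K, schedule = schedule,
                 contaminants = contaminants, noise = noise, seed = seed),
            class = "simulation_spec")
}

#' Decay model implied by a tissue composition
#'
#' One component per element present, amplitude = mass fraction x yield
#' weight (renormalized over the elements), half-life from the nuclide
#' table (C -> 11C, O -> 15O, N -> 13N); contaminant components are appended
#' as given and the background becomes the model constant.
#'
#' @param spec A [simulation_spec()].
#' @param nuclide_tab A [nuclide_table()].
#' @return A [multiexp_model()] with reference time 0 (end of irradiation).
#' @export
#' @examples
#' composition_to_model(simulation_spec(tissue = "urinary_bladder_filled"))
composition_to_model <- function(spec, nuclide_tab = default_nuclide_table()) {
  stopifnot(inherits(spec, "simulation_spec"))
  comp <- if (!is.null(spec$composition)) spec$composition else
    get_adjusted_composition(spec$tissue)$fractions
  bad <- setdiff(names(comp), c("C", "N", "O"))
  if (length(bad)) {
    stop_input("no activation product known for element(s): %s",
               paste(bad, collapse = ", "))
  }
  el2sym <- c(C = "C11", O = "O15", N = "N13")
  # canonical order C, O, N (slow, fast, intermediate)
  els <- intersect(c("C", "O", "N"), names(comp))
  amp <- comp[els]
  if (!is.null(spec$yield_weights)) {
    wy <- setNames(rep(1, length(els)), els)
    wy[intersect(names(spec$yield_weights), els)] <-
      spec$yield_weights[intersect(names(spec$yield_weights), els)]
    amp <- amp * wy
  }
  amp <- amp / sum(amp)
  hl <- vapply(el2sym[els], function(s) get_nuclide(s, nuclide_tab)$half_life,
               numeric(1))
  labels <- unname(el2sym[els])
  if (!is.null(spec$contaminants)) {
    for (cc in spec$contaminants) {
      amp <- c(amp, cc$amplitude)
      hl <- c(hl, cc$half_life)
      labels <- c(labels, if (!is.null(cc$label)) cc$label else NA_character_)
    }
  }
  multiexp_model(unname(amp), unname(hl), constant = spec$background_K,
                 reference_time = 0, labels = labels)
}

#' Simulate a time-activity curve
#'
#' Noiseless curves are exactly the frame-averaged model prediction. Under
#' Poisson noise, each frame's expected count is `amplitude_scale x mean
#' rate x frame duration`; a Poisson draw is converted back to a rate
#' (counts / duration / amplitude_scale), so the noiseless curve is the
#' expectation of the noisy one. Identical seeds give identical curves.
#'
#' @param spec A [simulation_spec()].
#' @param nuclide_tab A [nuclide_table()].
#' @param voi_label Label for the returned curve.
#' @return A [tac()].
#' @export
simulate_tac <- function(spec, nuclide_tab = default_nuclide_table(),
                         voi_label = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(voi_label)) {
    voi_label <- if (!is.null(spec$tissue)) spec$tissue else "synthetic"
  }
  model <- composition_to_model(spec, nuclide_tab)
  clean <- predicted_tac(model, spec$schedule, voi_label = voi_label)
  if (spec$noise == "none") return(clean)
  dur <- clean$frame_bounds[, 2] - clean$frame_bounds[, 1]
  mu <- spec$amplitude_scale * clean$values * dur
  counts <- with_seed(spec$seed, rpois(length(mu), mu))
  tac(clean$frame_bounds, counts / (dur * spec$amplitude_scale),
      voi_label = voi_label)
}

#' Simulate a two-region 4-D phantom
#'
#' A desk-scale miniature of the imaging situation: a central sphere follows
#' one tissue's decay model (the bladder-like region) and a surrounding
#' spherical shell another's (the subcutaneous-fat-like region at the beam
#' entrances); background voxels are zero. Each region's voxels share the
#' region TAC; under Poisson noise every voxel gets independent draws at the
#' spec's count scale. The two regions are disjoint by construction and an
#' overlap raises an error.
#'
#' @param spec_fat [simulation_spec()] for the shell region.
#' @param spec_bladder [simulation_spec()] for the central sphere.
#' @param grid Length-3 integer vector of volume dimensions (each <= 64).
#' @param voxel_mm Voxel size in mm.
#' @return List with `volume` ([dynamic_volume()]), `mask_fat`, and
#'   `mask_bladder` ([voi_mask()]s).
#' @export
simulate_phantom <- function(spec_fat, spec_bladder, grid = c(16, 16, 16),
                             voxel_mm = 4) {
  stopifnot(inherits(spec_fat, "simulation_spec"),
            inherits(spec_bladder, "simulation_spec"))
  if (length(grid) != 3 || any(grid < 4) || any(grid > 64)) {
    stop_input("grid must be 3 dimensions, each in 4..64")
  }
  if (!isTRUE(all.equal(spec_fat$schedule$frame_bounds,
                        spec_bladder$schedule$frame_bounds))) {
    stop_input("both regions must share one acquisition schedule")
  }
  ctr <- (grid + 1) / 2
  r <- sqrt(outer(
    outer((seq_len(grid[1]) - ctr[1])^2, (seq_len(grid[2]) - ctr[2])^2, "+"),
    (seq_len(grid[3]) - ctr[3])^2, "+"))
  rmax <- min(grid) / 2
  m_bladder <- r <= 0.35 * rmax
  m_fat <- r > 0.6 * rmax & r <= 0.9 * rmax
  if (any(m_bladder & m_fat)) stop_input("phantom regions overlap")

  tac_fat <- simulate_tac(spec_fat, voi_label = "fat")
  tac_bladder <- simulate_tac(spec_bladder, voi_label = "bladder")
  fb <- spec_fat$schedule$frame_bounds
  n_fr <- nrow(fb)
  vol <- array(0, dim = c(grid, n_fr))

  fill <- function(vol, mask, spec, region_tac, seed_offset) {
    idx <- which(mask)
    clean <- predicted_tac(composition_to_model(spec), spec$schedule)
    for (f in seq_len(n_fr)) {
      frame <- vol[, , , f]
      if (spec$noise == "none") {
        frame[idx] <- clean$values[f]
      } else {
        dur <- fb[f, 2] - fb[f, 1]
        mu <- spec$amplitude_scale * clean$values[f] * dur
        frame[idx] <- with_seed(spec$seed + seed_offset + f,
                                rpois(length(idx), mu)) /
          (dur * spec$amplitude_scale)
      }
      vol[, , , f] <- frame
    }
    vol
  }
  vol <- fill(vol, m_fat, spec_fat, tac_fat, 0L)
  vol <- fill(vol, m_bladder, spec_bladder, tac_bladder, 10000L)

  list(volume = dynamic_volume(vol, fb, voxel_mm = voxel_mm),
       mask_fat = voi_mask(m_fat, "fat"),
       mask_bladder = voi_mask(m_bladder, "bladder"))
}
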