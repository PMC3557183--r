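#' Hydrogen-omitted renormalization of an elemental composition
#'
#' Hydrogen undergoes no (gamma,n) activation to a positron emitter, so a
#' count-rate analysis can only see the C, N and O content of a tissue. This
#' drops hydrogen and every trace element from a raw mass-fraction table and
#' renormalizes C, N and O over their own sum. The operation is idempotent
#' and invariant to a uniform rescaling of the input (percent vs unit
#' fractions both work).
#'
#' @param x Named numeric vector of elemental mass fractions (must contain
#'   `C`, `N` and `O`), or a [composition_table()].
#' @param tissue_name Label for the result; defaults to the input's when `x`
#'   is a `composition_table`, else `""`.
#' @return A [composition_table()] with `adjusted = TRUE`.
#' @export
#' @examples
#' h_adjust(c(H = 11.4, C = 59.8, N = 0.7, O = 27.8))$fractions
h_adjust <- function(x, tissue_name = NULL) {
  if (inherits(x, "composition_table")) {
    if (is.null(tissue_name)) tissue_name <- x$tissue_name
    x <- x$fractions
  }
  if (is.null(tissue_name)) tissue_name <- ""
  if (is.null(names(x))) stop_input("composition must be a named vector")
  missing <- setdiff(c("C", "N", "O"), names(x))
  if (length(missing)) {
    stop_input("composition lacks element(s): %s (use an explicit 0)",
               paste(missing, collapse = ", "))
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_input("fractions must be finite and non-negative")
  }
  cno <- x[c("C", "N", "O")]
  if (sum(cno) <= 0) stop_input("C+N+O is zero: nothing activates")
  composition_table(tissue_name, cno / sum(cno), adjusted = TRUE)
}

#' Map fitted count-rate fractions to an elemental composition
#'
#' Identifies each fitted component with the parent element of its nuclide
#' (11C -> C, 15O -> O, 13N -> N) and reads the normalized amplitude as that
#' element's fraction. Fixed-mode components carry their labels; free-mode
#' components are labelled by the nearest physical half-life within a
#' relative tolerance (default 35%: wide enough that fitted values like 19.4
#' or 20.9 min label as 11C and 1.99 or 2.01 min as 15O, and wide enough
#' that a 2.5-min 30P contaminant is absorbed into the 15O label, which is
#' physically unavoidable at these count levels). Components outside every
#' window are reported as unassigned.
#'
#' Optional per-element activation-yield weights undo a non-uniform
#' count-per-mass yield: element fraction proportional to amplitude/weight,
#' renormalized. The default (all 1) identifies count-rate fraction with
#' mass fraction directly.
#'
#' @param result A `fit_result` with defined fractions.
#' @param nuclide_tab A [nuclide_table()].
#' @param yield_weights Named numeric (element -> relative counts per unit
#'   mass fraction), default all 1.
#' @param label_tolerance Relative half-life window for free-mode labelling.
#' @return Named numeric of element fractions over C, N, O (summing to 1
#'   over assigned elements), with attribute `"unassigned"` holding the
#'   unassigned amplitude fraction.
#' @export
fractions_to_composition <- function(result,
                                     nuclide_tab = default_nuclide_table(),
                                     yield_weights = NULL,
                                     label_tolerance = 0.35) {
  stopifnot(inherits(result, "fit_result"))
  result <- normalize_amplitudes(result)
  if (!result$fractions_defined) {
    stop_input("all fitted amplitudes are zero; composition undefined")
  }
  k <- length(result$amplitudes)
  labels <- result$labels
  if (result$mode == "fixed") {
    if (any(is.na(labels))) {
      stop_fit("fixed-mode result lacks nuclide labels")  # internal invariant
    }
  } else {
    # candidate labels are the three analysis nuclides; bone products such
    # as 30P share no parent element with the model and are intentionally
    # absorbed by whichever window their half-life falls into
    cand <- nuclide_tab[nuclide_tab$parent_element %in% c("C", "N", "O"), ,
                        drop = FALSE]
    labels <- vapply(seq_len(k), function(i) {
      if (!result$identified[i]) return(NA_character_)
      rel <- abs(result$half_lives[i] - cand$half_life_min) /
        cand$half_life_min
      j <- which.min(rel)
      if (rel[j] <= label_tolerance) cand$symbol[j] else "unassigned"
    }, character(1))
  }
  elements <- c("C", "N", "O")
  out <- setNames(numeric(3), elements)
  unassigned <- 0
  for (i in seq_len(k)) {
    f <- result$normalized_fractions[i]
    if (f == 0) next
    lab <- labels[i]
    el <- if (!is.na(lab) && lab %in% nuclide_tab$symbol) {
      get_nuclide(lab, nuclide_tab)$parent_element
    } else NA_character_
    if (is.na(el) || !el %in% elements) {
      unassigned <- unassigned + f
    } else {
      out[el] <- out[el] + f
    }
  }
  if (!is.null(yield_weights)) {
    wy <- setNames(rep(1, 3), elements)
    wy[names(yield_weights)] <- yield_weights
    if (any(wy <= 0)) stop_input("yield weights must be > 0")
    out <- out / wy
  }
  if (sum(out) > 0) out <- out * (1 - unassigned) / sum(out)
  attr(out, "unassigned") <- unassigned
  out
}

#' Compare a fitted composition with a reference tissue
#'
#' Reports per-element differences (fitted minus reference) and, when the
#' fit carries confidence intervals on its normalized amplitudes, whether
#' each element's interval contains the reference value. No accept/reject
#' verdict is computed -- the comparison is descriptive.
#'
#' @param fitted Named numeric of element fractions (as returned by
#'   [fractions_to_composition()]), or a `fit_result`.
#' @param tissue A bundled tissue name (see [get_adjusted_composition()]) or
#'   a [composition_table()] (raw tables are H-adjusted first).
#' @param ci95 Optional 3 x 2 matrix of per-element 95% bounds on the fitted
#'   fractions (rows C, N, O).
#' @return An object of class `composition_comparison` with fields
#'   `tissue_name`, `fitted`, `reference`, `difference`, `ci95_overlap`,
#'   `missing_elements`.
#' @export
compare_to_reference <- function(fitted, tissue, ci95 = NULL) {
  if (inherits(fitted, "fit_result")) fitted <- fractions_to_composition(fitted)
  ref <- if (inherits(tissue, "composition_table")) {
    if (tissue$adjusted) tissue else h_adjust(tissue)
  } else {
    get_adjusted_composition(tissue)
  }
  elements <- c("C", "N", "O")
  missing_elements <- setdiff(elements, names(fitted))
  f <- setNames(numeric(3), elements)
  f[intersect(names(fitted), elements)] <-
    fitted[intersect(names(fitted), elements)]
  r <- ref$fractions[elements]
  overlap <- if (is.null(ci95)) {
    setNames(rep(NA, 3), elements)
  } else {
    setNames(r >= ci95[elements, 1] & r <= ci95[elements, 2], elements)
  }
  structure(list(tissue_name = ref$tissue_name, fitted = f, reference = r,
                 difference = f - r, ci95_overlap = overlap,
                 missing_elements = missing_elements),
            class = "composition_comparison")
}

#' @export
print.composition_comparison <- function(x, ...) {
  cat(format_comparison(x), sep = "\n")
  invisible(x)
}

# Plain-text table form of a comparison (used by print and the CLI report).
format_comparison <- function(x) {
  tab <- data.frame(element = names(x$fitted),
                    fitted = sprintf("%.4f", x$fitted),
                    reference = sprintf("%.4f", x$reference),
                    difference = sprintf("%+.4f", x$difference),
                    ci95_covers_ref = ifelse(is.na(x$ci95_overlap), "-",
                                             ifelse(x$ci95_overlap, "yes", "no")))
  out <- c(sprintf("Composition vs H-omitted reference '%s'", x$tissue_name),
           utils::capture.output(print(tab, row.names = FALSE)))
  if (length(x$missing_elements)) {
    out <- c(out, sprintf("note: element(s) %s absent from the fit (taken as 0)",
                          paste(x$missing_elements, collapse = ", ")))
  }
  out
}

comparison_to_list <- function(x) {
  list(tissue = x$tissue_name,
       fitted = as.list(x$fitted),
       reference = as.list(x$reference),
       difference = as.list(x$difference),
       ci95_overlap = as.list(x$ci95_overlap),
       missing_elements = x$missing_elements)
}
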