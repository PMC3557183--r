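#' Table of photonuclear activation products
#'
#' Loads the bundled table of positron-emitting activation products:
#' physical half-life (minutes), parent element and producing reaction.
#' The bundle covers 11C (20.39 min), 15O (2.04 min), 13N (9.97 min) --
#' the three nuclides the decay analysis resolves -- plus 30P (2.5 min) and
#' 39Ca (0.86 s), which matter only as potential contaminants from bone:
#' 39Ca decays away before any post-transport scan and 30P is too close in
#' half-life to 15O to separate.
#'
#' @param path Optional path to an alternative table in the same tab-separated
#'   format (columns `symbol`, `half_life_min`, `parent_element`, `reaction`;
#'   `#` comment lines allowed).
#' @return A data frame of class `nuclide_table`.
#' @export
#' @examples
#' nt <- nuclide_table()
#' get_nuclide("O15", nt)$half_life
nuclide_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nuclides.tsv", package = "photopet",
                        mustWork = TRUE)
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("symbol", "half_life_min", "parent_element")
  if (!all(need %in% names(tab))) {
    stop_input("nuclide table %s lacks columns: %s", path,
               paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (anyDuplicated(tab$symbol)) {
    stop_input("duplicate nuclide symbols in %s", path)
  }
  if (any(!is.finite(tab$half_life_min)) || any(tab$half_life_min <= 0)) {
    stop_input("nuclide half-lives must be finite and > 0")
  }
  structure(tab, class = c("nuclide_table", "data.frame"))
}

# Package-level cache of the bundled table (loaded once per session).
.photopet_cache <- new.env(parent = emptyenv())

default_nuclide_table <- function() {
  if (is.null(.photopet_cache$nuclides)) {
    .photopet_cache$nuclides <- nuclide_table()
  }
  .photopet_cache$nuclides
}

#' Look up one activation product
#'
#' @param symbol Nuclide symbol, e.g. `"C11"`, `"O15"`, `"N13"`.
#' @param table A [nuclide_table()]; defaults to the bundled one.
#' @return A list of class `nuclide` with fields `symbol`, `half_life`
#'   (minutes), `parent_element` and `reaction`.
#' @export
get_nuclide <- function(symbol, table = default_nuclide_table()) {
  i <- match(symbol, table$symbol)
  if (is.na(i)) {
    stop_input("unknown nuclide symbol '%s' (known: %s)", symbol,
               paste(table$symbol, collapse = ", "))
  }
  structure(
    list(symbol = table$symbol[i], half_life = table$half_life_min[i],
         parent_element = table$parent_element[i],
         reaction = if ("reaction" %in% names(table)) table$reaction[i] else NA_character_),
    class = "nuclide"
  )
}

#' Elemental composition table for one tissue
#'
#' A named vector of elemental mass fractions for one tissue, plus a flag
#' recording whether hydrogen (and trace elements) have already been removed
#' and C/N/O renormalized. Fractions are stored as unit fractions (0..1)
#' throughout the package; percent appears only at I/O boundaries.
#'
#' @param tissue_name Text label.
#' @param fractions Named numeric vector (element symbol -> mass fraction).
#'   Values may be given in percent; they are taken as-is, so divide by 100
#'   upstream if needed. All values must be non-negative.
#' @param adjusted Logical; `TRUE` means hydrogen-omitted C/N/O fractions
#'   summing to 1.
#' @return An object of class `composition_table`.
#' @export
composition_table <- function(tissue_name, fractions, adjusted = FALSE) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop_input("composition fractions must be a named vector")
  }
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop_input("composition fractions must be finite and non-negative")
  }
  if (adjusted) {
    if (!setequal(names(fractions), c("C", "N", "O"))) {
      stop_input("an adjusted composition contains exactly C, N and O")
    }
    if (abs(sum(fractions) - 1) > 0.005) {
      stop_input("adjusted composition for '%s' sums to %.4f, not 1 within 0.5%%",
                 tissue_name, sum(fractions))
    }
  }
  structure(list(tissue_name = tissue_name,
                 fractions = fractions[order(names(fractions))],
                 adjusted = adjusted),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %s (%s)\n", x$tissue_name,
              if (x$adjusted) "H-omitted, C/N/O renormalized" else "raw"))
  print(round(x$fractions, 4))
  invisible(x)
}

# Bundled raw compositions, read once.
raw_composition_bank <- function() {
  if (is.null(.photopet_cache$compositions)) {
    path <- system.file("extdata", "compositions.tsv", package = "photopet",
                        mustWork = TRUE)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .photopet_cache$compositions <- tab
  }
  .photopet_cache$compositions
}

#' Bundled raw (hydrogen-containing) composition for one tissue
#'
#' @param tissue `"adipose_adult2"` or `"urinary_bladder_filled"`.
#' @return A `composition_table` with `adjusted = FALSE`, unit fractions.
#' @export
get_raw_composition <- function(tissue) {
  bank <- raw_composition_bank()
  rows <- bank[bank$tissue == tissue, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_input("unknown tissue '%s' (bundled: %s)", tissue,
               paste(unique(bank$tissue), collapse = ", "))
  }
  composition_table(tissue, setNames(rows$mass_percent / 100, rows$element),
                    adjusted = FALSE)
}

#' Hydrogen-omitted reference composition for one tissue
#'
#' Returns the bundled tissue's C/N/O mass fractions renormalized over
#' C+N+O, i.e. with hydrogen and trace elements -- which produce no positron
#' emitter under (gamma,n) activation -- removed. These are the reference
#' values fitted count-rate fractions are compared against.
#'
#' @inheritParams get_raw_composition
#' @return A `composition_table` with `adjusted = TRUE`.
#' @export
#' @examples
#' get_adjusted_composition("adipose_adult2")$fractions  # C 0.677, O 0.315
get_adjusted_composition <- function(tissue) {
  h_adjust(get_raw_composition(tissue))
}
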