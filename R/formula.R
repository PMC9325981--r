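#' Monoisotopic element masses used throughout the package
#'
#' Masses (Da) of the light isotopes of the CHNOS alphabet, plus the proton
#' mass used for the \eqn{[M-H]^-} deprotonation arithmetic. Values follow
#' the CODATA/AME compilations at sub-ppb precision, far beyond the 0.5 ppm
#' assignment tolerance.
#'
#' @format Named numeric vector with elements `C`, `H`, `N`, `O`, `S`,
#'   and `proton`.
#' @export
element_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  proton = 1.007276467
)

.elements <- c("C", "H", "N", "O", "S")

#' Parse molecular formula strings
#'
#' Parses canonical Hill-order CHNOS formula strings (e.g. `"C8H6O4"`,
#' `"CH4"`) into atom counts. Only the isotope-free CHNOS alphabet is
#' accepted; a count of 1 may be written implicitly.
#'
#' @param x character vector of formula strings.
#' @return data.frame with integer columns `c`, `h`, `n`, `o`, `s`, one row
#'   per input formula.
#' @examples
#' parse_formula(c("C8H6O4", "CH4"))
#' @export
parse_formula <- function(x) {
  x <- as.character(x)
  out <- matrix(0L, nrow = length(x), ncol = 5,
                dimnames = list(NULL, c("c", "h", "n", "o", "s")))
  tokens <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))
  for (i in seq_along(x)) {
    tk <- tokens[[i]]
    if (length(tk) == 0L || paste(tk, collapse = "") != x[i]) {
      stop("cannot parse formula: ", x[i])
    }
    el <- sub("[0-9]*$", "", tk)
    ct <- sub("^[A-Za-z]+", "", tk)
    ct <- ifelse(ct == "", 1L, as.integer(ct))
    if (!all(el %in% .elements)) {
      stop("formula ", x[i], " contains elements outside CHNOS")
    }
    if (anyDuplicated(el)) stop("duplicated element in formula: ", x[i])
    out[i, tolower(el)] <- ct
  }
  out <- as.data.frame(out)
  if (any(out$c < 1L)) stop("formulas must contain at least one carbon")
  out
}

#' Format atom counts as canonical formula strings
#'
#' Inverse of [parse_formula()]: writes Hill order (C, H, then N, O, S
#' alphabetically), omitting absent elements and implicit counts of 1, so
#' that `parse_formula(format_formula(f))` round-trips.
#'
#' @param f data.frame with columns `c`, `h`, `n`, `o`, `s` (as returned by
#'   [parse_formula()]), or a named vector for a single formula.
#' @return character vector of formula strings.
#' @export
format_formula <- function(f) {
  f <- .as_formula_df(f)
  piece <- function(sym, cnt) {
    ifelse(cnt == 0L, "", paste0(sym, ifelse(cnt == 1L, "", cnt)))
  }
  paste0(piece("C", f$c), piece("H", f$h), piece("N", f$n),
         piece("O", f$o), piece("S", f$s))
}

.as_formula_df <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  if (!is.data.frame(f)) f <- as.data.frame(as.list(f))
  names(f) <- tolower(names(f))
  for (el in c("h", "n", "o", "s")) if (is.null(f[[el]])) f[[el]] <- 0L
  stopifnot(all(c("c", "h", "n", "o", "s") %in% names(f)))
  f
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' @param f formula strings or an atom-count data.frame
#'   (see [parse_formula()]).
#' @return numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("C8H6O4") # 166.0266
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula_df(f)
  f$c * element_masses[["C"]] + f$h * element_masses[["H"]] +
    f$n * element_masses[["N"]] + f$o * element_masses[["O"]] +
    f$s * element_masses[["S"]]
}

#' m/z of the deprotonated molecular anion
#'
#' Computes the \eqn{[M-H]^-} ion mass (singly charged assumed, the standard
#' negative-mode electrospray species for dissolved organic matter). The only
#' supported ionisation mode is negative-mode deprotonation.
#'
#' @inheritParams monoisotopic_mass
#' @param mode ionisation mode; only `"negative"` is supported.
#' @return numeric vector of ion m/z values in Da.
#' @export
ion_mass <- function(f, mode = "negative") {
  if (!identical(mode, "negative")) {
    stop("unsupported ionisation mode: ", mode,
         " (only negative-mode [M-H]- is implemented)")
  }
  f <- .as_formula_df(f)
  if (any(f$h < 1L)) stop("cannot deprotonate a formula with no hydrogen")
  monoisotopic_mass(f) - element_masses[["proton"]]
}

#' Derived formula descriptors: H:C, O:C and double-bond equivalents
#'
#' DBE is computed as \eqn{c - h/2 + n/2 + 1}, the valence-based count of
#' rings plus double bonds; chemically plausible neutral formulas have
#' integer DBE \eqn{\ge 0}.
#'
#' @inheritParams monoisotopic_mass
#' @return data.frame with columns `hc`, `oc`, `dbe`.
#' @export
formula_ratios <- function(f) {
  f <- .as_formula_df(f)
  data.frame(hc = f$h / f$c, oc = f$o / f$c,
             dbe = f$c - f$h / 2 + f$n / 2 + 1)
}
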