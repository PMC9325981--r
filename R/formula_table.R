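#' Per-sample molecular-formula table
#'
#' The substrate of all DOM composition statistics: the set of molecular
#' formulas detected in one sample, with raw peak intensities and
#' sum-normalised relative intensities `p`. Duplicate formulas (e.g. several
#' peaks assigned the same composition) are merged by summing intensity.
#' When no positive intensity is available, `p` falls back to uniform
#' weights.
#'
#' @param formula character vector of canonical formula strings.
#' @param intensity non-negative raw intensities (recycled scalar allowed);
#'   defaults to 1 per formula (presence/absence data).
#' @param sample_id sample identifier stored as an attribute.
#' @return data.frame of class `"formula_table"` with columns `formula`,
#'   `c`, `h`, `n`, `o`, `s`, `intensity`, `p`, `hc`, `oc`, `dbe`.
#' @export
formula_table <- function(formula, intensity = 1, sample_id = NA_character_) {
  formula <- as.character(formula)
  intensity <- rep_len(as.numeric(intensity), length(formula))
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (anyDuplicated(formula)) {
    intensity <- tapply(intensity, formula, sum)
    formula <- names(intensity)
    intensity <- as.numeric(intensity)
  }
  atoms <- if (length(formula)) parse_formula(formula) else
    data.frame(c = integer(), h = integer(), n = integer(), o = integer(),
               s = integer())
  tab <- cbind(data.frame(formula = formula, stringsAsFactors = FALSE), atoms)
  tab$intensity <- intensity
  tot <- sum(intensity, na.rm = TRUE)
  tab$p <- if (length(formula) == 0L) {
    numeric()
  } else if (is.finite(tot) && tot > 0) {
    ifelse(is.na(intensity), 0, intensity) / tot
  } else {
    rep(1 / length(formula), length(formula))
  }
  r <- if (nrow(tab)) formula_ratios(tab) else
    data.frame(hc = numeric(), oc = numeric(), dbe = numeric())
  tab$hc <- r$hc
  tab$oc <- r$oc
  tab$dbe <- r$dbe
  attr(tab, "sample_id") <- sample_id
  class(tab) <- c("formula_table", "data.frame")
  tab
}

#' Build a formula table from assignment results
#'
#' Keeps the best-ranked candidate of each assigned peak and merges peaks
#' sharing a formula by summing intensity.
#'
#' @param assignments output of [assign_formulas()].
#' @param sample_id sample identifier; defaults to the (single) `sample_id`
#'   present in `assignments`.
#' @return a [formula_table()].
#' @export
formula_table_from_assignments <- function(assignments, sample_id = NULL) {
  best <- assignments[!is.na(assignments$formula) & assignments$is_best, ,
                      drop = FALSE]
  if (is.null(sample_id)) {
    ids <- unique(stats::na.omit(assignments$sample_id))
    sample_id <- if (length(ids) == 1L) ids else NA_character_
  }
  formula_table(best$formula, best$intensity, sample_id = sample_id)
}

#' Remove blank-detected formulas from a sample
#'
#' Procedural blank correction on formula identity: any formula also detected
#' in the blank is removed from the sample outright (rather than subtracting
#' intensities), and the remaining intensities are renormalised.
#'
#' @param sample,blank [formula_table()] objects produced under the same
#'   assignment configuration.
#' @return the blank-corrected [formula_table()].
#' @export
blank_correct <- function(sample, blank) {
  stopifnot(inherits(sample, "formula_table"), inherits(blank, "formula_table"))
  keep <- !(sample$formula %in% blank$formula)
  formula_table(sample$formula[keep], sample$intensity[keep],
                sample_id = attr(sample, "sample_id"))
}

#' @export
print.formula_table <- function(x, ...) {
  cat("<formula_table> sample ", attr(x, "sample_id"), ": ",
      nrow(x), " formulas\n", sep = "")
  NextMethod()
}
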