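#' Functional diversity of a DOM sample (Rao quadratic entropy)
#'
#' Computes the abundance-weighted expected pairwise difference in carbon-atom
#' number across a sample's molecular formulas:
#' \deqn{FD = \sum_i \sum_j p_i p_j |C_i - C_j|}
#' over all ordered pairs (the i = j diagonal contributes 0, each unordered
#' pair counts twice). Higher values indicate more diversity in molecular
#' size, and hence in the potential substrate niches DOM offers microbial
#' decomposers. Weights default to normalised peak intensities; uniform
#' weights treat every formula equally.
#'
#' The ordered-pair sum is evaluated with an O(n log n) sorted-prefix
#' identity rather than the quadratic double loop.
#'
#' @param table a [formula_table()].
#' @param weights `"intensity"` (normalised peak intensity, default) or
#'   `"uniform"`.
#' @return non-negative scalar; 0 for empty or single-formula tables.
#' @export
functional_diversity <- function(table, weights = c("intensity", "uniform")) {
  weights <- match.arg(weights)
  if (nrow(table) <= 1L) return(0)
  p <- if (weights == "uniform") rep(1 / nrow(table), nrow(table)) else table$p
  ci <- table$c
  ord <- order(ci)
  ci <- ci[ord]
  p <- p[ord]
  # sum_{i<j} p_i p_j (C_j - C_i) doubled:
  cp <- cumsum(p)
  cpc <- cumsum(p * ci)
  n <- length(ci)
  2 * sum(p[-1] * (ci[-1] * cp[-n] - cpc[-n]))
}

#' Lability classification of a DOM sample
#'
#' Classifies molecular formulas with H:C >= `threshold` as having a high
#' lability index (likely bioavailable), and summarises the sample by the
#' fraction of formulas so classified and the fraction of normalised peak
#' intensity they carry. The boundary H:C exactly at the threshold counts as
#' high-lability.
#'
#' @param table a [formula_table()].
#' @param threshold H:C cutoff, default 1.5.
#' @return list with `frac_count` and `frac_intensity`, both in [0, 1]
#'   (both 0 for an empty table).
#' @export
lability_summary <- function(table, threshold = 1.5) {
  if (nrow(table) == 0L) return(list(frac_count = 0, frac_intensity = 0))
  high <- table$hc >= threshold
  list(frac_count = mean(high), frac_intensity = sum(table$p[high]))
}

#' Formulas unique to a target sample
#'
#' Subsets a target formula table to the formulas occurring in none of the
#' reference tables (exact canonical-formula identity), and reports the
#' unique percentage relative to the full target. All tables should be
#' blank-corrected under the same assignment configuration.
#'
#' @param target a [formula_table()].
#' @param references list of [formula_table()] objects; an empty list leaves
#'   the target whole (100% unique).
#' @return list with `table` (unique subset, intensities renormalised),
#'   `n_target`, `n_unique`, and `pct_unique` (= 100 n_unique / n_target).
#' @export
unique_formulas <- function(target, references = list()) {
  stopifnot(inherits(target, "formula_table"))
  if (inherits(references, "formula_table")) references <- list(references)
  seen <- unique(unlist(lapply(references, function(r) r$formula)))
  keep <- !(target$formula %in% seen)
  uniq <- formula_table(target$formula[keep], target$intensity[keep],
                        sample_id = attr(target, "sample_id"))
  list(table = uniq, n_target = nrow(target), n_unique = nrow(uniq),
       pct_unique = if (nrow(target) == 0L) NA_real_ else
         100 * nrow(uniq) / nrow(target))
}

#' Packaged reference table of known plastic additives
#'
#' Molecular formulas, putative compound names and main industrial
#' applications of additives and breakdown products known from plastic
#' manufacture, shipped with the package as a CSV. Two rows share the formula
#' C10H14O2 (distinct isomers); formula matching reports both as candidate
#' identities.
#'
#' @return data.frame with columns `formula`, `putative_name`, `application`,
#'   `abundance_pct`.
#' @export
plastic_additives <- function() {
  path <- system.file("extdata", "plastic_additives.csv",
                      package = "plasticdom", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cross-reference unique formulas against a plastic-additive table
#'
#' Matches leachate-unique formulas to known additives on exact isotope-free
#' formula identity (no isomer resolution: a formula matching several
#' additives reports every candidate). Relative abundance of each match is
#' the formula's share of normalised intensity in the FULL sample (before
#' taking the unique subset), as a percent.
#'
#' @param uniques unique-formula table (the `table` element of
#'   [unique_formulas()]).
#' @param full_table the full [formula_table()] the uniques were drawn from,
#'   used as the abundance normalisation basis.
#' @param additives reference table, defaults to [plastic_additives()].
#' @return data.frame with columns `formula`, `putative_name`, `application`,
#'   `rel_abundance_pct`; zero rows when nothing matches.
#' @export
crossref_additives <- function(uniques, full_table,
                               additives = plastic_additives()) {
  hit <- additives[additives$formula %in% uniques$formula, , drop = FALSE]
  p_full <- full_table$p[match(hit$formula, full_table$formula)]
  out <- data.frame(formula = hit$formula,
                    putative_name = hit$putative_name,
                    application = hit$application,
                    rel_abundance_pct = 100 * p_full,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-row DOM composition summary of a sample
#'
#' @param table a [formula_table()].
#' @param weights weighting passed to [functional_diversity()].
#' @param threshold H:C lability cutoff passed to [lability_summary()].
#' @return data.frame row with `sample_id`, `fd`, `n_formulas`,
#'   `frac_high_lability_count`, `frac_high_lability_intensity`.
#' @export
dom_summary <- function(table, weights = "intensity", threshold = 1.5) {
  lab <- lability_summary(table, threshold)
  data.frame(sample_id = attr(table, "sample_id"),
             fd = functional_diversity(table, weights),
             n_formulas = nrow(table),
             frac_high_lability_count = lab$frac_count,
             frac_high_lability_intensity = lab$frac_intensity,
             stringsAsFactors = FALSE)
}
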