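#' Configuration for molecular-formula assignment
#'
#' Element bounds, mass tolerance, analytical window and plausibility filters
#' for the exhaustive CHNOS search of [assign_formulas()]. Defaults reflect
#' common practice for negative-mode FT-ICR-MS of dissolved organic matter:
#' a 0.5 ppm tolerance (typical for a 15 T instrument), the exported
#' 150--1000 m/z window, H:C in [0, 2.5], O:C in [0, 1.2], DBE >= 0 and an
#' even-electron \eqn{[M-H]^-} parity constraint (h + n even for the neutral,
#' so the deprotonated anion carries an even electron count).
#'
#' @param c_range,h_range,n_range,o_range,s_range integer length-2 bounds on
#'   atom counts of the neutral formula.
#' @param tol_ppm assignment tolerance in parts per million (> 0).
#' @param window length-2 analytical window for ion m/z (Da). The preset for
#'   the wider 150--2000 Da description of the same spectra is available via
#'   `window = c(150, 2000)`.
#' @param hc_range,oc_range permitted H:C and O:C ratio windows.
#' @return list of class `"assign_config"`.
#' @export
assignment_config <- function(c_range = c(1L, 60L), h_range = c(1L, 120L),
                              n_range = c(0L, 4L), o_range = c(0L, 40L),
                              s_range = c(0L, 2L), tol_ppm = 0.5,
                              window = c(150, 1000),
                              hc_range = c(0, 2.5), oc_range = c(0, 1.2)) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  stopifnot(length(window) == 2L, window[1] < window[2])
  structure(list(c_range = as.integer(c_range), h_range = as.integer(h_range),
                 n_range = as.integer(n_range), o_range = as.integer(o_range),
                 s_range = as.integer(s_range), tol_ppm = tol_ppm,
                 window = as.numeric(window), hc_range = hc_range,
                 oc_range = oc_range),
            class = "assign_config")
}

# Cache of enumerated candidate tables, keyed by the config values. The
# enumeration is the expensive step (~10^6 formulas at default bounds); peaks
# are then matched against the mass-sorted table by binary search.
.candidate_cache <- new.env(parent = emptyenv())

.config_key <- function(config) {
  paste(unlist(config[c("c_range", "h_range", "n_range", "o_range",
                        "s_range", "window", "hc_range", "oc_range")]),
        collapse = "|")
}

# Enumerate every CHNOS formula passing the plausibility filters whose
# [M-H]- ion falls in the analytical window (with a small margin so that
# tolerance windows straddling the edge are complete). Returns a data.frame
# sorted by ion mass.
.enumerate_candidates <- function(config) {
  key <- .config_key(config)
  hit <- .candidate_cache[[key]]
  if (!is.null(hit)) return(hit)

  cs <- seq(config$c_range[1], config$c_range[2])
  ns <- seq(config$n_range[1], config$n_range[2])
  ss <- seq(config$s_range[1], config$s_range[2])
  grid <- expand.grid(c = cs, n = ns, o = 0L, s = ss,
                      KEEP.OUT.ATTRS = FALSE)
  # expand o per carbon count under the O:C ceiling and the o bounds
  o_max <- pmin(config$o_range[2], floor(config$oc_range[2] * grid$c))
  o_min <- config$o_range[1]
  keep <- o_max >= o_min
  grid <- grid[keep, , drop = FALSE]
  o_max <- o_max[keep]
  reps <- o_max - o_min + 1L
  grid <- grid[rep(seq_len(nrow(grid)), reps), , drop = FALSE]
  grid$o <- unlist(lapply(seq_along(reps),
                          function(i) seq.int(o_min, o_max[i])),
                   use.names = FALSE)

  # hydrogen bounds: configured range, H:C window, DBE >= 0 (h <= 2c + n + 2),
  # and even-electron [M-H]- parity (h + n even for the neutral)
  h_lo <- pmax(config$h_range[1], ceiling(config$hc_range[1] * grid$c), 1L)
  h_hi <- pmin(config$h_range[2], floor(config$hc_range[2] * grid$c),
               2L * grid$c + grid$n + 2L)
  # shift lower bound up to matching parity
  h_lo <- h_lo + ((h_lo + grid$n) %% 2L)
  keep <- h_hi >= h_lo
  grid <- grid[keep, , drop = FALSE]
  h_lo <- h_lo[keep]
  h_hi <- h_hi[keep]
  nh <- (h_hi - h_lo) %/% 2L + 1L
  idx <- rep(seq_len(nrow(grid)), nh)
  cand <- grid[idx, , drop = FALSE]
  cand$h <- unlist(lapply(seq_along(nh),
                          function(i) seq.int(h_lo[i], h_hi[i], by = 2L)),
                   use.names = FALSE)
  cand <- cand[, c("c", "h", "n", "o", "s")]
  cand$ion_mz <- monoisotopic_mass(cand) - element_masses[["proton"]]
  margin <- 0.01
  cand <- cand[cand$ion_mz >= config$window[1] - margin &
                 cand$ion_mz <= config$window[2] + margin, , drop = FALSE]
  cand <- cand[order(cand$ion_mz), , drop = FALSE]
  rownames(cand) <- NULL
  .candidate_cache[[key]] <- cand
  cand
}

#' Assign molecular formulas to negative-mode peak lists
#'
#' Exhaustive search over the configured CHNOS space for every candidate
#' neutral formula whose \eqn{[M-H]^-} ion matches a measured peak within the
#' ppm tolerance and passes all plausibility filters. Candidates per peak are
#' ranked by absolute mass error, ties broken by fewer heteroatoms (N + S),
#' then lower DBE, then formula string, making the assignment fully
#' deterministic. Peaks with no passing candidate are returned unassigned.
#'
#' @param peaks data.frame with columns `mz` and `intensity` (and optionally
#'   `sample_id`); one row per calibrated peak, singly charged ions assumed.
#' @param config an [assignment_config()].
#' @return data.frame with one row per (peak, candidate) pair plus one row per
#'   unassigned peak: columns `peak`, `mz`, `intensity`, `sample_id`,
#'   `formula`, `c`, `h`, `n`, `o`, `s`, `mass_error_ppm`, `rank`, `is_best`.
#'   `formula` is `NA` for unassigned peaks.
#' @examples
#' pk <- data.frame(mz = ion_mass("C8H6O4"), intensity = 1)
#' assign_formulas(pk)
#' @export
assign_formulas <- function(peaks, config = assignment_config()) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (config$tol_ppm <= 0) stop("tol_ppm must be > 0")
  empty <- data.frame(peak = integer(), mz = numeric(), intensity = numeric(),
                      sample_id = character(), formula = character(),
                      c = integer(), h = integer(), n = integer(),
                      o = integer(), s = integer(),
                      mass_error_ppm = numeric(), rank = integer(),
                      is_best = logical())
  if (nrow(peaks) == 0L) return(empty)
  if (any(peaks$intensity < 0)) stop("peak intensities must be >= 0")
  sample_id <- if ("sample_id" %in% names(peaks)) {
    as.character(peaks$sample_id)
  } else {
    rep(NA_character_, nrow(peaks))
  }
  in_win <- peaks$mz >= config$window[1] & peaks$mz <= config$window[2]
  if (!all(in_win)) {
    warning(sum(!in_win), " peak(s) outside the analytical window ",
            "were left unassigned")
  }

  cand <- .enumerate_candidates(config)
  tol <- config$tol_ppm * 1e-6
  lo <- findInterval(peaks$mz * (1 - tol), cand$ion_mz) + 1L
  hi <- findInterval(peaks$mz * (1 + tol), cand$ion_mz)
  hi <- ifelse(in_win, hi, lo - 1L)
  ncand <- pmax(hi - lo + 1L, 0L)

  has <- ncand > 0L
  rows <- sequence(ncand[has]) + rep(lo[has] - 1L, ncand[has])
  pk <- rep(which(has), ncand[has])
  matched <- cand[rows, , drop = FALSE]
  res <- data.frame(peak = pk, mz = peaks$mz[pk],
                    intensity = peaks$intensity[pk],
                    sample_id = sample_id[pk],
                    formula = format_formula(matched),
                    c = matched$c, h = matched$h, n = matched$n,
                    o = matched$o, s = matched$s,
                    mass_error_ppm =
                      (matched$ion_mz - peaks$mz[pk]) / peaks$mz[pk] * 1e6,
                    stringsAsFactors = FALSE)
  het <- res$n + res$s
  dbe <- res$c - res$h / 2 + res$n / 2 + 1
  ord <- order(res$peak, abs(res$mass_error_ppm), het, dbe, res$formula)
  res <- res[ord, , drop = FALSE]
  res$rank <- stats::ave(res$peak, res$peak, FUN = seq_along)
  res$is_best <- res$rank == 1L

  miss <- which(ncand == 0L)
  if (length(miss)) {
    res <- rbind(res, data.frame(
      peak = miss, mz = peaks$mz[miss], intensity = peaks$intensity[miss],
      sample_id = sample_id[miss], formula = NA_character_,
      c = NA_integer_, h = NA_integer_, n = NA_integer_, o = NA_integer_,
      s = NA_integer_, mass_error_ppm = NA_real_, rank = NA_integer_,
      is_best = FALSE, stringsAsFactors = FALSE))
  }
  res <- res[order(res$peak, res$rank), , drop = FALSE]
  rownames(res) <- NULL
  res
}
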