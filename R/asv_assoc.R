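#' Shannon diversity of a sample's ASV counts
#'
#' H = -sum p_i ln(p_i) over taxa with positive counts, in nats, computed on
#' unrarefied counts (via `vegan::diversity`).
#'
#' @param counts non-negative count vector for one sample, or an ASV x sample
#'   matrix (columns are samples).
#' @return diversity in nats (vector for a matrix input); `NA` for an
#'   all-zero sample.
#' @export
shannon_index <- function(counts) {
  if (is.matrix(counts)) {
    tot <- colSums(counts)
    h <- vegan::diversity(t(counts), index = "shannon")
    h[tot == 0] <- NA_real_
    return(h)
  }
  if (sum(counts) == 0) return(NA_real_)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Remove low-abundance ASVs
#'
#' Drops ASVs whose total read count across samples is strictly below
#' `min_reads` (default 100), avoiding spurious associations driven by rare
#' taxa; an ASV with exactly `min_reads` reads is retained. Setting
#' `per_sample = TRUE` applies the threshold to every sample instead of the
#' row total.
#'
#' @param counts ASV x sample integer matrix (rownames = ASV ids).
#' @param min_reads read threshold.
#' @param per_sample require the threshold in every sample rather than in
#'   total.
#' @return the filtered count matrix.
#' @export
filter_low_abundance <- function(counts, min_reads = 100,
                                 per_sample = FALSE) {
  if (nrow(counts) == 0L) return(counts)
  keep <- if (per_sample) {
    apply(counts, 1, function(r) all(r >= min_reads))
  } else {
    rowSums(counts) >= min_reads
  }
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Library-depth normalisation constants per sample: the median, over ASVs
#' with positive counts in every sample, of the ratio of each sample's count
#' to the ASV's geometric mean across samples.
#'
#' @param counts ASV x sample count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ubiq <- rowSums(counts > 0) == ncol(counts)
  if (!any(ubiq)) {
    stop("no ASV has positive counts in all samples; ",
         "consider adding a pseudocount")
  }
  logc <- log(counts[ubiq, , drop = FALSE])
  geo <- rowMeans(logc)
  # median taken on the log scale (even-length medians then average
  # geometrically, matching the canonical median-of-ratios estimator)
  exp(apply(logc - geo, 2, stats::median))
}

#' Negative-binomial association of ASV abundance with a metabolic covariate
#'
#' For each ASV, fits a negative binomial GLM with log link,
#' `count ~ covariate` with `log(size factor)` offset, and reports the slope
#' in log2 units with a Wald test. Per-ASV dispersion is estimated by the
#' method of moments on size-factor-normalised counts
#' (`alpha = max((var - mu) / mu^2, floor)`, floor 1e-8, so near-Poisson data
#' reduce to an effectively Poisson fit). The Wald statistic is referred to a
#' t distribution with n - 2 degrees of freedom, the standard small-sample
#' reference for per-feature GLMs at modest sample counts. No dispersion
#' shrinkage, outlier filtering or independent filtering is applied. ASVs
#' whose fit fails to converge are returned with missing statistics rather
#' than erroring.
#'
#' @param counts filtered ASV x sample count matrix.
#' @param covariate numeric per-sample covariate (e.g. log2 fold change in
#'   BPP or BGE of the sample's lake); must be finite. A constant covariate
#'   yields missing slopes/p-values for every ASV.
#' @param sf size factors, defaults to [size_factors()] of `counts`.
#' @param dispersion_floor lower bound for the moment dispersion estimate.
#' @return data.frame with one row per ASV: `asv`, `log2_fc_per_unit`, `se`,
#'   `p`, `padj` (Benjamini-Hochberg), `base_mean` (mean normalised count),
#'   `converged`.
#' @export
nb_association <- function(counts, covariate, sf = size_factors(counts),
                           dispersion_floor = 1e-8) {
  counts <- as.matrix(counts)
  stopifnot(length(covariate) == ncol(counts), all(is.finite(covariate)),
            length(sf) == ncol(counts))
  asv <- rownames(counts)
  if (is.null(asv)) asv <- paste0("ASV", seq_len(nrow(counts)))
  off <- log(sf)
  constant <- stats::sd(covariate) == 0
  fit_one <- function(y) {
    q <- y / sf
    mu <- mean(q); v <- stats::var(q)
    alpha <- max((v - mu) / mu^2, dispersion_floor)
    res <- tryCatch({
      g <- suppressWarnings(stats::glm(
        y ~ covariate + offset(off),
        family = MASS::negative.binomial(theta = 1 / alpha)))
      cf <- summary(g)$coefficients
      if (!g$converged || nrow(cf) < 2L) stop("no convergence")
      # Wald statistic on the NB slope (log2 units), t reference with n-2 df
      est <- cf["covariate", "Estimate"]
      se <- cf["covariate", "Std. Error"]
      c(est / log(2), se / log(2),
        2 * stats::pt(-abs(est / se), df = length(y) - 2L), 1)
    }, error = function(e) c(NA_real_, NA_real_, NA_real_, 0))
    c(res, mu)
  }
  if (constant) {
    out <- data.frame(asv = asv, log2_fc_per_unit = NA_real_, se = NA_real_,
                      p = NA_real_, base_mean = rowMeans(counts / rep(sf, each = nrow(counts))),
                      converged = FALSE, stringsAsFactors = FALSE)
  } else {
    m <- t(apply(counts, 1, fit_one))
    out <- data.frame(asv = asv, log2_fc_per_unit = m[, 1], se = m[, 2],
                      p = m[, 3], base_mean = m[, 5],
                      converged = m[, 4] == 1, stringsAsFactors = FALSE)
  }
  out$padj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[, c("asv", "log2_fc_per_unit", "se", "p", "padj", "base_mean",
          "converged")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate correction (via `stats::p.adjust`), with
#' missing p-values passed through unchanged and excluded from the number of
#' tests.
#'
#' @param p numeric vector of p-values in [0, 1], `NA` allowed.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
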