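# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use the naive definitions.

# Rao quadratic entropy by the O(n^2) ordered-pair double sum
fd_brute <- function(carbon, p) {
  sum(outer(p, p) * abs(outer(carbon, carbon, "-")))
}

# Benjamini-Hochberg by the step-up definition: sort ascending,
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Unpruned brute-force CHNOS candidate search: full loop over element
# bounds, applying the same plausibility filters as the assignment config.
# Only usable for small bounds.
assign_brute <- function(mz, bounds, tol_ppm) {
  em <- plasticdom::element_masses
  res <- character()
  for (c_ in bounds$c[1]:bounds$c[2])
    for (n_ in bounds$n[1]:bounds$n[2])
      for (o_ in bounds$o[1]:bounds$o[2])
        for (s_ in bounds$s[1]:bounds$s[2])
          for (h_ in bounds$h[1]:bounds$h[2]) {
            hc <- h_ / c_; oc <- o_ / c_
            dbe <- c_ - h_ / 2 + n_ / 2 + 1
            if (hc < 0 || hc > 2.5 || oc > 1.2 || dbe < 0) next
            if ((h_ + n_) %% 2 != 0) next       # even-electron [M-H]-
            ion <- c_ * em[["C"]] + h_ * em[["H"]] + n_ * em[["N"]] +
              o_ * em[["O"]] + s_ * em[["S"]] - em[["proton"]]
            if (abs(ion - mz) / mz * 1e6 <= tol_ppm) {
              res <- c(res, plasticdom::format_formula(
                data.frame(c = c_, h = h_, n = n_, o = o_, s = s_)))
            }
          }
  sort(res)
}

# random formula tables for property tests
random_formula_table <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  space <- plasticdom:::.cho_space(c(5, 45))
  idx <- sample.int(nrow(space), n)
  formula_table(space$formula[idx], stats::rlnorm(n, 0, 1),
                sample_id = "random")
}
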