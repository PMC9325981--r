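test_that("formula strings round-trip through parse and format", {
  strs <- c("C8H6O4", "CH4", "C20H26O4", "C5H10N2O3S", "C10H14O2", "C2H2")
  expect_identical(format_formula(parse_formula(strs)), strs)
  # property over a random slice of the CHO space
  set.seed(1)
  sp <- plasticdom:::.cho_space(c(5, 45))
  f <- sp$formula[sample.int(nrow(sp), 300)]
  expect_identical(format_formula(parse_formula(f)), f)
  expect_error(parse_formula("H2O"), "carbon")
  expect_error(parse_formula("C2P1"), "CHNOS")
})

test_that("monoisotopic masses match hand-summed values", {
  expect_equal(monoisotopic_mass("C"), 12, tolerance = 1e-9)
  expect_equal(monoisotopic_mass("C8H6O4"), 166.02661, tolerance = 1e-5)
  expect_equal(monoisotopic_mass("C20H26O4"), 330.18311, tolerance = 1e-5)
})

test_that("[M-H]- ion mass is neutral mass minus one proton", {
  expect_equal(ion_mass("C8H6O4"), 165.01933, tolerance = 1e-5)
  expect_equal(ion_mass("CH2"), 13.00838, tolerance = 1e-5)
  set.seed(2)
  sp <- plasticdom:::.cho_space(c(5, 40))
  f <- sp$formula[sample.int(nrow(sp), 100)]
  expect_equal(monoisotopic_mass(f) - ion_mass(f),
               rep(element_masses[["proton"]], 100), tolerance = 1e-12)
  expect_error(ion_mass("C6O6"), "deprotonate")
  expect_error(ion_mass("C8H6O4", mode = "positive"), "unsupported")
})

test_that("assignment recovers known compositions and ranks by mass error", {
  pk <- data.frame(mz = c(165.01933, 329.17583), intensity = c(1, 2))
  res <- assign_formulas(pk)
  best <- res[res$is_best, ]
  expect_identical(best$formula, c("C8H6O4", "C20H26O4"))
  expect_true(all(abs(best$mass_error_ppm) <= 0.5))
  # candidate lists are sorted by |ppm error| within each peak
  for (p in unique(res$peak)) {
    e <- abs(res$mass_error_ppm[res$peak == p])
    expect_true(all(diff(e) >= -1e-12))
  }
})

test_that("assignment handles empty, unassignable and invalid inputs", {
  expect_identical(nrow(assign_formulas(data.frame(mz = numeric(),
                                                   intensity = numeric()))),
                   0L)
  cfg <- assignment_config(tol_ppm = 1e-4)
  res <- assign_formulas(data.frame(mz = 150.0, intensity = 1), cfg)
  expect_true(is.na(res$formula))
  expect_error(assignment_config(tol_ppm = 0), "tol_ppm")
})

test_that("assignment is deterministic and idempotent", {
  set.seed(3)
  pk <- data.frame(mz = runif(20, 200, 600), intensity = runif(20))
  expect_identical(assign_formulas(pk), assign_formulas(pk))
})

test_that("pruned search equals the unpruned brute-force loop", {
  bounds <- list(c = c(1, 20), h = c(1, 40), n = c(0, 2), o = c(0, 10),
                 s = c(0, 1))
  cfg <- assignment_config(c_range = bounds$c, h_range = bounds$h,
                           n_range = bounds$n, o_range = bounds$o,
                           s_range = bounds$s, tol_ppm = 5,
                           window = c(100, 300))
  for (mz in c(165.019, 187.0976, 241.0112, 299.9)) {
    fast <- assign_formulas(data.frame(mz = mz, intensity = 1), cfg)
    fast <- sort(fast$formula[!is.na(fast$formula)])
    expect_identical(fast, assign_brute(mz, bounds, 5))
  }
})

test_that("blank correction removes formulas by identity and renormalises", {
  s <- formula_table(c("C6H6O2", "C7H8O2"), c(0.5, 0.5))
  b <- formula_table("C7H8O2", 3)
  out <- blank_correct(s, b)
  expect_identical(out$formula, "C6H6O2")
  expect_equal(out$p, 1)
  # empty blank is the identity
  out2 <- blank_correct(s, formula_table(character()))
  expect_identical(out2$formula, s$formula)
  # equal intensities, two of three blanked
  s3 <- formula_table(c("C6H6O2", "C7H8O2", "C8H10O2"), 1)
  out3 <- blank_correct(s3, formula_table(c("C6H6O2", "C7H8O2"), 1))
  expect_identical(out3$formula, "C8H10O2")
  expect_equal(out3$p, 1)
})

test_that("formula tables merge duplicates and normalise intensity", {
  ft <- formula_table(c("C6H6O2", "C6H6O2", "C7H8O2"), c(1, 2, 3))
  expect_identical(nrow(ft), 2L)
  expect_equal(sum(ft$p), 1, tolerance = 1e-12)
  expect_equal(ft$intensity[ft$formula == "C6H6O2"], 3)
  # zero intensities fall back to uniform weights
  ft0 <- formula_table(c("C6H6O2", "C7H8O2"), 0)
  expect_equal(ft0$p, c(0.5, 0.5))
})
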