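reduced_universe <- function(seed = 1) {
  make_formula_universe(study_design(),
                        n_leachate_formulas = 300,
                        lake_formula_range = c(400, 600),
                        seed = seed)
}

test_that("generators are deterministic functions of the seed", {
  u1 <- reduced_universe(7)
  u2 <- reduced_universe(7)
  expect_identical(u1$peaks, u2$peaks)
  expect_identical(u1$leachate$formula, u2$leachate$formula)
  t1 <- make_asv_table(n_asv = 50, planted_fraction = 0.1, seed = 8)
  t2 <- make_asv_table(n_asv = 50, planted_fraction = 0.1, seed = 8)
  expect_identical(t1$counts, t2$counts)
  r1 <- make_response_data(seed = 9)
  r2 <- make_response_data(seed = 9)
  expect_identical(r1, r2)
})

test_that("formula universe hits its lability and overlap targets", {
  u <- reduced_universe(2)
  leach_clean <- blank_correct(u$leachate, u$blank)
  expect_identical(nrow(leach_clean), 300L)
  expect_equal(lability_summary(leach_clean)$frac_count, 0.186,
               tolerance = 0.011)
  lakes_clean <- lapply(u$lakes, blank_correct, blank = u$blank)
  uq <- unique_formulas(leach_clean, lakes_clean)
  expect_equal(uq$pct_unique, 35, tolerance = 0.01)  # 0.65 overlap default
  # additive formulas are always among the leachate-unique set
  expect_true(all(unique(plastic_additives()$formula) %in%
                    uq$table$formula))
  # every generated formula satisfies the consuming module's invariants
  expect_true(all(leach_clean$hc <= 2.5 & leach_clean$oc <= 1.2 &
                    leach_clean$dbe >= 0))
  expect_error(make_formula_universe(overlap_fraction = 1.3), "overlap")
})

test_that("generated peak lists are recoverable by the assignment module", {
  u <- reduced_universe(3)
  pk <- u$peaks[u$peaks$sample_id == "leachate", ]
  res <- assign_formulas(pk)
  best <- res[res$is_best, ]
  # nearly every peak recovers its generating formula at 0.1 ppm error
  expect_gt(mean(best$formula %in% u$leachate$formula), 0.95)
})

test_that("response generator embeds its stated effects", {
  # zero noise, zero random effects: the realised fold change is exact
  d <- make_response_data(lake_sd = 0, resid_sd = 0, seed = 4)
  fold <- mean(d$bpp[d$treatment == "plastic"]) /
    mean(d$bpp[d$treatment == "control"])
  expect_equal(fold, 2.29, tolerance = 1e-9)
  # availability masks: BGE rows only for respiration lakes, fd NA past 22
  des <- study_design()
  g <- make_response_data(des, "bge", seed = 5)
  expect_identical(length(unique(g$lake_id)), des$lakes_with_respiration)
  cv <- make_lake_covariates(des, seed = 6)
  expect_true(all(is.na(cv$fd[23:29])))
  expect_true(all(is.na(cv$shannon[21:29])))
  expect_true(all(!is.na(cv$temperature)))
})

test_that("noisy counting still recovers BPP with small dispersion", {
  des <- study_design(n_lakes = 1)
  truth <- data.frame(lake_id = "lake_01", treatment = "control",
                      replicate = 1, bpp = 0.1, respiration = NA)
  set.seed(10)
  est <- replicate(100, {
    inc <- make_incubation_data(des, truth, noise = TRUE)
    incubation_rates(inc$scint)$bpp
  })
  expect_lt(sd(est) / mean(est), 0.05)     # CV < 5% at ~10^4 CPM
  expect_equal(mean(est), 0.1, tolerance = 0.02)
})

test_that("zero respiration yields a flat oxygen series", {
  des <- study_design(n_lakes = 1)
  truth <- data.frame(lake_id = "lake_01", treatment = "control",
                      replicate = 1, bpp = 0.1, respiration = 0)
  inc <- make_incubation_data(des, truth, noise = FALSE)
  s <- inc$oxygen[inc$oxygen$vial == "start", "pct_saturation"]
  e <- inc$oxygen[inc$oxygen$vial == "end", "pct_saturation"]
  expect_equal(s, e, tolerance = 1e-12)
})

test_that("null ASV tables produce few significant associations", {
  tab <- make_asv_table(n_asv = 200, planted_fraction = 0, seed = 11)
  filt <- filter_low_abundance(tab$counts)
  res <- nb_association(filt, tab$covariate)
  expect_lte(mean(res$p < 0.05, na.rm = TRUE), 0.1)
  expect_lte(sum(res$padj < 0.05, na.rm = TRUE), 2)
})
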