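make_lmm_data <- function(n_lakes = 12, reps = 3, log_fold = log(2),
                          lake_sd = 0.4, resid_sd = 0.3, seed = 1,
                          covariates = 0) {
  set.seed(seed)
  d <- expand.grid(replicate = seq_len(reps),
                   treatment = c("control", "plastic"),
                   lake_id = sprintf("L%02d", seq_len(n_lakes)),
                   stringsAsFactors = FALSE)
  b <- rnorm(n_lakes, 0, lake_sd)
  names(b) <- sprintf("L%02d", seq_len(n_lakes))
  eta <- log(0.1) + (d$treatment == "plastic") * log_fold + b[d$lake_id] +
    rnorm(nrow(d), 0, resid_sd)
  d$y <- exp(eta)
  if (covariates > 0) {
    for (k in seq_len(covariates)) {
      v <- rnorm(n_lakes)
      d[[paste0("x", k)]] <- v[match(d$lake_id, names(b))]
    }
  }
  d
}

test_that("with zero lake variance the LMM matches ordinary least squares", {
  d <- make_lmm_data(n_lakes = 20, lake_sd = 0, seed = 3, covariates = 2)
  fit <- fit_lmm(d, "y", c("x1", "x2"), interactions = FALSE, REML = FALSE)
  ols <- lm(.logresp ~ treatment + x1 + x2, data = fit$data)
  expect_equal(unname(lme4::fixef(fit$model)), unname(coef(ols)),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  expect_lt(vc$vcov[vc$grp == "lake_id"], 1e-3)
})

test_that("balanced two-group fit returns the difference of log-mean groups", {
  d <- make_lmm_data(n_lakes = 10, seed = 4)
  fit <- fit_lmm(d, "y", REML = FALSE)
  est <- lme4::fixef(fit$model)[["treatmentplastic"]]
  expect_equal(est, mean(log(d$y[d$treatment == "plastic"])) -
                 mean(log(d$y[d$treatment == "control"])),
               tolerance = 1e-6)
})

test_that("scaling the response only shifts the intercept by log(c)", {
  d <- make_lmm_data(seed = 5)
  f1 <- fit_lmm(d, "y", REML = FALSE)
  d$y <- d$y * 7
  f2 <- fit_lmm(d, "y", REML = FALSE)
  b1 <- lme4::fixef(f1$model)
  b2 <- lme4::fixef(f2$model)
  expect_equal(b2[["(Intercept)"]] - b1[["(Intercept)"]], log(7),
               tolerance = 1e-6)
  expect_equal(b2[["treatmentplastic"]], b1[["treatmentplastic"]],
               tolerance = 1e-6)
})

test_that("positivity and design requirements are enforced", {
  d <- make_lmm_data(seed = 6)
  d$y[1] <- -1
  expect_error(fit_lmm(d, "y"), "positive")
  d2 <- make_lmm_data(seed = 7, covariates = 1)
  d2$x2 <- d2$x1
  expect_error(fit_lmm(d2, "y", c("x1", "x2"), interactions = FALSE),
               "collinear")
})

test_that("collinearity screening drops the lower-priority member strictly above r = 0.9", {
  set.seed(8)
  d <- data.frame(fd = rnorm(60))
  d$doc <- d$fd + rnorm(60, 0, 0.05)        # |r| ~ 0.999
  d$temperature <- rnorm(60)
  scr <- collinearity_screen(d, c("fd", "doc", "temperature"))
  expect_identical(scr$retained, c("fd", "temperature"))
  expect_identical(scr$dropped$dropped, "doc")
  # boundary: a pair at exactly the threshold is kept (strict inequality)
  r <- abs(cor(d$fd, d$doc))
  scr2 <- collinearity_screen(d, c("fd", "doc"), threshold = r)
  expect_identical(sort(scr2$retained), c("doc", "fd"))
  # independent covariates are never dropped
  set.seed(9)
  ind <- as.data.frame(matrix(rnorm(100 * 5), ncol = 5))
  scr3 <- collinearity_screen(ind, names(ind), priority = names(ind))
  expect_identical(scr3$retained, names(ind))
})

test_that("backward elimination drops null terms, keeps real ones, respects marginality", {
  set.seed(10)
  d <- make_lmm_data(n_lakes = 29, seed = 10, covariates = 2)
  # x1 has a strong main effect; x2 is pure noise
  d$y <- d$y * exp(0.8 * d$x1)
  fit <- fit_lmm(d, "y", c("x1", "x2"), interactions = FALSE, REML = FALSE)
  sel <- backward_eliminate(fit)
  expect_true("x1" %in% sel$terms)
  expect_false("x2" %in% sel$terms)
  expect_true("treatment" %in% sel$terms)   # design variable never dropped
  expect_true(sel$REML)
  # with an interaction present, its main effect is not droppable before it
  fit2 <- fit_lmm(d, "y", c("x1", "x2"), interactions = TRUE, REML = FALSE)
  dropped <- backward_eliminate(fit2)$aic_trace$dropped
  i_main <- match("x2", dropped)
  i_int <- match("treatment:x2", dropped)
  if (!is.na(i_main)) expect_true(!is.na(i_int) && i_int < i_main)
  # refitting the selected model reproduces its AIC
  refit <- fit_lmm(d, "y", intersect(c("x1", "x2"), sel$terms),
                   interactions = FALSE, REML = FALSE)
  expect_equal(AIC(refit$model),
               tail(sel$aic_trace$aic, 1), tolerance = 1e-8)
})

test_that("strong interactions survive elimination", {
  set.seed(11)
  d <- make_lmm_data(n_lakes = 29, seed = 11, covariates = 1)
  z <- (d$x1 - mean(d$x1)) / sd(d$x1)
  d$y <- d$y * exp((d$treatment == "plastic") * 1.2 * z)
  fit <- fit_lmm(d, "y", "x1", interactions = TRUE, REML = FALSE)
  sel <- backward_eliminate(fit)
  expect_true("treatment:x1" %in% sel$terms)
})

test_that("marginal effects back-transform exactly and probe moderators", {
  d <- make_lmm_data(n_lakes = 20, seed = 12, covariates = 1)
  fit <- fit_lmm(d, "y", "x1", interactions = TRUE, REML = TRUE)
  eff <- marginal_effects(fit, moderator = "x1")
  expect_identical(nrow(eff$means), 6L)
  expect_identical(nrow(eff$fold), 3L)
  # fold change equals the ratio of back-transformed means exactly
  for (lv in unique(eff$means$moderator_level)) {
    m <- eff$means[eff$means$moderator_level == lv, ]
    f <- eff$fold[eff$fold$moderator_level == lv, ]
    expect_equal(f$fold_change,
                 m$response_mean[m$treatment == "plastic"] /
                   m$response_mean[m$treatment == "control"],
                 tolerance = 1e-12)
  }
  expect_true(all(eff$fold$lcl <= eff$fold$fold_change),
              all(eff$fold$fold_change <= eff$fold$ucl))
  expect_error(marginal_effects(fit, moderator = "x9"), "moderator")
  # null treatment effect: fold ~ 1 with CI covering 1
  d0 <- make_lmm_data(n_lakes = 25, log_fold = 0, seed = 13)
  f0 <- marginal_effects(fit_lmm(d0, "y", REML = TRUE))$fold
  expect_true(f0$lcl <= 1 && f0$ucl >= 1)
})

test_that("marginal means agree with emmeans on the same REML fit", {
  d <- make_lmm_data(n_lakes = 15, seed = 14, covariates = 1)
  fit <- fit_lmm(d, "y", "x1", interactions = FALSE, REML = TRUE)
  eff <- marginal_effects(fit)
  em <- emmeans::emmeans(fit$model, "treatment",
                         lmer.df = "asymptotic", data = fit$data)
  es <- as.data.frame(em)
  expect_equal(eff$means$log_mean, es$emmean, tolerance = 1e-6)
  expect_equal(eff$means$se, es$SE, tolerance = 1e-6)
})
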