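#' Screen covariates for collinearity
#'
#' Inspects pairwise Pearson correlations among candidate covariates and, for
#' each pair with |r| strictly above the threshold, drops the covariate lower
#' in a priority order expressing biological relevance (the default puts DOM
#' functional diversity first and geographic position last). A pair at
#' exactly the threshold is kept whole.
#'
#' @param data data.frame containing the covariates.
#' @param covariates character vector of covariate column names.
#' @param priority character vector ordering covariates from most to least
#'   biologically relevant; covariates absent from it rank last,
#'   alphabetically.
#' @param threshold |r| above which a pair is collinear (default 0.90,
#'   strict).
#' @return list with `retained` (character vector) and `dropped`
#'   (data.frame of `dropped`, `kept`, `r`).
#' @export
collinearity_screen <- function(data, covariates,
                                priority = c("fd", "doc", "tn",
                                             "temperature", "ph",
                                             "latitude", "shannon"),
                                threshold = 0.90) {
  stopifnot(all(covariates %in% names(data)))
  pr <- match(covariates, priority)
  pr[is.na(pr)] <- length(priority) + seq_len(sum(is.na(pr)))
  retained <- covariates
  dropped <- data.frame(dropped = character(), kept = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (length(retained) < 2L) break
    cm <- stats::cor(data[retained], use = "pairwise.complete.obs")
    diag(cm) <- 0
    if (all(abs(cm) <= threshold, na.rm = TRUE)) break
    idx <- which(abs(cm) == max(abs(cm), na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- retained[idx[1]]; b <- retained[idx[2]]
    drop <- if (pr[match(a, covariates)] > pr[match(b, covariates)]) a else b
    keep <- setdiff(c(a, b), drop)
    dropped <- rbind(dropped, data.frame(dropped = drop, kept = keep,
                                         r = cm[idx[1], idx[2]],
                                         stringsAsFactors = FALSE))
    retained <- setdiff(retained, drop)
  }
  list(retained = retained, dropped = dropped)
}

#' Fit a log-scale linear mixed model with a lake random intercept
#'
#' Models the natural log of a positive metabolic response (BPP or BGE) as a
#' function of the leachate treatment, z-standardised lake covariates, and
#' (optionally) treatment-by-covariate interactions, with a random intercept
#' per lake to account for repeated measures. Covariates are standardised
#' internally (means/SDs stored) so that "+/- 1 SD" moderator probing and
#' effect-size comparability are exact.
#'
#' @param data data.frame with one row per bottle: the response column,
#'   `treatment` (`"control"`/`"plastic"`), `lake_id`, and covariate columns.
#'   Rows with missing response or covariates are dropped listwise.
#' @param response name of the (positive) response column.
#' @param covariates character vector of covariate columns (may be empty).
#' @param interactions include treatment-by-covariate interactions
#'   (default TRUE).
#' @param REML fit by REML (TRUE) or maximum likelihood (FALSE, required for
#'   AIC-based elimination).
#' @return object of class `"dom_lmm"`: list with elements `model` (the
#'   `lmerMod`), `data` (standardised analysis frame), `response`,
#'   `covariates`, `scaling` (covariate means/SDs), `terms` (fixed-effect
#'   term labels) and `REML`.
#' @export
fit_lmm <- function(data, response, covariates = character(),
                    interactions = TRUE, REML = FALSE) {
  stopifnot(response %in% names(data),
            all(c("treatment", "lake_id") %in% names(data)),
            all(covariates %in% names(data)))
  d <- data[, c(response, "treatment", "lake_id", covariates), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (any(d[[response]] <= 0)) stop("response must be positive (log scale)")
  if (length(unique(d$lake_id)) < 2L) stop("need at least 2 lakes")
  d$.logresp <- log(d[[response]])
  d$treatment <- factor(d$treatment, levels = c("control", "plastic"))
  d$lake_id <- factor(d$lake_id)
  scaling <- lapply(covariates, function(v) {
    m <- mean(d[[v]]); s <- stats::sd(d[[v]])
    if (!is.finite(s) || s == 0) stop("covariate ", v, " is constant")
    d[[v]] <<- (d[[v]] - m) / s
    c(mean = m, sd = s)
  })
  names(scaling) <- covariates
  terms <- "treatment"
  if (length(covariates)) {
    terms <- c(terms, covariates,
               if (interactions) paste0("treatment:", covariates))
  }
  fit <- .refit_lmm(d, terms, REML)
  structure(list(model = fit, data = d, response = response,
                 covariates = covariates, scaling = scaling,
                 terms = terms, REML = REML),
            class = "dom_lmm")
}

.refit_lmm <- function(d, terms, REML) {
  rhs <- paste(c(terms, "(1 | lake_id)"), collapse = " + ")
  f <- stats::as.formula(paste(".logresp ~", rhs))
  # rank check on the fixed part before handing to lme4
  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(terms, collapse = " + "))), d)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressMessages(lme4::lmer(
    f, data = d, REML = REML,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  fit
}

#' @export
print.dom_lmm <- function(x, ...) {
  cat("<dom_lmm> log(", x$response, ") ~ ",
      paste(x$terms, collapse = " + "), " + (1 | lake_id)  [",
      if (x$REML) "REML" else "ML", "]\n", sep = "")
  print(lme4::fixef(x$model))
  invisible(x)
}

# term labels droppable under marginality: interactions always; a covariate
# main effect only once its interaction is gone; treatment never.
.droppable <- function(terms) {
  inter <- grep(":", terms, value = TRUE)
  inter_cov <- sub("^treatment:", "", inter)
  mains <- setdiff(terms, c(inter, "treatment"))
  c(inter, setdiff(mains, inter_cov))
}

#' AIC backwards stepwise elimination of fixed effects
#'
#' Starting from an ML fit, repeatedly refits the model without each
#' droppable term (marginality respected: a covariate main effect is only
#' droppable once its treatment interaction is gone; the treatment main
#' effect, being the design variable, is never dropped) and removes the term
#' whose deletion yields the lowest AIC, provided that AIC is strictly below
#' the current model's AIC + 2 (i.e. the term's retention does not improve
#' AIC by 2 or more). Ties are broken by fewer parameters then term name.
#' The selected model is refit by REML.
#'
#' @param fit a `"dom_lmm"` fitted with `REML = FALSE`.
#' @return the selected model as a `"dom_lmm"` (REML refit), with an
#'   `aic_trace` element recording each elimination step.
#' @export
backward_eliminate <- function(fit) {
  stopifnot(inherits(fit, "dom_lmm"))
  if (fit$REML) stop("backward elimination requires an ML fit (REML = FALSE)")
  d <- fit$data
  terms <- fit$terms
  cur <- fit$model
  trace <- data.frame(step = 0L, dropped = NA_character_,
                      aic = stats::AIC(cur), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    cand <- sort(.droppable(terms))
    if (length(cand) == 0L) break
    fits <- lapply(cand, function(tm) .refit_lmm(d, setdiff(terms, tm),
                                                 REML = FALSE))
    aics <- vapply(fits, stats::AIC, numeric(1))
    npar <- vapply(fits, function(f) length(lme4::fixef(f)), numeric(1))
    ord <- order(aics, npar, cand)
    best <- ord[1]
    if (!(aics[best] < stats::AIC(cur) + 2)) break
    step <- step + 1L
    terms <- setdiff(terms, cand[best])
    cur <- fits[[best]]
    trace <- rbind(trace, data.frame(step = step, dropped = cand[best],
                                     aic = aics[best]))
  }
  out <- fit
  out$terms <- terms
  out$REML <- TRUE
  out$model <- .refit_lmm(d, terms, REML = TRUE)
  out$aic_trace <- trace
  out
}

#' Marginal treatment effects, fold changes and interaction probing
#'
#' Estimated marginal means per treatment at covariate means (all
#' standardised covariates at 0), back-transformed from the log scale by
#' exponentiation, with 95% Wald normal intervals. When a moderator is
#' given, effects are additionally evaluated with that covariate at -1 SD,
#' the mean, and +1 SD (its z-score at -1, 0, +1). The fold change is
#' `exp(plastic - control contrast)` so it equals the ratio of the
#' back-transformed means exactly.
#'
#' @param fit a `"dom_lmm"`, normally the REML refit from
#'   [backward_eliminate()].
#' @param moderator optional covariate name to probe; must appear in the
#'   retained model terms.
#' @param level confidence level (default 0.95).
#' @return list with `means` (rows: moderator level x treatment; columns
#'   `response_mean`, `lcl`, `ucl`) and `fold` (rows: moderator level;
#'   columns `fold_change`, `lcl`, `ucl`).
#' @export
marginal_effects <- function(fit, moderator = NULL, level = 0.95) {
  stopifnot(inherits(fit, "dom_lmm"))
  if (!is.null(moderator) &&
      !(moderator %in% unlist(strsplit(fit$terms, ":", fixed = TRUE)))) {
    stop("moderator '", moderator, "' is not in the fitted model")
  }
  beta <- lme4::fixef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  z <- stats::qnorm(1 - (1 - level) / 2)
  mod_levels <- if (is.null(moderator)) {
    data.frame(.modz = 0, moderator_level = "mean")
  } else {
    data.frame(.modz = c(-1, 0, 1),
               moderator_level = c("-1 SD", "mean", "+1 SD"))
  }
  covs <- intersect(fit$covariates,
                    unlist(strsplit(fit$terms, ":", fixed = TRUE)))
  rowX <- function(trt, modz) {
    nd <- data.frame(treatment = factor(trt,
                                        levels = c("control", "plastic")))
    for (v in covs) nd[[v]] <- if (!is.null(moderator) && v == moderator)
      modz else 0
    stats::model.matrix(stats::as.formula(
      paste("~", paste(fit$terms, collapse = " + "))), nd)
  }
  means <- do.call(rbind, lapply(seq_len(nrow(mod_levels)), function(i) {
    do.call(rbind, lapply(c("control", "plastic"), function(trt) {
      X <- rowX(trt, mod_levels$.modz[i])
      est <- drop(X %*% beta)
      se <- sqrt(drop(X %*% V %*% t(X)))
      data.frame(moderator_level = mod_levels$moderator_level[i],
                 treatment = trt, log_mean = est, se = se,
                 response_mean = exp(est),
                 lcl = exp(est - z * se), ucl = exp(est + z * se),
                 stringsAsFactors = FALSE)
    }))
  }))
  fold <- do.call(rbind, lapply(seq_len(nrow(mod_levels)), function(i) {
    L <- rowX("plastic", mod_levels$.modz[i]) -
      rowX("control", mod_levels$.modz[i])
    est <- drop(L %*% beta)
    se <- sqrt(drop(L %*% V %*% t(L)))
    data.frame(moderator_level = mod_levels$moderator_level[i],
               log_contrast = est, se = se, fold_change = exp(est),
               lcl = exp(est - z * se), ucl = exp(est + z * se),
               stringsAsFactors = FALSE)
  }))
  rownames(means) <- rownames(fold) <- NULL
  list(means = means, fold = fold)
}
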