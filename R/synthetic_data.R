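#' Study design for the synthetic-data generators
#'
#' Encodes the field design the generators emulate: 29 lakes sampled across
#' two treatments (plastic leachate at 0.1 mg C L-1 added vs distilled-water
#' control), with DOM spectra for 22 lakes, 16S communities for 20,
#' respiration vials for 18; 3 replicate bottles per treatment for BPP and a
#' single vial pair per treatment for respiration/BGE. Covariate ranges match
#' the surveyed gradients (DOC 0.55-7.97 mg L-1, pH 5.81-6.95, temperature
#' 9.4-20.6 degC, DOM functional diversity 6.12-6.96, latitude 59.1-70.3 N,
#' Shannon diversity 3.46-6.38). Default true effect sizes are the reported
#' treatment fold changes (2.29x for BPP, 1.72x for BGE, with a negative
#' FD-by-treatment interaction on BGE), so the default run is calibrated to
#' the study's summary values.
#'
#' @param n_lakes,lakes_with_dom,lakes_with_16s,lakes_with_respiration lake
#'   counts; data-availability subsets are taken as the first k lakes.
#' @param bpp_replicates,bge_replicates replicates per treatment per lake.
#' @param effects list of per-response true effects: each of `bpp` and `bge`
#'   has `control_mean` (response scale), `log_fold` (treatment effect on the
#'   log scale) and `interactions` (named vector of per-SD
#'   treatment-by-covariate slopes).
#' @param noise list with `lake_sd` and `resid_sd`, the random-intercept and
#'   residual SDs on the log scale.
#' @return list of class `"study_design"`.
#' @export
study_design <- function(n_lakes = 29, lakes_with_dom = 22,
                         lakes_with_16s = 20, lakes_with_respiration = 18,
                         bpp_replicates = 3, bge_replicates = 1,
                         effects = list(
                           bpp = list(control_mean = 0.078,
                                      log_fold = log(2.29),
                                      interactions = c()),
                           bge = list(control_mean = 0.081,
                                      log_fold = log(1.72),
                                      interactions = c(fd = -0.34))),
                         noise = list(lake_sd = 0.45, resid_sd = 0.35)) {
  # subset sizes never exceed the lake count (reduced designs shrink them)
  structure(list(
    n_lakes = as.integer(n_lakes),
    lakes_with_dom = as.integer(min(lakes_with_dom, n_lakes)),
    lakes_with_16s = as.integer(min(lakes_with_16s, n_lakes)),
    lakes_with_respiration = as.integer(min(lakes_with_respiration,
                                            n_lakes)),
    bpp_replicates = bpp_replicates, bge_replicates = bge_replicates,
    covariate_ranges = list(
      fd = c(6.12, 6.96), doc = c(0.55, 7.97), tn = c(0.10, 0.90),
      temperature = c(9.4, 20.6), ph = c(5.81, 6.95),
      latitude = c(59.1, 70.3), shannon = c(3.46, 6.38)),
    effects = effects, noise = noise), class = "study_design")
}

.lake_ids <- function(design) sprintf("lake_%02d", seq_len(design$n_lakes))

#' Draw lake covariates for a synthetic study
#'
#' Covariates are drawn independently and uniformly within the design's
#' ranges. Availability masks follow the design: DOM-derived covariates
#' (`fd`, `doc`, `tn`) are `NA` outside the DOM lakes and `shannon` outside
#' the 16S lakes.
#'
#' @param design a [study_design()].
#' @param seed optional RNG seed.
#' @return data.frame with `lake_id` and one column per covariate.
#' @export
make_lake_covariates <- function(design = study_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_lakes
  cov <- data.frame(lake_id = .lake_ids(design))
  for (v in names(design$covariate_ranges)) {
    r <- design$covariate_ranges[[v]]
    cov[[v]] <- stats::runif(n, r[1], r[2])
  }
  dom <- seq_len(design$lakes_with_dom)
  cov$fd[-dom] <- NA
  cov$doc[-dom] <- NA
  cov$tn[-dom] <- NA
  cov$shannon[-seq_len(design$lakes_with_16s)] <- NA
  cov
}

#' Generate metabolic responses from a known mixed model
#'
#' Draws log-normal responses from the same random-intercept model the
#' inference module fits: per bottle,
#' `log y = log(control_mean) + treat * (log_fold + sum slopes * z) +
#' b_lake + eps`, with `z` the z-scores of the interacting covariates across
#' the included lakes, `b_lake ~ N(0, lake_sd^2)` and
#' `eps ~ N(0, resid_sd^2)`. The BGE scenario uses the respiration-lake
#' subset with 1 replicate; BPP uses all lakes with 3 replicates.
#'
#' @param design a [study_design()].
#' @param scenario `"bpp"` or `"bge"`.
#' @param covariates optional lake covariates (from
#'   [make_lake_covariates()]); drawn afresh if `NULL`.
#' @param lake_sd,resid_sd noise SDs, defaulting to the design's; set both 0
#'   for an exact, noiseless dataset.
#' @param seed optional RNG seed.
#' @return data.frame with one row per bottle (`lake_id`, `treatment`,
#'   `replicate`, the response column named after the scenario, covariates),
#'   with attribute `truth` recording the generating effects.
#' @export
make_response_data <- function(design = study_design(),
                               scenario = c("bpp", "bge"),
                               covariates = NULL,
                               lake_sd = design$noise$lake_sd,
                               resid_sd = design$noise$resid_sd,
                               seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(covariates)) covariates <- make_lake_covariates(design)
  eff <- design$effects[[scenario]]
  n_lakes <- if (scenario == "bge") design$lakes_with_respiration else
    design$n_lakes
  reps <- if (scenario == "bge") design$bge_replicates else
    design$bpp_replicates
  lakes <- .lake_ids(design)[seq_len(n_lakes)]
  d <- expand.grid(replicate = seq_len(reps),
                   treatment = c("control", "plastic"),
                   lake_id = lakes, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d <- d[, c("lake_id", "treatment", "replicate")]
  d <- merge(d, covariates, by = "lake_id", sort = TRUE)
  b <- stats::rnorm(length(lakes), 0, lake_sd)
  names(b) <- lakes
  trt <- as.numeric(d$treatment == "plastic")
  eta <- log(eff$control_mean) + trt * eff$log_fold + b[d$lake_id] +
    stats::rnorm(nrow(d), 0, resid_sd)
  for (v in names(eff$interactions)) {
    z <- (d[[v]] - mean(covariates[[v]], na.rm = TRUE)) /
      stats::sd(covariates[[v]], na.rm = TRUE)
    eta <- eta + trt * eff$interactions[[v]] * z
  }
  d[[scenario]] <- exp(eta)
  rownames(d) <- NULL
  attr(d, "truth") <- list(scenario = scenario,
                           control_mean = eff$control_mean,
                           log_fold = eff$log_fold,
                           fold = exp(eff$log_fold),
                           interactions = eff$interactions,
                           lake_sd = lake_sd, resid_sd = resid_sd)
  d
}

# Enumerate the CHO formula space (even h, O:C <= 1.2, H:C in [0.3, 2.2],
# DBE >= 0, neutral mass inside the analytical window) with carbon count and
# lability flag. Small enough (tens of thousands of rows) to sample from
# directly.
.cho_space <- function(c_range, mass_window = c(152, 995)) {
  cc <- seq(c_range[1], c_range[2])
  grid <- do.call(rbind, lapply(cc, function(ci) {
    h_lo <- max(2L, 2L * ceiling(0.3 * ci / 2))
    h_hi <- min(2L * ci + 2L, 2L * floor(2.2 * ci / 2))
    if (h_hi < h_lo) return(NULL)
    h <- seq.int(h_lo, h_hi, by = 2L)
    o <- seq_len(min(40L, floor(1.2 * ci)))
    g <- expand.grid(h = h, o = o, KEEP.OUT.ATTRS = FALSE)
    g$c <- ci
    g
  }))
  grid$n <- 0L
  grid$s <- 0L
  mass <- monoisotopic_mass(grid)
  grid <- grid[mass >= mass_window[1] & mass <= mass_window[2], ,
               drop = FALSE]
  grid$labile <- grid$h / grid$c >= 1.5
  grid$formula <- format_formula(grid)
  grid
}

# Sample n distinct CHO formulas with n_labile of them at H:C >= 1.5,
# excluding `exclude`, with carbon counts weighted towards a normal profile
# (mean/sd) so the functional-diversity scale of the sample is controllable.
.random_cho <- function(n, n_labile, c_range, c_profile = NULL,
                        exclude = character()) {
  space <- .cho_space(c_range)
  space <- space[!(space$formula %in% exclude), , drop = FALSE]
  if (is.null(c_profile)) c_profile <- c(mean(c_range), diff(c_range) / 4)
  pick <- function(sub, k) {
    if (k == 0L) return(character())
    if (nrow(sub) < k) stop("could not generate enough distinct formulas")
    w <- stats::dnorm(sub$c, c_profile[1], c_profile[2]) + 1e-9
    sub$formula[sample.int(nrow(sub), k, prob = w)]
  }
  c(pick(space[space$labile, , drop = FALSE], n_labile),
    pick(space[!space$labile, , drop = FALSE], n - n_labile))
}

#' Generate a synthetic DOM formula universe and peak lists
#'
#' Builds one leachate sample, `lakes_with_dom` lake samples and a procedural
#' blank, with controlled leachate/lake overlap and lability fractions, then
#' degrades every table to a calibrated peak list by perturbing exact
#' \eqn{[M-H]^-} masses with Gaussian ppm error. The packaged plastic-additive
#' formulas are always injected into the leachate-unique set; blank
#' contaminant formulas are injected into every sample so that blank
#' correction is exercised. Leachate formulas span a narrower carbon range
#' than lake DOM, giving the leachate a markedly lower functional diversity.
#'
#' @param design a [study_design()].
#' @param n_leachate_formulas leachate formula count after blank correction
#'   (default 855).
#' @param lake_formula_range range of per-lake formula counts
#'   (default 3684-7116).
#' @param overlap_fraction fraction of leachate formulas shared with at least
#'   one lake (default 0.65, i.e. ~35% unique).
#' @param leachate_lability,lake_lability target count fractions of formulas
#'   with H:C >= 1.5.
#' @param labile_intensity_factor multiplicative intensity boost applied to
#'   high-lability leachate formulas so that labile compounds dominate the
#'   leachate's normalised peak intensity (default 20, putting roughly 80%
#'   of intensity on the labile fraction).
#' @param ppm_sd Gaussian mass-error SD applied to peak m/z, in ppm.
#' @param n_blank number of blank contaminant formulas.
#' @param seed optional RNG seed.
#' @return list with `leachate`, `lakes` (named list) and `blank`
#'   ([formula_table()]s, samples still containing blank contaminants),
#'   `peaks` (data.frame `sample_id`, `mz`, `intensity`) and `truth`
#'   (clean leachate formula set, unique formulas and percentage).
#' @export
make_formula_universe <- function(design = study_design(),
                                  n_leachate_formulas = 855,
                                  lake_formula_range = c(3684, 7116),
                                  overlap_fraction = 0.65,
                                  leachate_lability = 0.186,
                                  lake_lability = 0.115,
                                  labile_intensity_factor = 20,
                                  ppm_sd = 0.1, n_blank = 25,
                                  seed = NULL) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]")
  }
  if (leachate_lability < 0 || leachate_lability > 1 ||
      lake_lability < 0 || lake_lability > 1) {
    stop("lability targets must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  additives <- unique(plastic_additives()$formula)

  pool_n <- max(9000, lake_formula_range[2] + 500)
  pool_labile <- round(lake_lability * pool_n)
  pool <- .random_cho(pool_n, pool_labile, c_range = c(8, 50),
                      c_profile = c(25, 5), exclude = additives)

  # lake tables first, so the leachate's shared formulas can be drawn from
  # compositions genuinely present in at least one lake
  lake_sets <- list()
  lake_ids <- .lake_ids(design)[seq_len(design$lakes_with_dom)]
  for (id in lake_ids) {
    n_l <- sample(seq(lake_formula_range[1], lake_formula_range[2]), 1)
    lake_sets[[id]] <- sample(pool, n_l)
  }
  lake_union <- unique(unlist(lake_sets, use.names = FALSE))
  union_atoms <- parse_formula(lake_union)
  union_labile <- union_atoms$h / union_atoms$c >= 1.5
  # weight towards the leachate's narrow carbon band (low size diversity)
  union_w <- stats::dnorm(union_atoms$c, 15, 3) + 1e-9

  n_shared <- round(overlap_fraction * n_leachate_formulas)
  n_unique <- n_leachate_formulas - n_shared
  n_labile_total <- round(leachate_lability * n_leachate_formulas)
  n_unique_rand <- n_unique - length(additives)
  if (n_unique_rand < 0) stop("n_leachate_formulas too small for overlap")
  uniq_labile <- min(round(leachate_lability * n_unique_rand),
                     n_labile_total)
  uniq_rand <- .random_cho(n_unique_rand, uniq_labile, c_range = c(10, 20),
                           c_profile = c(15, 3),
                           exclude = c(pool, additives))
  shared_labile <- min(max(n_labile_total - uniq_labile, 0L),
                       sum(union_labile))
  draw_from_union <- function(sel, k) {
    idx <- which(sel)
    idx[sample.int(length(idx), k, prob = union_w[idx])]
  }
  shared <- lake_union[c(draw_from_union(union_labile, shared_labile),
                         draw_from_union(!union_labile,
                                         n_shared - shared_labile))]
  leachate_formulas <- c(uniq_rand, additives, shared)

  blank_formulas <- .random_cho(n_blank, round(0.1 * n_blank),
                                c_range = c(8, 50),
                                exclude = c(pool, leachate_formulas))

  lakes <- lapply(lake_ids, function(id) {
    fs <- c(lake_sets[[id]], blank_formulas)
    formula_table(fs, stats::rlnorm(length(fs), 0, 1), sample_id = id)
  })
  names(lakes) <- lake_ids
  leach_all <- c(leachate_formulas, blank_formulas)
  leach_atoms <- parse_formula(leach_all)
  leach_int <- stats::rlnorm(length(leach_all), 0, 1) *
    ifelse(leach_atoms$h / leach_atoms$c >= 1.5, labile_intensity_factor, 1)
  leachate <- formula_table(leach_all, leach_int, sample_id = "leachate")
  blank <- formula_table(blank_formulas,
                         stats::rlnorm(n_blank, 0, 1), sample_id = "blank")

  tables <- c(list(leachate = leachate), lakes, list(blank = blank))
  peaks <- do.call(rbind, lapply(tables, function(tb) {
    mz <- ion_mass(tb) * (1 + stats::rnorm(nrow(tb), 0, ppm_sd * 1e-6))
    data.frame(sample_id = attr(tb, "sample_id"), mz = mz,
               intensity = tb$intensity, stringsAsFactors = FALSE)
  }))
  rownames(peaks) <- NULL
  list(leachate = leachate, lakes = lakes, blank = blank, peaks = peaks,
       truth = list(leachate_formulas = leachate_formulas,
                    unique_formulas = c(uniq_rand, additives),
                    pct_unique = 100 * n_unique / n_leachate_formulas,
                    lability_count_frac =
                      (uniq_labile + shared_labile) / n_leachate_formulas))
}

#' Generate raw incubation measurements from known true rates
#'
#' Inverts the metabolism chain: scintillation CPMs are produced from true
#' per-bottle BPP through the leucine arithmetic (counting efficiency 0.8,
#' specific activity 60 Ci mmol-1, 1 h / 1.5 mL assay), and oxygen
#' percent-saturation series are produced from true respiration with an
#' exponential equilibration transient followed by a stable plateau. With
#' `noise = FALSE` the generated records are exactly invertible by
#' [incubation_rates()] (up to the vanishing transient remnant).
#'
#' @param design a [study_design()].
#' @param rates data.frame of true rates with columns `lake_id`, `treatment`,
#'   `replicate`, `bpp` (ug C L-1 h-1) and `respiration` (ug C L-1 h-1,
#'   used for replicate 1 only, the single respiration vial); `NA`
#'   respiration skips the lake's oxygen series.
#' @param temperature_C per-lake water temperature; either a single value or
#'   a named vector by `lake_id` (default 15).
#' @param duration_h incubation duration (default 72).
#' @param noise add Poisson counting noise and optode plateau noise.
#' @param seed optional RNG seed.
#' @return list with `scint` (per-bottle scintillation records) and `oxygen`
#'   (long-format optode series), matching the [incubation_rates()] input
#'   contract, plus `truth` (the input rates).
#' @export
make_incubation_data <- function(design = study_design(), rates,
                                 temperature_C = 15, duration_h = 72,
                                 noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("lake_id", "treatment", "replicate", "bpp") %in%
                  names(rates)))
  eff <- 0.8
  standard_dpm <- 1e5
  sa <- 60             # Ci/mmol
  vol <- 0.0015
  hrs <- 1
  leu_c <- 1.55
  temp <- if (length(temperature_C) == 1L) {
    stats::setNames(rep(temperature_C, design$n_lakes), .lake_ids(design))
  } else temperature_C

  dpm_per_mol <- 2.22e12 * sa * 1000
  mol_leu <- rates$bpp * vol * hrs / (leu_c * 1e9)
  net_cpm <- mol_leu * dpm_per_mol * eff
  killed <- 40; blank <- 30
  live <- net_cpm + killed + blank
  if (noise) {
    live <- stats::rpois(length(live), live)
    killed <- stats::rpois(length(live), killed)
    blank <- stats::rpois(length(live), blank)
  }
  scint <- data.frame(lake_id = rates$lake_id, treatment = rates$treatment,
                      bottle = rates$replicate, cpm_live = live,
                      cpm_killed = killed, cpm_blank = blank,
                      cpm_standard = eff * standard_dpm,
                      standard_dpm = standard_dpm, specific_activity = sa,
                      incubation_hours = hrs, sample_volume_L = vol,
                      stringsAsFactors = FALSE)

  resp <- rates[rates$replicate == 1 & !is.na(rates$respiration), ,
                drop = FALSE]
  oxy <- NULL
  if (nrow(resp)) {
    n_read <- 240L
    series <- lapply(seq_len(nrow(resp)), function(i) {
      tc <- temp[[resp$lake_id[i]]]
      sat <- o2_saturation_mgL(tc)
      start_pct <- 95
      drop_mg <- resp$respiration[i] * duration_h * 31.9988 / 12.011 / 1000
      end_pct <- (start_pct / 100 * sat - drop_mg) / sat * 100
      one <- function(vial, pct) {
        t <- seq_len(n_read)
        x <- pct + 4 * exp(-t / 25) +
          if (noise) stats::rnorm(n_read, 0, 0.02) else 0
        data.frame(lake_id = resp$lake_id[i], treatment = resp$treatment[i],
                   vial = vial, t_seconds = t, pct_saturation = x,
                   temperature_C = tc, salinity_psu = 0,
                   pressure_hPa = 1013.25, stringsAsFactors = FALSE)
      }
      rbind(one("start", start_pct), one("end", end_pct))
    })
    oxy <- do.call(rbind, series)
    rownames(oxy) <- NULL
  }
  list(scint = scint, oxygen = oxy, truth = rates)
}

#' Generate a synthetic ASV count table with planted associations
#'
#' Negative-binomial counts with log-normal baseline abundances, per-sample
#' library-size factors drawn uniformly in [0.5, 2], and a chosen subset of
#' ASVs carrying a planted log2-per-unit slope on a per-sample covariate
#' (e.g. the lake's log2 fold change in BPP). Genus labels are drawn from
#' taxa prominent in northern-lake surface waters.
#'
#' @param design a [study_design()].
#' @param n_asv number of ASVs (default 300, a reduced emulation of the
#'   2148-ASV field scale).
#' @param covariate per-sample covariate; defaults to draws around the
#'   study-level log2 BPP fold change.
#' @param planted_fraction fraction of ASVs given the planted slope.
#' @param planted_log2_slope the planted association strength.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param mean_log,sd_log log-normal baseline abundance parameters.
#' @param seed optional RNG seed.
#' @return list with `counts` (ASV x sample matrix), `taxonomy` (data.frame
#'   `asv`, `genus`), `covariate`, and `truth` (`planted` ids and the slope).
#' @export
make_asv_table <- function(design = study_design(), n_asv = 300,
                           covariate = NULL, planted_fraction = 0,
                           planted_log2_slope = 1.5, dispersion = 0.2,
                           mean_log = 4, sd_log = 1.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_samp <- design$lakes_with_16s
  samples <- .lake_ids(design)[seq_len(n_samp)]
  if (is.null(covariate)) {
    covariate <- stats::rnorm(n_samp, log2(2.29), 0.5)
  }
  stopifnot(length(covariate) == n_samp)
  base <- stats::rlnorm(n_asv, mean_log, sd_log)
  lib <- stats::runif(n_samp, 0.5, 2)
  slopes <- rep(0, n_asv)
  n_planted <- round(planted_fraction * n_asv)
  planted <- if (n_planted > 0) sample.int(n_asv, n_planted) else integer()
  slopes[planted] <- planted_log2_slope
  cov_c <- covariate - mean(covariate)
  mu <- outer(base, lib) * 2^(outer(slopes, cov_c))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = n_asv,
                   dimnames = list(paste0("ASV", sprintf("%04d",
                                                         seq_len(n_asv))),
                                   samples))
  genera <- c("Acinetobacter", "Exiguobacterium", "Brevundimonas",
              "Hymenobacter", "Deinococcus", "Pseudomonas", "Flavobacterium",
              "Polynucleobacter", "Limnohabitans", "Sphingomonas")
  taxonomy <- data.frame(asv = rownames(counts),
                         genus = sample(genera, n_asv, replace = TRUE),
                         stringsAsFactors = FALSE)
  list(counts = counts, taxonomy = taxonomy, covariate = covariate,
       truth = list(planted = rownames(counts)[planted],
                    log2_slope = planted_log2_slope,
                    dispersion = dispersion))
}
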