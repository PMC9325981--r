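#' Bacterial protein production from leucine scintillation counts
#'
#' Converts raw counts-per-minute from a tritiated-leucine incorporation
#' assay into a carbon-uptake rate. Net signal = live - killed - blank CPM,
#' clamped at zero (field noise can push it negative), converted to
#' disintegrations per minute via the counting efficiency of a standard of
#' known activity, to moles of leucine via the lot's specific activity
#' (2.22e12 DPM per Ci), and to carbon with a fixed leucine-to-carbon factor
#' (default 1.55 kg C per mol leucine, no isotope-dilution correction).
#'
#' @param cpm_live,cpm_killed,cpm_blank counts per minute of the live sample,
#'   the TCA-killed control, and the blank.
#' @param cpm_standard,standard_dpm CPM and known DPM of the calibration
#'   standard; their ratio is the counting efficiency, required in (0, 1].
#' @param specific_activity specific activity of the leucine lot, Ci per mmol.
#' @param incubation_hours assay duration in hours (default 1).
#' @param sample_volume_L assay volume in litres (default 0.0015, i.e. 1.5 mL).
#' @param leucine_to_carbon kg C per mol leucine (default 1.55).
#' @return bacterial protein production in ug C L-1 h-1 (vectorised).
#' @export
bpp_from_counts <- function(cpm_live, cpm_killed, cpm_blank,
                            cpm_standard, standard_dpm,
                            specific_activity,
                            incubation_hours = 1,
                            sample_volume_L = 0.0015,
                            leucine_to_carbon = 1.55) {
  if (any(c(cpm_live, cpm_killed, cpm_blank, cpm_standard) < 0)) {
    stop("CPM values must be >= 0")
  }
  eff <- cpm_standard / standard_dpm
  if (any(eff <= 0 | eff > 1)) {
    stop("counting efficiency (cpm_standard/standard_dpm) must be in (0, 1]")
  }
  stopifnot(all(sample_volume_L > 0), all(incubation_hours > 0))
  net_cpm <- cpm_live - cpm_killed - cpm_blank
  if (any(net_cpm < 0)) {
    warning("negative net CPM clamped to zero")
    net_cpm <- pmax(net_cpm, 0)
  }
  dpm <- net_cpm / eff
  dpm_per_mol <- 2.22e12 * specific_activity * 1000  # Ci/mmol -> DPM/mol
  mol_leu <- dpm / dpm_per_mol
  ug_c <- mol_leu * leucine_to_carbon * 1e9          # kg C -> ug C
  ug_c / (sample_volume_L * incubation_hours)
}

#' Equilibrium oxygen solubility in freshwater/brackish water
#'
#' Air-saturation dissolved-oxygen concentration (mg L-1) from temperature
#' and salinity via the Garcia & Gordon refit of the Benson & Krause
#' solubility data, scaled linearly by barometric pressure relative to
#' 1013.25 hPa. Valid over roughly 0--40 degC and 0--40 PSU.
#'
#' @param temperature_C water temperature in degrees Celsius.
#' @param salinity_psu practical salinity (default 0, fresh water).
#' @param pressure_hPa barometric pressure (default 1013.25).
#' @return saturation concentration in mg O2 L-1.
#' @export
o2_saturation_mgL <- function(temperature_C, salinity_psu = 0,
                              pressure_hPa = 1013.25) {
  if (any(temperature_C < 0 | temperature_C > 40) ||
      any(salinity_psu < 0 | salinity_psu > 40)) {
    stop("temperature/salinity outside the solubility model's validity range")
  }
  ts <- log((298.15 - temperature_C) / (273.15 + temperature_C))
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
  b <- c(-0.00624523, -0.00737614, -0.0103410, -0.00817083)
  c0 <- -4.88682e-7
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity_psu * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity_psu^2
  ml_per_L <- exp(lnc)
  ml_per_L * 1.42905 * pressure_hPa / 1013.25
}

#' Dissolved oxygen from an optode percent-saturation series
#'
#' Optode readings drift during an equilibration transient before reaching a
#' steady state. Stability is detected with a rolling 10-point standard
#' deviation: the trailing run of readings whose window SD stays at or below
#' `stability_sd` is taken as stable, and the oxygen value is the median of
#' the last 10 stable readings, converted to mg L-1 with
#' [o2_saturation_mgL()]. If no trailing stable window exists, the median of
#' the last 10 raw readings is used and a warning is issued.
#'
#' @param pct_saturation numeric vector of percent air-saturation readings at
#'   1 s cadence (>= 10 readings, each in [0, 150]).
#' @param temperature_C,salinity_psu,pressure_hPa physical conditions of the
#'   reading, passed to [o2_saturation_mgL()].
#' @param stability_sd rolling-SD threshold in percent saturation
#'   (default 0.1).
#' @return dissolved oxygen in mg L-1, with attribute `stable` (logical).
#' @export
o2_concentration <- function(pct_saturation, temperature_C,
                             salinity_psu = 0, pressure_hPa = 1013.25,
                             stability_sd = 0.1) {
  x <- as.numeric(pct_saturation)
  if (length(x) < 10L) stop("need at least 10 optode readings")
  if (any(x < 0 | x > 150)) stop("percent saturation outside [0, 150]")
  w <- 10L
  n <- length(x)
  roll_sd <- vapply(seq.int(w, n),
                    function(i) stats::sd(x[(i - w + 1L):i]), numeric(1))
  stable_end <- roll_sd <= stability_sd  # window ending at index w..n
  stable <- isTRUE(stable_end[length(stable_end)])
  if (stable) {
    # trailing run of stable windows; the last 10 readings of it
    run <- rev(cumprod(rev(stable_end))) == 1
    first_win <- which(run)[1] + w - 1L  # index where stability starts
    tail_idx <- seq.int(max(first_win - w + 1L, n - w + 1L), n)
    val <- stats::median(x[utils::tail(tail_idx, w)])
  } else {
    warning("no trailing stable window found; using median of last 10 readings")
    val <- stats::median(x[(n - w + 1L):n])
  }
  out <- val / 100 * o2_saturation_mgL(temperature_C, salinity_psu,
                                       pressure_hPa)
  attr(out, "stable") <- stable
  out
}

#' Respiration rate from start/end dissolved-oxygen concentrations
#'
#' Converts oxygen drawdown over a dark incubation to a carbon
#' mineralisation rate assuming a respiratory quotient `rq` (mol CO2 per mol
#' O2, default 1). Oxygen production (negative consumption) is clamped to
#' zero with a warning, as expected for dark incubations.
#'
#' @param o2_start_mgL,o2_end_mgL dissolved oxygen (mg L-1) at the start and
#'   end of the incubation.
#' @param duration_h incubation duration in hours (> 0).
#' @param rq respiratory quotient.
#' @return respiration in ug C L-1 h-1.
#' @export
respiration_rate <- function(o2_start_mgL, o2_end_mgL, duration_h, rq = 1) {
  stopifnot(all(duration_h > 0))
  delta <- o2_start_mgL - o2_end_mgL
  if (any(delta < 0)) {
    warning("oxygen increased during incubation; respiration clamped to 0")
    delta <- pmax(delta, 0)
  }
  # mg O2 -> mmol O2 -> mmol C (x rq) -> ug C
  delta / duration_h / 31.9988 * rq * 12.011 * 1000
}

#' Bacterial growth efficiency
#'
#' Fraction of processed carbon allocated to biomass:
#' BGE = BPP / (BPP + respiration).
#'
#' @param bpp,respiration non-negative rates in the same units.
#' @return BGE in (0, 1]; `NA` when both rates are zero.
#' @export
growth_efficiency <- function(bpp, respiration) {
  stopifnot(all(bpp >= 0, na.rm = TRUE), all(respiration >= 0, na.rm = TRUE))
  tot <- bpp + respiration
  ifelse(tot > 0, bpp / tot, NA_real_)
}

#' Total carbon processed to sustain a biomass increase
#'
#' Given a cumulative increase in bacterial production and a growth
#' efficiency, the total carbon bacteria must have processed is
#' `delta_bpp_total / bge`.
#'
#' @param delta_bpp_total cumulative BPP increase (ug C L-1).
#' @param bge growth efficiency in (0, 1].
#' @return carbon processed (ug C L-1).
#' @export
carbon_processed <- function(delta_bpp_total, bge) {
  if (any(bge <= 0 | bge > 1)) stop("bge must be in (0, 1]")
  delta_bpp_total / bge
}

#' Leachate volume needed to reach a target added carbon concentration
#'
#' Solves the dosing equation `v * leachate_doc = target * (V + v)` for the
#' spike volume `v`, accounting for dilution of the incubation by the added
#' volume.
#'
#' @param target_added_conc target added carbon in the final mixture
#'   (mg C L-1).
#' @param leachate_doc DOC concentration of the leachate (mg C L-1); must
#'   exceed `target_added_conc`.
#' @param incubation_volume_L receiving water volume (L).
#' @return volume of leachate to add, in litres.
#' @export
spike_volume <- function(target_added_conc, leachate_doc,
                         incubation_volume_L) {
  stopifnot(all(target_added_conc >= 0), all(incubation_volume_L > 0))
  if (any(leachate_doc <= target_added_conc)) {
    stop("leachate DOC must exceed the target added concentration")
  }
  incubation_volume_L * target_added_conc / (leachate_doc - target_added_conc)
}

#' Per-bottle metabolic rates from raw incubation records
#'
#' Batch driver converting an incubation bundle (scintillation counts per
#' bottle and oxygen series per respiration vial) into per-lake,
#' per-treatment rates. BPP per lake x treatment is the mean over replicate
#' bottles; respiration uses the single start/end vial pair per treatment
#' (the study design has one respiration replicate), paired with that mean
#' BPP to form BGE.
#'
#' @param scint data.frame with columns `lake_id`, `treatment`, `bottle`,
#'   `cpm_live`, `cpm_killed`, `cpm_blank`, `cpm_standard`, `standard_dpm`,
#'   `specific_activity`, and optionally `incubation_hours`,
#'   `sample_volume_L`.
#' @param oxygen long data.frame with columns `lake_id`, `treatment`, `vial`
#'   (`"start"` or `"end"`), `t_seconds`, `pct_saturation`, `temperature_C`,
#'   `salinity_psu`, `pressure_hPa`.
#' @param duration_h incubation duration in hours for the oxygen drawdown
#'   (default 72).
#' @param rq respiratory quotient.
#' @param stability_sd optode stability threshold, see [o2_concentration()].
#' @param leucine_to_carbon kg C per mol leucine.
#' @return data.frame with one row per lake x treatment: `lake_id`,
#'   `treatment`, `bpp`, `respiration`, `bge` (respiration/bge `NA` for
#'   lakes without oxygen data).
#' @export
incubation_rates <- function(scint, oxygen = NULL, duration_h = 72, rq = 1,
                             stability_sd = 0.1, leucine_to_carbon = 1.55) {
  hrs <- if ("incubation_hours" %in% names(scint)) scint$incubation_hours else 1
  vol <- if ("sample_volume_L" %in% names(scint)) scint$sample_volume_L
         else 0.0015
  scint$bpp <- bpp_from_counts(scint$cpm_live, scint$cpm_killed,
                               scint$cpm_blank, scint$cpm_standard,
                               scint$standard_dpm, scint$specific_activity,
                               incubation_hours = hrs, sample_volume_L = vol,
                               leucine_to_carbon = leucine_to_carbon)
  agg <- stats::aggregate(bpp ~ lake_id + treatment, data = scint, FUN = mean)
  agg$respiration <- NA_real_
  if (!is.null(oxygen) && nrow(oxygen)) {
    key <- interaction(oxygen$lake_id, oxygen$treatment, oxygen$vial,
                       drop = TRUE)
    conc <- lapply(split(oxygen, key), function(d) {
      d <- d[order(d$t_seconds), , drop = FALSE]
      data.frame(lake_id = d$lake_id[1], treatment = d$treatment[1],
                 vial = d$vial[1],
                 o2 = as.numeric(o2_concentration(
                   d$pct_saturation, d$temperature_C[1], d$salinity_psu[1],
                   d$pressure_hPa[1], stability_sd = stability_sd)))
    })
    conc <- do.call(rbind, conc)
    wide <- stats::reshape(conc, idvar = c("lake_id", "treatment"),
                           timevar = "vial", direction = "wide")
    i <- match(paste(agg$lake_id, agg$treatment),
               paste(wide$lake_id, wide$treatment))
    ok <- !is.na(i)
    agg$respiration[ok] <- respiration_rate(wide$o2.start[i[ok]],
                                            wide$o2.end[i[ok]],
                                            duration_h, rq)
  }
  agg$bge <- ifelse(is.na(agg$respiration), NA_real_,
                    growth_efficiency(agg$bpp, agg$respiration))
  agg <- agg[order(agg$lake_id, agg$treatment), ]
  rownames(agg) <- NULL
  bottles <- scint[, c("lake_id", "treatment", "bottle", "bpp")]
  names(bottles)[3] <- "replicate"
  attr(agg, "bottles") <- bottles
  agg
}
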