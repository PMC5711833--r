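# 13C mass-balance partitioning of respired CO2-C.

VPDB_R <- 0.0111802  # 13C/12C isotope ratio of the VPDB standard

#' Convert delta-13C (per mil) to 13C atom fraction
#'
#' `R = R_VPDB * (delta/1000 + 1)`; `x = R / (1 + R)`.
#'
#' @param delta_13c delta-13C values in per mil vs VPDB; must be > -1000.
#' @param r_std Standard isotope ratio (default VPDB, 0.0111802).
#' @return Atom fraction of 13C.
#' @export
#' @examples
#' delta_to_atom_fraction(0)  # 0.011056
delta_to_atom_fraction <- function(delta_13c, r_std = VPDB_R) {
  if (any(delta_13c <= -1000, na.rm = TRUE))
    stop("`delta_13c` must be > -1000 per mil")
  r <- r_std * (delta_13c / 1000 + 1)
  r / (1 + r)
}

#' @rdname delta_to_atom_fraction
#' @param atom_fraction 13C atom fraction in (0, 1).
#' @export
atom_fraction_to_delta <- function(atom_fraction, r_std = VPDB_R) {
  check_number(atom_fraction, "atom_fraction", 0, 1, TRUE, TRUE)
  r <- atom_fraction / (1 - atom_fraction)
  (r / r_std - 1) * 1000
}

#' Convert a headspace CO2 concentration to CO2-C mass per g soil
#'
#' Standard ideal-gas accounting: blank-corrected mixing ratio times
#' `P * V / (R * T)` gives moles of CO2, converted to ug C per g dry soil.
#' A negative blank-corrected concentration is set to zero with a warning.
#'
#' @param concentration CO2 mixing ratio, uL per L.
#' @param headspace_volume Jar headspace volume, L (> 0).
#' @param soil_mass Dry soil mass, g (> 0).
#' @param temperature K (> 0).
#' @param pressure kPa.
#' @param blank_concentration Mean blank-jar mixing ratio, uL per L.
#' @return ug CO2-C per g soil.
#' @export
#' @examples
#' headspace_to_co2c_mass(1000, 1, 20)  # 24.55
headspace_to_co2c_mass <- function(concentration, headspace_volume,
                                   soil_mass, temperature = 298.15,
                                   pressure = 101.325,
                                   blank_concentration = 0) {
  check_number(headspace_volume, "headspace_volume", 0, strict_lower = TRUE)
  check_number(soil_mass, "soil_mass", 0, strict_lower = TRUE)
  check_number(temperature, "temperature", 0, strict_lower = TRUE)
  net <- concentration - blank_concentration
  if (any(net < 0, na.rm = TRUE)) {
    warning("negative blank-corrected concentration set to 0")
    net <- pmax(net, 0)
  }
  moles <- net * 1e-6 * pressure * 1000 * headspace_volume * 1e-3 /
    (8.314 * temperature)
  moles * 12.011e6 / soil_mass
}

#' Accumulate interval CO2-C masses over a window
#'
#' With a flushed-headspace design, cumulative respiration is the sum of
#' the per-interval amounts. The window end must coincide with a sampling
#' time; if a `schedule` is supplied, any missing interval fails loudly
#' rather than being imputed.
#'
#' @param time_h Interval end times, hours (sorted, unique).
#' @param co2c Interval CO2-C masses, ug C per g soil.
#' @param window `c(0, t)` accumulation window, hours.
#' @param schedule Optional full sampling schedule to check completeness
#'   against.
#' @return Cumulative CO2-C (ug C per g soil) over the window.
#' @export
#' @examples
#' accumulate_intervals(c(4, 12, 24, 36, 48), c(10, 20, 30, 20, 20))  # 100
accumulate_intervals <- function(time_h, co2c, window = c(0, max(time_h)),
                                 schedule = NULL) {
  if (is.unsorted(time_h, strictly = TRUE))
    stop("`time_h` must be strictly increasing")
  if (length(time_h) != length(co2c)) stop("length mismatch")
  if (!is.null(schedule)) {
    expected <- schedule[schedule > window[1] & schedule <= window[2]]
    missing <- setdiff(expected, time_h)
    if (length(missing))
      stop("missing sampling interval(s) at ",
           paste(missing, collapse = ", "), " h; no imputation is done")
  }
  keep <- time_h > window[1] & time_h <= window[2]
  sum(co2c[keep])
}

#' Partition total CO2-C into its glucose-derived component
#'
#' Two-source isotope mixing:
#' `R_glucose = R_t * (x_sample - x_soil) / (x_glucose - x_soil)`.
#' Vectorized over intervals; apply per interval and sum (exact when
#' abundances vary in time) or once on cumulative weighted-mean
#' abundances.
#'
#' @param rt Total CO2-C (ug C per g soil).
#' @param x_sample Measured 13C atom fraction of the evolved CO2.
#' @param x_soil Atom fraction of CO2 from water-only control soil.
#' @param x_glucose Atom fraction of the added glucose; must exceed
#'   `x_soil`.
#' @return Glucose-derived CO2-C (ug C per g soil).
#' @export
#' @examples
#' partition_glucose(100, 0.100, 0.0108, 0.195)  # 48.43
partition_glucose <- function(rt, x_sample, x_soil, x_glucose) {
  if (any(x_glucose <= x_soil, na.rm = TRUE))
    stop("endmember collapse: `x_glucose` must exceed `x_soil`")
  rt * (x_sample - x_soil) / (x_glucose - x_soil)
}

#' SOM-derived and primed CO2-C
#'
#' `R_SOM = R_t - R_glucose`; `R_primed = R_SOM - R_basal`. Negative
#' priming is biologically meaningful and is preserved, not truncated.
#'
#' @param rt Total CO2-C from the glucose-amended jar.
#' @param rglucose Glucose-derived CO2-C.
#' @param rbasal Basal CO2-C from matching water-only controls.
#' @return Data frame with columns `rsom`, `rprimed`.
#' @export
som_and_primed <- function(rt, rglucose, rbasal) {
  if (any(c(rt, rglucose, rbasal) < 0, na.rm = TRUE))
    stop("inputs must be >= 0")
  rsom <- rt - rglucose
  data.frame(rsom = rsom, rprimed = rsom - rbasal)
}

#' Percentage contributions of the partitioned pools
#'
#' @param rt,rglucose,rprimed,rsom Partitioned CO2-C masses; `rt` and
#'   `rsom` must be nonzero where used as denominators.
#' @return Data frame: `p_glucose_of_total`, `p_primed_of_total`
#'   (percent of total CO2-C), `p_primed_of_som` (percent of SOM-derived
#'   CO2-C).
#' @export
partition_proportions <- function(rt, rglucose, rprimed, rsom) {
  if (any(rt == 0)) stop("`rt` must be nonzero")
  if (any(rsom == 0)) stop("`rsom` must be nonzero")
  data.frame(p_glucose_of_total = 100 * rglucose / rt,
             p_primed_of_total = 100 * rprimed / rt,
             p_primed_of_som = 100 * rprimed / rsom)
}

#' Microbial biomass carbon by chloroform fumigation-extraction
#'
#' `MBC = (EC_fumigated - EC_unfumigated) / kec` with the conventional
#' extraction efficiency factor `kec = 0.45`. A negative extraction flux
#' is set to 0 with a warning.
#'
#' @param ec_fumigated,ec_unfumigated Extractable organic C of fumigated
#'   and unfumigated soil, ug C per g.
#' @param kec Extraction efficiency, in (0, 1].
#' @return MBC, ug C per g soil.
#' @export
#' @examples
#' microbial_biomass_c(155, 65)  # 200
microbial_biomass_c <- function(ec_fumigated, ec_unfumigated, kec = 0.45) {
  check_number(kec, "kec", 0, 1, strict_lower = TRUE)
  flux <- ec_fumigated - ec_unfumigated
  if (any(flux < 0, na.rm = TRUE)) {
    warning("negative fumigation flux set to 0")
    flux <- pmax(flux, 0)
  }
  flux / kec
}

#' Partition all jars of a gas-sampling table
#'
#' Full mass-balance pipeline over a long-format gas table (as produced by
#' [simulate_gas_series()] or read from a bundle): blank-corrects interval
#' masses with the per-time mean of the blank jars, estimates the
#' soil endmember `x_soil` as the time-matched mean atom fraction of the
#' water-control jars within each treatment (or pooled over time), sums
#' basal respiration from the water jars, and partitions every glucose jar
#' into total, glucose-derived, SOM-derived, and primed CO2-C.
#'
#' @param gas Data frame with columns `jar_id`, `treatment` (or
#'   `management` + `crop`), `replicate`, `amendment`, `time_h`,
#'   `co2c_ug_per_g_interval`, `atom_fraction_13c`. Blank jars are rows
#'   with `amendment == "blank"`.
#' @param x_glucose Atom fraction of the added glucose (default 0.195,
#'   i.e. 19.5 atom% 13C).
#' @param granularity `"interval"` (partition each flush interval, then
#'   sum; default) or `"cumulative"` (partition once on mass-weighted mean
#'   abundances).
#' @param pool_x_soil_time If `TRUE`, pool the soil endmember over time
#'   instead of matching by time point.
#' @param blank_correct Subtract the mean blank-jar mass per time point.
#' @param window Accumulation window, hours.
#' @return Data frame of class `partition_result`, one row per glucose
#'   jar: metadata plus `rt`, `rglucose`, `rsom`, `rprimed`, `rbasal`,
#'   the percentage contributions, and the per-jar
#'   `priming_coefficient = rprimed / rbasal`.
#' @export
partition_jars <- function(gas, x_glucose = 0.195,
                           granularity = c("interval", "cumulative"),
                           pool_x_soil_time = FALSE, blank_correct = TRUE,
                           window = c(0, max(gas$time_h))) {
  granularity <- match.arg(granularity)
  if (!"treatment" %in% names(gas))
    gas$treatment <- paste(gas$management, gas$crop, sep = "-")
  gas <- gas[gas$time_h > window[1] & gas$time_h <= window[2], ]
  blanks <- gas[gas$amendment %in% "blank", ]
  soil_jars <- gas[!gas$amendment %in% "blank", ]
  if (blank_correct && nrow(blanks)) {
    bc <- tapply(blanks$co2c_ug_per_g_interval, blanks$time_h, mean)
    soil_jars$co2c_ug_per_g_interval <-
      soil_jars$co2c_ug_per_g_interval -
      as.numeric(bc[as.character(soil_jars$time_h)])
  }
  neg <- soil_jars$co2c_ug_per_g_interval < 0
  if (any(neg)) {
    warning(sum(neg), " negative blank-corrected interval mass(es) ",
            "clamped to 0")
    soil_jars$co2c_ug_per_g_interval[neg] <- 0
  }
  water <- soil_jars[soil_jars$amendment == "water", ]
  gluc <- soil_jars[soil_jars$amendment == "glucose", ]
  if (!nrow(water)) stop("no water-control jars found")
  if (!nrow(gluc)) stop("no glucose jars found")

  res <- lapply(split(gluc, gluc$jar_id), function(j) {
    j <- j[order(j$time_h), ]
    tr <- j$treatment[1]
    w <- water[water$treatment == tr, ]
    if (!nrow(w)) stop("no water controls for treatment ", tr)
    if (pool_x_soil_time) {
      xs <- rep(mean(w$atom_fraction_13c, na.rm = TRUE), nrow(j))
    } else {
      xs_t <- tapply(w$atom_fraction_13c, w$time_h, mean, na.rm = TRUE)
      xs <- as.numeric(xs_t[as.character(j$time_h)])
      if (anyNA(xs))
        stop("water controls missing a time point in treatment ", tr)
    }
    rbasal <- mean(tapply(w$co2c_ug_per_g_interval, w$jar_id, sum))
    rt <- sum(j$co2c_ug_per_g_interval)
    rglucose <- if (granularity == "interval") {
      sum(partition_glucose(j$co2c_ug_per_g_interval, j$atom_fraction_13c,
                            xs, x_glucose))
    } else {
      xbar <- stats::weighted.mean(j$atom_fraction_13c,
                                   j$co2c_ug_per_g_interval)
      xsbar <- stats::weighted.mean(xs, j$co2c_ug_per_g_interval)
      partition_glucose(rt, xbar, xsbar, x_glucose)
    }
    # the identities below hold for any rglucose, including noisy values
    # outside [0, rt]; negative priming is preserved
    rsom <- rt - rglucose
    rprimed <- rsom - rbasal
    data.frame(jar_id = j$jar_id[1], management = j$management[1],
               crop = j$crop[1], treatment = tr,
               replicate = j$replicate[1],
               rt = rt, rglucose = rglucose, rsom = rsom,
               rprimed = rprimed, rbasal = rbasal,
               partition_proportions(rt, rglucose, rprimed, rsom),
               priming_coefficient = rprimed / rbasal,
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("partition_result", "data.frame")
  out
}
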