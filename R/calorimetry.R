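#' Thermodynamic constants for efficiency calculations
#'
#' @param dH_glucose Heat energy stored in the added glucose, J per g soil.
#'   The default 18.05 corresponds to glucose added at 500 ug C per g soil
#'   (combustion enthalpy of glucose scaled by the addition rate).
#' @param dH_CO Heat released per mole of glucose-derived CO2-C, J per mol
#'   C. Default 467200 = glucose combustion enthalpy 2,803,000 J/mol
#'   divided by 6 C atoms. Configurable because the effective constant
#'   implied by published index values can differ (see the methods
#'   vignette).
#' @param molar_mass_c Molar mass of carbon, g per mol.
#' @return List of class `thermo_constants`.
#' @export
thermo_constants <- function(dH_glucose = 18.05, dH_CO = 467200,
                             molar_mass_c = 12.011) {
  check_number(dH_glucose, "dH_glucose", 0, strict_lower = TRUE)
  check_number(dH_CO, "dH_CO", 0, strict_lower = TRUE)
  check_number(molar_mass_c, "molar_mass_c", 0, strict_lower = TRUE)
  structure(list(dH_glucose = dH_glucose, dH_CO = dH_CO,
                 molar_mass_c = molar_mass_c), class = "thermo_constants")
}

#' Cumulative heat from a calorimeter power record
#'
#' Integrates heat flow (uW per g dry soil) over time (h) to cumulative
#' heat in J per g soil. Integration is trapezoidal by default; composite
#' Simpson is available for uniformly spaced records. An optional initial
#' equilibration exclusion replaces power readings before
#' `window[1] + exclusion_h` with the first retained value (constant
#' back-fill), mimicking removal of the ampoule-insertion artifact.
#'
#' @param time_h Strictly increasing times, hours.
#' @param power_uW_per_g Heat flow at `time_h`, uW per g soil.
#' @param window Integration window `c(t0, t1)` in hours; defaults to the
#'   full record. Must lie within the recorded range and contain at least
#'   two points.
#' @param exclusion_h Length (h) of the initial equilibration segment to
#'   back-fill; 0 uses all data.
#' @param rule `"trapezoid"` (default) or `"simpson"`.
#'
#' @return Cumulative heat Q (J per g soil) with attributes `window`,
#'   `rule`, and `n_points`. Negative Q triggers a warning, not an error.
#' @export
#' @examples
#' tt <- seq(0, 48, by = 1 / 60)
#' cumulative_heat(tt, rep(10, length(tt)))  # 1.728 J/g
cumulative_heat <- function(time_h, power_uW_per_g, window = NULL,
                            exclusion_h = 0, rule = c("trapezoid",
                                                      "simpson")) {
  rule <- match.arg(rule)
  if (length(time_h) != length(power_uW_per_g))
    stop("`time_h` and `power_uW_per_g` lengths differ")
  if (any(diff(time_h) <= 0)) stop("`time_h` must be strictly increasing")
  if (is.null(window)) window <- range(time_h)
  if (window[1] < min(time_h) || window[2] > max(time_h) ||
      window[1] >= window[2])
    stop("`window` must be a nonempty interval within the recorded range")
  check_number(exclusion_h, "exclusion_h", 0)
  keep <- time_h >= window[1] & time_h <= window[2]
  t <- time_h[keep]
  p <- power_uW_per_g[keep]
  if (length(t) < 2) stop("fewer than 2 points in integration window")
  if (exclusion_h > 0) {
    cut <- window[1] + exclusion_h
    first_kept <- which(t >= cut)[1]
    if (is.na(first_kept)) stop("`exclusion_h` excludes the whole window")
    p[seq_len(first_kept - 1L)] <- p[first_kept]
  }
  n <- length(t)
  q_uWh <- if (rule == "trapezoid" || n < 3) {
    sum(diff(t) * (p[-1] + p[-n])) / 2
  } else {
    h <- diff(t)
    if (max(h) - min(h) > 1e-9 * max(h)) {
      warning("Simpson rule needs uniform spacing; falling back to trapezoid")
      sum(h * (p[-1] + p[-n])) / 2
    } else {
      m <- n - 1L  # number of intervals
      even_m <- if (m %% 2L == 1L) m - 1L else m
      i <- seq_len(even_m + 1L)
      coef <- rep(c(2, 4), length.out = even_m + 1L)
      coef[c(1L, even_m + 1L)] <- 1
      q <- h[1] / 3 * sum(coef * p[i])
      if (m > even_m)  # trailing odd interval by trapezoid
        q <- q + h[m] * (p[n] + p[n - 1L]) / 2
      q
    }
  }
  q <- q_uWh * 3600 * 1e-6  # uW h -> J
  if (q < 0) warning("negative cumulative heat (", signif(q, 3), " J/g)")
  structure(q, window = window, rule = rule, n_points = n)
}

#' Thermodynamic efficiency index
#'
#' `eta_eff = 1 - (Q_glucose - Q_control) / dH_glucose`: one minus the net
#' substrate-induced heat relative to the energy content of the added
#' glucose. Values are not clamped; a negative index (more net heat
#' released than substrate energy added) is reported as-is with a warning.
#'
#' @param q_glucose,q_control Cumulative heats (J per g soil) of
#'   glucose-amended and water-control soils; vectorized.
#' @param constants A [thermo_constants()].
#' @return Numeric vector of efficiency indices.
#' @export
#' @examples
#' thermodynamic_efficiency(7.47, 1.76)  # 0.684
thermodynamic_efficiency <- function(q_glucose, q_control,
                                     constants = thermo_constants()) {
  stopifnot(inherits(constants, "thermo_constants"))
  eta <- 1 - (q_glucose - q_control) / constants$dH_glucose
  if (any(eta < 0, na.rm = TRUE))
    warning("negative thermodynamic efficiency index; reported unclamped")
  eta
}

#' Thermal yield of glucose-derived heat
#'
#' Converts a glucose-derived CO2-C mass to moles and partitions the
#' substrate energy between the fraction dissipated through CO2
#' (`eta_co2 = dH_CO * n(CO2-C) / dH_glucose`) and the fraction retained in
#' soil (`eta_soil = 1 - eta_co2`). The operation is a pure formula on the
#' supplied mass: `mode` only records which CO2-C accounting the caller
#' used (`"as_written"`, glucose-derived CO2-C only, with primed and
#' control moles already excluded; or `"net_of_control"`, total
#' glucose-jar CO2-C minus the control, which still contains primed
#' moles).
#'
#' @param glucose_co2c Glucose-derived CO2-C (ug C per g soil); >= 0,
#'   vectorized.
#' @param constants A [thermo_constants()].
#' @param mode Accounting label stored on the result; see Details.
#' @return Data frame with columns `eta_co2`, `eta_soil` (summing to 1 by
#'   construction) and attribute `mode`.
#' @export
#' @examples
#' thermal_yield(172.5)  # eta_co2 = 0.372
thermal_yield <- function(glucose_co2c, constants = thermo_constants(),
                          mode = c("as_written", "net_of_control")) {
  mode <- match.arg(mode)
  stopifnot(inherits(constants, "thermo_constants"))
  if (any(glucose_co2c < 0, na.rm = TRUE))
    stop("`glucose_co2c` must be >= 0")
  moles <- glucose_co2c * 1e-6 / constants$molar_mass_c
  eta_co2 <- constants$dH_CO * moles / constants$dH_glucose
  structure(data.frame(eta_co2 = eta_co2, eta_soil = 1 - eta_co2),
            mode = mode)
}

#' Calorespirometric ratio
#'
#' Heat released per unit CO2-C respired, mJ per ug CO2-C.
#'
#' @param q Cumulative heat, J per g soil.
#' @param r CO2-C respired over the same window, ug C per g soil; must be
#'   > 0.
#' @return Numeric vector, mJ per ug CO2-C.
#' @export
#' @examples
#' calorespirometric_ratio(1.20, 26.5)  # 45.3
calorespirometric_ratio <- function(q, r) {
  if (any(r <= 0, na.rm = TRUE))
    stop("respiration `r` must be > 0")
  q * 1000 / r
}

#' Metabolic quotient
#'
#' Basal respiration per unit microbial biomass carbon over the incubation
#' window (ug CO2-C per ug MBC).
#'
#' @param r_basal Basal respiration, ug CO2-C per g soil.
#' @param mbc Microbial biomass carbon, ug C per g soil; must be > 0.
#' @return Numeric vector.
#' @export
#' @examples
#' metabolic_quotient(26.5, 302.3)  # 0.09 at 2 dp
metabolic_quotient <- function(r_basal, mbc) {
  if (any(mbc <= 0, na.rm = TRUE)) stop("`mbc` must be > 0")
  r_basal / mbc
}
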