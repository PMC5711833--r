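#' Simulate flushed-headspace gas sampling series
#'
#' Emits, for every respiration jar and inter-flush interval, the interval
#' CO2-C mass (ug C per g soil) and the interval 13C atom fraction.
#' Glucose jars release glucose-derived C following first-order depletion of
#' the respirable glucose pool (default half-life 10 h), normalized over the
#' incubation window so interval masses sum exactly to
#' `frac_glucose_respired * glucose_c_rate` before noise; they additionally
#' release SOM-derived basal C and primed C (`priming_coef` times basal,
#' constant in time), both at the soil atom fraction. Interval atom
#' fractions are the mass-weighted two-source mixtures. Water jars release
#' basal C only; two blank jars carry zero-mean measurement noise only.
#'
#' @inheritParams simulate_heat_curves
#' @param glucose_halflife_h Half-life (h) of the respirable glucose pool.
#' @param n_blanks Number of soil-free blank jars.
#'
#' @return Data frame with columns `jar_id`, `management`, `crop`,
#'   `treatment`, `replicate`, `amendment`, `time_h`,
#'   `co2c_ug_per_g_interval`, `atom_fraction_13c`. Blank jars have `NA`
#'   metadata and atom fractions.
#' @export
simulate_gas_series <- function(design, truth, glucose_halflife_h = 10,
                                n_blanks = 2) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "synthetic_truth"))
  if (any(truth$priming_coef < 0)) stop("priming coefficient must be >= 0")
  k <- log(2) / glucose_halflife_h
  bounds <- c(0, design$sampling_times_h)
  dur <- design$duration_h
  # fraction of the respirable pool emitted in each interval, renormalized
  # over [0, duration] so the interval masses sum exactly to the true total
  w <- (exp(-k * bounds[-length(bounds)]) - exp(-k * bounds[-1])) /
    (1 - exp(-k * dur))
  dt <- diff(bounds)
  units <- design_units(design)
  times <- design$sampling_times_h
  nt <- length(times)
  with_seed(substream_seed(design$seed, "gas"), {
    rows <- lapply(seq_len(nrow(units)), function(i) {
      u <- units[i, ]
      tr <- u$treatment
      basal <- truth$basal_co2c[[tr]] * dt / dur
      if (u$amendment == design$amendments[1]) {
        gluc <- truth$frac_glucose_respired[[tr]] * design$glucose_c_rate * w
        primed <- truth$priming_coef[[tr]] * basal
      } else {
        gluc <- rep(0, nt)
        primed <- rep(0, nt)
      }
      som <- basal + primed
      mass <- gluc + som
      atom <- (gluc * truth$x_glucose + som * truth$x_soil) / mass
      if (truth$co2c_noise_sd > 0)
        mass <- mass + stats::rnorm(nt, 0, truth$co2c_noise_sd)
      if (truth$atom_noise_sd > 0)
        atom <- atom + stats::rnorm(nt, 0, truth$atom_noise_sd)
      data.frame(jar_id = paste0(u$unit_id, "-jar"),
                 u[rep(1, nt), c("management", "crop", "treatment",
                                 "replicate", "amendment")],
                 time_h = times, co2c_ug_per_g_interval = mass,
                 atom_fraction_13c = atom, row.names = NULL)
    })
    blanks <- lapply(seq_len(n_blanks), function(b) {
      data.frame(jar_id = sprintf("BLANK-%d", b), management = NA_character_,
                 crop = NA_character_, treatment = NA_character_,
                 replicate = NA_integer_, amendment = "blank",
                 time_h = times,
                 co2c_ug_per_g_interval =
                   if (truth$co2c_noise_sd > 0)
                     stats::rnorm(nt, 0, truth$co2c_noise_sd)
                   else rep(0, nt),
                 atom_fraction_13c = NA_real_, row.names = NULL)
    })
  })
  do.call(rbind, c(rows, blanks))
}
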