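#' Define a split-plot glucose-amendment incubation design
#'
#' Describes the layout of a soil incubation experiment contrasting
#' management systems and cropping histories, with replicate field units
#' receiving either a 13C-glucose amendment or a water control. The default
#' arguments reproduce the study conditions emulated by the synthetic data
#' generator: two management systems (conventional `CON`, organic `ORG`),
#' two cropping histories (annual `ANN`, annual-perennial `PER`), four field
#' replicates, glucose added at 500 ug C per g dry soil, and headspace
#' sampling 4, 12, 24, 36, and 48 h after amendment.
#'
#' @param management_systems Character vector of management system labels.
#' @param cropping_histories Character vector of cropping history labels.
#' @param n_replicates Number of field replicates per treatment (>= 2).
#' @param amendments Amendment labels; the first is the labelled substrate,
#'   the second the water control.
#' @param glucose_c_rate Glucose carbon addition rate (ug C per g dry soil).
#' @param sampling_times_h Strictly increasing headspace sampling times (h).
#' @param duration_h Incubation duration (h); must be >= the last sampling
#'   time.
#' @param seed Integer seed from which all simulation substreams derive.
#'
#' @return An object of class `experiment_design`.
#' @seealso [synthetic_truth()], [simulate_experiment()]
#' @export
#' @examples
#' design <- experiment_design(seed = 42)
#' nrow(design_units(design))  # 2 systems x 2 histories x 4 reps x 2 amendments
experiment_design <- function(management_systems = c("CON", "ORG"),
                              cropping_histories = c("ANN", "PER"),
                              n_replicates = 4,
                              amendments = c("glucose", "water"),
                              glucose_c_rate = 500,
                              sampling_times_h = c(4, 12, 24, 36, 48),
                              duration_h = 48,
                              seed = 1L) {
  if (n_replicates < 2) stop("`n_replicates` must be >= 2")
  if (any(diff(sampling_times_h) <= 0) || any(sampling_times_h <= 0))
    stop("`sampling_times_h` must be strictly increasing and positive")
  if (max(sampling_times_h) > duration_h)
    stop("last sampling time must not exceed `duration_h`")
  check_number(glucose_c_rate, "glucose_c_rate", lower = 0,
               strict_lower = TRUE)
  structure(
    list(management_systems = as.character(management_systems),
         cropping_histories = as.character(cropping_histories),
         n_replicates = as.integer(n_replicates),
         amendments = as.character(amendments),
         glucose_c_rate = glucose_c_rate,
         sampling_times_h = as.numeric(sampling_times_h),
         duration_h = as.numeric(duration_h),
         seed = as.integer(seed)),
    class = "experiment_design")
}

#' Treatment labels of a design
#' @param design An `experiment_design`.
#' @return Character vector, e.g. `"CON-ANN"`.
#' @export
design_treatments <- function(design) {
  as.vector(outer(design$management_systems, design$cropping_histories,
                  paste, sep = "-"))
}

#' Expand a design into its experimental units
#'
#' @param design An `experiment_design`.
#' @return Data frame with one row per ampoule/jar: `unit_id`, `management`,
#'   `crop`, `treatment`, `replicate`, `amendment`.
#' @export
design_units <- function(design) {
  g <- expand.grid(amendment = design$amendments,
                   replicate = seq_len(design$n_replicates),
                   crop = design$cropping_histories,
                   management = design$management_systems,
                   stringsAsFactors = FALSE)
  g <- g[, c("management", "crop", "replicate", "amendment")]
  g$treatment <- paste(g$management, g$crop, sep = "-")
  g$unit_id <- paste(g$treatment, paste0("R", g$replicate), g$amendment,
                     sep = "-")
  g[, c("unit_id", "management", "crop", "treatment", "replicate",
        "amendment")]
}

#' Ground truth for a synthetic incubation experiment
#'
#' Holds the per-treatment true quantities from which the simulators
#' generate data and against which the pipeline's estimates are checked.
#' Defaults are the treatment-level study conditions: cumulative heats of
#' roughly 1.2-1.8 J/g (controls) and 6.9-7.5 J/g (glucose-amended), 48-h
#' basal respiration of 26-37 ug CO2-C/g, about a third of the added
#' glucose-C respired within 48 h, priming coefficients (primed : basal
#' CO2-C) slightly above 1 under conventional and about 1.3 under organic
#' management, 19.5 atom% 13C glucose, and soil-derived CO2 at 1.08 atom%.
#'
#' @param design An `experiment_design`.
#' @param q_control,q_glucose True cumulative heats (J per g soil) of water
#'   control and glucose-amended units; scalar or named by treatment.
#' @param basal_co2c True basal respiration over the incubation
#'   (ug CO2-C per g soil).
#' @param frac_glucose_respired True fraction of added glucose-C respired
#'   within the incubation, in (0, 1).
#' @param priming_coef True primed CO2-C as a fraction of basal CO2-C
#'   (>= 0).
#' @param x_glucose,x_soil 13C atom fractions of the added glucose and of
#'   soil-derived CO2; must satisfy `0 < x_soil < x_glucose < 1`.
#' @param power_noise_sd Gaussian noise sd on calorimeter power (uW/g).
#' @param co2c_noise_sd Gaussian noise sd on interval CO2-C masses (ug/g).
#' @param atom_noise_sd Gaussian noise sd on measured atom fractions.
#' @param n_enriched Number of OTUs planted as glucose utilizers.
#' @param enriched_log2fc Planted log2 fold-change of enriched OTUs in the
#'   13C-heavy vs 13C-light fraction.
#'
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(design,
                            q_control = c("CON-ANN" = 1.76, "CON-PER" = 1.54,
                                          "ORG-ANN" = 1.18, "ORG-PER" = 1.22),
                            q_glucose = c("CON-ANN" = 7.47, "CON-PER" = 7.41,
                                          "ORG-ANN" = 7.01, "ORG-PER" = 6.86),
                            basal_co2c = c("CON-ANN" = 37.4, "CON-PER" = 31.2,
                                           "ORG-ANN" = 26.1, "ORG-PER" = 26.9),
                            frac_glucose_respired =
                              c("CON-ANN" = 0.345, "CON-PER" = 0.347,
                                "ORG-ANN" = 0.338, "ORG-PER" = 0.336),
                            priming_coef = c("CON-ANN" = 1.021,
                                             "CON-PER" = 1.071,
                                             "ORG-ANN" = 1.329,
                                             "ORG-PER" = 1.309),
                            x_glucose = 0.195,
                            x_soil = 0.0108,
                            power_noise_sd = 0.1,
                            co2c_noise_sd = 1.0,
                            atom_noise_sd = 5e-4,
                            n_enriched = 20,
                            enriched_log2fc = 2) {
  stopifnot(inherits(design, "experiment_design"))
  tr <- design_treatments(design)
  pt <- function(x, name) {
    if (length(x) == 1L) {
      out <- rep(as.numeric(x), length(tr)); names(out) <- tr; out
    } else {
      if (!all(tr %in% names(x)))
        stop("`", name, "` must be a scalar or named by treatment")
      out <- as.numeric(x[tr]); names(out) <- tr; out
    }
  }
  check_number(x_glucose, "x_glucose", 0, 1, TRUE, TRUE)
  check_number(x_soil, "x_soil", 0, 1, TRUE, TRUE)
  if (x_glucose <= x_soil) stop("`x_glucose` must exceed `x_soil`")
  check_number(power_noise_sd, "power_noise_sd", 0)
  check_number(co2c_noise_sd, "co2c_noise_sd", 0)
  check_number(atom_noise_sd, "atom_noise_sd", 0)
  out <- list(q_control = pt(q_control, "q_control"),
              q_glucose = pt(q_glucose, "q_glucose"),
              basal_co2c = pt(basal_co2c, "basal_co2c"),
              frac_glucose_respired = pt(frac_glucose_respired,
                                         "frac_glucose_respired"),
              priming_coef = pt(priming_coef, "priming_coef"),
              x_glucose = x_glucose, x_soil = x_soil,
              power_noise_sd = power_noise_sd,
              co2c_noise_sd = co2c_noise_sd,
              atom_noise_sd = atom_noise_sd,
              n_enriched = as.integer(n_enriched),
              enriched_log2fc = as.numeric(enriched_log2fc))
  check_number(out$frac_glucose_respired, "frac_glucose_respired", 0, 1)
  if (any(out$priming_coef < 0)) stop("`priming_coef` must be >= 0")
  if (any(out$q_control <= 0) || any(out$q_glucose <= 0))
    stop("true cumulative heats must be positive")
  structure(out, class = "synthetic_truth")
}
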