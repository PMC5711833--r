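#' Run the full analysis pipeline on a dataset bundle
#'
#' End-to-end analysis of a simulated (or equivalently formatted real)
#' experiment: integrates calorimeter curves to cumulative heats, pairs
#' glucose and control units per replicate to compute thermodynamic
#' efficiency indices, partitions respired CO2-C by 13C mass balance,
#' derives thermal yields, calorespirometric ratios and metabolic
#' quotients, summarizes everything at treatment and pooled level,
#' computes headline contrasts, and (optionally) runs the SIP community
#' stage: rarefaction, Bray-Curtis, PCoA, PERMANOVA on the 13C-heavy
#' fraction, the differential-abundance screen (13C-heavy vs 13C-light
#' within each management system and CON vs ORG within the heavy
#' fraction), and OTU-soil Spearman correlations.
#'
#' @param bundle A directory written by [simulate_experiment()] or a list
#'   as returned by [read_bundle()].
#' @param out_dir Optional report directory; when given,
#'   [assemble_report()] is called.
#' @param window Analysis window, hours.
#' @param constants A [thermo_constants()].
#' @param x_glucose Atom fraction of the added glucose.
#' @param thermal_yield_mode Which CO2-C accounting feeds the thermal
#'   yield: `"as_written"` uses glucose-derived CO2-C only (primed and
#'   control moles excluded); `"net_of_control"` uses total glucose-jar
#'   CO2-C minus basal.
#' @param community Run the community stage.
#' @param rarefy_depth Rarefaction depth; default the minimum sample sum.
#' @param n_perm Permutations for PERMANOVA and the screen.
#' @param seed Seed for community-stage randomness.
#' @param kec Fumigation-extraction efficiency factor.
#' @return List of class `thermosip_pipeline` with per-unit tables
#'   (`heat_units`, `partition`, `indices`), the four summary tables,
#'   `contrasts`, and community results (`permanova`, `enrichment`,
#'   `pcoa`, `correlations`) when run.
#' @export
run_pipeline <- function(bundle, out_dir = NULL, window = NULL,
                         constants = thermo_constants(), x_glucose = 0.195,
                         thermal_yield_mode = c("as_written",
                                                "net_of_control"),
                         community = TRUE, rarefy_depth = NULL,
                         n_perm = 199, seed = 1L, kec = 0.45) {
  thermal_yield_mode <- match.arg(thermal_yield_mode)
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  heat <- bundle$heat
  if (is.null(window)) window <- c(0, max(heat$time_h))

  # --- calorimetry: per-unit cumulative heat -------------------------------
  heat_units <- do.call(rbind, lapply(split(heat, heat$unit_id), function(h) {
    h <- h[order(h$time_h), ]
    data.frame(unit_id = h$unit_id[1], management = h$management[1],
               crop = h$crop[1], treatment = h$treatment[1],
               replicate = h$replicate[1], amendment = h$amendment[1],
               q = as.numeric(cumulative_heat(h$time_h, h$power_uW_per_g,
                                              window = window)),
               row.names = NULL)
  }))
  rownames(heat_units) <- NULL

  # --- isotope partition ---------------------------------------------------
  part <- partition_jars(bundle$gas, x_glucose = x_glucose, window = window)

  # --- chemistry / MBC -----------------------------------------------------
  chem <- bundle$chemistry
  if (!"mbc_fe" %in% names(chem) && all(c("ec_fumigated", "ec_unfumigated")
                                        %in% names(chem)))
    chem$mbc_fe <- microbial_biomass_c(chem$ec_fumigated,
                                       chem$ec_unfumigated, kec = kec)

  # --- per-replicate indices ----------------------------------------------
  qg <- heat_units[heat_units$amendment == "glucose", ]
  qw <- heat_units[heat_units$amendment == "water", ]
  key <- function(df) paste(df$treatment, df$replicate)
  qw_q <- qw$q[match(key(qg), key(qw))]
  part_m <- part[match(key(qg), key(part)), ]
  chem_m <- chem[match(key(qg), paste(chem$treatment, chem$replicate)), ]
  mbc <- if ("mbc_fe" %in% names(chem_m)) chem_m$mbc_fe else chem_m$mbc
  yield_input <- switch(thermal_yield_mode,
                        as_written = part_m$rglucose,
                        net_of_control = part_m$rt - part_m$rbasal)
  ty <- thermal_yield(pmax(yield_input, 0), constants,
                      mode = thermal_yield_mode)
  indices <- data.frame(
    treatment = qg$treatment, management = qg$management, crop = qg$crop,
    replicate = qg$replicate,
    q_glucose = qg$q, q_control = qw_q,
    eta_eff = thermodynamic_efficiency(qg$q, qw_q, constants),
    eta_co2 = ty$eta_co2, eta_soil = ty$eta_soil,
    caloresp_control = calorespirometric_ratio(qw_q, part_m$rbasal),
    caloresp_glucose = calorespirometric_ratio(qg$q, part_m$rt),
    qco2 = metabolic_quotient(part_m$rbasal, mbc),
    row.names = NULL)

  # --- summaries -----------------------------------------------------------
  chem_vars <- intersect(c("soc_pct", "doc", "no3_n", "nh4_n", "po4_p", "ph",
                           "mbc", "mbc_fe", "bg", "phox"), names(chem))
  chemistry_summary <- treatment_summary(chem, chem_vars)
  metab_units <- cbind(indices,
                       resp_control = part_m$rbasal, resp_glucose = part_m$rt)
  metabolic_summary <- treatment_summary(
    metab_units, c("resp_control", "q_control", "caloresp_control", "qco2",
                   "resp_glucose", "q_glucose", "caloresp_glucose"))
  partition_summary <- treatment_summary(
    part, c("rt", "rglucose", "rsom", "rprimed", "rbasal",
            "p_glucose_of_total", "p_primed_of_total", "p_primed_of_som",
            "priming_coefficient"))
  efficiency_summary <- treatment_summary(
    indices, c("eta_eff", "eta_co2", "eta_soil"))

  # --- headline contrasts --------------------------------------------------
  pool_mean <- function(df, var, mgmt)
    mean(df[[var]][df$management == mgmt])
  contrasts <- do.call(rbind, lapply(c("CON", "ORG"), function(ms) {
    if (!ms %in% metab_units$management) return(NULL)
    sub <- metab_units[metab_units$management == ms, ]
    rbind(
      cbind(contrast = paste0(ms, " respiration glucose/control"),
            contrast_ratios(sub$resp_glucose, sub$resp_control,
                            paired = TRUE)),
      cbind(contrast = paste0(ms, " heat glucose/control"),
            contrast_ratios(sub$q_glucose, sub$q_control, paired = TRUE)))
  }))
  if (all(c("CON", "ORG") %in% metab_units$management)) {
    contrasts <- rbind(
      contrasts,
      cbind(contrast = "glucose-amended heat CON vs ORG",
            contrast_ratios(
              metab_units$q_glucose[metab_units$management == "CON"],
              metab_units$q_glucose[metab_units$management == "ORG"],
              paired = FALSE)),
      cbind(contrast = "DOC CON vs ORG",
            contrast_ratios(chem$doc[chem$management == "CON"],
                            chem$doc[chem$management == "ORG"],
                            paired = FALSE)))
  }

  results <- list(heat_units = heat_units, partition = part,
                  indices = indices,
                  chemistry_summary = chemistry_summary,
                  metabolic_summary = metabolic_summary,
                  partition_summary = partition_summary,
                  efficiency_summary = efficiency_summary,
                  contrasts = contrasts,
                  config = list(seed = seed, window = window,
                                x_glucose = x_glucose, kec = kec,
                                thermal_yield_mode = thermal_yield_mode,
                                n_perm = n_perm,
                                dH_glucose = constants$dH_glucose,
                                dH_CO = constants$dH_CO))

  # --- community stage -----------------------------------------------------
  if (community && !is.null(bundle$otu)) {
    seq_meta <- bundle$samples[bundle$samples$assay == "sequencing", ]
    seq_meta <- seq_meta[match(colnames(bundle$otu), seq_meta$sample_id), ]
    depth <- if (is.null(rarefy_depth)) min(colSums(bundle$otu))
             else rarefy_depth
    rare <- rarefy_counts(bundle$otu, depth = depth,
                          seed = substream_seed(seed, "rarefy"))
    seq_meta <- seq_meta[match(colnames(rare), seq_meta$sample_id), ]
    heavy <- seq_meta$fraction == "13C-heavy"
    d_heavy <- bray_curtis(rare[, heavy, drop = FALSE])
    results$bray_curtis <- d_heavy
    results$pcoa <- pcoa(d_heavy, k = 2)
    results$permanova <- permanova(
      d_heavy, factors = seq_meta[heavy, c("management", "crop")],
      terms = c("management", "crop"), n_perm = n_perm,
      seed = substream_seed(seed, "perm"))
    # glucose utilizers: heavy vs light within each management system
    screens <- lapply(unique(seq_meta$management), function(ms) {
      idx <- seq_meta$management == ms &
        seq_meta$fraction %in% c("13C-light", "13C-heavy")
      sc <- enrichment_screen(
        rare[, idx, drop = FALSE],
        factor(seq_meta$fraction[idx],
               levels = c("13C-light", "13C-heavy")),
        n_perm = n_perm, seed = substream_seed(seed, "screen"))
      cbind(management = ms, as.data.frame(sc))
    })
    results$enrichment <- do.call(rbind, screens)
    # CON vs ORG within the heavy fraction, correlated to soil attributes
    if (all(c("CON", "ORG") %in% seq_meta$management)) {
      sc_ms <- enrichment_screen(
        rare[, heavy, drop = FALSE],
        factor(seq_meta$management[heavy], levels = c("CON", "ORG")),
        n_perm = n_perm, seed = substream_seed(seed, "screen"))
      soil <- chem
      soil$unit_id <- paste(soil$treatment, paste0("R", soil$replicate),
                            sep = "-")
      pk <- paste(part$treatment, part$replicate)
      pm <- match(paste(soil$treatment, soil$replicate), pk)
      soil$rt <- part$rt[pm]
      soil$rglucose <- part$rglucose[pm]
      soil$rprimed <- part$rprimed[pm]
      soil$p_primed_of_som <- part$p_primed_of_som[pm]
      ik <- paste(indices$treatment, indices$replicate)
      im <- match(paste(soil$treatment, soil$replicate), ik)
      soil$eta_eff <- indices$eta_eff[im]
      soil$qco2 <- indices$qco2[im]
      if (any(sc_ms$significant)) {
        units_of <- paste(seq_meta$treatment[heavy],
                          paste0("R", seq_meta$replicate[heavy]), sep = "-")
        results$correlations <- otu_soil_correlations(
          sc_ms, rare[, heavy, drop = FALSE], units_of, soil)
      }
      results$enrichment_management <- sc_ms
    }
  }

  class(results) <- "thermosip_pipeline"
  if (!is.null(out_dir)) assemble_report(results, out_dir)
  results
}

#' Recover ground truth from a synthetic experiment
#'
#' Simulates heat and gas data in memory for a design/truth pair, runs the
#' calorimetry and isotope-partition stages, and compares the recovered
#' per-treatment quantities with the truth. Used by the validation suite
#' to quantify parameter-recovery error with and without measurement
#' noise.
#'
#' @inheritParams simulate_heat_curves
#' @param dt_min Power record step, minutes.
#' @return Data frame with one row per treatment: true and recovered
#'   cumulative heats (`q_glucose`, `q_control`), glucose-derived CO2-C
#'   (`rglucose`), and priming coefficient, plus their relative errors
#'   (`*_relerr`).
#' @export
parameter_recovery <- function(design, truth, dt_min = 1) {
  heat <- simulate_heat_curves(design, truth, dt_min = dt_min)
  gas <- simulate_gas_series(design, truth)
  q <- do.call(rbind, lapply(split(heat, heat$unit_id), function(h) {
    data.frame(treatment = h$treatment[1], amendment = h$amendment[1],
               q = as.numeric(cumulative_heat(h$time_h, h$power_uW_per_g)))
  }))
  part <- partition_jars(gas, x_glucose = truth$x_glucose)
  trs <- design_treatments(design)
  out <- do.call(rbind, lapply(trs, function(tr) {
    qg <- mean(q$q[q$treatment == tr & q$amendment == "glucose"])
    qw <- mean(q$q[q$treatment == tr & q$amendment == "water"])
    p <- part[part$treatment == tr, ]
    true_rg <- truth$frac_glucose_respired[[tr]] * design$glucose_c_rate
    data.frame(
      treatment = tr,
      q_glucose_true = truth$q_glucose[[tr]], q_glucose_est = qg,
      q_control_true = truth$q_control[[tr]], q_control_est = qw,
      rglucose_true = true_rg, rglucose_est = mean(p$rglucose),
      priming_true = truth$priming_coef[[tr]],
      priming_est = mean(p$priming_coefficient),
      row.names = NULL)
  }))
  out$q_glucose_relerr <- abs(out$q_glucose_est / out$q_glucose_true - 1)
  out$q_control_relerr <- abs(out$q_control_est / out$q_control_true - 1)
  out$rglucose_relerr <- abs(out$rglucose_est / out$rglucose_true - 1)
  out$priming_relerr <- abs(out$priming_est / out$priming_true - 1)
  out
}
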