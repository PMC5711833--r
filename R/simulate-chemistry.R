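#' Default soil chemistry treatment means
#'
#' Treatment-level means of the soil chemical and biological variables the
#' simulator reproduces: soil organic carbon (`soc_pct`, %), dissolved
#' organic C (`doc`), nitrate and ammonium N (`no3_n`, `nh4_n`), available
#' phosphorus (`po4_p`) (all ug per g soil), `ph`, microbial biomass carbon
#' (`mbc`, ug C/g), and potential beta-glucosidase (`bg`) and phenol
#' oxidase (`phox`) activities (umol per g). Values are the published
#' summary statistics of the long-term organic-vs-conventional cropping
#' trial the package's worked examples are built around; `nh4_n` is a
#' plausible stand-in as no published mean is available.
#'
#' @return Data frame with one row per treatment.
#' @export
default_chemistry_means <- function() {
  data.frame(
    treatment = c("CON-ANN", "CON-PER", "ORG-ANN", "ORG-PER"),
    soc_pct = c(3.09, 2.73, 2.89, 2.55),
    doc = c(61.7, 61.3, 46.3, 44.2),
    no3_n = c(51.2, 53.3, 41.7, 42.9),
    nh4_n = c(7.1, 6.8, 7.0, 6.7),
    po4_p = c(53.7, 65.5, 14.8, 16.2),
    ph = c(5.26, 5.03, 4.91, 5.35),
    mbc = c(362.8, 254.2, 298.4, 306.2),
    bg = c(1.66, 0.97, 1.10, 0.98),
    phox = c(0.56, 0.52, 0.36, 0.37),
    stringsAsFactors = FALSE)
}

#' Default between-replicate standard deviations for chemistry draws
#'
#' Two times the published standard errors of the treatment means
#' (n = 4 replicates), i.e. the implied replicate-level standard deviation.
#' @return Data frame matching [default_chemistry_means()].
#' @export
default_chemistry_sds <- function() {
  data.frame(
    treatment = c("CON-ANN", "CON-PER", "ORG-ANN", "ORG-PER"),
    soc_pct = 2 * c(0.30, 0.04, 0.29, 0.20),
    doc = 2 * c(10.1, 4.6, 3.4, 3.3),
    no3_n = 2 * c(7.1, 1.1, 1.1, 2.8),
    nh4_n = 2 * c(0.8, 0.7, 0.8, 0.7),
    po4_p = 2 * c(7.2, 2.0, 1.3, 1.1),
    ph = 2 * c(0.14, 0.04, 0.15, 0.16),
    mbc = 2 * c(32.9, 17.5, 17.6, 21.6),
    bg = 2 * c(0.37, 0.22, 0.11, 0.11),
    phox = 2 * c(0.05, 0.05, 0.11, 0.11),
    stringsAsFactors = FALSE)
}

#' Simulate the soil chemistry/biology table
#'
#' Draws one row per field unit (management x crop x replicate) from
#' Gaussian distributions around treatment means. Fumigation-extraction
#' organic C columns are derived so that the standard
#' fumigation-extraction calculation with `kec = 0.45` recovers the drawn
#' MBC exactly: `ec_unfumigated = doc` and
#' `ec_fumigated = doc + 0.45 * mbc`.
#'
#' @inheritParams simulate_heat_curves
#' @param means Data frame of per-treatment means
#'   (default [default_chemistry_means()]).
#' @param sds Per-treatment standard deviations, same shape as `means`;
#'   a single number is recycled. All sds must be >= 0.
#'
#' @return Data frame with one row per field unit.
#' @export
simulate_soil_chemistry <- function(design, means = default_chemistry_means(),
                                    sds = default_chemistry_sds()) {
  stopifnot(inherits(design, "experiment_design"))
  vars <- setdiff(names(means), "treatment")
  if (is.numeric(sds) && length(sds) == 1L) {
    tmp <- means
    tmp[vars] <- sds
    sds <- tmp
  }
  if (any(as.matrix(sds[vars]) < 0)) stop("all sds must be >= 0")
  units <- unique(design_units(design)[, c("management", "crop", "treatment",
                                           "replicate")])
  with_seed(substream_seed(design$seed, "chemistry"), {
    draws <- lapply(vars, function(v) {
      mu <- means[[v]][match(units$treatment, means$treatment)]
      sd <- sds[[v]][match(units$treatment, sds$treatment)]
      mu + stats::rnorm(nrow(units), 0, sd)
    })
  })
  names(draws) <- vars
  out <- cbind(unit_id = paste(units$treatment, paste0("R", units$replicate),
                               sep = "-"),
               units, as.data.frame(draws))
  out$ec_unfumigated <- out$doc
  out$ec_fumigated <- out$doc + 0.45 * out$mbc
  rownames(out) <- NULL
  out
}
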