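#' Simulate a complete experiment and write it to disk
#'
#' Runs every simulator and writes a self-contained dataset bundle from
#' which the full analysis pipeline can be re-run: `heat_curves.tsv`,
#' `gas_samples.tsv`, `chemistry.tsv`, `otu_counts.tsv` (OTU id + taxonomy
#' + one column per sample), `samples.tsv`, and a `truth.json` ground-truth
#' manifest. Output is byte-deterministic given the design seed.
#'
#' @inheritParams simulate_heat_curves
#' @param out_dir Output directory (created if missing).
#' @param dt_min Power record step, minutes.
#' @param n_taxa,depth,theta,enriched_system Passed to
#'   [simulate_otu_table()].
#'
#' @return Invisibly, a list with the simulated objects and `dir`.
#' @export
#' @examples
#' \donttest{
#' d <- experiment_design(seed = 3)
#' tr <- synthetic_truth(d)
#' bundle <- simulate_experiment(d, tr, tempfile("bundle"), dt_min = 10)
#' }
simulate_experiment <- function(design, truth, out_dir, dt_min = 1,
                                n_taxa = 120, depth = 5000, theta = 0.001,
                                enriched_system = "ORG") {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "synthetic_truth"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  heat <- simulate_heat_curves(design, truth, dt_min = dt_min)
  gas <- simulate_gas_series(design, truth)
  chem <- simulate_soil_chemistry(design)
  otu <- simulate_otu_table(design, truth, n_taxa = n_taxa, depth = depth,
                            theta = theta, enriched_system = enriched_system)

  write_tsv_plain(heat[, c("unit_id", "time_h", "power_uW_per_g")],
                  file.path(out_dir, "heat_curves.tsv"))
  write_tsv_plain(gas[, c("jar_id", "time_h", "co2c_ug_per_g_interval",
                          "atom_fraction_13c")],
                  file.path(out_dir, "gas_samples.tsv"))
  write_tsv_plain(chem, file.path(out_dir, "chemistry.tsv"))
  otu_out <- data.frame(otu_id = rownames(otu$counts),
                        taxonomy = unname(otu$taxonomy),
                        otu$counts, check.names = FALSE)
  write_tsv_plain(otu_out, file.path(out_dir, "otu_counts.tsv"))

  units <- design_units(design)
  units$sample_id <- units$unit_id
  jar_meta <- unique(gas[, c("jar_id", "management", "crop", "treatment",
                             "replicate", "amendment")])
  seq_meta <- otu$samples
  meta <- rbind(
    data.frame(sample_id = units$unit_id, assay = "calorimetry",
               units[, c("management", "crop", "treatment", "replicate",
                         "amendment")],
               fraction = NA_character_, row.names = NULL),
    data.frame(sample_id = jar_meta$jar_id, assay = "gas",
               jar_meta[, c("management", "crop", "treatment", "replicate",
                            "amendment")],
               fraction = NA_character_, row.names = NULL),
    data.frame(sample_id = seq_meta$sample_id, assay = "sequencing",
               seq_meta[, c("management", "crop", "treatment", "replicate")],
               amendment = "glucose", fraction = seq_meta$fraction,
               row.names = NULL))
  write_tsv_plain(meta, file.path(out_dir, "samples.tsv"))

  manifest <- list(
    design = unclass(design),
    truth = lapply(unclass(truth), function(x)
      if (is.null(names(x))) x else as.list(x)),
    enriched_taxa = otu$enriched_taxa,
    simulator = list(dt_min = dt_min, n_taxa = n_taxa, depth = depth,
                     theta = theta, enriched_system = enriched_system))
  jsonlite::write_json(manifest, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, heat = heat, gas = gas, chemistry = chem,
                 otu = otu, manifest = manifest))
}

#' Read a simulated dataset bundle
#'
#' @param dir Directory written by [simulate_experiment()].
#' @return List with `heat`, `gas`, `chemistry`, `otu` (counts matrix),
#'   `taxonomy`, `samples` (full metadata), and `truth` (manifest, `NULL`
#'   if absent).
#' @export
read_bundle <- function(dir) {
  need <- c("heat_curves.tsv", "gas_samples.tsv", "chemistry.tsv",
            "otu_counts.tsv", "samples.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("bundle is missing: ", paste(missing, collapse = ", "))
  samples <- read_tsv_plain(file.path(dir, "samples.tsv"))
  heat <- read_tsv_plain(file.path(dir, "heat_curves.tsv"))
  gas <- read_tsv_plain(file.path(dir, "gas_samples.tsv"))
  chem <- read_tsv_plain(file.path(dir, "chemistry.tsv"))
  otu_raw <- read_tsv_plain(file.path(dir, "otu_counts.tsv"))
  counts <- as.matrix(otu_raw[, -(1:2)])
  rownames(counts) <- otu_raw$otu_id
  taxonomy <- stats::setNames(otu_raw$taxonomy, otu_raw$otu_id)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  # re-attach metadata to the measurement tables
  hmeta <- samples[samples$assay == "calorimetry", ]
  heat <- merge(heat, hmeta, by.x = "unit_id", by.y = "sample_id",
                sort = FALSE)
  gmeta <- samples[samples$assay == "gas", ]
  gas <- merge(gas, gmeta, by.x = "jar_id", by.y = "sample_id", sort = FALSE)
  list(heat = heat, gas = gas, chemistry = chem, otu = counts,
       taxonomy = taxonomy, samples = samples, truth = truth)
}
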