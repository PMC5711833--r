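#' Simulate a SIP-fraction OTU count table
#'
#' Draws Dirichlet-multinomial OTU counts for every combination of density
#' fraction (`12C-light`, `13C-light`, `13C-heavy`), treatment, and
#' replicate. A configurable set of planted "glucose utilizer" OTUs carries
#' a log2 fold-change (`truth$enriched_log2fc`) in the 13C-heavy relative
#' to the light fractions within the designated management system. Column
#' sums equal `depth` exactly by construction.
#'
#' @inheritParams simulate_heat_curves
#' @param n_taxa Number of OTUs (>= 10).
#' @param depth Sequencing depth per sample (>= 100).
#' @param theta Dirichlet-multinomial overdispersion (0 = multinomial);
#'   the Dirichlet concentration is `1/theta`.
#' @param enriched_system Management system in which the planted taxa are
#'   enriched.
#' @param fractions Density-fraction labels.
#'
#' @return List of class `otu_sim`: `counts` (integer matrix, OTUs x
#'   samples), `taxonomy` (named lineage strings), `samples` (metadata with
#'   `sample_id`, `management`, `crop`, `treatment`, `replicate`,
#'   `fraction`), and `enriched_taxa` (planted OTU ids).
#' @export
simulate_otu_table <- function(design, truth, n_taxa = 120, depth = 5000,
                               theta = 0.001, enriched_system = "ORG",
                               fractions = c("12C-light", "13C-light",
                                             "13C-heavy")) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "synthetic_truth"))
  if (n_taxa < 10) stop("`n_taxa` must be >= 10")
  if (depth < 100) stop("`depth` must be >= 100")
  if (truth$n_enriched > n_taxa)
    stop("enriched taxa set larger than `n_taxa`")
  units <- unique(design_units(design)[, c("management", "crop", "treatment",
                                           "replicate")])
  samples <- do.call(rbind, lapply(fractions, function(f) {
    cbind(units, fraction = f, stringsAsFactors = FALSE)
  }))
  samples$sample_id <- paste(samples$treatment,
                             paste0("R", samples$replicate),
                             samples$fraction, sep = "-")
  otu_ids <- sprintf("OTU_%04d", seq_len(n_taxa))
  phyla <- c("Actinobacteria", "Proteobacteria", "Firmicutes",
             "Bacteroidetes", "Acidobacteria", "Verrucomicrobia",
             "Chloroflexi", "Crenarchaeota")
  with_seed(substream_seed(design$seed, "otu"), {
    base <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = 1.2)
    base <- base / sum(base)
    enriched <- sort(sample.int(n_taxa, truth$n_enriched))
    phy <- sample(phyla, n_taxa, replace = TRUE,
                  prob = c(0.25, 0.25, 0.1, 0.12, 0.12, 0.06, 0.06, 0.04))
    # planted glucose utilizers drawn from the lineages that dominate
    # heavy-fraction communities
    phy[enriched] <- sample(c("Actinobacteria", "Proteobacteria",
                              "Firmicutes"),
                            length(enriched), replace = TRUE,
                            prob = c(0.5, 0.35, 0.15))
    counts <- vapply(seq_len(nrow(samples)), function(j) {
      p <- base
      if (samples$fraction[j] == "13C-heavy" &&
          samples$management[j] == enriched_system &&
          truth$enriched_log2fc != 0) {
        p[enriched] <- p[enriched] * 2^truth$enriched_log2fc
        p <- p / sum(p)
      }
      w <- if (theta > 0) {
        g <- stats::rgamma(n_taxa, shape = p / theta)
        if (sum(g) == 0) p else g / sum(g)
      } else p
      as.integer(stats::rmultinom(1, size = depth, prob = w))
    }, integer(n_taxa))
  })
  dimnames(counts) <- list(otu_ids, samples$sample_id)
  taxonomy <- paste0("k__Bacteria; p__", phy, "; g__Genus",
                     seq_len(n_taxa) %% 37 + 1)
  names(taxonomy) <- otu_ids
  structure(list(counts = counts, taxonomy = taxonomy,
                 samples = samples[, c("sample_id", "management", "crop",
                                       "treatment", "replicate", "fraction")],
                 enriched_taxa = otu_ids[enriched]),
            class = "otu_sim")
}
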