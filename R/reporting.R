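# Summary tables, contrasts, and the machine-readable report bundle.

#' Treatment and pooled summary statistics
#'
#' Means and standard errors (sd / sqrt(n)) of per-unit variables at two
#' grouping levels: individual treatments (management x cropping history,
#' n = replicates) and management systems pooled across cropping histories
#' (n = 2 x replicates in a balanced design).
#'
#' @param units Data frame with `management`, `crop` columns and numeric
#'   variables.
#' @param vars Variables to summarize; defaults to all numeric columns
#'   except `replicate`.
#' @return Data frame of class `summary_table`: `level` (`"treatment"` or
#'   `"pooled"`), `management`, `crop` (`NA` when pooled), `variable`,
#'   `n`, `mean`, `se`.
#' @export
treatment_summary <- function(units, vars = NULL) {
  if (is.null(vars))
    vars <- setdiff(names(units)[vapply(units, is.numeric, logical(1))],
                    "replicate")
  if (!all(vars %in% names(units)))
    stop("missing variable(s): ",
         paste(setdiff(vars, names(units)), collapse = ", "))
  summarize <- function(df, level, crop_label) {
    if (!nrow(df)) stop("empty group")
    do.call(rbind, lapply(vars, function(v) {
      x <- df[[v]]
      data.frame(level = level, management = df$management[1],
                 crop = crop_label, variable = v, n = length(x),
                 mean = mean(x),
                 se = stats::sd(x) / sqrt(length(x)),
                 row.names = NULL)
    }))
  }
  groups <- split(units, list(units$management, units$crop), drop = TRUE)
  trt <- do.call(rbind, lapply(groups, function(g)
    summarize(g, "treatment", g$crop[1])))
  pools <- split(units, units$management, drop = TRUE)
  pool <- do.call(rbind, lapply(pools, function(g)
    summarize(g, "pooled", NA_character_)))
  out <- rbind(pool, trt)
  rownames(out) <- NULL
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Fold-ratios and percent differences between two groups
#'
#' Computes `a / b` and `100 * (a - b) / b` from group means
#' (ratio-of-means) and, when observations are paired, also the mean of
#' per-pair ratios (mean-of-ratios). Both aggregation conventions are
#' reported side by side because summary tables in the field mix them.
#'
#' @param a,b Numeric vectors (or scalars, e.g. printed pooled means) for
#'   the two groups. `mean(b)` and, when paired, every `b` must be
#'   nonzero.
#' @param paired Treat `a` and `b` as replicate-paired (same length).
#' @return One-row data frame: `ratio_of_means`, `pct_diff_of_means`,
#'   `mean_of_ratios`, `mean_of_pct_diffs` (the last two `NA` when
#'   unpaired).
#' @export
#' @examples
#' contrast_ratios(229.8, 26.5)  # ratio 8.7
contrast_ratios <- function(a, b, paired = length(a) == length(b) &&
                              length(a) > 1) {
  if (mean(b) == 0) stop("zero denominator")
  out <- data.frame(ratio_of_means = mean(a) / mean(b),
                    pct_diff_of_means = 100 * (mean(a) - mean(b)) / mean(b),
                    mean_of_ratios = NA_real_,
                    mean_of_pct_diffs = NA_real_)
  if (paired) {
    if (any(b == 0)) stop("zero denominator in paired ratios")
    out$mean_of_ratios <- mean(a / b)
    out$mean_of_pct_diffs <- mean(100 * (a - b) / b)
  }
  out
}

# Display rounding mirroring the field's table conventions; full precision
# is always retained in the TSVs themselves.
display_digits <- c(heat = 2, respiration = 1, index = 3, quotient = 2,
                    ratio = 1)

#' Assemble the report bundle
#'
#' Writes the pipeline's summary surfaces to `out_dir`: analogues of the
#' four standard result tables (soil properties; respiration/heat/
#' calorespirometric/metabolic-quotient summaries; CO2-C source
#' partitioning; thermodynamic efficiency indices), a contrast table,
#' community-stage outputs if present, run metadata (seed, package
#' version, config hash), and a plain-text summary. Output is
#' deterministic given identical inputs (no timestamps).
#'
#' @param results List as returned by [run_pipeline()].
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
assemble_report <- function(results, out_dir) {
  need <- c("chemistry_summary", "metabolic_summary", "partition_summary",
            "efficiency_summary")
  missing <- need[!need %in% names(results)]
  if (length(missing))
    stop("missing upstream result(s): ", paste(missing, collapse = ", "))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create report directory: ", out_dir)
  paths <- character(0)
  wr <- function(df, file) {
    p <- write_tsv_plain(df, file.path(out_dir, file))
    paths <<- c(paths, p)
  }
  wr(results$chemistry_summary, "table1_soil_properties.tsv")
  wr(results$metabolic_summary, "table2_heat_respiration.tsv")
  wr(results$partition_summary, "table3_partition.tsv")
  wr(results$efficiency_summary, "table4_efficiency.tsv")
  if (!is.null(results$contrasts)) wr(results$contrasts, "contrasts.tsv")
  if (!is.null(results$permanova))
    wr(as.data.frame(results$permanova), "permanova.tsv")
  if (!is.null(results$enrichment))
    wr(as.data.frame(results$enrichment), "enrichment.tsv")
  if (!is.null(results$bray_curtis)) {
    bc <- unclass(results$bray_curtis)
    wr(data.frame(sample_id = rownames(bc), as.data.frame(bc),
                  check.names = FALSE), "braycurtis.tsv")
  }
  if (!is.null(results$pcoa)) {
    pc <- results$pcoa
    wr(data.frame(sample_id = rownames(pc$points),
                  as.data.frame(pc$points),
                  eigenvalue = pc$eigenvalues[seq_len(ncol(pc$points))],
                  check.names = FALSE), "pcoa.tsv")
  }
  if (!is.null(results$correlations)) {
    rho <- results$correlations
    wr(data.frame(otu = rownames(rho), as.data.frame(unclass(rho)),
                  check.names = FALSE), "correlations.tsv")
  }
  cfg <- results$config
  cfg_path <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  meta <- list(package = "thermosip",
               version = as.character(utils::packageVersion("thermosip")),
               seed = cfg$seed,
               config_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(meta, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  eff <- results$efficiency_summary
  lines <- c(
    "thermosip pipeline report",
    "=========================",
    "",
    sprintf("Efficiency index (eta_eff), pooled means: %s",
            paste(sprintf("%s %.3f",
                          eff$management[eff$level == "pooled" &
                                           eff$variable == "eta_eff"],
                          eff$mean[eff$level == "pooled" &
                                     eff$variable == "eta_eff"]),
                  collapse = ", ")),
    sprintf("Tables written: %s",
            paste(basename(paths), collapse = ", ")))
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(c(paths, cfg_path, file.path(out_dir, c("run_info.json",
                                                    "summary.txt"))))
}

#' Published reference summary tables
#'
#' Treatment-level and pooled means (with standard errors) from the
#' long-term organic-vs-conventional cropping trial incubation study that
#' the package's worked examples reproduce: soil properties, heat and
#' respiration, CO2-C source partitioning, and thermodynamic efficiency
#' indices. These printed summary statistics serve as desk-check inputs
#' for the index and mass-balance calculations.
#'
#' @param which One of `"soil"`, `"heat"`, `"partition"`, `"efficiency"`.
#' @return Data frame.
#' @export
#' @examples
#' heat <- reference_means("heat")
#' subset(heat, level == "treatment" & treatment == "CON-ANN")
reference_means <- function(which = c("soil", "heat", "partition",
                                      "efficiency")) {
  which <- match.arg(which)
  f <- system.file("extdata", "reference_means",
                   paste0(which, ".tsv"), package = "thermosip")
  if (f == "") stop("reference table not found")
  read_tsv_plain(f)
}
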