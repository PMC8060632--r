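#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Exactly one data source is
#' active: either real inputs (an image directory plus metadata CSV and a
#' destructive-sampling CSV) or a synthetic trial generated from a
#' [trial_config()].
#'
#' @param image_dir,meta_csv,sampling_csv Paths for the real-data source
#'   (all three required together), or \code{NULL}.
#' @param trial A [trial_config()] for the synthetic source, or \code{NULL}.
#' @param threshold Segmentation threshold: integer or \code{"auto"}.
#' @param curve An [nc_curve()].
#' @param alpha Significance level for the coincidence tests.
#' @param out_dir Output directory for report artifacts, or \code{NULL} to
#'   skip writing.
#' @param seed Integer seed used for any randomness.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(image_dir = NULL, meta_csv = NULL,
                            sampling_csv = NULL, trial = NULL,
                            threshold = 0, curve = nc_curve(),
                            alpha = 0.05, out_dir = NULL, seed = 1L) {
  real <- !is.null(image_dir)
  synth <- !is.null(trial)
  if (real == synth)
    stop("exactly one data source must be given: image_dir/meta_csv/",
         "sampling_csv or a trial_config", call. = FALSE)
  if (real && (is.null(meta_csv) || is.null(sampling_csv)))
    stop("the real-data source needs image_dir, meta_csv and sampling_csv",
         call. = FALSE)
  if (synth && !inherits(trial, "trial_config"))
    stop("'trial' must be a trial_config object", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  structure(list(image_dir = image_dir, meta_csv = meta_csv,
                 sampling_csv = sampling_csv, trial = trial,
                 threshold = threshold, curve = curve, alpha = alpha,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

plot_keys <- c("site", "season", "cultivar", "n_rate_kg_ha", "replicate",
               "stage")

#' Join a canopy-cover table with a destructive-sampling table
#'
#' Inner join on the plot keys (site, season, cultivar, n_rate_kg_ha,
#' replicate, stage). Shoot N accumulation is recomputed as
#' \eqn{10 \times SDM \times SNC} when absent. Duplicate keys in either
#' table raise an integrity error; disjoint keys give an empty result with
#' a reconciliation warning listing orphan keys.
#'
#' @param cc_table Data frame with the plot keys and a \code{cc} column.
#' @param sampling Data frame with the plot keys and columns
#'   \code{sdm_t_ha}, \code{lai}, \code{snc_pct} (and optionally
#'   \code{sna_kg_ha}).
#' @return The joined plot-record table.
#' @export
join_cc_with_sampling <- function(cc_table, sampling) {
  for (tab in list(cc_table, sampling))
    if (!all(plot_keys %in% names(tab)))
      stop("both tables need the key columns: ",
           paste(plot_keys, collapse = ", "), call. = FALSE)
  key_of <- function(d) do.call(paste, c(d[plot_keys], sep = "\r"))
  k1 <- key_of(cc_table); k2 <- key_of(sampling)
  if (anyDuplicated(k1) || anyDuplicated(k2))
    stop("duplicate plot keys found; each plot x stage must be unique",
         call. = FALSE)
  joined <- merge(cc_table, sampling, by = plot_keys, sort = TRUE)
  orphans <- c(setdiff(k1, k2), setdiff(k2, k1))
  if (length(orphans))
    warning(length(orphans), " unmatched plot key(s) dropped in join, e.g. ",
            paste(utils::head(gsub("\r", "/", orphans), 3), collapse = "; "),
            call. = FALSE)
  if (!"sna_kg_ha" %in% names(joined) && nrow(joined) >= 0)
    joined$sna_kg_ha <- sna_from(joined$sdm_t_ha, joined$snc_pct)
  joined
}

#' Run the full canopy-cover to NNI analysis
#'
#' Orchestrates the analysis end to end: (1) obtain the plot-record table,
#' either by segmenting an image directory and joining with the sampling
#' CSV, or by generating a synthetic trial; (2) compute critical N, NNI
#' and N status per record; (3) fit allometric models of SDM, LAI and SNA
#' (and SNC) against CC per cultivar and per N rate, plus pooled; (4) run
#' coincidence F tests across cultivars and N rates, pooled over stages
#' and per stage; (5) fit per-stage direct CC-to-NNI models and compose
#' per-stage indirect models from the stage SDM and SNC fits. The run is
#' deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return An object of class \code{"analysis_report"}: a list with
#'   \code{records} (the NNI-augmented plot table), \code{fits} (named list
#'   of per-group parameter tables), \code{comparisons} (named list of
#'   coincidence-test summaries), \code{nni_models} (per-stage direct and
#'   indirect model table), and \code{meta} (config echo, seed, package
#'   version). If \code{config$out_dir} is set, CSV/JSON artifacts are
#'   written there.
#' @examples
#' rep <- run_pipeline(pipeline_config(trial = trial_config(seed = 2)))
#' rep$nni_models
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)

  if (!is.null(config$trial)) {
    records <- simulate_trial(config$trial)
  } else {
    meta <- utils::read.csv(config$meta_csv, stringsAsFactors = FALSE)
    cc_tab <- canopy_cover_table(config$image_dir, meta = meta,
                                 threshold = config$threshold)
    sampling <- utils::read.csv(config$sampling_csv,
                                stringsAsFactors = FALSE)
    records <- join_cc_with_sampling(cc_tab, sampling)
    if (nrow(records) == 0)
      stop("no records after joining images with sampling data",
           call. = FALSE)
  }
  records <- add_n_status(records, curve = config$curve)
  records <- records[do.call(order, records[plot_keys]), ]
  rownames(records) <- NULL

  indices <- c(sdm = "sdm_t_ha", lai = "lai", sna = "sna_kg_ha")
  fits <- list()
  for (nm in names(indices)) {
    fits[[paste0(nm, "_by_cultivar")]] <-
      fit_allometric_by_group(records, indices[[nm]], "cc", "cultivar")
    fits[[paste0(nm, "_by_n_rate")]] <-
      fit_allometric_by_group(records, indices[[nm]], "cc", "n_rate_kg_ha")
  }
  fits$snc_by_n_rate <-
    fit_allometric_by_group(records, "snc_pct", "cc", "n_rate_kg_ha")

  # comparisons are only defined across >= 2 group levels
  comparisons <- list()
  for (nm in names(indices)) {
    if (length(unique(records$cultivar)) >= 2)
      comparisons[[paste0(nm, "_cultivar")]] <-
        compare_allometric(records, indices[[nm]], "cc", "cultivar",
                           alpha = config$alpha)
    if (length(unique(records$n_rate_kg_ha)) >= 2)
      comparisons[[paste0(nm, "_n_rate")]] <-
        compare_allometric(records, indices[[nm]], "cc", "n_rate_kg_ha",
                           alpha = config$alpha)
  }
  stages <- unique(records$stage)
  if (length(unique(records$cultivar)) >= 2) {
    for (st in stages) {
      d <- records[records$stage == st, ]
      comparisons[[paste0("sdm_cultivar_", st)]] <-
        compare_allometric(d, "sdm_t_ha", "cc", "cultivar",
                           alpha = config$alpha)
      comparisons[[paste0("snc_cultivar_", st)]] <-
        compare_allometric(d, "snc_pct", "cc", "cultivar",
                           alpha = config$alpha)
    }
  }

  nni_models <- list()
  rows <- list()
  for (st in stages) {
    d <- records[records$stage == st, ]
    direct <- fit_nni_direct(d$cc, d$nni, stage = st)
    sdm_fit <- fit_allometric(d$cc, d$sdm_t_ha)
    snc_fit <- fit_allometric(d$cc, d$snc_pct)
    indirect <- compose_indirect(snc_fit$a, snc_fit$b, sdm_fit$a, sdm_fit$b,
                                 curve = config$curve, stage = st)
    nni_models[[st]] <- list(direct = direct, indirect = indirect,
                             sdm_fit = sdm_fit, snc_fit = snc_fit)
    rows[[st]] <- data.frame(
      stage = st,
      a_direct = direct$a_prime, b_direct = direct$b_prime,
      r2_direct = direct$provenance$r2,
      a_s = snc_fit$a, b_s = snc_fit$b, r2_snc = snc_fit$r2,
      a_d = sdm_fit$a, b_d = sdm_fit$b, r2_sdm = sdm_fit$r2,
      a_indirect = indirect$a_prime, b_indirect = indirect$b_prime,
      stringsAsFactors = FALSE)
  }
  # pooled-over-stages direct fit: the headline check that no unified
  # CC-NNI relation holds across stages (its r2 is low relative to
  # the per-stage fits)
  pooled_direct <- fit_nni_direct(records$cc, records$nni, stage = "pooled")
  nni_table <- do.call(rbind, c(rows, list(data.frame(
    stage = "pooled",
    a_direct = pooled_direct$a_prime, b_direct = pooled_direct$b_prime,
    r2_direct = pooled_direct$provenance$r2,
    a_s = NA, b_s = NA, r2_snc = NA, a_d = NA, b_d = NA, r2_sdm = NA,
    a_indirect = NA, b_indirect = NA, stringsAsFactors = FALSE))))
  rownames(nni_table) <- NULL
  nni_models$pooled <- list(direct = pooled_direct)

  report <- structure(
    list(records = records, fits = fits,
         comparisons = comparisons,
         comparison_table = comparison_table(comparisons),
         nni_models = nni_models, nni_table = nni_table,
         meta = list(seed = config$seed, alpha = config$alpha,
                     curve = unclass(config$curve),
                     threshold = config$threshold,
                     source = if (is.null(config$trial)) "images" else
                       "synthetic",
                     package_version = as.character(
                       utils::packageVersion("ccnni")))),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Flattens the comparison objects into one decision table.
comparison_table <- function(comparisons) {
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    data.frame(comparison = nm, k = cmp$k, f = cmp$f,
               df1 = cmp$df_diff, df2 = cmp$df_within,
               f_crit = cmp$f_crit, p_value = cmp$p_value,
               poolable = cmp$poolable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an analysis report to disk
#'
#' Serializes the report tables as CSV and the model parameters plus run
#' metadata as JSON. Outputs are byte-identical across runs with the same
#' config and seed.
#'
#' @param report An \code{"analysis_report"}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wcsv <- function(d, name) {
    path <- file.path(dir, name)
    utils::write.csv(d, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wcsv(report$records, "records.csv")
  for (nm in names(report$fits)) {
    tab <- report$fits[[nm]]
    attr(tab, "fits") <- NULL
    wcsv(tab, paste0("fits_", nm, ".csv"))
  }
  wcsv(report$comparison_table, "comparisons.csv")
  wcsv(report$nni_table, "nni_models.csv")
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(meta = report$meta,
         nni_models = report$nni_table,
         comparisons = report$comparison_table),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, json_path)
  invisible(files)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Canopy-cover / NNI analysis report\n")
  cat(sprintf("  source: %s;  records: %d;  seed: %d\n",
              x$meta$source, nrow(x$records), x$meta$seed))
  cat("\nPer-stage CC-to-NNI models (direct a, b | indirect a', b'):\n")
  print(x$nni_table[, c("stage", "a_direct", "b_direct", "r2_direct",
                        "a_indirect", "b_indirect")],
        digits = 3, row.names = FALSE)
  cat("\nCoincidence tests:\n")
  print(x$comparison_table[, c("comparison", "f", "f_crit", "poolable")],
        digits = 4, row.names = FALSE)
  invisible(x)
}
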