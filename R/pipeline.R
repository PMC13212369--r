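#' Derive a deterministic per-stage seed from a top-level seed
#'
#' Mixes the run seed with a stage name so stages can be re-run in isolation
#' while everything still flows from one integer. The result is a positive
#' integer below 2^31.
#'
#' @param seed top-level integer seed.
#' @param stage stage name (character).
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 2147483647
  as.integer(max(1, h))
}

#' Configuration of an end-to-end synthetic run
#'
#' Bundles every knob of the pipeline: generator settings, mask settings,
#' quantile-fit settings and bootstrap settings, under a single seed. The
#' configuration is serialized (JSON) next to the outputs of
#' [run_end_to_end()], so a bundle can always be regenerated.
#'
#' @param seed top-level integer seed.
#' @param out_dir output directory for the artifact bundle.
#' @param spacing_mm mm per pixel of the synthetic masks.
#' @param n_per_sex_per_agegroup cohort size knob (see [generator_config()]).
#' @param bilateral_corr,reader_bias_mm,reader_noise_sd_mm generator knobs.
#' @param n_masks number of synthetic mask cases to rasterize and measure.
#' @param mask_shape `(rows, cols)` of each mask.
#' @param taus,degree,grid_step quantile-fit knobs
#'   (see [fit_quantile_curves()]).
#' @param n_boot bootstrap replicates for interval estimates.
#' @param table_ages ages (years) of the percentile reference table.
#' @return List of class `fhoc_run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("fhoc_run_"),
                       spacing_mm = 0.2, n_per_sex_per_agegroup = 25,
                       bilateral_corr = 0.98, reader_bias_mm = 0,
                       reader_noise_sd_mm = 0.96, n_masks = 12,
                       mask_shape = c(128, 128),
                       taus = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95),
                       degree = 3, grid_step = 0.25, n_boot = 500,
                       table_ages = c(0.5, 1:11)) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 spacing_mm = spacing_mm,
                 n_per_sex_per_agegroup = n_per_sex_per_agegroup,
                 bilateral_corr = bilateral_corr,
                 reader_bias_mm = reader_bias_mm,
                 reader_noise_sd_mm = reader_noise_sd_mm,
                 n_masks = n_masks, mask_shape = mask_shape,
                 taus = taus, degree = degree, grid_step = grid_step,
                 n_boot = n_boot, table_ages = table_ages),
            class = "fhoc_run_config")
}

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  dt <- as.numeric(Sys.time() - t0, units = "secs")
  cat(sprintf("[%s] stage %-12s %.2f s\n", format(Sys.time(), "%H:%M:%S"),
              name, dt), file = log, append = TRUE)
  res
}

#' Run the full synthetic pipeline and write an artifact bundle
#'
#' Generates a synthetic cohort and masks, measures the masks, evaluates the
#' segmentation/landmark metrics against the analytic ground truth, runs the
#' stratified agreement analysis of simulated automatic-vs-reader pairs, fits
#' the monotone quantile growth chart, and writes everything (CSV tables with
#' units in their column names, the growth-chart figure, the config echo, and
#' a stage log) to `config$out_dir`. Identical configs give identical tables.
#'
#' @param config an [run_config()] object.
#' @return Invisibly, a list with the fitted chart, the cohort, the
#'   agreement and error tables, and the output paths.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "fhoc_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  mask_dir <- file.path(config$out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  log <- file.path(config$out_dir, "log.txt")
  cat(sprintf("fhocgrowth %s run, seed %d\n",
              as.character(utils::packageVersion("fhocgrowth")), config$seed),
      file = log)
  paths <- list(log = log)

  # -- simulate ------------------------------------------------------------
  cohort <- .stage("simulate", log, {
    cfg <- generator_config(
      n_per_sex_per_agegroup = config$n_per_sex_per_agegroup,
      bilateral_corr = config$bilateral_corr,
      reader_bias_mm = config$reader_bias_mm,
      reader_noise_sd_mm = config$reader_noise_sd_mm,
      seed = derive_seed(config$seed, "cohort"))
    co <- gen_cohort(cfg)
    gen_paired_measurements(co, bias_mm = config$reader_bias_mm,
                            noise_sd_mm = config$reader_noise_sd_mm,
                            seed = derive_seed(config$seed, "reader"))
  })
  paths$cohort <- file.path(config$out_dir, "cohort.csv")
  utils::write.csv(cohort, paths$cohort, row.names = FALSE)

  # -- masks: rasterize, measure, evaluate ---------------------------------
  mask_eval <- .stage("masks", log, {
    set.seed(derive_seed(config$seed, "masks"))
    nr <- config$mask_shape[1]; nc <- config$mask_shape[2]
    rows <- lapply(seq_len(config$n_masks), function(i) {
      a <- stats::runif(1, 0.12, 0.3) * nc
      b <- a * stats::runif(1, 0.6, 1)
      pr <- shape_params(a, b,
                         rotation_deg = stats::runif(1, -40, 40),
                         boundary_noise_sd = stats::runif(1, 0, 1),
                         crescent_fraction = sample(c(0, 0.2, 0.3), 1))
      sd_mask <- derive_seed(config$seed, paste0("mask", i))
      g <- gen_fhoc_mask(pr, image_shape = c(nr, nc),
                         spacing_mm = config$spacing_mm, seed = sd_mask)
      truth_g <- gen_fhoc_mask(shape_params(a, b, pr$rotation_deg,
                                            crescent_fraction =
                                              pr$crescent_fraction),
                               image_shape = c(nr, nc),
                               spacing_mm = config$spacing_mm)
      f <- file.path(mask_dir, sprintf("case%03d.png", i))
      write_mask(g$mask, f)
      meas <- measure_mask(g$mask)
      lm_pred <- rbind(meas$landmarks$medial, meas$landmarks$lateral)
      lm_true <- rbind(g$truth$p_left, g$truth$p_right)
      list(row = data.frame(case = sprintf("case%03d", i),
                            measured_size_mm = meas$size_mm,
                            truth_size_mm = g$truth$diameter_mm,
                            dice = dice(g$mask, truth_g$mask),
                            hausdorff_mm = hausdorff(g$mask, truth_g$mask),
                            stringsAsFactors = FALSE),
           lm_pred = lm_pred, lm_true = lm_true)
    })
    list(table = do.call(rbind, lapply(rows, `[[`, "row")),
         lm_pred = do.call(rbind, lapply(rows, `[[`, "lm_pred")),
         lm_true = do.call(rbind, lapply(rows, `[[`, "lm_true")))
  })
  paths$seg_metrics <- file.path(config$out_dir, "seg_metrics.csv")
  utils::write.csv(mask_eval$table, paths$seg_metrics, row.names = FALSE)
  sdr <- radial_errors(mask_eval$lm_pred, mask_eval$lm_true,
                       spacing_mm = config$spacing_mm)
  sdr_tab <- data.frame(threshold_mm = sdr$thresholds_mm,
                        sdr_pct = sdr$rates_pct,
                        mre_mm = sdr$mre_mm)
  paths$sdr <- file.path(config$out_dir, "landmark_sdr.csv")
  utils::write.csv(sdr_tab, paths$sdr, row.names = FALSE)

  # -- agreement -----------------------------------------------------------
  agree <- .stage("agreement", log, {
    stratified_agreement(cohort, by = c("sex"),
                         n_boot = config$n_boot,
                         seed = derive_seed(config$seed, "boot"))
  })
  paths$agreement <- file.path(config$out_dir, "agreement.csv")
  utils::write.csv(agree, paths$agreement, row.names = FALSE)

  # -- growth chart --------------------------------------------------------
  chart <- .stage("growthchart", log, {
    fit_quantile_curves(cohort, taus = config$taus, degree = config$degree,
                        grid_step = config$grid_step,
                        age_domain = range(default_age_bins()))
  })
  ptab <- predict_percentiles(chart, ages = config$table_ages)
  paths$percentiles <- file.path(config$out_dir, "percentile_table.csv")
  utils::write.csv(ptab, paths$percentiles, row.names = FALSE)
  gerr <- group_errors(chart, cohort, n_boot = config$n_boot,
                       seed = derive_seed(config$seed, "boot"))
  paths$age_bin_errors <- file.path(config$out_dir, "age_bin_errors.csv")
  utils::write.csv(gerr, paths$age_bin_errors, row.names = FALSE)
  r2 <- adjusted_r2(chart, cohort)
  paths$fit_summary <- file.path(config$out_dir, "fit_summary.json")
  jsonlite::write_json(list(adjusted_r2 = as.list(r2)),
                       paths$fit_summary, auto_unbox = TRUE, digits = NA)
  paths$figure <- file.path(config$out_dir, "growth_chart.png")
  grDevices::png(paths$figure, width = 1400, height = 700, res = 150)
  print(plot_growth_chart(chart, cohort))
  grDevices::dev.off()

  # -- config echo ---------------------------------------------------------
  paths$config <- file.path(config$out_dir, "config.json")
  cfg_out <- unclass(config)
  cfg_out$package_version <-
    as.character(utils::packageVersion("fhocgrowth"))
  jsonlite::write_json(cfg_out, paths$config, auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, mask_eval = mask_eval$table,
                 landmark_sdr = sdr_tab, agreement = agree,
                 chart = chart, percentile_table = ptab,
                 age_bin_errors = gerr, adjusted_r2 = r2, paths = paths))
}
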