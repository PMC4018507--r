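## The reproducible pipeline entry point: one config file + one seed in,
## result tables, JSON summaries and a run manifest out. Re-running with an
## identical config and seed reproduces byte-identical result tables (the
## manifest timestamp excepted).

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

.write_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.ce_as_list <- function(ce) {
  list(deaths_prevented = ce$deaths_prevented,
       deaths_with_undiagnosed_crc_change = ce$deaths_with_undiagnosed_crc_change,
       delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
       delta_ly_undiscounted = ce$delta_ly_undisc,
       delta_ly_discounted = ce$delta_ly_disc,
       icer = if (is.na(ce$icer)) NULL else ce$icer,
       nmb = ce$nmb, wtp = ce$wtp)
}

#' Run the configured pipeline
#'
#' Reads and validates the configuration, builds the model, executes every
#' experiment listed under `experiments.run` (`base_case`, `grid`, `psa`,
#' `uptake_equivalence`, `simulate_pilot`, `pilot_stats`), writes result
#' tables (CSV), summaries (JSON) and a run manifest, and logs parameters to
#' `stderr`.
#'
#' @param config_path Path to a YAML configuration file (see
#'   [default_config()]; the canonical transcription ships as
#'   `system.file("extdata", "params_default.yaml", package = "crcaware")`).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed controlling every stochastic component.
#' @param quiet Suppress the parameter log.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = "crcaware-results",
                         seed = 1L, quiet = FALSE) {
  config <- read_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message(sprintf(...))
  log("crcaware pipeline: config %s, seed %d", config_path, seed)

  model <- config_to_model(config)
  campaign <- config_to_campaign(config)
  experiments <- unlist(config$experiments$run)
  files <- character(0)
  emit <- function(name) files <<- c(files, name)

  for (exp in experiments) {
    log("running experiment: %s", exp)
    switch(exp,
      base_case = {
        ce <- run_base_case(model, campaign)
        .write_json(.ce_as_list(ce), file.path(out_dir, "base_case.json"))
        .write_csv(ce_table(ce), file.path(out_dir, "base_case_table.csv"))
        emit("base_case.json"); emit("base_case_table.csv")
      },
      grid = {
        gr <- run_sensitivity_grid(model,
                                   config$experiments$grid_durations,
                                   config$experiments$grid_magnitudes,
                                   config$experiments$stage_restricted,
                                   template = campaign)
        .write_csv(as.data.frame(gr), file.path(out_dir, "grid.csv"))
        emit("grid.csv")
      },
      psa = {
        ps <- run_psa(model, campaign,
                      n_samples = config$experiments$psa_samples,
                      seed = seed, rel_se = config$experiments$psa_rel_se)
        .write_csv(ps$samples, file.path(out_dir, "psa_samples.csv"))
        .write_json(list(n_samples = ps$n_samples, seed = ps$seed,
                         rel_se = ps$rel_se,
                         intervals = as.data.frame(ps$intervals)),
                    file.path(out_dir, "psa_summary.json"))
        emit("psa_samples.csv"); emit("psa_summary.json")
      },
      uptake_equivalence = {
        ce <- run_base_case(model, campaign)
        eq <- screening_uptake_equivalence(model, max(ce$delta_qaly, 0))
        .write_json(eq, file.path(out_dir, "uptake_equivalence.json"))
        emit("uptake_equivalence.json")
      },
      simulate_pilot = {
        sp <- config$pilot
        spec <- pilot_series_spec(sp$n_months, sp$baseline_mean,
                                  sp$step_month_index, sp$step_multiplier,
                                  n_regions = sp$n_regions, seed = seed)
        series <- generate_pilot_incidence_series(spec)
        write_pilot_series(series, file.path(out_dir, "pilot_series.csv"))
        emit("pilot_series.csv")
      },
      pilot_stats = {
        sp <- config$pilot
        spec <- pilot_series_spec(sp$n_months, sp$baseline_mean,
                                  sp$step_month_index, sp$step_multiplier,
                                  n_regions = sp$n_regions, seed = seed)
        series <- generate_pilot_incidence_series(spec)
        tests <- pooled_and_regional_tests(series, sp$test_month)
        .write_json(lapply(tests, function(tt)
          list(t_statistic = tt$t_statistic, p_value = tt$p_value,
               baseline_mean = tt$baseline_mean,
               baseline_sd = tt$baseline_sd, observed = tt$observed,
               pct_vs_same_month_prior_year =
                 if (is.na(tt$pct_vs_same_month_prior_year)) NULL
                 else tt$pct_vs_same_month_prior_year,
               pct_vs_mean_plus_2sd = tt$pct_vs_mean_plus_2sd)),
          file.path(out_dir, "pilot_stats.json"))
        emit("pilot_stats.json")
      },
      stop("unknown experiment in experiments.run: ", exp))
  }

  manifest <- list(
    package = "crcaware",
    version = as.character(utils::packageVersion("crcaware")),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    fixtures = list(demography = config$population$shape,
                    survival = config$model$survival_preset),
    experiments = as.list(experiments),
    outputs = as.list(files),
    timestamp = format(Sys.time(), tz = "UTC"))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  log("wrote %d output file(s) to %s", length(files) + 1L, out_dir)
  invisible(manifest)
}
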