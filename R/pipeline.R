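#' Configuration for a full pipeline run
#'
#' Bundles the landscape and panel generator configurations with the
#' classification threshold and output location. The single top-level
#' `seed` fans out to fixed per-stage substreams so that each stage is
#' independently reproducible.
#'
#' @param landscape a [landscape_config()].
#' @param panel a [panel_config()].
#' @param threshold_hours remoteness threshold, hours (default 5).
#' @param poverty_line poverty line, dollars/person/day (metadata only;
#'   survey headcounts are already expressed against it).
#' @param output_dir directory for all outputs.
#' @param seed integer master seed; overrides the stage configs' seeds.
#' @return a `run_config` list.
#' @export
run_config <- function(landscape = landscape_config(),
                       panel = panel_config(), threshold_hours = 5,
                       poverty_line = 2.00,
                       output_dir = tempfile("landpov_run_"), seed = 42L) {
  landscape$seed <- seed + 100L
  panel$seed <- seed + 200L
  structure(list(landscape = landscape, panel = panel,
                 threshold_hours = threshold_hours,
                 poverty_line = poverty_line, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulate a landscape, classify it, tabulate rural populations by land
#' class for both epochs, aggregate to regions, compute epoch changes and
#' density-change summaries; then simulate a survey panel, rebuild it from
#' its raw spell fields, fit the growth-poverty system (3SLS, without and
#' with controls) for the configured share variable, run the
#' direct-vs-indirect restriction test, and evaluate the impact schedule.
#' All tables are written as CSV under `config$output_dir` together with a
#' YAML manifest (config, seed, file checksums, stage timings).
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (a list; `$files` names every output).
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest <- list(seed = config$seed, failed_stage = name,
                       error = conditionMessage(e))
      yaml::write_yaml(manifest,
                       file.path(config$output_dir, "manifest.yaml"))
      stop(e)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  stack <- stage("simulate_landscape", generate_landscape(config$landscape))
  files <- c(files, stage("write_landscape",
                          write_stack(stack,
                                      file.path(config$output_dir,
                                                "landscape"))))
  report <- stage("validate", validate_stack(stack))
  if (any(report$fatal)) {
    abort_landpov("generated stack failed validation",
                  "landpov_validation_error")
  }

  labels <- stage("classify", classify_land(stack, config$threshold_hours))
  files <- c(files, labels = stage("write_labels", write_labels_csv(
    labels, file.path(config$output_dir, "labels.csv"))))

  tabs <- list()
  for (ep in c("2000", "2010")) {
    tab <- stage(paste0("tabulate_", ep), tabulate_country(
      labels, stack$layers[[paste0("population_", ep)]],
      stack$layers$urban_mask, stack$layers$country_zone))
    reg <- compute_region_table(tab, stack$region_map)
    tabs[[ep]] <- list(country = tab, region = reg)
    files <- c(files,
               write_table(tab, config$output_dir,
                           sprintf("country_table_%s.csv", ep)),
               write_table(reg, config$output_dir,
                           sprintf("region_table_%s.csv", ep)))
  }
  chg <- stage("epoch_change",
               epoch_change(tabs[["2000"]]$region, tabs[["2010"]]$region))
  files <- c(files, write_table(chg, config$output_dir,
                                "region_change.csv"))
  dens <- stage("density_change", density_change(
    stack$layers$population_2000, stack$layers$population_2010, labels))
  files <- c(files, write_table(dens$summary, config$output_dir,
                                "density_change_summary.csv"))

  sim <- stage("simulate_panel", generate_panel(config$panel))
  files <- c(files, write_table(sim$panel, config$output_dir, "panel.csv"))
  yaml::write_yaml(lapply(sim$truth, function(x) {
    if (is.matrix(x)) as.vector(x) else x
  }), file.path(config$output_dir, "panel_truth.yaml"))
  files <- c(files, file.path(config$output_dir, "panel_truth.yaml"))

  # rebuild growth rates from the raw spell fields (round-trip check path)
  shares <- sim$panel[, c("country", "d1", "d2", "i1", "i2")]
  rebuilt <- stage("build_panel", build_panel(
    sim$panel[, c("country", "t0", "t1", "welfare_type",
                  "H0", "H1", "mu0", "mu1", "spell_years")],
    shares,
    sim$panel[, c("country", "g", grep("^[wz][0-9]+$",
                                       names(sim$panel), value = TRUE))]))
  desc <- describe_panel(rebuilt)
  files <- c(files, write_table(desc, config$output_dir,
                                "panel_descriptives.csv"))

  sv <- config$panel$share_variable
  fit_nc <- stage("fit_3sls", fit_system_3sls(
    rebuilt, model_spec(sv, include_controls = FALSE)))
  fit_wc <- stage("fit_3sls_controls", fit_system_3sls(
    rebuilt, model_spec(sv, include_controls = TRUE)))
  for (nm in c("no_controls", "with_controls")) {
    f <- if (nm == "no_controls") fit_nc else fit_wc
    yaml::write_yaml(list(estimator = f$estimator, n_obs = f$n_obs,
                          coefficients = f$coefficients),
                     file.path(config$output_dir,
                               sprintf("fit_%s_%s.yaml", sv, nm)))
    files <- c(files, file.path(config$output_dir,
                                sprintf("fit_%s_%s.yaml", sv, nm)))
  }
  restr <- stage("restriction_test",
                 test_restrictions(rebuilt, model_spec(sv,
                                                       estimator = "2sls")))
  files <- c(files, write_table(restr$wald, config$output_dir,
                                "restriction_test.csv"))

  fits <- stats::setNames(
    list(list(no_controls = fit_nc, with_controls = fit_wc)), sv)
  imp <- stage("impact_table", impact_table(
    fits, desc[, c("variable", "mean", "sd")] |>
      stats::setNames(c("variable", "mean", "sd")),
    growth = mean(rebuilt$gamma_mu, na.rm = TRUE)))
  files <- c(files, write_table(imp, config$output_dir,
                                "impact_table.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("landpov")),
    seed = config$seed,
    threshold_hours = config$threshold_hours,
    poverty_line = config$poverty_line,
    share_variable = sv,
    restriction_verdict = restr$supported_channel,
    output_dir = config$output_dir,
    files = as.list(stats::setNames(unname(tools::md5sum(unname(files))),
                                    basename(unname(files)))),
    timings = timings)
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Render a human-readable report from a run manifest
#'
#' Formats the run's tables at the conventional printed precisions
#' (populations to 0.1 M where applicable, shares to 0.1%, impacts to 2
#' decimals) and appends a reproduction checklist recomputing, from the
#' bundled reference values, the share arithmetic, the world totals, the
#' evaluation points and the impact schedule, each marked pass/fail. An
#' incomplete manifest produces a partial report flagged as such.
#'
#' @param manifest list returned by [run_pipeline()] (or read back from
#'   `manifest.yaml`).
#' @return character scalar, the markdown report; also written to
#'   `report.md` in the run directory when it exists.
#' @export
render_report <- function(manifest) {
  out <- c(sprintf("# landpov run report (seed %s)", manifest$seed), "")
  dir <- manifest$output_dir %||% "."
  partial <- FALSE

  fmt_table <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round_half_up(x, 2))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1L, paste, collapse = " | "), "")
  }
  add_csv <- function(title, file) {
    p <- file.path(dir, file)
    if (!file.exists(p)) {
      partial <<- TRUE
      return(c(sprintf("## %s", title), "", "*absent*", ""))
    }
    c(sprintf("## %s", title), "",
      fmt_table(utils::read.csv(p, stringsAsFactors = FALSE)))
  }
  out <- c(out,
           add_csv("Regional tabulation, 2000", "region_table_2000.csv"),
           add_csv("Regional change 2000-2010 (%)", "region_change.csv"),
           add_csv("Panel descriptives", "panel_descriptives.csv"),
           add_csv("Restriction test", "restriction_test.csv"),
           add_csv("Impact schedule", "impact_table.csv"))
  if (!is.null(manifest$restriction_verdict)) {
    out <- c(out, sprintf("Supported channel: **%s**",
                          manifest$restriction_verdict), "")
  }

  out <- c(out, "## Reproduction checklist", "")
  checks <- reproduction_checklist()
  out <- c(out, fmt_table(checks))
  if (partial || !is.null(manifest$failed_stage)) {
    out <- c(out, "", "**Partial report: some outputs were absent.**")
  }
  text <- paste(out, collapse = "\n")
  if (dir.exists(dir)) writeLines(text, file.path(dir, "report.md"))
  text
}

#' Recompute the published arithmetic checks
#'
#' Recomputes, from the bundled reference values, (1) regional shares from
#' their population columns, (2) the world land-class totals, (3) the
#' evaluation points from the sample moments, and (4) the marginal-impact
#' schedule, and compares each with its published counterpart.
#'
#' @return data frame `check`, `value`, `expected`, `pass`.
#' @export
reproduction_checklist <- function() {
  ref <- reference_population_2000()
  share_dev <- max(abs(100 * ref$pop_class / ref$rural_pop -
                         ref$share_class))
  remote_dev <- max(abs(100 * ref$pop_remote / ref$rural_pop -
                          ref$share_remote))
  world_dal <- sum(ref$pop_class[ref$table == "DAL" &
                                   ref$region %in% c("Developing",
                                                     "Developed")])
  world_ial <- sum(ref$pop_class[ref$table == "IAL" &
                                   ref$region %in% c("Developing",
                                                     "Developed")])
  mom <- reference_moments()
  d1 <- mom[mom$variable == "d1", ]
  pts <- evaluation_points(d1$mean, d1$sd)
  imp <- marginal_impact(-2.15, 0.54, c(6.1, 27.1, 48.2), "DAL", 3.36)
  rows <- list(
    list("max |recomputed - printed| class share (pp)",
         round(share_dev, 3), "<= 0.1", share_dev <= 0.1),
    list("max |recomputed - printed| remote share (pp)",
         round(remote_dev, 3), "<= 0.1", remote_dev <= 0.1),
    list("world DAL total (billions)",
         round_half_up(world_dal / 1000, 2), "1.33",
         round_half_up(world_dal / 1000, 2) == 1.33),
    list("world IAL total (billions)",
         round_half_up(world_ial / 1000, 2), "1.54",
         round_half_up(world_ial / 1000, 2) == 1.54),
    list("d1 evaluation points", paste(pts, collapse = "/"),
         "6.1/27.1/48.2",
         identical(unname(pts), c(6.1, 27.1, 48.2))),
    list("d1 no-controls impact column",
         paste(round_half_up(imp, 2), collapse = "/"),
         "-3.66/-2.84/-2.02",
         identical(round_half_up(imp, 2), c(-3.66, -2.84, -2.02))))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(check = r[[1]], value = as.character(r[[2]]),
               expected = r[[3]], pass = r[[4]],
               stringsAsFactors = FALSE)
  }))
}
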