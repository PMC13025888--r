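# End-to-end orchestration: configuration, staged execution with labelled
# errors, publication-layout table renderers and a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects everything a full run needs. Paths default to the packaged
#' survey fixtures; constants can be overridden per [tox_constants()].
#'
#' @param concentrations_path,consumption_path,body_weights_path Input CSVs.
#' @param constants A [tox_constants()] list.
#' @param ages Age groups for the deterministic grid.
#' @param n_per_age Synthetic consumption records per (type, age) cell.
#' @param zero_prob_default Non-consumer probability for zero-median cells.
#' @param mc An [mc_config()].
#' @param q Exceedance probability for the reverse assessment.
#' @param reproduce_table4 Use organotin fraction 1 in the scenario screen
#'   (the published-table convention) instead of 0.0583.
#' @param out_dir Output directory (created if missing).
#' @param seed Seed for the synthetic-data stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(concentrations_path = fixture_path("concentrations.csv"),
                            consumption_path = fixture_path("consumption.csv"),
                            body_weights_path = fixture_path("body_weights.csv"),
                            constants = tox_constants(),
                            ages = NULL,
                            n_per_age = 500L,
                            zero_prob_default = 0.6,
                            mc = mc_config(),
                            q = 0.005,
                            reproduce_table4 = TRUE,
                            out_dir = tempfile("tindiet_run_"),
                            seed = 1L) {
  structure(list(
    concentrations_path = concentrations_path,
    consumption_path = consumption_path,
    body_weights_path = body_weights_path,
    constants = constants, ages = ages, n_per_age = as.integer(n_per_age),
    zero_prob_default = zero_prob_default, mc = mc, q = q,
    reproduce_table4 = reproduce_table4, out_dir = out_dir,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full exposure-assessment pipeline
#'
#' Executes, in order: fixture loading, synthetic-data generation,
#' descriptive summary and compliance screening of the synthetic samples,
#' the deterministic scenario grid with hazard quotients and category
#' contributions, the organotin scenario screen, the reverse
#' minimum-conversion assessment, and the Monte Carlo percentile-at-TDI
#' table. Writes publication-layout CSVs plus a YAML manifest (config echo,
#' seeds, versions) to `config$out_dir`; any stage failure is reported with
#' the stage name. Two runs with the same configuration produce identical
#' numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  const <- config$constants

  bw <- .stage("load", load_body_weights(config$body_weights_path))
  summaries <- .stage("load",
                      load_concentration_summaries(config$concentrations_path))
  consumption <- .stage("load", load_consumption_quantiles(
    config$consumption_path, body_weights = bw, on_inverted = "keep"))

  synth <- .stage("simulate-data", simulate_study_data(
    summaries, consumption, n_per_age = config$n_per_age,
    seed = config$seed, zero_prob_default = config$zero_prob_default))

  synth_summary <- .stage("summarize",
                          summarize_concentrations_by_item(synth$samples))
  compliance <- .stage("summarize",
                       compliance_screen(synth$samples, const))

  grid <- .stage("deterministic", scenario_exposure_table(
    summaries, consumption, ages = config$ages))
  hazards <- .stage("deterministic",
                    hazard_table(grid, const$rfd_total_sn))
  contributions <- .stage("deterministic",
                          category_contributions(grid$cells))

  organotin <- .stage("organotin-screen", organotin_scenario_assessment(
    summaries, consumption, ages = config$ages, constants = const,
    reproduce_table4 = config$reproduce_table4))

  aquatic <- synth$samples[synth$samples$category == "fresh_aquatic", ]
  reverse <- .stage("reverse", reverse_assessment(
    synth$samples, synth$records, constants = const, config = config$mc,
    q = config$q))
  tdi_tab <- .stage("montecarlo", tdi_percentile_table(
    aquatic, synth$records, constants = const, config = config$mc,
    fraction = if (config$reproduce_table4) 1 else const$organotin_fraction))

  outs <- list(
    table1 = render_table(synth_summary, "table1"),
    table3 = render_table(list(grid = grid, hazards = hazards,
                               reference = const$rfd_total_sn), "table3"),
    table4 = render_table(organotin, "table4"),
    table5 = render_table(tdi_tab, "table5"),
    fig1_contributions = render_table(contributions, "fig1"),
    fig2_reverse = render_table(reverse, "fig2")
  )
  for (nm in names(outs)) {
    utils::write.csv(outs[[nm]], file.path(config$out_dir,
                                           paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(compliance, file.path(config$out_dir, "compliance.csv"),
                   row.names = FALSE)
  utils::write.csv(synth$samples, file.path(config$out_dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(synth$records, file.path(config$out_dir, "records.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "tindiet",
    version = as.character(utils::packageVersion("tindiet")),
    seed = config$seed,
    mc = unclass(config$mc),
    n_per_age = config$n_per_age,
    zero_prob_default = config$zero_prob_default,
    q = config$q,
    reproduce_table4 = config$reproduce_table4,
    constants = unclass(const),
    inputs = list(concentrations = config$concentrations_path,
                  consumption = config$consumption_path,
                  body_weights = config$body_weights_path)
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(summaries = summaries, consumption = consumption,
                 synthetic = synth, synthetic_summary = synth_summary,
                 compliance = compliance, grid = grid, hazards = hazards,
                 contributions = contributions, organotin = organotin,
                 reverse = reverse, tdi_table = tdi_tab,
                 out_dir = config$out_dir))
}

.round_df <- function(df, digits) {
  for (nm in names(digits)) {
    if (nm %in% names(df)) df[[nm]] <- round(df[[nm]], digits[[nm]])
  }
  df
}

#' Render results in the publication table layouts
#'
#' Formats a stage result the way the corresponding published table prints
#' it (column order, row order, rounding): `"table1"` concentration
#' summaries (2-decimal concentrations, integer detect percent),
#' `"table3"` the deterministic grid (EDI to 2 decimals, THQ to 4),
#' `"table4"` the organotin scenario screen (EDI to 2 decimals, THQ to 1),
#' `"table5"` the percentile-at-TDI table, `"fig1"` category contribution
#' shares and `"fig2"` the reverse assessment. Empty results yield a
#' header-only table.
#'
#' @param results The matching stage result (see Details).
#' @param layout One of `"table1"`, `"table3"`, `"table4"`, `"table5"`,
#'   `"fig1"`, `"fig2"`.
#' @return A data.frame ready for `write.csv()`.
#' @export
render_table <- function(results, layout = c("table1", "table3", "table4",
                                             "table5", "fig1", "fig2")) {
  layout <- match.arg(layout)
  switch(layout,
    table1 = {
      .check_columns(results, c("category", "type_name", "n", "n_detect"),
                     "table1 results")
      df <- as.data.frame(results)
      df$detect_pct <- round(100 * df$n_detect / df$n)
      .round_df(df[, c("category", "type_name", "n", "n_detect",
                       "detect_pct", "mean", "p50", "p95", "iqr", "min",
                       "max")],
                list(mean = 2, p50 = 2, p95 = 2, iqr = 2, min = 2, max = 2))
    },
    table3 = {
      if (!is.list(results) || is.null(results$grid)) {
        .validation_error("table3 layout needs list(grid, hazards)")
      }
      cells <- results$grid$cells
      if (nrow(cells) == 0L) {
        return(data.frame(category = character(), type_name = character(),
                          scenario = character()))
      }
      cells$edi <- round(cells$edi, 2)
      wide <- stats::reshape(
        cells[, c("category", "type_name", "scenario", "age_group", "edi")],
        idvar = c("category", "type_name", "scenario"),
        timevar = "age_group", direction = "wide")
      names(wide) <- sub("^edi\\.", "", names(wide))
      h <- results$hazards
      extra <- do.call(rbind, lapply(split(h, h$scenario), function(g) {
        ages <- g$age_group
        sums <- stats::setNames(as.list(round(g$sum_edi, 2)), ages)
        thqs <- stats::setNames(as.list(round(g$thq, 4)), ages)
        rbind(
          cbind(data.frame(category = "", type_name = "Sum of EDIs",
                           scenario = g$scenario[1]), as.data.frame(sums,
                           check.names = FALSE)),
          cbind(data.frame(category = "", type_name = "THQ",
                           scenario = g$scenario[1]), as.data.frame(thqs,
                           check.names = FALSE))
        )
      }))
      out <- rbind(wide, extra[, names(wide)])
      out <- out[order(out$scenario), ]
      rownames(out) <- NULL
      out
    },
    table4 = {
      .check_columns(results, c("age_group", "scenario", "sum_edi", "thq"),
                     "table4 results")
      if (nrow(results) == 0L) {
        return(data.frame(scenario = character(), quantity = character()))
      }
      df <- as.data.frame(results)
      df$sum_edi <- round(df$sum_edi, 2)
      df$thq <- round(df$thq, 1)
      long <- rbind(
        data.frame(scenario = df$scenario, quantity = "sum_edi",
                   age_group = df$age_group, value = df$sum_edi),
        data.frame(scenario = df$scenario, quantity = "thq",
                   age_group = df$age_group, value = df$thq)
      )
      wide <- stats::reshape(long, idvar = c("scenario", "quantity"),
                             timevar = "age_group", direction = "wide")
      names(wide) <- sub("^value\\.", "", names(wide))
      wide <- wide[order(wide$scenario, wide$quantity), ]
      rownames(wide) <- NULL
      wide
    },
    table5 = {
      .check_columns(results, c("age_group", "percentile", "ci_low",
                                "ci_high"), "table5 results")
      .round_df(as.data.frame(results),
                list(percentile = 1, ci_low = 1, ci_high = 1))
    },
    fig1 = {
      .check_columns(results, c("age_group", "scenario", "category",
                                "share"), "fig1 results")
      .round_df(as.data.frame(results), list(sum_edi = 4, share = 4))
    },
    fig2 = {
      .check_columns(results, c("category", "p_min", "ci_low", "ci_high"),
                     "fig2 results")
      .round_df(as.data.frame(results),
                list(p_min = 2, ci_low = 2, ci_high = 2))
    }
  )
}
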