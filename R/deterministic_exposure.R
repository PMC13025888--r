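# Deterministic exposure: the EDI formula, the four-scenario P50/P95 grid,
# hazard quotients against the reference dose, category contribution shares
# and the conservative organotin scenario screen.

#' Estimated daily intake of tin
#'
#' `EDI = Cv x CR / BW`: concentration (mg/kg, numerically equal to ug/g)
#' times daily consumption (g/day) divided by body weight (kg), giving an
#' intake in ug per kg body weight per day.
#'
#' @param conc Concentration, mg/kg.
#' @param intake Daily consumption, g/day.
#' @param bw Body weight, kg (> 0).
#' @return EDI in ug/kg bw/day (vectorised).
#' @export
#' @examples
#' compute_edi(80.73, 40, 62.1)  # 52.00 for canned fruit, adults, P95 x P95
compute_edi <- function(conc, intake, bw) {
  if (any(!is.finite(bw) | bw <= 0)) stop("bw must be > 0", call. = FALSE)
  if (any(conc < 0) || any(intake < 0)) {
    stop("conc and intake must be >= 0", call. = FALSE)
  }
  conc * intake / bw
}

#' Deterministic scenario exposure grid
#'
#' Crosses every food type with every age group and scenario, pairing the
#' scenario's concentration percentile (from the summary table) with its
#' consumption percentile (from the consumption table) and the age group's
#' body weight, and sums intakes within each age group and scenario.
#'
#' @param summaries Concentration summary table
#'   (default the packaged fixture).
#' @param consumption Consumption quantile table
#'   (default the packaged fixture).
#' @param ages Age groups to include (default all five study groups).
#' @param scenarios Scenario table as from [scenario_grid()].
#' @return An object of class `"sn_exposure_grid"`: a list with `cells`
#'   (one row per type x age x scenario, with `conc`, `intake`,
#'   `body_weight`, `edi`) and `totals` (per age x scenario `sum_edi`).
#' @export
scenario_exposure_table <- function(summaries = zj_concentrations(),
                                    consumption = zj_consumption(),
                                    ages = NULL,
                                    scenarios = scenario_grid()) {
  if (is.null(ages)) ages <- intersect(age_group_levels,
                                       unique(consumption$age_group))
  cons <- consumption[consumption$age_group %in% ages, , drop = FALSE]
  want <- merge(data.frame(type_name = unique(summaries$type_name)),
                data.frame(age_group = ages))
  have <- cons[, c("type_name", "age_group")]
  gaps <- want[!paste(want$type_name, want$age_group) %in%
                 paste(have$type_name, have$age_group), , drop = FALSE]
  if (nrow(gaps)) {
    .validation_error(paste0(
      "missing (type, age) pairings: ",
      paste(paste0(gaps$type_name, "/", gaps$age_group), collapse = "; ")))
  }
  cells <- merge(cons, summaries[, c("category", "type_name", "p50", "p95")],
                 by = "type_name", suffixes = c("_cons", "_conc"))
  cells <- merge(cells, scenarios)
  cells$conc <- ifelse(cells$conc_q == 0.5, cells$p50_conc, cells$p95_conc)
  cells$intake <- ifelse(cells$cons_q == 0.5, cells$p50_cons, cells$p95_cons)
  cells$edi <- compute_edi(cells$conc, cells$intake, cells$body_weight)
  reg <- food_items()
  cells <- cells[order(cells$scenario,
                       match(cells$age_group, age_group_levels),
                       match(cells$type_name, reg$type_name)),
                 c("category", "type_name", "age_group", "scenario",
                   "conc", "intake", "body_weight", "edi")]
  rownames(cells) <- NULL
  totals <- stats::aggregate(edi ~ age_group + scenario, data = cells, sum)
  names(totals)[names(totals) == "edi"] <- "sum_edi"
  totals <- totals[order(totals$scenario,
                         match(totals$age_group, age_group_levels)), ]
  rownames(totals) <- NULL
  structure(list(cells = cells, totals = totals),
            class = "sn_exposure_grid")
}

#' @export
print.sn_exposure_grid <- function(x, ...) {
  cat("Deterministic Sn exposure grid:",
      length(unique(x$cells$type_name)), "food types x",
      length(unique(x$cells$age_group)), "age groups x",
      length(unique(x$cells$scenario)), "scenarios\n")
  cat("Sum of EDIs (ug/kg bw/day) by age group and scenario:\n")
  wide <- stats::reshape(x$totals, idvar = "scenario", timevar = "age_group",
                         direction = "wide")
  names(wide) <- sub("^sum_edi\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Total hazard quotient for one age group and scenario
#'
#' Per-item hazard quotients `HQ_i = EDI_i / reference` and their sum, the
#' total hazard quotient `THQ`. A THQ above 1 flags potential concern.
#'
#' @param cells Exposure cells sharing one age group and scenario (rows of
#'   `scenario_exposure_table()$cells`). An empty set yields zero exposure.
#' @param reference Toxicological reference dose, ug/kg bw/day (> 0); the
#'   chronic oral MRL for total tin is 300 ug/kg bw/day.
#' @return A list of class `"hazard_summary"`: `age_group`, `scenario`,
#'   `sum_edi`, `thq`, `exceeds`, and `per_item_hq`.
#' @export
total_hazard <- function(cells, reference) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0) {
    stop("reference must be a positive scalar", call. = FALSE)
  }
  if (nrow(cells) == 0L) {
    return(structure(list(age_group = NA_character_, scenario = NA_character_,
                          sum_edi = 0, thq = 0, exceeds = FALSE,
                          per_item_hq = stats::setNames(numeric(0),
                                                        character(0)),
                          reference = reference),
                     class = "hazard_summary"))
  }
  if (length(unique(cells$age_group)) != 1L ||
      length(unique(cells$scenario)) != 1L) {
    .validation_error("cells must share one age group and one scenario")
  }
  hq <- stats::setNames(cells$edi / reference, cells$type_name)
  thq <- sum(hq)
  structure(list(age_group = cells$age_group[1], scenario = cells$scenario[1],
                 sum_edi = sum(cells$edi), thq = thq, exceeds = thq > 1,
                 per_item_hq = hq, reference = reference),
            class = "hazard_summary")
}

#' @export
print.hazard_summary <- function(x, ...) {
  cat(sprintf("Scenario %s, age %s: sum(EDI) = %.4g ug/kg bw/day, THQ = %.4g (ref %.4g)%s\n",
              x$scenario, x$age_group, x$sum_edi, x$thq, x$reference,
              if (x$exceeds) " [THQ > 1]" else ""))
  invisible(x)
}

#' @rdname total_hazard
#' @param grid An `"sn_exposure_grid"` object.
#' @details `hazard_table()` applies [total_hazard()] to every age x
#'   scenario combination of a grid and returns one row per combination.
#' @export
hazard_table <- function(grid, reference) {
  cells <- grid$cells
  groups <- unique(cells[, c("age_group", "scenario")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- cells[cells$age_group == groups$age_group[i] &
                 cells$scenario == groups$scenario[i], , drop = FALSE]
    h <- total_hazard(g, reference)
    data.frame(age_group = h$age_group, scenario = h$scenario,
               sum_edi = h$sum_edi, thq = h$thq, exceeds = h$exceeds,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scenario, match(out$age_group, age_group_levels)), ]
  rownames(out) <- NULL
  out
}

#' Food-category contribution shares within each age group and scenario
#'
#' Splits each age x scenario total intake into per-category shares
#' (category sum over overall sum). Shares sum to one wherever the total is
#' positive; a degenerate all-zero combination is reported with `NA` shares
#' and `defined = FALSE` rather than a division error.
#'
#' @param cells Exposure cells (`scenario_exposure_table()$cells`).
#' @return data.frame with columns `age_group`, `scenario`, `category`,
#'   `sum_edi`, `share`, `defined`.
#' @export
category_contributions <- function(cells) {
  if (nrow(cells) == 0L) stop("empty cells", call. = FALSE)
  agg <- stats::aggregate(edi ~ age_group + scenario + category,
                          data = cells, sum)
  tot <- stats::aggregate(edi ~ age_group + scenario, data = agg, sum)
  names(tot)[names(tot) == "edi"] <- "total"
  out <- merge(agg, tot)
  out$defined <- out$total > 0
  out$share <- ifelse(out$defined, out$edi / out$total, NA_real_)
  names(out)[names(out) == "edi"] <- "sum_edi"
  out <- out[order(out$scenario, match(out$age_group, age_group_levels),
                   match(out$category, food_category_levels)),
             c("age_group", "scenario", "category", "sum_edi", "share",
               "defined")]
  rownames(out) <- NULL
  out
}

#' Scenario-based organotin screening for fresh aquatic products
#'
#' Conservative screening of organotin exposure: the total-tin scenario
#' intakes for the aquatic food types are scaled by the assumed organotin
#' fraction of total tin and compared with the organotin tolerable daily
#' intake (as tin). The default fraction is the literature-derived 5.83%;
#' `reproduce_table4 = TRUE` sets the fraction to 1, which treats the whole
#' total-tin intake as potentially organotin — the convention under which
#' the published screening table is reproduced.
#'
#' @param summaries,consumption,ages,scenarios As in
#'   [scenario_exposure_table()].
#' @param constants A [tox_constants()] list (supplies the default fraction
#'   and TDI).
#' @param fraction Organotin fraction of total tin, in `(0, 1]`.
#' @param tdi Organotin TDI expressed as tin, ug-Sn/kg bw/day (> 0).
#' @param categories Food categories screened (default fresh aquatic).
#' @param reproduce_table4 Use fraction 1 (see Details).
#' @return data.frame with one row per scenario x age group: `sum_edi`
#'   (organotin, ug/kg bw/day), `thq`, `exceeds`, plus the `fraction`
#'   applied.
#' @export
organotin_scenario_assessment <- function(summaries = zj_concentrations(),
                                          consumption = zj_consumption(),
                                          ages = NULL,
                                          scenarios = scenario_grid(),
                                          constants = tox_constants(),
                                          fraction = constants$organotin_fraction,
                                          tdi = constants$tdi_organotin_as_sn,
                                          categories = "fresh_aquatic",
                                          reproduce_table4 = FALSE) {
  if (reproduce_table4) fraction <- 1
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (tdi <= 0) stop("tdi must be > 0", call. = FALSE)
  sub <- summaries[summaries$category %in% categories, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no food types in requested categories",
                            call. = FALSE)
  grid <- scenario_exposure_table(sub, consumption, ages, scenarios)
  out <- grid$totals
  out$sum_edi <- out$sum_edi * fraction
  out$thq <- out$sum_edi / tdi
  out$exceeds <- out$thq > 1
  out$fraction <- fraction
  rownames(out) <- NULL
  out
}
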