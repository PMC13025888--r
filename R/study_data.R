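# Domain registry, packaged survey fixtures, CSV IO and validation.

food_category_levels <- c(
  "fresh_vegetables", "tea", "fresh_aquatic", "fresh_fruits", "canned"
)

age_group_levels <- c("le6", "7_12", "13_17", "18_59", "ge60")

.item_registry <- local({
  reg <- rbind(
    data.frame(category = "fresh_vegetables", type_name = c(
      "Solanaceous Vegetables", "Cruciferous Vegetables", "Cucurbit Vegetables",
      "Tuber and Root Vegetables", "Aquatic Vegetables", "Leafy Vegetables")),
    data.frame(category = "tea", type_name = c(
      "Green Tea", "Black Tea", "Oolong Tea", "Dark Tea")),
    data.frame(category = "fresh_aquatic", type_name = c(
      "Fish", "Crustaceans", "Mollusks")),
    data.frame(category = "fresh_fruits", type_name = c(
      "Citrus Fruits", "Melons and Gourd Fruits", "Stone Fruits",
      "Berries and Other Small Fruits", "Tropical and Subtropical Fruits",
      "Pome Fruits")),
    data.frame(category = "canned", type_name = c(
      "Cereal-based Canned Foods", "Canned Vegetables and Vegetable Products",
      "Canned Fruits and Fruit Products", "Canned Meat and Meat Products",
      "Canned Aquatic Products", "Canned Edible Fungi and Fungal Product"))
  )
  # tea is analysed as dried leaves and carries a higher detection limit
  reg$lod <- ifelse(reg$category == "tea", 0.008, 0.004)
  reg
})

#' Registry of the 25 surveyed food types
#'
#' Returns the canonical food-type registry used throughout the package:
#' 25 food types in five categories (6 fresh-vegetable, 4 tea, 3 fresh-aquatic,
#' 6 fresh-fruit and 6 canned types), each with its analytical limit of
#' detection (LOD) for tin in mg/kg dry weight (0.008 mg/kg for tea, 0.004
#' mg/kg otherwise).
#'
#' @return A data.frame with columns `category`, `type_name` and `lod`.
#' @export
#' @examples
#' nrow(food_items())  # 25
food_items <- function() .item_registry

#' Age groups and reference body weights
#'
#' The five study age groups with their survey-average body weights (kg),
#' plus the whole-population row (`total`, 57 kg) used for population-level
#' Monte Carlo runs.
#'
#' @param include_total Keep the `total` row (default `TRUE`).
#' @return A data.frame with columns `age_group` and `body_weight`.
#' @export
age_groups <- function(include_total = TRUE) {
  out <- data.frame(
    age_group = c(age_group_levels, "total"),
    body_weight = c(19.9, 33.7, 52.3, 62.1, 60.4, 57),
    stringsAsFactors = FALSE
  )
  if (!include_total) out <- out[out$age_group != "total", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deterministic exposure scenarios
#'
#' The four screening scenarios combining median/high consumption with
#' median/high contamination: A = P50 consumption x P50 concentration,
#' B = P95 x P50, C = P50 x P95, D = P95 x P95.
#'
#' @return A data.frame with columns `scenario`, `cons_q` and `conc_q`.
#' @export
scenario_grid <- function() {
  data.frame(
    scenario = c("A", "B", "C", "D"),
    cons_q = c(0.50, 0.95, 0.50, 0.95),
    conc_q = c(0.50, 0.50, 0.95, 0.95),
    stringsAsFactors = FALSE
  )
}

#' Toxicological constants and regulatory limits
#'
#' Assembles the constants used by the hazard calculations, all overridable:
#' the chronic oral reference dose for total (inorganic) tin
#' (`rfd_total_sn`, 300 ug/kg bw/day, i.e. the ATSDR MRL of 0.3 mg/kg bw/day),
#' the group tolerable daily intake for organotin compounds
#' (`tdi_organotin_compound`, 0.25 ug/kg bw/day; `tdi_organotin_as_sn`,
#' 0.10 ug-Sn/kg bw/day when expressed as tin), the conservative
#' literature-derived organotin fraction of total tin
#' (`organotin_fraction`, 0.0583), and the regulatory concentration limits
#' (`limit_canned`, default 200 mg/kg with a 100 mg/kg canned-beverage
#' variant; `limit_other`, 200 mg/kg).
#'
#' @param ... Named overrides for any constant.
#' @param config Optional path to a YAML file whose top-level keys override
#'   the defaults (applied before `...`).
#' @return A named list of class `"tox_constants"`.
#' @export
#' @examples
#' tox_constants()$organotin_fraction
#' tox_constants(limit_canned = 100)$limit_canned
tox_constants <- function(..., config = NULL) {
  const <- list(
    rfd_total_sn = 300,
    tdi_organotin_compound = 0.25,
    tdi_organotin_as_sn = 0.10,
    organotin_fraction = 0.0583,
    limit_canned = 200,
    limit_canned_beverage = 100,
    limit_other = 200
  )
  if (!is.null(config)) {
    over <- yaml::read_yaml(config)
    const[names(over)] <- over
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(const))
    if (length(unknown)) {
      stop("unknown tox constant(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    const[names(dots)] <- dots
  }
  bad <- names(const)[!vapply(const, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("tox constants must be positive scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (const$organotin_fraction > 1) {
    stop("organotin_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(const, class = "tox_constants")
}

#' Minimum sample size for a proportion survey
#'
#' Closed-form minimum sample size `z^2 * p * (1 - p) / d^2` for estimating a
#' proportion `p` with allowable error `d` at the confidence level implied by
#' the standard-normal quantile `z`. The value is returned unrounded; at
#' `z = 1.96`, `p = 0.5`, `d = 0.10` it equals 96.04.
#'
#' @param z Standard-normal quantile (e.g. 1.96 for 95% confidence).
#' @param p Anticipated proportion, in `[0, 1]`.
#' @param d Allowable (absolute) error, > 0.
#' @return The required sample size (fractional, not rounded).
#' @export
#' @examples
#' required_sample_size(1.96, 0.5, 0.10)
required_sample_size <- function(z, p, d) {
  stopifnot(is.numeric(z), is.numeric(p), is.numeric(d))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(d <= 0)) stop("d must be > 0", call. = FALSE)
  z^2 * p * (1 - p) / d^2
}

# ---- errors ------------------------------------------------------------

.schema_error <- function(msg) {
  stop(errorCondition(msg, class = c("tindiet_schema_error", "error")))
}

.validation_error <- function(msg, row = NULL, col = NULL) {
  where <- character(0)
  if (!is.null(row)) where <- c(where, paste0("row ", row))
  if (!is.null(col)) where <- c(where, paste0("column '", col, "'"))
  if (length(where)) msg <- paste0(msg, " (", paste(where, collapse = ", "), ")")
  stop(errorCondition(msg, class = c("tindiet_validation_error", "error")))
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    .schema_error(paste0(what, ": missing column(s) ",
                         paste0("'", missing, "'", collapse = ", ")))
  }
}

# ---- fixture paths and accessors ---------------------------------------

#' Path to a packaged fixture file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path to the file.
#' @export
fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "tindiet", mustWork = FALSE)
  if (!nzchar(p)) stop("no packaged fixture '", file, "'", call. = FALSE)
  p
}

#' @rdname load_concentration_summaries
#' @export
zj_concentrations <- function() {
  load_concentration_summaries(fixture_path("concentrations.csv"))
}

#' @rdname load_consumption_quantiles
#' @export
zj_consumption <- function() {
  # the published dark-tea row is quantile-inverted (P50 > P95) and the
  # published exposure grid uses it verbatim; keep it as printed here
  load_consumption_quantiles(fixture_path("consumption.csv"),
                             on_inverted = "keep")
}

#' Load per-age-group body weights
#'
#' @param path CSV with columns `age_group`, `kg`.
#' @return data.frame with columns `age_group`, `body_weight`.
#' @export
load_body_weights <- function(path = fixture_path("body_weights.csv")) {
  bw <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(bw, c("age_group", "kg"), "body_weights")
  bad <- which(!is.finite(bw$kg) | bw$kg <= 0)
  if (length(bad)) .validation_error("body weight must be > 0", bad[1], "kg")
  data.frame(age_group = bw$age_group, body_weight = bw$kg,
             stringsAsFactors = FALSE)
}

#' Load per-food-type concentration summaries
#'
#' Reads a Table-1-style summary table of tin concentrations (mg/kg dry
#' weight): one row per food type with the sample size, number of detects and
#' descriptive statistics of the half-LOD-substituted measurements.
#' `zj_concentrations()` loads the packaged Zhejiang surveillance fixture
#' (25 food types, 2014 samples).
#'
#' @param path CSV with columns `category`, `type_name`, `n`, `n_detect`,
#'   `mean`, `p50`, `p95`, `iqr`, `min`, `max`, `lod`.
#' @return A data.frame of class `"sn_summary"`, one row per food type.
#' @export
load_concentration_summaries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("category", "type_name", "n", "n_detect", "mean", "p50", "p95",
            "iqr", "min", "max", "lod")
  .check_columns(df, cols, "concentrations")
  df <- df[, cols]
  validate_concentration_summaries(df)
  class(df) <- c("sn_summary", "data.frame")
  df
}

#' @rdname load_concentration_summaries
#' @param x Summary data.frame to validate.
#' @export
validate_concentration_summaries <- function(x) {
  reg <- food_items()
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    j <- which(reg$type_name == r$type_name)
    if (!length(j)) .validation_error("unknown food type", i, "type_name")
    if (reg$category[j] != r$category) {
      .validation_error("category does not match registry", i, "category")
    }
    if (!isTRUE(all.equal(reg$lod[j], r$lod))) {
      .validation_error("LOD does not match registry", i, "lod")
    }
    if (r$n < 1) .validation_error("n must be >= 1", i, "n")
    if (r$n_detect < 0 || r$n_detect > r$n) {
      .validation_error("n_detect must lie in [0, n]", i, "n_detect")
    }
    if (r$iqr < 0) .validation_error("iqr must be >= 0", i, "iqr")
    if (!(r$min <= r$p50)) .validation_error("min must be <= p50", i, "p50")
    if (!(r$p50 <= r$p95)) .validation_error("p50 must be <= p95", i, "p95")
    if (!(r$p95 <= r$max)) .validation_error("p95 must be <= max", i, "max")
    if (r$mean < r$min || r$mean > r$max) {
      .validation_error("mean must lie within [min, max]", i, "mean")
    }
  }
  invisible(x)
}

#' Load per-age-group consumption quantiles
#'
#' Reads a Table-2-style long-format table of daily food consumption
#' (g/day): one row per (food type, age group) with the median (`p50`) and
#' 95th-percentile (`p95`) intake, with the age group's body weight attached.
#' `zj_consumption()` loads the packaged Zhejiang survey fixture
#' (25 food types x 5 age groups).
#'
#' @param path CSV with columns `type_name`, `age_group`, `p50_g_day`,
#'   `p95_g_day`.
#' @param body_weights Optional body-weight table as from
#'   [load_body_weights()]; defaults to the packaged weights.
#' @param on_inverted What to do with a row whose `p50 > p95`: `"error"`
#'   (default, a validation error naming the row), `"keep"` (use the printed
#'   values verbatim) or `"swap"`.
#' @return A data.frame of class `"sn_consumption"` with columns `type_name`,
#'   `age_group`, `p50`, `p95`, `body_weight`.
#' @export
load_consumption_quantiles <- function(path,
                                       body_weights = load_body_weights(),
                                       on_inverted = c("error", "keep", "swap")) {
  on_inverted <- match.arg(on_inverted)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("type_name", "age_group", "p50_g_day", "p95_g_day"),
                 "consumption")
  reg <- food_items()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$type_name %in% reg$type_name) {
      .validation_error("unknown food type", i, "type_name")
    }
    if (!r$age_group %in% age_group_levels) {
      .validation_error("unknown age group", i, "age_group")
    }
    if (r$p50_g_day < 0 || r$p95_g_day < 0) {
      .validation_error("consumption must be >= 0", i, "p50_g_day")
    }
    if (r$p50_g_day > r$p95_g_day) {
      if (on_inverted == "error") {
        .validation_error("p50 exceeds p95", i, "p95_g_day")
      } else if (on_inverted == "swap") {
        df[i, c("p50_g_day", "p95_g_day")] <- r[c("p95_g_day", "p50_g_day")]
      }
    }
  }
  out <- data.frame(
    type_name = df$type_name, age_group = df$age_group,
    p50 = df$p50_g_day, p95 = df$p95_g_day, stringsAsFactors = FALSE
  )
  out <- merge(out, body_weights, by = "age_group", sort = FALSE)
  out <- out[order(match(out$type_name, reg$type_name),
                   match(out$age_group, age_group_levels)),
             c("type_name", "age_group", "p50", "p95", "body_weight")]
  rownames(out) <- NULL
  class(out) <- c("sn_consumption", "data.frame")
  out
}

#' Write summary tables back to their CSV layouts
#'
#' Inverse of the loaders: round-trips a loaded table to the documented CSV
#' layout so that re-loading yields identical values.
#'
#' @param x Table as returned by the corresponding loader.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_summaries <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_concentration_summaries
#' @export
write_consumption_quantiles <- function(x, path) {
  out <- data.frame(type_name = x$type_name, age_group = x$age_group,
                    p50_g_day = x$p50, p95_g_day = x$p95)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
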