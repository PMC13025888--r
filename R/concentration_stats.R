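# Non-detect substitution, descriptive summaries and compliance screening
# for sample-level concentration data.

#' Substitute non-detects at half the detection limit
#'
#' Applies the standard treatment for left-censored trace-contaminant data:
#' every measurement below its limit of detection is replaced by `lod / 2`
#' and flagged as substituted. Detected values are returned unchanged, and
#' the operation is idempotent.
#'
#' @param samples Sample-level data.frame with columns `type_name`,
#'   `category`, `lod`, `value`, `detected` and (optionally) `substituted`.
#' @return The same data.frame with all non-detects at `lod / 2` and
#'   `substituted = TRUE`.
#' @export
#' @examples
#' s <- data.frame(category = "fresh_aquatic", type_name = "Fish",
#'                 lod = 0.004, value = c(NA, 0.15), detected = c(FALSE, TRUE))
#' substitute_nondetects(s)$value  # 0.002, 0.15
substitute_nondetects <- function(samples) {
  .check_columns(samples, c("lod", "value", "detected"), "samples")
  if (is.null(samples$substituted)) samples$substituted <- FALSE
  nd <- !samples$detected
  bad <- which(nd & !is.na(samples$value) & samples$value > samples$lod)
  if (length(bad)) {
    .validation_error("non-detect sample has value above its LOD",
                      bad[1], "value")
  }
  samples$value[nd] <- samples$lod[nd] / 2
  samples$substituted[nd] <- TRUE
  if (any(samples$value < 0, na.rm = TRUE)) {
    .validation_error("negative concentration",
                      which(samples$value < 0)[1], "value")
  }
  samples
}

#' Empirical quantile of concentrations or exposures
#'
#' The package-wide quantile convention: linear interpolation between order
#' statistics at position `(n - 1) * q` (type 7), with a nearest-rank
#' (type 1) alternative for sensitivity checks. `q = 0` returns the minimum
#' and `q = 1` the maximum under both conventions.
#'
#' @param values Non-empty numeric vector.
#' @param q Probability (vectorised), in `[0, 1]`.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return Quantile value(s).
#' @export
empirical_quantile <- function(values, q, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  unname(stats::quantile(values, probs = q,
                         type = if (method == "linear") 7L else 1L))
}

#' Summarise substituted concentration samples for one food type
#'
#' Reproduces the descriptive record of the surveillance table from
#' sample-level data: sample size, detect count, and mean / P50 / P95 /
#' IQR / min / max of the half-LOD-substituted values.
#'
#' @param samples Substituted samples for a single food type (see
#'   [substitute_nondetects()]).
#' @param method Quantile convention, as in [empirical_quantile()].
#' @return One-row data.frame of class `"sn_summary"` in the layout of
#'   [load_concentration_summaries()].
#' @export
summarize_concentrations <- function(samples, method = "linear") {
  if (nrow(samples) == 0L) stop("empty input", call. = FALSE)
  .check_columns(samples, c("category", "type_name", "lod", "value",
                            "detected"), "samples")
  if (length(unique(samples$type_name)) != 1L) {
    .validation_error("samples mix food types; summarise one type at a time",
                      col = "type_name")
  }
  v <- samples$value
  qs <- empirical_quantile(v, c(0.25, 0.5, 0.75, 0.95), method = method)
  out <- data.frame(
    category = samples$category[1], type_name = samples$type_name[1],
    n = nrow(samples), n_detect = sum(samples$detected),
    mean = mean(v), p50 = qs[2], p95 = qs[4], iqr = qs[3] - qs[1],
    min = min(v), max = max(v), lod = samples$lod[1],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("sn_summary", "data.frame")
  out
}

#' @rdname summarize_concentrations
#' @details `summarize_concentrations_by_item()` applies the summary to every
#'   food type present in `samples` and returns one row per type.
#' @export
summarize_concentrations_by_item <- function(samples, method = "linear") {
  parts <- lapply(split(samples, samples$type_name),
                  summarize_concentrations, method = method)
  out <- do.call(rbind, parts)
  reg <- food_items()
  out <- out[order(match(out$type_name, reg$type_name)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sn_summary", "data.frame")
  out
}

#' Screen concentrations against regulatory limits
#'
#' Counts, per food type, the samples whose tin concentration exceeds the
#' applicable national maximum level: `limit_canned` for canned foods
#' (user-selectable between the 200 mg/kg general and 100 mg/kg beverage
#' limits) and `limit_other` for everything else. Zero counts are reported
#' explicitly.
#'
#' @param samples Substituted sample-level data.frame (possibly many types).
#' @param constants A [tox_constants()] list.
#' @return data.frame with columns `type_name`, `category`, `n`, `limit`,
#'   `n_exceed`.
#' @export
compliance_screen <- function(samples, constants = tox_constants()) {
  reg <- food_items()
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    lim <- if (reg$category[i] == "canned") constants$limit_canned
           else constants$limit_other
    s <- samples[samples$type_name == reg$type_name[i], , drop = FALSE]
    data.frame(type_name = reg$type_name[i], category = reg$category[i],
               n = nrow(s), limit = lim,
               n_exceed = sum(s$value > lim), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
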