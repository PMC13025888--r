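# Calibrated synthetic-data generator: censored lognormal mixtures for
# concentrations, zero-inflated lognormals for consumption. The generator
# reproduces the printed summary structure (detection counts exactly,
# P50/P95 to tolerance) so the downstream pipeline runs without the
# unpublished sample-level study data.

.z95 <- stats::qnorm(0.95)  # 1.6449, the standard-normal 0.95 quantile

.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

#' Calibrate a censored concentration spec to a printed summary
#'
#' Fits the generator's mixture model to one food type's summary record.
#' The mixture has three parts: a point mass of non-detects at `lod / 2`
#' (mass `1 - detect_prob`), a lognormal body for detected values, and an
#' optional single upper spike at the printed maximum (mass `tail_prob`,
#' capped at 2% so the spike stays above the matched 95th percentile).
#' `detect_prob` is taken as `n_detect / n`. The lognormal parameters are
#' solved so the mixture's P50 and P95 match the printed targets; when the
#' median is covered by the non-detect mass (detect rate at most 50%) or the
#' printed P50 does not exceed `lod / 2`, only P95 is matched and
#' `log_sigma` falls back to `log_sigma_default`. Printed quantiles below
#' `lod / 2` are treated as display-censored and clamped up to `lod / 2`.
#'
#' @param summary One summary row (as from [load_concentration_summaries()]).
#' @param log_sigma_default Lognormal log-sd used when only one quantile is
#'   matched (default 1, a typical spread for trace contaminants).
#' @param tail_prob_cap Upper bound for the spike mass (default 0.02).
#' @return A one-row data.frame of class `"conc_spec"` with the mixture
#'   parameters and the targets actually matched.
#' @export
calibrate_concentration_spec <- function(summary, log_sigma_default = 1,
                                         tail_prob_cap = 0.02) {
  s <- as.data.frame(summary)
  if (nrow(s) != 1L) stop("calibrate one summary row at a time", call. = FALSE)
  if (!is.finite(s$n) || s$n < 1) stop("summary has n < 1", call. = FALSE)
  if (any(!is.finite(c(s$p50, s$p95))) || s$p50 < 0 || s$p95 < 0) {
    .validation_error("quantile targets must be finite and >= 0", col = "p50")
  }
  if (s$p95 < s$p50) .validation_error("p95 below p50", col = "p95")
  d <- s$n_detect / s$n
  lod2 <- s$lod / 2
  p50t <- max(s$p50, lod2)
  p95t <- max(s$p95, lod2)
  tail_value <- NA_real_
  tp <- 0
  if (is.finite(s$max) && s$max > p95t && d > 0) {
    tail_value <- s$max
    tp <- min(1 / s$n, tail_prob_cap, d)
  }
  match_p50 <- d > 0.5
  if (d == 0) {
    log_mu <- NA_real_; log_sigma <- NA_real_
    match_p50 <- FALSE; match_p95 <- FALSE
  } else if (1 - d >= 0.95) {
    # detected mass too small to pin the 95th percentile
    log_mu <- log(p95t); log_sigma <- log_sigma_default
    match_p50 <- FALSE; match_p95 <- FALSE
  } else {
    u95 <- (0.95 - (1 - d)) / (d - tp)
    z95 <- stats::qnorm(u95)
    match_p95 <- TRUE
    if (match_p50) {
      u50 <- (0.5 - (1 - d)) / (d - tp)
      z50 <- stats::qnorm(u50)
      if (p95t <= p50t * (1 + 1e-12)) {
        log_sigma <- 0; log_mu <- log(p50t)
      } else {
        log_sigma <- (log(p95t) - log(p50t)) / (z95 - z50)
        log_mu <- log(p50t) - z50 * log_sigma
      }
    } else {
      log_sigma <- log_sigma_default
      log_mu <- log(p95t) - z95 * log_sigma
    }
  }
  if (!is.na(tail_value) && is.finite(log_mu) && tail_value < exp(log_mu)) {
    tail_value <- NA_real_; tp <- 0
  }
  out <- data.frame(
    category = s$category, type_name = s$type_name, lod = s$lod,
    n = s$n, detect_prob = d, log_mu = log_mu, log_sigma = log_sigma,
    tail_value = tail_value, tail_prob = tp,
    cap_value = max(s$max, p95t, s$lod, na.rm = TRUE),
    matched_p50 = match_p50, matched_p95 = match_p95,
    target_p50 = if (match_p50) p50t else lod2, target_p95 = p95t,
    stringsAsFactors = FALSE
  )
  class(out) <- c("conc_spec", "data.frame")
  out
}

#' @rdname calibrate_concentration_spec
#' @param summaries Multi-row summary table; calibrates every row.
#' @export
calibrate_concentration_specs <- function(summaries, log_sigma_default = 1,
                                          tail_prob_cap = 0.02) {
  out <- do.call(rbind, lapply(seq_len(nrow(summaries)), function(i) {
    calibrate_concentration_spec(summaries[i, ], log_sigma_default,
                                 tail_prob_cap)
  }))
  rownames(out) <- NULL
  class(out) <- c("conc_spec", "data.frame")
  out
}

# Adjust the order statistic(s) flanking the type-7 position of q so the
# sample's empirical quantile equals `target` exactly, preserving sort
# order. Coarse detected grids (small study n) otherwise overshoot convex
# upper quantiles under linear interpolation.
.pin_quantile <- function(v, q, target) {
  n <- length(v)
  if (n < 2L || target <= 0) return(v)
  h <- (n - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h); frac <- h - lo
  if (lo == hi) {
    cand <- target
    if ((lo > 1 && cand < v[lo - 1]) || (lo < n && cand > v[lo + 1])) return(v)
    v[lo] <- cand
    return(v)
  }
  cand_hi <- (target - (1 - frac) * v[lo]) / frac
  if (cand_hi < v[lo]) {
    # would invert; move both endpoints onto the target
    cand_lo <- cand_hi <- target
    if (lo > 1 && cand_lo < v[lo - 1]) return(v)
    v[lo] <- cand_lo
  }
  if (hi < n && cand_hi > v[hi + 1]) return(v)
  v[hi] <- cand_hi
  v
}

# Quantile function of the calibrated mixture (vectorised over q).
mixture_quantile <- function(spec, q) {
  s <- as.data.frame(spec)
  d <- s$detect_prob; tp <- s$tail_prob; lod2 <- s$lod / 2
  out <- rep(lod2, length(q))
  if (d > 0) {
    det <- q > (1 - d)
    u <- pmin(pmax((q - (1 - d)) / (d - tp), 1e-9), 1 - 1e-9)
    v <- stats::qlnorm(u, s$log_mu, s$log_sigma)
    v <- pmax(v, s$lod)  # a detected value cannot sit below the LOD
    v <- pmin(v, s$cap_value)  # ... nor above the observed maximum
    if (!is.na(s$tail_value)) {
      v[q > 1 - tp] <- s$tail_value
    }
    out[det] <- v[det]
  }
  out
}

#' Generate sample-level concentration data from a calibrated spec
#'
#' Draws `n` samples from the calibrated mixture. The number of detected
#' samples is fixed at `round(n * detect_prob)` (not binomially drawn), so
#' the study's detection counts are reproduced exactly at the study sample
#' size. Non-detects carry `lod / 2` with `substituted = TRUE`. Detected
#' values are placed by stratified inversion of the mixture quantile
#' function at plotting positions `(k - 1) / (n - 1)` and then shuffled
#' under `seed`, so empirical quantiles of the generated sample track the
#' calibration targets by construction and the output is bit-identical for
#' a given seed.
#'
#' @param spec A `"conc_spec"` row from [calibrate_concentration_spec()].
#' @param n Number of samples (> 0); defaults to the study `n` in the spec.
#' @param seed Integer seed.
#' @return Sample-level data.frame with columns `category`, `type_name`,
#'   `lod`, `value`, `detected`, `substituted`.
#' @export
generate_concentration_samples <- function(spec, n = spec$n, seed = 1L) {
  s <- as.data.frame(spec)
  stopifnot(nrow(s) == 1L)
  if (!is.finite(n) || n < 1) stop("n must be > 0", call. = FALSE)
  n <- as.integer(n)
  m_det <- as.integer(round(n * s$detect_prob))
  m_nd <- n - m_det
  values <- rep(s$lod / 2, n)
  if (m_det > 0) {
    k <- (m_nd + 1L):n
    p <- if (n == 1L) 0.5 else (k - 1) / (n - 1)
    values[k] <- mixture_quantile(s, p)
    values <- sort(values)
    if (isTRUE(s$matched_p95)) {
      values <- .pin_quantile(values, 0.95, s$target_p95)
    }
    if (isTRUE(s$matched_p50)) {
      values <- .pin_quantile(values, 0.50, s$target_p50)
    }
  }
  ord <- .with_seed(seed, sample.int(n))
  detected <- c(rep(FALSE, m_nd), rep(TRUE, m_det))[ord]
  out <- data.frame(
    category = s$category, type_name = s$type_name, lod = s$lod,
    value = values[ord], detected = detected, substituted = !detected,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Calibrate a zero-inflated consumption spec to printed quantiles
#'
#' Fits the generator's intake model for one (food type, age group) cell.
#' With a positive median the intake is lognormal with `log_mu = log(p50)`
#' and `log_sigma = log(p95 / p50) / 1.6449` (1.6449 being the
#' standard-normal 0.95 quantile). With a zero median but positive P95 the
#' intake is zero with probability `zero_prob_default` and otherwise
#' lognormal, solved so the mixture P95 matches. A fully zero cell yields a
#' degenerate all-zero spec. A quantile-inverted cell (P50 > P95, which the
#' published dark-tea row contains) keeps the median and uses the absolute
#' log-ratio for the spread.
#'
#' @param q One consumption row (as from [load_consumption_quantiles()]).
#' @param zero_prob_default Non-consumer probability for zero-median cells
#'   (default 0.6; any value above 0.5 keeps the mixture median at zero).
#' @param log_sigma_default Log-sd for zero-median cells (default 0.5).
#' @return One-row data.frame of class `"cons_spec"`.
#' @export
calibrate_consumption_spec <- function(q, zero_prob_default = 0.6,
                                       log_sigma_default = 0.5) {
  s <- as.data.frame(q)
  if (nrow(s) != 1L) stop("calibrate one consumption row at a time",
                          call. = FALSE)
  if (s$p50 < 0 || s$p95 < 0 || !all(is.finite(c(s$p50, s$p95)))) {
    .validation_error("consumption quantiles must be finite and >= 0",
                      col = "p50")
  }
  if (zero_prob_default < 0 || zero_prob_default >= 0.95) {
    stop("zero_prob_default must lie in [0, 0.95)", call. = FALSE)
  }
  if (s$p50 > 0) {
    zero_prob <- 0
    log_mu <- log(s$p50)
    log_sigma <- abs(log(s$p95 / s$p50)) / .z95
  } else if (s$p95 > 0) {
    zero_prob <- zero_prob_default
    log_sigma <- log_sigma_default
    u95 <- (0.95 - zero_prob) / (1 - zero_prob)
    log_mu <- log(s$p95) - stats::qnorm(u95) * log_sigma
  } else {
    zero_prob <- 1; log_mu <- NA_real_; log_sigma <- NA_real_
  }
  out <- data.frame(
    type_name = s$type_name, age_group = s$age_group,
    body_weight = s$body_weight, zero_prob = zero_prob,
    log_mu = log_mu, log_sigma = log_sigma, stringsAsFactors = FALSE
  )
  class(out) <- c("cons_spec", "data.frame")
  out
}

#' @rdname calibrate_consumption_spec
#' @param quantiles Multi-row consumption table; calibrates every row.
#' @export
calibrate_consumption_specs <- function(quantiles, zero_prob_default = 0.6,
                                        log_sigma_default = 0.5) {
  out <- do.call(rbind, lapply(seq_len(nrow(quantiles)), function(i) {
    calibrate_consumption_spec(quantiles[i, ], zero_prob_default,
                               log_sigma_default)
  }))
  rownames(out) <- NULL
  class(out) <- c("cons_spec", "data.frame")
  out
}

# Sorted intake vector for one spec: zeros then stratified lognormal body.
.cons_values <- function(s, n) {
  m_zero <- as.integer(round(n * s$zero_prob))
  values <- numeric(n)
  m_pos <- n - m_zero
  if (m_pos > 0L) {
    u <- (seq_len(m_pos) - 0.5) / m_pos
    values[(m_zero + 1L):n] <- stats::qlnorm(u, s$log_mu, s$log_sigma)
  }
  values
}

#' Generate respondent-level consumption records
#'
#' Draws `n_per_age` intake records per calibrated (food type, age group)
#' spec: `round(n_per_age * zero_prob)` exact zeros, the rest placed by
#' stratified inversion of the lognormal body and shuffled. Respondent
#' `i` of an age group shares one id across food types, and the age group's
#' body weight is attached. Output is bit-identical for a given seed.
#'
#' @param specs A `"cons_spec"` table from [calibrate_consumption_specs()].
#' @param n_per_age Records per (type, age) cell (> 0).
#' @param seed Integer seed.
#' @return data.frame with columns `respondent_id`, `age_group`,
#'   `type_name`, `intake`, `body_weight`.
#' @export
generate_consumption_records <- function(specs, n_per_age, seed = 1L) {
  if (!is.finite(n_per_age) || n_per_age < 1) {
    stop("n_per_age must be > 0", call. = FALSE)
  }
  n <- as.integer(n_per_age)
  specs <- as.data.frame(specs)
  reg <- food_items()
  specs <- specs[order(match(specs$type_name, reg$type_name),
                       match(specs$age_group, c(age_group_levels, "total"))), ]
  .with_seed(seed, {
    parts <- lapply(seq_len(nrow(specs)), function(i) {
      s <- specs[i, ]
      values <- .cons_values(s, n)[sample.int(n)]
      data.frame(
        respondent_id = sprintf("%s_%04d", s$age_group, seq_len(n)),
        age_group = s$age_group, type_name = s$type_name,
        intake = values, body_weight = s$body_weight,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full synthetic study data set
#'
#' Convenience wrapper over the calibrate/generate pair: calibrates every
#' food type's concentration spec and every (type, age) consumption spec,
#' generates sample-level concentrations at each type's study sample size
#' (seeded per type as `seed + row index`) and respondent-level consumption
#' records, and returns both with the calibration tables.
#'
#' @param summaries Concentration summary table (default packaged fixture).
#' @param consumption Consumption quantile table (default packaged fixture).
#' @param n_per_age Consumption records per (type, age) cell.
#' @param seed Integer seed.
#' @param zero_prob_default,log_sigma_default Passed to the calibrators.
#' @return A list with elements `samples`, `records`, `conc_specs`,
#'   `cons_specs`.
#' @export
simulate_study_data <- function(summaries = zj_concentrations(),
                                consumption = zj_consumption(),
                                n_per_age = 500L, seed = 1L,
                                zero_prob_default = 0.6,
                                log_sigma_default = 0.5) {
  conc_specs <- calibrate_concentration_specs(summaries)
  cons_specs <- calibrate_consumption_specs(consumption, zero_prob_default,
                                            log_sigma_default)
  samples <- do.call(rbind, lapply(seq_len(nrow(conc_specs)), function(i) {
    generate_concentration_samples(conc_specs[i, ], n = conc_specs$n[i],
                                   seed = seed + i)
  }))
  rownames(samples) <- NULL
  records <- generate_consumption_records(cons_specs, n_per_age, seed = seed)
  list(samples = samples, records = records,
       conc_specs = conc_specs, cons_specs = cons_specs)
}
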