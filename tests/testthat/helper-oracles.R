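# Independent oracles and small fixture builders used across the suite.

# Brute-force linear-interpolation quantile: sort, place the target at
# position (n - 1) * q + 1 and interpolate by hand. Written independently
# of empirical_quantile().
brute_quantile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Exposure = (conc / bw) * intake with conc ~ LN(mu1, s1), intake ~
# LN(mu2, s2): a lognormal with summed log-parameters.
prodln_cdf_at <- function(x, mu1, s1, mu2, s2, bw) {
  plnorm(x, mu1 + mu2 - log(bw), sqrt(s1^2 + s2^2))
}
prodln_quantile <- function(p, mu1, s1, mu2, s2, bw) {
  qlnorm(p, mu1 + mu2 - log(bw), sqrt(s1^2 + s2^2))
}
prodln_density <- function(x, mu1, s1, mu2, s2, bw) {
  dlnorm(x, mu1 + mu2 - log(bw), sqrt(s1^2 + s2^2))
}

# Sample-level fixtures whose empirical quantiles sit on a lognormal grid,
# so closed-form lognormal results apply to the resampling simulation.
make_lognormal_samples <- function(n, meanlog, sdlog, type_name = "Fish",
                                   category = "fresh_aquatic", lod = 0.004) {
  data.frame(
    category = category, type_name = type_name, lod = lod,
    value = qlnorm((seq_len(n) - 0.5) / n, meanlog, sdlog),
    detected = TRUE, substituted = FALSE, stringsAsFactors = FALSE
  )
}

make_lognormal_records <- function(n, meanlog, sdlog, type_name = "Fish",
                                   age_group = "18_59", body_weight = 62.1) {
  data.frame(
    respondent_id = sprintf("%s_%04d", age_group, seq_len(n)),
    age_group = age_group, type_name = type_name,
    intake = qlnorm((seq_len(n) - 0.5) / n, meanlog, sdlog),
    body_weight = body_weight, stringsAsFactors = FALSE
  )
}

make_constant_samples <- function(n, value, type_name = "Fish",
                                  category = "fresh_aquatic") {
  data.frame(category = category, type_name = type_name, lod = 0.004,
             value = value, detected = TRUE, substituted = FALSE,
             stringsAsFactors = FALSE)
}

make_constant_records <- function(n, intake, type_name = "Fish",
                                  age_group = "18_59", body_weight = 62.1) {
  data.frame(respondent_id = as.character(seq_len(n)), age_group = age_group,
             type_name = type_name, intake = intake,
             body_weight = body_weight, stringsAsFactors = FALSE)
}

# Printed deterministic exposure grid (items x ages x scenarios) in long
# format, for full-grid comparisons.
load_printed_grid <- function() {
  pr <- utils::read.csv(test_path("table3-printed.csv"), check.names = FALSE)
  long <- stats::reshape(
    pr, direction = "long",
    varying = c("le6", "a7_12", "a13_17", "a18_59", "ge60"),
    v.names = "printed", timevar = "age_group",
    times = c("le6", "7_12", "13_17", "18_59", "ge60"),
    idvar = c("type_name", "scenario"))
  rownames(long) <- NULL
  long
}
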