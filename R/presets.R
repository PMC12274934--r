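# Preset configurations for the synthetic-data generators.
#
# `japan_core` encodes the national anchors the pipeline must recover
# end-to-end: 2001/2019 risk-factor means and smoking prevalences, population
# totals, crude CHD/stroke incidence and mortality, and the health-economic
# anchors including the JPY->USD conversion. `flat_null` is a global null:
# every trend is time-constant and every relative risk is 1, so all
# counterfactual scenarios coincide with the base-case in distribution.

#' Build a synthetic-input preset
#'
#' @param name One of `"japan_core"`, `"flat_null"`, or `"custom:<path>"`
#'   where `<path>` is an R file whose last expression evaluates to a preset
#'   list (it is validated like the built-ins).
#' @return A `cvd_preset` object: a nested list with survey/population/epi/
#'   relative-risk/econ specifications and a seed.
#' @examples
#' cfg <- make_preset("japan_core")
#' cfg$factors$sbp$mean$male[["y0"]]  # 140.1 mmHg in 2001
#' @export
make_preset <- function(name) {
  if (startsWith(name, "custom:")) {
    path <- sub("^custom:", "", name)
    if (!file.exists(path)) stop("custom preset file not found: ", path)
    cfg <- source(path, local = TRUE)$value
    return(validate_preset(cfg))
  }
  cfg <- switch(name,
    japan_core = .preset_japan_core(),
    flat_null  = .preset_flat_null(),
    stop("unknown preset '", name, "'; available presets: japan_core, flat_null, custom:<path>")
  )
  validate_preset(cfg)
}

.anchor <- function(y0, y1) c(y0 = y0, y1 = y1)

.preset_japan_core <- function() {
  factors <- list(
    sbp = list(family = "lognormal3", shift = 60, sigma_log = 0.20, age_gradient = 0.08,
               mean = list(male = .anchor(140.1, 133.4), female = .anchor(135.3, 128.1))),
    ldl = list(family = "lognormal3", shift = 30, sigma_log = 0.28, age_gradient = 0.05,
               mean = list(male = .anchor(123, 118), female = .anchor(125, 121))),
    bmi = list(family = "lognormal3", shift = 10, sigma_log = 0.15, age_gradient = 0.01,
               mean = list(male = .anchor(23.5, 24.2), female = .anchor(22.6, 22.9))),
    hba1c = list(family = "gamma", shape = 120, age_gradient = 0.004,
                 mean = list(male = .anchor(5.48, 5.44), female = .anchor(5.42, 5.38))),
    pa = list(family = "gamma", shape = 1.6, age_gradient = 0,
              mean = list(male = .anchor(0.60, 0.53), female = .anchor(0.58, 0.52))),
    fv = list(family = "gamma", shape = 4, age_gradient = 0.8,
              mean = list(male = .anchor(300, 280), female = .anchor(305, 285))),
    smoking = list(
      family = "multinomial_count",
      # current prevalence declines by 18.4 (men) / 6.8 (women) percentage points
      p_current = list(male = .anchor(0.493, 0.309), female = .anchor(0.141, 0.073)),
      p_past = list(male = .anchor(0.20, 0.30), female = .anchor(0.040, 0.070)),
      logit_age_gradient = -0.020, past_logit_age_gradient = 0.015,
      cig_mean = list(male = .anchor(19, 16), female = .anchor(14, 12)),
      cig_size = 5
    )
  )

  rd <- diag(1, length(RANK_DIMS))
  dimnames(rd) <- list(RANK_DIMS, RANK_DIMS)
  set_r <- function(i, j, v) { rd[i, j] <<- v; rd[j, i] <<- v }
  set_r("sbp", "ldl", 0.10); set_r("sbp", "bmi", 0.25); set_r("sbp", "hba1c", 0.15)
  set_r("ldl", "bmi", 0.20); set_r("ldl", "hba1c", 0.15); set_r("bmi", "hba1c", 0.30)
  set_r("pa", "bmi", -0.15); set_r("pa", "fv", 0.15)
  set_r("smoking", "fv", -0.10); set_r("smoking", "bmi", -0.10); set_r("smoking", "cig", 0.30)

  crude <- data.table::rbindlist(list(
    list("incidence",  "chd",    "male",   340, 420, 200, 660),
    list("incidence",  "chd",    "female", 190, 300, 110, 370),
    list("incidence",  "stroke", "male",   390, 330, 240, 630),
    list("incidence",  "stroke", "female", 280, 250, 200, 420),
    list("prevalence", "chd",    "male",   3100, 4800, 2600, 3700),
    list("prevalence", "chd",    "female", 1300, 2700, 1100, 1700),
    list("prevalence", "stroke", "male",   4100, 5200, 3600, 4500),
    list("prevalence", "stroke", "female", 2700, 3600, 2500, 3000),
    list("mortality",  "chd",    "male",   90,  83, 55, 140),
    list("mortality",  "chd",    "female", 65,  45, 41, 100),
    list("mortality",  "stroke", "male",   150, 100, 110, 220),
    list("mortality",  "stroke", "female", 140, 85, 110, 210)
  ))
  data.table::setnames(crude, c("measure", "disease", "sex", "y0", "y1", "lo0", "hi0"))
  # 95% interval half-width on the log scale, from the printed 2001 intervals
  crude[, log_sd := log(hi0 / lo0) / (2 * 1.96)]

  rr <- data.table::rbindlist(list(
    list("sbp",     "chd",    1.50, NA_real_, 115, 20,   0.04, 5L,  FALSE),
    list("sbp",     "stroke", 1.80, NA_real_, 115, 20,   0.04, 5L,  FALSE),
    list("ldl",     "chd",    1.30, NA_real_, 100, 38.7, 0.05, 5L,  FALSE),
    list("ldl",     "stroke", 1.05, NA_real_, 100, 38.7, 0.05, 5L,  FALSE),
    list("hba1c",   "chd",    1.18, NA_real_, 5.0, 1,    0.05, 5L,  FALSE),
    list("hba1c",   "stroke", 1.15, NA_real_, 5.0, 1,    0.05, 5L,  FALSE),
    list("bmi",     "chd",    1.25, NA_real_, 22,  5,    0.04, 5L,  FALSE),
    list("bmi",     "stroke", 1.20, NA_real_, 22,  5,    0.04, 5L,  FALSE),
    list("pa",      "chd",    0.75, NA_real_, 1.0, 1,    0.06, 5L,  TRUE),
    list("pa",      "stroke", 0.80, NA_real_, 1.0, 1,    0.06, 5L,  TRUE),
    list("fv",      "chd",    0.95, NA_real_, 400, 100,  0.03, 5L,  TRUE),
    list("fv",      "stroke", 0.94, NA_real_, 400, 100,  0.03, 5L,  TRUE),
    list("smoking", "chd",    2.00, 1.25, NA_real_, NA_real_, 0.05, 10L, FALSE),
    list("smoking", "stroke", 1.90, 1.15, NA_real_, NA_real_, 0.05, 10L, FALSE)
  ))
  data.table::setnames(rr, c("factor", "disease", "rr", "rr_past", "ref", "unit",
                             "log_se", "lag", "protective"))

  econ <- list(
    utility_agegroups = seq(30, 90, by = 10),  # lower bounds of 10-year groups
    utility = list(
      male   = c(0.935, 0.920, 0.905, 0.885, 0.855, 0.815, 0.765),
      female = c(0.930, 0.915, 0.895, 0.870, 0.835, 0.790, 0.740)
    ),
    disutility = c(chd = 0.06, stroke = 0.10, diabetes = 0.04),
    disutility_log_se = 0.10,
    diabetes_hba1c_threshold = 6.5,
    # 2019 national annual cost anchors, billions of JPY (direct costs carry
    # no uncertainty; indirect costs do)
    direct_2019_bjpy   = c(chd_male = 490, chd_female = 210, stroke_male = 930, stroke_female = 890),
    indirect_2019_bjpy = c(chd_male = 2100, chd_female = 250, stroke_male = 2300, stroke_female = 1100),
    indirect_log_se = 0.20,
    productivity_share = 0.6,   # share of indirect costs accruing below age 65
    usd_per_1000_jpy = 10.56,
    # printed 2001 JPY/USD cell pairs (billions) used for the currency
    # consistency check
    pairs_2001 = data.table::data.table(
      disease   = rep(c("chd", "stroke"), each = 4),
      sex       = rep(rep(c("male", "female"), each = 2), 2),
      component = rep(c("direct", "indirect"), 4),
      jpy_b     = c(310, 2700, 100, 360, 580, 2600, 530, 960),
      usd_b     = c(3.3, 29, 1.1, 3.8, 6.1, 28, 5.6, 10)
    )
  )

  cfg <- list(
    name = "japan_core",
    survey_years = 1995:2019,
    survey_ages = 20:99,
    sim_years = 2001:2019,
    sim_ages = 30:99,
    seed = 1L,
    factors = factors,
    rank_correlation = rd,
    population = list(
      total = list(male = .anchor(39989, 44256), female = .anchor(43766, 48500)),
      share_65plus = c(male = 9618 / 39989, female = 13253 / 43766),
      age_slope = 12,
      young_survey_weight = 0.25,  # 20-29 sampling weight relative to age 30
      stationary = FALSE,
      entrants = "balance"
    ),
    mortality = list(q0 = c(male = 8e-4, female = 4.5e-4), gompertz_b = 0.095,
                     annual_decline = 0.005, cap = 0.6),
    epi = list(crude = crude, inc_age_slope = 0.075, inc_peak_age = 85,
               prev_age_mid = 70, prev_age_scale = 8, other_log_sd = 0.05),
    rr = rr,
    econ = econ
  )
  class(cfg) <- "cvd_preset"
  cfg
}

.preset_flat_null <- function() {
  cfg <- .preset_japan_core()
  cfg$name <- "flat_null"
  for (k in names(cfg$factors)) {
    f <- cfg$factors[[k]]
    for (fld in c("mean", "p_current", "p_past", "cig_mean")) {
      if (!is.null(f[[fld]])) {
        for (s in SEXES) f[[fld]][[s]]["y1"] <- f[[fld]][[s]]["y0"]
      }
    }
    cfg$factors[[k]] <- f
  }
  cfg$population$total <- lapply(cfg$population$total, function(v) { v["y1"] <- v["y0"]; v })
  cfg$epi$crude[, `:=`(y1 = y0, log_sd = 0)]
  cfg$epi$other_log_sd <- 0
  cfg$rr[, `:=`(rr = 1, rr_past = ifelse(is.na(rr_past), NA_real_, 1), log_se = 0)]
  cfg$econ$disutility_log_se <- 0
  cfg$econ$indirect_log_se <- 0
  cfg
}

#' Validate a preset configuration
#'
#' Checks the structural invariants: probabilities in (0,1), positive
#' dispersions, strictly increasing year ranges, positive relative risks with
#' lags in \[0,10\], a positive-definite rank-correlation matrix.
#'
#' @param cfg A preset list.
#' @return The validated `cvd_preset` (invisibly classed).
#' @export
validate_preset <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$factors), !is.null(cfg$population))
  if (any(diff(cfg$survey_years) <= 0) || any(diff(cfg$sim_years) <= 0)) {
    stop("year ranges must be strictly increasing")
  }
  for (k in names(cfg$factors)) {
    f <- cfg$factors[[k]]
    if (identical(f$family, "lognormal3") && f$sigma_log < 0) {
      stop("dispersion must be >= 0 for factor ", k)
    }
    if (identical(f$family, "gamma") && f$shape <= 0) {
      stop("gamma shape must be > 0 for factor ", k)
    }
    if (identical(f$family, "multinomial_count")) {
      for (s in SEXES) {
        p <- f$p_current[[s]] + f$p_past[[s]]
        if (any(f$p_current[[s]] < 0) || any(p >= 1)) {
          stop("smoking prevalences must lie in (0,1) with current+past < 1")
        }
      }
    }
  }
  if (!is.null(cfg$rr)) {
    if (any(cfg$rr$rr <= 0)) stop("relative risks must be > 0")
    if (any(cfg$rr$lag < 0 | cfg$rr$lag > 10)) stop("lags must lie in [0,10] years")
  }
  ch <- tryCatch(chol(cfg$rank_correlation), error = function(e) NULL)
  if (is.null(ch)) stop("rank correlation matrix is not positive definite")
  if (is.null(cfg$econ) || cfg$econ$usd_per_1000_jpy <= 0) {
    stop("exchange rate must be positive")
  }
  cfg$age_ref <- vapply(SEXES, function(s) .age_ref(cfg, s), numeric(1))
  class(cfg) <- "cvd_preset"
  invisible(cfg)
}

#' @export
print.cvd_preset <- function(x, ...) {
  cat("<cvd_preset>", x$name, "\n")
  cat("  survey years:", min(x$survey_years), "-", max(x$survey_years),
      " ages:", min(x$survey_ages), "-", max(x$survey_ages), "\n")
  cat("  simulation years:", min(x$sim_years), "-", max(x$sim_years),
      " ages:", min(x$sim_ages), "-", max(x$sim_ages), "\n")
  cat("  factors:", paste(names(x$factors), collapse = ", "), "\n")
  invisible(x)
}

# Linear trend between the 2001 and 2019 anchors, extended linearly outside
# the anchored range (back-projection before the baseline year).
.trend <- function(anchor, year, y0 = 2001, y1 = 2019) {
  anchor[["y0"]] + (anchor[["y1"]] - anchor[["y0"]]) * (year - y0) / (y1 - y0)
}

# 2001 age structure for one sex over the simulated ages: logistic decline
# whose midpoint is solved so the 65+ share matches the preset anchor.
.pop_age_weights <- function(cfg, sex) {
  ages <- cfg$sim_ages
  slope <- cfg$population$age_slope
  target <- cfg$population$share_65plus[[sex]]
  if (is.null(target)) {  # uniform fallback for degenerate test configs
    w <- rep(1, length(ages)); names(w) <- ages
    return(w / sum(w))
  }
  share <- function(a50) {
    w <- 1 / (1 + exp((ages - a50) / slope))
    sum(w[ages >= 65]) / sum(w)
  }
  a50 <- uniroot(function(z) share(z) - target, c(30, 200))$root
  w <- 1 / (1 + exp((ages - a50) / slope))
  names(w) <- ages
  w / sum(w)
}

# Weighted mean age of the 2001 population aged 30-99; the location anchors
# are interpreted at this reference age so that population means match them.
# Cached on the preset by validate_preset().
.age_ref <- function(cfg, sex) {
  if (!is.null(cfg$age_ref)) return(cfg$age_ref[[sex]])
  w <- .pop_age_weights(cfg, sex)
  sum(as.numeric(names(w)) * w)
}

# Stratum mean of a continuous factor at (age, sex, year).
.factor_mean <- function(cfg, factor_name, age, sex, year) {
  f <- cfg$factors[[factor_name]]
  m <- .trend(f$mean[[sex]], year)
  m + f$age_gradient * (age - .age_ref(cfg, sex))
}

# Smoking state probabilities at (age, sex, year): logit-linear year trends
# anchored at the reference age, with linear age gradients on the logit scale.
.smoking_probs_cfg <- function(cfg, age, sex, year) {
  f <- cfg$factors$smoking
  aref <- .age_ref(cfg, sex)
  lc <- qlogis(.trend(f$p_current[[sex]], year)) + f$logit_age_gradient * (age - aref)
  lp <- qlogis(.trend(f$p_past[[sex]], year)) + f$past_logit_age_gradient * (age - aref)
  p_cur <- plogis(lc)
  p_past <- plogis(lp)
  # guard: keep a never-smoker share
  tot <- p_cur + p_past
  over <- tot > 0.98
  if (any(over)) {
    p_cur[over] <- p_cur[over] * 0.98 / tot[over]
    p_past[over] <- p_past[over] * 0.98 / tot[over]
  }
  list(current = p_cur, past = p_past)
}
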