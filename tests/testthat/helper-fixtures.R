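# Shared fixtures, memoised across test files. Everything is generated in
# code at test time; sizes are chosen so the full suite stays desk-scale.

.fx <- new.env(parent = emptyenv())

# japan_core pipeline fixture: survey (8000 records/year), fitted models,
# input tables, calibration at the default cohort size, and a calibrated
# 9-scenario run at n_inner = 20000 under one seed.
jc_fixture <- function() {
  if (!is.null(.fx$jc)) return(.fx$jc)
  cfg <- make_preset("japan_core")
  survey <- generate_survey(cfg, n_per_year = 8000, seed = 101)
  models <- fit_exposure_models(survey)
  pop <- generate_population_counts(cfg)
  epi <- generate_epi_inputs(cfg, pop)
  inputs <- microsim_inputs(models, pop, epi, generate_rr_table(cfg),
                            generate_econ_inputs(cfg, pop))
  .fx$jc <- list(cfg = cfg, survey = survey, models = models, pop = pop,
                 epi = epi, inputs = inputs)
  .fx$jc
}

# calibrated base-case plus all counterfactual runs on a 20k cohort
jc_runs <- function() {
  if (!is.null(.fx$jc_runs)) return(.fx$jc_runs)
  fx <- jc_fixture()
  scalers <- calibrate_rates(fx$inputs, n_cal = 20000, seed = 207)
  cohort <- build_cohort(fx$pop, fx$epi, fx$models, n_inner = 20000,
                         year0 = 2001, seed = 207)
  std <- cvdmicrosim:::.std_quantiles(fx$models, cohort)
  cache <- new.env(parent = emptyenv())
  outs <- lapply(build_scenarios(), function(s) {
    run_scenario(fx$inputs, s, cohort, scalers = scalers, seed = 207,
                 std = std, exp_cache = cache)
  })
  .fx$jc_runs <- list(scalers = scalers, cohort = cohort, outs = outs)
  .fx$jc_runs
}

# flat_null pipeline at small scale
fn_fixture <- function() {
  if (!is.null(.fx$fn)) return(.fx$fn)
  cfg <- make_preset("flat_null")
  survey <- generate_survey(cfg, n_per_year = 3000, seed = 5)
  models <- fit_exposure_models(survey)
  pop <- generate_population_counts(cfg)
  epi <- generate_epi_inputs(cfg, pop)
  inputs <- microsim_inputs(models, pop, epi, generate_rr_table(cfg),
                            generate_econ_inputs(cfg, pop))
  cohort <- build_cohort(pop, epi, models, n_inner = 4000, year0 = 2001, seed = 11)
  .fx$fn <- list(cfg = cfg, survey = survey, models = models, pop = pop,
                 epi = epi, inputs = inputs, cohort = cohort)
  .fx$fn
}

# ---- hand-built toy model sets and cohorts (no fitting involved) ----------

# a shifted log-normal spec with exact coefficient control
toy_spec_ln3 <- function(factor_name, icpt, yr = 0, a = 0, sigma = 0, shift = 0,
                         age_range = c(20, 99), year_range = c(1995, 2019)) {
  structure(list(
    factor = factor_name, family = "lognormal3", shift = shift,
    fit_age_range = age_range, fit_year_range = year_range,
    frozen_year = NA_integer_,
    coef = list(male = c(icpt = icpt, a = a, a2 = 0, a3 = 0, yr = yr),
                female = c(icpt = icpt, a = a, a2 = 0, a3 = 0, yr = yr)),
    sigma = list(male = sigma, female = sigma),
    shape = list(), smoking = list(), deviance = list()
  ), class = "exposure_spec")
}

toy_spec_smoking <- function(eta_current = -20, eta_past = -20,
                             age_range = c(20, 99), year_range = c(1995, 2019)) {
  sm <- list(coef_past = c(icpt = eta_past, a = 0, a2 = 0, a3 = 0, yr = 0),
             coef_current = c(icpt = eta_current, a = 0, a2 = 0, a3 = 0, yr = 0),
             cig_coef = c(icpt = log(15), a = 0, a2 = 0, a3 = 0, yr = 0),
             cig_theta = 5)
  structure(list(
    factor = "smoking", family = "multinomial_count", shift = NULL,
    fit_age_range = age_range, fit_year_range = year_range,
    frozen_year = NA_integer_,
    coef = list(), sigma = list(), shape = list(),
    smoking = list(male = sm, female = sm), deviance = list()
  ), class = "exposure_spec")
}

# model set in which only SBP trends with year: SBP = 60 + exp(icpt + yr*t),
# every other factor constant, all lags `lag`
toy_model_set <- function(sbp_icpt = log(80), sbp_yr = -0.05, lag = 0L) {
  specs <- list(
    sbp = toy_spec_ln3("sbp", icpt = sbp_icpt, yr = sbp_yr, shift = 60),
    ldl = toy_spec_ln3("ldl", icpt = log(120)),
    bmi = toy_spec_ln3("bmi", icpt = log(23)),
    hba1c = toy_spec_ln3("hba1c", icpt = log(5.5)),
    pa = toy_spec_ln3("pa", icpt = log(0.5)),
    fv = toy_spec_ln3("fv", icpt = log(300)),
    smoking = toy_spec_smoking()
  )[c("sbp", "smoking", "ldl", "hba1c", "bmi", "pa", "fv")]
  R <- diag(1, 8)
  dimnames(R) <- list(cvdmicrosim:::RANK_DIMS, cvdmicrosim:::RANK_DIMS)
  lags <- setNames(rep(as.integer(lag), 7),
                   c("sbp", "smoking", "ldl", "hba1c", "bmi", "pa", "fv"))
  structure(list(specs = specs, rank_dependence = R, lags = lags),
            class = "exposure_model_set")
}

# constant-rate epi table over a small age/year window
toy_epi <- function(years, ages, p_inc_chd = 0.05, p_inc_stroke = 0.02,
                    f_chd = 0.1, f_stroke = 0.08, m_other = 0.01,
                    prev = 0, log_sd = 0) {
  g <- data.table::CJ(year = years, age = ages)
  mk <- function(d, meas, v) {
    data.table::rbindlist(lapply(c("male", "female"), function(s) {
      data.table::data.table(year = g$year, age = g$age, sex = s, disease = d,
                             measure = meas, value = v,
                             lo95 = v * exp(-1.96 * log_sd),
                             hi95 = v * exp(1.96 * log_sd))
    }))
  }
  data.table::rbindlist(list(
    mk("chd", "incidence", p_inc_chd), mk("chd", "prevalence", prev),
    mk("chd", "case_fatality", f_chd),
    mk("stroke", "incidence", p_inc_stroke), mk("stroke", "prevalence", prev),
    mk("stroke", "case_fatality", f_stroke),
    mk("none", "other_mortality", m_other)
  ))
}

toy_pop <- function(years, ages, count = 10) {
  g <- data.table::CJ(year = years, age = ages, sex = c("male", "female"))
  g[, count_thousands := count]
  g[]
}

# RR table: SBP acts on CHD; everything else null
toy_rr <- function(rr_sbp_chd = 2.0, log_se = 0) {
  rr_val <- rr_sbp_chd; se_val <- log_se  # avoid NSE capture of column names
  f7 <- c("sbp", "smoking", "ldl", "hba1c", "bmi", "pa", "fv")
  rr <- data.table::CJ(factor = f7, disease = c("chd", "stroke"))
  rr[, `:=`(rr = 1, rr_past = ifelse(factor == "smoking", 1, NA_real_),
            ref = 100, unit = 20, log_se = 0, lag = 0L, protective = FALSE)]
  rr[factor == "smoking", `:=`(ref = NA_real_, unit = NA_real_)]
  data.table::set(rr, which(rr$factor == "sbp" & rr$disease == "chd"),
                  c("rr", "ref", "log_se"), list(rr_val, 80, se_val))
  rr[]
}

# a hand-built cohort of n persons per (age, sex) archetype
toy_cohort <- function(archetypes, clones = 1L, year0 = 2001, seed = 99) {
  rows <- archetypes[rep(seq_len(nrow(archetypes)), each = clones)]
  n <- nrow(rows)
  co <- data.table::data.table(
    sex = rows$sex, birth_year = year0 - rows$age, entry_year = year0,
    weight = if ("weight" %in% names(rows)) rows$weight else 1
  )
  for (rk in paste0("rank_", cvdmicrosim:::RANK_DIMS)) data.table::set(co, j = rk, value = 0.5)
  co[, `:=`(init_chd = FALSE, init_stroke = FALSE, id = seq_len(n))]
  data.table::setattr(co, "seed", seed)
  data.table::setattr(co, "year0", year0)
  data.table::setattr(co, "class", c("cvd_cohort", class(co)))
  co
}

# Brute-force enumeration of the annual step over all outcome paths for one
# person: returns expected cumulative incident cases, deaths and case-years.
# `rates` is a list of per-year lists (p_chd, p_stroke, f_chd, f_stroke,
# m_other). Independent oracle for the engine's within-year event order.
enumerate_person <- function(rates) {
  states <- list(list(p = 1, chd = FALSE, stroke = FALSE))
  exp_ <- c(cases_chd = 0, cases_stroke = 0, deaths_chd = 0, deaths_stroke = 0,
            deaths_other = 0, caseyears_chd = 0, caseyears_stroke = 0)
  for (r in rates) {
    nxt <- list()
    for (st in states) {
      chd_branch <- if (st$chd) list(c(1, TRUE)) else
        list(c(1 - r$p_chd, FALSE), c(r$p_chd, TRUE))
      for (cb in chd_branch) {
        p1 <- st$p * cb[1]; chd1 <- as.logical(cb[2])
        if (p1 == 0) next
        if (!st$chd && chd1) exp_["cases_chd"] <- exp_["cases_chd"] + p1
        stroke_branch <- if (st$stroke) list(c(1, TRUE)) else
          list(c(1 - r$p_stroke, FALSE), c(r$p_stroke, TRUE))
        for (sb in stroke_branch) {
          p2 <- p1 * sb[1]; stroke1 <- as.logical(sb[2])
          if (p2 == 0) next
          if (!st$stroke && stroke1) exp_["cases_stroke"] <- exp_["cases_stroke"] + p2
          dc <- if (chd1) r$f_chd else 0
          ds <- if (stroke1) r$f_stroke else 0
          dm <- r$m_other
          tot <- dc + ds + dm
          scl <- if (tot > 1) 1 / tot else 1
          exp_["deaths_chd"] <- exp_["deaths_chd"] + p2 * dc * scl
          exp_["deaths_stroke"] <- exp_["deaths_stroke"] + p2 * ds * scl
          exp_["deaths_other"] <- exp_["deaths_other"] + p2 * dm * scl
          p_surv <- p2 * (1 - (dc + ds + dm) * scl)
          if (chd1) exp_["caseyears_chd"] <- exp_["caseyears_chd"] + p_surv
          if (stroke1) exp_["caseyears_stroke"] <- exp_["caseyears_stroke"] + p_surv
          if (p_surv > 0) nxt[[length(nxt) + 1L]] <-
              list(p = p_surv, chd = chd1, stroke = stroke1)
        }
      }
    }
    states <- nxt
  }
  exp_
}

# calibrated 50k base-case bundle (production-scale desk run): calibration at
# the same cohort size and seed as the reported run
jc50 <- function() {
  if (!is.null(.fx$jc50)) return(.fx$jc50)
  fx <- jc_fixture()
  scalers <- calibrate_rates(fx$inputs, n_cal = 50000, seed = 77)
  cohort <- build_cohort(fx$pop, fx$epi, fx$models, n_inner = 50000,
                         year0 = 2001, seed = 77)
  base <- run_scenario(fx$inputs, build_scenarios()$base, cohort,
                       scalers = scalers, seed = 77)
  .fx$jc50 <- list(scalers = scalers, cohort = cohort, base = base)
  .fx$jc50
}

# memoised heavy property computations shared by the uncertainty and
# acceptance suites

toy_world_fixture <- function(log_se = 0.25, epi_log_sd = 0.3) {
  years <- 2001:2002
  models <- toy_model_set(sbp_icpt = log(80), sbp_yr = -0.5, lag = 0L)
  epi <- toy_epi(years, 38:50, p_inc_chd = 0.08, p_inc_stroke = 0.03,
                 f_chd = 0.1, f_stroke = 0.08, m_other = 0.01,
                 log_sd = epi_log_sd)
  microsim_inputs(models, toy_pop(years, 40:45), epi,
                  toy_rr(rr_sbp_chd = 2.0, log_se = log_se))
}

varred_result <- function() {
  if (!is.null(.fx$varred)) return(.fx$varred)
  inp <- toy_world_fixture()
  scn <- build_scenarios()[c("base", "sbp")]
  v <- function(shared) {
    e <- run_ensemble(inp, scn, n_outer = 30, n_inner = 1200, master_seed = 55,
                      years = 2001:2002, shared_params = shared)
    e$diffs[cumulative == TRUE, .(v = var(cpp_chd)), by = sex][, sum(v)]
  }
  .fx$varred <- list(shared = v(TRUE), indep = v(FALSE))
  .fx$varred
}

ui_coverage_result <- function(n_rep = 60) {
  if (!is.null(.fx$uicov)) return(.fx$uicov)
  inp <- toy_world_fixture()
  scn <- build_scenarios()[c("base", "sbp")]
  years <- 2001:2002
  sbp_at <- function(y) 60 + exp(log(80) - 0.5 * (y - 2001) / 10)
  rr_at <- function(x) 2^((x - 80) / 20)
  rho <- function(y) rr_at(sbp_at(2001)) / rr_at(sbp_at(y))
  base <- enumerate_person(lapply(years, function(y) list(
    p_chd = 0.08, p_stroke = 0.03, f_chd = 0.1, f_stroke = 0.08,
    m_other = 0.01)))
  cf <- enumerate_person(lapply(years, function(y) list(
    p_chd = 0.08 * rho(y), p_stroke = 0.03, f_chd = 0.1, f_stroke = 0.08,
    m_other = 0.01)))
  truth <- (cf[["cases_chd"]] - base[["cases_chd"]]) * 120 +
    20 * 0.08 * (rho(2002) - 1)
  cover <- 0L
  for (r in seq_len(n_rep)) {
    e <- run_ensemble(inp, scn, n_outer = 8, n_inner = 1200,
                      master_seed = 1000 + r, years = years)
    cc <- e$diffs[cumulative == TRUE, .(v = sum(cpp_chd)), by = outer_iter]
    lo <- quantile(cc$v, 0.025, type = 7, names = FALSE)
    hi <- quantile(cc$v, 0.975, type = 7, names = FALSE)
    if (lo <= truth && truth <= hi) cover <- cover + 1L
  }
  .fx$uicov <- list(coverage = cover / n_rep, truth = truth)
  .fx$uicov
}
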