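# Scenario definition and execution under common random numbers.

#' Bundle the pipeline inputs for simulation
#'
#' @param models Fitted `exposure_model_set`.
#' @param population Population-count table.
#' @param epi Epidemiological rate table.
#' @param rr Relative-risk table.
#' @param econ `econ_inputs` (may be `NULL` to skip health economics).
#' @return A `microsim_inputs` list.
#' @export
microsim_inputs <- function(models, population, epi, rr, econ = NULL) {
  out <- list(models = models, population = data.table::as.data.table(population),
              epi = data.table::as.data.table(epi),
              rr = data.table::as.data.table(rr), econ = econ)
  class(out) <- "microsim_inputs"
  out
}

#' The nine analysis scenarios
#'
#' Base-case (observed trends), the combined counterfactual (all seven risk
#' factors frozen at the baseline year), and one single-factor counterfactual
#' per risk factor.
#'
#' @param freeze_year Baseline year for the counterfactuals.
#' @return Named list of 9 `scenario_spec`s: base, combined, sbp, smoking,
#'   ldl, hba1c, bmi, pa, fv.
#' @export
build_scenarios <- function(freeze_year = 2001L) {
  mk <- function(name, frozen) {
    s <- list(name = name, frozen_factors = frozen, freeze_year = freeze_year)
    class(s) <- "scenario_spec"
    s
  }
  out <- c(list(base = mk("base", character(0)),
                combined = mk("combined", FACTORS)),
           lapply(setNames(FACTORS, FACTORS), function(k) mk(k, k)))
  out
}

#' Run one scenario
#'
#' Executes the annual loop over the simulated years: lagged exposures from
#' the (possibly frozen) exposure models, multiplicative relative-risk
#' products, mean-preserving normalisation against the calibrated stratum
#' rates, and the fixed-order annual transition step. All event draws are
#' indexed by (person id, year, event type) so they are identical across
#' scenarios.
#'
#' @param inputs A `microsim_inputs`.
#' @param spec A `scenario_spec` from [build_scenarios()].
#' @param cohort A `cvd_cohort`.
#' @param scalers `calibration_scalers` (or `NULL` for uncalibrated rates).
#' @param seed Population/event seed (defaults to the cohort's).
#' @param years Simulated years.
#' @param param_draw Optional `parameter_draw` from [draw_parameters()].
#' @param outer_iter Outer-iteration index recorded in the output.
#' @param cig_gamma Cigarettes/day RR scaling exponent (default 0 = off).
#' @param econ_off Skip QALY/cost accounting (used during calibration).
#' @param std Precomputed standardised person quantiles (internal reuse
#'   across the scenarios of one outer draw); computed when `NULL`.
#' @param exp_cache Optional environment shared across the scenarios of one
#'   outer draw; exposure vectors per (factor, year, frozen-flag) are
#'   scenario-invariant over the full id universe, so the base-case and
#'   frozen variants are each computed once per draw.
#' @return An OutcomeTable: one row per (year, sex) with weighted incident
#'   cases (realised and expected), case-years (total and under-65), deaths
#'   by cause (realised and expected), person-years, QALYs, costs (JPY), and
#'   validation summaries (mean SBP, current-smoking prevalence). Counts are
#'   in the population table's units (thousands).
#' @export
run_scenario <- function(inputs, spec, cohort, scalers = NULL,
                         seed = attr(cohort, "seed"), years = NULL,
                         param_draw = NULL, outer_iter = 1L, cig_gamma = 0,
                         econ_off = FALSE, std = NULL, exp_cache = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(inputs$models)) stop("inputs$models missing: fit exposure models first")
  if (is.null(years)) years <- sort(unique(inputs$population$year))
  yn <- as.character(years)

  models <- inputs$models
  for (k in spec$frozen_factors) {
    models$specs[[k]] <- freeze_at_year(models$specs[[k]], spec$freeze_year)
  }
  rr_dt <- if (!is.null(param_draw$rr)) param_draw$rr else inputs$rr
  rr_chd <- rr_dt[disease == "chd"]
  rr_stroke <- rr_dt[disease == "stroke"]
  lags <- models$lags

  ea <- .epi_arrays(inputs$epi)
  if (!is.null(param_draw$epi_mult)) {
    for (s in SEXES) {
      for (d in DISEASES) {
        ea[[s]][[d]]$p_inc <- pmin(ea[[s]][[d]]$p_inc *
          param_draw$epi_mult[[paste0("incidence_", d, ".", s)]], 0.99)
        ea[[s]][[d]]$f <- pmin(ea[[s]][[d]]$f *
          param_draw$epi_mult[[paste0("fatality_", d, ".", s)]], 0.99)
      }
      ea[[s]]$m_other <- pmin(ea[[s]]$m_other *
        param_draw$epi_mult[[paste0("mortality_other.", s)]], 0.99)
    }
  }
  if (is.null(scalers)) {
    ms <- c("incidence_chd", "incidence_stroke", "fatality_chd",
            "fatality_stroke", "mortality_other")
    scalers <- lapply(setNames(ms, ms), function(m) {
      matrix(1, 2, length(years), dimnames = list(SEXES, yn))
    })
  }
  econ <- if (econ_off) NULL else inputs$econ
  if (!is.null(param_draw$econ) && !is.null(econ)) {
    econ$disutility <- param_draw$econ$disutility
    econ$unit_costs <- param_draw$econ$unit_costs
  }

  n_ids <- nrow(cohort)
  # standardised quantiles are scenario-invariant (freezing pins only the
  # location surfaces) so callers running several scenarios can precompute
  if (is.null(std)) std <- .std_quantiles(models, cohort)
  cohort_dt <- data.table::as.data.table(cohort)
  # full-id exposure vector for factor k as seen in simulation year y
  # (lagged by the factor's lag; lag 0 with `now = TRUE`), under the frozen
  # or unfrozen models; cacheable across scenarios of one parameter draw
  full_exposure <- function(k, y, frozen_k, now = FALSE) {
    key <- paste(k, y, frozen_k, now, spec$freeze_year, sep = "|")
    if (!is.null(exp_cache) && !is.null(exp_cache[[key]])) return(exp_cache[[key]])
    sp <- if (frozen_k) models$specs[[k]] else inputs$models$specs[[k]]
    L <- if (now) 0L else lags[[k]]
    agef <- y - L - cohort_dt$birth_year
    v <- if (k == "smoking") {
      .smoking_state(sp, agef, cohort_dt$sex, y - L, cohort_dt$rank_smoking)
    } else {
      .cont_exposure_std(sp, agef, cohort_dt$sex, y - L, std[[k]])
    }
    if (!is.null(exp_cache)) exp_cache[[key]] <- v
    v
  }
  state <- .init_state(cohort, year0 = years[1])
  a0 <- ea$ages[1]; y0e <- ea$years[1]
  rows <- vector("list", length(years))

  for (j in seq_along(years)) {
    y <- years[j]
    act <- .active_idx(state, y)
    ii <- which(act)
    age <- y - state$birth_year[ii]
    sex <- state$sex[ii]
    w <- state$weight[ii]
    sex_i <- ifelse(sex == "male", 1L, 2L)
    ids <- state$id[ii]

    # lagged exposures per factor (shared by both diseases); frozen factors
    # are also evaluated under the unfrozen (base-case) models because the
    # risk-normalisation denominator stays pinned to the base-case, so that
    # counterfactual rate changes flow only through the risk-factor
    # distributions
    exposures <- list()
    exposures_ref <- list()
    for (k in FACTORS) {
      frozen_k <- k %in% spec$frozen_factors
      exposures[[k]] <- full_exposure(k, y, frozen_k)[ids]
      exposures_ref[[k]] <- if (frozen_k) full_exposure(k, y, FALSE)[ids] else
        exposures[[k]]
      if (k == "smoking" && cig_gamma > 0) {
        L <- lags[[k]]
        exposures$cigs <- .cigs_per_day(models$specs$smoking, age - L, sex, y - L,
                                        state$rank_cig[ii])
        exposures_ref$cigs <- exposures$cigs
      }
    }
    pi_chd <- risk_product(rr_chd, exposures, cig_gamma)
    pi_stroke <- risk_product(rr_stroke, exposures, cig_gamma)
    if (length(pi_chd) == 1L) pi_chd <- rep(pi_chd, length(ii))
    if (length(pi_stroke) == 1L) pi_stroke <- rep(pi_stroke, length(ii))
    if (length(spec$frozen_factors)) {
      pi_chd_ref <- risk_product(rr_chd, exposures_ref, cig_gamma)
      pi_stroke_ref <- risk_product(rr_stroke, exposures_ref, cig_gamma)
      if (length(pi_chd_ref) == 1L) pi_chd_ref <- rep(pi_chd_ref, length(ii))
      if (length(pi_stroke_ref) == 1L) pi_stroke_ref <- rep(pi_stroke_ref, length(ii))
    } else {
      pi_chd_ref <- pi_chd
      pi_stroke_ref <- pi_stroke
    }

    ai <- age - a0 + 1L
    yi <- y - y0e + 1L
    grp <- sex_i * 1000L + age

    p_chd <- numeric(length(ii))
    free <- !state$chd[ii]
    pt <- ea$male$chd$p_inc[cbind(ai, yi)]
    pt[sex_i == 2L] <- ea$female$chd$p_inc[cbind(ai, yi)][sex_i == 2L]
    pt <- pt * scalers$incidence_chd[cbind(sex_i, j)]
    p_chd[free] <- .normalised_risk_ref(pt[free], pi_chd[free], pi_chd_ref[free],
                                        w[free], grp[free])

    p_stroke <- numeric(length(ii))
    free_s <- !state$stroke[ii]
    pts <- ea$male$stroke$p_inc[cbind(ai, yi)]
    pts[sex_i == 2L] <- ea$female$stroke$p_inc[cbind(ai, yi)][sex_i == 2L]
    pts <- pts * scalers$incidence_stroke[cbind(sex_i, j)]
    p_stroke[free_s] <- .normalised_risk_ref(pts[free_s], pi_stroke[free_s],
                                             pi_stroke_ref[free_s],
                                             w[free_s], grp[free_s])

    f_chd <- ea$male$chd$f[cbind(ai, yi)]
    f_chd[sex_i == 2L] <- ea$female$chd$f[cbind(ai, yi)][sex_i == 2L]
    f_chd <- pmin(f_chd * scalers$fatality_chd[cbind(sex_i, j)], 0.99)
    f_stroke <- ea$male$stroke$f[cbind(ai, yi)]
    f_stroke[sex_i == 2L] <- ea$female$stroke$f[cbind(ai, yi)][sex_i == 2L]
    f_stroke <- pmin(f_stroke * scalers$fatality_stroke[cbind(sex_i, j)], 0.99)
    m_oth <- ea$male$m_other[cbind(ai, yi)]
    m_oth[sex_i == 2L] <- ea$female$m_other[cbind(ai, yi)][sex_i == 2L]
    m_oth <- pmin(m_oth * scalers$mortality_other[cbind(sex_i, j)], 0.99)

    u <- list(u_chd = event_uniforms(seed, y, "chd_incidence", n_ids)[ids],
              u_stroke = event_uniforms(seed, y, "stroke_incidence", n_ids)[ids],
              u_death = event_uniforms(seed, y, "death", n_ids)[ids])
    stp <- step_disease(state, act, y,
                        list(p_chd = p_chd, p_stroke = p_stroke, f_chd = f_chd,
                             f_stroke = f_stroke, m_other = m_oth), u)
    state <- stp$state

    surv <- !stp$died
    chd1 <- state$chd[ii]
    stroke1 <- state$stroke[ii]
    lt65 <- age < 65

    # QALYs: all persons alive during the year, disease status incl.
    # same-year onset, diabetes proxied by current-year HbA1c
    qaly <- rep(NA_real_, length(ii))
    if (!is.null(econ)) {
      hba1c_now <- full_exposure("hba1c", y, "hba1c" %in% spec$frozen_factors,
                                 now = TRUE)[ids]
      diab <- hba1c_now > econ$diabetes_hba1c_threshold
      qaly <- person_year_utility(age, sex, chd1, stroke1, diab, econ)
    }
    sbp_now <- full_exposure("sbp", y, "sbp" %in% spec$frozen_factors,
                             now = TRUE)[ids]
    smoke_now <- full_exposure("smoking", y, "smoking" %in% spec$frozen_factors,
                               now = TRUE)[ids]

    acc <- data.table::data.table(
      sex = sex, w = w, lt65 = lt65, surv = surv, chd = chd1, stroke = stroke1,
      new_chd = stp$new_chd, new_stroke = stp$new_stroke,
      p_chd = p_chd, p_stroke = p_stroke,
      e_dc = stp$e_death_chd, e_ds = stp$e_death_stroke, e_do = stp$e_death_other,
      died_chd = stp$died & stp$cause == "chd",
      died_stroke = stp$died & stp$cause == "stroke",
      died_other = stp$died & stp$cause == "other",
      qaly = qaly, sbp = sbp_now, smoke_cur = smoke_now == 2L
    )
    r <- acc[, .(
      cases_chd = sum(w * new_chd), cases_stroke = sum(w * new_stroke),
      cases_chd_exp = sum(w * p_chd), cases_stroke_exp = sum(w * p_stroke),
      caseyears_chd = sum(w * (surv & chd)), caseyears_stroke = sum(w * (surv & stroke)),
      caseyears_chd_lt65 = sum(w * (surv & chd & lt65)),
      caseyears_stroke_lt65 = sum(w * (surv & stroke & lt65)),
      deaths_chd = sum(w * died_chd), deaths_stroke = sum(w * died_stroke),
      deaths_other = sum(w * died_other),
      deaths_chd_exp = sum(w * e_dc), deaths_stroke_exp = sum(w * e_ds),
      deaths_other_exp = sum(w * e_do),
      person_years = sum(w),
      qalys = if (is.null(econ)) NA_real_ else sum(w * qaly),
      mean_sbp = sum(w * sbp) / sum(w),
      smoking_current_prev = sum(w * smoke_cur) / sum(w)
    ), by = sex]
    r[, `:=`(scenario = spec$name, outer_iter = outer_iter, year = y)]
    rows[[j]] <- r

    if (j < length(years)) state <- advance_year(state, y, cohort)
  }

  out <- data.table::rbindlist(rows)
  out[, deaths_all := deaths_chd + deaths_stroke + deaths_other]
  data.table::setcolorder(out, c("scenario", "outer_iter", "year", "sex"))
  if (!is.null(econ)) out <- annual_costs(out, econ)
  # final person-level state, for snapshots and structural validation
  data.table::setattr(out, "final_state", state)
  data.table::setattr(out, "final_year", years[length(years)])
  out[]
}

#' Paired-scenario differences: CPPs, CYPPs, DPPs, net QALYs, net costs
#'
#' Sign convention: positive values mean the base-case (observed trends)
#' prevented/postponed cases, case-years or deaths, gained QALYs or saved
#' costs relative to the counterfactual; negative values mean cases caused
#' or accelerated.
#'
#' @param base,cf OutcomeTables with identical (outer_iter, year, sex) keys.
#' @param econ Optional `econ_inputs` for USD conversion of saved costs.
#' @return A DiffTable with annual rows plus cumulative rows
#'   (`cumulative == TRUE`, summed over the simulated years) per
#'   (outer_iter, sex): `cpp_*`, `cpp_*_exp`, `cypp_*`, `dpp`, `net_qalys`,
#'   `saved_direct_*`/`saved_indirect_*` (JPY and, when `econ` is given,
#'   USD).
#' @export
diff_scenarios <- function(base, cf, econ = NULL) {
  base <- data.table::as.data.table(base)
  cf <- data.table::as.data.table(cf)
  keys <- c("outer_iter", "year", "sex")
  for (k in setdiff(keys, names(base))) base[[k]] <- if (k == "outer_iter") 1L else NA
  for (k in setdiff(keys, names(cf))) cf[[k]] <- if (k == "outer_iter") 1L else NA
  data.table::setkeyv(base, keys); data.table::setkeyv(cf, keys)
  aligned <- nrow(base) == nrow(cf) &&
    all(base$outer_iter == cf$outer_iter) &&
    all(base$year == cf$year, na.rm = TRUE) &&
    !xor(anyNA(base$year), anyNA(cf$year)) &&
    all(base$sex == cf$sex)
  if (!aligned) {
    stop("base and counterfactual tables must share identical (outer_iter, year, sex) keys")
  }
  map <- c(cases_chd = "cpp_chd", cases_stroke = "cpp_stroke",
           cases_chd_exp = "cpp_chd_exp", cases_stroke_exp = "cpp_stroke_exp",
           caseyears_chd = "cypp_chd", caseyears_stroke = "cypp_stroke",
           deaths_all = "dpp")
  neg <- c(qalys = "net_qalys")
  cost_map <- c(direct_chd_jpy = "saved_direct_chd_jpy",
                direct_stroke_jpy = "saved_direct_stroke_jpy",
                indirect_chd_jpy = "saved_indirect_chd_jpy",
                indirect_stroke_jpy = "saved_indirect_stroke_jpy")
  d <- data.table::copy(base[, ..keys])
  for (m in names(map)) if (m %in% names(base) && m %in% names(cf)) {
    data.table::set(d, j = map[[m]], value = cf[[m]] - base[[m]])
  }
  for (m in names(neg)) if (m %in% names(base) && m %in% names(cf)) {
    data.table::set(d, j = neg[[m]], value = base[[m]] - cf[[m]])
  }
  for (m in names(cost_map)) if (m %in% names(base) && m %in% names(cf)) {
    data.table::set(d, j = cost_map[[m]], value = cf[[m]] - base[[m]])
  }
  d[, cumulative := FALSE]
  meas <- setdiff(names(d), c(keys, "cumulative"))
  cum <- d[, lapply(.SD, sum), by = .(outer_iter, sex), .SDcols = meas]
  cum[, `:=`(year = NA_integer_, cumulative = TRUE)]
  out <- data.table::rbindlist(list(d, cum), use.names = TRUE)
  if (!is.null(econ)) {
    for (m in intersect(unname(cost_map), names(out))) {
      data.table::set(out, j = sub("_jpy$", "_usd", m),
                      value = jpy_to_usd(out[[m]], econ$usd_per_1000_jpy))
    }
  }
  out[]
}

#' Internal validation of a base-case run against its inputs
#'
#' Compares simulated crude incidence, disease mortality and other-cause
#' mortality (conditional-expectation estimators) and the simulated mean SBP
#' with the values implied by the input tables and fitted exposure models.
#'
#' @param out A base-case OutcomeTable.
#' @param inputs The `microsim_inputs` used for the run.
#' @param tol Pass threshold on the relative error (default 5%).
#' @return A `data.table` (measure, sex, year, simulated, target, rel_err,
#'   pass).
#' @export
internal_validation_report <- function(out, inputs, tol = 0.05) {
  out <- data.table::as.data.table(out)
  targets <- .calibration_targets(inputs$epi, inputs$population)
  sim <- .simulated_crude(out)
  rows <- list()
  for (nm in names(sim)) {
    ms <- strsplit(nm, ".", fixed = TRUE)[[1]]
    yrs <- sort(unique(out$year))
    yn <- as.character(yrs)
    rows[[nm]] <- data.table::data.table(
      measure = ms[1], sex = ms[2], year = yrs,
      simulated = sim[[nm]][yn], target = targets[[nm]][yn])
  }
  # exposure check: mean SBP against the fitted-model population mean
  spec <- inputs$models$specs$sbp
  pop <- inputs$population
  for (s in SEXES) {
    N <- .pop_matrix(pop, s)
    yrs <- sort(unique(out$year)); yn <- as.character(yrs)
    ages <- as.numeric(rownames(N))
    tgt <- vapply(yrs, function(y) {
      p <- evaluate_params(spec, ages, s, y)
      m <- p$shift + exp(p$mu + p$sigma^2 / 2)
      sum(N[, as.character(y)] * m) / sum(N[, as.character(y)])
    }, numeric(1))
    rows[[paste0("mean_sbp.", s)]] <- data.table::data.table(
      measure = "mean_sbp", sex = s, year = yrs,
      simulated = out[sex == s][match(yrs, year), mean_sbp], target = tgt)
  }
  rep_ <- data.table::rbindlist(rows)
  rep_[, rel_err := abs(simulated / target - 1)]
  rep_[target == 0 & simulated == 0, rel_err := 0]
  rep_[, pass := rel_err <= tol]
  rep_[]
}
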