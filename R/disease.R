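# Disease dynamics: lagged relative risks, mean-preserving risk
# normalisation, annual state transitions, and calibration of annual rates to
# the input trends.
#
# Within a simulated year events resolve in a fixed order: (1) first-ever CHD
# incidence draw for the CHD-free, (2) first-ever stroke incidence draw for
# the stroke-free, (3) a single competing-risk death draw partitioning one
# uniform into CHD-death / stroke-death / other-death intervals (case
# fatality applies to prevalent cases including same-year incident ones).
# Survivors accrue one case-year per prevalent disease.

#' Relative risk for one factor at an exposure value
#'
#' Continuous factors follow a log-linear dose-response,
#' `RR = rr^((x - ref)/unit)`, floored at 1 below the reference level unless
#' the factor is configured as protective (physical activity, fruit and
#' vegetable intake), in which case `rr < 1` per unit and no floor applies.
#' Smoking is categorical (never = 1, past, current), with an optional
#' `(cigarettes/20)^gamma` scaling of the current-smoker RR (off by default).
#'
#' @param entry One row of the relative-risk table (list or 1-row data.table).
#' @param x Exposure values: numeric for continuous factors; for smoking,
#'   integer status codes (0 never, 1 past, 2 current).
#' @param cigs Cigarettes/day for current smokers (used when `cig_gamma > 0`).
#' @param cig_gamma Exponent of the cigarettes/day scaling (default 0 = off).
#' @return Relative risks, same length as `x`.
#' @export
relative_risk <- function(entry, x, cigs = NULL, cig_gamma = 0) {
  entry <- as.list(entry)
  if (identical(entry$factor, "smoking")) {
    rr <- c(1, entry$rr_past, entry$rr)[as.integer(x) + 1L]
    if (cig_gamma > 0 && !is.null(cigs)) {
      cur <- as.integer(x) == 2L
      rr[cur] <- rr[cur] * (cigs[cur] / 20)^cig_gamma
    }
    return(rr)
  }
  rr <- entry$rr^((x - entry$ref) / entry$unit)
  if (!isTRUE(entry$protective)) rr <- pmax(rr, 1)
  rr
}

#' Multiplicative risk product across factors
#'
#' @param rr_rows Relative-risk table rows for one disease.
#' @param exposures Named list of exposure vectors (per factor; smoking as
#'   status codes, plus optional `cigs`).
#' @param cig_gamma Cigarettes/day scaling exponent.
#' @return The per-person product of factor relative risks.
#' @export
risk_product <- function(rr_rows, exposures, cig_gamma = 0) {
  rr_rows <- data.table::as.data.table(rr_rows)
  pi_ <- 1
  for (i in seq_len(nrow(rr_rows))) {
    e <- rr_rows[i]
    x <- exposures[[e$factor]]
    if (is.null(x)) next
    pi_ <- pi_ * relative_risk(e, x, cigs = exposures$cigs, cig_gamma = cig_gamma)
  }
  pi_
}

#' Mean-preserving individual risk normalisation
#'
#' Scales the stratum target probability by each person's relative-risk
#' product divided by the stratum's weighted mean product, so the weighted
#' mean individual probability equals the stratum target exactly (when no
#' clipping occurs). Individual probabilities are clipped to \[0, 0.99\].
#'
#' @param p_target Stratum probability.
#' @param pi_ Individual relative-risk products.
#' @param w Individual weights (default equal).
#' @return Individual probabilities.
#' @export
normalised_risk <- function(p_target, pi_, w = rep(1, length(pi_))) {
  if (!length(pi_)) return(numeric(0))
  mean_pi <- sum(w * pi_) / sum(w)
  pmin(pmax(p_target * pi_ / mean_pi, 0), 0.99)
}

# grouped version: p_target per stratum via an integer group code
.normalised_risk_by <- function(p_target, pi_, w, group) {
  .normalised_risk_ref(p_target, pi_, pi_, w, group)
}

# normalisation against a reference (base-case) risk product: the stratum
# mean of pi_ref anchors the denominator, so in the base-case the weighted
# mean probability equals p_target while counterfactual exposure shifts move
# the stratum rate by the ratio of mean risk products
.normalised_risk_ref <- function(p_target, pi_, pi_ref, w, group) {
  dt <- data.table::data.table(g = group, wp = w * pi_ref, w = w)
  mp <- dt[, sum(wp) / sum(w), by = g]
  mpv <- mp$V1[match(group, mp$g)]
  pmin(pmax(p_target * pi_ / mpv, 0), 0.99)
}

#' One annual disease/death step
#'
#' Applies the fixed within-year event order to a state table given
#' individual probabilities and pre-drawn uniforms (one per person per event
#' slot, the common-random-numbers interface).
#'
#' @param state State table (columns alive, chd, stroke, ...).
#' @param idx Logical index of persons at risk this year (active).
#' @param year Current year.
#' @param probs List of vectors over `sum(idx)` persons: `p_chd`, `p_stroke`
#'   (first-ever incidence), `f_chd`, `f_stroke` (case fatality), `m_other`.
#' @param u List of uniform vectors over `sum(idx)` persons: `u_chd`,
#'   `u_stroke`, `u_death`.
#' @return List: updated `state`, logical vectors `new_chd`, `new_stroke`,
#'   `died` (within idx), character `cause`, and expected cause-specific
#'   death probabilities (`e_death_chd`, `e_death_stroke`, `e_death_other`).
#' @export
step_disease <- function(state, idx, year, probs, u) {
  ii <- which(idx)
  chd0 <- state$chd[ii]
  stroke0 <- state$stroke[ii]

  new_chd <- !chd0 & (u$u_chd < probs$p_chd)
  chd1 <- chd0 | new_chd
  new_stroke <- !stroke0 & (u$u_stroke < probs$p_stroke)
  stroke1 <- stroke0 | new_stroke

  h_chd <- ifelse(chd1, probs$f_chd, 0)
  h_stroke <- ifelse(stroke1, probs$f_stroke, 0)
  h_oth <- probs$m_other
  tot <- h_chd + h_stroke + h_oth
  scl <- ifelse(tot > 1, 1 / tot, 1)
  t1 <- h_chd * scl
  t2 <- t1 + h_stroke * scl
  t3 <- t2 + h_oth * scl
  died_chd <- u$u_death < t1
  died_stroke <- !died_chd & u$u_death < t2
  died_other <- !died_chd & !died_stroke & u$u_death < t3
  died <- died_chd | died_stroke | died_other
  cause <- rep(NA_character_, length(ii))
  cause[died_chd] <- "chd"; cause[died_stroke] <- "stroke"; cause[died_other] <- "other"

  state$chd[ii] <- chd1
  state$chd_onset[ii[new_chd]] <- year
  state$stroke[ii] <- stroke1
  state$stroke_onset[ii[new_stroke]] <- year
  state$alive[ii[died]] <- FALSE
  state$death_year[ii[died]] <- year
  state$death_cause[ii[died]] <- cause[died]

  list(state = state, new_chd = new_chd, new_stroke = new_stroke,
       died = died, cause = cause,
       e_death_chd = t1, e_death_stroke = t2 - t1, e_death_other = t3 - t2)
}

# epi table -> fast lookup arrays [age, year] per sex/disease/measure
.epi_arrays <- function(epi) {
  epi <- data.table::as.data.table(epi)
  ages <- sort(unique(epi$age)); years <- sort(unique(epi$year))
  arr <- function(sub) {
    m <- matrix(0, length(ages), length(years), dimnames = list(ages, years))
    m[cbind(match(sub$age, ages), match(sub$year, years))] <- sub$value
    m
  }
  out <- list(ages = ages, years = years)
  for (s in SEXES) {
    out[[s]] <- list(
      m_other = arr(epi[measure == "other_mortality" & sex == s]),
      chd = list(p_inc = arr(epi[measure == "incidence" & disease == "chd" & sex == s]),
                 prev = arr(epi[measure == "prevalence" & disease == "chd" & sex == s]),
                 f = arr(epi[measure == "case_fatality" & disease == "chd" & sex == s])),
      stroke = list(p_inc = arr(epi[measure == "incidence" & disease == "stroke" & sex == s]),
                    prev = arr(epi[measure == "prevalence" & disease == "stroke" & sex == s]),
                    f = arr(epi[measure == "case_fatality" & disease == "stroke" & sex == s]))
    )
  }
  out
}

# crude input-trend targets per (measure, sex, year) from the epi + pop tables
.calibration_targets <- function(epi, pop) {
  ea <- .epi_arrays(epi)
  pop <- data.table::as.data.table(pop)
  out <- list()
  for (s in SEXES) {
    Np <- .pop_matrix(pop, s)
    N <- matrix(0, length(ea$ages), length(ea$years),
                dimnames = list(ea$ages, ea$years))
    ri <- match(rownames(Np), rownames(N)); ci <- match(colnames(Np), colnames(N))
    N[ri[!is.na(ri)], ci[!is.na(ci)]] <- Np[!is.na(ri), !is.na(ci)]
    tot <- colSums(N)
    for (d in DISEASES) {
      a <- ea[[s]][[d]]
      out[[paste0("incidence_", d, ".", s)]] <-
        colSums(N * (1 - a$prev) * a$p_inc) / tot
      # disease deaths accrue to prevalent cases incl. same-year incident
      at_death <- a$prev + (1 - a$prev) * a$p_inc
      out[[paste0("fatality_", d, ".", s)]] <- colSums(N * at_death * a$f) / tot
    }
    out[[paste0("mortality_other.", s)]] <- colSums(N * ea[[s]]$m_other) / tot
  }
  out  # named list of per-year vectors (names = years)
}

#' Calibrate annual rates to the input trends
#'
#' Iterative proportional fitting: the base-case is simulated with the
#' current scalers, expected crude incidence / disease-mortality /
#' other-mortality per (measure, sex, year) are compared with the targets
#' implied by the input tables, and each scaler is multiplied by
#' target/simulated. Crude rates are measured with the conditional-
#' expectation estimator (sum of weighted individual probabilities), so the
#' fit is not limited by Bernoulli noise.
#'
#' @param inputs A list with `population`, `epi`, `rr` and fitted `models`
#'   (see [microsim_inputs()]).
#' @param n_cal Cohort size used during calibration.
#' @param seed Seed for the calibration cohort.
#' @param max_iter,tol Stop when the maximum relative error is below `tol`
#'   (default 2%) or after `max_iter` sweeps (warning, not fatal).
#' @param years Simulated years.
#' @return A `calibration_scalers` object: list of per-measure matrices
#'   `[sex, year]`, with the residual table as attribute `residuals`.
#' @export
calibrate_rates <- function(inputs, n_cal = 20000, seed = 1L, max_iter = 10L,
                            tol = 0.02, years = NULL) {
  if (is.null(years)) years <- sort(unique(inputs$population$year))
  targets <- .calibration_targets(inputs$epi, inputs$population)
  measures <- c("incidence_chd", "incidence_stroke", "fatality_chd",
                "fatality_stroke", "mortality_other")
  yn <- as.character(years)
  scalers <- lapply(setNames(measures, measures), function(m) {
    matrix(1, 2, length(years), dimnames = list(SEXES, yn))
  })
  cohort <- build_cohort(inputs$population, inputs$epi, inputs$models,
                         n_inner = n_cal, year0 = min(years), seed = seed)
  base <- build_scenarios()$base
  resid_tab <- NULL
  exp_cache <- new.env(parent = emptyenv())  # exposures constant across sweeps
  for (it in seq_len(max_iter)) {
    out <- run_scenario(inputs, base, cohort, scalers = scalers, seed = seed,
                        years = years, econ_off = TRUE, exp_cache = exp_cache)
    sim <- .simulated_crude(out)
    err <- 0
    rows <- list()
    for (m in measures) {
      for (s in SEXES) {
        tg <- targets[[paste0(m, ".", s)]][yn]
        sm <- sim[[paste0(m, ".", s)]][yn]
        ratio <- ifelse(sm > 0, tg / sm, 1)
        scalers[[m]][s, ] <- scalers[[m]][s, ] * ratio
        rel <- abs(sm / tg - 1)
        rel[tg == 0] <- 0
        err <- max(err, max(rel))
        rows[[paste(m, s)]] <- data.table::data.table(
          measure = m, sex = s, year = years, target = tg, simulated = sm,
          rel_err = rel)
      }
    }
    resid_tab <- data.table::rbindlist(rows)
    if (err <= tol) break
  }
  if (err > tol) {
    warning("calibration did not reach ", tol * 100, "% after ", max_iter,
            " iterations (max residual ", round(err * 100, 2), "%)")
  }
  data.table::setattr(scalers, "residuals", resid_tab)
  data.table::setattr(scalers, "class", "calibration_scalers")
  scalers
}

# expected crude rates per (measure, sex, year) from an OutcomeTable
.simulated_crude <- function(out) {
  res <- list()
  for (s in SEXES) {
    o <- out[sex == s]
    yn <- as.character(o$year)
    res[[paste0("incidence_chd.", s)]] <- setNames(o$cases_chd_exp / o$person_years, yn)
    res[[paste0("incidence_stroke.", s)]] <- setNames(o$cases_stroke_exp / o$person_years, yn)
    res[[paste0("fatality_chd.", s)]] <- setNames(o$deaths_chd_exp / o$person_years, yn)
    res[[paste0("fatality_stroke.", s)]] <- setNames(o$deaths_stroke_exp / o$person_years, yn)
    res[[paste0("mortality_other.", s)]] <- setNames(o$deaths_other_exp / o$person_years, yn)
  }
  res
}
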