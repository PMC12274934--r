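# Synthetic demographic counts and epidemiological rate tables.
#
# The population table is built by a survival recursion: the 2001 age
# structure is a logistic curve solved to match the preset's 65+ share, total
# annual mortality is Gompertz in age with a slow secular decline, and 30-
# year-old entrants are injected each year so that totals follow the preset's
# linear 2001->2019 trajectory. Disease-specific mortality is a per-(sex,
# year) share of total mortality scaled to the crude anchors; other-cause
# mortality is the remainder, so the survival recursion
# N(a+1, y+1) = N(a, y) * (1 - m_other - md_chd - md_stroke) holds exactly.

# total annual death probability at (age, sex, year)
.q_total <- function(cfg, age, sex, year) {
  m <- cfg$mortality
  pmin(m$cap, m$q0[[sex]] * exp(m$gompertz_b * (age - 30)) *
         (1 - m$annual_decline)^(year - min(cfg$sim_years)))
}

#' Generate the population-count table
#'
#' @param cfg A `cvd_preset`.
#' @return A `data.table` (year, age, sex, count_thousands) covering every
#'   simulated (year, age, sex) cell; totals per sex and year follow the
#'   preset anchors and consecutive years satisfy the survival recursion.
#' @export
generate_population_counts <- function(cfg) {
  stopifnot(inherits(cfg, "cvd_preset"))
  years <- cfg$sim_years
  ages <- cfg$sim_ages
  na <- length(ages)
  out <- list()
  for (s in SEXES) {
    w <- .pop_age_weights(cfg, s)
    tot0 <- .trend(cfg$population$total[[s]], years[1])
    N <- matrix(0, na, length(years), dimnames = list(ages, years))
    N[, 1] <- w * tot0
    zero_mort <- all(outer(ages, years, function(a, y) .q_total(cfg, a, s, y)) == 0)
    if (isTRUE(cfg$population$stationary) ||
        (identical(cfg$population$entrants, "none") && zero_mort)) {
      # degenerate stationary case: constant counts every year
      for (j in seq_along(years)[-1]) N[, j] <- N[, 1]
    } else {
      for (j in seq_along(years)[-1]) {
        y <- years[j - 1]
        surv <- N[-na, j - 1] * (1 - .q_total(cfg, ages[-na], s, y))
        N[-1, j] <- surv
        if (identical(cfg$population$entrants, "none")) {
          N[1, j] <- 0
        } else {
          target <- .trend(cfg$population$total[[s]], years[j])
          N[1, j] <- max(0, target - sum(surv))
        }
      }
    }
    out[[s]] <- data.table::data.table(
      year = rep(years, each = na), age = rep(ages, length(years)),
      sex = s, count_thousands = as.vector(N)
    )
  }
  data.table::rbindlist(out)[]
}

# population counts as a matrix [age, year] for one sex
.pop_matrix <- function(pop, sex_) {
  p <- pop[sex == sex_]
  data.table::dcast(p, age ~ year, value.var = "count_thousands") |>
    (\(d) { m <- as.matrix(d[, -1]); rownames(m) <- d$age; m })()
}

# Internal: all epi rate surfaces for one preset, as arrays [age, year] per
# (sex, disease, measure). Curves are scaled so the implied crude rates match
# the preset anchors (linear in year) against the generated population table.
.epi_surfaces <- function(cfg, pop = generate_population_counts(cfg)) {
  years <- cfg$sim_years
  ages <- cfg$sim_ages
  crude <- cfg$epi$crude
  g_prev <- plogis((ages - cfg$epi$prev_age_mid) / cfg$epi$prev_age_scale)
  h_inc <- exp(cfg$epi$inc_age_slope * (pmin(ages, cfg$epi$inc_peak_age) - 30))
  res <- list()
  nt <- length(years)
  na <- length(ages)
  for (s in SEXES) {
    N <- .pop_matrix(pop, s)
    q <- outer(ages, years, function(a, y) .q_total(cfg, a, s, y))
    crude_q <- colSums(N * q) / colSums(N)
    tgt <- function(meas, d) {
      r <- crude[measure == meas & disease == d & sex == s]
      .trend(c(y0 = r$y0, y1 = r$y1), years) / 1e5
    }
    # disease mortality: a per-(sex, year) share of total mortality, scaled
    # to the crude anchors; the share tapers beyond the incidence peak so
    # that the case fatality implied by the attainable prevalence stays well
    # below 1 at the oldest ages; other-cause mortality is the remainder
    taper_age <- if (is.null(cfg$epi$dis_mort_taper_age)) 85 else cfg$epi$dis_mort_taper_age
    taper_rate <- if (is.null(cfg$epi$dis_mort_taper_rate)) 0.045 else cfg$epi$dis_mort_taper_rate
    phi <- pmax(1 - pmax(ages - taper_age, 0) * taper_rate, 0.3)
    md <- list()
    for (d in DISEASES) {
      mort_t <- tgt("mortality", d)
      crude_qphi <- colSums(N * q * phi) / colSums(N)
      if (any(mort_t >= crude_q)) {
        stop("disease mortality target exceeds total mortality for ", d, " ", s)
      }
      md[[d]] <- sweep(q * phi, 2, mort_t / crude_qphi, `*`)
    }
    m_other <- q - md$chd - md$stroke
    if (any(m_other < 0)) stop("other-cause mortality went negative for ", s)

    # initial-year prevalence from the anchored age sigmoid; later years are
    # constructed forward from the model's own dynamics so that simulated
    # prevalence (hence disease mortality by age) is self-consistent with
    # the incidence and case-fatality surfaces
    prev <- list(); p_inc <- list(); f <- list()
    for (d in DISEASES) {
      p0 <- tgt("prevalence", d)[1] / (sum(N[, 1] * g_prev) / sum(N[, 1]))
      pr <- matrix(0, na, nt, dimnames = dimnames(q))
      pr[, 1] <- p0 * g_prev
      prev[[d]] <- pr
    }
    for (iter in 1:3) {
      for (d in DISEASES) {
        inc_t <- tgt("incidence", d)
        mean_h <- colSums(N * (1 - prev[[d]]) * h_inc) / colSums(N)
        p_inc[[d]] <- outer(h_inc, inc_t / mean_h)
        # case fatality applies to prevalent cases including same-year
        # incident ones, so the at-death prevalence includes them
        at_death <- prev[[d]] + (1 - prev[[d]]) * p_inc[[d]]
        f[[d]] <- pmin(md[[d]] / pmax(at_death, 1e-8), 0.9)
      }
      for (d in DISEASES) {
        pr <- prev[[d]]
        for (j in seq_len(nt - 1)) {
          P <- pr[-na, j]
          fa <- f[[d]][-na, j]
          mo <- m_other[-na, j]
          pi_ <- p_inc[[d]][-na, j]
          surv_dis <- pmax(1 - fa - mo, 0)
          num <- P * surv_dis + (1 - P) * pi_ * surv_dis
          den <- num + (1 - P) * (1 - pi_) * (1 - mo)
          pr[-1, j + 1] <- ifelse(den > 0, num / den, 0)
          pr[1, j + 1] <- 0  # entrants are disease-free
        }
        prev[[d]] <- pr
      }
    }
    # final pass: rescale incidence and case fatality against the converged
    # prevalence so the emitted tables are mutually consistent
    for (d in DISEASES) {
      inc_t <- tgt("incidence", d)
      mean_h <- colSums(N * (1 - prev[[d]]) * h_inc) / colSums(N)
      p_inc[[d]] <- outer(h_inc, inc_t / mean_h)
      at_death <- prev[[d]] + (1 - prev[[d]]) * p_inc[[d]]
      f[[d]] <- pmin(md[[d]] / pmax(at_death, 1e-8), 0.9)
    }
    sx <- list()
    for (d in DISEASES) {
      sx[[d]] <- list(prev = prev[[d]], p_inc = p_inc[[d]], md = md[[d]],
                      f = f[[d]])
    }
    res[[s]] <- list(diseases = sx, m_other = m_other, q = q)
  }
  res
}

#' Generate the epidemiological rate tables
#'
#' First-ever incidence, prevalence, annual case fatality and other-cause
#' mortality by (year, age, sex), each with a 95% interval for the outer
#' uncertainty loop (log-normal, width anchored to the printed 2001
#' intervals). The implied crude rates reproduce the preset anchors against
#' the generated population table.
#'
#' @param cfg A `cvd_preset`.
#' @param pop Optional population table (regenerated if missing).
#' @return A `data.table` (year, age, sex, disease, measure, value, lo95,
#'   hi95) with `measure` in incidence/prevalence/case_fatality and one
#'   `other_mortality` block with `disease = "none"`.
#' @export
generate_epi_inputs <- function(cfg, pop = generate_population_counts(cfg)) {
  stopifnot(inherits(cfg, "cvd_preset"))
  surf <- .epi_surfaces(cfg, pop)
  years <- cfg$sim_years
  ages <- cfg$sim_ages
  crude <- cfg$epi$crude
  grid <- data.table::CJ(year = years, age = ages)
  out <- list()
  for (s in SEXES) {
    for (d in DISEASES) {
      sdx <- surf[[s]]$diseases[[d]]
      for (meas in c("incidence", "prevalence", "case_fatality")) {
        arr <- switch(meas, incidence = sdx$p_inc, prevalence = sdx$prev,
                      case_fatality = sdx$f)
        cmeas <- if (meas == "case_fatality") "mortality" else meas
        lsd <- crude[measure == cmeas & disease == d & sex == s, log_sd]
        v <- arr[cbind(match(grid$age, ages), match(grid$year, years))]
        out[[paste(s, d, meas)]] <- data.table::data.table(
          year = grid$year, age = grid$age, sex = s, disease = d, measure = meas,
          value = v, lo95 = v * exp(-1.96 * lsd), hi95 = v * exp(1.96 * lsd)
        )
      }
    }
    mo <- surf[[s]]$m_other
    v <- mo[cbind(match(grid$age, ages), match(grid$year, years))]
    osd <- if (is.null(cfg$epi$other_log_sd)) 0.05 else cfg$epi$other_log_sd
    out[[paste(s, "other")]] <- data.table::data.table(
      year = grid$year, age = grid$age, sex = s, disease = "none",
      measure = "other_mortality", value = v,
      lo95 = v * exp(-1.96 * osd), hi95 = v * exp(1.96 * osd)
    )
  }
  epi <- data.table::rbindlist(out)
  bad <- epi[value < 0 | value >= 1 | !is.finite(value)]
  if (nrow(bad)) {
    b <- bad[1]
    stop(sprintf("implied probability outside [0,1) for %s/%s sex=%s age=%d year=%d: %g",
                 b$measure, b$disease, b$sex, b$age, b$year, b$value))
  }
  epi[]
}
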