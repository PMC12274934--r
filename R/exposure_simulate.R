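# Rank-persistent life-course simulation.
#
# Each person carries one lifetime rank per factor (plus one for
# cigarettes/day). A continuous exposure in a given year is the family
# quantile of that rank at the parameters for (age, sex, year), so exposures
# track distribution shifts while preserving individual ordering. Smoking is
# a one-way never -> current -> past status trajectory: within the
# ever-smoker band, a person is current while their rank exceeds the
# (declining) current-smoking threshold and becomes a past smoker when it no
# longer does.

# Precompute per-person standardised quantiles for the continuous families.
# A person's rank is fixed for life and the scale/shape parameters are
# constant per sex, so the expensive inverse-CDF work reduces to a one-off:
# gamma  : value = mean(a,s,y) * qgamma(u, shape, 1) / shape
# ln3    : value = shift + exp(mu(a,s,y) + sigma * qnorm(u))
.std_quantiles <- function(models, cohort) {
  out <- list()
  sexv <- cohort$sex
  for (k in CONTINUOUS_FACTORS) {
    spec <- models$specs[[k]]
    u <- cohort[[paste0("rank_", k)]]
    g <- numeric(length(u))
    for (s in SEXES) {
      i <- which(sexv == s)
      if (!length(i)) next
      g[i] <- if (spec$family == "gamma") {
        qgamma(u[i], shape = spec$shape[[s]], scale = 1)
      } else {
        qnorm(u[i])
      }
    }
    out[[k]] <- g
  }
  out
}

# fast continuous exposure using precomputed standardised quantiles
.cont_exposure_std <- function(spec, age, sex, year, g) {
  out <- numeric(length(g))
  for (s in SEXES) {
    i <- which(sex == s)
    if (!length(i)) next
    p <- evaluate_params(spec, age[i], s, if (length(year) > 1) year[i] else year)
    out[i] <- if (spec$family == "gamma") {
      p$mean * g[i] / spec$shape[[s]]
    } else {
      p$shift + exp(p$mu + p$sigma * g[i])
    }
  }
  out
}

# vectorised continuous exposure for persons (age, sex may be vectors)
.cont_exposure <- function(spec, age, sex, year, u) {
  out <- numeric(length(u))
  for (s in SEXES) {
    i <- which(sex == s)
    if (!length(i)) next
    p <- evaluate_params(spec, age[i], s, if (length(year) > 1) year[i] else year)
    out[i] <- exposure_quantile(spec, p, u[i])
  }
  out
}

# vectorised smoking state via the band rule at a single (age, year) slice:
# 2 = current, 1 = past, 0 = never
.smoking_state <- function(spec, age, sex, year, u) {
  out <- integer(length(u))
  for (s in SEXES) {
    i <- which(sex == s)
    if (!length(i)) next
    p <- evaluate_params(spec, age[i], s, if (length(year) > 1) year[i] else year)
    cur <- u[i] > 1 - p$p_current
    past <- !cur & (u[i] > 1 - p$p_current - p$p_past)
    out[i] <- ifelse(cur, 2L, ifelse(past, 1L, 0L))
  }
  out
}

.cigs_per_day <- function(spec, age, sex, year, u_cig) {
  out <- numeric(length(u_cig))
  for (s in SEXES) {
    i <- which(sex == s)
    if (!length(i)) next
    p <- evaluate_params(spec, age[i], s, if (length(year) > 1) year[i] else year)
    out[i] <- 1 + qnbinom(u_cig[i], mu = pmax(p$cig_mu - 1, 1e-6), size = p$cig_size)
  }
  out
}

#' Simulate one person's exposure life course
#'
#' @param models An `exposure_model_set` from [fit_exposure_models()].
#' @param person A list with `sex`, `birth_year`, and `ranks` (named vector
#'   over `sbp, ldl, bmi, hba1c, pa, fv, smoking, cig`, each in (0,1)).
#' @param years Calendar years to simulate (must extend far enough back for
#'   every factor's lag when used for disease dynamics).
#' @return A `data.table` with one row per year: age, the six continuous
#'   exposures, `smoking_status` and `cigarettes_per_day` (`NA` unless
#'   current).
#' @export
simulate_life_course <- function(models, person, years) {
  stopifnot(inherits(models, "exposure_model_set"))
  u <- person$ranks
  if (!all(RANK_DIMS %in% names(u))) {
    stop("person$ranks must name all of: ", paste(RANK_DIMS, collapse = ", "))
  }
  sex <- person$sex
  age <- years - person$birth_year
  out <- data.table::data.table(year = years, age = age)
  for (k in CONTINUOUS_FACTORS) {
    p <- evaluate_params(models$specs[[k]], age, sex, years)
    data.table::set(out, j = k,
                    value = exposure_quantile(models$specs[[k]], p,
                                              rep(u[[k]], length(years))))
  }
  # sequential one-way status path
  sp <- models$specs$smoking
  pr <- evaluate_params(sp, age, sex, years)
  ever <- u[["smoking"]] > 1 - pr$p_current[1] - pr$p_past[1]
  status <- integer(length(years))
  cur <- ever && u[["smoking"]] > 1 - pr$p_current[1]
  for (j in seq_along(years)) {
    cur <- cur && u[["smoking"]] > 1 - pr$p_current[j]
    status[j] <- if (cur) 2L else if (ever) 1L else 0L
  }
  out[, smoking_status := c("never", "past", "current")[status + 1L]]
  cig <- .cigs_per_day(sp, age, rep(sex, length(years)), years,
                       rep(u[["cig"]], length(years)))
  out[, cigarettes_per_day := ifelse(status == 2L, cig, NA_real_)]
  out[]
}
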