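# Distributional (location-scale-shape) exposure trend models.
#
# Each factor gets, per sex, a location surface that is cubic in age and
# linear in calendar year (a deliberately light GAMLSS-style basis), plus a
# constant scale/shape parameter: log-normal location fitted by least squares
# on the log scale, gamma by a log-link GLM, smoking status by a multinomial
# logit and cigarettes/day by a unit-shifted negative binomial. Evaluation
# outside the fitted age/year ranges is clamped to the boundary, never
# extrapolated.

.basis <- function(age, year) {
  a <- (age - 60) / 30
  yr <- (year - 2001) / 10
  cbind(icpt = 1, a = a, a2 = a^2, a3 = a^3, yr = yr)
}

.clamp <- function(x, rng) pmin(pmax(x, rng[1]), rng[2])

#' Fit a distributional trend model for one risk factor
#'
#' @param survey A survey `data.table` from [generate_survey()] (or the same
#'   schema).
#' @param factor_name One of the seven factor names.
#' @param family Distribution family; defaults to the factor's registered
#'   family (`lognormal3`, `gamma`, or `multinomial_count` for smoking).
#' @param shift Lower support bound for `lognormal3` (registry default).
#' @return An `exposure_spec`: per-sex coefficient vectors over the
#'   cubic-age/linear-year basis plus scale/shape parameters, fit ranges, and
#'   a deviance fit report.
#' @export
fit_factor_model <- function(survey, factor_name, family = NULL, shift = NULL) {
  .assert_factor(factor_name)
  if (is.null(family)) family <- FACTOR_FAMILY[[factor_name]]
  if (is.null(shift) && family == "lognormal3") shift <- FACTOR_SHIFT[[factor_name]]
  dt <- data.table::as.data.table(survey)
  for (s in SEXES) {
    if (sum(dt$sex == s) < 30) stop("need >= 30 records per sex to fit ", factor_name)
  }
  spec <- list(
    factor = factor_name, family = family, shift = shift,
    fit_age_range = range(dt$age), fit_year_range = range(dt$survey_year),
    frozen_year = NA_integer_, coef = list(), sigma = list(), shape = list(),
    smoking = list(), deviance = list()
  )
  for (s in SEXES) {
    d <- dt[sex == s]
    X <- .basis(d$age, d$survey_year)
    if (family == "lognormal3") {
      x <- d[[factor_name]]
      if (any(x <= shift)) stop("values at or below the support shift for ", factor_name)
      z <- log(x - shift)
      if (sd(z) < 1e-10) {
        # degenerate: all mass at one point; represent exactly
        fitc <- c(icpt = mean(z), a = 0, a2 = 0, a3 = 0, yr = 0)
        spec$coef[[s]] <- fitc; spec$sigma[[s]] <- 0
        spec$deviance[[s]] <- 0
        next
      }
      fit <- lm.fit(X, z)
      spec$coef[[s]] <- setNames(fit$coefficients, colnames(X))
      spec$sigma[[s]] <- sqrt(sum(fit$residuals^2) / (length(z) - ncol(X)))
      spec$deviance[[s]] <- sum(fit$residuals^2)
    } else if (family == "gamma") {
      x <- d[[factor_name]]
      if (sd(x) < 1e-10) stop("degenerate support: all values equal for ", factor_name)
      df <- data.frame(x = x, X[, -1])
      fit <- glm(x ~ a + a2 + a3 + yr, data = df, family = Gamma(link = "log"))
      if (!fit$converged) stop("gamma fit did not converge for ", factor_name,
                               " (deviance ", round(fit$deviance, 2), ")")
      spec$coef[[s]] <- setNames(coef(fit), colnames(X))
      spec$shape[[s]] <- 1 / summary(fit)$dispersion
      spec$deviance[[s]] <- fit$deviance
    } else if (family == "multinomial_count") {
      df <- data.frame(status = factor(d$smoking_status,
                                       levels = c("never", "past", "current")),
                       X[, -1])
      mfit <- nnet::multinom(status ~ a + a2 + a3 + yr, data = df,
                             trace = FALSE, maxit = 200)
      cm <- coef(mfit)  # rows: past, current; cols: (Intercept), a, a2, a3, yr
      colnames(cm) <- colnames(X)
      cur <- d[smoking_status == "current" & !is.na(cigarettes_per_day)]
      cdf <- data.frame(y = cur$cigarettes_per_day - 1L,
                        .basis(cur$age, cur$survey_year)[, -1])
      nb <- MASS::glm.nb(y ~ a + a2 + a3 + yr, data = cdf)
      spec$smoking[[s]] <- list(
        coef_past = cm["past", ], coef_current = cm["current", ],
        cig_coef = setNames(coef(nb), colnames(X)), cig_theta = nb$theta
      )
      spec$deviance[[s]] <- mfit$deviance
    } else {
      stop("unknown family '", family, "'")
    }
  }
  class(spec) <- "exposure_spec"
  spec
}

#' Fit all seven factor models plus the rank-dependence structure
#'
#' @param survey A survey dataset.
#' @param lags Named integer vector of exposure lags per factor (years,
#'   0-10); defaults: 5 for the biological factors and diet/activity, 10 for
#'   smoking.
#' @return An `exposure_model_set`: one `exposure_spec` per factor, a latent
#'   rank-correlation matrix estimated from the survey (normal-scores
#'   correlation), and the per-factor lags.
#' @export
fit_exposure_models <- function(survey,
                                lags = c(sbp = 5L, smoking = 10L, ldl = 5L, hba1c = 5L,
                                         bmi = 5L, pa = 5L, fv = 5L)) {
  stopifnot(all(FACTORS %in% names(lags)), all(lags >= 0 & lags <= 10))
  specs <- lapply(FACTORS, function(k) fit_factor_model(survey, k))
  names(specs) <- FACTORS
  dt <- data.table::as.data.table(survey)
  # normal-scores (van der Waerden) correlation of the latent ranks
  ns <- function(x) qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
  Z <- cbind(
    sbp = ns(dt$sbp), ldl = ns(dt$ldl), bmi = ns(dt$bmi), hba1c = ns(dt$hba1c),
    pa = ns(dt$pa), fv = ns(dt$fv),
    smoking = ns(as.integer(factor(dt$smoking_status,
                                   levels = c("never", "past", "current")))),
    cig = ns(data.table::fifelse(is.na(dt$cigarettes_per_day), 0,
                                 as.numeric(dt$cigarettes_per_day)))
  )
  R <- stats::cor(Z)
  # project to the nearest well-conditioned correlation matrix if needed
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    v <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% diag(v) %*% t(ev$vectors)
    D <- diag(1 / sqrt(diag(R)))
    R <- D %*% R %*% D
    dimnames(R) <- list(RANK_DIMS, RANK_DIMS)
  }
  out <- list(specs = specs, rank_dependence = R, lags = lags)
  class(out) <- "exposure_model_set"
  out
}

#' Evaluate the distribution parameters of a fitted spec
#'
#' Age and year are clamped to the fitted ranges; if the spec has been frozen
#' at a baseline year, years beyond it are pinned to that year (earlier,
#' back-projected years pass through so that pre-baseline history is shared
#' between scenarios).
#'
#' @param spec An `exposure_spec`.
#' @param age,year Numeric vectors (recycled).
#' @param sex `"male"` or `"female"`.
#' @return A named list of parameter vectors: `mu`/`sigma`/`shift`
#'   (lognormal3), `mean`/`shape` (gamma), or `p_current`/`p_past`/`p_never`/
#'   `cig_mu`/`cig_size` (smoking).
#' @export
evaluate_params <- function(spec, age, sex, year) {
  stopifnot(inherits(spec, "exposure_spec"))
  .assert_sex(sex)
  if (!is.na(spec$frozen_year)) year <- pmin(year, spec$frozen_year)
  age <- .clamp(age, spec$fit_age_range)
  year <- .clamp(year, spec$fit_year_range)
  X <- .basis(age, year)
  if (spec$family == "lognormal3") {
    list(mu = drop(X %*% spec$coef[[sex]]), sigma = spec$sigma[[sex]],
         shift = spec$shift)
  } else if (spec$family == "gamma") {
    list(mean = exp(drop(X %*% spec$coef[[sex]])), shape = spec$shape[[sex]])
  } else {
    sm <- spec$smoking[[sex]]
    ep <- exp(drop(X %*% sm$coef_past))
    ec <- exp(drop(X %*% sm$coef_current))
    den <- 1 + ep + ec
    list(p_current = ec / den, p_past = ep / den, p_never = 1 / den,
         cig_mu = 1 + exp(drop(X %*% sm$cig_coef)), cig_size = sm$cig_theta)
  }
}

#' Inverse-CDF of a fitted continuous family at rank u
#'
#' Strictly increasing in `u`; the mechanism behind rank-persistent life
#' courses.
#'
#' @param spec An `exposure_spec` with a continuous family.
#' @param params Parameters from [evaluate_params()].
#' @param u Ranks in (0,1).
#' @return Exposure values on the factor's natural scale.
#' @export
exposure_quantile <- function(spec, params, u) {
  if (any(u <= 0 | u >= 1)) stop("ranks u must lie strictly in (0,1)")
  if (spec$family == "lognormal3") {
    params$shift + qlnorm(u, meanlog = params$mu, sdlog = params$sigma)
  } else if (spec$family == "gamma") {
    qgamma(u, shape = params$shape, scale = params$mean / params$shape)
  } else {
    stop("exposure_quantile applies to continuous families; smoking is ",
         "simulated as a status trajectory")
  }
}

#' Freeze a fitted spec at a baseline year
#'
#' The returned spec evaluates its parameter surfaces at `y0` for every
#' simulation year at or after `y0` (age and sex dependence unchanged);
#' years before `y0` are untouched, so shared pre-baseline exposure history
#' is preserved across scenarios. Idempotent.
#'
#' @param spec An `exposure_spec`.
#' @param y0 Baseline year, within the fitted year range.
#' @return The frozen `exposure_spec`.
#' @export
freeze_at_year <- function(spec, y0) {
  stopifnot(inherits(spec, "exposure_spec"))
  if (y0 < spec$fit_year_range[1] || y0 > spec$fit_year_range[2]) {
    stop("freeze year must lie within the fitted year range")
  }
  spec$frozen_year <- as.integer(y0)
  spec
}

#' @export
print.exposure_spec <- function(x, ...) {
  cat("<exposure_spec>", x$factor, " family:", x$family,
      if (!is.na(x$frozen_year)) paste0(" [frozen at ", x$frozen_year, "]"), "\n")
  cat("  ages", x$fit_age_range[1], "-", x$fit_age_range[2],
      " years", x$fit_year_range[1], "-", x$fit_year_range[2], "\n")
  invisible(x)
}

#' @export
print.exposure_model_set <- function(x, ...) {
  cat("<exposure_model_set> factors:", paste(names(x$specs), collapse = ", "), "\n")
  cat("  lags:", paste(names(x$lags), x$lags, sep = "=", collapse = " "), "\n")
  invisible(x)
}
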