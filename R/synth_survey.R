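# Synthetic survey of individual risk-factor observations.
#
# Records are drawn from the preset's per-stratum distributions via a Gaussian
# copula on latent ranks, which induces the configured inter-factor
# dependence. Location trends are linear in calendar year between the 2001 and
# 2019 anchors (extended linearly before 2001); age enters through a linear
# gradient centred at the population reference age so that sample means
# reproduce the printed anchors.

#' Generate a synthetic risk-factor survey
#'
#' @param cfg A `cvd_preset` from [make_preset()].
#' @param n_per_year Total records per survey year (split evenly by sex).
#' @param seed Integer seed; identical `(cfg, seed)` give identical datasets.
#' @return A `data.table` with one row per record: `survey_year`, `age`,
#'   `sex`, `sbp`, `smoking_status`, `cigarettes_per_day` (current smokers
#'   only, `NA` otherwise), `ldl`, `hba1c`, `bmi`, `pa`, `fv`,
#'   medication-adjustment flags (`med_bp`, `med_lipid`, `med_dm`, carried but
#'   unused downstream) and `survey_weight`.
#' @export
generate_survey <- function(cfg, n_per_year = 4000, seed = cfg$seed) {
  stopifnot(inherits(cfg, "cvd_preset"))
  n_sex_year <- floor(n_per_year / 2)
  if (n_sex_year < 50) stop("per-year sample size must be >= 50 per sex")

  years <- cfg$survey_years
  ages <- cfg$survey_ages

  # survey age-sampling weights: population structure over 30-99 with a
  # down-weighted 20-29 plateau
  age_w <- lapply(SEXES, function(s) {
    w30 <- .pop_age_weights(cfg, s)
    w <- numeric(length(ages)); names(w) <- ages
    w[as.character(cfg$sim_ages)] <- w30
    young <- ages[ages < min(cfg$sim_ages)]
    if (length(young)) {
      w[as.character(young)] <- w30[[1]] * cfg$population$young_survey_weight
    }
    w / sum(w)
  })
  names(age_w) <- SEXES

  R <- cfg$rank_correlation
  ch <- chol(R)

  out <- .with_seed(derive_seed(seed, "survey"), {
    rows <- vector("list", length(years) * 2L)
    i <- 0L
    for (y in years) {
      for (s in SEXES) {
        i <- i + 1L
        n <- n_sex_year
        a <- sample(ages, n, replace = TRUE, prob = age_w[[s]])
        z <- matrix(rnorm(n * nrow(R)), n, nrow(R)) %*% ch
        u <- pnorm(z)
        colnames(u) <- colnames(R)
        vals <- lapply(setNames(CONTINUOUS_FACTORS, CONTINUOUS_FACTORS), function(k) {
          m <- .factor_mean(cfg, k, a, s, y)
          .cfg_quantile(cfg$factors[[k]], m, u[, k])
        })
        sp <- .smoking_probs_cfg(cfg, a, s, y)
        us <- u[, "smoking"]
        status <- ifelse(us > 1 - sp$current, "current",
                         ifelse(us > 1 - sp$current - sp$past, "past", "never"))
        cigm <- pmax(1.5, .trend(cfg$factors$smoking$cig_mean[[s]], y))
        cig <- 1 + qnbinom(u[, "cig"], mu = cigm - 1, size = cfg$factors$smoking$cig_size)
        rows[[i]] <- data.table::data.table(
          survey_year = y, age = a, sex = s,
          sbp = vals$sbp, smoking_status = status,
          cigarettes_per_day = ifelse(status == "current", cig, NA_real_),
          ldl = vals$ldl, hba1c = vals$hba1c, bmi = vals$bmi,
          pa = vals$pa, fv = vals$fv,
          # medication flags: adjusted values are emitted directly; the flag
          # is carried but unused downstream
          med_bp = runif(n) < plogis((vals$sbp - 160) / 8),
          med_lipid = runif(n) < plogis((vals$ldl - 170) / 12),
          med_dm = runif(n) < plogis((vals$hba1c - 7.5) / 0.5),
          survey_weight = 1
        )
      }
    }
    data.table::rbindlist(rows)
  })
  data.table::setcolorder(out, c("survey_year", "age", "sex", "sbp", "smoking_status",
                                 "cigarettes_per_day", "ldl", "hba1c", "bmi", "pa", "fv",
                                 "med_bp", "med_lipid", "med_dm", "survey_weight"))
  out[]
}

# Quantile of a configured continuous family with stratum mean m.
.cfg_quantile <- function(f, m, u) {
  if (identical(f$family, "lognormal3")) {
    m <- pmax(m, f$shift + 0.5)
    mu <- log(m - f$shift) - f$sigma_log^2 / 2
    f$shift + qlnorm(u, meanlog = mu, sdlog = f$sigma_log)
  } else if (identical(f$family, "gamma")) {
    m <- pmax(m, 1e-6)
    qgamma(u, shape = f$shape, scale = m / f$shape)
  } else {
    stop("not a continuous family")
  }
}
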