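# Relative-risk and health-economics input tables.

#' Generate the relative-risk table
#'
#' One row per (factor, disease): relative risk per unit for continuous
#' factors (RR < 1 for the protective factors, physical activity and
#' fruit/vegetable intake), per-category RRs for smoking (never = 1), a
#' log-scale standard error for the outer uncertainty loop, and an exposure
#' lag in years.
#'
#' @param cfg A `cvd_preset`.
#' @return A `data.table` (factor, disease, rr, rr_past, ref, unit, log_se,
#'   lag, protective).
#' @export
generate_rr_table <- function(cfg) {
  stopifnot(inherits(cfg, "cvd_preset"))
  rr <- data.table::copy(cfg$rr)
  if (any(rr$rr <= 0) || any(!is.na(rr$rr_past) & rr$rr_past <= 0)) {
    stop("relative risks must be > 0")
  }
  if (any(rr$lag < 0 | rr$lag > 10)) stop("lags must lie in [0,10] years")
  if (any(rr$log_se < 0)) stop("log-scale standard errors must be >= 0")
  rr[]
}

#' Generate the health-economics inputs
#'
#' Utility norms by 10-year age group and sex, additive disutilities for
#' prevalent CHD, stroke and diabetes, per-case-year direct and indirect
#' costs, and the JPY->USD exchange rate. Per-case-year costs are derived by
#' apportioning the preset's 2019 national cost anchors over the 2019
#' prevalent case-years implied by the epidemiological tables; the same
#' per-case-year cost applies in every year (constant real cost). Indirect
#' costs are split into an informal-care component (all ages) and a
#' productivity component that accrues only below age 65.
#'
#' @param cfg A `cvd_preset`.
#' @param pop Optional population table.
#' @return An `econ_inputs` list: `utility` (data.table agegroup_low x sex),
#'   `disutility`, `diabetes_hba1c_threshold`, `unit_costs` (data.table:
#'   disease, sex, component, jpy_per_case_year), `usd_per_1000_jpy`,
#'   uncertainty metadata, and the printed 2001 JPY/USD pairs.
#' @export
generate_econ_inputs <- function(cfg, pop = generate_population_counts(cfg)) {
  stopifnot(inherits(cfg, "cvd_preset"))
  ec <- cfg$econ
  surf <- .epi_surfaces(cfg, pop)
  y_anchor <- max(cfg$sim_years)
  ages <- cfg$sim_ages
  jcol <- as.character(y_anchor)
  unit_costs <- list()
  for (d in DISEASES) {
    for (s in SEXES) {
      N <- .pop_matrix(pop, s)[, jcol]
      prev <- surf[[s]]$diseases[[d]]$prev[, ncol(surf[[s]]$diseases[[d]]$prev)]
      cy_all <- sum(N * prev) * 1e3          # person-years
      cy_lt65 <- sum((N * prev)[ages < 65]) * 1e3
      key <- paste(d, s, sep = "_")
      c_direct <- ec$direct_2019_bjpy[[key]] * 1e9 / cy_all
      ind_total <- ec$indirect_2019_bjpy[[key]] * 1e9
      c_informal <- (1 - ec$productivity_share) * ind_total / cy_all
      c_product <- ec$productivity_share * ind_total / max(cy_lt65, 1)
      unit_costs[[key]] <- data.table::data.table(
        disease = d, sex = s,
        component = c("direct", "indirect_informal", "indirect_productivity"),
        jpy_per_case_year = c(c_direct, c_informal, c_product)
      )
    }
  }
  util <- data.table::data.table(
    agegroup_low = rep(ec$utility_agegroups, 2),
    sex = rep(SEXES, each = length(ec$utility_agegroups)),
    utility = c(ec$utility$male, ec$utility$female)
  )
  if (any(util$utility < 0 | util$utility > 1)) stop("utility norms must lie in [0,1]")
  out <- list(
    utility = util,
    disutility = ec$disutility,
    disutility_log_se = ec$disutility_log_se,
    diabetes_hba1c_threshold = ec$diabetes_hba1c_threshold,
    unit_costs = data.table::rbindlist(unit_costs),
    indirect_log_se = ec$indirect_log_se,
    usd_per_1000_jpy = ec$usd_per_1000_jpy,
    pairs_2001 = data.table::copy(ec$pairs_2001)
  )
  class(out) <- "econ_inputs"
  out
}

#' Generate every pipeline input from a preset
#'
#' Convenience wrapper producing the survey, population counts, epi rates,
#' relative risks and econ inputs in one call, optionally writing the CSV
#' representations to a directory.
#'
#' @param cfg A `cvd_preset`.
#' @param n_per_year Survey records per year (total, both sexes).
#' @param seed Integer seed for the survey draw.
#' @param dir Optional output directory for CSV files.
#' @return A list (survey, population, epi, rr, econ, cfg).
#' @export
generate_inputs <- function(cfg, n_per_year = 4000, seed = cfg$seed, dir = NULL) {
  pop <- generate_population_counts(cfg)
  inputs <- list(
    survey = generate_survey(cfg, n_per_year, seed),
    population = pop,
    epi = generate_epi_inputs(cfg, pop),
    rr = generate_rr_table(cfg),
    econ = generate_econ_inputs(cfg, pop),
    cfg = cfg
  )
  if (!is.null(dir)) write_inputs(inputs, dir)
  inputs
}

#' Write generated inputs as CSV files
#'
#' Writes `survey.csv`, `population.csv`, `epi_rates.csv`, `rr_table.csv` and
#' `econ.csv` (one header row, UTF-8, decimal point) to `dir`.
#'
#' @param inputs A list from [generate_inputs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_inputs <- function(inputs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f) data.table::fwrite(x, file.path(dir, f))
  wr(inputs$survey, "survey.csv")
  wr(inputs$population, "population.csv")
  wr(inputs$epi, "epi_rates.csv")
  wr(inputs$rr, "rr_table.csv")
  ec <- inputs$econ
  econ_long <- data.table::rbindlist(list(
    ec$unit_costs[, .(component, disease, sex, ageband = ifelse(
      component == "indirect_productivity", "30-64", "all"), value_jpy = jpy_per_case_year)],
    ec$utility[, .(component = "utility_norm", disease = "none", sex,
                   ageband = paste0(agegroup_low, "+"), value_jpy = utility)],
    data.table::data.table(component = "disutility", disease = names(ec$disutility),
                           sex = "all", ageband = "all", value_jpy = unname(ec$disutility)),
    data.table::data.table(component = "usd_per_1000_jpy", disease = "none",
                           sex = "all", ageband = "all", value_jpy = ec$usd_per_1000_jpy)
  ))
  wr(econ_long, "econ.csv")
  invisible(dir)
}
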