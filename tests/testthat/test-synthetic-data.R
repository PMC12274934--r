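# Synthetic-data generators: presets, survey, population, epi, RR, econ.

test_that("presets encode the anchors and reject unknown names", {
  cfg <- make_preset("japan_core")
  expect_equal(cfg$factors$sbp$mean$male[["y0"]], 140.1)
  expect_equal(cfg$factors$sbp$mean$female[["y0"]], 135.3)
  expect_equal(cfg$factors$sbp$mean$male[["y1"]], 133.4)
  expect_equal(cfg$factors$smoking$p_current$male[["y0"]], 0.493)
  expect_equal(cfg$factors$smoking$p_current$male[["y0"]] -
                 cfg$factors$smoking$p_current$male[["y1"]], 0.184)
  expect_equal(cfg$population$total$male, c(y0 = 39989, y1 = 44256))
  expect_equal(cfg$econ$usd_per_1000_jpy, 10.56)

  fn <- make_preset("flat_null")
  expect_true(all(fn$rr$rr == 1))
  expect_true(all(fn$rr$log_se == 0))
  expect_equal(fn$factors$sbp$mean$male[["y1"]], fn$factors$sbp$mean$male[["y0"]])

  expect_error(make_preset("nonexistent"), "japan_core")
})

test_that("custom presets load from an R file and are validated", {
  path <- withr::local_tempfile(fileext = ".R")
  writeLines("cvdmicrosim::make_preset('flat_null')", path)
  cfg <- make_preset(paste0("custom:", path))
  expect_s3_class(cfg, "cvd_preset")
  expect_error(make_preset("custom:/no/such/file.R"), "not found")
})

test_that("survey generation is deterministic in (cfg, seed) and respects invariants", {
  cfg <- make_preset("japan_core")
  s1 <- generate_survey(cfg, 300, seed = 1)
  s2 <- generate_survey(cfg, 300, seed = 1)
  s3 <- generate_survey(cfg, 300, seed = 2)
  expect_identical(s1, s2)
  expect_false(isTRUE(all.equal(s1$sbp, s3$sbp)))
  # cigarettes present iff current smoker
  expect_true(all(is.na(s1$cigarettes_per_day) == (s1$smoking_status != "current")))
  expect_true(all(s1$sbp > 60 & is.finite(s1$sbp)))
  expect_true(all(s1$pa > 0 & s1$fv > 0 & s1$hba1c > 0))
  expect_error(generate_survey(cfg, 50), ">= 50 per sex")
})

test_that("zero dispersion collapses a factor onto its stratum mean", {
  cfg <- make_preset("japan_core")
  cfg$factors$bmi$sigma_log <- 0
  s <- generate_survey(cfg, 300, seed = 3)
  # per-record stratum mean for each record's own sex
  m <- vapply(seq_len(nrow(s)), function(i) {
    cvdmicrosim:::.factor_mean(cfg, "bmi", s$age[i], s$sex[i], s$survey_year[i])
  }, numeric(1))
  expect_equal(s$bmi, m, tolerance = 1e-12)
})

test_that("survey sample means track the preset anchors", {
  fx <- jc_fixture()
  sv <- fx$survey
  expect_equal(sv[survey_year == 2001 & sex == "male", mean(sbp)], 140.1,
               tolerance = 0.5 / 140.1)
  expect_equal(sv[survey_year == 2001 & sex == "female", mean(sbp)], 135.3,
               tolerance = 0.5 / 135.3)
  expect_equal(sv[survey_year == 2019 & sex == "male", mean(sbp)], 133.4,
               tolerance = 0.5 / 133.4)
  expect_equal(sv[survey_year == 2001 & sex == "male",
                  mean(smoking_status == "current")], 0.493, tolerance = 0.05)
})

test_that("population counts hit the total anchors and satisfy the survival recursion", {
  fx <- jc_fixture()
  pop <- fx$pop
  tot <- pop[, .(t = sum(count_thousands)), by = .(year, sex)]
  expect_equal(tot[year == 2001 & sex == "male", t], 39989, tolerance = 1e-10)
  expect_equal(tot[year == 2019 & sex == "male", t], 44256, tolerance = 1e-10)
  expect_equal(tot[year == 2001 & sex == "female", t], 43766, tolerance = 1e-10)
  expect_equal(tot[year == 2019 & sex == "female", t], 48500, tolerance = 1e-10)

  # N(a+1, y+1) = N(a, y) * (1 - m_other - md_chd - md_stroke), within 0.1%
  epi <- fx$epi
  for (s in c("male", "female")) {
    N <- data.table::dcast(pop[sex == s], age ~ year,
                           value.var = "count_thousands")
    Nm <- as.matrix(N[, -1]); rownames(Nm) <- N$age
    mo <- data.table::dcast(epi[measure == "other_mortality" & sex == s],
                            age ~ year, value.var = "value")
    mom <- as.matrix(mo[, -1])
    md <- matrix(0, nrow(mom), ncol(mom))
    for (d in c("chd", "stroke")) {
      fa <- data.table::dcast(epi[measure == "case_fatality" & disease == d & sex == s],
                              age ~ year, value.var = "value")
      pv <- data.table::dcast(epi[measure == "prevalence" & disease == d & sex == s],
                              age ~ year, value.var = "value")
      pi_ <- data.table::dcast(epi[measure == "incidence" & disease == d & sex == s],
                               age ~ year, value.var = "value")
      # case fatality applies to prevalence including same-year incidence
      at_death <- as.matrix(pv[, -1]) +
        (1 - as.matrix(pv[, -1])) * as.matrix(pi_[, -1])
      md <- md + as.matrix(fa[, -1]) * at_death
    }
    surv <- 1 - mom - md
    pred <- Nm[-nrow(Nm), -ncol(Nm)] * surv[-nrow(surv), -ncol(surv)]
    obs <- Nm[-1, -1]
    rel <- abs(pred / pmax(obs, 1e-9) - 1)
    expect_lt(max(rel), 0.001)
  }
})

test_that("degenerate stationary population: zero mortality, no entrants", {
  cfg <- make_preset("flat_null")
  cfg$mortality$q0 <- c(male = 0, female = 0)
  cfg$population$entrants <- "none"
  pop <- generate_population_counts(cfg)
  y1 <- pop[year == 2001][order(sex, age), count_thousands]
  for (y in unique(pop$year)) {
    expect_equal(pop[year == y][order(sex, age), count_thousands], y1)
  }
})

test_that("epi tables reproduce the crude anchors and the configured age curve", {
  fx <- jc_fixture()
  epi <- fx$epi; pop <- fx$pop; cfg <- fx$cfg
  # implied crude CHD incidence, men 2001 -> 340 per 100,000 (exact by scaling)
  crude <- function(d, s, y) {
    inc <- epi[measure == "incidence" & disease == d & sex == s & year == y]
    prev <- epi[measure == "prevalence" & disease == d & sex == s & year == y]
    N <- pop[sex == s & year == y][order(age), count_thousands]
    sum(N * (1 - prev[order(age), value]) * inc[order(age), value]) / sum(N) * 1e5
  }
  expect_equal(crude("chd", "male", 2001), 340, tolerance = 1e-8)
  expect_equal(crude("chd", "male", 2019), 420, tolerance = 1e-8)
  expect_equal(crude("chd", "female", 2001), 190, tolerance = 1e-8)
  expect_equal(crude("stroke", "male", 2001), 390, tolerance = 1e-8)

  # age-specific incidence non-decreasing up to the configured peak age,
  # matching the preset's age-curve formula directly
  inc <- epi[measure == "incidence" & disease == "chd" & sex == "male" &
               year == 2001][order(age)]
  peak <- cfg$epi$inc_peak_age
  below <- inc[age <= peak, value]
  expect_true(all(diff(below) >= 0))
  h <- exp(cfg$epi$inc_age_slope * (pmin(inc$age, peak) - 30))
  expect_equal(inc$value / inc$value[1], h / h[1], tolerance = 1e-9)

  # intervals: lo < value < hi with the log-width from the printed intervals
  r <- epi[measure == "incidence" & disease == "chd" & sex == "male"][1]
  lsd <- cfg$epi$crude[measure == "incidence" & disease == "chd" & sex == "male", log_sd]
  expect_equal(log(r$hi95 / r$lo95) / (2 * 1.96), lsd, tolerance = 1e-9)
})

test_that("zero anchors give all-zero tables; impossible rates raise errors", {
  cfg <- make_preset("flat_null")
  cfg$epi$crude[, `:=`(y0 = 0, y1 = 0)]
  epi <- generate_epi_inputs(cfg)
  expect_true(all(epi[measure != "other_mortality", value] == 0))

  cfg2 <- make_preset("japan_core")
  cfg2$epi$crude[measure == "incidence" & disease == "chd" & sex == "male",
                 `:=`(y0 = 90000, y1 = 90000)]
  expect_error(generate_epi_inputs(cfg2), "outside \\[0,1\\)")
})

test_that("RR tables validate their support and lags", {
  cfg <- make_preset("japan_core")
  rr <- generate_rr_table(cfg)
  expect_true(all(rr$rr > 0))
  expect_true(all(rr$lag >= 0 & rr$lag <= 10))
  expect_equal(rr[factor == "smoking" & disease == "chd", lag], 10L)
  expect_true(all(rr[factor %in% c("pa", "fv"), rr] < 1))  # protective

  cfg$rr[1, rr := -1]
  expect_error(generate_rr_table(cfg), "> 0")
  cfg$rr[1, rr := 1.5]
  cfg$rr[1, lag := 11L]
  expect_error(generate_rr_table(cfg), "\\[0,10\\]")
})

test_that("econ inputs carry the exchange rate and sane unit costs", {
  fx <- jc_fixture()
  econ <- fx$inputs$econ
  expect_equal(econ$usd_per_1000_jpy, 10.56)
  expect_true(all(econ$unit_costs$jpy_per_case_year > 0))
  expect_true(all(econ$utility$utility >= 0 & econ$utility$utility <= 1))
  expect_equal(nrow(econ$pairs_2001), 8)
  # direct unit cost reproduces the 2019 national anchor when applied to the
  # 2019 prevalent case-years implied by the inputs
  cy <- fx$epi[measure == "prevalence" & disease == "chd" & sex == "male" &
                 year == 2019][order(age), value]
  N <- fx$pop[sex == "male" & year == 2019][order(age), count_thousands]
  total <- sum(cy * N) * 1e3 *
    econ$unit_costs[disease == "chd" & sex == "male" & component == "direct",
                    jpy_per_case_year]
  expect_equal(total, 490e9, tolerance = 1e-9)
})

test_that("written input CSVs round-trip through plain text", {
  fx <- jc_fixture()
  dir <- withr::local_tempdir()
  inputs <- list(survey = fx$survey[1:500], population = fx$pop, epi = fx$epi,
                 rr = fx$inputs$rr, econ = fx$inputs$econ)
  write_inputs(inputs, dir)
  expect_true(all(file.exists(file.path(dir, c("survey.csv", "population.csv",
                                               "epi_rates.csv", "rr_table.csv",
                                               "econ.csv")))))
  pop2 <- data.table::fread(file.path(dir, "population.csv"))
  expect_equal(pop2$count_thousands, fx$pop$count_thousands, tolerance = 1e-6)
})
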