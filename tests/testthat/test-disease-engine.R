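# Disease dynamics: dose-response, risk products, normalisation, annual
# steps, and calibration.

test_that("relative risks follow the log-linear dose-response", {
  e <- list(factor = "sbp", rr = 2, ref = 120, unit = 20, protective = FALSE)
  expect_equal(relative_risk(e, 120), 1.0)
  expect_equal(relative_risk(e, 160), 4.0)     # rr^2 over two units
  expect_equal(relative_risk(e, 130), sqrt(2))
  # floored at 1 below the reference when not protective
  expect_equal(relative_risk(e, 100), 1.0)
  # protective factors are not floored
  ep <- list(factor = "pa", rr = 0.8, ref = 1, unit = 1, protective = TRUE)
  expect_equal(relative_risk(ep, 2), 0.8)
  expect_equal(relative_risk(ep, 0), 1.25)
  # null RR
  en <- list(factor = "ldl", rr = 1, ref = 100, unit = 38.7, protective = FALSE)
  expect_equal(relative_risk(en, 250), 1.0)
  # smoking categories, never = 1
  es <- list(factor = "smoking", rr = 2.0, rr_past = 1.25)
  expect_equal(relative_risk(es, c(0L, 1L, 2L)), c(1, 1.25, 2))
  # optional cigarettes scaling
  expect_equal(relative_risk(es, 2L, cigs = 40, cig_gamma = 1), 4)
})

test_that("risk products multiply across factors and match brute force", {
  rrt <- toy_rr(rr_sbp_chd = 1.5)
  rrt[factor == "bmi" & disease == "chd", `:=`(rr = 2.0, ref = 22, unit = 5)]
  ex <- list(sbp = 80 + 20, smoking = 0L, ldl = 100, hba1c = 100, bmi = 27,
             pa = 100, fv = 100)
  expect_equal(risk_product(rrt[disease == "chd"], ex), 1.5 * 2.0)
  ex_ref <- list(sbp = 80, smoking = 0L, ldl = 100, hba1c = 100, bmi = 22,
                 pa = 100, fv = 100)
  expect_equal(risk_product(rrt[disease == "chd"], ex_ref), 1.0)

  # 100 random persons: product equals per-factor recomputation
  set.seed(1)
  n <- 100
  fx <- jc_fixture()
  rr_chd <- fx$inputs$rr[disease == "chd"]
  ex <- list(sbp = runif(n, 100, 180), smoking = sample(0:2, n, TRUE),
             ldl = runif(n, 70, 190), hba1c = runif(n, 4.5, 9),
             bmi = runif(n, 18, 35), pa = runif(n, 0.05, 2),
             fv = runif(n, 50, 600))
  pi_ <- risk_product(rr_chd, ex)
  brute <- rep(1, n)
  for (i in seq_len(nrow(rr_chd))) {
    brute <- brute * relative_risk(rr_chd[i], ex[[rr_chd$factor[i]]])
  }
  expect_equal(pi_, brute, tolerance = 1e-12)
})

test_that("normalised risk preserves the stratum mean", {
  expect_equal(normalised_risk(0.05, rep(1, 7)), rep(0.05, 7))
  expect_equal(normalised_risk(0.02, c(1, 3)), c(0.01, 0.03))
  set.seed(2)
  pi_ <- exp(rnorm(500, 0, 0.6))
  w <- runif(500, 0.5, 2)
  p <- normalised_risk(0.03, pi_, w)
  expect_equal(sum(w * p) / sum(w), 0.03, tolerance = 1e-12)
  # clipping engages at the top
  expect_equal(max(normalised_risk(0.9, c(1, 10))), 0.99)
})

test_that("the annual step applies the fixed event order", {
  st <- data.table::data.table(
    alive = rep(TRUE, 3), chd = c(FALSE, TRUE, FALSE),
    stroke = c(FALSE, FALSE, FALSE),
    chd_onset = c(NA_integer_, 1999L, NA_integer_),
    stroke_onset = rep(NA_integer_, 3),
    death_year = rep(NA_integer_, 3), death_cause = rep(NA_character_, 3))
  # all probabilities zero: nothing changes
  z <- rep(0, 3)
  stp <- step_disease(st, rep(TRUE, 3), 2005,
                      list(p_chd = z, p_stroke = z, f_chd = z, f_stroke = z,
                           m_other = z),
                      list(u_chd = runif(3), u_stroke = runif(3),
                           u_death = runif(3)))
  expect_true(all(stp$state$alive))
  expect_false(any(stp$new_chd | stp$new_stroke | stp$died))
  # certain case fatality kills the prevalent case with cause chd
  stp2 <- step_disease(st, rep(TRUE, 3), 2005,
                       list(p_chd = z, p_stroke = z, f_chd = rep(1, 3),
                            f_stroke = z, m_other = z),
                       list(u_chd = rep(0.99, 3), u_stroke = rep(0.99, 3),
                            u_death = rep(0.5, 3)))
  expect_equal(stp2$state$alive, c(TRUE, FALSE, TRUE))
  expect_equal(stp2$state$death_cause[2], "chd")
  expect_equal(stp2$state$death_year[2], 2005L)
  # same-year incident cases are exposed to that year's case fatality
  stp3 <- step_disease(st, rep(TRUE, 3), 2005,
                       list(p_chd = rep(1, 3), p_stroke = z, f_chd = rep(1, 3),
                            f_stroke = z, m_other = z),
                       list(u_chd = rep(0.5, 3), u_stroke = rep(0.99, 3),
                            u_death = rep(0.5, 3)))
  expect_true(all(!stp3$state$alive))
  expect_true(all(stp3$state$death_cause == "chd"))
})

test_that("incidence draws are binomially consistent", {
  n <- 10000
  st <- data.table::data.table(
    alive = rep(TRUE, n), chd = FALSE, stroke = FALSE,
    chd_onset = NA_integer_, stroke_onset = NA_integer_,
    death_year = NA_integer_, death_cause = NA_character_)
  u <- event_uniforms(3, 2001, "chd_incidence", n)
  stp <- step_disease(st, rep(TRUE, n), 2001,
                      list(p_chd = rep(0.1, n), p_stroke = rep(0, n),
                           f_chd = rep(0, n), f_stroke = rep(0, n),
                           m_other = rep(0, n)),
                      list(u_chd = u, u_stroke = u, u_death = u))
  frac <- mean(stp$new_chd)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("engine events match exhaustive enumeration on a small cohort", {
  # 4 archetypes x 2 years, cloned for the Monte Carlo estimate
  years <- 2001:2002
  arch <- data.table::data.table(
    age = c(40, 45, 40, 45), sex = c("male", "male", "female", "female"))
  clones <- 1500
  coh <- toy_cohort(arch, clones = clones, seed = 57)
  rates <- list(p_inc_chd = 0.12, p_inc_stroke = 0.06, f_chd = 0.2,
                f_stroke = 0.15, m_other = 0.03)
  epi <- toy_epi(years, 38:50, rates$p_inc_chd, rates$p_inc_stroke,
                 rates$f_chd, rates$f_stroke, rates$m_other)
  inp <- microsim_inputs(toy_model_set(), toy_pop(years, 40:45), epi, toy_rr(1.0))
  out <- run_scenario(inp, build_scenarios()$base, coh, seed = 57, years = years)

  oracle <- enumerate_person(rep(list(list(
    p_chd = rates$p_inc_chd, p_stroke = rates$p_inc_stroke,
    f_chd = rates$f_chd, f_stroke = rates$f_stroke,
    m_other = rates$m_other)), 2))
  n_eff <- nrow(coh)  # every person identical in rates
  tot <- out[, .(cases_chd = sum(cases_chd), cases_stroke = sum(cases_stroke),
                 deaths_chd = sum(deaths_chd), deaths_stroke = sum(deaths_stroke),
                 deaths_other = sum(deaths_other),
                 caseyears_chd = sum(caseyears_chd))]
  for (m in c("cases_chd", "cases_stroke", "deaths_chd", "deaths_stroke",
              "deaths_other", "caseyears_chd")) {
    mc <- tot[[m]] / n_eff
    tr <- oracle[[m]]
    se <- sqrt(tr * (1 - min(tr, 0.99)) / n_eff) + sqrt(tr / n_eff) * 0.5
    expect_lt(abs(mc - tr), 3 * max(se, 1e-4))
  }
})

test_that("calibration is a fixed point when rates already match and scalers rescale rates", {
  # mortality-only toy: the uncalibrated expected crude rate equals the
  # target, so the other-mortality scalers stay at 1 up to composition noise
  years <- 2001:2003
  epi <- toy_epi(years, 38:50, p_inc_chd = 0, p_inc_stroke = 0, f_chd = 0,
                 f_stroke = 0, m_other = 0.02)
  inp0 <- microsim_inputs(toy_model_set(), toy_pop(years, 40:45), epi, toy_rr(1.0))
  sc0 <- calibrate_rates(inp0, n_cal = 2000, seed = 3, years = years)
  expect_true(all(abs(sc0$mortality_other - 1) < 0.02))
  expect_true(all(sc0$incidence_chd == 1))  # zero targets leave scalers alone

  fx <- jc_fixture()
  runs <- jc_runs()
  # calibration on the full preset converges to the input trends
  expect_lt(max(attr(runs$scalers, "residuals")$rel_err), 0.02)
  expect_true(all(unlist(runs$scalers) > 0))
  # incidence needs essentially no correction (generator and engine agree)
  expect_true(all(abs(runs$scalers$incidence_chd - 1) < 0.1))
  # a manual x2 scaler doubles the simulated expected rate
  sc2 <- runs$scalers
  sc2$incidence_chd["male", "2010"] <- sc2$incidence_chd["male", "2010"] * 2
  out1 <- runs$outs$base
  out2 <- run_scenario(fx$inputs, build_scenarios()$base, runs$cohort,
                       scalers = sc2, seed = 207)
  r1 <- out1[year == 2010 & sex == "male", cases_chd_exp / person_years]
  r2 <- out2[year == 2010 & sex == "male", cases_chd_exp / person_years]
  expect_equal(r2 / r1, 2, tolerance = 0.02)
})

test_that("lowering the SBP distribution never raises CHD risk", {
  # frozen-at-2001 SBP is *higher* than base in later years under japan_core,
  # so expected incidence under the counterfactual dominates the base-case
  runs <- jc_runs()
  b <- runs$outs$base; s <- runs$outs$sbp
  late <- b$year >= 2010
  expect_true(all(s$cases_chd_exp[late] >= b$cases_chd_exp[late]))
  # and the reverse comparison: base (lower SBP) has fewer expected cases
  expect_true(sum(b$cases_chd_exp) < sum(s$cases_chd_exp))
})
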