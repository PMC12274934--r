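# Second-order Monte Carlo: outer-loop parameter draws shared by all
# scenarios of a given iteration (inducing the covariance that makes paired
# differences precise), inner-loop individual simulation, and median/95%-UI
# summarisation.

#' Draw one outer-loop parameter set
#'
#' Relative risks are drawn log-normally around their point estimates with
#' the tabulated log-scale standard errors; epidemiological rates get one
#' log-normal multiplier per (measure, disease, sex) whose spread matches the
#' tabulated 95% intervals (rates move coherently across ages and years, as
#' with source-study uncertainty); disutilities and indirect costs are drawn
#' log-normally. Direct 2019 costs and the exchange rate are fixed (no
#' uncertainty). Zero-width intervals reproduce the point estimates exactly.
#'
#' @param inputs A `microsim_inputs`.
#' @param draw_id Outer iteration index.
#' @param master_seed Ensemble master seed.
#' @return A `parameter_draw` list (`rr`, `epi_mult`, `econ`), reproducible
#'   given `(master_seed, draw_id)`.
#' @export
draw_parameters <- function(inputs, draw_id, master_seed) {
  s <- derive_seed(master_seed, "draw", as.integer(draw_id))
  .with_seed(s, {
    rr <- data.table::copy(inputs$rr)
    z <- rnorm(nrow(rr))
    idx <- which(!is.na(rr$rr_past))
    rr[, rr := exp(log(rr) + z * log_se)]
    data.table::set(rr, i = idx, j = "rr_past",
                    value = exp(log(rr$rr_past[idx]) + z[idx] * rr$log_se[idx]))

    epi <- inputs$epi
    key <- epi[, .(log_sd = {
      i <- which(value > 0 & hi95 > lo95)[1]
      if (is.na(i)) 0 else log(hi95[i] / lo95[i]) / (2 * 1.96)
    }), by = .(measure, disease, sex)]
    mult <- list()
    for (r in seq_len(nrow(key))) {
      m <- key$measure[r]
      nm <- switch(m,
                   incidence = paste0("incidence_", key$disease[r], ".", key$sex[r]),
                   case_fatality = paste0("fatality_", key$disease[r], ".", key$sex[r]),
                   other_mortality = paste0("mortality_other.", key$sex[r]),
                   NA_character_)
      if (is.na(nm)) next  # prevalence enters only at cohort build
      mult[[nm]] <- exp(rnorm(1, 0, key$log_sd[r]))
    }

    econ_draw <- NULL
    if (!is.null(inputs$econ)) {
      ec <- inputs$econ
      du <- ec$disutility * exp(rnorm(length(ec$disutility), 0, ec$disutility_log_se))
      uc <- data.table::copy(ec$unit_costs)
      ind <- uc$component != "direct"
      uc$jpy_per_case_year[ind] <- uc$jpy_per_case_year[ind] *
        exp(rnorm(sum(ind), 0, ec$indirect_log_se))
      econ_draw <- list(disutility = du, unit_costs = uc)
    }
    out <- list(draw_id = draw_id, rr = rr, epi_mult = mult, econ = econ_draw)
    class(out) <- "parameter_draw"
    out
  })
}

#' Run the second-order Monte Carlo ensemble
#'
#' For each outer draw: one parameter set, one shared population seed, all
#' requested scenarios simulated under common random numbers, and
#' differences of every counterfactual against the base-case. Draws are
#' self-seeded from `(master_seed, draw_id)`, so results are independent of
#' execution order.
#'
#' @param inputs A `microsim_inputs`.
#' @param scenarios List of `scenario_spec`s (must include `base` first for
#'   differencing); default all nine.
#' @param n_outer,n_inner Outer draws and cohort size.
#' @param master_seed Ensemble master seed.
#' @param scalers Calibration scalers (computed on the base-case at point
#'   estimates and reused for every draw and scenario).
#' @param years Simulated years.
#' @param shared_params If `FALSE`, each scenario of a draw gets an
#'   independently re-drawn parameter set (diagnostic mode for quantifying
#'   the variance reduction of shared draws).
#' @return List: `outcomes` (all scenario OutcomeTables, stacked), `diffs`
#'   (all pairwise DiffTables vs base, with a `pair` column), `n_completed`.
#' @export
run_ensemble <- function(inputs, scenarios = build_scenarios(), n_outer = 20,
                         n_inner = 50000, master_seed = 1L, scalers = NULL,
                         years = NULL, shared_params = TRUE) {
  stopifnot(n_outer >= 1)
  if (is.null(years)) years <- sort(unique(inputs$population$year))
  outcomes <- list(); diffs <- list(); completed <- 0L
  for (d in seq_len(n_outer)) {
    res <- tryCatch({
      draw <- draw_parameters(inputs, d, master_seed)
      pop_seed <- derive_seed(master_seed, "pop", d)
      cohort <- build_cohort(inputs$population, inputs$epi, inputs$models,
                             n_inner = n_inner, year0 = min(years), seed = pop_seed)
      std <- .std_quantiles(inputs$models, cohort)
      exp_cache <- new.env(parent = emptyenv())
      outs <- list()
      k <- 0L
      for (sc in scenarios) {
        k <- k + 1L
        dr <- if (shared_params || identical(sc$name, "base")) draw else {
          draw_parameters(inputs, d + k * 10000L, master_seed)
        }
        outs[[sc$name]] <- run_scenario(inputs, sc, cohort, scalers = scalers,
                                        seed = pop_seed, years = years,
                                        param_draw = dr, outer_iter = d, std = std,
                                        exp_cache = exp_cache)
      }
      dl <- list()
      for (nm in setdiff(names(outs), "base")) {
        dd <- diff_scenarios(outs$base, outs[[nm]], econ = inputs$econ)
        dd[, pair := paste0(nm, "_vs_base")]
        dl[[nm]] <- dd
      }
      list(out = data.table::rbindlist(outs), diff = data.table::rbindlist(dl))
    }, error = function(e) {
      warning("outer draw ", d, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      completed <- completed + 1L
      outcomes[[d]] <- res$out
      diffs[[d]] <- res$diff
    }
  }
  list(outcomes = data.table::rbindlist(outcomes),
       diffs = data.table::rbindlist(diffs),
       n_completed = completed)
}

#' Summarise per-draw results as median and 95% uncertainty interval
#'
#' Empirical 2.5/50/97.5 percentiles across outer draws (linear
#' interpolation, quantile type 7), per group.
#'
#' @param per_draw A long table with one row per outer draw per cell.
#' @param measures Columns to summarise.
#' @param by Grouping columns (e.g. `c("pair", "sex", "cumulative")`).
#' @return A `data.table` with `measure`, the grouping columns, `median`,
#'   `lo95`, `hi95`.
#' @export
summarise_ensemble <- function(per_draw,
                               measures = intersect(
                                 c("cpp_chd", "cpp_stroke", "cypp_chd", "cypp_stroke",
                                   "dpp", "net_qalys",
                                   "saved_direct_chd_jpy", "saved_direct_stroke_jpy",
                                   "saved_indirect_chd_jpy", "saved_indirect_stroke_jpy"),
                                 names(per_draw)),
                               by = intersect(c("pair", "sex", "cumulative"),
                                              names(per_draw))) {
  per_draw <- data.table::as.data.table(per_draw)
  out <- list()
  for (m in measures) {
    g <- per_draw[, .(
      median = quantile(.SD[[1]], 0.5, type = 7, names = FALSE),
      lo95 = quantile(.SD[[1]], 0.025, type = 7, names = FALSE),
      hi95 = quantile(.SD[[1]], 0.975, type = 7, names = FALSE)
    ), by = by, .SDcols = m]
    g[, measure := m]
    out[[m]] <- g
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("measure", by))
  res[]
}
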