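# Open-cohort population engine.
#
# The cohort universe -- every person who will ever exist across 2001-2019,
# including future 30-year-old entrants -- is constructed up front from the
# population-count table alone, so person ids, entry times, weights and
# lifetime ranks are identical across scenarios (the common-random-numbers
# contract). Scenario-dependent state (disease, death) lives in a separate
# state table initialised per run.

#' Build the simulation cohort
#'
#' Individuals are allocated across (age, sex) strata proportional to the
#' baseline-year counts (largest-remainder rounding) with weight =
#' stratum count / persons allocated, so weights sum exactly to the stratum
#' counts. Entrants at the youngest simulated age are pre-allocated for every
#' later year with weights matching the count table. Lifetime ranks are drawn
#' from the model set's rank-dependence structure; baseline disease
#' prevalence is seeded by Bernoulli draws from the 2001 prevalence.
#'
#' @param pop Population-count table from [generate_population_counts()].
#' @param epi Epi table from [generate_epi_inputs()] (for baseline
#'   prevalence); may be `NULL` for a disease-free cohort.
#' @param models An `exposure_model_set` (for the rank-dependence matrix); if
#'   `NULL`, independent ranks are drawn.
#' @param n_inner Number of synthetic individuals at baseline (>= 1000).
#' @param year0 Baseline year.
#' @param seed Population seed; also indexes all event streams.
#' @return A `cvd_cohort` data.table: id, sex, birth_year, entry_year,
#'   weight, rank columns, and baseline prevalence flags.
#' @export
build_cohort <- function(pop, epi = NULL, models = NULL, n_inner = 20000,
                         year0 = 2001, seed = 1L) {
  if (n_inner < 1000) stop("n_inner must be >= 1000")
  pop <- data.table::as.data.table(pop)
  strata <- pop[year == year0][order(sex, age)]
  if (!nrow(strata)) stop("population table has no rows for year ", year0)
  if (any(strata$count_thousands < 0)) stop("negative population counts")
  tot <- sum(strata$count_thousands)
  exact <- n_inner * strata$count_thousands / tot
  n_j <- floor(exact)
  rem <- n_inner - sum(n_j)
  if (rem > 0) {
    o <- order(exact - n_j, decreasing = TRUE)[seq_len(rem)]
    n_j[o] <- n_j[o] + 1L
  }
  if (any(n_j == 0 & strata$count_thousands > 0)) {
    # guarantee coverage of populated strata
    need <- which(n_j == 0 & strata$count_thousands > 0)
    n_j[need] <- 1L
  }
  base <- strata[rep(seq_len(nrow(strata)), n_j)]
  base[, weight := count_thousands / n_j[rep(seq_len(nrow(strata)), n_j)]]
  base[, entry_year := year0]
  base[, birth_year := year0 - age]

  # entrants at the youngest simulated age, every later year
  age_min <- min(strata$age)
  w_ref <- vapply(SEXES, function(s) median(base[sex == s, weight]), numeric(1))
  later <- sort(unique(pop$year))
  later <- later[later > year0]
  ent <- list()
  for (y in later) {
    for (s in SEXES) {
      cnt <- pop[year == y & age == age_min & sex == s, count_thousands]
      if (!length(cnt) || cnt <= 0) next
      ne <- max(1L, as.integer(round(cnt / w_ref[[s]])))
      ent[[paste(y, s)]] <- data.table::data.table(
        year = y, age = age_min, sex = s, count_thousands = cnt,
        weight = cnt / ne, entry_year = y, birth_year = y - age_min
      )[rep(1L, ne)]
    }
  }
  cohort <- data.table::rbindlist(c(list(base), ent), use.names = TRUE)
  cohort[, c("year", "count_thousands") := NULL]
  cohort[, id := seq_len(.N)]

  # lifetime ranks from the rank-dependence structure
  R <- if (!is.null(models)) models$rank_dependence else diag(1, length(RANK_DIMS))
  dimnames(R) <- list(RANK_DIMS, RANK_DIMS)
  ch <- chol(R)
  n <- nrow(cohort)
  U <- .with_seed(derive_seed(seed, "ranks"), {
    pnorm(matrix(rnorm(n * nrow(R)), n, nrow(R)) %*% ch)
  })
  U <- pmin(pmax(U, 1e-9), 1 - 1e-9)
  colnames(U) <- paste0("rank_", RANK_DIMS)
  cohort <- cbind(cohort, data.table::as.data.table(U))

  # baseline disease prevalence for the year0 cohort
  cohort[, `:=`(init_chd = FALSE, init_stroke = FALSE)]
  if (!is.null(epi)) {
    epi <- data.table::as.data.table(epi)
    for (d in DISEASES) {
      pv <- epi[measure == "prevalence" & disease == d & year == year0,
                .(age, sex, value)]
      idx0 <- cohort$entry_year == year0
      m <- pv[cohort[idx0], on = c("age" = "age", "sex" = "sex")]
      # age column: cohort age at entry
      u <- event_uniforms(seed, year0 - 1L, paste0("init_", d), n)[cohort$id[idx0]]
      cohort[[paste0("init_", d)]][idx0] <- u < m$value
    }
  }
  cohort[, age := NULL]
  data.table::setattr(cohort, "seed", seed)
  data.table::setattr(cohort, "year0", year0)
  data.table::setattr(cohort, "class", c("cvd_cohort", class(cohort)))
  cohort[]
}

# initialise the mutable per-scenario state from a cohort
.init_state <- function(cohort, year0 = attr(cohort, "year0")) {
  st <- data.table::as.data.table(cohort)
  data.table::setattr(st, "class", c("data.table", "data.frame"))
  st <- st[entry_year <= year0]
  st[, `:=`(
    alive = TRUE,
    chd = init_chd, chd_onset = ifelse(init_chd, year0 - 1L, NA_integer_),
    stroke = init_stroke, stroke_onset = ifelse(init_stroke, year0 - 1L, NA_integer_),
    death_year = NA_integer_, death_cause = NA_character_
  )]
  st
}

#' Advance the cohort state by one year
#'
#' Survivors age by one year (implicitly, via `year - birth_year`); persons
#' exceeding the maximum simulated age exit the active population; new
#' entrants for `year + 1` join disease-free with their pre-allocated weights
#' and ranks. Dead persons are retained for accounting.
#'
#' @param state A state table (from an ongoing run).
#' @param year The year just simulated.
#' @param cohort The `cvd_cohort` the run was built from.
#' @param age_max Maximum simulated age (exit above this).
#' @return The updated state table.
#' @export
advance_year <- function(state, year, cohort, age_max = 99) {
  newc <- data.table::as.data.table(cohort)
  data.table::setattr(newc, "class", c("data.table", "data.frame"))
  newc <- newc[entry_year == year + 1L]
  if (nrow(newc)) {
    newc[, `:=`(alive = TRUE, chd = FALSE, chd_onset = NA_integer_,
                stroke = FALSE, stroke_onset = NA_integer_,
                death_year = NA_integer_, death_cause = NA_character_)]
    state <- data.table::rbindlist(list(state, newc), use.names = TRUE)
  }
  state
}

# active = alive and within the simulated age range in `year`
.active_idx <- function(state, year, age_min = 30, age_max = 99) {
  state$alive & (year - state$birth_year) >= age_min &
    (year - state$birth_year) <= age_max
}
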