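# Counter-based random streams.
#
# Cross-scenario common random numbers require that the uniform deciding a
# given (person, year, event) is identical no matter which scenario is being
# run and no matter how many persons happen to be alive. Streams are therefore
# indexed: for each (year, event) a deterministic seed is derived and a vector
# of uniforms over *all person ids ever created* is generated; scenarios then
# subset by id. The set of ids is scenario-invariant because cohort entry is
# driven by the population-count table alone.

EVENT_CODES <- c(
  chd_incidence = 1L, stroke_incidence = 2L, death = 3L,
  init_chd = 4L, init_stroke = 5L
)

#' Derive a child seed from a master seed and a stream label
#'
#' Deterministic, order-free seed derivation so that independent parts of the
#' pipeline (cohort build, parameter draws, per-year event draws) get
#' non-overlapping streams from one master seed. Kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param ... Character or integer stream labels.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  labs <- unlist(list(...), use.names = FALSE)
  h <- as.double(seed) %% 2147483647
  for (lab in labs) {
    codes <- if (is.character(lab)) utf8ToInt(lab) else as.integer(lab) + 7919L
    for (cc in codes) h <- (h * 69069 + cc * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(h)
}

#' Uniform draws indexed by (seed, year, event) for a fixed id universe
#'
#' Returns `n_ids` uniforms such that element `i` is the draw for person id
#' `i` in the given year and event slot. Identical arguments give identical
#' draws, which is the common-random-numbers contract shared by all scenarios.
#'
#' @param seed Integer master population seed.
#' @param year Calendar year of the event.
#' @param event Event name (one of `names(EVENT_CODES)`) or integer code.
#' @param n_ids Total number of person ids in the cohort universe.
#' @return Numeric vector of `n_ids` uniforms in (0,1).
#' @export
event_uniforms <- function(seed, year, event, n_ids) {
  code <- if (is.character(event)) EVENT_CODES[[event]] else as.integer(event)
  s <- derive_seed(seed, "event", as.integer(year), code)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(s)
  runif(n_ids)
}

# Save/restore the global RNG state so library internals do not perturb
# user-level set.seed() reproducibility.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr with a local RNG seeded at `seed`, restoring global state after.
.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}
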