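# Health-economic valuation: QALY weights, cost-of-illness accounting, and
# currency conversion. All amounts are carried in JPY internally; USD is
# derived at reporting time only. No discounting anywhere (retrospective
# analysis).

#' Annual utility weight for a person-year
#'
#' Utility = max(0, age/sex norm - sum of disutilities of active
#' conditions). Diabetes is proxied by current-year HbA1c exceeding the
#' configured threshold.
#'
#' @param age,sex Vectors over persons.
#' @param chd,stroke,diabetes Logical vectors of active conditions.
#' @param econ An `econ_inputs`.
#' @return Utility weights in \[0, 1\].
#' @export
person_year_utility <- function(age, sex, chd, stroke, diabetes, econ) {
  ag <- econ$utility$agegroup_low
  u <- numeric(length(age))
  for (s in SEXES) {
    i <- which(sex == s)
    if (!length(i)) next
    us <- econ$utility[sex == s][order(agegroup_low)]
    bin <- findInterval(age[i], sort(unique(us$agegroup_low)))
    bin[bin < 1] <- 1
    u[i] <- us$utility[bin]
  }
  d <- econ$disutility
  u <- u - chd * d[["chd"]] - stroke * d[["stroke"]] - diabetes * d[["diabetes"]]
  pmax(u, 0)
}

#' Attach annual cost columns to an OutcomeTable
#'
#' Direct costs accrue per prevalent case-year; indirect costs are an
#' informal-care component at all ages plus a productivity component below
#' age 65. Case-year columns are in thousands of person-years; costs are in
#' JPY.
#'
#' @param out An OutcomeTable with case-year columns (total and under-65).
#' @param econ An `econ_inputs`.
#' @return The table with `direct_*_jpy` and `indirect_*_jpy` columns added.
#' @export
annual_costs <- function(out, econ) {
  out <- data.table::as.data.table(out)
  uc <- econ$unit_costs
  get_uc <- function(d, s, comp) uc[disease == d & sex == s & component == comp,
                                    jpy_per_case_year]
  for (d in DISEASES) {
    dcol <- paste0("direct_", d, "_jpy")
    icol <- paste0("indirect_", d, "_jpy")
    cy <- out[[paste0("caseyears_", d)]] * 1e3
    cy65 <- out[[paste0("caseyears_", d, "_lt65")]] * 1e3
    cd <- ci <- cp <- numeric(nrow(out))
    for (s in SEXES) {
      i <- which(out$sex == s)
      cd[i] <- get_uc(d, s, "direct")
      ci[i] <- get_uc(d, s, "indirect_informal")
      cp[i] <- get_uc(d, s, "indirect_productivity")
    }
    out[[dcol]] <- cy * cd
    out[[icol]] <- cy * ci + cy65 * cp
  }
  out[]
}

#' Convert JPY to USD
#'
#' @param amount_jpy Amounts in JPY.
#' @param usd_per_1000_jpy Exchange rate (USD per 1000 JPY).
#' @return Amounts in USD. Exactly linear; no discounting is applied
#'   anywhere in the pipeline.
#' @export
jpy_to_usd <- function(amount_jpy, usd_per_1000_jpy = 10.56) {
  if (usd_per_1000_jpy <= 0) stop("exchange rate must be positive")
  amount_jpy * usd_per_1000_jpy / 1000
}

#' Consistency of a printed JPY/USD cell pair under an exchange rate
#'
#' Two printed cells (each rounded to 2 significant figures) are consistent
#' if some unrounded JPY amount rounds to the printed JPY cell while its USD
#' conversion rounds to the printed USD cell, i.e. if the conversion of the
#' JPY rounding interval overlaps the USD rounding interval.
#'
#' @param jpy,usd Printed amounts (same unit prefix, e.g. billions).
#' @param usd_per_1000_jpy Exchange rate.
#' @return Logical.
#' @export
jpy_usd_pair_consistent <- function(jpy, usd, usd_per_1000_jpy = 10.56) {
  half <- function(x) 10^(floor(log10(abs(x))) - 1) / 2  # half-ulp at 2 sig figs
  j_lo <- jpy - half(jpy); j_hi <- jpy + half(jpy)
  u_lo <- usd - half(usd); u_hi <- usd + half(usd)
  c_lo <- jpy_to_usd(j_lo, usd_per_1000_jpy)
  c_hi <- jpy_to_usd(j_hi, usd_per_1000_jpy)
  c_lo <= u_hi && c_hi >= u_lo
}
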