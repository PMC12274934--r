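# Internal registry of the seven modelled risk factors.
#
# Continuous factors use one of two location-scale families:
#   lognormal3 : shifted log-normal, value = shift + exp(N(mu, sigma))
#   gamma      : gamma parameterised by (mean, shape)
# Smoking is a three-state categorical (never/past/current) plus a count of
# cigarettes per day for current smokers (unit-shifted negative binomial).

FACTORS <- c("sbp", "smoking", "ldl", "hba1c", "bmi", "pa", "fv")
CONTINUOUS_FACTORS <- setdiff(FACTORS, "smoking")

# latent-rank dimensions: one per factor plus one for cigarettes/day
RANK_DIMS <- c("sbp", "ldl", "bmi", "hba1c", "pa", "fv", "smoking", "cig")

FACTOR_FAMILY <- c(
  sbp = "lognormal3", ldl = "lognormal3", bmi = "lognormal3",
  hba1c = "gamma", pa = "gamma", fv = "gamma",
  smoking = "multinomial_count"
)

# fixed lower support bound of the shifted log-normal families
FACTOR_SHIFT <- c(sbp = 60, ldl = 30, bmi = 10)

FACTOR_UNITS <- c(
  sbp = "mmHg", ldl = "mg/dL", bmi = "kg/m2", hba1c = "%",
  pa = "times/day", fv = "g/day", smoking = "status"
)

SEXES <- c("male", "female")
DISEASES <- c("chd", "stroke")

.assert_sex <- function(sex) {
  if (!all(sex %in% SEXES)) stop("sex must be one of: ", paste(SEXES, collapse = ", "))
  invisible(sex)
}

.assert_factor <- function(factor_name) {
  if (!factor_name %in% FACTORS) {
    stop("unknown factor '", factor_name, "'; expected one of: ",
         paste(FACTORS, collapse = ", "))
  }
  invisible(factor_name)
}
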