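#' Survey codebook: dimensions and their levels
#'
#' The analysis data model mirrors an English national health examination
#' survey: nine Government Office Regions, five Index of Multiple Deprivation
#' (IMD) quintiles, six deprivation-ordered occupational classes (NS-SEC),
#' eight deprivation-ordered educational-qualification levels (NVQ-based),
#' seven adult age bands, and binary/nominal person characteristics.
#'
#' For the three deprivation scales the integer coding increases with
#' deprivation: `imd_quintile` 1 = least deprived neighbourhood quintile,
#' 5 = most deprived; `occupation` 1 = managerial/professional through
#' 6 = "other"; `education` 1 = degree-level through 8 = full-time student.
#'
#' @return Named list of character vectors, one per dimension, giving the
#'   declared levels in coding order.
#' @export
#' @examples
#' names(survey_codebook())
#' survey_codebook()$imd_quintile
survey_codebook <- function() {
  list(
    region = c(
      "North East", "North West", "Yorkshire and The Humber",
      "East Midlands", "West Midlands", "East of England",
      "London", "South East", "South West"
    ),
    age_group = c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+"),
    gender = c("male", "female"),
    ethnicity = c("white", "mixed", "asian", "black", "other"),
    education = as.character(1:8),
    occupation = as.character(1:6),
    imd_quintile = as.character(1:5),
    limiting_illness = c("0", "1"),
    marital_status = c("single", "married", "cohabiting", "separated", "widowed"),
    urbanicity = c("0", "1")
  )
}

## deprivation-ordered scales: higher integer code = more deprived
deprivation_dimensions <- function() c("imd_quintile", "occupation", "education")

## all covariate dimensions (everything except outcome/weight columns)
all_dimensions <- function() names(survey_codebook())

## columns a SurveyTable must carry
survey_columns <- function() {
  c("id", "bmi", "excess_weight", "obese", "morbid",
    all_dimensions(), "design_weight", "responded")
}
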