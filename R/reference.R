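#' Reference coefficient table for the odds-ratio arithmetic
#'
#' Coefficient and standard-error pairs, with the odds ratios and 95
#' percent confidence bounds printed alongside them, as reported by a
#' published community study of confidant-network depressive-symptom
#' homophily in older adults (n = 660; the motivating application of
#' this package). They serve two purposes: validating the
#' [or_ci()] reporting transform against independently printed values,
#' and providing realistic coefficient magnitudes for examples.
#'
#' `consistent` flags rows whose printed OR and CI agree with
#' exp-transforming their own printed coefficient and SE at two
#' decimals; a handful of printed cells do not (presumably typesetting
#' slips in the source table), and only consistent rows should be used
#' to check arithmetic.
#'
#' @return Data frame: `model` ("overall", "apathy",
#'   "suicidal_ideation"), `term`, `coefficient`, `se`, `or_printed`,
#'   `ci_lower_printed`, `ci_upper_printed` (NA for structural terms,
#'   whose ORs are not reported), `consistent`.
#' @export
reference_estimates <- function() {
  df <- read.csv(text = '
model,term,coefficient,se,or_printed,ci_lower_printed,ci_upper_printed,consistent
overall,absdiff.gds_total,-0.052,0.029,0.95,0.90,1.00,TRUE
overall,nodal.female,0.01,0.12,1.01,0.80,1.28,TRUE
overall,nodal.age_ge75,0.13,0.13,1.14,0.88,1.47,TRUE
overall,nodal.lives_with_family,-0.19,0.18,0.83,0.58,1.18,TRUE
overall,nodal.disability,0.38,0.14,1.46,1.11,1.92,TRUE
overall,nodal.edu_10_12,0.07,0.12,1.07,0.85,1.36,TRUE
overall,nodal.edu_13plus,-0.001,0.14,1.00,0.76,1.31,TRUE
overall,nodal.gds_total,0.0066,0.018,1.01,0.97,1.04,TRUE
overall,edges,-8.67,0.37,NA,NA,NA,NA
overall,mutual,8.02,0.46,NA,NA,NA,NA
apathy,absdiff.apathy,-0.21,0.099,0.81,0.67,0.98,TRUE
apathy,nodal.female,0.07,0.13,1.07,0.83,1.40,FALSE
apathy,nodal.age_ge75,-1.45,0.15,0.23,0.17,0.31,TRUE
apathy,nodal.lives_with_family,0.65,0.18,1.92,1.30,2.73,FALSE
apathy,nodal.disability,0.38,0.17,1.46,1.00,2.04,FALSE
apathy,nodal.edu_10_12,0.13,0.16,1.14,0.83,1.56,TRUE
apathy,nodal.edu_13plus,0.35,0.2,1.42,0.96,2.10,TRUE
apathy,nodal.apathy,0.22,0.074,1.24,1.07,1.44,FALSE
apathy,edges,-8.5,0.48,NA,NA,NA,NA
apathy,mutual,25.41,0.22,NA,NA,NA,NA
suicidal_ideation,absdiff.suicidal_ideation,-0.0043,0.07,1.00,0.87,1.14,TRUE
suicidal_ideation,nodal.female,0.01,0.11,1.01,0.81,1.25,TRUE
suicidal_ideation,nodal.age_ge75,0.17,0.11,1.19,0.96,1.47,TRUE
suicidal_ideation,nodal.lives_with_family,-0.09,0.13,0.91,0.71,1.18,TRUE
suicidal_ideation,nodal.disability,0.35,0.12,1.42,1.10,1.80,FALSE
suicidal_ideation,nodal.edu_10_12,0.17,0.13,1.19,0.92,1.53,TRUE
suicidal_ideation,nodal.edu_13plus,0.25,0.16,1.28,0.94,1.76,TRUE
suicidal_ideation,nodal.suicidal_ideation,0.058,0.04,1.06,0.98,1.15,TRUE
suicidal_ideation,edges,-9.2,0.27,NA,NA,NA,NA
suicidal_ideation,mutual,8.6,0.23,NA,NA,NA,NA
', stringsAsFactors = FALSE, strip.white = TRUE)
  df
}
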