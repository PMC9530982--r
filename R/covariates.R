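#' Code the analysis covariates for one survey roster
#'
#' Applies the reference codings used throughout the models:
#' \describe{
#'   \item{female}{1 = female (reference male).}
#'   \item{age_ge75}{1 = age 75 or older (reference under 75; the boundary
#'     age 75 codes 1, a literal reading of "ref: <75 years-old").}
#'   \item{lives_with_family}{1 = household of two or more persons, i.e.
#'     at least one listed household member (reference living alone).}
#'   \item{disability}{1 = TMIG-IC score below the full 13
#'     (see [code_disability()]); `NA` when items are missing.}
#'   \item{edu_10_12, edu_13plus}{education dummies against the reference
#'     "9 years or less"; the band "other" (including unknown) yields `NA`
#'     dummies and is dropped listwise at model time unless
#'     `edu_other_as_category = TRUE`, which instead codes both dummies 0
#'     and adds an `edu_other` indicator.}
#'   \item{smc_score}{subjective memory complaint total, 4-28
#'     (see [score_smc()]); `NA` when items are missing.}
#' }
#'
#' @param participants Participant table (one row per respondent) with
#'   columns `participant_id`, `sex` ("male"/"female"), `age`,
#'   `education_band` (one of "<6", "6-9", "10-12", "13+", "other"), GDS
#'   item columns `gds_01`..`gds_15`, SMC item columns `smc_1`..`smc_4`,
#'   and TMIG-IC columns `tmig_01`..`tmig_13` (item columns optional; the
#'   corresponding scores are `NA` when absent).
#' @param household_members Optional household-member listing (one row per
#'   listed co-resident) with a `participant_id` column naming the
#'   respondent who listed the member. Used for `lives_with_family`.
#' @param edu_other_as_category Keep "other" education as its own
#'   indicator instead of coding it missing.
#' @return A data frame keyed by `participant_id` with the covariates
#'   above plus `gds_total`, `apathy` and `suicidal_ideation`.
#' @export
code_covariates <- function(participants, household_members = NULL,
                            edu_other_as_category = FALSE) {
  stopifnot(is.data.frame(participants))
  req <- c("participant_id", "sex", "age", "education_band")
  missing_cols <- setdiff(req, names(participants))
  if (length(missing_cols)) {
    stop("participants table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant_id in participants table")
  }
  if (any(participants$age < 65, na.rm = TRUE)) {
    stop("roster contains ages below 65; the survey population is 65+")
  }
  sex <- tolower(as.character(participants$sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  band <- as.character(participants$education_band)
  known <- c("<6", "6-9", "10-12", "13+", "other")
  if (!all(band %in% known)) {
    stop("unknown education_band value(s): ",
         paste(setdiff(unique(band), known), collapse = ", "))
  }
  edu_10_12 <- as.integer(band == "10-12")
  edu_13plus <- as.integer(band == "13+")
  edu_other <- as.integer(band == "other")
  if (!edu_other_as_category) {
    edu_10_12[band == "other"] <- NA_integer_
    edu_13plus[band == "other"] <- NA_integer_
  }

  n_members <- integer(nrow(participants))
  if (!is.null(household_members) && nrow(household_members)) {
    tab <- table(household_members$participant_id)
    idx <- match(participants$participant_id, names(tab))
    n_members <- ifelse(is.na(idx), 0L, as.integer(tab[idx]))
  }

  gds <- item_block(participants, "gds", 15L)
  scores <- if (is.null(gds)) {
    data.frame(gds_total = NA_integer_, apathy = NA_integer_,
               suicidal_ideation = NA_integer_)[rep(1, nrow(participants)), ]
  } else {
    score_gds(gds)
  }
  smc <- item_block(participants, "smc", 4L)
  tmig <- item_block(participants, "tmig", 13L)

  out <- data.frame(
    participant_id = as.character(participants$participant_id),
    female = as.integer(sex == "female"),
    age_ge75 = as.integer(participants$age >= 75),
    lives_with_family = as.integer(n_members >= 1L),
    disability = if (is.null(tmig)) NA_integer_ else code_disability(tmig),
    edu_10_12 = edu_10_12,
    edu_13plus = edu_13plus,
    smc_score = if (is.null(smc)) NA_integer_ else score_smc(smc),
    gds_total = scores$gds_total,
    apathy = scores$apathy,
    suicidal_ideation = scores$suicidal_ideation,
    stringsAsFactors = FALSE
  )
  if (edu_other_as_category) out$edu_other <- edu_other
  rownames(out) <- NULL
  out
}

# pull columns <prefix>_1.. or zero-padded <prefix>_01.. from a table;
# NULL when the block is absent
item_block <- function(df, prefix, n) {
  padded <- sprintf("%s_%02d", prefix, seq_len(n))
  plain <- sprintf("%s_%d", prefix, seq_len(n))
  cols <- if (all(padded %in% names(df))) padded
          else if (all(plain %in% names(df))) plain
          else return(NULL)
  df[, cols, drop = FALSE]
}
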