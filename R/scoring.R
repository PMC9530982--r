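#' GDS-15 item key
#'
#' Returns the scoring key for the 15-item Geriatric Depression Scale:
#' the item wording, the response scored as symptomatic (standard keying:
#' positively worded items -- e.g. "full of energy", "happy most of the
#' time", "wonderful to be alive" -- score on "no", negatively worded items
#' on "yes"), and the subscale membership. The three-item apathy subscale
#' (range 0-3) and the five-item suicidal-ideation subscale (range 0-5)
#' are disjoint subsets of the 15 items.
#'
#' The key is returned as a data frame so an alternative keying can be
#' passed to [score_gds()] if a different instrument version is in use.
#'
#' @return A data frame with columns `item` (1-15), `wording`,
#'   `symptomatic` ("yes" or "no") and `subscale`
#'   ("apathy", "suicidal_ideation" or NA).
#' @export
gds_item_key <- function() {
  data.frame(
    item = 1:15,
    wording = c(
      "Are you basically satisfied with your life?",
      "Have you dropped many of your activities and interests?",
      "Do you feel that your life is empty?",
      "Do you often get bored?",
      "Are you in good spirits most of the time?",
      "Are you afraid that something bad is going to happen to you?",
      "Do you feel happy most of the time?",
      "Do you often feel helpless?",
      "Do you prefer to stay at home rather than go out and do new things?",
      "Do you feel you have more problems with memory than most?",
      "Do you think it is wonderful to be alive now?",
      "Do you feel pretty worthless the way you are now?",
      "Do you feel full of energy?",
      "Do you feel that your situation is hopeless?",
      "Do you think that most people are better off than you are?"
    ),
    # items 1, 5, 7, 11, 13 are positively worded: "no" is symptomatic
    symptomatic = c("no", "yes", "yes", "yes", "no", "yes", "no", "yes",
                    "yes", "yes", "no", "yes", "no", "yes", "yes"),
    subscale = c(NA, "apathy", "suicidal_ideation", NA, NA, NA,
                 "suicidal_ideation", NA, "apathy", NA,
                 "suicidal_ideation", "suicidal_ideation", "apathy",
                 "suicidal_ideation", NA),
    stringsAsFactors = FALSE
  )
}

#' Score the GDS-15 and its subscales
#'
#' Each of the 15 dichotomous items contributes one point when answered in
#' the symptomatic direction. The total ranges 0-15 (higher = more
#' depressive symptoms); the apathy subscale sums the three apathy items
#' (0-3) and the suicidal-ideation subscale the five suicidal-ideation
#' items (0-5).
#'
#' Missing responses never zero-fill: any missing item yields `NA` scores,
#' and the participant is excluded from the analysis set downstream.
#'
#' @param items Responses to the 15 items, in item order. Either a
#'   character vector of "yes"/"no" (case-insensitive; `NA` allowed) or a
#'   matrix/data.frame with 15 columns, one row per participant.
#' @param key Item key as returned by [gds_item_key()].
#' @return A data frame with columns `gds_total`, `apathy`,
#'   `suicidal_ideation`, one row per participant.
#' @examples
#' key <- gds_item_key()
#' score_gds(key$symptomatic)             # all symptomatic: 15, 3, 5
#' @export
score_gds <- function(items, key = gds_item_key()) {
  m <- as_item_matrix(items, 15L, "GDS")
  resp <- tolower(trimws(m))
  bad <- !is.na(resp) & !(resp %in% c("yes", "no"))
  if (any(bad)) {
    stop("GDS responses must be 'yes', 'no' or NA; got: ",
         paste(unique(m[bad]), collapse = ", "))
  }
  sympt <- matrix(rep(key$symptomatic, each = nrow(resp)), nrow = nrow(resp))
  pts <- (resp == sympt) * 1L        # NA propagates
  total <- rowSums(pts)
  apathy_cols <- which(!is.na(key$subscale) & key$subscale == "apathy")
  si_cols <- which(!is.na(key$subscale) & key$subscale == "suicidal_ideation")
  out <- data.frame(
    gds_total = total,
    apathy = rowSums(pts[, apathy_cols, drop = FALSE]),
    suicidal_ideation = rowSums(pts[, si_cols, drop = FALSE])
  )
  # any missing item invalidates the total and both subscales
  out[is.na(total), ] <- NA_integer_
  out
}

#' Score the subjective memory complaint (SMC) scale
#'
#' Four frequency items, each scored 1-7 (higher = more frequent
#' forgetfulness: a person's name, a place, a plan, today's date), are
#' summed to a total in 4-28; higher indicates a higher degree of
#' subjective memory complaint. A separate severe-problem indicator (e.g.
#' forgetting to turn off the stove) is accepted but carried as metadata
#' only; it does not enter the score.
#'
#' @param items A length-4 numeric vector or a 4-column matrix/data.frame
#'   of item responses in 1-7.
#' @return Integer total(s) in 4-28; `NA` when any item is missing.
#' @export
score_smc <- function(items) {
  m <- as_item_matrix(items, 4L, "SMC")
  storage.mode(m) <- "double"
  if (any(!is.na(m) & (m < 1 | m > 7 | m != round(m)))) {
    stop("SMC items must be integers in 1..7")
  }
  as.integer(rowSums(m))
}

#' Code disability from the TMIG Index of Competence
#'
#' The 13-item Tokyo Metropolitan Institute of Gerontology Index of
#' Competence scores one point per independently performed activity.
#' Anything less than the full score of 13 is coded as disability.
#'
#' @param items A length-13 binary vector or 13-column matrix/data.frame.
#' @return 0 (full score, no disability) or 1 per participant; `NA` when
#'   any item is missing.
#' @export
code_disability <- function(items) {
  m <- as_item_matrix(items, 13L, "TMIG-IC")
  storage.mode(m) <- "double"
  if (any(!is.na(m) & !(m %in% c(0, 1)))) {
    stop("TMIG-IC items must be 0/1")
  }
  as.integer(rowSums(m) < 13)
}

#' Absolute-difference similarity of two symptom scores
#'
#' The dyadic dissimilarity used in the homophily terms: the absolute
#' difference of the two nodes' scores. Symmetric, zero iff equal.
#'
#' @param score_i,score_j Numeric scores (vectorised).
#' @return Non-negative absolute difference(s).
#' @export
score_similarity <- function(score_i, score_j) {
  if (any(is.na(score_i)) || any(is.na(score_j))) {
    stop("score_similarity requires non-missing scores; ",
         "pairs with missing scores must be excluded upstream")
  }
  abs(score_i - score_j)
}

# coerce vector / data.frame input to a character or numeric matrix with
# a fixed number of columns, one row per participant
as_item_matrix <- function(items, n_items, label) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) {
    if (length(items) != n_items) {
      stop(label, " expects ", n_items, " items, got ", length(items))
    }
    items <- matrix(items, nrow = 1L)
  }
  if (ncol(items) != n_items) {
    stop(label, " expects ", n_items, " item columns, got ", ncol(items))
  }
  items
}
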