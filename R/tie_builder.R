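#' Tie-identification rule set
#'
#' Parameters of the two-step confidant identification procedure.
#'
#' @param poor_satisfaction_threshold Marital-satisfaction score strictly
#'   above which satisfaction counts as "poor" on the 10-point Likert
#'   scale. The default orientation takes higher scores as more
#'   dissatisfied (a literal "more than six points" reading); set
#'   `higher_is_dissatisfied = FALSE` for the opposite orientation, in
#'   which case scores strictly below `11 - threshold` count as poor.
#' @param higher_is_dissatisfied Orientation of the satisfaction scale.
#' @param spouse_age_gap Household exception window: for a respondent with
#'   poor marital satisfaction who reports having no confidants, ties to
#'   opposite-sex co-residents with an age difference strictly below this
#'   many years are suppressed.
#' @param nomination_age_gap Community-matching criterion (3): candidate
#'   age may differ from the nominator's by at most this many years.
#' @param member_age_tol Household-member resolution: listed age may
#'   differ from the roster age by at most this many years.
#' @return A list of class `tie_rules`.
#' @export
tie_rules <- function(poor_satisfaction_threshold = 6,
                      higher_is_dissatisfied = TRUE,
                      spouse_age_gap = 15,
                      nomination_age_gap = 3,
                      member_age_tol = 1) {
  structure(list(
    poor_satisfaction_threshold = poor_satisfaction_threshold,
    higher_is_dissatisfied = higher_is_dissatisfied,
    spouse_age_gap = spouse_age_gap,
    nomination_age_gap = nomination_age_gap,
    member_age_tol = member_age_tol
  ), class = "tie_rules")
}

# exact-match name normalisation: Unicode NFC + whitespace trim;
# empty strings become NA so they can never match anything
normalize_name <- function(x) {
  x <- trimws(as.character(x))
  x <- stringi::stri_trans_nfc(x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

name_cols <- c("family_name_kanji", "given_name_kanji",
               "family_name_kana", "given_name_kana")

# TRUE where the full name of `a` (row-wise) equals the full name of `b`
# in the kanji rendering OR the kana rendering; absent fields never match
full_name_match <- function(a_family_kanji, a_given_kanji,
                            a_family_kana, a_given_kana,
                            b_family_kanji, b_given_kanji,
                            b_family_kana, b_given_kana) {
  eq <- function(x, y) !is.na(x) & !is.na(y) & x == y
  (eq(a_family_kanji, b_family_kanji) & eq(a_given_kanji, b_given_kanji)) |
    (eq(a_family_kana, b_family_kana) & eq(a_given_kana, b_given_kana))
}

is_poor_satisfaction <- function(score, rules) {
  ifelse(is.na(score), FALSE,
         if (rules$higher_is_dissatisfied) {
           score > rules$poor_satisfaction_threshold
         } else {
           score < 11 - rules$poor_satisfaction_threshold
         })
}

#' Identify household confidant ties for one respondent
#'
#' Step one of tie identification: every co-residing participant is a
#' confidant of the respondent, unless the respondent reports poor marital
#' satisfaction together with having no confidants, in which case ties to
#' opposite-sex co-residents within the spouse age-gap window (default
#' under 15 years of age difference) are suppressed.
#'
#' Listed household members are resolved to roster participants by shared
#' `household_id`, exact full-name equality (kanji or kana rendering) and
#' sex/age agreement (age within `member_age_tol`); members who do not
#' resolve (e.g. younger family members outside the survey population)
#' produce no tie and are returned in the log.
#'
#' @param respondent_id Id of the respondent whose listing is processed.
#' @param participants Participant roster table.
#' @param household_members Household listing table (rows for this
#'   respondent are used).
#' @param rules A [tie_rules()] object.
#' @return A list with `ties` (data frame `from`, `to`, `provenance`) and
#'   `log` (data frame of member rows with a `resolution` outcome:
#'   "tie", "suppressed_spouse_rule" or "unresolved").
#' @export
identify_household_ties <- function(respondent_id, participants,
                                    household_members,
                                    rules = tie_rules()) {
  resp <- participants[participants$participant_id == respondent_id, ,
                       drop = FALSE]
  if (nrow(resp) != 1) stop("respondent not found (or duplicated): ",
                            respondent_id)
  rows <- household_members[household_members$participant_id ==
                              respondent_id, , drop = FALSE]
  empty_ties <- data.frame(from = character(), to = character(),
                           provenance = character(), stringsAsFactors = FALSE)
  if (!nrow(rows)) return(list(ties = empty_ties, log = rows))

  mates <- participants[participants$household_id == resp$household_id &
                          participants$participant_id != respondent_id, ,
                        drop = FALSE]
  for (cl in name_cols) {
    rows[[cl]] <- normalize_name(rows[[cl]])
    if (nrow(mates)) mates[[cl]] <- normalize_name(mates[[cl]])
  }

  suppress_mode <- is_poor_satisfaction(resp$marital_satisfaction, rules) &&
    identical(as.logical(resp$reports_any_confidant), FALSE)

  resolution <- character(nrow(rows))
  to <- character(0)
  for (k in seq_len(nrow(rows))) {
    hit <- if (nrow(mates)) {
      full_name_match(rows$family_name_kanji[k], rows$given_name_kanji[k],
                      rows$family_name_kana[k], rows$given_name_kana[k],
                      mates$family_name_kanji, mates$given_name_kanji,
                      mates$family_name_kana, mates$given_name_kana) &
        tolower(mates$sex) == tolower(rows$sex[k]) &
        abs(mates$age - rows$age[k]) <= rules$member_age_tol
    } else logical(0)
    if (sum(hit) != 1) {
      resolution[k] <- "unresolved"
      next
    }
    m <- mates[hit, , drop = FALSE]
    if (suppress_mode &&
        tolower(m$sex) != tolower(resp$sex) &&
        abs(resp$age - m$age) < rules$spouse_age_gap) {
      resolution[k] <- "suppressed_spouse_rule"
      next
    }
    resolution[k] <- "tie"
    to <- c(to, m$participant_id)
  }
  rows$resolution <- resolution
  ties <- if (length(to)) {
    data.frame(from = respondent_id, to = to, provenance = "household",
               stringsAsFactors = FALSE)
  } else empty_ties
  list(ties = ties, log = rows)
}

#' Match one community nomination to the roster
#'
#' Step two of tie identification. A nomination (a written name) resolves
#' to a roster participant when all five criteria hold: (1) the first and
#' family names are spelled exactly the same in either the kanji or the
#' kana rendering; (2) same sex as the nominator; (3) at most
#' `nomination_age_gap` (default 3) years of age difference from the
#' nominator; (4) same residential district as, but not the same address
#' as, the nominator; and (5) exactly one roster member satisfies
#' (1)-(4). Comparisons (2)-(4) are against the nominator, because a
#' nomination carries only a name.
#'
#' @param nomination One-row data frame (or list) with the four name
#'   fields `family_name_kanji`, `given_name_kanji`, `family_name_kana`,
#'   `given_name_kana` (any rendering may be absent).
#' @param nominator_id Id of the nominating participant.
#' @param participants Participant roster table.
#' @param rules A [tie_rules()] object.
#' @return A one-row data frame: `nominator_id`, the name fields,
#'   `outcome` ("matched", "no_candidate", "excluded_by_criterion" or
#'   "ambiguous"), `matched_id` (`NA` unless matched), `n_candidates`
#'   (count satisfying criteria 1-4) and `failed_criterion` (for
#'   "excluded_by_criterion": the criterion that eliminated the
#'   most-nearly-matching name candidate).
#' @export
match_nomination <- function(nomination, nominator_id, participants,
                             rules = tie_rules()) {
  nom <- as.list(nomination)
  for (cl in name_cols) nom[[cl]] <- normalize_name(nom[[cl]])
  nominator <- participants[participants$participant_id == nominator_id, ,
                            drop = FALSE]
  if (nrow(nominator) != 1) stop("nominator not on roster: ", nominator_id)

  others <- participants[participants$participant_id != nominator_id, ,
                         drop = FALSE]
  pf_kanji <- normalize_name(others$family_name_kanji)
  pg_kanji <- normalize_name(others$given_name_kanji)
  pf_kana <- normalize_name(others$family_name_kana)
  pg_kana <- normalize_name(others$given_name_kana)

  c1 <- full_name_match(nom$family_name_kanji, nom$given_name_kanji,
                        nom$family_name_kana, nom$given_name_kana,
                        pf_kanji, pg_kanji, pf_kana, pg_kana)
  c2 <- tolower(others$sex) == tolower(nominator$sex)
  c3 <- abs(others$age - nominator$age) <= rules$nomination_age_gap
  c4 <- others$district_id == nominator$district_id &
    others$address_id != nominator$address_id
  candidates <- which(c1 & c2 & c3 & c4)

  out <- data.frame(
    nominator_id = nominator_id,
    family_name_kanji = nom$family_name_kanji %||% NA_character_,
    given_name_kanji = nom$given_name_kanji %||% NA_character_,
    family_name_kana = nom$family_name_kana %||% NA_character_,
    given_name_kana = nom$given_name_kana %||% NA_character_,
    outcome = NA_character_, matched_id = NA_character_,
    n_candidates = length(candidates),
    failed_criterion = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (length(candidates) == 1) {
    out$outcome <- "matched"
    out$matched_id <- others$participant_id[candidates]
  } else if (length(candidates) > 1) {
    out$outcome <- "ambiguous"
  } else if (!any(c1)) {
    out$outcome <- "no_candidate"
  } else {
    # name matches exist but criteria (2)-(4) eliminated all of them;
    # report the first failing criterion of the candidate that survived
    # the longest prefix of (2), (3), (4)
    fails <- vapply(which(c1), function(i) {
      if (!c2[i]) 2L else if (!c3[i]) 3L else 4L
    }, integer(1))
    out$outcome <- "excluded_by_criterion"
    out$failed_criterion <- max(fails)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Build the directed confidant network from survey tables
#'
#' Runs both identification steps over the analysis set (participants with
#' a complete GDS-15 and non-missing confidant information), unions
#' household and matched community ties, and attaches coded covariates and
#' symptom scores as node attributes. Nominations are matched against the
#' full roster (criterion 5 counts every beneficiary), but a tie enters
#' the network only when both endpoints are in the analysis set.
#'
#' @param participants Participant roster table.
#' @param household_members Household listing table (may be empty).
#' @param nominations Community nomination table with a `nominator_id`
#'   column and the four name fields (may be empty).
#' @param rules A [tie_rules()] object.
#' @param edu_other_as_category Passed to [code_covariates()].
#' @return A list with `network` (a [confidant_network()] over the
#'   analysis set), `match_report` (one row per nomination),
#'   `household_log` (member-resolution log) and `n_excluded` (roster rows
#'   outside the analysis set).
#' @export
build_network <- function(participants, household_members = NULL,
                          nominations = NULL, rules = tie_rules(),
                          edu_other_as_category = FALSE) {
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant_id in roster")
  }
  if (is.null(household_members)) {
    household_members <- data.frame(participant_id = character())
  }
  if (is.null(nominations)) {
    nominations <- data.frame(nominator_id = character())
  }
  covs <- code_covariates(participants, household_members,
                          edu_other_as_category = edu_other_as_category)
  in_analysis <- !is.na(covs$gds_total) &
    !is.na(participants$reports_any_confidant)
  analysis_ids <- covs$participant_id[in_analysis]

  hh_ties <- list()
  hh_logs <- list()
  for (id in analysis_ids) {
    res <- identify_household_ties(id, participants, household_members,
                                   rules)
    hh_ties[[id]] <- res$ties
    if (nrow(res$log)) hh_logs[[id]] <- res$log
  }
  hh <- do.call(rbind, c(hh_ties, list(
    data.frame(from = character(), to = character(),
               provenance = character(), stringsAsFactors = FALSE))))

  reports <- list()
  comm <- data.frame(from = character(), to = character(),
                     provenance = character(), stringsAsFactors = FALSE)
  if (nrow(nominations)) {
    keep <- nominations$nominator_id %in% analysis_ids
    for (k in seq_len(nrow(nominations))) {
      if (!keep[k]) next
      rep_k <- match_nomination(nominations[k, , drop = FALSE],
                                nominations$nominator_id[k],
                                participants, rules)
      reports[[length(reports) + 1L]] <- rep_k
    }
  }
  match_report <- if (length(reports)) do.call(rbind, reports) else
    data.frame(nominator_id = character(), outcome = character(),
               matched_id = character(), n_candidates = integer(),
               stringsAsFactors = FALSE)
  matched <- match_report[!is.na(match_report$matched_id) &
                            match_report$matched_id %in% analysis_ids, ,
                          drop = FALSE]
  if (nrow(matched)) {
    comm <- data.frame(from = matched$nominator_id, to = matched$matched_id,
                       provenance = "community", stringsAsFactors = FALSE)
  }

  edges <- rbind(hh, comm)
  edges <- edges[edges$from %in% analysis_ids &
                   edges$to %in% analysis_ids, , drop = FALSE]
  net <- confidant_network(analysis_ids, edges,
                           node_data = covs[in_analysis, , drop = FALSE])
  list(
    network = net,
    match_report = match_report,
    household_log = if (length(hh_logs)) do.call(rbind, hh_logs) else NULL,
    n_excluded = sum(!in_analysis)
  )
}
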