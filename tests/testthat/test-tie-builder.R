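test_that("household ties follow the co-residence rule and its exception", {
  # household H1: P01 (male 70) and P02 (female 64? no: ages >= 65)
  p <- make_participants(3, sex = c("male", "female", "male"),
                         age = c(70, 66, 72),
                         household = c("H1", "H1", "H1"),
                         address = c("A1", "A1", "A1"))
  hm <- list_household(p, p$participant_id)

  # satisfied respondent: ties to every co-resident
  res <- identify_household_ties("P01", p, hm)
  expect_setequal(res$ties$to, c("P02", "P03"))

  # poor satisfaction + reports no confidants: opposite-sex co-resident
  # within 15 years suppressed, same-sex kept
  p2 <- p
  p2$marital_satisfaction[1] <- 8
  p2$reports_any_confidant[1] <- FALSE
  res2 <- identify_household_ties("P01", p2, hm)
  expect_setequal(res2$ties$to, "P03")
  expect_true("suppressed_spouse_rule" %in% res2$log$resolution)

  # same situation but the opposite-sex co-resident is 20 years younger:
  # the exception does not apply
  p3 <- p2
  p3$age[1] <- 85
  hm3 <- list_household(p3, p3$participant_id)
  res3 <- identify_household_ties("P01", p3, hm3)
  expect_true("P02" %in% res3$ties$to)

  # poor satisfaction alone (still reports confidants) never suppresses
  p4 <- p
  p4$marital_satisfaction[1] <- 9
  res4 <- identify_household_ties("P01", p4, hm)
  expect_setequal(res4$ties$to, c("P02", "P03"))
})

test_that("household members who do not resolve produce no tie", {
  p <- make_participants(2, household = c("H1", "H2"))
  # P01 lists a member whose name matches nobody in H1
  hm <- data.frame(participant_id = "P01", family_name_kanji = "z",
                   given_name_kanji = "z", family_name_kana = "z",
                   given_name_kana = "z", sex = "male", age = 70,
                   relationship = "other", stringsAsFactors = FALSE)
  res <- identify_household_ties("P01", p, hm)
  expect_equal(nrow(res$ties), 0)
  expect_equal(res$log$resolution, "unresolved")
})

test_that("nomination matching applies the five criteria", {
  p <- make_participants(4, sex = c("male", "male", "male", "female"),
                         age = c(70, 72, 74, 71),
                         district = c("D1", "D1", "D2", "D1"))
  nom <- nominate("P01", p[2, ])

  # exactly one candidate satisfying (1)-(4)
  rep1 <- match_nomination(nom, "P01", p)
  expect_equal(rep1$outcome, "matched")
  expect_equal(rep1$matched_id, "P02")

  # criterion (3): age difference of 4 years excludes
  p3 <- p
  p3$age[2] <- 74
  rep3 <- match_nomination(nom, "P01", p3)
  expect_equal(rep3$outcome, "excluded_by_criterion")
  expect_equal(rep3$failed_criterion, 3L)

  # criterion (2): wrong sex excludes
  p2 <- p
  p2$sex[2] <- "female"
  rep2 <- match_nomination(nom, "P01", p2)
  expect_equal(rep2$outcome, "excluded_by_criterion")
  expect_equal(rep2$failed_criterion, 2L)

  # criterion (4): same address excludes; different district excludes
  p4 <- p
  p4$address_id[2] <- p4$address_id[1]
  expect_equal(match_nomination(nom, "P01", p4)$failed_criterion, 4L)
  p4b <- p
  p4b$district_id[2] <- "D9"
  expect_equal(match_nomination(nom, "P01", p4b)$outcome,
               "excluded_by_criterion")

  # criterion (5): a second candidate matching (1)-(4) makes it ambiguous
  p5 <- p
  p5[3, c("family_name_kanji", "given_name_kanji", "family_name_kana",
          "given_name_kana")] <-
    p5[2, c("family_name_kanji", "given_name_kanji", "family_name_kana",
            "given_name_kana")]
  p5$district_id[3] <- "D1"
  p5$age[3] <- 72
  rep5 <- match_nomination(nom, "P01", p5)
  expect_equal(rep5$outcome, "ambiguous")
  expect_equal(rep5$n_candidates, 2L)

  # a name matching nobody
  nom0 <- nom
  nom0[, c("family_name_kanji", "given_name_kanji", "family_name_kana",
           "given_name_kana")] <- c("無", "名", "なし", "なまえ")
  expect_equal(match_nomination(nom0, "P01", p)$outcome, "no_candidate")
})

test_that("names match on either rendering, exactly, after trimming", {
  p <- make_participants(2, age = c(70, 71))
  # kana-only nomination still matches via the kana rendering
  nom <- nominate("P01", p[2, ])
  nom$family_name_kanji <- ""
  nom$given_name_kanji <- ""
  expect_equal(match_nomination(nom, "P01", p)$outcome, "matched")
  # whitespace is trimmed before comparison
  nom2 <- nominate("P01", p[2, ])
  nom2$family_name_kanji <- paste0(" ", nom2$family_name_kanji, " ")
  expect_equal(match_nomination(nom2, "P01", p)$outcome, "matched")
  # near-miss spelling never matches
  nom3 <- nominate("P01", p[2, ])
  nom3$given_name_kanji <- paste0(nom3$given_name_kanji, "x")
  nom3$given_name_kana <- paste0(nom3$given_name_kana, "x")
  expect_equal(match_nomination(nom3, "P01", p)$outcome, "no_candidate")
})

test_that("build_network unions household and community ties", {
  # P01-P02 share a household; P03 nominates P04 unambiguously
  p <- make_participants(4, sex = rep("male", 4), age = c(70, 71, 72, 73),
                         household = c("H1", "H1", "H3", "H4"),
                         address = c("A1", "A1", "A3", "A4"))
  hm <- list_household(p, c("P01", "P02"))
  noms <- nominate("P03", p[4, ])
  built <- build_network(p, hm, noms)
  expect_equal(edge_key(built$network$edges),
               sort(c("P01 P02", "P02 P01", "P03 P04")))
  expect_equal(sort(unique(built$network$edges$provenance)),
               c("community", "household"))
  expect_equal(built$n_excluded, 0)

  # empty inputs give an empty network over the analysis set
  built0 <- build_network(p, NULL, NULL)
  expect_equal(nrow(built0$network$edges), 0)
  expect_equal(network_size(built0$network), 4)

  # duplicate ids are a hard error
  pd <- rbind(p, p[1, ])
  expect_error(build_network(pd, hm, noms), "duplicate")
})

test_that("participants without scored GDS or confidant info are excluded", {
  p <- make_participants(3, age = c(70, 71, 72))
  p$gds_05[2] <- NA
  p$reports_any_confidant[3] <- NA
  built <- build_network(p, NULL, NULL)
  expect_equal(built$network$nodes, "P01")
  expect_equal(built$n_excluded, 2)
})

test_that("tie identification is deterministic and monotone in nominations", {
  p <- make_participants(5, sex = rep("female", 5), age = 70:74,
                         household = c("H1", "H1", "H3", "H4", "H5"),
                         address = c("A1", "A1", "A3", "A4", "A5"))
  hm <- list_household(p, c("P01", "P02"))
  noms <- rbind(nominate("P03", p[4, ]), nominate("P04", p[5, ]))
  b1 <- build_network(p, hm, noms)
  b2 <- build_network(p, hm, noms)
  expect_identical(b1$network$edges, b2$network$edges)
  expect_identical(b1$match_report, b2$match_report)
  # dropping a nomination never adds a tie
  b3 <- build_network(p, hm, noms[1, , drop = FALSE])
  expect_true(all(edge_key(b3$network$edges) %in%
                    edge_key(b1$network$edges)))
})
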