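test_that("the community config validates its inputs", {
  expect_error(community_config(), "seed")
  expect_error(community_config(seed = 1, n = 1), "n must be")
  expect_error(community_config(seed = 1, theta = c(edges = -1)),
               "theta length")
  cfg <- community_config(seed = 1, n = 50)
  expect_s3_class(cfg, "community_config")
  expect_equal(cfg$theta_terms$label,
               c("edges", "mutual", "absdiff.gds_total"))
})

test_that("roster generation is deterministic and hits its marginals", {
  cfg <- community_config(seed = 101, n = 2000)
  r1 <- generate_roster(cfg)
  r2 <- generate_roster(cfg)
  expect_identical(r1$participants, r2$participants)
  p <- r1$participants
  n <- nrow(p)
  expect_equal(n, 2000)
  expect_true(all(p$age >= 65))
  expect_false(anyDuplicated(p$participant_id) > 0)
  # female share within 3 binomial SEs of the configured 53.2%
  expect_lt(abs(mean(p$sex == "female") - 0.532),
            3 * sqrt(0.532 * 0.468 / n))
  # GDS marginals near their targets
  sc <- score_gds(p[, sprintf("gds_%02d", 1:15)])
  expect_lt(abs(mean(sc$gds_total) - 5.0), 3 * 3.8 / sqrt(n))
  expect_lt(abs(mean(sc$apathy) - 1.4), 3 * 1.2 / sqrt(n))
  expect_lt(abs(mean(sc$suicidal_ideation) - 1.3), 3 * 1.6 / sqrt(n))
  expect_lt(abs(sd(sc$gds_total) - 3.8), 0.4)
  # SMC in range, ages plausible, districts coarsen addresses
  smc <- score_smc(p[, sprintf("smc_%d", 1:4)])
  expect_true(all(smc >= 4 & smc <= 28))
  addr_district <- tapply(p$district_id, p$address_id,
                          function(d) length(unique(d)))
  expect_true(all(addr_district == 1))
})

test_that("a two-person couple household shares household and address ids", {
  cfg <- community_config(seed = 102, n = 2, p_couple = 1,
                          n_districts = 1)
  p <- generate_roster(cfg)$participants
  expect_equal(length(unique(p$household_id)), 1)
  expect_equal(length(unique(p$address_id)), 1)
  expect_setequal(p$sex, c("male", "female"))
})

test_that("full names are unique in noiseless mode", {
  p <- generate_roster(community_config(seed = 103, n = 660))$participants
  kanji <- paste(p$family_name_kanji, p$given_name_kanji)
  kana <- paste(p$family_name_kana, p$given_name_kana)
  expect_equal(anyDuplicated(kanji), 0)
  expect_equal(anyDuplicated(kana), 0)
})

test_that("community ties satisfy the matching criteria by construction", {
  sim <- simulate_community(community_config(seed = 104, n = 200))
  p <- sim$roster$participants
  comm <- sim$network$edges[sim$network$edges$provenance == "community", ]
  i <- match(comm$from, p$participant_id)
  j <- match(comm$to, p$participant_id)
  expect_true(all(p$sex[i] == p$sex[j]))
  expect_true(all(abs(p$age[i] - p$age[j]) <= 3))
  expect_true(all(p$district_id[i] == p$district_id[j]))
  expect_true(all(p$address_id[i] != p$address_id[j]))
  expect_true(all(p$household_id[i] != p$household_id[j]))
})

test_that("a strongly negative homophily coefficient concentrates ties on similar nodes", {
  cfg <- community_config(seed = 105, n = 150,
                          theta = c(edges = -3, mutual = 1,
                                    absdiff.gds_total = -0.8))
  diffs_tie <- c()
  diffs_all <- c()
  for (s in 1:10) {
    cfg$seed <- 105L + s
    gen <- generate_network(generate_roster(cfg))
    nd <- gen$network$node_data
    comm <- gen$network$edges[gen$network$edges$provenance ==
                                "community", ]
    if (!nrow(comm)) next
    x <- nd$gds_total[match(comm$from, nd$participant_id)]
    y <- nd$gds_total[match(comm$to, nd$participant_id)]
    diffs_tie <- c(diffs_tie, abs(x - y))
    ap <- gen$allowed_pairs
    diffs_all <- c(diffs_all, abs(nd$gds_total[ap[, 1]] -
                                    nd$gds_total[ap[, 2]]))
  }
  expect_lt(mean(diffs_tie), mean(diffs_all))
})

test_that("household ties honour the marital-dissatisfaction exception", {
  cfg <- community_config(seed = 106, n = 300, p_couple = 0.5,
                          satisfaction_probs = c(rep(0, 9), 1),
                          p_reports_confidant = 0)
  gen <- generate_network(generate_roster(cfg))
  p <- gen$roster$participants
  hh <- gen$network$edges[gen$network$edges$provenance == "household", ]
  # every remaining household tie must escape the suppression rule
  i <- match(hh$from, p$participant_id)
  j <- match(hh$to, p$participant_id)
  suppressed <- p$marital_satisfaction[i] > 6 &
    !p$reports_any_confidant[i] & p$sex[i] != p$sex[j] &
    abs(p$age[i] - p$age[j]) < 15
  expect_false(any(suppressed))
  # the configuration really exercises the rule: some respondents are
  # dissatisfied, report no confidant, and live with a close-aged spouse
  expect_gt(sum(!p$reports_any_confidant), 0)
  expect_lt(nrow(hh), 2 * sum(duplicated(p$household_id)))
})

test_that("the emitted survey round-trips to the exact ground truth", {
  for (seed in c(107, 108)) {
    sim <- simulate_community(community_config(seed = seed, n = 150))
    built <- build_network(sim$survey$participants,
                           sim$survey$household_members,
                           sim$survey$nominations)
    expect_equal(edge_key(built$network$edges),
                 edge_key(sim$network$edges))
    # provenance survives the round trip
    expect_equal(sort(table(built$network$edges$provenance)),
                 sort(table(sim$network$edges$provenance)))
    # all community nominations match uniquely in noiseless mode
    expect_true(all(built$match_report$outcome == "matched"))
  }
})

test_that("emitted GDS items re-score to the node attributes", {
  sim <- simulate_community(community_config(seed = 109, n = 100))
  sc <- score_gds(sim$survey$participants[, sprintf("gds_%02d", 1:15)])
  nd <- sim$network$node_data
  expect_equal(sc$gds_total, nd$gds_total)
  expect_equal(sc$apathy, nd$apathy)
  expect_equal(sc$suicidal_ideation, nd$suicidal_ideation)
})

test_that("an injected name collision turns a match ambiguous", {
  sim <- simulate_community(community_config(seed = 110, n = 150))
  p <- sim$survey$participants
  comm <- sim$network$edges[sim$network$edges$provenance == "community", ]
  expect_gt(nrow(comm), 0)   # seed 110 is known to produce community ties
  # clone the first nominated person's name onto another same-sex,
  # same-district, age-compatible participant
  tgt <- comm$to[1]
  nominator <- comm$from[1]
  ti <- match(tgt, p$participant_id)
  ni <- match(nominator, p$participant_id)
  clone_pool <- which(p$sex == p$sex[ti] &
                        p$district_id == p$district_id[ni] &
                        abs(p$age - p$age[ni]) <= 3 &
                        p$address_id != p$address_id[ni] &
                        !(p$participant_id %in% c(tgt, nominator)))
  expect_gt(length(clone_pool), 0)
  ci <- clone_pool[1]
  p[ci, c("family_name_kanji", "given_name_kanji", "family_name_kana",
          "given_name_kana")] <-
    p[ti, c("family_name_kanji", "given_name_kanji", "family_name_kana",
            "given_name_kana")]
  built <- build_network(p, sim$survey$household_members,
                         sim$survey$nominations)
  rep1 <- built$match_report[built$match_report$nominator_id ==
                               nominator, ][1, ]
  expect_equal(rep1$outcome, "ambiguous")
  expect_equal(rep1$n_candidates, 2L)
  # the corrupted tie disappears from the rebuilt network
  expect_false(paste(nominator, tgt) %in% edge_key(built$network$edges))
})

test_that("out-of-roster nominations are counted but never create ties", {
  cfg <- community_config(seed = 111, n = 120, mode = "noisy",
                          out_of_roster_rate = 0.5)
  sim <- simulate_community(cfg)
  built <- build_network(sim$survey$participants,
                         sim$survey$household_members,
                         sim$survey$nominations)
  expect_true(any(built$match_report$outcome == "no_candidate"))
  expect_equal(edge_key(built$network$edges), edge_key(sim$network$edges))
})

test_that("emit_survey refuses a roster without the confidant flag", {
  cfg <- community_config(seed = 112, n = 30)
  roster <- generate_roster(cfg)
  gen <- generate_network(roster)
  expect_error(emit_survey(roster, gen$network), "confidant flag")
  expect_silent(emit_survey(gen$roster, gen$network))
})
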