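#' Configuration of a synthetic community
#'
#' Parameters of the synthetic survey population and its ground-truth
#' confidant network. The defaults emulate the study conditions the
#' pipeline is designed for: about 660 community-dwelling adults aged
#' 65+, mean age 76.2 (SD 7.3), 53.2% female, 85.1% living with family,
#' GDS-15 total mean 5.0 (SD ~3.8) with apathy mean 1.4 and
#' suicidal-ideation mean 1.3, subjective memory complaints mean 10.5
#' (SD 4.9), and a sparse directed confidant network (collapsed density
#' around 0.001) with strong reciprocity and attribute homophily.
#'
#' @param seed Integer seed (mandatory); all three generator stages are
#'   deterministic given the config.
#' @param n Number of participants (>= 2).
#' @param n_districts Number of residential districts; households are
#'   spread uniformly over districts and each household has a unique
#'   address within its district.
#' @param p_female Female share.
#' @param age_mean,age_sd Age distribution (normal, truncated at 65,
#'   rounded to integer years).
#' @param p_couple Share of participants living with another participant
#'   (opposite-sex two-participant households, i.e. spousal pairs).
#' @param p_with_family Target share of participants living in a
#'   household of two or more (participant spouses plus younger
#'   non-participant family members make up the difference).
#' @param education_probs Probabilities of the education bands
#'   `<6`, `6-9`, `10-12`, `13+`, `other` (must sum to 1).
#' @param gds_item_means Target marginal symptomatic probability of each
#'   GDS-15 item, in item order; the default spreads the apathy-subscale
#'   mean 1.4 over its 3 items, the suicidal-ideation mean 1.3 over its
#'   5 items, and the remainder of the total mean 5.0 over the other 7.
#' @param gds_sigma SD of the per-person latent depressive propensity
#'   (logit scale); items are conditionally independent Bernoullis whose
#'   intercepts are calibrated so the marginal item means stay on target
#'   for any sigma. The default 1.4 puts the total-score SD near 3.8.
#' @param gds_household_cor Share of the latent propensity variance that
#'   is common to a household (0 = independent participants).
#' @param smc_mean,smc_sd Subjective-memory-complaint total distribution
#'   (rounded, clipped to 4-28, then spread over the four items).
#' @param p_disability Probability of a TMIG-IC score below 13.
#' @param disability_missing_rate Fraction of participants with missing
#'   TMIG-IC items.
#' @param satisfaction_probs Distribution of the 10-point marital
#'   satisfaction score (higher = more dissatisfied under the default
#'   [tie_rules()] orientation); the default puts 10 percent of
#'   respondents above the "poor" threshold of 6.
#' @param p_reports_confidant Target share of participants reporting at
#'   least one confidant; participants whose sampled network gives them
#'   an out-of-household tie always report one.
#' @param theta Ground-truth ERGM coefficients for the community
#'   (out-of-household) ties, named by term label; the default preset
#'   (edges -3.8, mutual 2.9, absdiff.gds_total -0.05) targets the
#'   sparse, reciprocity- and homophily-rich regime described above and
#'   is a documented choice, not an estimate of any real community.
#' @param theta_terms Term specification matching `theta`.
#' @param mode "noiseless" (survey tables round-trip to the exact
#'   ground-truth network) or "noisy" (corruptions below are applied).
#' @param name_collision_rate In noisy mode, fraction of participants
#'   whose full name is overwritten with another same-sex participant's
#'   name (creates ambiguous or spurious nominations).
#' @param out_of_roster_rate In noisy mode, number of extra nominations
#'   naming non-roster persons, as a fraction of the true nominations.
#' @return A list of class `community_config`.
#' @export
community_config <- function(seed,
                             n = 660,
                             n_districts = 8,
                             p_female = 0.532,
                             age_mean = 76.2, age_sd = 7.3,
                             p_couple = 0.20,
                             p_with_family = 0.851,
                             education_probs = c("<6" = 0.050,
                                                 "6-9" = 0.276,
                                                 "10-12" = 0.468,
                                                 "13+" = 0.192,
                                                 "other" = 0.014),
                             gds_item_means = NULL,
                             gds_sigma = 1.4,
                             gds_household_cor = 0,
                             smc_mean = 10.5, smc_sd = 4.9,
                             p_disability = 0.545,
                             disability_missing_rate = 0,
                             satisfaction_probs = c(0.25, 0.20, 0.15,
                                                    0.12, 0.10, 0.08,
                                                    0.04, 0.03, 0.02,
                                                    0.01),
                             p_reports_confidant = 0.583,
                             theta = c(edges = -3.8, mutual = 2.9,
                                       absdiff.gds_total = -0.05),
                             theta_terms = c("edges", "mutual",
                                             "absdiff:gds_total"),
                             mode = c("noiseless", "noisy"),
                             name_collision_rate = 0,
                             out_of_roster_rate = 0) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("community_config requires an integer seed")
  }
  mode <- match.arg(mode)
  if (n < 2) stop("n must be >= 2")
  # tolerate list-valued fields from YAML/JSON config files
  education_probs <- unlist(education_probs)
  satisfaction_probs <- unlist(satisfaction_probs)
  theta <- unlist(theta)
  theta_terms <- unlist(theta_terms)
  if (!is.null(gds_item_means)) gds_item_means <- unlist(gds_item_means)
  stopifnot(abs(sum(education_probs) - 1) < 1e-8,
            length(satisfaction_probs) == 10,
            abs(sum(satisfaction_probs) - 1) < 1e-6)
  if (is.null(gds_item_means)) {
    key <- gds_item_key()
    gds_item_means <- numeric(15)
    gds_item_means[which(key$subscale %in% "apathy")] <- 1.4 / 3
    gds_item_means[which(key$subscale %in% "suicidal_ideation")] <- 1.3 / 5
    gds_item_means[is.na(key$subscale)] <- (5.0 - 1.4 - 1.3) / 7
  }
  stopifnot(length(gds_item_means) == 15,
            all(gds_item_means > 0 & gds_item_means < 1),
            gds_household_cor >= 0, gds_household_cor <= 1)
  terms <- ergm_terms(theta_terms)
  if (length(theta) != nrow(terms)) {
    stop("theta length does not match theta_terms")
  }
  structure(list(
    seed = as.integer(seed), n = as.integer(n),
    n_districts = as.integer(n_districts),
    p_female = p_female, age_mean = age_mean, age_sd = age_sd,
    p_couple = p_couple, p_with_family = p_with_family,
    education_probs = education_probs,
    gds_item_means = gds_item_means, gds_sigma = gds_sigma,
    gds_household_cor = gds_household_cor,
    smc_mean = smc_mean, smc_sd = smc_sd,
    p_disability = p_disability,
    disability_missing_rate = disability_missing_rate,
    satisfaction_probs = satisfaction_probs,
    p_reports_confidant = p_reports_confidant,
    theta = setNames(as.numeric(theta), terms$label),
    theta_terms = terms,
    mode = mode,
    name_collision_rate = name_collision_rate,
    out_of_roster_rate = out_of_roster_rate
  ), class = "community_config")
}

# Japanese-style name pools: kanji with hiragana readings. Within each
# pool the readings are unique, so full-name uniqueness in one rendering
# implies it in the other.
surname_pool <- function() {
  data.frame(
    kanji = c("佐藤", "鈴木", "高橋",
              "田中", "伊藤", "渡辺",
              "山本", "中村", "小林",
              "加藤", "吉田", "山田",
              "佐々木", "山口", "松本",
              "井上", "木村", "林",
              "斉藤", "清水", "山崎",
              "森", "池田", "橋本",
              "阿部", "石川", "中島",
              "前田", "藤田", "後藤",
              "小川", "岡田", "村上",
              "長谷川", "近藤", "石井",
              "坂本", "遠藤", "青木",
              "藤井", "西村", "福田",
              "太田", "三浦", "藤原",
              "岡本", "松田", "中川",
              "中野", "原田"),
    kana = c("さとう", "すずき",
             "たかはし", "たなか",
             "いとう", "わたなべ",
             "やまもと", "なかむら",
             "こばやし", "かとう",
             "よしだ", "やまだ",
             "ささき", "やまぐち",
             "まつもと", "いのうえ",
             "きむら", "はやし",
             "さいとう", "しみず",
             "やまざき", "もり",
             "いけだ", "はしもと",
             "あべ", "いしかわ",
             "なかじま", "まえだ",
             "ふじた", "ごとう",
             "おがわ", "おかだ",
             "むらかみ", "はせがわ",
             "こんどう", "いしい",
             "さかもと", "えんどう",
             "あおき", "ふじい",
             "にしむら", "ふくだ",
             "おおた", "みうら",
             "ふじわら", "おかもと",
             "まつだ", "なかがわ",
             "なかの", "はらだ"),
    stringsAsFactors = FALSE
  )
}

given_name_pool <- function(sex) {
  if (sex == "male") {
    data.frame(
      kanji = c("博", "清", "勇", "茂", "実",
                "進", "正", "昭", "豊",
                "博之", "健一", "正雄",
                "和夫", "幸雄", "義雄",
                "三郎", "次郎", "太郎",
                "一郎", "勝", "誠", "修",
                "隆", "学", "武", "明夫",
                "英夫", "光男", "哲夫",
                "信夫"),
      kana = c("ひろし", "きよし",
               "いさむ", "しげる",
               "みのる", "すすむ",
               "ただし", "あきら",
               "ゆたか", "ひろゆき",
               "けんいち", "まさお",
               "かずお", "ゆきお",
               "よしお", "さぶろう",
               "じろう", "たろう",
               "いちろう", "まさる",
               "まこと", "おさむ",
               "たかし", "まなぶ",
               "たけし", "あきお",
               "ひでお", "みつお",
               "てつお", "のぶお"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      kanji = c("幸子", "和子", "洋子",
                "節子", "弘子", "美代子",
                "京子", "恵子", "久子",
                "悦子", "君江", "文子",
                "光子", "貞子", "春子",
                "静子", "信子", "良子",
                "敏子", "栄子", "千代子",
                "正子", "明美", "典子",
                "郁子", "孝子", "道子",
                "八重子", "登美子",
                "澄子"),
      kana = c("さちこ", "かずこ",
               "ようこ", "せつこ",
               "ひろこ", "みよこ",
               "きょうこ", "けいこ",
               "ひさこ", "えつこ",
               "きみえ", "ふみこ",
               "みつこ", "さだこ",
               "はるこ", "しずこ",
               "のぶこ", "よしこ",
               "としこ", "えいこ",
               "ちよこ", "まさこ",
               "あけみ", "のりこ",
               "いくこ", "たかこ",
               "みちこ", "やえこ",
               "とみこ", "すみこ"),
      stringsAsFactors = FALSE
    )
  }
}

# solve E[plogis(a + u)] = p for a, u ~ N(0, sigma^2), by quadrature
calibrate_item_intercepts <- function(p, sigma) {
  if (sigma == 0) return(qlogis(p))
  x <- seq(-6, 6, length.out = 64)
  w <- stats::dnorm(x)
  w <- w / sum(w)
  vapply(p, function(pj) {
    uniroot(function(a) sum(w * plogis(a + x * sigma)) - pj,
            c(-25, 25))$root
  }, numeric(1))
}

#' Generate a synthetic participant roster
#'
#' Draws demographics, household structure, names (kanji and kana
#' renderings), scale item responses and marital satisfaction according
#' to a [community_config()]. Deterministic given the config (the
#' config's seed initialises the RNG). The confidant-presence flag is
#' left missing here; it is filled by [generate_network()] so that it is
#' consistent with the sampled ties.
#'
#' @param config A [community_config()].
#' @return A list of class `community_roster`: `participants` (one row
#'   per participant, survey-dialect columns) and `extra_members`
#'   (non-participant co-residents: household_id, name fields, sex, age,
#'   relationship).
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  n <- config$n

  # households: couples are opposite-sex participant pairs
  n_couples <- floor(n * config$p_couple / 2)
  if (2 * n_couples > n) stop("p_couple infeasible for n")
  n_single <- n - 2 * n_couples
  n_households <- n_couples + n_single
  household_of <- c(rep(seq_len(n_couples), each = 2),
                    n_couples + seq_len(n_single))
  hh_id <- sprintf("H%04d", household_of)
  district_of_hh <- sample(config$n_districts, n_households, replace = TRUE)
  district_id <- sprintf("D%02d", district_of_hh[household_of])
  address_id <- sprintf("A%04d", household_of)

  sex <- character(n)
  couple_first_sex <- sample(c("male", "female"), n_couples,
                             replace = TRUE)
  if (n_couples) {
    sex[seq_len(2 * n_couples)] <- rbind(couple_first_sex,
                                         ifelse(couple_first_sex == "male",
                                                "female", "male"))
  }
  if (n_single) {
    sex[2 * n_couples + seq_len(n_single)] <- ifelse(
      runif(n_single) < config$p_female, "female", "male")
  }

  age <- pmax(65, round(rnorm(n, config$age_mean, config$age_sd)))
  if (n_couples) {
    # spouses close in age
    idx2 <- 2 * seq_len(n_couples)
    age[idx2] <- pmax(65, age[idx2 - 1] + round(rnorm(n_couples, 0, 3)))
  }

  # names: shared surname within a household; full names unique in both
  # renderings unless collisions are requested. Surnames are drawn per
  # household with retry, so a surname whose same-sex given-name pool is
  # exhausted is simply passed over.
  sp <- surname_pool()
  pools <- list(male = given_name_pool("male"),
                female = given_name_pool("female"))
  capacity <- nrow(sp) * min(nrow(pools$male), nrow(pools$female))
  if (max(table(sex)) > 0.9 * capacity) {
    stop("name pools too small for n = ", n,
         "; unique full names cannot be guaranteed")
  }
  s_idx <- integer(n)
  g_idx <- integer(n)
  used <- new.env(parent = emptyenv())
  for (h in seq_len(n_households)) {
    members <- which(household_of == h)
    committed <- FALSE
    for (attempt in 1:1000) {
      s <- sample(nrow(sp), 1)
      gi <- integer(length(members))
      taken_local <- list()
      ok <- TRUE
      for (m in seq_along(members)) {
        k <- members[m]
        key <- paste0(s, ".", sex[k])
        taken <- c(if (!is.null(used[[key]])) used[[key]],
                   taken_local[[key]])
        avail <- setdiff(seq_len(nrow(pools[[sex[k]]])), taken)
        if (!length(avail)) {
          ok <- FALSE
          break
        }
        gi[m] <- if (length(avail) == 1) avail else sample(avail, 1)
        taken_local[[key]] <- c(taken_local[[key]], gi[m])
      }
      if (ok) {
        s_idx[members] <- s
        g_idx[members] <- gi
        for (key in names(taken_local)) {
          used[[key]] <- c(if (!is.null(used[[key]])) used[[key]],
                           taken_local[[key]])
        }
        committed <- TRUE
        break
      }
    }
    if (!committed) stop("could not assign unique names; name pools ",
                         "exhausted")
  }
  family_name_kanji <- sp$kanji[s_idx]
  family_name_kana <- sp$kana[s_idx]
  given_name_kanji <- vapply(seq_len(n), function(k)
    pools[[sex[k]]]$kanji[g_idx[k]], "")
  given_name_kana <- vapply(seq_len(n), function(k)
    pools[[sex[k]]]$kana[g_idx[k]], "")

  if (config$mode == "noisy" && config$name_collision_rate > 0) {
    n_coll <- round(config$name_collision_rate * n)
    if (n_coll > 0) {
      victims <- sample(n, n_coll)
      for (v in victims) {
        donors <- setdiff(which(sex == sex[v]), v)
        d <- sample(donors, 1)
        family_name_kanji[v] <- family_name_kanji[d]
        family_name_kana[v] <- family_name_kana[d]
        given_name_kanji[v] <- given_name_kanji[d]
        given_name_kana[v] <- given_name_kana[d]
      }
    }
  }

  education_band <- sample(names(config$education_probs), n,
                           replace = TRUE, prob = config$education_probs)

  # GDS items: conditionally independent given a latent propensity that
  # may be partly shared within the household
  alpha <- calibrate_item_intercepts(config$gds_item_means,
                                     config$gds_sigma)
  u_house <- rnorm(n_households)[household_of]
  u_ind <- rnorm(n)
  u <- config$gds_sigma * (sqrt(config$gds_household_cor) * u_house +
                             sqrt(1 - config$gds_household_cor) * u_ind)
  gds <- vapply(1:15, function(j)
    rbinom(n, 1, plogis(alpha[j] + u)), numeric(n))
  key <- gds_item_key()
  gds_items <- vapply(1:15, function(j) {
    ifelse(gds[, j] == 1, key$symptomatic[j],
           ifelse(key$symptomatic[j] == "yes", "no", "yes"))
  }, character(n))
  colnames(gds_items) <- sprintf("gds_%02d", 1:15)

  # SMC: draw the clipped total, then spread it over the four items
  smc_total <- pmin(28, pmax(4, round(rnorm(n, config$smc_mean,
                                            config$smc_sd))))
  smc_items <- t(vapply(smc_total, function(t) {
    extra <- t - 4
    add <- tabulate(sample(rep(1:4, each = 6))[seq_len(extra)], nbins = 4)
    1 + add
  }, numeric(4)))
  colnames(smc_items) <- sprintf("smc_%d", 1:4)
  smc_severe <- rbinom(n, 1, 0.1)

  # TMIG-IC: full score unless disabled; disabled fail >= 1 items
  disabled <- rbinom(n, 1, config$p_disability)
  tmig <- matrix(1L, n, 13, dimnames = list(NULL, sprintf("tmig_%02d",
                                                          1:13)))
  for (k in which(disabled == 1)) {
    n_fail <- 1 + rpois(1, 1.5)
    tmig[k, sample(13, min(n_fail, 13))] <- 0L
  }
  if (config$disability_missing_rate > 0) {
    miss <- runif(n) < config$disability_missing_rate
    tmig[miss, ] <- NA_integer_
  }

  marital_satisfaction <- sample(1:10, n, replace = TRUE,
                                 prob = config$satisfaction_probs)

  participants <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    family_name_kanji = family_name_kanji,
    given_name_kanji = given_name_kanji,
    family_name_kana = family_name_kana,
    given_name_kana = given_name_kana,
    sex = sex, age = age,
    district_id = district_id, address_id = address_id,
    household_id = hh_id,
    marital_satisfaction = marital_satisfaction,
    reports_any_confidant = NA,
    education_band = education_band,
    stringsAsFactors = FALSE
  )
  participants <- cbind(participants, as.data.frame(gds_items),
                        as.data.frame(smc_items),
                        smc_severe = smc_severe, as.data.frame(tmig))

  # younger non-participant co-residents bring the living-with-family
  # share up to target
  with_family <- household_of %in% household_of[duplicated(household_of)]
  deficit <- config$p_with_family * n - sum(with_family)
  solo_hh <- unique(household_of[!with_family])
  p_extra <- min(1, max(0, deficit / length(solo_hh)))
  extra_hh <- solo_hh[runif(length(solo_hh)) < p_extra]
  extra_members <- if (length(extra_hh)) {
    anchor <- match(extra_hh, household_of)
    esex <- sample(c("male", "female"), length(extra_hh), replace = TRUE)
    egiven <- t(vapply(esex, function(s) {
      pool <- pools[[s]]
      k <- sample(nrow(pool), 1)
      c(pool$kanji[k], pool$kana[k])
    }, character(2)))
    data.frame(
      household_id = hh_id[anchor],
      family_name_kanji = family_name_kanji[anchor],
      given_name_kanji = egiven[, 1],
      family_name_kana = family_name_kana[anchor],
      given_name_kana = egiven[, 2],
      sex = esex,
      age = pmax(20, age[anchor] - 25 - sample(0:15,
                                               length(extra_hh),
                                               replace = TRUE)),
      relationship = "child",
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(household_id = character(), family_name_kanji = character(),
               given_name_kanji = character(),
               family_name_kana = character(),
               given_name_kana = character(), sex = character(),
               age = integer(), relationship = character(),
               stringsAsFactors = FALSE)
  }

  structure(list(participants = participants,
                 extra_members = extra_members,
                 config = config),
            class = "community_roster")
}

# household-member listings as the survey would record them: every
# respondent lists every other member of the household
roster_household_members <- function(roster) {
  p <- roster$participants
  rows <- list()
  for (hid in unique(p$household_id)) {
    inmates <- p[p$household_id == hid, , drop = FALSE]
    extras <- roster$extra_members[
      roster$extra_members$household_id == hid, , drop = FALSE]
    for (k in seq_len(nrow(inmates))) {
      others <- inmates[-k, , drop = FALSE]
      if (nrow(others)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = inmates$participant_id[k],
          family_name_kanji = others$family_name_kanji,
          given_name_kanji = others$given_name_kanji,
          family_name_kana = others$family_name_kana,
          given_name_kana = others$given_name_kana,
          sex = others$sex, age = others$age,
          relationship = "spouse", stringsAsFactors = FALSE)
      }
      if (nrow(extras)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = inmates$participant_id[k],
          family_name_kanji = extras$family_name_kanji,
          given_name_kanji = extras$given_name_kanji,
          family_name_kana = extras$family_name_kana,
          given_name_kana = extras$given_name_kana,
          sex = extras$sex, age = extras$age,
          relationship = extras$relationship, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(participant_id = character(),
                      family_name_kanji = character(),
                      given_name_kanji = character(),
                      family_name_kana = character(),
                      given_name_kana = character(),
                      sex = character(), age = integer(),
                      relationship = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the ground-truth confidant network of a synthetic community
#'
#' Out-of-household ties are drawn from the configured ERGM restricted
#' to the identifiable dyad support (same sex, at most 3 years of age
#' difference, same district, different address) so the emitted survey
#' can be re-identified exactly. The confidant-presence flag is then
#' filled in (everyone with an outgoing community tie reports a
#' confidant; a Bernoulli top-up reaches the configured population
#' share), and household ties are added deterministically by the
#' household identification rule: all co-residing participant pairs are
#' mutually tied, except ties from a respondent with poor marital
#' satisfaction who reports no confidants to opposite-sex co-residents
#' within 15 years of age, which are suppressed.
#'
#' @param roster A `community_roster` from [generate_roster()].
#' @param rules A [tie_rules()] object (the same rules the builder will
#'   apply).
#' @return A list: `network` (the ground-truth [confidant_network()]
#'   with provenance), `roster` (with `reports_any_confidant` filled),
#'   `allowed_pairs` (the community dyad support, node-index matrix).
#' @export
generate_network <- function(roster, rules = tie_rules()) {
  stopifnot(inherits(roster, "community_roster"))
  config <- roster$config
  set.seed(config$seed + 1L)
  p <- roster$participants
  n <- nrow(p)
  scores <- score_gds(item_block(p, "gds", 15L))
  node_data <- data.frame(participant_id = p$participant_id,
                          gds_total = scores$gds_total,
                          apathy = scores$apathy,
                          suicidal_ideation = scores$suicidal_ideation,
                          stringsAsFactors = FALSE)

  pairs <- pair_index(n)
  ok <- p$sex[pairs[, 1]] == p$sex[pairs[, 2]] &
    abs(p$age[pairs[, 1]] - p$age[pairs[, 2]]) <= rules$nomination_age_gap &
    p$district_id[pairs[, 1]] == p$district_id[pairs[, 2]] &
    p$address_id[pairs[, 1]] != p$address_id[pairs[, 2]] &
    p$household_id[pairs[, 1]] != p$household_id[pairs[, 2]]
  if (any(ok)) {
    sim <- simulate_ergm(node_data, roster$config$theta_terms,
                         config$theta, nsim = 1, allowed = ok,
                         return_networks = TRUE)
    community <- sim$networks[[1]]$edges
    if (nrow(community)) community$provenance <- "community"
  } else {
    # degenerate but valid community (e.g. a single household): no pair
    # is identifiable out of household, so there are no community ties
    warning("no identifiable out-of-household dyads; ",
            "community tie set is empty")
    community <- data.frame(from = character(), to = character(),
                            provenance = character(),
                            stringsAsFactors = FALSE)
  }

  has_comm <- p$participant_id %in% community$from
  target <- round(config$p_reports_confidant * n)
  p$reports_any_confidant <- has_comm
  rest <- which(!has_comm)
  topup <- max(0, target - sum(has_comm))
  if (topup > 0 && length(rest)) {
    p$reports_any_confidant[sample(rest, min(topup, length(rest)))] <- TRUE
  }

  # deterministic household ties under the identification rule
  hh_edges <- list()
  for (hid in unique(p$household_id[duplicated(p$household_id)])) {
    inmates <- which(p$household_id == hid)
    for (i in inmates) {
      poor <- is_poor_satisfaction(p$marital_satisfaction[i], rules) &&
        !p$reports_any_confidant[i]
      for (m in setdiff(inmates, i)) {
        if (poor && p$sex[i] != p$sex[m] &&
            abs(p$age[i] - p$age[m]) < rules$spouse_age_gap) next
        hh_edges[[length(hh_edges) + 1L]] <- c(p$participant_id[i],
                                               p$participant_id[m])
      }
    }
  }
  hh <- if (length(hh_edges)) {
    m <- do.call(rbind, hh_edges)
    data.frame(from = m[, 1], to = m[, 2], provenance = "household",
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(),
               provenance = character(), stringsAsFactors = FALSE)
  }

  roster$participants <- p
  net <- confidant_network(p$participant_id, rbind(hh, community),
                           node_data = node_data)
  list(network = net, roster = roster,
       allowed_pairs = pairs[ok, , drop = FALSE])
}

#' Emit survey tables for a synthetic community
#'
#' The inverse of the tie builder: household listings for every
#' respondent, and one name-only nomination per out-of-household tie.
#' In noiseless mode, running [build_network()] on the emitted tables
#' reproduces the ground-truth network exactly; in noisy mode the
#' configured fraction of extra out-of-roster nominations is appended
#' (name collisions are injected at roster level).
#'
#' @param roster A `community_roster` with the confidant flag filled
#'   (i.e. as returned by [generate_network()]).
#' @param network The ground-truth [confidant_network()].
#' @return A list of class `community_survey`: `participants`,
#'   `household_members`, `nominations`, `truth_edges` (the ground-truth
#'   edge list) and `config`.
#' @export
emit_survey <- function(roster, network) {
  stopifnot(inherits(roster, "community_roster"))
  config <- roster$config
  p <- roster$participants
  if (anyNA(p$reports_any_confidant)) {
    stop("confidant flag missing: pass the roster returned by ",
         "generate_network()")
  }
  if (!all(network$nodes %in% p$participant_id)) {
    stop("network nodes missing from roster")
  }
  comm <- network$edges[network$edges$provenance %in% "community", ,
                        drop = FALSE]
  tgt <- match(comm$to, p$participant_id)
  nominations <- data.frame(
    nominator_id = comm$from,
    family_name_kanji = p$family_name_kanji[tgt],
    given_name_kanji = p$given_name_kanji[tgt],
    family_name_kana = p$family_name_kana[tgt],
    given_name_kana = p$given_name_kana[tgt],
    stringsAsFactors = FALSE
  )
  if (config$mode == "noisy" && config$out_of_roster_rate > 0) {
    set.seed(config$seed + 2L)
    n_extra <- ceiling(config$out_of_roster_rate *
                         max(1, nrow(nominations)))
    if (n_extra > 0) {
      nominators <- sample(p$participant_id, n_extra, replace = TRUE)
      sp <- surname_pool()
      extra <- data.frame(
        nominator_id = nominators,
        family_name_kanji = sp$kanji[sample(nrow(sp), n_extra,
                                            replace = TRUE)],
        given_name_kanji = "外部",      # placeholder given name
        family_name_kana = sp$kana[sample(nrow(sp), n_extra,
                                          replace = TRUE)],
        given_name_kana = "がいぶ",
        stringsAsFactors = FALSE
      )
      nominations <- rbind(nominations, extra)
    }
  }
  structure(list(
    participants = p,
    household_members = roster_household_members(roster),
    nominations = nominations,
    truth_edges = network$edges,
    config = config
  ), class = "community_survey")
}

#' Generate a complete synthetic community
#'
#' Convenience wrapper running [generate_roster()],
#' [generate_network()] and [emit_survey()] in sequence.
#'
#' @param config A [community_config()].
#' @param rules A [tie_rules()] object.
#' @return A list: `roster`, `network`, `survey`, `allowed_pairs`.
#' @export
simulate_community <- function(config, rules = tie_rules()) {
  roster <- generate_roster(config)
  gen <- generate_network(roster, rules)
  survey <- emit_survey(gen$roster, gen$network)
  list(roster = gen$roster, network = gen$network, survey = survey,
       allowed_pairs = gen$allowed_pairs)
}
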