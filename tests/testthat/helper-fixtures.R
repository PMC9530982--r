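# Shared fixtures and independent oracles for the test suite.

# --- tiny roster builder ----------------------------------------------------

# participants with complete scales; override any column afterwards
make_participants <- function(n, sex = rep("male", n),
                              age = rep(70, n),
                              district = rep("D1", n),
                              address = sprintf("A%d", seq_len(n)),
                              household = sprintf("H%d", seq_len(n))) {
  key <- gds_item_key()
  nonsym <- ifelse(key$symptomatic == "yes", "no", "yes")
  gds <- matrix(rep(nonsym, each = n), nrow = n,
                dimnames = list(NULL, sprintf("gds_%02d", 1:15)))
  smc <- matrix(1L, n, 4, dimnames = list(NULL, sprintf("smc_%d", 1:4)))
  tmig <- matrix(1L, n, 13, dimnames = list(NULL, sprintf("tmig_%02d",
                                                          1:13)))
  df <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    family_name_kanji = sprintf("family%d", seq_len(n)),
    given_name_kanji = sprintf("given%d", seq_len(n)),
    family_name_kana = sprintf("fkana%d", seq_len(n)),
    given_name_kana = sprintf("gkana%d", seq_len(n)),
    sex = sex, age = age, district_id = district, address_id = address,
    household_id = household,
    marital_satisfaction = 1L,
    reports_any_confidant = TRUE,
    education_band = "10-12",
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(gds), as.data.frame(smc), smc_severe = 0L,
        as.data.frame(tmig))
}

# nomination row naming participant `target` of a roster
nominate <- function(nominator_id, target_row) {
  data.frame(nominator_id = nominator_id,
             family_name_kanji = target_row$family_name_kanji,
             given_name_kanji = target_row$given_name_kanji,
             family_name_kana = target_row$family_name_kana,
             given_name_kana = target_row$given_name_kana,
             stringsAsFactors = FALSE)
}

# household listing rows: each member of `ids` lists all the others
list_household <- function(participants, ids) {
  rows <- list()
  for (id in ids) {
    others <- participants[participants$participant_id %in%
                             setdiff(ids, id), , drop = FALSE]
    rows[[id]] <- data.frame(
      participant_id = id,
      family_name_kanji = others$family_name_kanji,
      given_name_kanji = others$given_name_kanji,
      family_name_kana = others$family_name_kana,
      given_name_kana = others$given_name_kana,
      sex = others$sex, age = others$age, relationship = "spouse",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

edge_key <- function(edges) sort(paste(edges$from, edges$to))

# --- independent ERGM oracles ----------------------------------------------

# loop-based statistics over ordered pairs; deliberately naive
oracle_stats <- function(adj, node_data, terms) {
  terms <- ergm_terms(terms)
  n <- nrow(adj)
  s <- numeric(nrow(terms))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !adj[i, j]) next
    for (k in seq_len(nrow(terms))) {
      s[k] <- s[k] + switch(terms$kind[k],
        edges = 1,
        mutual = 0,
        nodal = node_data[[terms$attribute[k]]][i] +
          node_data[[terms$attribute[k]]][j],
        absdiff = abs(node_data[[terms$attribute[k]]][i] -
                        node_data[[terms$attribute[k]]][j]))
    }
  }
  if ("mutual" %in% terms$kind) {
    m <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (adj[i, j] && adj[j, i]) m <- m + 1
    }
    s[terms$kind == "mutual"] <- m
  }
  stats::setNames(s, terms$label)
}

# all 2^(n(n-1)) directed graphs on n nodes as adjacency matrices
enumerate_graphs <- function(n) {
  slots <- which(diag(n) == 0)
  lapply(0:(2^length(slots) - 1), function(code) {
    adj <- matrix(FALSE, n, n)
    adj[slots] <- bitwAnd(code, 2^(seq_along(slots) - 1)) > 0
    adj
  })
}

# exact log-likelihood by summing over every directed graph
oracle_loglik <- function(theta, adj_obs, node_data, terms) {
  graphs <- enumerate_graphs(nrow(adj_obs))
  ss <- vapply(graphs, function(g) sum(theta * oracle_stats(g, node_data,
                                                            terms)),
               numeric(1))
  m <- max(ss)
  logZ <- m + log(sum(exp(ss - m)))
  sum(theta * oracle_stats(adj_obs, node_data, terms)) - logZ
}

# random directed network over n nodes with given tie probability
random_network <- function(n, p = 0.3, node_data = NULL) {
  adj <- matrix(stats::runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  ids <- sprintf("n%02d", seq_len(n))
  idx <- which(adj, arr.ind = TRUE)
  if (is.null(node_data)) {
    node_data <- data.frame(participant_id = ids,
                            x = stats::rpois(n, 4))
  } else {
    node_data$participant_id <- ids
  }
  confidant_network(ids, data.frame(from = ids[idx[, 1]],
                                    to = ids[idx[, 2]],
                                    stringsAsFactors = FALSE),
                    node_data = node_data)
}
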