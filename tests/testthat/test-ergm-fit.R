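test_that("exact dyad likelihood equals full-graph enumeration (n = 3, 4)", {
  set.seed(21)
  tt <- c("edges", "mutual", "nodal:x", "absdiff:x")
  for (n in c(3, 4)) {
    net <- random_network(n, p = 0.4)
    for (rep in 1:3) {
      theta <- rnorm(4, 0, 0.7)
      got <- exact_dyad_loglik(theta, net, tt)$loglik
      want <- oracle_loglik(theta, as_adjacency(net), net$node_data, tt)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("the null model has likelihood -D log 4", {
  net <- random_network(5, p = 0.3)
  ll <- exact_dyad_loglik(rep(0, 2), net, c("edges", "mutual"))
  expect_equal(ll$loglik, -10 * log(4))
})

test_that("the edges-only model reduces to the Bernoulli closed form", {
  set.seed(22)
  net <- random_network(12, p = 0.2)
  m <- nrow(net$edges)
  N <- 12 * 11
  theta <- 0.3
  ll <- exact_dyad_loglik(theta, net, "edges")$loglik
  expect_equal(ll, m * theta - N * log(1 + exp(theta)))
  fit <- fit_exact(net, "edges")
  expect_equal(unname(fit$coefficients), qlogis(m / N), tolerance = 1e-7)
})

test_that("exact MLE satisfies the moment equation", {
  set.seed(23)
  tt <- c("edges", "mutual", "absdiff:x")
  net <- simulate_ergm(data.frame(participant_id = sprintf("p%02d", 1:30),
                                  x = rpois(30, 4)),
                       tt, c(-2.5, 1.5, -0.15), nsim = 1)$networks[[1]]
  fit <- fit_exact(net, tt)
  expect_true(fit$converged)
  ll <- exact_dyad_loglik(fit$coefficients, net, tt)
  s_obs <- term_statistics(net, tt)
  # at the MLE the expected statistics equal the observed statistics
  expect_equal(ll$expected_stats, s_obs, tolerance = 1e-5)
})

test_that("MPLE equals the exact MLE for dyad-independent models", {
  set.seed(24)
  tt <- c("edges", "nodal:x", "absdiff:x")
  for (rep in 1:3) {
    net <- random_network(15, p = 0.15)
    fe <- fit_exact(net, tt)
    fm <- fit_mple(net, tt)
    expect_equal(fe$coefficients, fm$coefficients, tolerance = 1e-5)
    expect_equal(fe$se, fm$se, tolerance = 1e-4)
  }
})

test_that("MPLE detects reciprocity on a reciprocity-heavy network", {
  # 10 mutual pairs plus sparse noise: reciprocity coefficient positive
  ids <- sprintf("q%02d", 1:24)
  mut <- data.frame(from = ids[seq(1, 19, 2)], to = ids[seq(2, 20, 2)])
  edges <- rbind(mut, data.frame(from = mut$to, to = mut$from),
                 data.frame(from = ids[21:23], to = ids[22:24]))
  net <- confidant_network(ids, edges,
                           data.frame(participant_id = ids, x = 1))
  fm <- fit_mple(net, c("edges", "mutual"))
  expect_gt(fm$coefficients[["mutual"]], 0)
})

test_that("parameter recovery is unbiased within Monte-Carlo error", {
  set.seed(25)
  tt <- c("edges", "mutual", "absdiff:x")
  # reciprocity strong enough that every replicate carries mutual dyads
  # (the MLE does not exist for a replicate with none)
  theta_star <- c(-3.0, 2.5, -0.15)
  R <- 60
  est <- matrix(NA_real_, R, 3)
  for (r in seq_len(R)) {
    nd <- data.frame(participant_id = sprintf("p%02d", 1:40),
                     x = rpois(40, 4))
    net <- simulate_ergm(nd, tt, theta_star, nsim = 1)$networks[[1]]
    est[r, ] <- fit_exact(net, tt)$coefficients
  }
  mcse <- apply(est, 2, sd) / sqrt(R)
  expect_true(all(abs(colMeans(est) - theta_star) < 3 * mcse))
})

test_that("separation and collinearity are reported, not returned", {
  ids <- c("A", "B", "C")
  nd <- data.frame(participant_id = ids, x = c(1, 1, 1))
  # complete mutual graph: edges MLE is +infinity
  full <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  full <- full[full$from != full$to, ]
  net <- confidant_network(ids, full, nd)
  expect_error(fit_exact(net, "edges"), "separation|boundary")
  # constant attribute makes nodal:x collinear with edges
  net2 <- confidant_network(ids, data.frame(from = "A", to = "B"), nd)
  expect_error(fit_exact(net2, c("edges", "nodal:x")),
               "collinear|singular")
})

test_that("nodes with missing model attributes are dropped listwise", {
  ids <- sprintf("r%d", 1:6)
  nd <- data.frame(participant_id = ids, x = c(1, 2, NA, 4, 5, 6))
  net <- confidant_network(ids, data.frame(from = ids[c(1, 4)],
                                           to = ids[c(2, 5)]), nd)
  fit <- fit_exact(net, c("edges", "absdiff:x"))
  expect_equal(fit$n_dropped, 1)
  expect_equal(fit$n_nodes, 5)
})

test_that("odds-ratio transform reproduces its closed form and ordering", {
  res <- or_ci(-0.052, 0.029)
  expect_equal(res$or, exp(-0.052))
  expect_equal(res$ci_lower, exp(-0.052 - 1.959964 * 0.029))
  expect_equal(res$ci_upper, exp(-0.052 + 1.959964 * 0.029))
  # null coefficient: OR 1, symmetric CI, p = 1
  res0 <- or_ci(0, 0.2)
  expect_equal(res0$or, 1)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$ci_lower * res0$ci_upper, 1)
  # monotone in the coefficient; CI always brackets the OR
  grid <- or_ci(seq(-2, 2, 0.25), 0.1)
  expect_true(all(diff(grid$or) > 0))
  expect_true(all(grid$ci_lower < grid$or & grid$or < grid$ci_upper))
  expect_error(or_ci(1, 0), "positive")
})

test_that("fit tables render the two-decimal reporting convention", {
  tab <- format_fit_table(structure(list(
    terms = ergm_terms(c("edges", "absdiff:x")),
    coefficients = c(edges = -8.67, absdiff.x = -0.052),
    se = c(edges = 0.37, absdiff.x = 0.029),
    z = c(-23.4, -1.8), p_value = c(0, 0.073),
    odds_ratio = exp(c(-8.67, -0.052)),
    ci_lower = exp(c(-8.67, -0.052) - 1.959964 * c(0.37, 0.029)),
    ci_upper = exp(c(-8.67, -0.052) + 1.959964 * c(0.37, 0.029))),
    class = "ergm_fit"))
  expect_equal(tab$or_95ci[2], "0.95 (0.90, 1.00)")
  expect_equal(tab$or_95ci[1], "")  # structural term: no OR reported
})
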