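#' Simulate networks from a dyad-separable directed ERGM
#'
#' Metropolis-Hastings over single-tie toggles: each proposal picks an
#' allowed ordered pair uniformly and flips that tie, accepting with
#' probability min(1, exp(theta . delta)) where delta is the change
#' statistic. Draws are recorded after `burnin` proposals and every
#' `thin` proposals thereafter. Reproducible under `set.seed()` (or pass
#' `seed`).
#'
#' @param node_data Node attribute data frame (one row per node); must
#'   contain a `participant_id` column or nodes are numbered.
#' @param terms Term specification ([ergm_terms()] or character).
#' @param theta Coefficient vector aligned with the terms.
#' @param nsim Number of networks to draw.
#' @param burnin Proposals before the first draw; default `10 * n(n-1)`.
#' @param thin Proposals between draws; default `n(n-1)`.
#' @param allowed Optional dyad support restriction (see
#'   [dyad_design()]).
#' @param init Optional starting network (a [confidant_network()] over
#'   the same nodes); default empty.
#' @param seed Optional integer seed (applied via `set.seed`).
#' @param return_networks Return full `confidant_network` objects
#'   (otherwise only the statistics matrix).
#' @return A list: `networks` (list of [confidant_network()], when
#'   requested), `stats` (nsim x p matrix of sufficient statistics of
#'   each draw), `design`.
#' @export
simulate_ergm <- function(node_data, terms, theta, nsim = 1,
                          burnin = NULL, thin = NULL, allowed = NULL,
                          init = NULL, seed = NULL,
                          return_networks = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  terms <- ergm_terms(terms)
  if (any(!is.finite(theta))) stop("theta must be finite")
  design <- dyad_design(node_data, terms, allowed = allowed)
  if (!nrow(design$A)) stop("empty allowed dyad set")
  n <- design$n
  if (is.null(burnin)) burnin <- 10 * n * (n - 1)
  if (is.null(thin)) thin <- n * (n - 1)
  if (burnin < 0 || thin < 1) stop("burnin must be >= 0 and thin >= 1")
  nodes <- if (!is.null(node_data$participant_id)) {
    as.character(node_data$participant_id)
  } else as.character(seq_len(n))
  init_state <- if (is.null(init)) {
    integer(nrow(design$pairs))
  } else {
    dyad_states(as_adjacency(init), design$pairs)
  }
  res <- mh_sample_dyads(design$A, design$mutual_col, as.numeric(theta),
                         init_state, as.numeric(burnin), as.numeric(thin),
                         as.integer(nsim), isTRUE(return_networks))
  colnames(res$stats) <- design$labels
  networks <- NULL
  if (return_networks) {
    networks <- lapply(res$states, function(st) {
      states_to_network(st, design, nodes, node_data)
    })
  }
  list(networks = networks, stats = res$stats, design = design)
}

# rebuild a confidant_network from a sparse dyad-state record
states_to_network <- function(st, design, nodes, node_data) {
  if (!length(st$dyad)) {
    return(confidant_network(nodes, node_data = node_data))
  }
  i <- design$pairs[st$dyad, 1]
  j <- design$pairs[st$dyad, 2]
  s <- st$state
  from <- c(i[s %in% c(1L, 3L)], j[s %in% c(2L, 3L)])
  to <- c(j[s %in% c(1L, 3L)], i[s %in% c(2L, 3L)])
  confidant_network(nodes,
                    data.frame(from = nodes[from], to = nodes[to],
                               stringsAsFactors = FALSE),
                    node_data = node_data)
}

#' Control settings for Monte-Carlo maximum likelihood
#'
#' @param n_sim Simulated networks per outer iteration.
#' @param burnin,thin Sampler settings per iteration (defaults as in
#'   [simulate_ergm()], except burnin drops to `2 n(n-1)` because chains
#'   restart from the observed network).
#' @param max_outer Outer (resampling) iteration cap.
#' @param max_inner Newton iterations per simulated sample.
#' @param step_max Trust region: largest coefficient change accepted per
#'   outer iteration (importance weights degrade for large steps).
#' @param t_tol Convergence: every term's |observed - simulated mean|
#'   must fall below `t_tol` simulated standard deviations.
#' @return A list of class `mcmle_control`.
#' @export
mcmle_control <- function(n_sim = 512, burnin = NULL, thin = NULL,
                          max_outer = 25, max_inner = 40,
                          step_max = 0.5, t_tol = 0.15) {
  structure(list(n_sim = n_sim, burnin = burnin, thin = thin,
                 max_outer = max_outer, max_inner = max_inner,
                 step_max = step_max, t_tol = t_tol),
            class = "mcmle_control")
}

#' Fit a directed ERGM by Monte-Carlo maximum likelihood
#'
#' The stochastic-approximation estimator used when the normalising
#' constant is intractable: starting from the pseudolikelihood estimate,
#' repeatedly (1) simulate networks at the current coefficients, (2)
#' maximise the importance-sampled likelihood ratio within a trust
#' region, and (3) stop once the simulated mean statistics match the
#' observed statistics to within `t_tol` simulated standard deviations.
#' Standard errors come from the inverse covariance of the simulated
#' sufficient statistics at the final estimate (the Fisher information
#' of an exponential family).
#'
#' For the dyad-separable term family the exact estimator [fit_exact()]
#' is available and faster; this routine exists for fidelity to the
#' MCMC-based estimation workflow and as scaffolding for non-separable
#' extensions, with [fit_exact()] serving as its oracle in the tests.
#'
#' @inheritParams fit_exact
#' @param control An [mcmle_control()] list.
#' @param seed Optional integer seed.
#' @return An `ergm_fit` with `method = "mcmle"`; `diagnostics` carries
#'   the final t-ratios, effective-sample-size estimates and the
#'   simulated statistic means.
#' @export
fit_mcmle <- function(net, terms, allowed = NULL,
                      control = mcmle_control(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prep <- prepare_fit(net, terms, allowed)
  design <- prep$design
  states <- prep$states
  s_obs <- design_statistics(design, states)
  p <- ncol(design$A)
  n <- design$n
  burnin <- control$burnin
  if (is.null(burnin)) burnin <- 2 * n * (n - 1)
  thin <- control$thin
  if (is.null(thin)) thin <- n * (n - 1)

  theta <- coef(fit_mple_prepared(prep))
  converged <- FALSE
  t_ratios <- rep(NA_real_, p)
  S <- NULL
  for (outer in seq_len(control$max_outer)) {
    S <- mh_sample_dyads(design$A, design$mutual_col, theta, states,
                         as.numeric(burnin), as.numeric(thin),
                         as.integer(control$n_sim), FALSE)$stats
    sim_sd <- pmax(apply(S, 2, stats::sd), .Machine$double.eps)
    t_ratios <- (s_obs - colMeans(S)) / sim_sd
    if (all(abs(t_ratios) < control$t_tol)) {
      converged <- TRUE
      break
    }
    theta <- mcmle_update(theta, s_obs, S, control)
  }
  # final variance sample at the accepted estimate
  S <- mh_sample_dyads(design$A, design$mutual_col, theta, states,
                       as.numeric(burnin), as.numeric(thin),
                       as.integer(control$n_sim), FALSE)$stats
  fisher <- stats::cov(S)
  vcov <- tryCatch(solve(fisher), error = function(e) {
    stop("singular simulated-statistic covariance; increase n_sim")
  })
  ess <- apply(S, 2, function(x) {
    r1 <- if (stats::sd(x) > 0) stats::cor(x[-1], x[-length(x)]) else 0
    if (!is.finite(r1)) r1 <- 0
    nrow(S) * (1 - r1) / (1 + r1)
  })
  fit <- new_ergm_fit(theta, vcov, design, method = "mcmle",
                      loglik = NA_real_, converged = converged,
                      iterations = outer, n_dropped = prep$n_dropped,
                      diagnostics = list(
                        t_ratios = setNames(t_ratios, design$labels),
                        ess = setNames(ess, design$labels),
                        sim_mean = setNames(colMeans(S), design$labels),
                        observed = s_obs))
  if (!converged) {
    warning("fit_mcmle did not reach the moment-matching tolerance in ",
            control$max_outer, " iterations (max |t| = ",
            signif(max(abs(t_ratios)), 3), "); inspect $diagnostics")
  }
  fit
}

# one importance-sampled likelihood-ratio maximisation:
# l(theta) - l(theta0) ~= d' s_obs - log mean exp(S d),  d = theta - theta0
mcmle_update <- function(theta0, s_obs, S, control) {
  d <- numeric(length(theta0))
  for (inner in seq_len(control$max_inner)) {
    u <- drop(S %*% d)
    u <- u - max(u)
    w <- exp(u)
    w <- w / sum(w)
    grad <- s_obs - drop(crossprod(S, w))
    Sw <- S * sqrt(w)
    hess <- crossprod(Sw) - tcrossprod(drop(crossprod(S, w)))
    step <- tryCatch(solve(hess + diag(1e-8, ncol(S)), grad),
                     error = function(e) grad / max(abs(grad), 1))
    d_new <- d + step
    # trust region keeps the importance weights usable
    if (max(abs(d_new)) > control$step_max) {
      d_new <- d_new * control$step_max / max(abs(d_new))
    }
    if (max(abs(d_new - d)) < 1e-10) {
      d <- d_new
      break
    }
    d <- d_new
  }
  theta0 + d
}

# MPLE on an already-prepared design (shared with fit_mcmle)
fit_mple_prepared <- function(prep) {
  design <- prep$design
  states <- prep$states
  y_ij <- as.numeric(states == 1L | states == 3L)
  y_ji <- as.numeric(states == 2L | states == 3L)
  X1 <- design$A
  X2 <- design$A
  if (design$mutual_col) {
    X1[, design$mutual_col] <- y_ji
    X2[, design$mutual_col] <- y_ij
  }
  fit <- glm.fit(rbind(X1, X2), c(y_ij, y_ji), family = binomial())
  structure(list(coefficients = setNames(coef(fit), design$labels)),
            class = "mple_init")
}
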