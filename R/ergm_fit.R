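#' Exact log-likelihood of a dyad-separable directed ERGM
#'
#' Because every supported term decomposes over dyads, the model
#' likelihood factorises into independent four-state multinomials (null,
#' i->j, j->i, mutual) per unordered dyad, and the log-likelihood,
#' analytic gradient and Fisher information can be computed exactly:
#' no MCMC approximation of the normalising constant is needed.
#'
#' @param theta Coefficient vector aligned with the terms.
#' @param net A [confidant_network()] (alternatively pass a prebuilt
#'   `design` and `states`).
#' @param terms Term specification (ignored when `design` is given).
#' @param design Optional [dyad_design()] result.
#' @param states Optional per-dyad state vector (0 null, 1 i->j, 2 j->i,
#'   3 mutual) aligned with `design$pairs`.
#' @return A list: `loglik`, `gradient`, `fisher` (the negative Hessian,
#'   equal to the summed per-dyad statistic covariance), and
#'   `expected_stats`.
#' @export
exact_dyad_loglik <- function(theta, net = NULL, terms = NULL,
                              design = NULL, states = NULL) {
  if (is.null(design)) {
    design <- dyad_design(net$node_data, terms)
    states <- dyad_states(as_adjacency(net), design$pairs)
  }
  p <- ncol(design$A)
  stopifnot(length(theta) == p)
  s_obs <- design_statistics(design, states)
  parts <- dyad_probabilities(theta, design)
  loglik <- sum(theta * s_obs) - sum(parts$logZ)
  # E[s] per dyad = 2 p_asym * A + p_mut * (2A + u)
  w_mean <- 2 * parts$p1 + 2 * parts$pm
  es <- drop(crossprod(design$A, w_mean))
  if (design$mutual_col) es[design$mutual_col] <-
      es[design$mutual_col] + sum(parts$pm)
  gradient <- s_obs - es
  # Fisher info = sum_d Var_d(s) = sum E[ss'] - sum (Es)(Es)'
  B <- 2 * design$A
  if (design$mutual_col) B[, design$mutual_col] <-
      B[, design$mutual_col] + 1
  M <- design$A * w_mean                      # per-dyad mean rows E_d[s]
  if (design$mutual_col) M[, design$mutual_col] <-
      M[, design$mutual_col] + parts$pm
  fisher <- crossprod(design$A, design$A * (2 * parts$p1)) +
    crossprod(B, B * parts$pm) - crossprod(M)
  list(loglik = loglik, gradient = gradient, fisher = fisher,
       expected_stats = setNames(es, design$labels))
}

# per-dyad state probabilities under theta: p1 = one asymmetric state,
# pm = mutual; log-sum-exp stabilised
dyad_probabilities <- function(theta, design) {
  eta <- drop(design$A %*% theta)
  theta_mut <- if (design$mutual_col) theta[design$mutual_col] else 0
  etam <- 2 * eta + theta_mut
  m <- pmax(0, eta, etam)
  logZ <- m + log(exp(-m) + 2 * exp(eta - m) + exp(etam - m))
  list(p1 = exp(eta - logZ), pm = exp(etam - logZ), logZ = logZ)
}

#' Fit a dyad-separable ERGM by exact maximum likelihood
#'
#' Newton-Raphson maximisation of [exact_dyad_loglik()] with step
#' halving; standard errors from the inverse observed information, Wald
#' z statistics and two-sided normal p-values, and odds ratios with 95
#' percent confidence intervals via [or_ci()]. Nodes with a missing value
#' on any model attribute are dropped listwise first (count reported).
#'
#' @param net A [confidant_network()].
#' @param terms Term specification ([ergm_terms()] or character).
#' @param allowed Optional dyad support restriction (see
#'   [dyad_design()]); observed ties outside the support are an error.
#' @param tol Convergence tolerance on the max absolute gradient.
#' @param max_iter Newton iteration cap.
#' @param theta_init Optional starting values (default zero).
#' @return An object of class `ergm_fit`.
#' @export
fit_exact <- function(net, terms, allowed = NULL, tol = 1e-8,
                      max_iter = 100, theta_init = NULL) {
  prep <- prepare_fit(net, terms, allowed)
  design <- prep$design
  states <- prep$states
  p <- ncol(design$A)
  # MLE existence: a statistic on the boundary of its attainable range
  # (e.g. an empty or complete graph for edges) has no finite MLE
  s_obs <- design_statistics(design, states)
  B <- 2 * design$A
  if (design$mutual_col) B[, design$mutual_col] <-
      B[, design$mutual_col] + 1
  s_min <- colSums(pmin(design$A, B, 0))
  s_max <- colSums(pmax(design$A, B, 0))
  on_boundary <- (s_obs <= s_min | s_obs >= s_max) & s_max > s_min
  if (any(on_boundary)) {
    stop("observed statistic lies on the boundary of its range for ",
         "term(s) ", paste(design$labels[on_boundary], collapse = ", "),
         ": the MLE does not exist (separation)")
  }
  theta <- if (is.null(theta_init)) numeric(p) else theta_init
  ll <- exact_dyad_loglik(theta, design = design, states = states)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(ll$gradient)) < tol * max(1, max(abs(ll$expected_stats)))) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(ll$fisher, ll$gradient), error = function(e) {
      stop("singular information matrix: the model is collinear or ",
           "separated in terms [",
           paste(design$labels, collapse = ", "), "]")
    })
    # step halving: never accept a decrease in the log-likelihood
    alpha <- 1
    repeat {
      cand <- theta + alpha * step
      ll_new <- exact_dyad_loglik(cand, design = design, states = states)
      if (is.finite(ll_new$loglik) && ll_new$loglik >= ll$loglik - 1e-12) {
        break
      }
      alpha <- alpha / 2
      if (alpha < 1e-8) {
        stop("Newton step failed to improve the likelihood; the MLE may ",
             "not exist (separation) for terms [",
             paste(design$labels, collapse = ", "), "]")
      }
    }
    theta <- cand
    ll <- ll_new
    if (any(abs(theta) > 30)) {
      stop("coefficient diverging (|theta| > 30) for term(s) ",
           paste(design$labels[abs(theta) > 30], collapse = ", "),
           ": the observed statistic lies on the boundary (separation)")
    }
  }
  if (!converged && max(abs(ll$gradient)) <
        1e-5 * max(1, max(abs(ll$expected_stats)))) converged <- TRUE
  vcov <- solve(ll$fisher)
  new_ergm_fit(theta, vcov, design, method = "exact_dyad",
               loglik = ll$loglik, converged = converged,
               iterations = iter, n_dropped = prep$n_dropped,
               diagnostics = list(gradient_norm = max(abs(ll$gradient))))
}

#' Fit a directed ERGM by maximum pseudolikelihood
#'
#' Logistic regression of every ordered-pair tie indicator on its change
#' statistic. For models without the `mutual` term the model is
#' dyad-independent and the MPLE coincides with the exact MLE; with
#' `mutual` it is the classical pseudolikelihood approximation (its
#' standard errors do not account for dyad dependence).
#'
#' @inheritParams fit_exact
#' @return An `ergm_fit` with `method = "mple"`.
#' @export
fit_mple <- function(net, terms, allowed = NULL) {
  prep <- prepare_fit(net, terms, allowed)
  design <- prep$design
  states <- prep$states
  y_ij <- as.numeric(states == 1L | states == 3L)
  y_ji <- as.numeric(states == 2L | states == 3L)
  X1 <- design$A
  X2 <- design$A
  if (design$mutual_col) {
    X1[, design$mutual_col] <- y_ji   # toggling i->j completes a mutual
    X2[, design$mutual_col] <- y_ij   # iff the reverse tie is present
  }
  X <- rbind(X1, X2)
  y <- c(y_ij, y_ji)
  fit <- glm.fit(X, y, family = binomial())
  if (!fit$converged) {
    stop("pseudolikelihood logistic regression did not converge ",
         "(possible separation)")
  }
  mu <- fit$fitted.values
  info <- crossprod(X, X * (mu * (1 - mu)))
  vcov <- tryCatch(solve(info), error = function(e) {
    stop("singular pseudolikelihood information (collinearity)")
  })
  new_ergm_fit(coef(fit), vcov, design, method = "mple",
               loglik = -fit$deviance / 2, converged = fit$converged,
               iterations = fit$iter, n_dropped = prep$n_dropped,
               diagnostics = list())
}

# shared preparation: listwise-drop nodes with missing model attributes,
# build the dyad design and the observed state vector
prepare_fit <- function(net, terms, allowed = NULL) {
  terms <- ergm_terms(terms)
  attrs <- unique(terms$attribute[!is.na(terms$attribute)])
  nd <- net$node_data
  if (length(attrs)) {
    missing_attr <- setdiff(attrs, names(nd))
    if (length(missing_attr)) {
      stop("network lacks node attribute(s): ",
           paste(missing_attr, collapse = ", "))
    }
    complete <- !Reduce(`|`, lapply(attrs, function(a) is.na(nd[[a]])))
  } else {
    complete <- rep(TRUE, network_size(net))
  }
  n_dropped <- sum(!complete)
  if (n_dropped) {
    keep <- net$nodes[complete]
    e <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ,
                   drop = FALSE]
    net <- confidant_network(keep, e, nd[complete, , drop = FALSE])
  }
  design <- dyad_design(net$node_data, terms, allowed = allowed)
  adj <- as_adjacency(net)
  states <- dyad_states(adj, design$pairs)
  if (!is.null(allowed) && sum(adj) > sum(states %in% 1:2) +
        2 * sum(states == 3L)) {
    stop("observed ties fall outside the allowed dyad support")
  }
  list(design = design, states = states, n_dropped = n_dropped, net = net)
}

#' Odds ratio and 95 percent Wald confidence interval
#'
#' The reporting transform used in the fit tables: OR = exp(coefficient),
#' CI bounds exp(coefficient -/+ z * SE) with the two-sided 95 percent
#' normal quantile z = 1.959964, and a two-sided normal p-value for
#' coefficient / SE. Values are returned at full precision; rounding to
#' two decimals happens only in [format_fit_table()].
#'
#' @param coefficient,standard_error Numeric (vectorised); every SE must
#'   be positive.
#' @return Data frame with `or`, `ci_lower`, `ci_upper`, `p_value`.
#' @examples
#' or_ci(-0.052, 0.029)  # OR 0.95, CI 0.90-1.00 at two decimals
#' @export
or_ci <- function(coefficient, standard_error) {
  if (any(is.na(standard_error)) || any(standard_error <= 0)) {
    stop("standard errors must be positive")
  }
  z975 <- 1.959964
  data.frame(
    or = exp(coefficient),
    ci_lower = exp(coefficient - z975 * standard_error),
    ci_upper = exp(coefficient + z975 * standard_error),
    p_value = 2 * pnorm(-abs(coefficient / standard_error))
  )
}

new_ergm_fit <- function(theta, vcov, design, method, loglik, converged,
                         iterations, n_dropped, diagnostics) {
  theta <- setNames(as.numeric(theta), design$labels)
  se <- sqrt(diag(vcov))
  tr <- or_ci(theta, se)
  structure(list(
    terms = design$terms,
    coefficients = theta,
    se = setNames(se, design$labels),
    vcov = vcov,
    z = setNames(theta / se, design$labels),
    p_value = setNames(tr$p_value, design$labels),
    odds_ratio = setNames(tr$or, design$labels),
    ci_lower = setNames(tr$ci_lower, design$labels),
    ci_upper = setNames(tr$ci_upper, design$labels),
    method = method,
    loglik = loglik,
    converged = converged,
    iterations = iterations,
    n_nodes = design$n,
    n_dyads = nrow(design$A),
    n_dropped = n_dropped,
    diagnostics = diagnostics
  ), class = "ergm_fit")
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat(sprintf("Dyad-separable directed ERGM (%s)\n", x$method))
  cat(sprintf("  %d nodes, %d dyads in support; %d node(s) dropped for ",
              x$n_nodes, x$n_dyads, x$n_dropped))
  cat("missing attributes\n")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  print(format_fit_table(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ergm_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  log-likelihood: %.3f; iterations: %d\n",
              object$loglik, object$iterations))
  invisible(object)
}

#' Full-precision coefficient table of a fit
#' @param x An `ergm_fit`.
#' @param ... Unused.
#' @return Data frame: term, coefficient, se, z, p_value, or, ci bounds.
#' @export
as.data.frame.ergm_fit <- function(x, ...) {
  data.frame(term = names(x$coefficients),
             coefficient = unname(x$coefficients),
             se = unname(x$se), z = unname(x$z),
             p_value = unname(x$p_value),
             or = unname(x$odds_ratio),
             ci_lower = unname(x$ci_lower),
             ci_upper = unname(x$ci_upper),
             stringsAsFactors = FALSE)
}

#' Report-style coefficient table
#'
#' The reporting convention of the fit tables: coefficients and odds
#' ratios to two decimals, with the OR column rendered as
#' "OR (lower, upper)". Structural terms (edges, mutual) keep their
#' coefficients but show no odds ratio.
#'
#' @param fit An `ergm_fit`.
#' @return Data frame: term, coefficient, se, p_value, or_95ci.
#' @export
format_fit_table <- function(fit) {
  tab <- as.data.frame(fit)
  structural <- fit$terms$kind %in% c("edges", "mutual")
  or_str <- sprintf("%.2f (%.2f, %.2f)", tab$or, tab$ci_lower,
                    tab$ci_upper)
  or_str[structural] <- ""
  data.frame(term = tab$term,
             coefficient = round(tab$coefficient, 2),
             se = signif(tab$se, 2),
             p_value = round(tab$p_value, 3),
             or_95ci = or_str,
             stringsAsFactors = FALSE)
}
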