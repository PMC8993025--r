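#' Quadrature grid over the latent ability scale
#'
#' Equally spaced nodes with standard-normal weights renormalized to sum to
#' one; the default (61 nodes on [-6, 6]) follows common practice for
#' marginal-likelihood work in item response models.
#'
#' @param n Number of nodes (>= 5).
#' @param bounds Length-2 interval covered by the nodes.
#' @return List with `nodes` and `weights`, class `quadrature_grid`.
#' @export
quadrature_grid <- function(n = 61L, bounds = c(-6, 6)) {
  stopifnot(n >= 5L, length(bounds) == 2L, bounds[1] < bounds[2])
  nodes <- seq(bounds[1], bounds[2], length.out = n)
  w <- dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)),
            class = "quadrature_grid")
}

# Per-person total log-likelihood at each node (P x Q), via the C++ kernel.
.loglik_at_nodes <- function(X, bank, nodes, floor = .PROB_FLOOR) {
  items <- bank$items[colnames(X)]
  grm_loglik_nodes(
    X, vapply(items, `[[`, integer(1), "n_categories"),
    vapply(items, `[[`, numeric(1), "discrimination"),
    lapply(items, `[[`, "thresholds"),
    nodes, floor)
}

# Normalized posterior weights over nodes plus the marginal log-likelihood.
.posterior_weights <- function(L, weights) {
  lp <- sweep(L, 2L, log(weights), `+`)
  m <- apply(lp, 1L, max)
  W <- exp(lp - m)
  marg <- rowSums(W)
  list(W = W / marg, loglik = sum(log(marg) + m))
}

# Expected complete-data negative log-likelihood for one item and gradient,
# in the unconstrained parameterization (log lambda, tau_2, log increments).
.item_mstep_obj <- function(par, R, nodes, J) {
  lam <- exp(par[1])
  tau <- cumsum(c(par[2], exp(par[-(1:2)])))
  cum <- cbind(1, plogis(lam * outer(nodes, tau, `-`)), 0, deparse.level = 0)
  P <- pmax(cum[, 1:J, drop = FALSE] - cum[, 2:(J + 1L), drop = FALSE], .PROB_FLOOR)
  -sum(R * log(P))
}

.item_mstep_grad <- function(par, R, nodes, J) {
  lam <- exp(par[1])
  tau <- cumsum(c(par[2], exp(par[-(1:2)])))
  cum <- cbind(1, plogis(lam * outer(nodes, tau, `-`)), 0, deparse.level = 0)
  P <- pmax(cum[, 1:J, drop = FALSE] - cum[, 2:(J + 1L), drop = FALSE], .PROB_FLOOR)
  G <- R / P
  f <- cum * (1 - cum)
  # d nll / d lambda via D_j = (theta - tau_j) f_j (0 at virtual bounds)
  D <- cbind(0, outer(nodes, tau, `-`) * f[, 2:J, drop = FALSE], 0,
             deparse.level = 0)
  glam <- -sum(G * (D[, 1:J, drop = FALSE] - D[, 2:(J + 1L), drop = FALSE]))
  # d nll / d tau_m = sum_q lambda f_m (G_{q,m} - G_{q,m-1}), m = 2..J
  gtau <- vapply(seq_len(J - 1L), function(m) {
    lam * sum(f[, m + 1L] * (G[, m + 1L] - G[, m]))
  }, numeric(1))
  gpar <- numeric(length(par))
  gpar[1] <- glam * lam
  gpar[2] <- sum(gtau)
  if (J > 2L)
    gpar[-(1:2)] <- rev(cumsum(rev(gtau)))[-1L] * exp(par[-(1:2)])
  gpar
}

# Data-driven starting thresholds: logistic quantiles of the observed
# cumulative frequencies, nudged apart where degenerate.
.init_thresholds <- function(codes, J) {
  codes <- codes[!is.na(codes)]
  pge <- vapply(2:J, function(j) mean(codes >= j), numeric(1))
  pge <- pmin(pmax(pge, 0.01), 0.99)
  tau <- qnorm(1 - pge)
  for (k in seq_along(tau)[-1L])
    if (tau[k] <= tau[k - 1L] + 0.05) tau[k] <- tau[k - 1L] + 0.05
  tau
}

#' Calibrate an item bank by marginal maximum likelihood (Bock-Aitkin EM)
#'
#' Empirical-Bayes calibration: the latent ability density is fixed at
#' N(0, 1) (which imposes the location and scale that make the GRM
#' identifiable) and item parameters maximize the marginal likelihood.  The
#' E-step computes each person's posterior over a fixed quadrature grid; the
#' M-step refits every item against its expected category counts in an
#' unconstrained parameterization (log slope, first threshold, log threshold
#' increments) so positivity and ordering hold by construction.
#'
#' @param responses Response matrix (see [response_matrix()]); `NA` entries
#'   are missing at random and contribute nothing.
#' @param grid Quadrature grid, default `quadrature_grid()`.
#' @param tol Convergence tolerance on the change in marginal log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param domain Domain label for the returned bank.
#' @return A `grm_mml_fit`: list with the calibrated `bank`, a
#'   `person_estimates` data frame (EAP under the N(0,1) latent, method tag
#'   `"CALIBRATION"`), the `loglik_trace`, `converged` flag and
#'   `n_iterations`.
#' @export
calibrate_mml <- function(responses, grid = quadrature_grid(),
                          tol = 1e-5, max_iter = 500L, domain = "domain") {
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  if (ncol(X) < 2L) stop("calibration requires at least 2 items")
  J <- integer(ncol(X))
  for (i in seq_len(ncol(X))) {
    codes <- X[, i][!is.na(X[, i])]
    if (length(codes) == 0L)
      stop(sprintf("item '%s' has no observed responses", colnames(X)[i]))
    J[i] <- max(codes)
    seen <- tabulate(codes, nbins = J[i])
    if (any(seen == 0L))
      stop(sprintf("item '%s': category %d never observed; collapse categories before calibrating",
                   colnames(X)[i], which(seen == 0L)[1]))
    if (J[i] < 2L)
      stop(sprintf("item '%s' shows a single category; uninformative", colnames(X)[i]))
  }

  items <- lapply(seq_len(ncol(X)), function(i) {
    item_params(colnames(X)[i], 1, .init_thresholds(X[, i], J[i]))
  })
  bank <- item_bank(items, domain = domain)

  nodes <- grid$nodes
  w <- grid$weights
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  # per-item indicator matrices (persons x categories), NA rows all-zero
  ind <- lapply(seq_len(ncol(X)), function(i) {
    M <- outer(X[, i], seq_len(J[i]), `==`)
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })

  repeat {
    iter <- iter + 1L
    L <- .loglik_at_nodes(X, bank, nodes)
    es <- .posterior_weights(L, w)
    trace <- c(trace, es$loglik)
    if (iter > 1L && abs(trace[iter] - trace[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    for (i in seq_len(ncol(X))) {
      R <- crossprod(es$W, ind[[i]])          # Q x J expected counts
      it <- bank$items[[i]]
      par0 <- c(log(it$discrimination), it$thresholds[1],
                if (J[i] > 2L) log(diff(it$thresholds)))
      opt <- optim(par0, .item_mstep_obj, .item_mstep_grad,
                   R = R, nodes = nodes, J = J[i],
                   method = "BFGS", control = list(maxit = 100L))
      bank$items[[i]] <- item_params(
        it$id, exp(opt$par[1]),
        cumsum(c(opt$par[2], exp(opt$par[-(1:2)]))))
    }
  }

  L <- .loglik_at_nodes(X, bank, nodes)
  es <- .posterior_weights(L, w)
  m1 <- drop(es$W %*% nodes)
  m2 <- drop(es$W %*% nodes^2)
  person_estimates <- data.frame(
    person_id = rownames(X) %||% sprintf("p%03d", seq_len(nrow(X))),
    theta = m1,
    se = sqrt(pmax(m2 - m1^2, 0)),
    method = "CALIBRATION",
    flagged = FALSE,
    stringsAsFactors = FALSE)
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations", iter))
  structure(list(bank = bank, person_estimates = person_estimates,
                 loglik_trace = trace, converged = converged,
                 n_iterations = iter),
            class = "grm_mml_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.grm_mml_fit <- function(x, ...) {
  cat(sprintf("<grm_mml_fit> %d items, %d persons; %d EM iterations (%s); logLik %.2f\n",
              n_items(x$bank), nrow(x$person_estimates), x$n_iterations,
              if (x$converged) "converged" else "NOT converged",
              tail(x$loglik_trace, 1)))
  invisible(x)
}

#' EAP ability estimate under the standard-normal latent density
#'
#' Posterior mean and standard deviation of ability for one person under the
#' N(0, 1) population density used at MML calibration, computed on a
#' quadrature grid.  This is the calibration-time score implied by the
#' empirical-Bayes model.
#'
#' @param responses Named (or bank-aligned) integer vector of codes.
#' @param bank A calibrated `grm_bank`.
#' @param grid Quadrature grid.
#' @return A one-row data frame `AbilityEstimate` (theta, se,
#'   method = "CALIBRATION", flagged).
#' @export
eap_under_standard_normal <- function(responses, bank, grid = quadrature_grid()) {
  ll <- log_likelihood(grid$nodes, responses, bank)
  lp <- ll + log(grid$weights)
  W <- exp(lp - max(lp))
  W <- W / sum(W)
  m1 <- sum(W * grid$nodes)
  m2 <- sum(W * grid$nodes^2)
  data.frame(person_id = NA_character_, theta = m1,
             se = sqrt(max(m2 - m1^2, 0)),
             method = "CALIBRATION", flagged = FALSE,
             stringsAsFactors = FALSE)
}

#' @importFrom utils tail
NULL
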