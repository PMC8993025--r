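#' Configuration for ability scoring
#'
#' @param truncation_bound Half-width B of the compact support of the EAP
#'   prior (default 5; under a unit-normal population, scores beyond +/-5 SD
#'   are about one-in-1.7-million events, so the bound loses essentially no
#'   mass while preventing divergent estimates).
#' @param prior_sd SD of the (pre-truncation) normal EAP prior.
#' @param quadrature_points Grid size on `[-B, B]` for the EAP integrals.
#' @param optimizer_bounds Search interval for likelihood-based estimators.
#' @param fixed_point_tol Convergence tolerance for the MML scoring fixed
#'   point.
#' @param max_fixed_point_iters Iteration cap for the MML scoring fixed
#'   point.
#' @return List of class `scoring_config`.
#' @export
scoring_config <- function(truncation_bound = 5, prior_sd = 1,
                           quadrature_points = 141L,
                           optimizer_bounds = c(-6, 6),
                           fixed_point_tol = 1e-4,
                           max_fixed_point_iters = 50L) {
  stopifnot(truncation_bound > 0, prior_sd > 0, quadrature_points >= 21L,
            length(optimizer_bounds) == 2L,
            optimizer_bounds[1] < optimizer_bounds[2],
            fixed_point_tol > 0, max_fixed_point_iters >= 1L)
  structure(list(truncation_bound = truncation_bound, prior_sd = prior_sd,
                 quadrature_points = as.integer(quadrature_points),
                 optimizer_bounds = optimizer_bounds,
                 fixed_point_tol = fixed_point_tol,
                 max_fixed_point_iters = as.integer(max_fixed_point_iters)),
            class = "scoring_config")
}

.estimate <- function(theta, se, method, flagged = FALSE) {
  data.frame(person_id = NA_character_, theta = theta, se = se,
             method = method, flagged = flagged, stringsAsFactors = FALSE)
}

# Maximize a smooth scalar objective on a bounded interval with restarts at
# {-2, 0, 2}; ties (within 1e-8 in objective) break toward the theta nearest 0.
.maximize_bounded <- function(obj, bounds, starts = c(-2, 0, 2)) {
  starts <- pmin(pmax(starts, bounds[1]), bounds[2])
  cand <- lapply(starts, function(s) {
    o <- optim(s, function(t) -obj(t), method = "L-BFGS-B",
               lower = bounds[1], upper = bounds[2])
    list(theta = o$par, value = -o$value)
  })
  vals <- vapply(cand, `[[`, numeric(1), "value")
  best <- max(vals)
  near <- which(vals >= best - 1e-8)
  th <- vapply(cand[near], `[[`, numeric(1), "theta")
  th[which.min(abs(th))]
}

#' Maximum likelihood ability score
#'
#' Maximizes the GRM log-likelihood over the optimizer bounds; the standard
#' error is the Cramer-Rao value `1/sqrt(I(theta_hat))`.  All-lowest or
#' all-highest response patterns drive the ML estimate to a bound; such
#' estimates are pinned there and flagged.
#'
#' @param responses Named (or bank-aligned) integer vector of codes.
#' @param bank A calibrated `grm_bank`.
#' @param config A [scoring_config()].
#' @return One-row `AbilityEstimate` data frame (theta, se, method = "MLE",
#'   flagged).
#' @export
score_mle <- function(responses, bank, config = scoring_config()) {
  b <- config$optimizer_bounds
  th <- .maximize_bounded(function(t) log_likelihood(t, responses, bank), b)
  flagged <- FALSE
  if (min(th - b[1], b[2] - th) < 1e-6) {
    flagged <- TRUE
    warning("ML estimate pinned to the optimizer bound; pattern is extreme")
  }
  .estimate(th, 1 / sqrt(fisher_information(th, bank)), "MLE", flagged)
}

#' Weighted likelihood (Warm-type) ability score
#'
#' Maximizes `l(theta) + 0.5 * log I(theta)` -- the Jeffreys-mode weighted
#' likelihood.  For dichotomous two-parameter items this is exactly Warm's
#' bias-corrected estimator; for polytomous items it is the Jeffreys-prior
#' mode, which shares the property of staying finite for all-extreme
#' response patterns.  SE is `1/sqrt(I(theta_hat))`.
#'
#' @inheritParams score_mle
#' @return One-row `AbilityEstimate` data frame (method = "WLE").
#' @export
score_wle <- function(responses, bank, config = scoring_config()) {
  b <- config$optimizer_bounds
  obj <- function(t) log_likelihood(t, responses, bank) +
    0.5 * log(pmax(fisher_information(t, bank), 1e-300))
  th <- .maximize_bounded(obj, b)
  flagged <- min(th - b[1], b[2] - th) < 1e-6
  .estimate(th, 1 / sqrt(fisher_information(th, bank)), "WLE", flagged)
}

#' EAP ability score under a truncated-normal prior
#'
#' Posterior mean and SD of ability under a Normal(0, prior_sd^2) prior
#' truncated to `[-B, B]`, computed on an equally spaced quadrature grid.
#' The compact support caps the influence of extreme response patterns: the
#' estimate is always strictly inside the truncation interval.
#'
#' @inheritParams score_mle
#' @return One-row `AbilityEstimate` data frame (method = "EAP").
#' @export
score_eap_truncated <- function(responses, bank, config = scoring_config()) {
  B <- config$truncation_bound
  grid <- seq(-B, B, length.out = config$quadrature_points)
  lp <- log_likelihood(grid, responses, bank) +
    dnorm(grid, 0, config$prior_sd, log = TRUE)
  W <- exp(lp - max(lp))
  W <- W / sum(W)
  m1 <- sum(W * grid)
  m2 <- sum(W * grid^2)
  .estimate(m1, sqrt(max(m2 - m1^2, 0)), "EAP")
}

#' Marginal-maximum-likelihood ability score
#'
#' Fixed point of: maximize the marginal log-likelihood
#' `sum_i log marginal_category_prob(theta, s, item_i, x_i)` over theta with
#' the score variance imposed as `s = 1/sqrt(I(theta))`, recomputing `s` at
#' each iterate.  Initialized at the truncated-prior EAP estimate.  The
#' integration over the score distribution induces shrinkage relative to
#' plain maximum likelihood.
#'
#' @inheritParams score_mle
#' @return One-row `AbilityEstimate` data frame (method = "MML"); `flagged`
#'   is `TRUE` when the fixed point did not converge within
#'   `max_fixed_point_iters`.
#' @export
score_mml <- function(responses, bank, config = scoring_config()) {
  resp <- .align_responses(responses, bank)
  obs <- which(!is.na(resp))
  if (length(obs) == 0L) stop("person has no observed responses; unscorable")
  b <- config$optimizer_bounds
  th <- score_eap_truncated(responses, bank, config)$theta
  conv <- FALSE
  # vectorized over items: thresholds bracketing each observed code
  lam <- vapply(bank$items[obs], `[[`, numeric(1), "discrimination")
  tau_lo <- tau_hi <- numeric(length(obs))
  for (k in seq_along(obs)) {
    it <- bank$items[[obs[k]]]
    x <- resp[obs[k]]
    tau_lo[k] <- if (x == 1L) -Inf else it$thresholds[x - 1L]
    tau_hi[k] <- if (x == it$n_categories) Inf else it$thresholds[x]
  }
  cc <- .PROBIT_C
  for (k in seq_len(config$max_fixed_point_iters)) {
    s <- 1 / sqrt(fisher_information(th, bank))
    shrink <- sqrt(1 + cc^2 * lam^2 * s^2)
    obj <- function(t) {
      plo <- ifelse(is.finite(tau_lo),
                    pnorm(cc * lam * (t - tau_lo) / shrink), 1)
      phi <- ifelse(is.finite(tau_hi),
                    pnorm(cc * lam * (t - tau_hi) / shrink), 0)
      sum(log(pmax(plo - phi, .PROB_FLOOR)))
    }
    th_new <- .maximize_bounded(obj, b)
    if (abs(th_new - th) < config$fixed_point_tol) {
      th <- th_new
      conv <- TRUE
      break
    }
    th <- th_new
  }
  if (!conv)
    warning("MML score fixed point did not converge; returning last iterate")
  .estimate(th, 1 / sqrt(fisher_information(th, bank)), "MML", !conv)
}

#' Score every person in a response matrix
#'
#' Applies the chosen estimator person by person, preserving row order.
#' Persons with no observed responses are returned with `NA` estimates and
#' flagged; counts of flagged and unscorable persons are reported via
#' `message()`.
#'
#' @param responses Response matrix.
#' @param bank A calibrated `grm_bank`.
#' @param method One of `"mle"`, `"wle"`, `"eap"`, `"mml"`,
#'   `"calibration"` (EAP under the untruncated standard-normal latent).
#' @param config A [scoring_config()].
#' @return Data frame with columns person_id, theta, se, method, flagged.
#' @export
score_all <- function(responses, bank,
                      method = c("eap", "mle", "wle", "mml", "calibration"),
                      config = scoring_config()) {
  method <- match.arg(method)
  scorer <- switch(method,
                   mle = score_mle, wle = score_wle,
                   eap = score_eap_truncated, mml = score_mml,
                   calibration = function(r, b, config) eap_under_standard_normal(r, b))
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  ids <- rownames(X) %||% sprintf("p%03d", seq_len(nrow(X)))
  if (nrow(X) == 0L)
    return(data.frame(person_id = character(0), theta = numeric(0),
                      se = numeric(0), method = character(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  rows <- vector("list", nrow(X))
  n_unscorable <- 0L
  for (p in seq_len(nrow(X))) {
    resp <- X[p, ]
    names(resp) <- colnames(X)
    if (all(is.na(resp))) {
      n_unscorable <- n_unscorable + 1L
      rows[[p]] <- .estimate(NA_real_, NA_real_, toupper(method), TRUE)
    } else {
      rows[[p]] <- suppressWarnings(scorer(resp, bank, config = config))
    }
    rows[[p]]$person_id <- ids[p]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_flagged <- sum(out$flagged)
  if (n_unscorable || n_flagged)
    message(sprintf("score_all[%s]: %d flagged, %d unscorable of %d persons",
                    method, n_flagged, n_unscorable, nrow(X)))
  out
}
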