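#' @useDynLib grmcv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm pnorm qnorm plogis dcauchy rnorm runif optim
#'   integrate sd var cor lm coef optimize
NULL

# Probability floor applied before any log so deviances stay finite for
# extreme response patterns.
.PROB_FLOOR <- 1e-12

# Logistic-to-probit scaling constant.  The minimax choice 1/1.702 keeps the
# boundary-curve approximation within 0.0095 absolute and category
# probabilities (differences of two boundary curves) within 0.02; the
# derivative-matched sqrt(pi/8) exceeds 0.02 on category differences.
.PROBIT_C <- 1 / 1.702

#' Item parameters for one graded-response item
#'
#' Bundles a positive discrimination (logit slope) with the strictly
#' increasing thresholds at which the cumulative probability of responding in
#' category `j` or above equals one half.  An item with `J` ordered categories
#' carries `J - 1` free thresholds; the boundary thresholds are virtual
#' (-Inf and +Inf) so cumulative probabilities telescope without
#' special-casing the first or last category.
#'
#' @param id Item identifier (scalar character).
#' @param discrimination Positive slope `lambda` on the logit scale.
#' @param thresholds Numeric vector of strictly increasing thresholds on the
#'   ability scale; its length fixes the number of categories to
#'   `length(thresholds) + 1`.
#' @return An object of class `grm_item`.
#' @export
#' @examples
#' item_params("it1", discrimination = 1.4, thresholds = c(-1, 0.5))
item_params <- function(id, discrimination, thresholds) {
  stopifnot(length(id) == 1L, length(discrimination) == 1L)
  if (!is.finite(discrimination) || discrimination <= 0)
    stop("discrimination must be a positive finite number")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || anyNA(thresholds))
    stop("at least one finite threshold is required")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  structure(
    list(id = as.character(id),
         n_categories = length(thresholds) + 1L,
         discrimination = as.numeric(discrimination),
         thresholds = thresholds),
    class = "grm_item")
}

#' Item bank for one unidimensional domain
#'
#' @param items List of [item_params()] objects with unique ids.
#' @param domain Label for the domain (dimension) this bank measures.
#' @return An object of class `grm_bank`.
#' @export
item_bank <- function(items, domain = "domain") {
  if (length(items) == 0L) stop("an item bank must contain at least one item")
  ok <- vapply(items, inherits, logical(1), what = "grm_item")
  if (!all(ok)) stop("all elements of `items` must be grm_item objects")
  ids <- vapply(items, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("item ids must be unique")
  names(items) <- ids
  structure(list(domain = domain, items = items), class = "grm_bank")
}

#' @export
print.grm_bank <- function(x, ...) {
  J <- vapply(x$items, `[[`, integer(1), "n_categories")
  cat(sprintf("<grm_bank> domain '%s': %d items, %d-%d categories\n",
              x$domain, length(x$items), min(J), max(J)))
  invisible(x)
}

#' Number of items in a bank
#' @param bank A `grm_bank`.
#' @return Integer count.
#' @export
n_items <- function(bank) length(bank$items)

#' Item identifiers of a bank
#' @param bank A `grm_bank`.
#' @return Character vector.
#' @export
item_ids <- function(bank) names(bank$items)

#' Construct and validate an ordinal response matrix
#'
#' Responses are stored as an integer matrix, persons in rows and items in
#' columns, with codes `1..J_i` and `NA` for missing.  When a bank is given,
#' every non-missing code is checked against that item's category count and
#' persons with no observed responses are rejected.
#'
#' @param x Matrix or data frame of integer codes (NA = missing) with row
#'   names as person ids and column names as item ids.
#' @param bank Optional `grm_bank` used to validate codes column by column.
#' @return An integer matrix with dimnames, class `grm_responses`.
#' @export
response_matrix <- function(x, bank = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(rownames(x))) rownames(x) <- sprintf("p%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) stop("response matrix must have item column names")
  if (anyDuplicated(rownames(x))) stop("duplicate person ids")
  if (any(x < 1L, na.rm = TRUE)) stop("response codes must be >= 1")
  if (!is.null(bank)) {
    missing_items <- setdiff(colnames(x), item_ids(bank))
    if (length(missing_items))
      stop("items absent from bank: ", paste(missing_items, collapse = ", "))
    for (id in colnames(x)) {
      J <- bank$items[[id]]$n_categories
      bad <- which(!is.na(x[, id]) & x[, id] > J)
      if (length(bad))
        stop(sprintf("invalid code for item '%s' (J=%d) in rows: %s",
                     id, J, paste(rownames(x)[bad], collapse = ", ")))
    }
    if (nrow(x) > 0) {
      allmiss <- rowSums(!is.na(x)) == 0L
      if (any(allmiss))
        stop("persons with no observed responses: ",
             paste(rownames(x)[allmiss], collapse = ", "))
    }
  }
  class(x) <- c("grm_responses", class(x))
  x
}

#' Cumulative response probability Pr(X >= j | theta)
#'
#' The graded response model's boundary characteristic curve: the probability
#' of responding in category `j` or above is `plogis(lambda * (theta -
#' tau_j))`, with the conventions `tau_1 = -Inf` (probability 1) and
#' `tau_{J+1} = +Inf` (probability 0).
#'
#' @param theta Ability value(s).
#' @param item A `grm_item`.
#' @param j Category index in `1..J+1`.
#' @return Probability (vectorized over `theta`).
#' @export
cumulative_prob <- function(theta, item, j) {
  J <- item$n_categories
  if (length(j) != 1L || j < 1L || j > J + 1L)
    stop(sprintf("category index j=%s out of range 1..%d", j, J + 1L))
  if (j == 1L) return(rep(1, length(theta)))
  if (j == J + 1L) return(rep(0, length(theta)))
  plogis(item$discrimination * (theta - item$thresholds[j - 1L]))
}

#' Category probabilities Pr(X = j | theta) for all categories
#'
#' Differences of adjacent cumulative probabilities.  For a vector `theta`
#' a `length(theta) x J` matrix is returned.
#'
#' @inheritParams cumulative_prob
#' @return Numeric vector of length `J` (or matrix for vector `theta`);
#'   entries are non-negative and sum to 1.
#' @export
category_prob <- function(theta, item) {
  J <- item$n_categories
  z <- outer(theta, item$thresholds, function(t, tau) item$discrimination * (t - tau))
  cum <- cbind(1, plogis(z), 0, deparse.level = 0)
  p <- cum[, 1:J, drop = FALSE] - cum[, 2:(J + 1L), drop = FALSE]
  if (length(theta) == 1L) drop(p) else p
}

#' GRM log-likelihood of one person's responses
#'
#' Sum of log category probabilities over the person's observed items;
#' probabilities are floored at `floor` before taking logs so the value stays
#' finite for arbitrarily extreme abilities.
#'
#' @param theta Ability value(s); vectorized for grid evaluation.
#' @param responses Named integer vector of codes (names = item ids, NA =
#'   missing), or unnamed vector aligned with the bank's item order.
#' @param bank A `grm_bank`.
#' @param floor Probability floor (default 1e-12).
#' @return Log-likelihood, vectorized over `theta`.
#' @export
log_likelihood <- function(theta, responses, bank, floor = .PROB_FLOOR) {
  responses <- .align_responses(responses, bank)
  obs <- which(!is.na(responses))
  if (length(obs) == 0L) stop("person has no observed responses; unscorable")
  ll <- numeric(length(theta))
  for (i in obs) {
    p <- category_prob(theta, bank$items[[i]])
    p <- if (is.matrix(p)) p[, responses[i]] else p[responses[i]]
    ll <- ll + log(pmax(p, floor))
  }
  ll
}

.align_responses <- function(responses, bank) {
  if (!is.null(names(responses))) {
    out <- rep(NA_integer_, n_items(bank))
    names(out) <- item_ids(bank)
    keep <- intersect(names(responses), item_ids(bank))
    out[keep] <- as.integer(responses[keep])
    out
  } else {
    if (length(responses) != n_items(bank))
      stop("unnamed responses must match the bank's item count")
    as.integer(responses)
  }
}

#' Fisher information of the GRM response pattern
#'
#' Expected information `I(theta) = sum_i sum_j (dP_ij/dtheta)^2 / P_ij`,
#' additive over items.  Its inverse is the Cramer-Rao lower bound on the
#' variance of unbiased ability estimators and supplies the standard errors
#' reported with ML, weighted-likelihood and MML scores.
#'
#' @param theta Ability value(s).
#' @param bank A `grm_bank`.
#' @param items Optional character vector of item ids restricting the sum.
#' @return Non-negative information, vectorized over `theta`.
#' @export
fisher_information <- function(theta, bank, items = NULL) {
  use <- if (is.null(items)) item_ids(bank) else items
  if (length(use) == 0L) {
    warning("empty item subset: information is 0")
    return(rep(0, length(theta)))
  }
  bad <- setdiff(use, item_ids(bank))
  if (length(bad)) stop("unknown items: ", paste(bad, collapse = ", "))
  info <- numeric(length(theta))
  for (id in use) {
    it <- bank$items[[id]]
    J <- it$n_categories
    z <- outer(theta, it$thresholds,
               function(t, tau) it$discrimination * (t - tau))
    cum <- cbind(1, plogis(z), 0, deparse.level = 0)
    f <- cum * (1 - cum)                       # density terms; 0 at bounds
    dP <- it$discrimination * (f[, 1:J, drop = FALSE] - f[, 2:(J + 1L), drop = FALSE])
    P <- pmax(cum[, 1:J, drop = FALSE] - cum[, 2:(J + 1L), drop = FALSE], .PROB_FLOOR)
    info <- info + rowSums(dP^2 / P)
  }
  info
}

#' Gaussian-smoothed logistic cumulative probability
#'
#' Probit-style closed form for the integral of the logistic boundary curve
#' against a normal ability distribution,
#' `J(theta, sigma; lambda, tau) = Integral plogis(lambda (phi - tau)) dN(phi; theta, sigma^2)`,
#' approximated as `pnorm(c * lambda * (theta - tau) / sqrt(1 + c^2 lambda^2
#' sigma^2))` with the minimax logistic-probit constant `c = 1/1.702`.  At
#' `sigma = 0` this reduces to the usual probit approximation of the
#' logistic; boundary thresholds map to exact probabilities 1 and 0.
#'
#' @param theta Ability estimate (mean of the Gaussian).
#' @param sigma Non-negative standard deviation of the Gaussian.
#' @param lambda Positive discrimination.
#' @param tau Threshold; `-Inf` and `+Inf` are honoured exactly.
#' @return Probability, vectorized over `theta`.
#' @export
logistic_normal_cdf <- function(theta, sigma, lambda, tau) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (is.infinite(tau)) return(rep(if (tau < 0) 1 else 0, length(theta)))
  cc <- .PROBIT_C
  pnorm(cc * lambda * (theta - tau) / sqrt(1 + cc^2 * lambda^2 * sigma^2))
}

#' Marginal category probability under a Gaussian ability approximation
#'
#' Probability of category `j` after integrating the GRM response curve over
#' `N(theta_hat, se^2)`, computed as the difference of
#' [logistic_normal_cdf()] at the two bracketing thresholds.  This is the
#' kernel of the uncertainty-aware predictive deviance.
#'
#' @param theta_hat Ability point estimate.
#' @param se Non-negative standard error attached to the estimate.
#' @param item A `grm_item`.
#' @param j Category index in `1..J`, or `NULL` for the full vector.
#' @param floor Probability floor.
#' @return Probability (or vector over categories when `j` is `NULL`).
#' @export
marginal_category_prob <- function(theta_hat, se, item, j = NULL,
                                   floor = .PROB_FLOOR) {
  J <- item$n_categories
  lam <- item$discrimination
  cum <- c(1, vapply(item$thresholds, function(tau)
    logistic_normal_cdf(theta_hat, se, lam, tau), numeric(1)), 0)
  p <- pmax(cum[1:J] - cum[2:(J + 1L)], floor)
  if (is.null(j)) return(p)
  if (j < 1L || j > J) stop(sprintf("category index j=%s out of range 1..%d", j, J))
  p[j]
}

#' Rarity of scores beyond z standard deviations of a unit normal
#'
#' Returns `1 / (2 * (1 - pnorm(z)))`: the expected "one in N" frequency of
#' observing a score more extreme than `z` SD in either tail of a standard
#' normal population.  Motivates restricting score estimation to a compact
#' interval: scores beyond +/-4 SD occur about once in sixteen thousand
#' respondents, beyond +/-5 SD about once in 1.7 million.
#'
#' @param z Positive number of standard deviations.
#' @return Expected denominator N of the "one in N" rarity.
#' @export
tail_odds <- function(z) {
  stopifnot(all(z > 0))
  1 / (2 * pnorm(z, lower.tail = FALSE))
}

# Run code with a temporarily-seeded RNG, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
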