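#' Specification of a synthetic population
#'
#' @param n_persons Number of persons (>= 1).
#' @param ability_mean Mean of the normal ability distribution.
#' @param ability_sd Positive SD of the ability distribution.
#' @param label One of `"claimant"`, `"control"`, `"custom"`.
#' @return List of class `population_spec`.
#' @export
population_spec <- function(n_persons, ability_mean = 0, ability_sd = 1,
                            label = c("claimant", "control", "custom")) {
  label <- match.arg(label)
  stopifnot(n_persons >= 1L, ability_sd > 0)
  structure(list(n_persons = as.integer(n_persons),
                 ability_mean = ability_mean, ability_sd = ability_sd,
                 label = label),
            class = "population_spec")
}

#' Specification of a synthetic Likert item bank
#'
#' Defaults emulate a functional-assessment battery: moderately to highly
#' discriminating items (slopes uniform on 0.8-2.5) whose thresholds span
#' the bulk of a unit-normal population.
#'
#' @param n_items Number of items (>= 2).
#' @param n_categories Scalar or per-item vector of category counts (>= 2).
#' @param discrimination_range Uniform range for slopes.
#' @param threshold_spread Interval containing all thresholds.
#' @param seed Integer seed.
#' @return List of class `bank_spec`.
#' @export
bank_spec <- function(n_items, n_categories = 5L,
                      discrimination_range = c(0.8, 2.5),
                      threshold_spread = c(-2.5, 2.5), seed = 1L) {
  stopifnot(n_items >= 2L, all(n_categories >= 2L),
            length(discrimination_range) == 2L,
            discrimination_range[1] > 0,
            discrimination_range[1] <= discrimination_range[2],
            length(threshold_spread) == 2L,
            threshold_spread[1] < threshold_spread[2])
  n_categories <- rep_len(as.integer(n_categories), n_items)
  structure(list(n_items = as.integer(n_items), n_categories = n_categories,
                 discrimination_range = discrimination_range,
                 threshold_spread = threshold_spread,
                 seed = as.integer(seed)),
            class = "bank_spec")
}

#' Simulate an item bank
#'
#' Discriminations are uniform on the configured range; thresholds are
#' sorted uniform draws within the spread, kept at least 0.1 apart by
#' reserving the mandatory gaps before drawing.  Fully deterministic under
#' the spec's seed.
#'
#' @param spec A [bank_spec()].
#' @param domain Domain label.
#' @return A `grm_bank`.
#' @export
simulate_bank <- function(spec, domain = "synthetic") {
  stopifnot(inherits(spec, "bank_spec"))
  gap <- 0.1
  lo <- spec$threshold_spread[1]
  hi <- spec$threshold_spread[2]
  maxJ <- max(spec$n_categories)
  if ((maxJ - 2L) * gap >= hi - lo)
    stop(sprintf("threshold spread [%g, %g] cannot hold %d thresholds with gap %.1f",
                 lo, hi, maxJ - 1L, gap))
  with_seed(spec$seed, {
    items <- lapply(seq_len(spec$n_items), function(i) {
      J <- spec$n_categories[i]
      lam <- runif(1, spec$discrimination_range[1], spec$discrimination_range[2])
      raw <- sort(runif(J - 1L, lo, hi - (J - 2L) * gap))
      tau <- raw + gap * (seq_len(J - 1L) - 1L)
      item_params(sprintf("i%02d", i), lam, tau)
    })
    item_bank(items, domain = domain)
  })
}

#' Simulate a response matrix from a bank and ability vector
#'
#' Each response is drawn categorically from the GRM category probabilities
#' at the person's ability; an independent missing-at-random mask is applied
#' at `missing_rate`.  If the mask would leave a person with zero observed
#' responses, one randomly chosen response is restored so that every person
#' stays scorable.
#'
#' @param bank A `grm_bank`.
#' @param abilities Numeric vector of true abilities (one per person).
#' @param missing_rate Probability in `[0, 1)` that a response is masked.
#' @param seed Integer seed.
#' @param person_ids Optional character ids (default p0001...).
#' @return Integer response matrix (class `grm_responses`).
#' @export
simulate_responses <- function(bank, abilities, missing_rate = 0, seed = 1L,
                               person_ids = NULL) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  P <- length(abilities)
  I <- n_items(bank)
  ids <- person_ids %||% sprintf("p%04d", seq_len(P))
  with_seed(seed, {
    X <- matrix(NA_integer_, P, I, dimnames = list(ids, item_ids(bank)))
    for (i in seq_len(I)) {
      probs <- category_prob(abilities, bank$items[[i]])
      if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1L)
      cum <- probs %*% upper.tri(diag(ncol(probs)), diag = TRUE)
      u <- runif(P)
      X[, i] <- 1L + as.integer(rowSums(u > cum[, -ncol(cum), drop = FALSE]))
    }
    if (missing_rate > 0) {
      mask <- matrix(runif(P * I) < missing_rate, P, I)
      allmiss <- rowSums(!mask) == 0L
      for (p in which(allmiss)) mask[p, sample.int(I, 1L)] <- FALSE
      X[mask] <- NA_integer_
    }
    response_matrix(X, bank)
  })
}

#' Simulate a two-population calibration study
#'
#' One bank; a "claimant"-like calibration sample drawn from its ability
#' distribution; and a shifted "control" sample (default mean offset +0.5,
#' i.e. healthier on a function scale) whose person ids are disjoint from
#' the claimants'.  True abilities are returned for recovery tests.
#'
#' @param bank_spec A [bank_spec()].
#' @param claimant_spec,control_spec [population_spec()] objects.
#' @param missing_rate Missing-at-random rate applied to both matrices.
#' @param seed Integer master seed (bank uses `bank_spec$seed`).
#' @return List with `bank`, `claimant` and `control`; each population is a
#'   list of `responses` and a `truth` data frame (person_id, true_theta,
#'   population).
#' @export
simulate_study <- function(bank_spec,
                           claimant_spec = population_spec(500, 0, 1, "claimant"),
                           control_spec = population_spec(200, 0.5, 1, "control"),
                           missing_rate = 0, seed = 1L) {
  bank <- simulate_bank(bank_spec)
  pops <- list(claimant = claimant_spec, control = control_spec)
  out <- list(bank = bank)
  for (nm in names(pops)) {
    sp <- pops[[nm]]
    sub_seed <- seed + match(nm, names(pops))
    ids <- sprintf("%s_%04d", nm, seq_len(sp$n_persons))
    theta <- with_seed(sub_seed,
                       rnorm(sp$n_persons, sp$ability_mean, sp$ability_sd))
    resp <- simulate_responses(bank, theta, missing_rate,
                               seed = sub_seed + 100L, person_ids = ids)
    out[[nm]] <- list(
      responses = resp,
      truth = data.frame(person_id = ids, true_theta = theta,
                         population = sp$label, stringsAsFactors = FALSE))
  }
  out
}
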