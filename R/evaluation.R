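#' Seeded balanced K-fold partition of persons
#'
#' Uniform random assignment with fold sizes differing by at most one;
#' reproducible under the seed.
#'
#' @param person_ids Character vector of person identifiers.
#' @param K Number of folds (2 <= K <= number of persons).
#' @param seed Integer seed.
#' @return List with `K`, named integer `assignment`, and `seed`; class
#'   `fold_partition`.
#' @export
make_folds <- function(person_ids, K, seed = 1L) {
  P <- length(person_ids)
  if (K < 2L) stop("K must be at least 2")
  if (K > P) stop("K exceeds the number of persons")
  assignment <- with_seed(seed, sample(rep_len(seq_len(K), P)))
  names(assignment) <- person_ids
  structure(list(K = as.integer(K), assignment = assignment,
                 seed = as.integer(seed)),
            class = "fold_partition")
}

#' Uncertainty-aware predictive deviance of scored persons
#'
#' The information-loss metric `-2 sum_p sum_i log Pr(X_pi = x_pi)`, where
#' the category probability integrates the GRM response curve over each
#' person's Gaussian ability approximation `N(theta_hat_p, se_p^2)` (see
#' [marginal_category_prob()]).  In `variance_mode = "point"` all standard
#' errors are treated as zero, which reduces the metric to a plug-in
#' deviance; by default the probit-style approximation is still used at
#' sigma = 0 for continuity with the full mode, with `exact_logistic = TRUE`
#' switching to the exact logistic probabilities.
#'
#' @param scored AbilityEstimate data frame (person_id, theta, se, ...).
#' @param responses Response matrix covering the scored persons.
#' @param bank A calibrated `grm_bank`.
#' @param variance_mode `"full"` (use each person's se) or `"point"` (se=0).
#' @param exact_logistic In point mode, use exact GRM probabilities instead
#'   of the probit approximation at sigma = 0.
#' @param folds Optional `fold_partition`; per-fold sums are reported when
#'   given.
#' @param calibration,scoring Optional tags recorded in the report.
#' @return A `deviance_report`: per_fold (named numeric), total, per_person
#'   contributions, and the tags.
#' @export
predictive_deviance <- function(scored, responses, bank,
                                variance_mode = c("full", "point"),
                                exact_logistic = FALSE, folds = NULL,
                                calibration = NA_character_,
                                scoring = NA_character_) {
  variance_mode <- match.arg(variance_mode)
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  ids <- rownames(X) %||% sprintf("p%03d", seq_len(nrow(X)))
  missing_persons <- setdiff(scored$person_id, ids)
  if (length(missing_persons))
    stop("scored persons absent from responses: ",
         paste(missing_persons, collapse = ", "))
  contrib <- numeric(nrow(scored))
  for (r in seq_len(nrow(scored))) {
    p <- match(scored$person_id[r], ids)
    se <- if (variance_mode == "point") 0 else scored$se[r]
    th <- scored$theta[r]
    ll <- 0
    for (id in colnames(X)) {
      x <- X[p, id]
      if (is.na(x)) next
      it <- bank$items[[id]]
      if (is.null(it)) stop("item missing from bank: ", id)
      prob <- if (exact_logistic && se == 0)
        max(category_prob(th, it)[x], .PROB_FLOOR)
      else
        marginal_category_prob(th, se, it, x)
      ll <- ll + log(prob)
    }
    contrib[r] <- -2 * ll
  }
  per_person <- data.frame(person_id = scored$person_id,
                           deviance = contrib, stringsAsFactors = FALSE)
  if (is.null(folds)) {
    per_fold <- c(all = sum(contrib))
  } else {
    f <- folds$assignment[scored$person_id]
    per_fold <- vapply(seq_len(folds$K),
                       function(k) sum(contrib[f == k]), numeric(1))
    names(per_fold) <- paste0("fold", seq_len(folds$K))
  }
  structure(list(per_fold = per_fold, total = sum(contrib),
                 per_person = per_person,
                 calibration = calibration, scoring = scoring,
                 variance_mode = variance_mode),
            class = "deviance_report")
}

#' @export
print.deviance_report <- function(x, ...) {
  cat(sprintf("<deviance_report> calibration=%s scoring=%s mode=%s total=%.2f\n",
              x$calibration, x$scoring, x$variance_mode, x$total))
  print(round(x$per_fold, 2))
  invisible(x)
}

# calibrate a training split with the requested route; returns a bank
.calibrate_route <- function(X, calibration, mml_args, bayes_args, domain) {
  if (calibration == "mml") {
    fit <- do.call(calibrate_mml, c(list(responses = X, domain = domain),
                                    mml_args))
    fit$bank
  } else {
    draws <- suppressWarnings(
      do.call(sample_posterior, c(list(responses = X, domain = domain),
                                  bayes_args)))
    suppressWarnings(point_estimates(draws))$bank
  }
}

#' K-fold cross-validated predictive deviance
#'
#' Leaves out one fold of persons at a time, calibrates the bank on the
#' remaining persons with the chosen route (MML-EM or Bayesian), scores the
#' held-out persons with the chosen estimator, and accumulates the
#' uncertainty-aware deviance.  Held-out persons with zero observed
#' responses are dropped from their fold's sum with a logged count.
#'
#' @param responses Response matrix.
#' @param K Number of folds (>= 2).
#' @param calibration `"mml"` or `"bayes"`.
#' @param scoring `"eap"`, `"mle"`, `"wle"` or `"mml"`.
#' @param seed Seed for the fold partition.
#' @param mml_args,bayes_args Lists of extra arguments forwarded to
#'   [calibrate_mml()] / [sample_posterior()].
#' @param config Scoring configuration.
#' @param variance_mode Passed to [predictive_deviance()].
#' @return A `deviance_report` with one entry per fold.
#' @export
cross_validated_deviance <- function(responses, K = 4L,
                                     calibration = c("mml", "bayes"),
                                     scoring = c("eap", "mle", "wle", "mml"),
                                     seed = 1L, mml_args = list(),
                                     bayes_args = list(),
                                     config = scoring_config(),
                                     variance_mode = "full") {
  calibration <- match.arg(calibration)
  scoring <- match.arg(scoring)
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  if (is.null(rownames(X))) rownames(X) <- sprintf("p%03d", seq_len(nrow(X)))
  folds <- make_folds(rownames(X), K, seed)
  per_fold <- numeric(K)
  names(per_fold) <- paste0("fold", seq_len(K))
  per_person <- list()
  for (k in seq_len(K)) {
    train <- X[folds$assignment != k, , drop = FALSE]
    test <- X[folds$assignment == k, , drop = FALSE]
    bank <- tryCatch(
      .calibrate_route(train, calibration, mml_args, bayes_args,
                       domain = sprintf("cv_fold%d", k)),
      error = function(e) stop(sprintf("calibration failed on fold %d: %s",
                                       k, conditionMessage(e))))
    scorable <- rowSums(!is.na(test)) > 0L
    if (any(!scorable))
      message(sprintf("fold %d: dropping %d person(s) with no observed responses",
                      k, sum(!scorable)))
    test <- test[scorable, , drop = FALSE]
    scored <- suppressMessages(score_all(test, bank, scoring, config))
    rep_k <- predictive_deviance(scored, test, bank,
                                 variance_mode = variance_mode,
                                 calibration = calibration, scoring = scoring)
    per_fold[k] <- rep_k$total
    per_person[[k]] <- rep_k$per_person
  }
  structure(list(per_fold = per_fold, total = sum(per_fold),
                 per_person = do.call(rbind, per_person),
                 calibration = calibration, scoring = scoring,
                 variance_mode = variance_mode, K = K, seed = seed),
            class = "deviance_report")
}

#' Deviance of a calibrated bank on a disjoint holdout population
#'
#' Scores the holdout persons with the chosen method against a bank
#' calibrated elsewhere (e.g. on a claimant sample) and evaluates the full
#' uncertainty-aware deviance, measuring how well the instrument transfers
#' to a population it was not calibrated on.
#'
#' @param bank Calibrated `grm_bank`.
#' @param holdout Response matrix of holdout persons (all items must exist
#'   in the bank).
#' @param scoring Scoring method tag.
#' @param config Scoring configuration.
#' @param variance_mode Passed to [predictive_deviance()].
#' @return A `deviance_report`.
#' @export
holdout_deviance <- function(bank, holdout,
                             scoring = c("eap", "mle", "wle", "mml"),
                             config = scoring_config(),
                             variance_mode = "full") {
  scoring <- match.arg(scoring)
  X <- as.matrix(holdout)
  if (nrow(X) == 0L) stop("holdout response matrix is empty")
  missing_items <- setdiff(colnames(X), item_ids(bank))
  if (length(missing_items))
    stop("holdout items missing from bank: ",
         paste(missing_items, collapse = ", "))
  scored <- suppressMessages(score_all(holdout, bank, scoring, config))
  predictive_deviance(scored, holdout, bank, variance_mode = variance_mode,
                      calibration = "external", scoring = scoring)
}

#' Pairwise agreement between two score tables
#'
#' Pearson correlation, mean signed difference (b minus a) and the
#' least-squares slope of `b` on `a` over the persons shared by both tables.
#'
#' @param a,b AbilityEstimate data frames with `person_id` and `theta`.
#' @return List (class `agreement_summary`) with `methods`, `n`,
#'   `correlation`, `mean_difference`, `slope`.
#' @export
score_agreement <- function(a, b) {
  m <- merge(a[, c("person_id", "theta")], b[, c("person_id", "theta")],
             by = "person_id", suffixes = c("_a", "_b"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 shared scored persons")
  structure(list(
    methods = c(a$method[1], b$method[1]),
    n = nrow(m),
    correlation = cor(m$theta_a, m$theta_b),
    mean_difference = mean(m$theta_b - m$theta_a),
    slope = unname(coef(lm(theta_b ~ theta_a, data = m))[2])),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement> %s vs %s (n=%d): r=%.4f, mean diff=%.4f, slope=%.4f\n",
              x$methods[1], x$methods[2], x$n, x$correlation,
              x$mean_difference, x$slope))
  invisible(x)
}
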