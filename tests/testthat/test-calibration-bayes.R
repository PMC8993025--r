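# Term-by-term oracle for the log posterior, coded independently of the
# package implementation (and of the C++ kernel used by the sampler).
lp_oracle <- function(params, X, prior = prior_config()) {
  lhc <- function(x, s) log(2) - log(pi * s) - log1p((x / s)^2)
  lp <- 0
  for (i in seq_along(params$lambda)) {
    tau <- params$thresholds[[i]]
    J <- length(tau) + 1L
    for (p in seq_len(nrow(X))) {
      x <- X[p, i]
      if (is.na(x)) next
      cum <- c(1, plogis(params$lambda[i] * (params$theta[p] - tau)), 0)
      lp <- lp + log(max(cum[x] - cum[x + 1L], 1e-12))
    }
    lp <- lp + lhc(params$lambda[i], prior$discrimination_scale)
    lp <- lp + sum(dnorm(tau, params$mu_tau, params$sigma_tau, log = TRUE))
  }
  lp + dnorm(params$mu_tau, 0, prior$threshold_mean_scale, log = TRUE) +
    lhc(params$sigma_tau, prior$threshold_sd_scale) +
    sum(dnorm(params$theta, 0, params$sigma, log = TRUE)) +
    lhc(params$sigma, prior$ability_sd_scale)
}

toy_params <- function() {
  list(lambda = c(1.2, 0.7),
       thresholds = list(c(-0.5, 0.8), 0.3),
       mu_tau = 0.1, sigma_tau = 0.9,
       theta = c(-1, 0.2, 1.4), sigma = 1.1)
}

toy_X <- function() {
  X <- rbind(c(1, 2), c(3, NA), c(2, 1))
  dimnames(X) <- list(c("p1", "p2", "p3"), c("a", "b"))
  X
}

test_that("log_posterior matches an independently coded oracle", {
  p <- toy_params()
  X <- toy_X()
  expect_equal(log_posterior(p, X), lp_oracle(p, X), tolerance = 1e-10)
  # additivity: doubling the person set adds exactly the extra terms
  X2 <- rbind(X, X)
  rownames(X2) <- paste0("q", 1:6)
  p2 <- p
  p2$theta <- c(p$theta, p$theta)
  extra <- log_posterior(p2, X2) - log_posterior(p, X)
  lik_one <- sum(sapply(seq_len(nrow(X)), function(r) {
    s <- 0
    for (i in 1:2) {
      x <- X[r, i]
      if (is.na(x)) next
      cum <- c(1, plogis(p$lambda[i] * (p$theta[r] - p$thresholds[[i]])), 0)
      s <- s + log(cum[x] - cum[x + 1L])
    }
    s
  }))
  prior_one <- sum(dnorm(p$theta, 0, p$sigma, log = TRUE))
  expect_equal(extra, lik_one + prior_one, tolerance = 1e-10)
})

test_that("log_posterior returns -Inf outside the support, finite inside", {
  X <- toy_X()
  p <- toy_params()
  expect_true(is.finite(log_posterior(p, X)))
  bad <- p; bad$lambda[1] <- -1
  expect_identical(log_posterior(bad, X), -Inf)
  bad <- p; bad$thresholds[[1]] <- c(0.8, -0.5)
  expect_identical(log_posterior(bad, X), -Inf)
  bad <- p; bad$sigma <- 0
  expect_identical(log_posterior(bad, X), -Inf)
  # random prior draws are always finite
  set.seed(3)
  for (k in 1:20) {
    pr <- list(lambda = abs(rcauchy(2, 0, 5)) + 1e-3,
               thresholds = list(sort(rnorm(2)), rnorm(1)),
               mu_tau = rnorm(1, 0, 5), sigma_tau = abs(rcauchy(1)) + 1e-3,
               theta = rnorm(3), sigma = abs(rcauchy(1)) + 1e-3)
    expect_true(is.finite(log_posterior(pr, X)))
  }
})

test_that("the C++ posterior kernel agrees with log_posterior + Jacobians", {
  X <- toy_X()
  model <- grmcv:::.bayes_model(X, prior_config())
  set.seed(12)
  par <- grmcv:::.bayes_init(model, jitter = 0.3)
  nat <- grmcv:::.to_natural(par, model)
  p <- list(lambda = c(nat[1], nat[4]),
            thresholds = list(nat[2:3], nat[5]),
            mu_tau = nat[6], sigma_tau = nat[7], sigma = nat[8],
            theta = nat[9:11])
  jac <- log(p$lambda[1]) + log(p$lambda[2]) + log(diff(p$thresholds[[1]])) +
    log(p$sigma_tau) + log(p$sigma)
  expect_equal(model$fn(par)$lp, log_posterior(p, X) + jac, tolerance = 1e-9)
  # gradient check against central differences
  r <- model$fn(par)
  h <- 1e-6
  num <- vapply(seq_along(par), function(k) {
    pp <- par; pp[k] <- pp[k] + h
    pm <- par; pm[k] <- pm[k] - h
    (model$fn(pp)$lp - model$fn(pm)$lp) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - r$grad)), 1e-5)
})

test_that("sampler is deterministic under seed and recovers a known bank", {
  st <- simulate_study(bank_spec(8, 4, seed = 44),
                       population_spec(500, 0, 1, "claimant"),
                       population_spec(5, 0.5, 1, "control"), 0, seed = 44)
  X <- st$claimant$responses
  d1 <- suppressWarnings(sample_posterior(X, chains = 1, draws = 250,
                                          warmup = 300, seed = 5))
  d2 <- suppressWarnings(sample_posterior(X, chains = 1, draws = 250,
                                          warmup = 300, seed = 5))
  expect_identical(d1$draws, d2$draws)
  expect_true(all(d1$draws[, grepl("^lambda", colnames(d1$draws))] > 0))
  expect_true(all(d1$draws[, "sigma"] > 0))
  pe <- suppressWarnings(point_estimates(d1))
  lt <- vapply(st$bank$items, `[[`, numeric(1), "discrimination")
  le <- vapply(pe$bank$items, `[[`, numeric(1), "discrimination")
  expect_gt(cor(lt, le), 0.9)
  # the sampler extracts the same information as the EM route
  lm_ <- vapply(calibrate_mml(X)$bank$items, `[[`, numeric(1),
                "discrimination")
  expect_gt(cor(le, lm_), 0.97)
  # diagnostics reported for every sampled parameter except raw sigma
  expect_true(all(is.finite(d1$diagnostics$rhat[colnames(d1$draws) != "sigma"])))
})

test_that("prior-only sampling reproduces prior marginals of lambda", {
  X <- matrix(integer(0), nrow = 0, ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  d <- suppressWarnings(sample_posterior(X, chains = 2, draws = 800,
                                         warmup = 500, seed = 13))
  lam <- d$draws[, "lambda[a]"]          # raw scale: half-Cauchy(0, 5)
  # median of half-Cauchy(0,5) is 5; compare on the tangent scale with a
  # generous Monte-Carlo band (heavy tails mix slowly)
  expect_gt(median(lam), 2)
  expect_lt(median(lam), 12)
  # interquartile band should bracket the half-Cauchy quartiles 2.07, 12.07
  expect_lt(quantile(lam, 0.25), 5)
  expect_gt(quantile(lam, 0.75), 5)
})

test_that("point_estimates preserves ordering and matches direct summaries", {
  st <- simulate_study(bank_spec(4, 4, seed = 2),
                       population_spec(60, 0, 1, "claimant"),
                       population_spec(5, 0.5, 1, "control"), 0, seed = 2)
  d <- suppressWarnings(sample_posterior(st$claimant$responses, chains = 1,
                                         draws = 100, warmup = 150, seed = 3))
  pe <- suppressWarnings(point_estimates(d))
  for (it in pe$bank$items) expect_true(all(diff(it$thresholds) > 0))
  # person posterior SDs equal a direct recomputation over draws
  cols <- sprintf("theta[%s]", d$person_names)
  direct <- apply(d$standardized[, cols, drop = FALSE], 2L, sd)
  expect_equal(pe$person_estimates$se, unname(direct), tolerance = 1e-12)
  # all draws identical -> point estimates equal that draw
  d0 <- d
  d0$draws <- d$draws[rep(1L, 50L), , drop = FALSE]
  d0$standardized <- d$standardized[rep(1L, 50L), , drop = FALSE]
  pe0 <- suppressWarnings(point_estimates(d0))
  expect_equal(vapply(pe0$bank$items, `[[`, numeric(1), "discrimination"),
               d$standardized[1L, grepl("^lambda", colnames(d$draws))],
               ignore_attr = TRUE)
  expect_equal(pe0$person_estimates$se, rep(0, length(cols)))
})

test_that("Bayesian shrinkage pulls an extreme discrimination toward the rest", {
  set.seed(77)
  items <- c(lapply(1:7, function(i)
    item_params(sprintf("i%02d", i), runif(1, 0.9, 1.8),
                sort(runif(2, -1.5, 1.5)) + c(0, 0.2))),
    list(item_params("wild", 6, c(-0.5, 0.5))))
  bk <- item_bank(items)
  theta <- rnorm(300)
  X <- simulate_responses(bk, theta, seed = 78)
  mml <- calibrate_mml(X)
  d <- suppressWarnings(sample_posterior(X, chains = 1, draws = 250,
                                         warmup = 300, seed = 79))
  pe <- suppressWarnings(point_estimates(d))
  lam_mml <- mml$bank$items[["wild"]]$discrimination
  lam_bayes <- pe$bank$items[["wild"]]$discrimination
  expect_lt(lam_bayes, lam_mml)
})
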