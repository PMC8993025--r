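test_that("item and bank constructors enforce their invariants", {
  expect_error(item_params("a", -1, 0), "positive")
  expect_error(item_params("a", 1, c(1, 0)), "increasing")
  it <- item_params("a", 1.5, c(-1, 0.5, 2))
  expect_equal(it$n_categories, 4L)
  expect_error(item_bank(list(item_params("a", 1, 0), item_params("a", 2, 0))),
               "unique")
  expect_error(item_bank(list()), "at least one")
})

test_that("response_matrix validates codes against the bank", {
  bk <- small_bank()
  X <- rbind(c(1, 2, 4), c(2, 3, 1))
  colnames(X) <- item_ids(bk)
  expect_silent(rm_ok <- response_matrix(X, bk))
  X[1, 3] <- 9
  expect_error(response_matrix(X, bk), "invalid code.*i3")
  X[1, ] <- c(1, 2, 4)
  X[2, ] <- NA
  expect_error(response_matrix(X, bk), "no observed responses")
})

test_that("cumulative_prob matches the logistic closed form and boundaries", {
  it1 <- item_params("a", 1, 0)
  expect_equal(cumulative_prob(0, it1, 2), 0.5)
  expect_equal(cumulative_prob(3, it1, 1), 1)
  expect_equal(cumulative_prob(3, it1, 3), 0)
  it2 <- item_params("b", 2, c(-1, 1))
  expect_equal(cumulative_prob(0.5, it2, 2), 1 / (1 + exp(-3)),
               tolerance = 1e-12)
  expect_error(cumulative_prob(0, it2, 5), "out of range")
  # non-increasing in j, increasing in theta
  for (j in 1:4) {
    p <- cumulative_prob(seq(-4, 4, 0.5), it2, j)
    expect_true(all(diff(p) >= 0))
  }
  probs <- vapply(1:4, function(j) cumulative_prob(0.3, it2, j), numeric(1))
  expect_true(all(diff(probs) <= 0))
})

test_that("category_prob telescopes, sums to one, and matches hand values", {
  it2 <- item_params("b", 2, c(-1, 1))
  p <- category_prob(0.5, it2)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p, c(0.04743, 0.68363, 0.26894), tolerance = 1e-4)
  expect_equal(category_prob(0, item_params("a", 1, 0)), c(0.5, 0.5))
  expect_gt(category_prob(10, it2)[3], 0.999)
  # property: random items over the spec's ranges
  set.seed(42)
  for (k in 1:50) {
    J <- sample(2:6, 1)
    it <- item_params("r", runif(1, 0.25, 3), sort(rnorm(J - 1, 0, 1.5)) +
                        cumsum(c(0, rep(0.01, J - 2))))
    th <- runif(1, -6, 6)
    p <- category_prob(th, it)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    for (j in 1:J)
      expect_equal(p[j], cumulative_prob(th, it, j) - cumulative_prob(th, it, j + 1L),
                   tolerance = 1e-12)
  }
})

test_that("log_likelihood is additive and floored", {
  bk1 <- item_bank(list(item_params("a", 1, 0)))
  expect_equal(log_likelihood(0, c(a = 2), bk1), log(0.5), tolerance = 1e-12)
  bk2 <- item_bank(list(item_params("a", 1, 0), item_params("b", 1, 0)))
  expect_equal(log_likelihood(0, c(a = 2, b = 2), bk2), 2 * log(0.5),
               tolerance = 1e-12)
  bk3 <- item_bank(list(item_params("b", 2, c(-1, 1))))
  expect_equal(log_likelihood(0.5, c(b = 2), bk3), log(0.68363),
               tolerance = 1e-4)
  expect_error(log_likelihood(0, c(a = NA, b = NA), bk2), "unscorable")
  # finite even at absurd abilities thanks to the floor
  expect_true(is.finite(log_likelihood(50, c(a = 1, b = 1), bk2)))
})

test_that("fisher_information matches the 2PL closed form and is additive", {
  it <- item_params("a", 2, 0)
  bk1 <- item_bank(list(it))
  expect_equal(fisher_information(0, bk1), 1.0, tolerance = 1e-10)
  bk2 <- item_bank(list(it, item_params("b", 2, 0)))
  expect_equal(fisher_information(0, bk2), 2.0, tolerance = 1e-10)
  expect_lt(fisher_information(10, bk2), 1e-6)
  expect_warning(i0 <- fisher_information(0, bk2, items = character(0)),
                 "empty")
  expect_equal(i0, 0)
})

test_that("fisher_information equals the variance of the score numerically", {
  # oracle: I(theta) = Var_X[d/dtheta log P(X)] computed by enumeration
  set.seed(7)
  for (k in 1:10) {
    J <- sample(2:5, 1)
    it <- item_params("r", runif(1, 0.5, 2.5),
                      sort(runif(J - 1, -2, 2)) + cumsum(c(0, rep(0.05, J - 2))))
    bk <- item_bank(list(it))
    th <- runif(1, -2, 2)
    h <- 1e-5
    p <- category_prob(th, it)
    dlog <- (log(category_prob(th + h, it)) - log(category_prob(th - h, it))) / (2 * h)
    expect_equal(fisher_information(th, bk), sum(p * dlog^2),
                 tolerance = 1e-4)
  }
})

test_that("logistic_normal_cdf tracks the quadrature oracle within 0.02", {
  expect_equal(logistic_normal_cdf(1.3, 0, 2, 1.3), 0.5)
  expect_equal(logistic_normal_cdf(0, 1, 2, -Inf), 1)
  expect_equal(logistic_normal_cdf(0, 1, 2, Inf), 0)
  expect_error(logistic_normal_cdf(0, -1, 2, 0), "non-negative")
  expect_lt(abs(logistic_normal_cdf(0, 0.8, 1.5, 0.5) -
                  logistic_normal_quad(0, 0.8, 1.5, 0.5)), 0.02)
  set.seed(11)
  for (k in 1:60) {
    lam <- runif(1, 0.25, 3); tau <- runif(1, -2, 2)
    th <- tau + runif(1, -4, 4); s <- runif(1, 0, 2)
    expect_lt(abs(logistic_normal_cdf(th, s, lam, tau) -
                    logistic_normal_quad(th, s, lam, tau)), 0.02)
  }
  # monotone increasing in theta, decreasing in tau
  v <- logistic_normal_cdf(seq(-3, 3, 0.25), 0.7, 1.2, 0.4)
  expect_true(all(diff(v) > 0))
})

test_that("marginal_category_prob telescopes and matches quadrature", {
  it <- item_params("b", 2, c(-1, 1))
  expect_equal(marginal_category_prob(0, 0, item_params("a", 1, 0), 1), 0.5)
  expect_equal(sum(marginal_category_prob(0.3, 0.5, it)), 1, tolerance = 1e-9)
  expect_lt(abs(marginal_category_prob(0.3, 0.5, it, 2) -
                  marginal_prob_quad(0.3, 0.5, it, 2)), 0.02)
  # se = 0 converges to the exact category probability within Eq-8 error
  expect_lt(max(abs(marginal_category_prob(0.3, 0, it) -
                      category_prob(0.3, it))), 0.02)
})

test_that("tail_odds reproduces the normal-tail rarity argument", {
  expect_equal(round(tail_odds(4), -3), 16000)
  expect_equal(signif(tail_odds(5), 2), 1.7e6)
  expect_equal(tail_odds(1e-10), 1, tolerance = 1e-6)
})
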