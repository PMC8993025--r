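# Shared fixtures and independent oracles used across the suite.

# Two-item bank symmetric about zero: responses (high, low) balance exactly.
symmetric_bank <- function(a = 1, lam = 1.5) {
  item_bank(list(item_params("plus", lam, a),
                 item_params("minus", lam, -a)))
}

small_bank <- function() {
  item_bank(list(
    item_params("i1", 1.0, 0),
    item_params("i2", 2.0, c(-1, 1)),
    item_params("i3", 1.3, c(-1.5, 0, 1.2))))
}

# Independent quadrature oracle for the Gaussian-smoothed logistic integral.
logistic_normal_quad <- function(theta, sigma, lambda, tau) {
  if (is.infinite(tau)) return(if (tau < 0) 1 else 0)
  if (sigma == 0) return(plogis(lambda * (theta - tau)))
  integrate(function(x) plogis(lambda * (x - tau)) * dnorm(x, theta, sigma),
            theta - 10 * sigma, theta + 10 * sigma, rel.tol = 1e-10)$value
}

# Independent quadrature oracle for marginal category probabilities.
marginal_prob_quad <- function(theta, sigma, item, j) {
  J <- item$n_categories
  lo <- if (j == 1L) 1 else logistic_normal_quad(theta, sigma,
                                                 item$discrimination,
                                                 item$thresholds[j - 1L])
  hi <- if (j == J) 0 else logistic_normal_quad(theta, sigma,
                                                item$discrimination,
                                                item$thresholds[j])
  lo - hi
}

# Fine grid argmax oracle for scalar objectives on an interval: a coarse
# pass followed by a dense pass around the coarse winner, giving argmax
# precision of about (width/n)^2 / width -- far below the 1e-4 tolerances.
grid_argmax <- function(obj, bounds, n = 4001L) {
  g <- seq(bounds[1], bounds[2], length.out = n)
  v <- vapply(g, obj, numeric(1))
  i <- which.max(v)
  lo <- g[max(1L, i - 2L)]
  hi <- g[min(n, i + 2L)]
  g2 <- seq(lo, hi, length.out = n)
  v2 <- vapply(g2, obj, numeric(1))
  g2[which.max(v2)]
}
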