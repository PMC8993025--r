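#' Prior scales for the hierarchical Bayesian GRM
#'
#' Weakly-informative defaults: half-Cauchy(0, 5) on each discrimination,
#' normal(0, 5) on the threshold population mean, half-Cauchy(0, 1) on the
#' threshold population SD, and half-Cauchy(0, 1) on the ability population
#' SD.  Thresholds form an ordered vector whose elements carry a
#' normal(mu_tau, sigma_tau) density; abilities are normal(0, sigma) so the
#' latent scale is encouraged (not imposed).
#'
#' @param discrimination_scale Half-Cauchy scale for discriminations.
#' @param threshold_mean_scale Normal SD for the threshold hyper-mean.
#' @param threshold_sd_scale Half-Cauchy scale for the threshold hyper-SD.
#' @param ability_sd_scale Half-Cauchy scale for the ability population SD.
#' @return List of class `prior_config`.
#' @export
prior_config <- function(discrimination_scale = 5,
                         threshold_mean_scale = 5,
                         threshold_sd_scale = 1,
                         ability_sd_scale = 1) {
  scales <- c(discrimination_scale, threshold_mean_scale,
              threshold_sd_scale, ability_sd_scale)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("all prior scales must be positive")
  structure(list(discrimination_scale = discrimination_scale,
                 threshold_mean_scale = threshold_mean_scale,
                 threshold_sd_scale = threshold_sd_scale,
                 ability_sd_scale = ability_sd_scale),
            class = "prior_config")
}

.log_half_cauchy <- function(x, scale) {
  ifelse(x > 0, log(2) + dcauchy(x, 0, scale, log = TRUE), -Inf)
}

#' Log posterior density of one parameter draw (natural scale)
#'
#' GRM log-likelihood plus log priors for a full parameter set
#' `list(lambda, thresholds, mu_tau, sigma_tau, theta, sigma)`, where
#' `thresholds` is a list of ordered numeric vectors (one per item).  Support
#' violations (non-positive scales or slopes, unordered thresholds) return
#' `-Inf` rather than raising, so the function can serve as a rejection
#' target.  No Jacobian terms are included: this is the density over the
#' natural parameters.
#'
#' @param params Named list as above.
#' @param responses Response matrix; columns in item order matching
#'   `params$lambda`.
#' @param prior A [prior_config()].
#' @return Finite log density, or `-Inf` outside the support.
#' @export
log_posterior <- function(params, responses, prior = prior_config()) {
  lam <- params$lambda
  taus <- params$thresholds
  th <- params$theta
  if (any(lam <= 0) || params$sigma_tau <= 0 || params$sigma <= 0) return(-Inf)
  if (any(vapply(taus, function(t) is.unsorted(t, strictly = TRUE), logical(1))))
    return(-Inf)
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  lp <- 0
  for (i in seq_along(lam)) {
    Jm1 <- length(taus[[i]])
    for (p in seq_len(nrow(X))) {
      x <- X[p, i]
      if (is.na(x)) next
      lo <- if (x == 1L) 1 else plogis(lam[i] * (th[p] - taus[[i]][x - 1L]))
      hi <- if (x == Jm1 + 1L) 0 else plogis(lam[i] * (th[p] - taus[[i]][x]))
      lp <- lp + log(max(lo - hi, .PROB_FLOOR))
    }
    lp <- lp + .log_half_cauchy(lam[i], prior$discrimination_scale)
    lp <- lp + sum(dnorm(taus[[i]], params$mu_tau, params$sigma_tau, log = TRUE))
  }
  lp <- lp + dnorm(params$mu_tau, 0, prior$threshold_mean_scale, log = TRUE)
  lp <- lp + .log_half_cauchy(params$sigma_tau, prior$threshold_sd_scale)
  lp <- lp + sum(dnorm(th, 0, params$sigma, log = TRUE))
  lp <- lp + .log_half_cauchy(params$sigma, prior$ability_sd_scale)
  lp
}

# ---------------------------------------------------------------------------
# unconstrained-space plumbing shared by HMC and the variational fallback

.bayes_model <- function(X, prior) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  I <- ncol(X)
  P <- nrow(X)
  ncat <- integer(I)
  for (i in seq_len(I)) {
    codes <- X[, i][!is.na(X[, i])]
    ncat[i] <- if (length(codes)) max(2L, max(codes)) else 2L
  }
  npar <- sum(ncat) + 3L + P
  list(X = X, ncat = ncat, I = I, P = P, npar = npar, prior = prior,
       fn = function(par) grm_lp_grad(par, X, ncat,
                                      prior$discrimination_scale,
                                      prior$threshold_mean_scale,
                                      prior$threshold_sd_scale,
                                      prior$ability_sd_scale,
                                      .PROB_FLOOR))
}

# parameter names on the natural scale, matching .unconstrain_to_natural
.bayes_par_names <- function(model, item_names, person_names) {
  nm <- character(0)
  for (i in seq_len(model$I)) {
    nm <- c(nm, sprintf("lambda[%s]", item_names[i]),
            sprintf("tau[%s,%d]", item_names[i], 2:model$ncat[i]))
  }
  c(nm, "mu_tau", "sigma_tau", "sigma",
    if (model$P) sprintf("theta[%s]", person_names))
}

# map one unconstrained vector to the natural scale (same column layout)
.to_natural <- function(par, model) {
  out <- numeric(model$npar)
  off <- 0L
  for (i in seq_len(model$I)) {
    J <- model$ncat[i]
    out[off + 1L] <- exp(par[off + 1L])
    tau <- cumsum(c(par[off + 2L], exp(par[off + 2L + seq_len(J - 2L)])))
    out[off + 1L + seq_len(J - 1L)] <- tau
    off <- off + J
  }
  out[off + 1L] <- par[off + 1L]              # mu_tau
  out[off + 2L] <- exp(par[off + 2L])         # sigma_tau
  out[off + 3L] <- exp(par[off + 3L])         # sigma
  if (model$P) out[(off + 4L):model$npar] <- par[(off + 4L):model$npar]
  out
}

.bayes_init <- function(model, jitter = 0.1) {
  par <- numeric(model$npar)
  off <- 0L
  for (i in seq_len(model$I)) {
    J <- model$ncat[i]
    codes <- model$X[, i]
    tau0 <- if (sum(!is.na(codes)) >= 5L) .init_thresholds(codes, J)
            else seq(-1, 1, length.out = J - 1L)
    par[off + 1L] <- 0                         # log lambda = 0
    par[off + 2L] <- tau0[1]
    if (J > 2L) par[off + 2L + seq_len(J - 2L)] <- log(pmax(diff(tau0), 0.05))
    off <- off + J
  }
  par[off + 1L] <- 0
  par[off + 2L] <- 0
  par[off + 3L] <- 0
  # start abilities at standardized mean item scores so the chain begins on
  # the unit latent scale the priors softly encourage (the likelihood has a
  # near-flat scale ridge, and an all-zero start mixes into it very slowly)
  if (model$P) {
    frac <- sweep(model$X - 1L, 2L, pmax(model$ncat - 1L, 1L), `/`)
    sc <- rowMeans(frac, na.rm = TRUE)
    sc[is.nan(sc)] <- 0.5
    z <- qnorm((rank(sc) - 0.5) / length(sc))
    par[(off + 4L):model$npar] <- z
  }
  par + rnorm(model$npar, 0, jitter)
}

# The GRM likelihood is invariant under the scale flow
#   lambda -> lambda / c,  tau, mu_tau, sigma_tau, theta, sigma -> c * (.)
# so the posterior has a long, weakly-identified ridge along it (only the
# priors pin the latent scale).  A Metropolis move along this flow, with the
# exact Jacobian of the map in unconstrained coordinates, mixes that ridge
# far faster than leapfrog steps do.
.make_scale_move <- function(model) {
  idx_mult <- integer(0)       # coordinates multiplied by c
  idx_neg <- integer(0)        # log-slopes: shifted by -psi
  idx_pos <- integer(0)        # log-increments and log-SDs: shifted by +psi
  off <- 0L
  for (i in seq_len(model$I)) {
    J <- model$ncat[i]
    idx_neg <- c(idx_neg, off + 1L)
    idx_mult <- c(idx_mult, off + 2L)
    if (J > 2L) idx_pos <- c(idx_pos, off + 2L + seq_len(J - 2L))
    off <- off + J
  }
  idx_mult <- c(idx_mult, off + 1L)             # mu_tau
  idx_pos <- c(idx_pos, off + 2L, off + 3L)     # log sigma_tau, log sigma
  if (model$P) idx_mult <- c(idx_mult, (off + 4L):model$npar)
  njac <- length(idx_mult)
  function(par, psi) {
    par[idx_neg] <- par[idx_neg] - psi
    par[idx_mult] <- par[idx_mult] * exp(psi)
    par[idx_pos] <- par[idx_pos] + psi
    list(par = par, log_jac = njac * psi)
  }
}

# ---------------------------------------------------------------------------
# Hamiltonian Monte Carlo with dual-averaging step size and a diagonal
# metric estimated during warmup.

.hmc_chain <- function(fn, init, warmup, draws, L = 20L,
                       target_accept = 0.8, max_deltaH = 1000,
                       scale_move = NULL, n_scale_moves = 3L,
                       scale_sd = 0.05) {
  d <- length(init)
  q <- init
  cur <- fn(q)
  inv_mass <- rep(1, d)                        # inverse metric = variances
  # dual averaging state
  eps <- 0.1 / d^0.25
  mu <- log(10 * eps)
  log_eps_bar <- 0
  Hbar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  adapt_iter <- 0L

  phase1 <- max(25L, floor(0.15 * warmup))
  phase3_start <- max(phase1 + 1L, floor(0.85 * warmup))
  var_acc_n <- 0L
  var_mean <- numeric(d)
  var_m2 <- numeric(d)

  out <- matrix(NA_real_, draws, d)
  divergences <- 0L
  accept_count <- 0L
  total <- warmup + draws

  for (it in seq_len(total)) {
    in_warmup <- it <= warmup
    p <- rnorm(d) / sqrt(inv_mass)
    Lj <- sample.int(L, 1L)
    Lj <- max(Lj, ceiling(L / 2))
    q_new <- q
    g <- cur$grad
    H0 <- -cur$lp + 0.5 * sum(p^2 * inv_mass)
    # leapfrog
    p_new <- p + 0.5 * eps * g
    diverged <- FALSE
    prop <- NULL
    for (s in seq_len(Lj)) {
      q_new <- q_new + eps * inv_mass * p_new
      prop <- fn(q_new)
      if (!is.finite(prop$lp) || any(!is.finite(prop$grad))) {
        diverged <- TRUE
        break
      }
      p_new <- p_new + (if (s < Lj) eps else 0.5 * eps) * prop$grad
    }
    if (!diverged) {
      H1 <- -prop$lp + 0.5 * sum(p_new^2 * inv_mass)
      dH <- H1 - H0
      if (!is.finite(dH) || dH > max_deltaH) diverged <- TRUE
    }
    if (diverged) {
      alpha <- 0
      if (!in_warmup) divergences <- divergences + 1L
    } else {
      alpha <- min(1, exp(-dH))
      if (runif(1) < alpha) {
        q <- q_new
        cur <- prop
        if (!in_warmup) accept_count <- accept_count + 1L
      }
    }
    if (in_warmup) {
      adapt_iter <- adapt_iter + 1L
      frac <- 1 / (adapt_iter + t0)
      Hbar <- (1 - frac) * Hbar + frac * (target_accept - alpha)
      log_eps <- mu - sqrt(adapt_iter) / gamma * Hbar
      eta <- adapt_iter^(-kappa)
      log_eps_bar <- eta * log_eps + (1 - eta) * log_eps_bar
      eps <- exp(log_eps)
      if (it > phase1 && it < phase3_start) {
        var_acc_n <- var_acc_n + 1L
        delta <- q - var_mean
        var_mean <- var_mean + delta / var_acc_n
        var_m2 <- var_m2 + delta * (q - var_mean)
      }
      if (it == phase3_start && var_acc_n > 10L) {
        v <- var_m2 / (var_acc_n - 1L)
        n <- var_acc_n
        inv_mass <- (n / (n + 5)) * v + (5 / (n + 5)) * 1e-3
        # restart step-size adaptation around the current value
        eps <- exp(log_eps_bar)
        mu <- log(10 * eps)
        Hbar <- 0; log_eps_bar <- 0; adapt_iter <- 0L
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    }
    if (!is.null(scale_move)) {
      for (s in seq_len(n_scale_moves)) {
        psi <- rnorm(1, 0, scale_sd)
        prop_s <- scale_move(q, psi)
        pr <- fn(prop_s$par)
        if (is.finite(pr$lp) &&
            runif(1) < exp(pr$lp - cur$lp + prop_s$log_jac)) {
          q <- prop_s$par
          cur <- pr
        }
      }
    }
    if (!in_warmup) out[it - warmup, ] <- q
  }
  list(draws = out, divergences = divergences,
       accept_rate = accept_count / draws, step_size = eps)
}

# mean-field Gaussian variational approximation (ADVI-style), used as the
# cheap fallback when MCMC is too expensive
.advi_fit <- function(fn, init, iters = 2000L, lr = 0.05, n_mc = 2L,
                      draws = 1000L) {
  d <- length(init)
  mu <- init
  omega <- rep(-1, d)                          # log sd
  m1 <- numeric(2 * d); v1 <- numeric(2 * d)   # Adam state
  b1 <- 0.9; b2 <- 0.999; eps0 <- 1e-8
  for (t in seq_len(iters)) {
    gmu <- numeric(d); gom <- numeric(d)
    for (s in seq_len(n_mc)) {
      z <- rnorm(d)
      q <- mu + exp(omega) * z
      r <- fn(q)
      if (!is.finite(r$lp)) next
      gmu <- gmu + r$grad / n_mc
      gom <- gom + (r$grad * z * exp(omega) + 1) / n_mc  # +1 = entropy grad
    }
    g <- c(gmu, gom)
    m1 <- b1 * m1 + (1 - b1) * g
    v1 <- b2 * v1 + (1 - b2) * g^2
    step <- lr / sqrt(t) * (m1 / (1 - b1^t)) / (sqrt(v1 / (1 - b2^t)) + eps0)
    mu <- mu + step[1:d]
    omega <- omega + step[(d + 1):(2 * d)]
  }
  matrix(rnorm(draws * d), draws, d) * rep(exp(omega), each = draws) +
    rep(mu, each = draws)
}

# split R-hat (Gelman et al.) over a draws x chains matrix
.split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2L, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size via initial positive sequence of autocovariances
.ess <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4L) return(n * m)
  W <- mean(apply(x, 2L, var))
  if (W <= 0) return(n * m)
  rho <- rep(0, n - 1)
  for (ch in seq_len(m)) {
    xc <- x[, ch] - mean(x[, ch])
    ac <- stats::acf(xc, lag.max = min(n - 2L, 200L), plot = FALSE,
                     demean = FALSE)$acf[-1]
    rho[seq_along(ac)] <- rho[seq_along(ac)] + ac / m
  }
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n * m / (1 + 2 * s))
}

#' Sample the hierarchical Bayesian GRM posterior
#'
#' Gradient-based MCMC (Hamiltonian Monte Carlo with dual-averaging step-size
#' adaptation and a diagonal metric estimated during warmup) on the
#' unconstrained parameterization: log slopes, first threshold plus log
#' increments, log hyper-SDs.  A mean-field Gaussian variational fit is
#' available as a fallback (`method = "advi"`).  Reproducible under `seed`.
#'
#' @param responses Response matrix (persons x items, NA = missing).  A
#'   zero-row matrix is allowed and yields prior-only sampling.
#' @param prior A [prior_config()].
#' @param chains Number of chains (default 4).
#' @param draws Post-warmup draws per chain (default 1000).
#' @param warmup Warmup iterations per chain (default = `draws`).
#' @param leapfrog Maximum leapfrog steps per trajectory.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param method `"hmc"` (default) or `"advi"`.
#' @param domain Domain label carried to extracted banks.
#' @return A `grm_posterior`: natural-scale draw matrix (`chains*draws` rows,
#'   named columns `lambda[i]`, `tau[i,j]`, `mu_tau`, `sigma_tau`, `sigma`,
#'   `theta[p]`), chain index, diagnostics (split R-hat, effective sample
#'   size, divergence count), `converged` flag, and the seed/config used.
#' @export
sample_posterior <- function(responses, prior = prior_config(),
                             chains = 4L, draws = 1000L, warmup = draws,
                             leapfrog = 40L, seed = 1L,
                             method = c("hmc", "advi"), domain = "domain") {
  method <- match.arg(method)
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  model <- .bayes_model(X, prior)
  item_names <- colnames(X) %||% sprintf("i%02d", seq_len(model$I))
  person_names <- rownames(X) %||%
    (if (model$P) sprintf("p%03d", seq_len(model$P)) else character(0))
  par_names <- .bayes_par_names(model, item_names, person_names)

  all_draws <- vector("list", chains)
  divergences <- 0L
  for (ch in seq_len(chains)) {
    with_seed(seed + ch - 1L, {
      init <- .bayes_init(model)
      if (method == "hmc") {
        res <- .hmc_chain(model$fn, init, warmup, draws, L = leapfrog,
                          scale_move = .make_scale_move(model))
        divergences <- divergences + res$divergences
        raw <- res$draws
      } else {
        raw <- .advi_fit(model$fn, init, draws = draws)
      }
    })
    nat <- t(apply(raw, 1L, .to_natural, model = model))
    all_draws[[ch]] <- nat
  }
  mat <- do.call(rbind, all_draws)
  colnames(mat) <- par_names
  chain_id <- rep(seq_len(chains), each = draws)

  # The latent scale is only encouraged by the priors (soft identifiability
  # along the flow lambda -> lambda/c, tau/theta/sigma -> c(.)), so the
  # identified quantities are the scale-free combinations lambda*sigma,
  # tau/sigma, theta/sigma.  Standardizing each draw to a unit-variance
  # latent population puts the Bayesian route on the same convention the
  # MML route imposes, and convergence is assessed on these identified
  # parameters.
  std <- mat
  sig <- mat[, "sigma"]
  lam_cols <- grepl("^lambda\\[", par_names)
  div_cols <- grepl("^(tau\\[|mu_tau$|sigma_tau$|theta\\[)", par_names)
  std[, lam_cols] <- mat[, lam_cols, drop = FALSE] * sig
  std[, div_cols] <- mat[, div_cols, drop = FALSE] / sig
  std[, "sigma"] <- 1

  rhat <- ess <- rep(NA_real_, ncol(mat))
  names(rhat) <- names(ess) <- par_names
  for (k in seq_len(ncol(mat))) {
    if (par_names[k] == "sigma") next
    per_chain <- matrix(std[, k], nrow = draws, ncol = chains)
    rhat[k] <- .split_rhat(per_chain)
    ess[k] <- .ess(per_chain)
  }
  item_par <- grepl("^(lambda|tau)\\[", par_names)
  converged <- all(rhat[item_par] < 1.05, na.rm = TRUE)
  if (!converged)
    warning(sprintf("R-hat > 1.05 on %d item parameter(s); treat results as non-converged",
                    sum(rhat[item_par] >= 1.05, na.rm = TRUE)))
  structure(list(draws = mat, standardized = std, chain = chain_id,
                 item_names = item_names, person_names = person_names,
                 ncat = model$ncat, domain = domain,
                 diagnostics = list(rhat = rhat, ess = ess,
                                    divergences = divergences),
                 converged = converged, method = method,
                 seed = seed, chains = chains, n_draws = draws,
                 warmup = warmup),
            class = "grm_posterior")
}

#' @export
print.grm_posterior <- function(x, ...) {
  cat(sprintf("<grm_posterior> %s: %d chains x %d draws, %d items, %d persons; max item R-hat %.3f; %d divergences\n",
              x$method, x$chains, x$n_draws, length(x$item_names),
              length(x$person_names),
              max(x$diagnostics$rhat[grepl("^(lambda|tau)\\[", names(x$diagnostics$rhat))],
                  na.rm = TRUE),
              x$diagnostics$divergences))
  invisible(x)
}

#' Point estimates from posterior draws
#'
#' Posterior means (L2-optimal) for item parameters and abilities, or
#' medians behind a flag.  Threshold ordering survives averaging because
#' every retained draw is ordered.  Person standard errors are the posterior
#' SDs of each `theta_p`.
#'
#' By default each draw is first standardized to a unit-variance latent
#' population (`lambda*sigma`, `tau/sigma`, `theta/sigma`): only these
#' scale-free combinations are identified by the data, and the convention
#' matches the N(0,1) latent density the MML route fixes, making the two
#' calibrated banks directly interchangeable.  `standardize = FALSE` returns
#' summaries of the raw draws.
#'
#' @param draws A `grm_posterior`.
#' @param estimator `"mean"` (default) or `"median"`.
#' @param standardize Standardize draws to unit latent scale (default TRUE).
#' @return List with `bank` (a `grm_bank`) and `person_estimates` (data
#'   frame, method tag `"CALIBRATION"`).
#' @export
point_estimates <- function(draws, estimator = c("mean", "median"),
                            standardize = TRUE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(draws, "grm_posterior"))
  if (!draws$converged)
    warning("extracting point estimates from a non-converged posterior")
  mat <- if (standardize) draws$standardized else draws$draws
  point <- if (estimator == "mean") colMeans(mat)
           else apply(mat, 2L, stats::median)
  items <- lapply(seq_along(draws$item_names), function(i) {
    id <- draws$item_names[i]
    J <- draws$ncat[i]
    item_params(id, point[sprintf("lambda[%s]", id)],
                unname(point[sprintf("tau[%s,%d]", id, 2:J)]))
  })
  bank <- item_bank(items, domain = draws$domain)
  person_estimates <- NULL
  if (length(draws$person_names)) {
    cols <- sprintf("theta[%s]", draws$person_names)
    person_estimates <- data.frame(
      person_id = draws$person_names,
      theta = unname(point[cols]),
      se = unname(apply(mat[, cols, drop = FALSE], 2L, sd)),
      method = "CALIBRATION",
      flagged = FALSE,
      stringsAsFactors = FALSE)
  }
  list(bank = bank, person_estimates = person_estimates)
}
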