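# Likelihood-free estimation for rank-frequency data. The exact
# permutation-sum likelihood is intractable beyond ~25 events, so these
# estimators simulate from the model and compare simulated to observed
# rank-frequency data with the Wasserstein distance (or a mean-log-count
# summary statistic), under uniform priors.

#' Configuration for the ABC estimators
#'
#' @param n_particles number of accepted particles per generation.
#' @param n_generations number of PMC generations (including the prior
#'   generation).
#' @param survival_fraction fraction in (0,1): the next tolerance is this
#'   quantile of the current generation's accepted distances.
#' @param prior_lambda uniform prior bounds for lambda; default
#'   \code{c(1.001, 3)} for unbounded models, \code{c(0.5, 3)} for finite
#'   \code{W} (a finite event set permits exponents at or below 1).
#' @param prior_q integer-uniform prior bounds for the Zipf-Mandelbrot
#'   offset (used only by the two-parameter family).
#' @param distance \code{"wasserstein"} (zero-padded quantile coupling of
#'   the count vectors) or \code{"mean_log_summary"} (absolute difference
#'   of mean log counts).
#' @param max_draws_per_generation safety cap on simulations per generation.
#' @param W event-set size of the generating model (default unbounded).
#' @param seed integer seed; every source of randomness in a run descends
#'   from it.
#' @param pad,log_counts passed to [wasserstein_distance()].
#' @param n_prior_draws,retain_fraction ABC-regression constants: number of
#'   prior simulations and the fraction retained closest to the observed
#'   summary statistic.
#' @return a list of class \code{"abc_config"}.
#' @export
abc_config <- function(n_particles = 200, n_generations = 10,
                       survival_fraction = 0.5, prior_lambda = NULL,
                       prior_q = c(0, 20),
                       distance = c("wasserstein", "mean_log_summary"),
                       max_draws_per_generation = 100 * n_particles,
                       W = Inf, seed = NULL, pad = TRUE, log_counts = FALSE,
                       n_prior_draws = 10000, retain_fraction = 0.1) {
  distance <- match.arg(distance)
  if (is.null(prior_lambda))
    prior_lambda <- if (is.infinite(W)) c(1.001, 3) else c(0.5, 3)
  stopifnot(survival_fraction > 0, survival_fraction < 1,
            prior_lambda[1] < prior_lambda[2], prior_q[1] <= prior_q[2],
            n_particles >= 2, n_generations >= 1)
  if (is.infinite(W) && prior_lambda[1] <= 1)
    stop("unbounded event set requires a lambda prior bounded below by 1",
         call. = FALSE)
  structure(list(n_particles = as.integer(n_particles),
                 n_generations = as.integer(n_generations),
                 survival_fraction = survival_fraction,
                 prior_lambda = prior_lambda,
                 prior_q = as.integer(round(prior_q)), distance = distance,
                 max_draws_per_generation = as.integer(max_draws_per_generation),
                 W = W, seed = seed, pad = pad, log_counts = log_counts,
                 n_prior_draws = as.integer(n_prior_draws),
                 retain_fraction = retain_fraction),
            class = "abc_config")
}

check_family <- function(model_family) {
  match.arg(model_family, c("zipf", "zipf_mandelbrot"))
}

# One simulated dataset: counts sorted non-increasing (no RNG seeding here;
# callers run inside a seeded context).
sim_counts <- function(family, lambda, q, N, W) {
  if (is.infinite(W)) {
    draws <- if (family == "zipf" || q == 0) cpp_sample_zeta(N, lambda)
             else cpp_sample_zm(N, lambda, q)
  } else {
    draws <- as.numeric(cpp_sample_finite(N, lambda,
                                          if (family == "zipf") 0 else q, W))
  }
  cpp_counts_sorted(draws)
}

abc_distance_fn <- function(obs, config) {
  obs_counts <- as.numeric(obs)
  if (config$distance == "wasserstein") {
    function(sim) wasserstein_distance(sim, obs_counts, pad = config$pad,
                                       log_counts = config$log_counts)
  } else {
    s_obs <- mean(log(obs_counts))
    function(sim) abs(mean(log(sim)) - s_obs)
  }
}

new_population <- function(particles, weights, distances, tolerance,
                           generation, family, config, n_draws) {
  structure(list(particles = particles, weights = weights / sum(weights),
                 distances = distances, tolerance = tolerance,
                 generation = generation, family = family, config = config,
                 n_draws = n_draws,
                 acceptance_rate = nrow(particles) / max(n_draws, 1)),
            class = "abc_population")
}

#' @export
print.abc_population <- function(x, ...) {
  cat(sprintf(
    "<abc_population> generation %d: %d particles, tolerance %.4g, acceptance %.1f%%\n",
    x$generation, nrow(x$particles), x$tolerance, 100 * x$acceptance_rate))
  invisible(x)
}

draw_prior <- function(n, family, config) {
  lam <- runif(n, config$prior_lambda[1], config$prior_lambda[2])
  if (family == "zipf") matrix(lam, ncol = 1, dimnames = list(NULL, "lambda"))
  else cbind(lambda = lam,
             q = sample(seq.int(config$prior_q[1], config$prior_q[2]),
                        n, replace = TRUE))
}

in_prior_support <- function(theta, family, config) {
  ok <- theta[1] >= config$prior_lambda[1] & theta[1] <= config$prior_lambda[2]
  if (family == "zipf_mandelbrot")
    ok <- ok && theta[2] >= config$prior_q[1] && theta[2] <= config$prior_q[2]
  ok
}

#' ABC rejection sampling
#'
#' Draws parameters from the uniform prior, simulates rank-frequency data
#' of the observed size from the model family, and accepts parameters whose
#' simulated data fall within \code{epsilon} of the observed data. With
#' \code{epsilon = Inf} the accepted particles are distributed as the prior.
#'
#' @param obs observed [rank_counts()] (non-empty).
#' @param model_family \code{"zipf"} or \code{"zipf_mandelbrot"}.
#' @param config an [abc_config()].
#' @param epsilon fixed acceptance tolerance.
#' @return an \code{"abc_population"} with uniform weights.
#' @export
abc_rejection <- function(obs, model_family = "zipf", config = abc_config(),
                          epsilon = Inf) {
  obs <- as_rank_counts(obs)
  if (w_obs(obs) == 0) stop("observed counts are empty", call. = FALSE)
  family <- check_family(model_family)
  dist_fn <- abc_distance_fn(obs, config)
  N <- n_total(obs)
  with_seed(config$seed, function() {
    acc <- list(); dists <- numeric(0); draws <- 0L
    while (length(acc) < config$n_particles) {
      if (draws >= config$max_draws_per_generation)
        stop(sprintf(
          "ABC rejection: %d simulations yielded only %d/%d acceptances",
          draws, length(acc), config$n_particles), call. = FALSE)
      theta <- draw_prior(1, family, config)[1, ]
      sim <- sim_counts(family, theta[1],
                        if (family == "zipf") 0 else theta[2], N, config$W)
      draws <- draws + 1L
      d <- dist_fn(sim)
      if (d < epsilon) { acc[[length(acc) + 1L]] <- theta; dists <- c(dists, d) }
    }
    particles <- do.call(rbind, acc)
    new_population(particles, rep(1, nrow(particles)), dists, epsilon, 0L,
                   family, config, draws)
  })
}

# Weighted sample variance / covariance (weights sum to 1).
wvar <- function(x, w) {
  m <- sum(w * x); sum(w * (x - m)^2)
}
wcov2 <- function(X, w) {
  m <- colSums(X * w)
  Xc <- sweep(X, 2, m)
  crossprod(Xc * sqrt(w), Xc * sqrt(w)) / 1
}

#' ABC population Monte Carlo (sequential ABC)
#'
#' Generation 0 accepts \code{n_particles} draws from the uniform prior.
#' Each later generation proposes particles by importance-resampling the
#' previous generation and perturbing with a Gaussian kernel whose variance
#' (covariance, in the two-parameter case) is twice the weighted variance
#' of the previous generation; proposals outside the prior are rejected
#' before simulation; accepted particles receive importance weights
#' \eqn{w_i \propto \pi(\theta_i) / \sum_j w_j K(\theta_i | \theta_j)}.
#' The tolerance for each generation is the \code{survival_fraction}
#' quantile of the previous generation's accepted distances, so the
#' schedule is non-increasing. The Zipf-Mandelbrot offset q is proposed
#' continuously, rounded to the nearest integer, and treated as a discrete
#' axis in the posterior.
#'
#' @inheritParams abc_rejection
#' @return a list with elements \code{population} (final
#'   \code{"abc_population"}), \code{posterior} (an \code{"abc_posterior"}),
#'   \code{tolerances} and \code{acceptance_rates} per generation.
#' @export
abc_pmc <- function(obs, model_family = "zipf", config = abc_config()) {
  obs <- as_rank_counts(obs)
  if (w_obs(obs) == 0) stop("observed counts are empty", call. = FALSE)
  family <- check_family(model_family)
  dist_fn <- abc_distance_fn(obs, config)
  N <- n_total(obs)
  np <- config$n_particles
  two_par <- family == "zipf_mandelbrot"
  with_seed(config$seed, function() {
    # generation 0: prior draws, all accepted
    particles <- draw_prior(np, family, config)
    dists <- vapply(seq_len(np), function(i) {
      dist_fn(sim_counts(family, particles[i, 1],
                         if (two_par) particles[i, 2] else 0, N, config$W))
    }, numeric(1))
    weights <- rep(1 / np, np)
    tolerances <- Inf
    acc_rates <- 1
    for (t in seq_len(config$n_generations - 1L)) {
      eps <- unname(quantile(dists, config$survival_fraction))
      if (two_par) {
        C <- 2 * wcov2(particles, weights)
        if (any(!is.finite(C)) || det(C) <= 1e-12)
          C <- C + diag(c(1e-6, 0.25))   # keep the kernel proper if a
                                         # discrete axis has collapsed
        R <- chol(C)
        Cinv <- chol2inv(R)
        kdet <- prod(diag(R))^2
      } else {
        sd_pert <- sqrt(2 * wvar(particles[, 1], weights))
        if (!is.finite(sd_pert) || sd_pert <= 0)
          stop("degenerate particle population: zero perturbation variance",
               call. = FALSE)
      }
      new_part <- matrix(NA_real_, np, ncol(particles),
                         dimnames = dimnames(particles))
      new_dist <- numeric(np)
      n_acc <- 0L; draws <- 0L; supp_rej <- 0L
      while (n_acc < np) {
        if (draws >= config$max_draws_per_generation)
          stop(sprintf(
            "ABC-PMC generation %d: %d simulations yielded only %d/%d acceptances",
            t, draws, n_acc, np), call. = FALSE)
        j <- sample.int(np, 1, prob = weights)
        if (two_par) {
          theta <- particles[j, ] + drop(rnorm(2) %*% R)
          theta[2] <- round(theta[2])
        } else {
          theta <- particles[j, ] + rnorm(1, 0, sd_pert)
        }
        if (!in_prior_support(theta, family, config)) {
          supp_rej <- supp_rej + 1L
          if (supp_rej > 1e7)
            stop("ABC-PMC: proposal kernel incompatible with the prior support",
                 call. = FALSE)
          next
        }
        sim <- sim_counts(family, theta[1], if (two_par) theta[2] else 0,
                          N, config$W)
        draws <- draws + 1L
        d <- dist_fn(sim)
        if (d < eps) {
          n_acc <- n_acc + 1L
          new_part[n_acc, ] <- theta
          new_dist[n_acc] <- d
        }
      }
      # importance weights under the uniform prior
      new_w <- vapply(seq_len(np), function(i) {
        if (two_par) {
          dx <- sweep(particles, 2, new_part[i, ], "-")
          k <- exp(-0.5 * rowSums((dx %*% Cinv) * dx)) / (2 * pi * sqrt(kdet))
        } else {
          k <- dnorm(new_part[i, 1] - particles[, 1], 0, sd_pert)
        }
        1 / sum(weights * k)
      }, numeric(1))
      particles <- new_part
      dists <- new_dist
      weights <- new_w / sum(new_w)
      tolerances <- c(tolerances, eps)
      acc_rates <- c(acc_rates, np / draws)
    }
    pop <- new_population(particles, weights, dists,
                          tolerances[length(tolerances)],
                          config$n_generations - 1L, family, config,
                          if (length(acc_rates) > 1)
                            round(np / acc_rates[length(acc_rates)]) else np)
    list(population = pop,
         posterior = posterior_approximation(pop),
         tolerances = tolerances, acceptance_rates = acc_rates)
  })
}

#' Regression-adjusted ABC with a mean-log-count summary statistic
#'
#' Simulates from the prior, summarises every dataset by the mean of the
#' log-transformed event counts, retains the fraction of draws closest to
#' the observed summary, and corrects the retained parameters by a
#' local-linear weighted regression (Epanechnikov weights) of the parameter
#' on the summary statistic. The weighted, adjusted draws form the
#' posterior sample; its weighted mean is the point estimate.
#'
#' @inheritParams abc_rejection
#' @return an \code{"abc_posterior"} with additional fields
#'   \code{point_estimate} (weighted mean of the adjusted draws),
#'   \code{adjusted}, \code{weights}.
#' @export
abc_regression <- function(obs, model_family = "zipf", config = abc_config()) {
  obs <- as_rank_counts(obs)
  if (w_obs(obs) == 0) stop("observed counts are empty", call. = FALSE)
  family <- check_family(model_family)
  if (family != "zipf")
    stop("ABC regression is implemented for the one-parameter Zipf family",
         call. = FALSE)
  N <- n_total(obs)
  s_obs <- mean_log_counts(obs)
  with_seed(config$seed, function() {
    M <- config$n_prior_draws
    lam <- runif(M, config$prior_lambda[1], config$prior_lambda[2])
    s <- vapply(lam, function(l)
      mean_log_counts(sim_counts("zipf", l, 0, N, config$W)), numeric(1))
    tdist <- abs(s - s_obs)
    keep <- order(tdist)[seq_len(max(2L, ceiling(config$retain_fraction * M)))]
    tmax <- max(tdist[keep])
    if (tmax == 0) tmax <- 1
    w <- 1 - (tdist[keep] / tmax)^2
    w[w <= 0] <- min(w[w > 0]) / 2
    if (var(s[keep]) == 0)
      stop("retained summary statistics are constant; regression undefined",
           call. = FALSE)
    fit <- stats::lm(y ~ x, data = data.frame(y = lam[keep], x = s[keep]),
                     weights = w)
    beta <- coef(fit)[["x"]]
    adj <- lam[keep] - beta * (s[keep] - s_obs)
    post <- wkde_posterior_1d(adj, w / sum(w), config)
    post$point_estimate <- weighted.mean(adj, w)
    post$adjusted <- adj
    post$weights <- w / sum(w)
    post
  })
}

#' Mean of the log-transformed event counts
#'
#' The summary statistic used by [abc_regression()]; 0 for all-singleton
#' counts since \eqn{\log 1 = 0}.
#'
#' @param counts a [rank_counts()] vector.
#' @return mean of \code{log(counts)} over observed events.
#' @export
mean_log_counts <- function(counts) mean(log(as.numeric(counts)))

weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][vapply(p, function(pp) which(cw >= pp)[1], integer(1))]
}

wkde_bandwidth <- function(x, w) {
  n_eff <- 1 / sum(w^2)
  sdw <- sqrt(wvar(x, w))
  iqr <- diff(weighted_quantile(x, w, c(0.25, 0.75)))
  sig <- min(sdw, iqr / 1.349)
  if (!is.finite(sig) || sig <= 0) sig <- max(sdw, 1e-3)
  0.9 * sig * n_eff^(-1 / 5)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

wkde_posterior_1d <- function(lam, w, config, grid_step = 0.001) {
  h <- wkde_bandwidth(lam, w)
  lo <- config$prior_lambda[1]; hi <- config$prior_lambda[2]
  grid <- seq(lo, hi, by = grid_step)
  dens <- vapply(grid, function(g) sum(w * dnorm(g, lam, h)), numeric(1))
  Z <- trapz(grid, dens)
  dens <- dens / Z
  ci <- credible_from_density(grid, dens, 0.95)
  structure(list(support = grid, density = dens,
                 map_estimate = grid[which.max(dens)],
                 credible_interval = ci, bandwidth = h, mass = 0.95),
            class = "abc_posterior")
}

credible_from_density <- function(grid, dens, mass) {
  dx <- diff(grid)
  cdf <- c(0, cumsum(dx * (head(dens, -1) + dens[-1]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  lo <- grid[which(cdf >= (1 - mass) / 2)[1]]
  hi <- grid[which(cdf >= 1 - (1 - mass) / 2)[1]]
  c(lo, hi)
}

#' Weighted kernel density posterior from an ABC particle population
#'
#' Gaussian kernel with a weighted Silverman bandwidth over lambda, on a
#' grid of resolution 0.001; the Zipf-Mandelbrot offset q is kept discrete
#' (probability mass per integer, no smoothing across q). Under the uniform
#' priors used here the posterior mode is a likelihood-proportional
#' (maximum-likelihood-type) estimate.
#'
#' @param pop an \code{"abc_population"}.
#' @param mass credible-interval mass for the lambda marginal.
#' @return an \code{"abc_posterior"}: \code{support} (lambda grid),
#'   \code{density} (vector, or q-by-lambda matrix whose total trapezoid
#'   mass is 1), \code{map_estimate} (named vector), \code{q_marginal}
#'   (two-parameter case), \code{credible_interval}.
#' @export
posterior_approximation <- function(pop, mass = 0.95) {
  stopifnot(inherits(pop, "abc_population"))
  config <- pop$config
  lam <- pop$particles[, 1]
  w <- pop$weights
  if (ncol(pop$particles) == 1) {
    out <- wkde_posterior_1d(lam, w, config)
    if (mass != 0.95) {
      out$credible_interval <- credible_from_density(out$support, out$density, mass)
      out$mass <- mass
    }
    out$map_estimate <- c(lambda = out$map_estimate)
    return(out)
  }
  qs <- seq.int(config$prior_q[1], config$prior_q[2])
  grid <- seq(config$prior_lambda[1], config$prior_lambda[2], by = 0.001)
  dens <- matrix(0, length(qs), length(grid),
                 dimnames = list(q = qs, NULL))
  qpart <- pop$particles[, 2]
  for (k in seq_along(qs)) {
    sel <- qpart == qs[k]
    if (!any(sel)) next
    wk <- w[sel]
    h <- if (sum(sel) > 1) wkde_bandwidth(lam[sel], wk / sum(wk)) else 0.01
    dens[k, ] <- vapply(grid, function(g)
      sum(wk * dnorm(g, lam[sel], h)), numeric(1))
  }
  # normalize: sum over q of the lambda-integral = 1
  tot <- sum(apply(dens, 1, function(row) trapz(grid, row)))
  dens <- dens / tot
  q_marginal <- apply(dens, 1, function(row) trapz(grid, row))
  best <- arrayInd(which.max(dens), dim(dens))
  lam_marg <- colSums(dens)
  lam_marg <- lam_marg / trapz(grid, lam_marg)
  structure(list(support = grid, q_values = qs, density = dens,
                 q_marginal = q_marginal,
                 map_estimate = c(lambda = grid[best[2]], q = qs[best[1]]),
                 credible_interval = credible_from_density(grid, lam_marg, mass),
                 mass = mass),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  map <- x$map_estimate
  cat(sprintf("<abc_posterior> MAP: %s; %.0f%% CI for lambda: [%.3f, %.3f]\n",
              paste(sprintf("%s = %.3f", names(map), map), collapse = ", "),
              100 * x$mass, x$credible_interval[1], x$credible_interval[2]))
  invisible(x)
}

#' Posterior mode (MAP) of an ABC result
#'
#' @param x an \code{"abc_population"} or \code{"abc_posterior"}.
#' @return named parameter vector at the mode of the weighted KDE, on a
#'   lambda grid of resolution 0.001 (integer q).
#' @export
map_estimate <- function(x) {
  if (inherits(x, "abc_population")) x <- posterior_approximation(x)
  stopifnot(inherits(x, "abc_posterior"))
  x$map_estimate
}
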