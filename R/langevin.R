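# Slow-fast Langevin engine and its Fokker-Planck reduction.  The cell's
# internal state X is the slow variable, the microenvironment Y the fast one.
# Under timescale separation the joint dynamics decompose hierarchically:
# the fast conditional law relaxes with X frozen, the slow marginal obeys a
# 1-D stationary equation, and a coupling equation constrains the cross
# diffusion.  Convention: the Fokker-Planck diffusion coefficients are
# sigma_pq = (Sigma Sigma^T)_pq / 2, so the Langevin noise amplitude of a
# variable with diffusion coefficient sigma is sqrt(2 sigma); this dictionary
# is pinned by the Ornstein-Uhlenbeck stationary-variance test
# (Var = sigma22 / k for drift -k x).

#' Specification of a slow-fast stochastic differential equation
#'
#' The pair `(X, Y)` follows Ito dynamics with drift `(K2(x), K1(y, x, t))`
#' and Fokker-Planck diffusion coefficients `sigma22` (slow, constant),
#' `sigma11(y, x)` (fast) and `sigma12(y, x)` (coupling). The timescale
#' ratio `epsilon` scales the fast drift and diffusion by `1/epsilon`.
#'
#' @param drift_K2 Slow drift, function `x -> real`.
#' @param sigma22 Constant slow diffusion coefficient (> 0, or 0 for the
#'   deterministic limit).
#' @param drift_K1 Optional fast drift, function `(y, x, t) -> real`; omit
#'   for a slow-only simulation.
#' @param sigma11 Optional fast diffusion coefficient, function
#'   `(y, x) -> real >= 0` (required with `drift_K1`).
#' @param sigma12 Optional coupling diffusion coefficient, function
#'   `(y, x) -> real`; default 0.
#' @param epsilon Timescale ratio scaling the fast dynamics (default 1).
#' @param dt Time step (> 0).
#' @param n_steps Number of steps.
#' @param n_paths Number of independent paths.
#' @param seed Integer seed.
#' @param x0,y0 Initial values (scalars, recycled across paths).
#' @return An object of class `sde_spec`.
#' @export
sde_spec <- function(drift_K2, sigma22, drift_K1 = NULL, sigma11 = NULL,
                     sigma12 = NULL, epsilon = 1, dt, n_steps, n_paths = 1L,
                     seed = 1L, x0 = 0, y0 = 0) {
  stopifnot(dt > 0, n_steps >= 1, n_paths >= 1, epsilon > 0,
            is.function(drift_K2), is.finite(sigma22), sigma22 >= 0)
  if (!is.null(drift_K1) && is.null(sigma11))
    stop("sde_spec: sigma11 is required when drift_K1 is given", call. = FALSE)
  structure(list(drift_K2 = drift_K2, drift_K1 = drift_K1,
                 sigma11 = sigma11, sigma12 = sigma12, sigma22 = sigma22,
                 epsilon = epsilon, dt = dt, n_steps = as.integer(n_steps),
                 n_paths = as.integer(n_paths), seed = as.integer(seed),
                 x0 = x0, y0 = y0),
            class = "sde_spec")
}

check_finite_state <- function(x, step) {
  if (any(!is.finite(x)))
    stop(sprintf(
      "euler_maruyama: non-finite state at step %d; reduce dt or soften the drift",
      step), call. = FALSE)
}

#' Euler-Maruyama integration of a slow-fast SDE
#'
#' Ito-Euler stepping with independent Wiener increments per component. With
#' the declared dictionary `sigma_pq = (Sigma Sigma^T)_pq / 2`, the noise
#' amplitude matrix is obtained from the Cholesky factor of `2 sigma`
#' evaluated pointwise; the fast row is scaled by `1/epsilon`.
#'
#' @param spec An [sde_spec()].
#' @return An object of class `sde_trajectory`: list with `times`, matrix
#'   `x` (`n_paths` x `n_steps + 1`), matrix `y` (or `NULL` for slow-only
#'   specs) and the `spec`.
#' @export
euler_maruyama <- function(spec) {
  stopifnot(inherits(spec, "sde_spec"))
  set.seed(spec$seed)
  np <- spec$n_paths; ns <- spec$n_steps; dt <- spec$dt
  x <- matrix(NA_real_, np, ns + 1L)
  x[, 1L] <- spec$x0
  has_fast <- !is.null(spec$drift_K1)
  y <- if (has_fast) matrix(NA_real_, np, ns + 1L) else NULL
  if (has_fast) y[, 1L] <- spec$y0
  amp_x <- sqrt(2 * spec$sigma22 * dt)
  t <- 0
  for (s in seq_len(ns)) {
    xc <- x[, s]
    if (has_fast) {
      yc <- y[, s]
      s11 <- vapply(seq_len(np),
                    function(i) spec$sigma11(yc[i], xc[i]), numeric(1)) /
        spec$epsilon
      s12 <- if (is.null(spec$sigma12)) rep(0, np)
      else vapply(seq_len(np),
                  function(i) spec$sigma12(yc[i], xc[i]), numeric(1)) /
        spec$epsilon
      k1 <- vapply(seq_len(np),
                   function(i) spec$drift_K1(yc[i], xc[i], t), numeric(1)) /
        spec$epsilon
      dW1 <- stats::rnorm(np)
      dW2 <- stats::rnorm(np)
      # Cholesky of 2*sigma (fast row first): B11 = sqrt(2 s11),
      # B21 = 2 s12 / B11, B22 = sqrt(2 sigma22 - B21^2)
      B11 <- sqrt(pmax(2 * s11, 0))
      B21 <- ifelse(B11 > 0, 2 * s12 / B11, 0)
      B22sq <- 2 * spec$sigma22 - B21^2
      if (any(B22sq < -1e-12))
        stop("euler_maruyama: diffusion matrix not positive semidefinite",
             call. = FALSE)
      B22 <- sqrt(pmax(B22sq, 0))
      y[, s + 1L] <- yc + k1 * dt + B11 * sqrt(dt) * dW1
      x[, s + 1L] <- xc + spec$drift_K2(xc) * dt +
        sqrt(dt) * (B21 * dW1 + B22 * dW2)
    } else {
      x[, s + 1L] <- xc + spec$drift_K2(xc) * dt + amp_x * stats::rnorm(np)
    }
    if (s %% 200L == 0L || s == ns) {
      check_finite_state(x[, s + 1L], s)
      if (has_fast) check_finite_state(y[, s + 1L], s)
    }
    t <- t + dt
  }
  structure(list(times = seq(0, ns * dt, by = dt), x = x, y = y, spec = spec),
            class = "sde_trajectory")
}

#' @export
print.sde_trajectory <- function(x, ...) {
  cat(sprintf("sde_trajectory: %d paths x %d steps (dt = %g)%s\n",
              nrow(x$x), ncol(x$x) - 1L, x$spec$dt,
              if (is.null(x$y)) ", slow variable only" else ""))
  invisible(x)
}

#' One-dimensional stationary Fokker-Planck solution
#'
#' For a slow variable with drift `K2` and constant diffusion coefficient
#' `sigma22`, the stationary density is
#' \eqn{P(x) \propto \exp\left(\int^x K_2(s)/\sigma_{22}\, ds\right)}
#' (the `-log sigma22` term is an absorbed constant), computed by cumulative
#' trapezoidal quadrature with overflow guarding.
#'
#' @param K2 Drift function `x -> real`, finite on the domain.
#' @param sigma22 Constant diffusion coefficient (> 0).
#' @param domain A [grid1d()].
#' @return An object of class `fp_stationary`: list with `density`
#'   (normalized [grid_density()]), the normalizer `f0`, and the inputs.
#' @export
stationary_solution_1d <- function(K2, sigma22, domain) {
  stopifnot(sigma22 > 0)
  k <- vapply(domain$x, K2, numeric(1))
  if (any(!is.finite(k)))
    stop("stationary_solution_1d: drift non-finite on the domain",
         call. = FALSE)
  expo <- as.vector(pracma::cumtrapz(domain$x, k / sigma22))
  shifted <- expo - max(expo)
  raw <- exp(shifted)
  mass <- sum(trapz_weights(domain) * raw)
  if (!is.finite(mass) || mass <= 0)
    stop("stationary_solution_1d: non-integrable exponent", call. = FALSE)
  structure(list(density = grid_density(domain, raw / mass, normalize = FALSE),
                 f0 = exp(-max(expo)) / mass / sigma22,
                 K2 = K2, sigma22 = sigma22),
            class = "fp_stationary")
}

#' Drift force implied by a microenvironmental entropy profile
#'
#' The unique slow drift whose stationary Fokker-Planck solution reproduces
#' the Gibbs steady state driven by conditional entropy:
#' \eqn{K_2(x) = -\beta\,\sigma_{22}\,S(Y|X=x) - \beta'\sigma_{22}}. Feeding
#' it to [stationary_solution_1d()] recovers the [steady_state_generic()]
#' density.
#'
#' @param entropy_profile Vectorized function `x -> S(Y|X=x)` (nats).
#' @param params A [sensitivity_params()].
#' @param sigma22 Constant slow diffusion coefficient.
#' @return Drift function `x -> real`.
#' @export
drift_from_entropy <- function(entropy_profile, params, sigma22) {
  force(entropy_profile); force(params); force(sigma22)
  function(x)
    -params$beta * sigma22 * entropy_profile(x) -
    params$beta_prime * sigma22
}

#' Kolmogorov-Smirnov distance between samples and a grid density
#'
#' @param samples Numeric sample vector.
#' @param density A normalized [grid_density()] whose CDF (by cumulative
#'   trapezoid) is the reference.
#' @return The KS statistic `sup |F_emp - F|` evaluated at the samples.
#' @export
ks_distance <- function(samples, density) {
  cdf <- as.vector(pracma::cumtrapz(density$grid$x, density$values))
  cdf <- cdf / cdf[length(cdf)]
  Fs <- stats::approx(density$grid$x, cdf, xout = sort(samples), rule = 2)$y
  n <- length(samples)
  i <- seq_len(n)
  max(pmax(abs(i / n - Fs), abs((i - 1) / n - Fs)))
}

# reflecting-boundary Euler-Maruyama for the slow variable alone
simulate_reflected_slow <- function(K2, sigma22, domain, dt, n_steps, n_paths,
                                    seed, x0) {
  set.seed(seed)
  amp <- sqrt(2 * sigma22 * dt)
  lo <- domain[1]; hi <- domain[2]
  x <- rep(x0, n_paths)
  out <- matrix(NA_real_, n_paths, n_steps)
  for (s in seq_len(n_steps)) {
    x <- x + K2(x) * dt + amp * stats::rnorm(n_paths)
    # reflect at the domain edges (entropy-derived drifts diverge there)
    x <- ifelse(x < lo, 2 * lo - x, x)
    x <- ifelse(x > hi, 2 * hi - x, x)
    x <- pmin(pmax(x, lo), hi)
    if (s %% 500L == 0L) check_finite_state(x, s)
    out[, s] <- x
  }
  out
}

#' Simulate the slow variable to its entropy-driven stationary law
#'
#' Runs reflected Euler-Maruyama for the slow variable with the drift from
#' [drift_from_entropy()], discards a burn-in fraction, and compares the
#' retained samples with the analytic stationary solution by the
#' Kolmogorov-Smirnov distance. This exercises the bridge between the
#' Langevin description and the Bayesian-learning steady state.
#'
#' @param entropy_profile Vectorized function `x -> S(Y|X=x)`.
#' @param params A [sensitivity_params()].
#' @param sigma22 Constant slow diffusion coefficient (> 0).
#' @param domain Numeric `c(lo, hi)` with reflecting boundaries.
#' @param dt,n_steps,n_paths,seed Simulation controls.
#' @param burn_in Fraction of initial steps discarded (default 0.2).
#' @param thin Keep every `thin`-th retained step (default 1).
#' @param n_grid Grid points for the analytic solution (default 2001).
#' @return List with `samples` (retained), `ks` (distance to the analytic
#'   density), `analytic` (the [stationary_solution_1d()] result),
#'   `empirical` (histogram density on bin centers) and `n_retained`.
#' @export
simulate_slow_stationary <- function(entropy_profile, params, sigma22, domain,
                                     dt = 0.02, n_steps = 10000L,
                                     n_paths = 100L, seed = 1L,
                                     burn_in = 0.2, thin = 1L,
                                     n_grid = 2001L) {
  K2 <- drift_from_entropy(entropy_profile, params, sigma22)
  x0 <- mean(domain)
  paths <- simulate_reflected_slow(K2, sigma22, domain, dt, n_steps, n_paths,
                                   seed, x0)
  keep <- seq.int(from = ceiling(burn_in * n_steps) + 1L, to = n_steps,
                  by = thin)
  samples <- as.vector(paths[, keep])
  grid <- grid1d(domain[1], domain[2], n_grid)
  analytic <- stationary_solution_1d(K2, sigma22, grid)
  n_bins <- max(40L, min(200L, floor(sqrt(length(samples)) / 4)))
  h <- graphics::hist(samples, breaks = seq(domain[1], domain[2],
                                            length.out = n_bins + 1L),
                      plot = FALSE)
  centers_grid <- grid1d(h$mids[1], h$mids[length(h$mids)], length(h$mids))
  empirical <- grid_density(centers_grid, h$density, normalize = TRUE)
  list(samples = samples, ks = ks_distance(samples, analytic$density),
       analytic = analytic, empirical = empirical,
       n_retained = length(samples))
}

#' Quasi-stationary conditional law of the fast variable
#'
#' Simulates the fast microenvironmental variable with the internal state
#' frozen at `x_frozen` and returns the empirical conditional density after
#' burn-in. For an Ornstein-Uhlenbeck fast drift `-(y - F(x))` with constant
#' diffusion `s`, this realizes the Gaussian sensing channel
#' `Normal(F(x), s)`.
#'
#' @param spec An [sde_spec()] with `drift_K1` and `sigma11` set.
#' @param x_frozen Frozen internal-state value.
#' @param y_grid A [grid1d()] for the histogram support.
#' @param burn_in Fraction of initial steps discarded (default 0.2).
#' @return List with `density` (histogram [grid_density()] on `y_grid` bin
#'   centers), `samples` and `mean`.
#' @export
fast_conditional_density <- function(spec, x_frozen, y_grid, burn_in = 0.2) {
  stopifnot(inherits(spec, "sde_spec"))
  if (is.null(spec$drift_K1))
    stop("fast_conditional_density: spec has no fast drift", call. = FALSE)
  set.seed(spec$seed)
  np <- spec$n_paths; ns <- spec$n_steps; dt <- spec$dt
  y <- rep(spec$y0, np)
  out <- matrix(NA_real_, np, ns)
  t <- 0
  for (s in seq_len(ns)) {
    s11 <- vapply(y, function(yy) spec$sigma11(yy, x_frozen), numeric(1)) /
      spec$epsilon
    k1 <- vapply(y, function(yy) spec$drift_K1(yy, x_frozen, t), numeric(1)) /
      spec$epsilon
    y <- y + k1 * dt + sqrt(pmax(2 * s11 * dt, 0)) * stats::rnorm(np)
    if (s %% 500L == 0L) check_finite_state(y, s)
    out[, s] <- y
    t <- t + dt
  }
  keep <- seq.int(ceiling(burn_in * ns) + 1L, ns)
  samples <- as.vector(out[, keep])
  brk <- seq(y_grid$lower, y_grid$upper, length.out = 101L)
  clipped <- pmin(pmax(samples, y_grid$lower), y_grid$upper)
  h <- graphics::hist(clipped, breaks = brk, plot = FALSE)
  centers <- grid1d(h$mids[1], h$mids[length(h$mids)], length(h$mids))
  list(density = grid_density(centers, h$density, normalize = TRUE),
       samples = samples, mean = mean(samples))
}

#' Residual of the slow-fast coupling equation
#'
#' Evaluates \eqn{2\,\partial_Y[\sigma_{12}(Y) P(Y|X)] + \sigma_{22}\,
#' \partial_Y P(Y|X)} on the conditional density's grid by central
#' differences. The constant choice `sigma12 = -sigma22/2` annihilates it
#' identically for any smooth density; with `sigma12 = 0` the residual is
#' `sigma22 * dP/dY`.
#'
#' @param sigma12 Function `y -> real` (coupling diffusion coefficient).
#' @param sigma22 Constant slow diffusion coefficient.
#' @param cond_density A [grid_density()] for `P(Y|X)` at fixed `X`.
#' @return List with `profile` (residual at interior nodes), `y` (those
#'   nodes) and `linf`.
#' @export
coupling_residual <- function(sigma12, sigma22, cond_density) {
  g <- cond_density$grid
  P <- cond_density$values
  s12 <- vapply(g$x, sigma12, numeric(1))
  n <- g$n_points
  h <- g$spacing
  central <- function(v) (v[3:n] - v[1:(n - 2)]) / (2 * h)
  profile <- 2 * central(s12 * P) + sigma22 * central(P)
  list(profile = profile, y = g$x[2:(n - 1)], linf = max(abs(profile)))
}

#' Residual of the stationary slow-variable equation
#'
#' Evaluates \eqn{-K_2(x) P(x) + \sigma_{22}\,\partial_x P(x)} (constant
#' `sigma22`) at interior nodes by central differences and returns the
#' maximum absolute residual scaled by the density maximum. The
#' [stationary_solution_1d()] output satisfies this by construction.
#'
#' @param solution An `fp_stationary` or [grid_density()].
#' @param K2 Drift function.
#' @param sigma22 Constant slow diffusion coefficient.
#' @return Scaled L-infinity residual (scalar).
#' @export
slow_equation_residual <- function(solution, K2, sigma22) {
  density <- if (inherits(solution, "fp_stationary")) solution$density
  else solution
  g <- density$grid
  P <- density$values
  n <- g$n_points
  dP <- (P[3:n] - P[1:(n - 2)]) / (2 * g$spacing)
  k <- vapply(g$x[2:(n - 1)], K2, numeric(1))
  max(abs(-k * P[2:(n - 1)] + sigma22 * dP)) / max(P)
}
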