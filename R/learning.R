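# Discrete-time Bayesian learning of the internal-state distribution: the
# posterior at one decision step becomes the prior of the next.  The module
# also provides the averaged identities that this iteration obeys — the
# expected posterior-prior KL divergence equals the cell-environment mutual
# information (a fluctuation-dissipation relation), and for small updates the
# KL divergence is the Fisher-information quadratic form.

#' Single Bayesian update of the internal-state distribution
#'
#' Multiplies the prior by the Gaussian sensing likelihood
#' `L(x) = Normal(y_obs; F(x), sigma(x)^2)` and renormalizes. The returned
#' posterior is used as the next step's prior in [iterate_learning()].
#'
#' @param prior A normalized [grid_density()] over internal states.
#' @param model A [sensing_model()] whose domain covers the prior's grid.
#' @param y_obs Observed environment value.
#' @return The posterior as a normalized `grid_density`.
#' @export
bayes_update <- function(prior, model, y_obs) {
  x <- prior$grid$x
  L <- stats::dnorm(y_obs, mean = conditional_mean(model, x),
                    sd = conditional_sd(model, x))
  post <- L * prior$values
  evidence <- sum(trapz_weights(prior$grid) * post)
  if (!is.finite(evidence) || evidence < 1e-300)
    stop("bayes_update: degenerate evidence (observation incompatible with prior support)",
         call. = FALSE)
  grid_density(prior$grid, post / evidence, normalize = TRUE)
}

# likelihood matrix L[i, j] = p(y_i | x_j) over a y-grid and the prior's x-grid
likelihood_matrix <- function(prior, model, y_grid) {
  x <- prior$grid$x
  mu <- conditional_mean(model, x)
  sd <- conditional_sd(model, x)
  outer(y_grid$x, seq_along(x),
        function(y, j) stats::dnorm(y, mean = mu[j], sd = sd[j]))
}

# evidence density p(y) = int p(y|x) prior(x) dx on a y-grid
evidence_density <- function(prior, model, y_grid, L = NULL) {
  if (is.null(L)) L <- likelihood_matrix(prior, model, y_grid)
  py <- as.vector(L %*% (trapz_weights(prior$grid) * prior$values))
  grid_density(y_grid, pmax(py, 0), normalize = FALSE)
}

check_coverage <- function(py, min_mass = 0.999) {
  mass <- density_mass(py)
  if (mass < min_mass)
    stop(sprintf(
      "y-grid too narrow: captured evidence mass %.6f < %.3f", mass, min_mass),
      call. = FALSE)
  invisible(mass)
}

#' Expected posterior-prior divergence over observations (nats)
#'
#' Computes \eqn{E_{P(Y)}[D(\,P(X|Y)\,\Vert\,P(X)\,)]} by quadrature over a
#' y-grid. On fully normalized supports this equals the mutual information of
#' the joint `P(x) P(y|x)` induced by the prior and the sensing channel — the
#' fluctuation-dissipation identity of Bayesian learning.
#'
#' @param prior A normalized [grid_density()].
#' @param model A [sensing_model()].
#' @param y_grid A [grid1d()] for the environment variable; must capture at
#'   least 99.9% of the evidence mass.
#' @return Expected KL divergence in nats (nonnegative).
#' @export
expected_update_divergence <- function(prior, model, y_grid) {
  L <- likelihood_matrix(prior, model, y_grid)
  py <- evidence_density(prior, model, y_grid, L = L)
  check_coverage(py)
  wx <- trapz_weights(prior$grid)
  wy <- trapz_weights(y_grid)
  pyv <- pmax(py$values, .LOG_CLIP)
  # integrand p(y|x) prior(x) ln(p(y|x)/p(y)) over the (y, x) product grid
  lr <- log(pmax(L, .LOG_CLIP)) - log(pyv)
  lr[L <= 0] <- 0
  integ <- (L * lr) %*% (wx * prior$values)
  sum(wy * integ)
}

#' Expected posterior-prior divergence for a discrete joint (nats)
#'
#' Discrete analogue of [expected_update_divergence()]:
#' \eqn{\sum_y p(y) D(p(x|y) \Vert p(x))}, which equals the mutual
#' information of the table exactly.
#'
#' @param joint A [joint_table()].
#' @return Expected KL divergence in nats.
#' @export
expected_kl_discrete <- function(joint) {
  p <- unname(joint$probs)
  px <- rowSums(p)
  py <- colSums(p)
  total <- 0
  for (j in seq_along(py)) {
    if (py[j] <= 0) next
    post <- p[, j] / py[j]
    keep <- post > 0 & px > 0
    total <- total + py[j] * sum(post[keep] * log(post[keep] / px[keep]))
  }
  total
}

#' Truncation-support normalization diagnostic
#'
#' The normalization object of the update identity is the ratio of two
#' windowed integrals: the Y-averaged posterior mass captured in a declared
#' X'-window over the likelihood Y-mass captured in declared (X, Y)-windows
#' (averaged over the X-window). Both equal 1 when the windows capture the
#' full mass, in which case the fluctuation-dissipation identity holds with
#' ratio 1; truncated supports make it deviate. This is a diagnostic for
#' truncation effects, not a quantity used by the update itself.
#'
#' @param window_xprime Numeric `c(lo, hi)` window for the posterior (X').
#' @param window_x,window_y Numeric windows for the likelihood integrals.
#' @param model A [sensing_model()].
#' @param prior A normalized [grid_density()].
#' @param y_grid A [grid1d()] covering the evidence.
#' @return The ratio of the two windowed integrals.
#' @export
beta_tilde <- function(window_xprime, window_x, window_y, model, prior,
                       y_grid) {
  if (window_xprime[1] >= window_xprime[2] || window_x[1] >= window_x[2] ||
      window_y[1] >= window_y[2])
    stop("beta_tilde: empty truncation window", call. = FALSE)
  x <- prior$grid$x
  # trapezoid weights for a contiguous sub-window of a uniform grid
  window_w <- function(idx, spacing) {
    w <- rep(spacing, length(idx))
    w[c(1L, length(idx))] <- spacing / 2
    w
  }
  in_xp <- which(x >= window_xprime[1] & x <= window_xprime[2])
  in_x <- which(x >= window_x[1] & x <= window_x[2])
  in_y <- which(y_grid$x >= window_y[1] & y_grid$x <= window_y[2])
  if (length(in_xp) < 2L || length(in_x) < 2L || length(in_y) < 2L)
    stop("beta_tilde: a window contains fewer than 2 grid nodes",
         call. = FALSE)
  wxp <- window_w(in_xp, prior$grid$spacing)
  wxx <- window_w(in_x, prior$grid$spacing)
  wyy <- window_w(in_y, y_grid$spacing)
  L <- likelihood_matrix(prior, model, y_grid)
  py <- evidence_density(prior, model, y_grid, L = L)
  pyv <- pmax(py$values, .LOG_CLIP)
  # numerator: Y-averaged posterior mass inside the X' window
  post_mass_y <- as.vector(L[, in_xp, drop = FALSE] %*%
                             (wxp * prior$values[in_xp])) / pyv
  num <- sum(wyy * py$values[in_y] * post_mass_y[in_y]) /
    sum(wyy * py$values[in_y])
  # denominator: likelihood Y-mass captured, averaged over the X window
  ymass_per_x <- as.vector(crossprod(L[in_y, , drop = FALSE], wyy))
  den <- sum(wxx * ymass_per_x[in_x]) / sum(wxx)
  num / den
}

#' Fisher-information quadratic form for a small mean shift
#'
#' For a small shift `delta` of a density, the KL divergence between the
#' shifted and original densities is approximately the quadratic form
#' \eqn{\tfrac12 \delta^2 F} with `F` the Fisher information. Returns both
#' the quadratic form and the exact KL divergence of the shifted density for
#' comparison (for a Gaussian the two agree exactly).
#'
#' @param density A normalized [grid_density()], strictly positive.
#' @param delta Shift size; mass moved off-grid must be below `1e-10`.
#' @return List with `quadratic` (`0.5 * delta^2 * F`), `exact_kl`
#'   (KL of the shifted density against the original) and `fisher`.
#' @export
fisher_quadratic_form <- function(density, delta) {
  fi <- fisher_information(density)
  if (delta == 0)
    return(list(quadratic = 0, exact_kl = 0, fisher = fi))
  g <- density$grid
  w <- trapz_weights(g)
  # mass that the shift would push past a boundary
  if (delta > 0) {
    off <- g$x > g$upper - delta
  } else {
    off <- g$x < g$lower - delta
  }
  if (sum(w[off] * density$values[off]) > 1e-10)
    stop("fisher_quadratic_form: shift pushes more than 1e-10 mass off-grid",
         call. = FALSE)
  k <- delta / g$spacing
  if (abs(k - round(k)) < 1e-9) {
    # whole-cell shift: exact relocation of the sampled values
    k <- as.integer(round(k))
    n <- g$n_points
    shifted <- rep(0, n)
    if (k >= 0) shifted[(1 + k):n] <- density$values[1:(n - k)]
    else shifted[1:(n + k)] <- density$values[(1 - k):n]
  } else {
    lp <- log(pmax(density$values, .LOG_CLIP))
    shifted <- exp(stats::spline(g$x, lp, xout = g$x - delta,
                                 method = "natural")$y)
    shifted[g$x - delta < g$lower | g$x - delta > g$upper] <- 0
  }
  keep <- shifted > 0 & density$values > 0
  exact <- sum(w[keep] * shifted[keep] *
                 (log(shifted[keep]) - log(density$values[keep])))
  list(quadratic = 0.5 * delta^2 * fi, exact_kl = exact, fisher = fi)
}

#' Pointwise mutual information of the sensing channel at an internal state
#'
#' The Y-average of the pointwise mutual information at fixed `x`:
#' \eqn{\int P(y|x) \ln[P(y|x)/P(y)]\,dy = D(P(Y|x)\,\Vert\,P(Y))}, where
#' the evidence `P(y)` is induced by the prior. Its prior-weighted average
#' over `x` equals [expected_update_divergence()].
#'
#' @param model A [sensing_model()].
#' @param prior A normalized [grid_density()] (defines the evidence).
#' @param x Internal state (scalar) at which to evaluate.
#' @param y_grid A [grid1d()] for the environment variable.
#' @return Pointwise mutual information in nats (nonnegative).
#' @export
pointwise_mi_given_x <- function(model, prior, x, y_grid) {
  py <- evidence_density(prior, model, y_grid)
  check_coverage(py)
  lik <- stats::dnorm(y_grid$x, mean = conditional_mean(model, x),
                      sd = conditional_sd(model, x))
  keep <- lik > 0
  sum(trapz_weights(y_grid)[keep] * lik[keep] *
        (log(lik[keep]) - log(pmax(py$values[keep], .LOG_CLIP))))
}

#' Aggregate pointwise mutual information over independent components
#'
#' Under mutual independence of the internal-state components, the pointwise
#' mutual information factorizes into a sum over components.
#'
#' @param components Numeric vector of per-component pointwise MI values.
#' @return Their sum.
#' @export
product_form_pmi <- function(components) {
  if (any(!is.finite(components)))
    stop("product_form_pmi: component values must be finite", call. = FALSE)
  sum(components)
}

#' Configuration of a Bayesian learning run
#'
#' @param prior Initial internal-state distribution ([grid_density()]).
#' @param sensing A [sensing_model()]; its domain must cover the prior grid.
#' @param n_steps Number of decision steps (>= 0).
#' @param y_grid Optional [grid1d()] for the environment; defaults to a grid
#'   covering the model-implied evidence to +-8 conditional sd.
#' @param environment_truth Optional [grid_density()] on `y_grid`: the true
#'   environment law observations are drawn from. Defaults to the
#'   model-implied evidence under the initial prior (perfect-sensing case);
#'   fixing it externally simulates model mismatch.
#' @param tau Decision time per step (bookkeeping only; default 1).
#' @param seed Root seed; per-step substreams are derived as
#'   `(seed mod 1e6) * 2017 + step`, so trajectories are reproducible and
#'   extendable.
#' @param update_mode `"observed"` draws one environment sample per step;
#'   `"averaged"` applies the deterministic update at the expected
#'   observation `E[Y]` under the current prior (the exact Y-average of the
#'   posterior density itself is the prior, so averaged-mode statistics are
#'   represented by the update at the mean observation, which reproduces the
#'   exact Y-averaged posterior mean and variance for conjugate chains).
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(prior, sensing, n_steps, y_grid = NULL,
                            environment_truth = NULL, tau = 1, seed = 1L,
                            update_mode = c("observed", "averaged")) {
  update_mode <- match.arg(update_mode)
  stopifnot(n_steps >= 0, tau > 0)
  gx <- prior$grid
  tol <- 1e-9 * max(1, abs(sensing$domain))
  if (gx$lower < sensing$domain[1] - tol || gx$upper > sensing$domain[2] + tol)
    stop("learning_config: prior grid extends beyond the sensing domain",
         call. = FALSE)
  if (is.null(y_grid)) {
    mu <- conditional_mean(sensing, gx$x)
    sd <- conditional_sd(sensing, gx$x)
    y_grid <- grid1d(min(mu - 8 * sd), max(mu + 8 * sd), 1201L)
  }
  if (is.null(environment_truth))
    environment_truth <- normalize(evidence_density(prior, sensing, y_grid))
  structure(list(prior = prior, sensing = sensing, n_steps = as.integer(n_steps),
                 y_grid = y_grid, environment_truth = environment_truth,
                 tau = tau, seed = as.integer(seed), update_mode = update_mode),
            class = "learning_config")
}

#' Iterate Bayesian learning over decision steps
#'
#' Runs `n_steps` of observe-then-update: an environment value is drawn (or
#' taken as the expected observation in `"averaged"` mode), the posterior is
#' computed with [bayes_update()], and becomes the next prior. Per-step
#' records include the observation, the posterior-prior KL divergence, the
#' mutual information available to the cell, the prior variance, the averaged
#' conditional variance / entropy of the environment, and the
#' internal-external covariance.
#'
#' @param config A [learning_config()].
#' @return An object of class `learning_trajectory`: a list with `records`
#'   (one row per step: `step, y_obs, kl, mi, sigma_x2, cond_entropy,
#'   cov_xy`), `final_prior` and the `config`.
#' @export
iterate_learning <- function(config) {
  stopifnot(inherits(config, "learning_config"))
  prior <- config$prior
  model <- config$sensing
  n <- config$n_steps
  rec <- data.frame(step = integer(0), y_obs = numeric(0), kl = numeric(0),
                    mi = numeric(0), sigma_x2 = numeric(0),
                    cond_entropy = numeric(0), cov_xy = numeric(0))
  wx <- trapz_weights(prior$grid)
  for (t in seq_len(n)) {
    sigma_x2 <- density_variance(prior)
    mi <- expected_update_divergence(prior, model, config$y_grid)
    mu_fx <- conditional_mean(model, prior$grid$x)
    # cov(X, Y) = cov(X, F(X)) under the joint prior x channel
    ex <- density_mean(prior)
    efx <- sum(wx * mu_fx * prior$values)
    cov_xy <- sum(wx * prior$grid$x * mu_fx * prior$values) - ex * efx
    s2_yx <- averaged_conditional_variance(model, sigma_x2)
    if (config$update_mode == "observed") {
      set.seed((config$seed %% 1000000L) * 2017L + t)
      y <- sample_from_density(config$environment_truth, 1L)
    } else {
      y <- density_mean(normalize(evidence_density(prior, model,
                                                   config$y_grid)))
    }
    posterior <- tryCatch(
      bayes_update(prior, model, y),
      error = function(e) stop(sprintf("iterate_learning: step %d: %s",
                                       t, conditionMessage(e)), call. = FALSE))
    kl <- kl_divergence(posterior, prior)
    rec[t, ] <- list(t, y, kl, mi, sigma_x2,
                     0.5 * log(2 * pi * exp(1) * s2_yx), cov_xy)
    prior <- posterior
  }
  structure(list(records = rec, final_prior = prior, config = config),
            class = "learning_trajectory")
}

#' @export
print.learning_trajectory <- function(x, ...) {
  cat(sprintf("learning_trajectory: %d steps (%s mode)\n",
              nrow(x$records), x$config$update_mode))
  if (nrow(x$records) > 0) print(utils::head(x$records))
  invisible(x)
}

#' Entropy-decay report for a learning trajectory
#'
#' Traces the averaged conditional variance
#' \eqn{\sigma^2_{Y|X,t} = b^2 + g^2\sigma^2_{x,t}} and the corresponding
#' Gaussian conditional entropy \eqn{S_t = \tfrac12\ln(2\pi e
#' \sigma^2_{Y|X,t})} along the trajectory, reports whether they are
#' nonincreasing, and the gap between the final variance and its learning
#' limit `b^2`.
#'
#' @param traj A [iterate_learning()] trajectory (nonempty).
#' @param model The [sensing_model()] supplying `b` and `g` (may differ from
#'   the one used to generate the trajectory).
#' @param tol Monotonicity tolerance (default `1e-9`).
#' @return List with `sigma2_yx`, `entropy`, `verdict`
#'   (`"nonincreasing"`, `"not monotone"` or `"insufficient data"`) and
#'   `limit_gap` (`|sigma2_end - b^2|`).
#' @export
entropy_decay_report <- function(traj, model, tol = 1e-9) {
  stopifnot(inherits(traj, "learning_trajectory"))
  sx2 <- c(traj$records$sigma_x2, density_variance(traj$final_prior))
  s2 <- averaged_conditional_variance(model, sx2)
  S <- 0.5 * log(2 * pi * exp(1) * s2)
  verdict <- if (nrow(traj$records) < 2L) "insufficient data"
  else if (all(diff(s2) <= tol)) "nonincreasing" else "not monotone"
  list(sigma2_yx = s2, entropy = S, verdict = verdict,
       limit_gap = abs(s2[length(s2)] - model$b^2))
}
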