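# Steady-state internal-state distributions under the Gibbs ansatz: the
# density is exp(-U(x))/Z with potential
#   U(x) = beta * int^x S(Y|X = s) ds + beta' * x,
# where S is the microenvironmental conditional entropy profile and beta is
# the sensitivity.  The primary computation is always cumulative trapezoidal
# quadrature of the exponent; closed forms serve as cross-check oracles,
# which also pins down the sign conventions where printed forms are
# ambiguous.

#' Sensitivity parameters of the Gibbs steady state
#'
#' @param beta Sensitivity: how strongly microenvironmental conditional
#'   entropy shapes the internal-state distribution. Its sign drives the
#'   monostable-bistable switch under linear sensing.
#' @param beta_prime Linear tilt (Lagrange multiplier of the mean internal
#'   state); default 0.
#' @param entropy_convention `"log_sd"` (default) drops the constant
#'   `0.5*log(2*pi*e)` from the Gaussian conditional entropy in the exponent
#'   (keeping it is equivalent to shifting `beta_prime` by
#'   `beta * 0.5*log(2*pi*e)`); `"full_gaussian"` keeps it.
#' @return An object of class `sensitivity_params`.
#' @export
sensitivity_params <- function(beta, beta_prime = 0,
                               entropy_convention = c("log_sd",
                                                      "full_gaussian")) {
  entropy_convention <- match.arg(entropy_convention)
  stopifnot(is.finite(beta), is.finite(beta_prime))
  structure(list(beta = beta, beta_prime = beta_prime,
                 entropy_convention = entropy_convention),
            class = "sensitivity_params")
}

new_stationary_solution <- function(density, potential, params,
                                    model = NULL, stationary_point = NULL) {
  cls <- classify_modality(density)
  structure(list(density = density, potential = potential, params = params,
                 model = model, modality = cls$modality,
                 mode_locations = cls$mode_locations,
                 stationary_point = stationary_point),
            class = "stationary_solution")
}

#' @export
print.stationary_solution <- function(x, ...) {
  cat(sprintf("stationary_solution: %s on [%g, %g]; modes at %s\n",
              x$modality, x$density$grid$lower, x$density$grid$upper,
              paste(signif(x$mode_locations, 6), collapse = ", ")))
  invisible(x)
}

# density ∝ exp(expo) on a grid, overflow-guarded by max-shift
density_from_exponent <- function(grid, expo) {
  if (any(!is.finite(expo)))
    stop("steady state: non-finite exponent on the grid", call. = FALSE)
  grid_density(grid, exp(expo - max(expo)), normalize = TRUE)
}

#' Gibbs steady state from a conditional-entropy profile
#'
#' The steady-state internal-state density
#' \eqn{P(x) \propto \exp(-\beta \int^x S(s)\,ds - \beta' x)} with the
#' cumulative integral taken from the lower domain edge by trapezoidal
#' quadrature. The potential `U(x)` (negative of the exponent) is returned
#' alongside.
#'
#' @param entropy_profile Vectorized function `x -> S(Y|X=x)` (nats).
#' @param params A [sensitivity_params()].
#' @param domain A [grid1d()].
#' @return A `stationary_solution` (density, potential, modality and mode
#'   locations).
#' @export
steady_state_generic <- function(entropy_profile, params, domain) {
  S <- entropy_profile(domain$x)
  if (any(!is.finite(S)))
    stop("steady_state_generic: entropy profile non-finite on the domain",
         call. = FALSE)
  cumS <- as.vector(pracma::cumtrapz(domain$x, S))
  expo <- -params$beta * cumS - params$beta_prime * domain$x
  new_stationary_solution(density_from_exponent(domain, expo),
                          potential = -expo, params = params)
}

#' Steady state under the linear cell-sensing model
#'
#' Specializes [steady_state_generic()] to the Gaussian linear-sensing
#' channel, where the conditional entropy profile is
#' `log(b + g (x - x_bar))` (plus a constant under the full-Gaussian
#' convention). The grid is truncated to the model's admissible domain if
#' needed. The analytic interior stationary point of the exponent,
#' `x* = x_bar + (exp(-beta_prime/beta - c) - b)/g` with `c` the
#' convention constant, is recorded when `beta != 0` and `g > 0`; it is an
#' interior maximum (unimodal regime) for `beta > 0` and a minimum
#' (boundary-bimodal regime) for `beta < 0`.
#'
#' @param model A [sensing_model()] (linear-sd mode).
#' @param params A [sensitivity_params()].
#' @param domain A [grid1d()]; truncated to the model's admissible interval.
#' @return A `stationary_solution` with `stationary_point` set when an
#'   interior stationary point exists.
#' @export
steady_state_linear_sensing <- function(model, params, domain) {
  if (model$variance_mode != "linear_sd")
    stop("steady_state_linear_sensing: requires the linear-sd sensing mode",
         call. = FALSE)
  domain <- truncate_grid(domain, model$domain)
  profile <- sensing_entropy_profile(model, params$entropy_convention)
  S <- profile(domain$x)
  cumS <- as.vector(pracma::cumtrapz(domain$x, S))
  expo <- -params$beta * cumS - params$beta_prime * domain$x
  sp <- NULL
  if (params$beta != 0 && model$g > 0) {
    cshift <- if (params$entropy_convention == "full_gaussian")
      HALF_LOG_2PIE else 0
    root <- model$x_bar +
      (exp(-params$beta_prime / params$beta - cshift) - model$b) / model$g
    if (root > domain$lower && root < domain$upper) sp <- root
  }
  new_stationary_solution(density_from_exponent(domain, expo),
                          potential = -expo, params = params, model = model,
                          stationary_point = sp)
}

# intersect a requested grid with an admissible interval, keeping uniformity
truncate_grid <- function(grid, interval) {
  if (grid$lower >= interval[1] - 1e-12 && grid$upper <= interval[2] + 1e-12)
    return(grid)
  keep <- which(grid$x >= interval[1] - 1e-12 & grid$x <= interval[2] + 1e-12)
  if (length(keep) < 8L)
    stop(sprintf(
      "domain incompatible with the admissible interval [%g, %g]",
      interval[1], interval[2]), call. = FALSE)
  warning(sprintf("grid truncated to [%g, %g] (admissible interval)",
                  grid$x[keep[1]], grid$x[keep[length(keep)]]), call. = FALSE)
  grid1d(grid$x[keep[1]], grid$x[keep[length(keep)]], length(keep))
}

#' Closed-form steady states of the linear-sensing model
#'
#' Cross-check oracles for [steady_state_linear_sensing()] under the
#' `log_sd` convention. In the sensor-OFF regime (`g = 0`) the
#' conditional entropy is constant and the steady state is a truncated
#' exponential with rate `beta_bar = beta * log(b) + beta_prime` (valid as a
#' half-line density only for `beta_bar > 0`). In the sensor-ON regime
#' (`g > 0`) the exponent integrates in closed form and
#' \eqn{P(x) \propto (b + g(x-\bar X))^{-\beta(x - \bar X + b/g)}
#' e^{(\beta-\beta')x}}; the sign assignment is fixed by requiring pointwise
#' agreement with the quadrature path.
#'
#' @param model A [sensing_model()].
#' @param params A [sensitivity_params()] (must use `log_sd`).
#' @param regime `"off"` (requires `g = 0`) or `"on"` (requires `g > 0`).
#' @param domain A [grid1d()]; truncated to the admissible interval.
#' @return List with `density` (normalized by quadrature on the domain),
#'   `log_density_unnorm` (the closed-form log density as a function), and
#'   for the OFF regime `rate` and `halfline_mean` (`1/rate`, the mean of
#'   the untruncated half-line exponential).
#' @export
closed_form_case <- function(model, params, regime = c("off", "on"), domain) {
  regime <- match.arg(regime)
  if (params$entropy_convention != "log_sd")
    stop("closed_form_case: closed forms are stated in the log_sd convention",
         call. = FALSE)
  domain <- truncate_grid(domain, model$domain)
  if (regime == "off") {
    if (model$g != 0)
      stop("closed_form_case: regime 'off' requires g = 0", call. = FALSE)
    rate <- params$beta * log(model$b) + params$beta_prime
    logf <- function(x) -rate * x
    dens <- density_from_exponent(domain, logf(domain$x))
    return(list(density = dens, log_density_unnorm = logf, rate = rate,
                halfline_mean = if (rate > 0) 1 / rate else NA_real_))
  }
  if (model$g <= 0)
    stop("closed_form_case: regime 'on' requires g > 0", call. = FALSE)
  b <- model$b; g <- model$g; xb <- model$x_bar
  beta <- params$beta; bp <- params$beta_prime
  logf <- function(x)
    -beta * (x - xb + b / g) * log(b + g * (x - xb)) + (beta - bp) * x
  dens <- density_from_exponent(domain, logf(domain$x))
  list(density = dens, log_density_unnorm = logf)
}

#' Classify the modality of a stationary density
#'
#' Counts strict discrete local maxima of the density (plateaus merged at a
#' relative tolerance); a boundary counts as a mode only when the density at
#' the boundary exceeds the adjacent interior value. Returns one of
#' `"flat"`, `"monotone"` (a single boundary mode), `"interior-unimodal"`,
#' or `"boundary-bimodal"` (both boundaries are modes and the interior
#' stationary point is a minimum).
#'
#' @param x A `stationary_solution` or [grid_density()] with at least 64
#'   points.
#' @param tol Relative plateau tolerance (default `1e-12`).
#' @return List with `modality` and `mode_locations`.
#' @export
classify_modality <- function(x, tol = 1e-12) {
  density <- if (inherits(x, "stationary_solution")) x$density else x
  if (!inherits(density, "grid_density"))
    stop("classify_modality: expected a stationary_solution or grid_density",
         call. = FALSE)
  v <- density$values
  n <- length(v)
  vmax <- max(v)
  if (vmax - min(v) < 1e-10 * max(vmax, 1))
    return(list(modality = "flat", mode_locations = numeric(0)))
  d <- diff(v)
  s <- sign(d)
  s[abs(d) <= tol * vmax] <- 0
  nz <- which(s != 0)
  runs <- s[nz]
  interior <- numeric(0)
  if (length(runs) >= 2) {
    flips <- which(runs[-length(runs)] > 0 & runs[-1] < 0)
    for (f in flips) {
      # maximum sits between the end of the rise and the start of the fall
      i_lo <- nz[f] + 1L
      i_hi <- nz[f + 1L]
      interior <- c(interior,
                    mean(density$grid$x[c(i_lo, i_hi)]))
    }
  }
  left <- length(runs) >= 1 && runs[1] < 0 && v[1] > v[2]
  right <- length(runs) >= 1 && runs[length(runs)] > 0 && v[n] > v[n - 1]
  modes <- c(if (left) density$grid$x[1], interior,
             if (right) density$grid$x[n])
  n_int <- length(interior)
  n_bnd <- sum(left, right)
  modality <-
    if (n_int >= 1 && n_bnd == 0) "interior-unimodal"
    else if (n_int == 0 && n_bnd == 2) "boundary-bimodal"
    else if (n_int == 0 && n_bnd == 1) "monotone"
    else if (n_int >= 1) "interior-unimodal"
    else "flat"
  list(modality = modality, mode_locations = modes)
}

#' LEUP variational distribution
#'
#' The least-microenvironmental-uncertainty distribution: entropy
#' maximization over internal states constrained by the cell-environment
#' mutual information and the mean internal state yields the Gibbs-like form
#' \eqn{P(x) \propto \exp(-\beta S(Y|X=x) - \beta' x)} — the entropy profile
#' itself in the exponent, not its cumulative integral.
#'
#' @param entropy_profile Vectorized function `x -> S(Y|X=x)` (nats).
#' @param params A [sensitivity_params()].
#' @param domain A [grid1d()].
#' @return A `stationary_solution`.
#' @export
leup_distribution <- function(entropy_profile, params, domain) {
  S <- entropy_profile(domain$x)
  if (any(!is.finite(S)))
    stop("leup_distribution: entropy profile non-finite on the domain",
         call. = FALSE)
  expo <- -params$beta * S - params$beta_prime * domain$x
  new_stationary_solution(density_from_exponent(domain, expo),
                          potential = -expo, params = params)
}

#' Compare the LEUP distribution with the Bayesian steady state
#'
#' The LEUP form and the Bayesian-learning steady state coincide locally: on
#' a finite domain, the mean value theorem replaces the cumulative entropy
#' integral by the entropy at an interior point `x_hat`, giving the
#' localized Bayesian form \eqn{\propto \exp(-\beta S(\hat x) - \beta' x)}.
#' This function reports distances between (i) the LEUP density and that
#' localized form (`leup_vs_localized`: exactly zero for constant entropy
#' profiles, and vanishing in shape as the domain shrinks around `x_hat`),
#' and (ii) the LEUP density and the full cumulative-integral steady state
#' (`leup_vs_cumulative`: genuinely different for nonconstant profiles;
#' reported, not asserted equal).
#'
#' @param entropy_profile Vectorized function `x -> S(Y|X=x)`.
#' @param params A [sensitivity_params()].
#' @param domain A [grid1d()].
#' @param x_hat Localization point (default: domain midpoint).
#' @return List with `leup_vs_localized` and `leup_vs_cumulative` (each a
#'   [density_distance()] list), plus `x_hat` and the domain `width`.
#' @export
compare_leup_bayes <- function(entropy_profile, params, domain,
                               x_hat = NULL) {
  if (is.null(x_hat)) x_hat <- (domain$lower + domain$upper) / 2
  leup <- leup_distribution(entropy_profile, params, domain)
  bayes <- steady_state_generic(entropy_profile, params, domain)
  s_hat <- entropy_profile(x_hat)
  localized <- density_from_exponent(
    domain, -params$beta * s_hat - params$beta_prime * domain$x)
  list(leup_vs_localized = density_distance(leup$density, localized),
       leup_vs_cumulative = density_distance(leup$density, bayes$density),
       x_hat = x_hat, width = domain$upper - domain$lower)
}

#' Modality phase sweep over sensitivity and sensing response
#'
#' Computes the steady-state modality over a grid of `(beta, g)` values for
#' fixed `b`, `x_bar`, `beta_prime` — the monostable-bistable phase surface
#' of the linear-sensing model.
#'
#' @param beta_values,g_values Numeric vectors to sweep.
#' @param b,x_bar,beta_prime Fixed sensing/sensitivity parameters.
#' @param domain A [grid1d()] for the internal state.
#' @return A long-format `data.frame` with columns
#'   `beta, g, modality, mode_count`.
#' @export
modality_sweep <- function(beta_values, g_values, b = 2, x_bar = 2,
                           beta_prime = 0, domain = grid1d(0.05, 6, 513)) {
  out <- expand.grid(beta = beta_values, g = g_values,
                     KEEP.OUT.ATTRS = FALSE)
  out$modality <- character(nrow(out))
  out$mode_count <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    model <- suppressWarnings(
      sensing_model(b = b, g = out$g[i], x_bar = x_bar,
                    domain = c(domain$lower, domain$upper)))
    sol <- suppressWarnings(steady_state_linear_sensing(
      model, sensitivity_params(out$beta[i], beta_prime), domain))
    out$modality[i] <- sol$modality
    out$mode_count[i] <- length(sol$mode_locations)
  }
  out
}
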