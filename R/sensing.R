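# The cell-sensing channel P(Y | X): a Gaussian conditional law whose mean is
# a sensing function F(x) of the internal state and whose standard deviation
# is linear in x, sigma_{Y|X}(x) = b + g (x - x_bar).  b (bias) and g (linear
# response) depend only on environment moments, never on x.

HALF_LOG_2PIE <- 0.5 * log(2 * pi * exp(1))

#' Linearize a sensing function around the mean internal state
#'
#' First-order expansion of the sensed mean around `x_bar`: the bias is
#' `b = F(x_bar) - y_bar` and the linear response is the absolute central
#' difference derivative `g = |dF/dx|` at `x_bar`.
#'
#' @param F Sensing function `x -> sensed mean`.
#' @param x_bar Mean internal state around which to expand.
#' @param y_bar Mean environment value.
#' @param h Central-difference step (default `1e-5`).
#' @return List with components `b` and `g` (`g >= 0`).
#' @export
#' @examples
#' linearize_sensing(identity, x_bar = 2, y_bar = 0)  # b = 2, g = 1
linearize_sensing <- function(F, x_bar, y_bar, h = 1e-5) {
  vals <- vapply(c(x_bar - h, x_bar, x_bar + h), F, numeric(1))
  if (any(!is.finite(vals)))
    stop("linearize_sensing: F is non-finite near x_bar", call. = FALSE)
  list(b = vals[2] - y_bar, g = abs((vals[3] - vals[1]) / (2 * h)))
}

#' Gaussian cell-sensing model
#'
#' The conditional law of the microenvironment given the internal state:
#' `Y | X = x ~ Normal(F(x), sigma(x)^2)` with conditional standard deviation
#' linear in the internal state, `sigma(x) = b + g (x - x_bar)`. If `b` and
#' `g` are not supplied they are obtained by [linearize_sensing()]; if `F` is
#' not supplied, the linearized mean `y_bar + b + g (x - x_bar)` is used.
#'
#' The admissible internal-state domain is truncated (with a warning) to the
#' region where the conditional standard deviation stays above `sigma_min`.
#'
#' @param F Optional sensing function `x -> sensed mean`.
#' @param b Bias (> 0); conditional sd at `x = x_bar`.
#' @param g Linear sensing response (>= 0).
#' @param x_bar Mean internal state.
#' @param y_bar Mean environment value (default 0).
#' @param domain Numeric `c(lo, hi)` of admissible internal states.
#' @param variance_mode `"linear_sd"` (default): sd linear in `x`,
#'   `sigma(x) = b + g(x - x_bar)` — the reading consistent with both the
#'   entropy-integral steady state and the averaged variance law
#'   `b^2 + g^2 sigma_x^2`. `"literal_variance"` instead takes the variance
#'   itself as `b + g (x - x_bar)^2`, an exploratory alternative reading.
#' @param sigma_min Smallest admissible conditional sd (default `1e-6`).
#' @return An object of class `sensing_model`.
#' @export
#' @examples
#' m <- sensing_model(b = 2, g = 1, x_bar = 2, domain = c(0.1, 6))
#' conditional_sd(m, 2)  # 2
sensing_model <- function(F = NULL, b = NULL, g = NULL, x_bar, y_bar = 0,
                          domain = NULL,
                          variance_mode = c("linear_sd", "literal_variance"),
                          sigma_min = 1e-6) {
  variance_mode <- match.arg(variance_mode)
  if (is.null(b) || is.null(g)) {
    if (is.null(F))
      stop("sensing_model: supply either (b, g) or a sensing function F",
           call. = FALSE)
    lin <- linearize_sensing(F, x_bar, y_bar)
    if (is.null(b)) b <- lin$b
    if (is.null(g)) g <- lin$g
  }
  if (!is.finite(b) || b <= 0)
    stop("sensing_model: b must be > 0 (a valid conditional sd at x_bar)",
         call. = FALSE)
  if (!is.finite(g) || g < 0)
    stop("sensing_model: g must be >= 0", call. = FALSE)
  if (is.null(F)) {
    force(b); force(g); force(x_bar); force(y_bar)
    F <- function(x) y_bar + b + g * (x - x_bar)
  }
  if (is.null(domain)) domain <- c(x_bar - 5, x_bar + 5)
  if (variance_mode == "linear_sd" && g > 0) {
    # positivity boundary of the linear sd
    x_min <- x_bar + (sigma_min - b) / g
    if (domain[1] < x_min) {
      warning(sprintf(
        "sensing_model: domain truncated to [%g, %g] to keep sigma >= %g",
        x_min, domain[2], sigma_min), call. = FALSE)
      domain[1] <- x_min
    }
    if (domain[2] <= domain[1])
      stop("sensing_model: domain incompatible with sd positivity",
           call. = FALSE)
  }
  structure(list(F = F, b = b, g = g, x_bar = x_bar, y_bar = y_bar,
                 domain = domain, variance_mode = variance_mode,
                 noise_family = "gaussian", sigma_min = sigma_min),
            class = "sensing_model")
}

#' @export
print.sensing_model <- function(x, ...) {
  cat(sprintf(
    "sensing_model: b = %g, g = %g, x_bar = %g, y_bar = %g, domain [%g, %g], %s\n",
    x$b, x$g, x$x_bar, x$y_bar, x$domain[1], x$domain[2], x$variance_mode))
  invisible(x)
}

assert_in_domain <- function(model, x) {
  tol <- 1e-9 * max(1, abs(model$domain))
  if (any(x < model$domain[1] - tol | x > model$domain[2] + tol))
    stop(sprintf(
      "x outside the admissible interval [%g, %g] of the sensing model",
      model$domain[1], model$domain[2]), call. = FALSE)
  invisible(x)
}

#' Conditional standard deviation of the sensed environment
#'
#' `sigma(x) = b + g (x - x_bar)` in the default linear-sd mode (or
#' `sqrt(b + g (x - x_bar)^2)` in the literal-variance mode). Vectorized in
#' `x`; errors when `x` leaves the admissible domain.
#'
#' @param model A [sensing_model()].
#' @param x Internal state value(s).
#' @return Conditional sd(s), strictly positive.
#' @export
conditional_sd <- function(model, x) {
  assert_in_domain(model, x)
  if (model$variance_mode == "linear_sd") {
    s <- model$b + model$g * (x - model$x_bar)
  } else {
    s <- sqrt(model$b + model$g * (x - model$x_bar)^2)
  }
  pmax(s, model$sigma_min)
}

#' Conditional mean of the sensed environment
#'
#' @param model A [sensing_model()].
#' @param x Internal state value(s).
#' @return `F(x)`, vectorized.
#' @export
conditional_mean <- function(model, x) {
  assert_in_domain(model, x)
  vapply(x, model$F, numeric(1))
}

#' Microenvironmental conditional entropy at an internal state (nats)
#'
#' For the Gaussian channel,
#' \eqn{S(Y|X=x) = \tfrac12\ln(2\pi e\,\sigma(x)^2)}.
#'
#' @param model A [sensing_model()].
#' @param x Internal state value(s).
#' @return Conditional entropy in nats, vectorized.
#' @export
conditional_entropy_at <- function(model, x) {
  log(conditional_sd(model, x)) + HALF_LOG_2PIE
}

#' Entropy profile of a sensing model as a function of x
#'
#' Returns `S(Y|X=x)` as a function, in one of two conventions:
#' `"log_sd"` keeps only the x-dependent part `log(sigma(x))` (the
#' constant `0.5*log(2*pi*e)` is dropped, as in the steady-state exponent the
#' package reproduces), while `"full_gaussian"` is the full Gaussian entropy.
#' The two differ by a constant, which in the cumulative-integral steady
#' state acts as a shift of the linear-tilt parameter.
#'
#' @param model A [sensing_model()].
#' @param convention `"log_sd"` (default) or `"full_gaussian"`.
#' @return A vectorized function `x -> S(Y|X=x)` in nats.
#' @export
sensing_entropy_profile <- function(model,
                                    convention = c("log_sd",
                                                   "full_gaussian")) {
  convention <- match.arg(convention)
  shift <- if (convention == "full_gaussian") HALF_LOG_2PIE else 0
  function(x) log(conditional_sd(model, x)) + shift
}

#' Sample the microenvironment at a fixed internal state
#'
#' Draws from `Normal(F(x), sigma(x)^2)`.
#'
#' @param model A [sensing_model()].
#' @param x Internal state (scalar).
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed for reproducible draws.
#' @return Numeric vector of `n` environment samples.
#' @export
sample_environment <- function(model, x, n, seed = NULL) {
  stopifnot(length(x) == 1L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, mean = conditional_mean(model, x),
               sd = conditional_sd(model, x))
}

#' Averaged conditional variance of the sensed environment
#'
#' The population average of `sigma(x)^2` when the internal state is
#' distributed with variance `sigma_x2` around `x_bar`:
#' \eqn{E[\sigma_{Y|X}^2] = b^2 + g^2 \sigma_x^2}. As learning contracts the
#' internal-state distribution (`sigma_x2 -> 0`), this tends to `b^2`.
#'
#' @param model A [sensing_model()].
#' @param sigma_x2 Variance of the internal state (>= 0).
#' @return The averaged conditional variance `b^2 + g^2 * sigma_x2`.
#' @export
averaged_conditional_variance <- function(model, sigma_x2) {
  if (any(!is.finite(sigma_x2)) || any(sigma_x2 < 0))
    stop("averaged_conditional_variance: sigma_x2 must be >= 0", call. = FALSE)
  model$b^2 + model$g^2 * sigma_x2
}
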