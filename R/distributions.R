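# Grid densities and information functionals.
#
# All probability densities live on uniform 1-D grids and all integrals are
# trapezoidal.  All logarithms are natural: entropies, divergences and
# informations are reported in nats, matching the exponential (Gibbs) forms
# used throughout the package.

# density values are clipped here before taking logs; 0*log(0) := 0
.LOG_CLIP <- 1e-300

#' One-dimensional uniform grid
#'
#' A uniform discretization of a finite interval, the common support for all
#' densities in the package (internal-state distributions, environment
#' distributions, posteriors, stationary solutions).
#'
#' @param lower,upper Finite endpoints with `lower < upper`.
#' @param n_points Number of nodes, at least 8. Default 2001 gives quadrature
#'   errors far below the tolerances used elsewhere for the default windows.
#'
#' @return An object of class `grid1d`: a list with `lower`, `upper`,
#'   `n_points`, `spacing` and the node vector `x`.
#' @export
#' @examples
#' g <- grid1d(0, 1, 101)
#' g$spacing  # 0.01
grid1d <- function(lower, upper, n_points = 2001L) {
  stopifnot(length(lower) == 1L, length(upper) == 1L, is.numeric(lower),
            is.numeric(upper))
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("grid1d: need finite lower < upper", call. = FALSE)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 8L)
    stop("grid1d: n_points must be an integer >= 8", call. = FALSE)
  structure(
    list(lower = lower, upper = upper, n_points = n_points,
         spacing = (upper - lower) / (n_points - 1L),
         x = seq(lower, upper, length.out = n_points)),
    class = "grid1d")
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("grid1d: [%g, %g], %d points, spacing %g\n",
              x$lower, x$upper, x$n_points, x$spacing))
  invisible(x)
}

# trapezoid quadrature weights for a uniform grid
trapz_weights <- function(grid) {
  w <- rep(grid$spacing, grid$n_points)
  w[c(1L, grid$n_points)] <- grid$spacing / 2
  w
}

is_grid1d <- function(x) inherits(x, "grid1d")

same_grid <- function(a, b) {
  a$n_points == b$n_points &&
    isTRUE(all.equal(a$lower, b$lower, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$upper, b$upper, tolerance = 1e-12))
}

#' Probability density on a uniform grid
#'
#' @param grid A [grid1d()] object.
#' @param values Nonnegative density values (per unit of the variable), one
#'   per grid node.
#' @param normalize If `TRUE` (default) the values are rescaled so the
#'   trapezoidal integral equals 1.
#'
#' @return An object of class `grid_density` with fields `grid` and `values`.
#' @export
#' @examples
#' g <- grid1d(-8, 8, 2001)
#' p <- grid_density(g, dnorm(g$x))
#' density_mass(p)  # 1
grid_density <- function(grid, values, normalize = TRUE) {
  if (!is_grid1d(grid)) stop("grid_density: grid must be a grid1d", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != grid$n_points)
    stop("grid_density: values length must equal grid$n_points", call. = FALSE)
  if (any(!is.finite(values)))
    stop("grid_density: non-finite density values", call. = FALSE)
  if (any(values < 0))
    stop("grid_density: negative density values", call. = FALSE)
  d <- structure(list(grid = grid, values = values), class = "grid_density")
  if (normalize) normalize(d) else d
}

#' @export
print.grid_density <- function(x, ...) {
  cat(sprintf("grid_density on [%g, %g] (%d points), mass %.6f\n",
              x$grid$lower, x$grid$upper, x$grid$n_points, density_mass(x)))
  invisible(x)
}

#' Trapezoidal mass of a grid density
#'
#' @param density A [grid_density()] object.
#' @return The trapezoidal integral of the density over its grid.
#' @export
density_mass <- function(density) {
  sum(trapz_weights(density$grid) * density$values)
}

#' Normalize a grid density to unit mass
#'
#' Rescales the values so the trapezoidal integral over the grid equals 1;
#' the shape is preserved up to a positive constant.
#'
#' @param density A [grid_density()] object (possibly unnormalized).
#' @return The normalized `grid_density`.
#' @export
normalize <- function(density) {
  if (!inherits(density, "grid_density"))
    stop("normalize: expected a grid_density", call. = FALSE)
  m <- density_mass(density)
  if (!is.finite(m) || m <= 0)
    stop("normalize: invalid density (all-zero or non-finite mass)",
         call. = FALSE)
  density$values <- density$values / m
  density
}

assert_normalized <- function(density, tol = 1e-6, what = "density") {
  m <- density_mass(density)
  if (abs(m - 1) > tol)
    stop(sprintf("%s is not normalized (mass = %.8g); call normalize() first",
                 what, m), call. = FALSE)
  invisible(density)
}

#' Differential entropy of a grid density (nats)
#'
#' Computes \eqn{-\int p \ln p \, dx} by the trapezoid rule with the
#' convention \eqn{0 \ln 0 = 0}.
#'
#' @param density A normalized [grid_density()].
#' @return Differential entropy in nats.
#' @export
#' @examples
#' g <- grid1d(0, 1, 101)
#' entropy(grid_density(g, rep(1, 101)))  # 0
entropy <- function(density) {
  if (!inherits(density, "grid_density"))
    stop("entropy: expected a grid_density", call. = FALSE)
  assert_normalized(density)
  p <- density$values
  term <- ifelse(p > 0, p * log(pmax(p, .LOG_CLIP)), 0)
  -sum(trapz_weights(density$grid) * term)
}

#' Kullback-Leibler divergence between two grid densities (nats)
#'
#' \eqn{D(p\Vert q) = \int p \ln(p/q)\,dx} on a shared grid. Requires
#' `q > 0` wherever `p > 0`.
#'
#' @param p,q Normalized [grid_density()] objects on the same grid.
#' @return KL divergence in nats (nonnegative up to quadrature roundoff).
#' @export
kl_divergence <- function(p, q) {
  if (!inherits(p, "grid_density") || !inherits(q, "grid_density"))
    stop("kl_divergence: expected grid_density arguments", call. = FALSE)
  if (!same_grid(p$grid, q$grid))
    stop("kl_divergence: p and q must share the same grid", call. = FALSE)
  pv <- p$values; qv <- q$values
  if (any(pv > 1e-12 & qv <= 0))
    stop("kl_divergence: support violation (p > 0 where q = 0)", call. = FALSE)
  term <- ifelse(pv > 0,
                 pv * (log(pmax(pv, .LOG_CLIP)) - log(pmax(qv, .LOG_CLIP))),
                 0)
  sum(trapz_weights(p$grid) * term)
}

#' Discrete joint probability table
#'
#' A finite joint distribution over labelled internal states (rows) and
#' environment states (columns); marginals are row and column sums.
#'
#' @param probs Matrix of nonnegative probabilities summing to 1 (within
#'   1e-12).
#' @param x_states,y_states Optional row/column labels.
#' @return An object of class `joint_table`.
#' @export
#' @examples
#' j <- joint_table(matrix(c(0.4, 0.1, 0.1, 0.4), 2))
#' mutual_information(j)
joint_table <- function(probs, x_states = NULL, y_states = NULL) {
  probs <- as.matrix(probs)
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("joint_table: probabilities must be finite and nonnegative",
         call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-12)
    stop(sprintf("joint_table: entries must sum to 1 (got %.15g)", sum(probs)),
         call. = FALSE)
  if (is.null(x_states)) x_states <- paste0("x", seq_len(nrow(probs)))
  if (is.null(y_states)) y_states <- paste0("y", seq_len(ncol(probs)))
  dimnames(probs) <- list(x_states, y_states)
  structure(list(probs = probs, x_states = x_states, y_states = y_states),
            class = "joint_table")
}

#' Mutual information of a discrete joint table (nats)
#'
#' \eqn{I(X;Y) = \sum_{x,y} p(x,y)\ln\frac{p(x,y)}{p(x)p(y)}}; zero cells
#' contribute zero.
#'
#' @param joint A [joint_table()].
#' @return Mutual information in nats (nonnegative).
#' @export
mutual_information <- function(joint) {
  if (!inherits(joint, "joint_table"))
    stop("mutual_information: expected a joint_table", call. = FALSE)
  p <- unname(joint$probs)
  px <- rowSums(p)
  py <- colSums(p)
  ref <- outer(px, py)
  keep <- p > 0
  sum(p[keep] * (log(p[keep]) - log(ref[keep])))
}

#' Fisher information of a grid density
#'
#' Returns \eqn{F = E_p[-\partial^2_x \ln p]} estimated by central second
#' differences of \eqn{\ln p} averaged under \eqn{p}. The sign convention is
#' the standard one under which a Gaussian with standard deviation
#' \eqn{\sigma} yields \eqn{+1/\sigma^2} (the curvature form is treated as a
#' nonnegative information "energy").
#'
#' @param density A normalized [grid_density()], strictly positive on the
#'   evaluation window.
#' @param window Optional index range `c(i1, i2)` of nodes delimiting the
#'   evaluation window; defaults to the full grid. The window must contain
#'   at least 3 interior points.
#' @return Fisher information (units of `x^-2`).
#' @export
fisher_information <- function(density, window = NULL) {
  if (!inherits(density, "grid_density"))
    stop("fisher_information: expected a grid_density", call. = FALSE)
  n <- density$grid$n_points
  if (is.null(window)) window <- c(1L, n)
  i1 <- max(1L, as.integer(window[1])); i2 <- min(n, as.integer(window[2]))
  if (i2 - i1 < 4L)
    stop("fisher_information: window must contain at least 3 interior points",
         call. = FALSE)
  v <- density$values[i1:i2]
  if (any(v <= 0))
    stop("fisher_information: density has zeros in the evaluation window",
         call. = FALSE)
  h <- density$grid$spacing
  lp <- log(v)
  m <- length(v)
  d2 <- (lp[3:m] - 2 * lp[2:(m - 1)] + lp[1:(m - 2)]) / h^2
  # expectation under p over the interior nodes of the window
  w <- rep(h, m - 2L); w[c(1L, m - 2L)] <- h / 2
  -sum(w * v[2:(m - 1)] * d2)
}

#' Write a grid density to CSV
#'
#' Columns `x,density` with a header row and '.' decimal separator.
#'
#' @param density A [grid_density()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_density_csv <- function(density, path) {
  df <- data.frame(x = density$grid$x, density = density$values)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Distances between two densities on a shared grid
#'
#' @param p,q [grid_density()] objects on the same grid.
#' @return List with `l1` (trapezoidal \eqn{\int|p-q|dx}), `linf`
#'   (max absolute difference) and `linf_rel` (`linf` divided by the larger
#'   density maximum).
#' @export
density_distance <- function(p, q) {
  if (!same_grid(p$grid, q$grid))
    stop("density_distance: densities must share a grid", call. = FALSE)
  diff <- p$values - q$values
  scale <- pmax(pmax(p$values, q$values), .LOG_CLIP)
  list(l1 = sum(trapz_weights(p$grid) * abs(diff)),
       linf = max(abs(diff)),
       linf_rel = max(abs(diff) / max(scale)))
}

#' Draw samples from a grid density by inverse-CDF interpolation
#'
#' @param density A normalized [grid_density()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Uses the current RNG stream.
#' @export
sample_from_density <- function(density, n) {
  cdf <- as.vector(pracma::cumtrapz(density$grid$x, density$values))
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  # cdf may have flat stretches where the density vanishes; keep first hits
  ok <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[ok], density$grid$x[ok], xout = u, rule = 2)$y
}

#' Mean of a grid density by quadrature
#' @param density A normalized [grid_density()].
#' @return The trapezoidal mean \eqn{\int x p(x) dx}.
#' @export
density_mean <- function(density) {
  sum(trapz_weights(density$grid) * density$grid$x * density$values)
}

#' Variance of a grid density by quadrature
#' @param density A normalized [grid_density()].
#' @return The trapezoidal variance \eqn{\int (x-\bar x)^2 p(x) dx}.
#' @export
density_variance <- function(density) {
  m <- density_mean(density)
  sum(trapz_weights(density$grid) * (density$grid$x - m)^2 * density$values)
}
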