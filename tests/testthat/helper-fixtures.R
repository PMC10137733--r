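# Shared fixtures, built in code at test time.

HALF_LOG_2PIE <- 0.5 * log(2 * pi * exp(1))

gaussian_grid_density <- function(mean = 0, sd = 1, lower = mean - 8 * sd,
                                  upper = mean + 8 * sd, n = 2001L) {
  g <- grid1d(lower, upper, n)
  grid_density(g, dnorm(g$x, mean, sd))
}

random_joint <- function(nx = 2L, ny = 2L) {
  m <- matrix(rexp(nx * ny), nx)
  joint_table(m / sum(m))
}

# conjugate-Gaussian sensing channel: Y | X = x ~ Normal(x, 1)
unit_noise_model <- function(domain = c(-8, 8)) {
  sensing_model(F = function(x) x, b = 1, g = 0, x_bar = 0, domain = domain)
}

# the reference linear-sensing models: b = 2, x_bar = 2, beta' = 0
off_model <- function(domain = c(0, 21.64)) {
  sensing_model(b = 2, g = 0, x_bar = 2, domain = domain)
}

on_model <- function(domain = c(0.05, 6)) {
  sensing_model(b = 2, g = 1, x_bar = 2, domain = domain)
}
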