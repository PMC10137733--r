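test_that("the generic Gibbs steady state integrates the entropy profile into the exponent", {
  dom <- grid1d(0, 1, 1001)
  # no forces: uniform
  flat <- steady_state_generic(function(x) rep(0.5, length(x)),
                               sensitivity_params(0), dom)
  expect_lt(max(abs(flat$density$values - 1)), 1e-10)
  expect_identical(flat$modality, "flat")

  # S(x) = x: half-Gaussian shape exp(-x^2/2)/Z
  sol <- steady_state_generic(function(x) x, sensitivity_params(1), dom)
  ref <- grid_density(dom, exp(-dom$x^2 / 2))
  expect_lt(density_distance(sol$density, ref)$linf, 1e-6)
  expect_equal(sol$potential, dom$x^2 / 2, tolerance = 1e-6)

  # constant profile: exponential with rate beta*s0 + beta'
  # (a constant entropy is exactly the sensor-off case, whose steady state
  # is exponential, not uniform)
  s0 <- 0.7
  solc <- steady_state_generic(function(x) rep(s0, length(x)),
                               sensitivity_params(2, beta_prime = 0.1), dom)
  rate <- 2 * s0 + 0.1
  refc <- grid_density(dom, exp(-rate * dom$x))
  expect_lt(density_distance(solc$density, refc)$linf, 1e-8)

  expect_error(steady_state_generic(function(x) 1 / (x - 0.5),
                                    sensitivity_params(1), dom),
               "non-finite")
})

test_that("the sensor-off steady state is exponential with rate beta*log(b) + beta'", {
  dom <- grid1d(0, 21.64, 8001)
  sol <- steady_state_linear_sensing(off_model(), sensitivity_params(1), dom)
  rate <- log(2)
  exact <- grid_density(dom, rate * exp(-rate * dom$x) /
                          (1 - exp(-rate * 21.64)), normalize = FALSE)
  expect_lt(density_distance(sol$density, exact)$l1, 1e-6)
  expect_identical(sol$modality, "monotone")

  cf <- closed_form_case(off_model(), sensitivity_params(1), "off", dom)
  expect_equal(cf$rate, log(2), tolerance = 1e-12)
  expect_equal(cf$halfline_mean, 1 / log(2), tolerance = 1e-12)
  # pointwise agreement needs the quadrature normalizer resolved to ~1e-9
  fine <- grid1d(0, 21.64, 64001)
  cf_fine <- closed_form_case(off_model(), sensitivity_params(1), "off", fine)
  exact_fine <- grid_density(fine, rate * exp(-rate * fine$x) /
                               (1 - exp(-rate * 21.64)), normalize = FALSE)
  expect_lt(density_distance(cf_fine$density, exact_fine)$linf, 1e-8)
  # mean of the closed form on a long half-line grid approaches 1/rate
  long <- grid1d(0, 60, 60001)
  cf_long <- closed_form_case(off_model(domain = c(0, 60)),
                              sensitivity_params(1), "off", long)
  expect_equal(density_mean(cf_long$density), 1 / log(2), tolerance = 1e-6)
})

test_that("the sensor-on closed form agrees with cumulative quadrature up to normalization", {
  dom <- grid1d(0.05, 6, 8001)
  params <- sensitivity_params(1)
  sol <- steady_state_linear_sensing(on_model(), params, dom)
  cf <- closed_form_case(on_model(), params, "on", dom)
  ratio <- sol$density$values / cf$density$values
  expect_lt((max(ratio) - min(ratio)) / mean(ratio), 1e-6)
  expect_error(closed_form_case(off_model(), params, "on", dom), "g > 0")
  expect_error(closed_form_case(on_model(), params, "off", dom), "g = 0")
})

test_that("the sensitivity sign switches interior-unimodal vs boundary-bimodal regimes", {
  dom <- grid1d(0.05, 6, 2001)
  for (beta in c(0.1, 1)) {
    pos <- steady_state_linear_sensing(on_model(), sensitivity_params(beta),
                                       dom)
    neg <- steady_state_linear_sensing(on_model(), sensitivity_params(-beta),
                                       dom)
    # interior stationary point at b + g(x - x_bar) = 1, i.e. x = 1,
    # invariant under the sign flip
    expect_equal(pos$stationary_point, 1, tolerance = 1e-9)
    expect_equal(neg$stationary_point, 1, tolerance = 1e-9)
    expect_identical(pos$modality, "interior-unimodal")
    expect_identical(neg$modality, "boundary-bimodal")
    expect_lt(abs(pos$mode_locations[1] - 1), 2 * dom$spacing)
    expect_equal(neg$mode_locations, c(0.05, 6), tolerance = 1e-9)
  }
  # beta = 0: no entropic force at all
  expect_identical(
    steady_state_linear_sensing(on_model(), sensitivity_params(0),
                                dom)$modality,
    "flat")
})

test_that("the sensor-on solution converges to the off exponential as g -> 0", {
  dom <- grid1d(0, 8, 2001)
  params <- sensitivity_params(1)
  off <- steady_state_linear_sensing(off_model(domain = c(0, 8)), params, dom)
  l1 <- vapply(c(0.1, 0.01, 0.001), function(g) {
    m <- sensing_model(b = 2, g = g, x_bar = 2, domain = c(0, 8))
    on <- steady_state_linear_sensing(m, params, dom)
    density_distance(on$density, off$density)$l1
  }, numeric(1))
  expect_true(all(diff(l1) < 0))
  expect_lt(l1[3], 1e-3)
})

test_that("modality classification handles flat, monotone, unimodal and bimodal shapes", {
  g <- grid1d(0, 5, 501)
  expon <- grid_density(g, exp(-g$x))
  expect_identical(classify_modality(expon)$modality, "monotone")
  bump <- grid_density(g, dnorm(g$x, 2.5, 0.5))
  cb <- classify_modality(bump)
  expect_identical(cb$modality, "interior-unimodal")
  expect_lt(abs(cb$mode_locations[1] - 2.5), 2 * g$spacing)
  valley <- grid_density(g, 0.1 + (g$x - 2.5)^2)
  cv <- classify_modality(valley)
  expect_identical(cv$modality, "boundary-bimodal")
  expect_identical(classify_modality(grid_density(g, rep(1, 501)))$modality,
                   "flat")
})

test_that("the LEUP distribution exponentiates the entropy profile directly", {
  dom <- grid1d(0, 1, 1001)
  u <- leup_distribution(function(x) rep(3, length(x)), sensitivity_params(1),
                         dom)
  expect_lt(max(abs(u$density$values - 1)), 1e-10)
  u0 <- leup_distribution(function(x) x^2, sensitivity_params(0), dom)
  expect_lt(max(abs(u0$density$values - 1)), 1e-10)

  lx <- leup_distribution(function(x) x, sensitivity_params(1), dom)
  ref <- grid_density(dom, exp(-dom$x) / (1 - exp(-1)), normalize = FALSE)
  expect_lt(density_distance(lx$density, ref)$linf, 1e-6)
})

test_that("LEUP coincides with the localized Bayesian steady state", {
  params <- sensitivity_params(1)
  # constant entropy: the localized (mean-value) Bayesian form is identical
  cmp <- compare_leup_bayes(function(x) rep(0.7, length(x)), params,
                            grid1d(0, 1, 501))
  expect_lt(cmp$leup_vs_localized$linf, 1e-10)

  # nonconstant profile on the full domain: genuinely different shapes
  dom <- grid1d(0.5, 3.5, 1001)
  cmp2 <- compare_leup_bayes(function(x) log(x), params, dom)
  expect_gt(cmp2$leup_vs_cumulative$l1, 0.01)

  # localization: the shape mismatch vanishes as the domain shrinks
  rel <- vapply(c(0.5, 0.1, 0.02), function(w) {
    d <- grid1d(2 - w / 2, 2 + w / 2, 501)
    c0 <- compare_leup_bayes(function(x) log(x), params, d)
    c0$leup_vs_localized$linf_rel
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[3], 0.01)
})

test_that("the modality sweep labels the (beta, g) phase surface", {
  sw <- modality_sweep(c(-1, 0, 1), c(0, 1), domain = grid1d(0.05, 6, 257))
  expect_equal(nrow(sw), 6L)
  expect_identical(sw$modality[sw$beta == 1 & sw$g == 1], "interior-unimodal")
  expect_identical(sw$modality[sw$beta == -1 & sw$g == 1], "boundary-bimodal")
  expect_identical(sw$modality[sw$beta == 1 & sw$g == 0], "monotone")
  expect_identical(sw$modality[sw$beta == 0 & sw$g == 0], "flat")
})
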