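test_that("Bayesian update reproduces conjugate-normal posteriors and ignores flat likelihoods", {
  g <- grid1d(-8, 8, 2001)
  prior <- grid_density(g, dnorm(g$x))
  # uninformative observation: constant sensed mean, so the likelihood is flat
  flat <- sensing_model(F = function(x) 5, b = 1, g = 0, x_bar = 0,
                        domain = c(-8, 8))
  post <- bayes_update(prior, flat, y_obs = 5)
  expect_lt(max(abs(post$values - prior$values)), 1e-12)

  post2 <- bayes_update(prior, unit_noise_model(), y_obs = 2)
  expect_lt(max(abs(post2$values - dnorm(g$x, 1, sqrt(0.5)))), 1e-6)

  expect_error(bayes_update(prior, unit_noise_model(), y_obs = 1e6),
               "degenerate evidence")
})

test_that("expected update divergence equals mutual information (fluctuation-dissipation)", {
  # discrete analogue: exact equality with the joint-table mutual information
  j <- joint_table(matrix(c(0.4, 0.1, 0.1, 0.4), 2))
  expect_equal(expected_kl_discrete(j), mutual_information(j),
               tolerance = 1e-12)
  expect_lt(abs(expected_kl_discrete(j) - 0.192745), 1e-6)

  # independence: zero information flow
  gx <- grid1d(-6, 6, 801)
  prior <- grid_density(gx, dnorm(gx$x))
  flat <- sensing_model(F = function(x) 0, b = 1, g = 0, x_bar = 0,
                        domain = c(-6, 6))
  gy <- grid1d(-9, 9, 801)
  expect_lt(abs(expected_update_divergence(prior, flat, gy)), 1e-10)

  # grid identity against the x-outer (Fubini) route
  m <- unit_noise_model(c(-6, 6))
  eud <- expected_update_divergence(prior, m, gy)
  expect_gte(eud, 0)
  expect_equal(eud, mutual_information_grid(prior, m, gy), tolerance = 1e-8)

  expect_error(expected_update_divergence(prior, m, grid1d(-0.5, 0.5, 64)),
               "y-grid too narrow")
})

test_that("the truncation diagnostic beta-tilde is 1 on full supports and tracks captured mass", {
  gx <- grid1d(-6, 6, 801)
  prior <- grid_density(gx, dnorm(gx$x))
  m <- unit_noise_model(c(-6, 6))
  gy <- grid1d(-12, 12, 1201)
  expect_equal(beta_tilde(c(-6, 6), c(-6, 6), c(-12, 12), m, prior, gy), 1,
               tolerance = 1e-6)
  # numerator window holding half of the (symmetric) averaged posterior mass
  expect_equal(beta_tilde(c(-6, 0), c(-6, 6), c(-12, 12), m, prior, gy), 0.5,
               tolerance = 1e-6)
  # identical symmetric truncations of a symmetric model
  expect_equal(beta_tilde(c(-5, 5), c(-5, 5), c(-10, 10), m, prior, gy), 1,
               tolerance = 1e-6)
  expect_error(beta_tilde(c(1, -1), c(-6, 6), c(-12, 12), m, prior, gy),
               "empty")
})

test_that("KL of a small shift equals the Fisher quadratic form", {
  p1 <- gaussian_grid_density(0, 1, -10, 10, 4001L)
  fq <- fisher_quadratic_form(p1, 0.1)
  expect_equal(fq$quadratic, 0.005, tolerance = 1e-6)
  expect_equal(fq$exact_kl, 0.005, tolerance = 1e-6)

  p2 <- gaussian_grid_density(0, 2, -14, 14, 5601L)
  fq2 <- fisher_quadratic_form(p2, 0.2)
  expect_equal(fq2$quadratic, 0.005, tolerance = 1e-6)
  expect_equal(fq2$exact_kl, 0.005, tolerance = 1e-6)

  fq0 <- fisher_quadratic_form(p1, 0)
  expect_identical(fq0$quadratic, 0)
  expect_identical(fq0$exact_kl, 0)

  expect_error(fisher_quadratic_form(p1, 5), "off-grid")
})

test_that("the quadratic-form error shrinks superquadratically for a quartic density", {
  gq <- grid1d(-4, 4, 3201)
  pq <- grid_density(gq, exp(-gq$x^4 / 4))
  errs <- vapply(c(0.2, 0.1, 0.05), function(d) {
    r <- fisher_quadratic_form(pq, d)
    abs(r$exact_kl - r$quadratic)
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 6)
  expect_gt(errs[2] / errs[3], 6)
})

test_that("iterated learning contracts the conjugate posterior as 1/(n+1)", {
  g <- grid1d(-8, 8, 1601)
  prior <- grid_density(g, dnorm(g$x))
  m <- unit_noise_model()

  cfg0 <- learning_config(prior, m, n_steps = 0)
  tr0 <- iterate_learning(cfg0)
  expect_equal(nrow(tr0$records), 0L)
  expect_equal(tr0$final_prior$values, prior$values)

  cfg <- learning_config(prior, m, n_steps = 10, seed = 7,
                         update_mode = "observed")
  tr <- iterate_learning(cfg)
  expect_equal(nrow(tr$records), 10L)
  expect_true(all(tr$records$kl >= 0))
  expect_equal(density_variance(tr$final_prior), 1 / 11, tolerance = 0.02)
})

test_that("averaged-mode learning is deterministic, monotone, and mean-preserving", {
  g <- grid1d(-8, 8, 1601)
  prior <- grid_density(g, dnorm(g$x))
  cfg <- learning_config(prior, unit_noise_model(), n_steps = 10,
                         update_mode = "averaged")
  tr <- iterate_learning(cfg)
  expect_true(all(diff(tr$records$sigma_x2) <= 1e-9))
  # martingale property: the expected-observation update leaves the mean fixed
  expect_lt(abs(density_mean(tr$final_prior)), 1e-10)
  tr2 <- iterate_learning(cfg)
  expect_identical(tr$records, tr2$records)
})

test_that("entropy decay reports a nonincreasing environment entropy with limit b^2", {
  g <- grid1d(-8, 8, 1601)
  prior <- grid_density(g, dnorm(g$x))
  cfg <- learning_config(prior, unit_noise_model(), n_steps = 10,
                         update_mode = "averaged")
  tr <- iterate_learning(cfg)

  report_model <- sensing_model(b = 2, g = 1, x_bar = 0, domain = c(-1.9, 8))
  rep <- entropy_decay_report(tr, report_model)
  expect_identical(rep$verdict, "nonincreasing")
  expect_true(all(diff(rep$entropy) <= 1e-12))
  # entropy decays toward log(b) + 0.5 log(2 pi e) as sigma_x^2 -> 0
  expect_lt(abs(rep$entropy[length(rep$entropy)] - (log(2) + HALF_LOG_2PIE)),
            0.02)
  expect_equal(rep$limit_gap, density_variance(tr$final_prior),
               tolerance = 1e-9)

  moff <- sensing_model(b = 2, g = 0, x_bar = 0, domain = c(-8, 8))
  rep_off <- entropy_decay_report(tr, moff)
  expect_lt(max(rep_off$entropy) - min(rep_off$entropy), 1e-12)

  cfg1 <- learning_config(prior, unit_noise_model(), n_steps = 1)
  expect_identical(entropy_decay_report(iterate_learning(cfg1),
                                        moff)$verdict,
                   "insufficient data")
})

test_that("pointwise mutual information is nonnegative and integrates to the expected divergence", {
  gx <- grid1d(-6, 6, 401)
  prior <- grid_density(gx, dnorm(gx$x))
  gy <- grid1d(-9, 9, 801)
  flat <- sensing_model(F = function(x) 0, b = 1, g = 0, x_bar = 0,
                        domain = c(-6, 6))
  expect_lt(abs(pointwise_mi_given_x(flat, prior, 1.3, gy)), 1e-10)

  m <- unit_noise_model(c(-6, 6))
  pmi <- vapply(gx$x, function(x) pointwise_mi_given_x(m, prior, x, gy),
                numeric(1))
  expect_true(all(pmi >= -1e-12))
  w <- rep(gx$spacing, gx$n_points); w[c(1, gx$n_points)] <- gx$spacing / 2
  expect_equal(sum(w * prior$values * pmi),
               expected_update_divergence(prior, m, gy), tolerance = 1e-8)
})

test_that("the steady-state log-gradient matches the sensitivity-weighted pointwise MI", {
  # d ln P/dx = beta * (i(x) + c(x) + const) - beta', with c(x) the
  # evidence cross term; checks the quadrature consistency of the
  # steady-state exponent with the pointwise-MI decomposition
  m <- on_model(c(0.3, 5))
  params <- sensitivity_params(0.8)
  dom <- grid1d(0.3, 5, 601)
  sol <- steady_state_linear_sensing(m, params, dom)
  P <- sol$density
  gy <- grid1d(-45, 55, 2001)
  py <- local({
    L <- outer(gy$x, dom$x, function(y, x)
      dnorm(y, conditional_mean(m, x), conditional_sd(m, x)))
    w <- rep(dom$spacing, dom$n_points); w[c(1, dom$n_points)] <- dom$spacing / 2
    as.vector(L %*% (w * P$values))
  })
  idx <- seq(31, 571, by = 30)
  wy <- rep(gy$spacing, gy$n_points); wy[c(1, gy$n_points)] <- gy$spacing / 2
  resid <- vapply(idx, function(i) {
    x <- dom$x[i]
    pmi <- pointwise_mi_given_x(m, P, x, gy)
    lik <- dnorm(gy$x, conditional_mean(m, x), conditional_sd(m, x))
    cross <- sum(wy * lik * log(pmax(py, 1e-300)))
    dlogp <- (log(P$values[i + 1]) - log(P$values[i - 1])) / (2 * dom$spacing)
    dlogp - (params$beta * (pmi + cross + HALF_LOG_2PIE) - params$beta_prime)
  }, numeric(1))
  expect_lt(max(abs(resid)), 1e-4)
})

test_that("component-wise pointwise MI aggregates additively", {
  expect_equal(product_form_pmi(0.3), 0.3)
  expect_equal(product_form_pmi(c(0.1, 0.2)), 0.3, tolerance = 1e-15)
  expect_equal(product_form_pmi(c(0, 0, 0)), 0)
  expect_error(product_form_pmi(c(0.1, NaN)), "finite")
})
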