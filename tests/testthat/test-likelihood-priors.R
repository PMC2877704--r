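test_that("expected_count: zero densities, effort linearity, arithmetic oracle", {
  p <- table1_msfr_params()
  d0 <- msfr_data(densities = matrix(0, 1, 3,
                                     dimnames = list(NULL, p$prey)),
                  counts = matrix(0L, 1, 3), effort = 100)
  expect_equal(unname(expected_count(d0, p)[1, ]), c(0, 0, 0))

  dens <- matrix(c(100, 9, 1), 1, dimnames = list(NULL, p$prey))
  d1 <- msfr_data(dens, matrix(0L, 1, 3), effort = 100)
  d2 <- msfr_data(dens, matrix(0L, 1, 3), effort = 200)
  expect_equal(expected_count(d2, p), 2 * expected_count(d1, p))

  # independent longhand arithmetic for mu_grouse at these densities
  w_g <- 0.000673 * 100^2.51
  w_p <- 1.904 * 9^1.18
  w_v <- 3.78 * 1^1.14
  mu_oracle <- 100 * w_g / (1 + 2.74 * w_g + 1.676 * w_p + 2.32 * w_v)
  expect_equal(unname(expected_count(d1, p, "grouse")), mu_oracle,
               tolerance = 1e-12)
})

test_that("negative-binomial log-pmf: NB2 contract", {
  # mu = 0 is a point mass at zero
  expect_equal(nb_log_pmf(0, 0, 2), 0)
  expect_equal(nb_log_pmf(3L, 0, 2), -Inf)
  expect_error(nb_log_pmf(1.5, 1, 1), "integer")
  expect_error(nb_log_pmf(2, 1, -1), "'k'")

  # variance mu + mu^2/k against the standard parameterisation
  y <- 0:400
  pm <- exp(nb_log_pmf(y, 5, 2))
  expect_equal(sum(pm), 1, tolerance = 1e-9)           # normalization
  expect_equal(sum(pm * y), 5, tolerance = 1e-8)       # mean
  expect_equal(sum(pm * (y - 5)^2), 5 + 25 / 2, tolerance = 1e-6)

  # Poisson limit: exact at k = Inf, 1e-6-close by k = 1e10
  for (mu in c(0.5, 5, 20)) {
    expect_equal(nb_log_pmf(0:50, mu, Inf), dpois(0:50, mu, log = TRUE))
    expect_equal(nb_log_pmf(0:50, mu, 1e10), dpois(0:50, mu, log = TRUE),
                 tolerance = 1e-6)
  }
})

test_that("log-likelihood: empty data, single cell, brute-force sum oracle", {
  p <- table1_msfr_params()
  empty <- msfr_data(matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, p$prey)),
                     counts = matrix(integer(0), 0, 3),
                     effort = numeric(0))
  expect_equal(log_likelihood(empty, p, k = c(2, 2, 2)), 0)

  p1 <- msfr_params(a = 0.01, t = 0.5, m = 1.2, prey = "g")
  d1 <- msfr_data(matrix(30, 1, 1, dimnames = list(NULL, "g")),
                  counts = matrix(4L, 1, 1), effort = 80)
  mu <- single_species_response(30, 0.01, 0.5, 1.2) * 80
  expect_equal(log_likelihood(d1, p1, k = 3), nb_log_pmf(4L, mu, 3))

  set.seed(21)
  dens <- matrix(runif(9, 1, 50), 3, dimnames = list(NULL, p$prey))
  cnt <- matrix(rpois(9, 10), 3)
  eff <- c(60, 100, 140)
  d <- msfr_data(dens, cnt, eff)
  k <- c(2, 4, 6)
  # brute force: loop over the 9 cells with dnbinom directly
  oracle <- 0
  for (i in 1:3) {
    w <- p$a * dens[i, ]^p$m
    F <- w / (1 + sum(p$t * w))
    for (j in 1:3)
      oracle <- oracle + dnbinom(cnt[i, j], size = k[j], mu = F[j] * eff[i],
                                 log = TRUE)
  }
  expect_equal(log_likelihood(d, p, k), oracle, tolerance = 1e-12)
})

test_that("shifted gamma: moment matching, quantiles, special cases", {
  g <- shifted_gamma_from_moments(2, 0.9, 1)
  expect_equal(g$shape, 1 / 0.9)
  expect_equal(g$scale, 0.9)
  # the shape-exponent prior has 95th percentile ~ 3.9
  expect_equal(qsgamma(0.95, 2, 0.9, 1), 3.9, tolerance = 0.005)
  # exponential special case: mean = shift + s, var = s^2 -> shape 1
  expect_equal(shifted_gamma_from_moments(3, 4, 1)$shape, 1)
  expect_equal(dsgamma(1.5, 3, 4, 1), dexp(0.5, rate = 0.5))
  expect_error(shifted_gamma_from_moments(1, 0.9, 1), "exceed")
  # density/cdf/quantile coherence
  expect_equal(psgamma(qsgamma(0.3, 2, 0.9, 1), 2, 0.9, 1), 0.3)
})

test_that("shape-exponent prior draws reproduce the stated moments", {
  set.seed(99)
  x <- rsgamma(1e6, 2, 0.9, 1)
  expect_true(all(x > 1))
  expect_equal(mean(x), 2, tolerance = 0.005)  # +/- 0.01 absolute
  expect_equal(var(x), 0.9, tolerance = 0.02 / 0.9)  # absolute 0.02
})

test_that("log_prior: support, oracle density, additivity, joint hook", {
  pri1 <- default_priors("g")
  th <- c(a_g = 1, t_g = 2, m_g = 2, k_g = 1)
  # out of support is a value, not an error
  expect_identical(log_prior(replace(th, "m_g", 0.5), pri1), -Inf)
  expect_identical(log_prior(replace(th, "a_g", -1), pri1), -Inf)

  # full default prior at th against independently coded gamma densities:
  # a ~ gamma(mean 1, var 0.99), t ~ gamma(2, 2), m - 1 ~ gamma(2 - 1, 0.9),
  # k ~ gamma(1, 10); shape = mean^2/var, scale = var/mean throughout
  lp <- log_prior(th, pri1)
  oracle <- dgamma(1, shape = 1 / 0.99, scale = 0.99, log = TRUE) +
    dgamma(2, shape = 2, scale = 1, log = TRUE) +
    dgamma(2 - 1, shape = 1 / 0.9, scale = 0.9, log = TRUE) +
    dgamma(1, shape = 1 / 10, scale = 10, log = TRUE)
  expect_equal(lp, oracle, tolerance = 1e-12)

  # two prey with identical values double the log prior
  pri2 <- default_priors(c("g", "h"))
  th2 <- c(a_g = 1, a_h = 1, t_g = 2, t_h = 2, m_g = 2, m_h = 2,
           k_g = 1, k_h = 1)
  expect_equal(log_prior(th2, pri2), 2 * lp, tolerance = 1e-12)

  # user-supplied joint term is added on top
  hook <- function(theta) -0.5 * (log(theta[["a_g"]]) + theta[["m_g"]])
  expect_equal(log_prior(th, pri1, extra_log_prior = hook), lp + hook(th))
})

test_that("log posterior composes likelihood and prior; -Inf off support", {
  set.seed(31)
  truth <- default_truth()
  d <- simulate_counts(generate_design(design_spec(n_site_years = 4,
                                                   seed = 5)),
                       truth, seed = 6)
  lpost <- make_log_posterior(d)
  pri <- attr(lpost, "priors")
  th <- truth_vector(truth)
  ref <- log_likelihood(d, truth$params, truth$k) + log_prior(th, pri)
  expect_equal(lpost(th), ref, tolerance = 1e-10)
  expect_true(is.finite(lpost(th)))
  expect_identical(lpost(replace(th, "m_vole", 0.99)), -Inf)
  expect_identical(lpost(replace(th, "t_pipit", -0.1)), -Inf)
  # name-order independence
  expect_equal(lpost(rev(th)), lpost(th))
})
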