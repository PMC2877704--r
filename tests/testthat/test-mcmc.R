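test_that("sampler recovers an injected standard-normal target", {
  lp <- function(theta) -0.5 * sum(theta^2)
  cfg <- sampler_config(n_iterations = 1e5, burn_in = 5000, seed = 7,
                        initial_step_sizes = 1)
  ch <- run_rwmh(lp, c(x = 0, y = 0, z = 0), cfg)
  expect_equal(dim(ch$draws), c(1e5L, 3L))
  expect_true(all(abs(colMeans(ch$draws)) < 0.05))
  expect_true(all(abs(apply(ch$draws, 2, var) - 1) < 0.1))
  # burn-in tuning reached the target acceptance band
  expect_true(all(ch$acceptance_rates > 0.10 & ch$acceptance_rates < 0.35))
})

test_that("sampler recovers a gamma target through the log transform", {
  # Gamma(shape 3, scale 2): mean 6, variance 12
  lp <- function(theta) dgamma(theta[["g"]], shape = 3, scale = 2, log = TRUE)
  cfg <- sampler_config(n_iterations = 1e5, burn_in = 5000, seed = 8)
  ch <- run_rwmh(lp, c(g = 2), cfg, transforms = "log")
  expect_true(all(ch$draws > 0))
  expect_equal(mean(ch$draws), 6, tolerance = 0.03)
  expect_equal(var(ch$draws[, 1]), 12, tolerance = 0.15)
})

test_that("sampler edge cases: empty chain, bad init, reproducibility", {
  lp <- function(theta) -0.5 * sum(theta^2)
  ch0 <- run_rwmh(lp, c(x = 0), sampler_config(n_iterations = 0,
                                               burn_in = 50, seed = 1))
  expect_identical(nrow(ch0$draws), 0L)
  expect_identical(ch0$seed, 1L)           # provenance survives
  expect_error(summarize_chains(ch0), "empty")

  expect_error(run_rwmh(function(theta) -Inf, c(x = 0),
                        sampler_config(n_iterations = 10, burn_in = 0)),
               "initial")
  expect_error(run_rwmh(lp, c(x = -1), sampler_config(),
                        transforms = "log"), "domain")

  cfg <- sampler_config(n_iterations = 500, burn_in = 100, seed = 33)
  expect_identical(run_rwmh(lp, c(x = 0), cfg)$draws,
                   run_rwmh(lp, c(x = 0), cfg)$draws)
  cfg2 <- sampler_config(n_iterations = 500, burn_in = 100, seed = 34)
  expect_false(identical(run_rwmh(lp, c(x = 0), cfg)$draws,
                         run_rwmh(lp, c(x = 0), cfg2)$draws))
})

test_that("fitted chains respect parameter support", {
  truth <- default_truth()
  d <- simulate_counts(generate_design(design_spec(n_site_years = 6,
                                                   seed = 2)),
                       truth, seed = 3)
  ch <- fit_msfr(d, config = quick_config())
  dr <- ch$draws
  expect_true(all(dr[, grepl("^a_", colnames(dr))] > 0))
  expect_true(all(dr[, grepl("^t_", colnames(dr))] >= 0))
  expect_true(all(dr[, grepl("^m_", colnames(dr))] >= 1))
  expect_true(all(dr[, grepl("^k_", colnames(dr))] > 0))
  expect_true(all(ch$acceptance_rates >= 0 & ch$acceptance_rates <= 1))
})

test_that("posterior summaries use the pinned quantile convention", {
  cc <- matrix(7, 100, 1, dimnames = list(NULL, "c"))
  s <- summarize_chains(chains_from_matrix(cc))
  expect_equal(s$mean, 7)
  expect_equal(s$lower, 7)
  expect_equal(s$upper, 7)

  ch <- matrix(1:10000, ncol = 1, dimnames = list(NULL, "x"))
  s <- summarize_chains(chains_from_matrix(ch))
  expect_equal(s$mean, 5000.5)
  expect_equal(s$lower, 250.975)   # type-7 quantile, pinned
  expect_equal(s$upper, 9750.025)
})

test_that("cumulative means and convergence flag", {
  ch <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "x"))
  cm <- cumulative_means(chains_from_matrix(ch))
  expect_equal(cm$series[, 1], c(1, 1.5, 2))

  const <- matrix(5, 200, 1, dimnames = list(NULL, "x"))
  cmc <- cumulative_means(chains_from_matrix(const))
  expect_true(all(cmc$series == 5))
  expect_true(cmc$converged[["x"]])

  # a trending chain is flagged unconverged under a tight band
  trend <- matrix(seq(0, 1, length.out = 500), ncol = 1,
                  dimnames = list(NULL, "x"))
  expect_false(cumulative_means(chains_from_matrix(trend),
                                band = 0.001)$converged[["x"]])
})

test_that("estimation error shrinks with data size (replicate-averaged RMSE)", {
  truth <- default_truth()
  tv <- truth_vector(truth)[1:9]          # a, t, m
  rmse1 <- function(S, r) {
    d <- simulate_counts(
      generate_design(design_spec(n_site_years = S,
                                  effort_range = c(450, 550),
                                  seed = 500 + S + r)),
      truth, seed = 600 + S + r)
    fit <- fit_msfr(d, config = sampler_config(n_iterations = 8000,
                                               burn_in = 4000,
                                               seed = 700 + S + r))
    s <- summarize_chains(fit)
    sqrt(mean((log(s$mean[1:9]) - log(tv))^2))
  }
  rmse <- vapply(c(5, 30, 150), function(S)
    mean(vapply(1:3, function(r) rmse1(S, r), numeric(1))), numeric(1))
  expect_true(rmse[1] > rmse[2] && rmse[2] > rmse[3])
})

test_that("95% intervals cover truth in ~90% of replicate synthetic worlds", {
  truth <- default_truth()
  tv <- truth_vector(truth)
  cover <- 0L
  for (rep in 1:20) {
    d <- simulate_counts(
      generate_design(design_spec(n_site_years = 11,
                                  effort_range = c(200, 600),
                                  seed = 1000 + rep)),
      truth, seed = 2000 + rep)
    fit <- fit_msfr(d, config = sampler_config(n_iterations = 6000,
                                               burn_in = 3000,
                                               seed = 3000 + rep))
    s <- summarize_chains(fit)
    cover <- cover + sum(s$lower <= unname(tv[s$parameter]) &
                           unname(tv[s$parameter]) <= s$upper)
  }
  expect_gte(cover / (20 * 12), 0.9)
})

test_that("randomized PIT is uniform under the true model and flags misfit", {
  truth <- default_truth()
  design <- generate_design(design_spec(n_site_years = 60,
                                        effort_range = c(200, 600),
                                        seed = 12))
  d <- simulate_counts(design, truth, seed = 13)
  # degenerate posterior: the truth itself
  ch <- chains_from_matrix(matrix(truth_vector(truth), 1, 12, byrow = TRUE,
                                  dimnames = list(NULL,
                                                  names(truth_vector(truth)))),
                           prey = d$prey)
  ppc <- posterior_predictive_pit(ch, d, seed = 14)
  expect_equal(nrow(ppc$cells), 180L)
  expect_true(all(ppc$cells$pit >= 0 & ppc$cells$pit <= 1))
  expect_lt(ppc$ks, 0.12)   # 95% KS band at n = 180 is ~0.10

  # heavy overdispersion fitted as near-Poisson: PIT piles up at the extremes
  d_over <- simulate_counts(design, list(params = truth$params,
                                         k = rep(0.2, 3)), seed = 15)
  th_pois <- truth_vector(truth)
  th_pois[10:12] <- 1e6
  chp <- chains_from_matrix(matrix(th_pois, 1, 12, byrow = TRUE,
                                   dimnames = list(NULL, names(th_pois))),
                            prey = d$prey)
  ppc_bad <- posterior_predictive_pit(chp, d_over, seed = 16)
  expect_gt(ppc_bad$ks, 0.2)
})

test_that("chain CSV round trip preserves draws", {
  lp <- function(theta) -0.5 * sum(theta^2)
  ch <- run_rwmh(lp, c(x = 0, y = 1),
                 sampler_config(n_iterations = 50, burn_in = 20, seed = 5))
  f <- tempfile(fileext = ".csv")
  write_chains_csv(ch, f)
  back <- read_chains_csv(f)
  expect_equal(back$draws, ch$draws, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(colnames(back$draws), c("x", "y"))
})
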