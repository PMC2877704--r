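#' Sampler configuration
#'
#' Settings for the component-wise random-walk Metropolis-Hastings sampler.
#' Proposal standard deviations are tuned only during burn-in: after every
#' `adapt_block` iterations each parameter whose block acceptance rate
#' falls outside `target_acceptance` has its step size divided or
#' multiplied by `adapt_factor`. Step sizes are frozen after burn-in so the
#' retained chain satisfies detailed balance.
#'
#' The defaults are a desk-scale run (50,000 retained draws after a 10,000
#' draw burn-in); production-scale runs in the millions of iterations are a
#' matter of configuration only.
#'
#' @param n_iterations retained post-burn-in iterations (>= 0).
#' @param burn_in discarded tuning iterations (>= 0).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer RNG seed; the whole run is reproducible from it.
#' @param target_acceptance length-2 acceptance-rate interval, default
#'   15-30% per parameter.
#' @param adapt_block iterations between step-size adjustments.
#' @param adapt_factor multiplicative step adjustment.
#' @param initial_step_sizes scalar or per-parameter proposal SD on the
#'   proposal (transformed) scale.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_iterations = 50000L, burn_in = 10000L,
                           thin = 1L, seed = 1L,
                           target_acceptance = c(0.15, 0.30),
                           adapt_block = 500L, adapt_factor = 1.5,
                           initial_step_sizes = 0.5) {
  stopifnot(n_iterations >= 0, burn_in >= 0, thin >= 1,
            length(target_acceptance) == 2L,
            all(target_acceptance > 0), all(target_acceptance < 1),
            target_acceptance[1] < target_acceptance[2],
            adapt_block >= 1, adapt_factor > 1,
            all(initial_step_sizes > 0))
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 target_acceptance = target_acceptance,
                 adapt_block = as.integer(adapt_block),
                 adapt_factor = adapt_factor,
                 initial_step_sizes = initial_step_sizes),
            class = "sampler_config")
}

tr_to_z <- function(theta, tr) {
  z <- theta
  z[tr == "log"] <- log(theta[tr == "log"])
  z[tr == "logm1"] <- log(theta[tr == "logm1"] - 1)
  z
}

tr_to_native <- function(z, tr) {
  theta <- z
  theta[tr == "log"] <- exp(z[tr == "log"])
  theta[tr == "logm1"] <- 1 + exp(z[tr == "logm1"])
  theta
}

#' Component-wise random-walk Metropolis-Hastings
#'
#' Systematic-scan single-parameter Gaussian random-walk updates of an
#' arbitrary log-posterior. Each parameter may be sampled on a transformed
#' scale (`"log"` for positive parameters, `"logm1"` for parameters bounded
#' below by 1, `"identity"`); the acceptance ratio carries the Jacobian of
#' the transform so the target on the native scale is unchanged. Step sizes
#' adapt during burn-in only (see [sampler_config]).
#'
#' @param log_post `function(theta)` returning the unnormalised log
#'   posterior of a named parameter vector; `-Inf` outside support.
#' @param init named numeric vector of starting values (native scale);
#'   `log_post(init)` must be finite.
#' @param config a [sampler_config].
#' @param transforms character vector (recycled) of per-parameter proposal
#'   scales: `"identity"`, `"log"` or `"logm1"`.
#' @return An `msfr_chains` object: `draws` (matrix, retained iteration x
#'   parameter, native scale), `acceptance_rates` and `step_sizes_final`
#'   per parameter, and the full `config`, `transforms` and seed for
#'   provenance.
#' @export
run_rwmh <- function(log_post, init, config = sampler_config(),
                     transforms = "identity") {
  p <- length(init)
  pn <- names(init)
  if (is.null(pn)) pn <- paste0("theta", seq_len(p))
  tr <- rep_len(transforms, p)
  if (!all(tr %in% c("identity", "log", "logm1")))
    stop("transforms must be identity, log or logm1", call. = FALSE)
  if (any(tr == "log" & init <= 0) || any(tr == "logm1" & init <= 1))
    stop("init outside the domain of its proposal transform", call. = FALSE)

  set.seed(config$seed)
  theta <- stats::setNames(as.numeric(init), pn)
  z <- tr_to_z(theta, tr)
  jac <- ifelse(tr == "identity", 0, z)    # log|d theta/d z| per parameter
  lp <- log_post(theta) + sum(jac)
  if (!is.finite(lp))
    stop("log posterior is not finite at the initial values", call. = FALSE)

  step <- rep_len(config$initial_step_sizes, p)
  n_total <- config$burn_in + config$n_iterations
  keep_idx <- if (config$n_iterations > 0)
    seq(config$burn_in + config$thin, n_total, by = config$thin) else integer()
  # thinning convention: keep draws burn_in + thin, burn_in + 2*thin, ...
  if (config$n_iterations > 0)
    keep_idx <- keep_idx[keep_idx <= n_total]
  draws <- matrix(NA_real_, length(keep_idx), p,
                  dimnames = list(NULL, pn))
  acc_block <- numeric(p)
  acc_post <- numeric(p)
  row <- 0L

  for (it in seq_len(n_total)) {
    for (j in seq_len(p)) {
      zj <- z[j] + stats::rnorm(1L, 0, step[j])
      theta_prop <- theta
      theta_prop[j] <- switch(tr[j], identity = zj, log = exp(zj),
                              logm1 = 1 + exp(zj))
      lpost <- log_post(theta_prop)
      if (is.nan(lpost))
        stop("NaN log posterior at iteration ", it, ", parameter '",
             pn[j], "'", call. = FALSE)
      jac_j <- if (tr[j] == "identity") 0 else zj
      lp_prop <- lpost + sum(jac) - jac[j] + jac_j
      if (log(stats::runif(1L)) < lp_prop - lp) {
        theta <- theta_prop
        z[j] <- zj
        jac[j] <- jac_j
        lp <- lp_prop
        acc_block[j] <- acc_block[j] + 1
        if (it > config$burn_in) acc_post[j] <- acc_post[j] + 1
      }
    }
    if (it <= config$burn_in && it %% config$adapt_block == 0L) {
      rate <- acc_block / config$adapt_block
      step[rate < config$target_acceptance[1]] <-
        step[rate < config$target_acceptance[1]] / config$adapt_factor
      step[rate > config$target_acceptance[2]] <-
        step[rate > config$target_acceptance[2]] * config$adapt_factor
      acc_block[] <- 0
    }
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      row <- row + 1L
      draws[row, ] <- theta
    }
  }

  structure(list(draws = draws,
                 param_names = pn,
                 acceptance_rates = if (config$n_iterations > 0)
                   acc_post / config$n_iterations else
                     rep(NA_real_, p),
                 step_sizes_final = step,
                 transforms = tr,
                 seed = config$seed,
                 config = config),
            class = "msfr_chains")
}

#' @export
print.msfr_chains <- function(x, ...) {
  cat("msfr_chains:", nrow(x$draws), "retained draws x",
      ncol(x$draws), "parameters (seed", x$seed, ")\n")
  cat("acceptance rates:",
      paste(sprintf("%s=%.2f", x$param_names, x$acceptance_rates),
            collapse = " "), "\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Posterior mean, standard deviation and central credible interval per
#' parameter, on the native parameter scale. Quantiles use R's default
#' definition (type 7); this convention is pinned so interval endpoints are
#' reproducible.
#'
#' @param chains an `msfr_chains` object (or bare draw matrix).
#' @param probs interval endpoints, default `c(0.025, 0.975)` (a 95%
#'   credible interval).
#' @return `data.frame` with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
summarize_chains <- function(chains, probs = c(0.025, 0.975)) {
  draws <- if (inherits(chains, "msfr_chains")) chains$draws else
    as.matrix(chains)
  if (nrow(draws) == 0L) stop("empty chain", call. = FALSE)
  qs <- apply(draws, 2L, stats::quantile, probs = probs, names = FALSE,
              type = 7)
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2L, stats::sd),
             lower = qs[1L, ], upper = qs[2L, ],
             row.names = NULL)
}

#' Cumulative-mean convergence series
#'
#' Running posterior mean of every parameter: flat late-series behaviour is
#' the convergence check used for long single-chain runs. A parameter is
#' flagged converged when its running mean over the last 10% of the chain
#' stays within a relative band of the final mean.
#'
#' @param chains an `msfr_chains` object (or draw matrix).
#' @param band relative half-width of the stability band (default 2%).
#' @return List: `series` (matrix, iteration x parameter),
#'   `converged` (named logical), `band`.
#' @export
cumulative_means <- function(chains, band = 0.02) {
  draws <- if (inherits(chains, "msfr_chains")) chains$draws else
    as.matrix(chains)
  n <- nrow(draws)
  if (n == 0L) stop("empty chain", call. = FALSE)
  series <- apply(draws, 2L, cumsum) / seq_len(n)
  if (n == 1L) series <- matrix(series, 1L, dimnames = list(NULL, colnames(draws)))
  tail_idx <- seq.int(max(1L, ceiling(0.9 * n)), n)
  final <- series[n, ]
  scale <- pmax(abs(final), .Machine$double.eps)
  converged <- vapply(seq_len(ncol(series)), function(j)
    all(abs(series[tail_idx, j] - final[j]) <= band * scale[j]), logical(1L))
  names(converged) <- colnames(draws)
  list(series = series, converged = converged, band = band)
}

chain_param_sets <- function(chains, prey, shared_k, idx) {
  lapply(idx, function(i)
    theta_to_params(chains$draws[i, ], prey, shared_k))
}

#' Posterior predictive check via randomized PIT
#'
#' For every observed count, the predictive cumulative probability is
#' averaged over (thinned) posterior draws of the negative-binomial
#' observation model. Because counts are discrete, the probability integral
#' transform is randomized: each datum's PIT value is drawn uniformly
#' between the predictive CDF just below and at the observation. If the
#' model fits, the PIT values are uniform on (0, 1); the returned QQ pairs
#' and Kolmogorov-Smirnov statistic measure departure from uniformity.
#'
#' @param chains an `msfr_chains` object from an MSFR fit.
#' @param data the fitted [msfr_data] (with counts).
#' @param n_draws number of (evenly thinned) posterior draws to average
#'   over.
#' @param seed seed for the PIT randomization (separate from the sampler
#'   seed).
#' @param prey,shared_k parameter layout; defaults recovered from the
#'   chain's column names.
#' @return List: `cells` (data.frame with site-year, prey, count, CDF
#'   bounds and PIT per observation cell), `qq` (sorted PIT vs uniform
#'   quantiles), `ks` (KS distance from uniformity).
#' @export
posterior_predictive_pit <- function(chains, data, n_draws = 200L,
                                     seed = 1L, prey = data$prey,
                                     shared_k = !any(paste0("k_", prey)
                                                     %in% chains$param_names)) {
  stopifnot(inherits(chains, "msfr_chains"), inherits(data, "msfr_data"),
            !is.null(data$counts))
  n_avail <- nrow(chains$draws)
  if (n_avail == 0L) stop("empty chain", call. = FALSE)
  idx <- unique(round(seq(1L, n_avail, length.out = min(n_draws, n_avail))))
  S <- nrow(data$counts); P <- length(prey)
  y <- as.vector(data$counts)
  cdf_hi <- numeric(S * P)
  cdf_lo <- numeric(S * P)
  for (i in idx) {
    pk <- theta_to_params(chains$draws[i, ], prey, shared_k)
    mu <- as.vector(expected_count(data, pk$params))
    kk <- rep(pk$k, each = S)
    cdf_hi <- cdf_hi + stats::pnbinom(y, size = kk, mu = mu)
    cdf_lo <- cdf_lo + ifelse(y > 0,
                              stats::pnbinom(y - 1, size = kk, mu = mu), 0)
  }
  cdf_hi <- cdf_hi / length(idx)
  cdf_lo <- cdf_lo / length(idx)
  set.seed(seed)
  pit <- stats::runif(S * P, min = cdf_lo, max = cdf_hi)
  n <- length(pit)
  sp <- sort(pit)
  ks <- max(seq_len(n) / n - sp, sp - (seq_len(n) - 1) / n)
  list(cells = data.frame(site_year_id = rep(data$site_year_id, P),
                          prey = rep(prey, each = S), count = y,
                          cdf_lower = cdf_lo, cdf_upper = cdf_hi,
                          pit = pit),
       qq = data.frame(theoretical = stats::ppoints(n), observed = sp),
       ks = ks)
}

#' Fit a functional response by MCMC
#'
#' End-to-end Bayesian fit: assembles the negative-binomial log-posterior
#' for the data set (multispecies by default; a generalised single-species
#' fit when `single_species` names one prey), and samples it with the
#' random-walk sampler using log-scale proposals for `a`, `t`, `k` and a
#' `log(m - 1)` proposal for the shape exponents. Initial values default to
#' the prior means.
#'
#' @inheritParams make_log_posterior
#' @param config a [sampler_config].
#' @param single_species optional prey name: fit that prey's counts as a
#'   function of its own density only, ignoring alternative prey.
#' @param init optional named starting values (native scale).
#' @return An `msfr_chains` object with `prey` and `shared_k` recorded for
#'   downstream analyses.
#' @examples
#' \donttest{
#' truth <- list(params = table1_msfr_params(), k = rep(5, 3))
#' d <- simulate_counts(generate_design(design_spec(seed = 1)), truth,
#'                      seed = 2)
#' fit <- fit_msfr(d, config = sampler_config(n_iterations = 2000,
#'                                            burn_in = 1000, seed = 3))
#' summarize_chains(fit)
#' }
#' @export
fit_msfr <- function(data, priors = NULL, config = sampler_config(),
                     shared_k = FALSE, single_species = NULL,
                     extra_log_prior = NULL, init = NULL) {
  stopifnot(inherits(data, "msfr_data"))
  if (!is.null(single_species)) data <- subset_prey(data, single_species)
  log_post <- make_log_posterior(data, priors, shared_k, extra_log_prior)
  pn <- attr(log_post, "param_names")
  priors <- attr(log_post, "priors")
  if (is.null(init)) {
    init <- vapply(priors[pn], function(s) s$mean, numeric(1L))
    names(init) <- pn
  }
  tr <- ifelse(startsWith(pn, "m_"), "logm1", "log")
  chains <- run_rwmh(log_post, init, config, transforms = tr)
  chains$prey <- data$prey
  chains$shared_k <- shared_k
  chains
}

#' Write chains / summary / diagnostics artifacts
#'
#' @param chains an `msfr_chains` object.
#' @param path output CSV path (one column per parameter).
#' @return The path, invisibly.
#' @export
write_chains_csv <- function(chains, path) {
  utils::write.csv(as.data.frame(chains$draws), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_chains_csv
#' @export
read_chains_csv <- function(path) {
  draws <- as.matrix(utils::read.csv(path, check.names = FALSE))
  structure(list(draws = draws, param_names = colnames(draws),
                 acceptance_rates = rep(NA_real_, ncol(draws)),
                 step_sizes_final = rep(NA_real_, ncol(draws)),
                 transforms = NULL, seed = NA_integer_, config = NULL),
            class = "msfr_chains")
}
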