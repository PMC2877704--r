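#' Expected delivery count for one observation cell
#'
#' Links the hourly consumption rate predicted by the multispecies
#' functional response to the observed delivery counts: the expected number
#' of items of prey `prey` delivered during a watch is the MSFR rate at
#' that site-year's densities times the watch effort in hours.
#'
#' @param data an [msfr_data] object.
#' @param params an [msfr_params] object.
#' @param prey prey index or name; if missing, all prey.
#' @return Matrix of expected counts (site-years x prey), or a vector for a
#'   single prey.
#' @export
expected_count <- function(data, params, prey = NULL) {
  stopifnot(inherits(data, "msfr_data"))
  mu <- msfr_response(data$densities, params) * data$effort
  if (is.null(prey)) return(mu)
  if (is.character(prey)) prey <- match(prey, params$prey)
  mu[, prey]
}

#' Negative-binomial log-pmf (NB2 parameterisation)
#'
#' `Var(Y) = mu + mu^2/k`; large `k` approaches the Poisson. `mu = 0`
#' is the degenerate point mass at zero. Thin wrapper around
#' [stats::dnbinom] that enforces the count-data contract.
#'
#' @param y non-negative integer count (vectorised).
#' @param mu mean, >= 0.
#' @param k dispersion, > 0 (may be `Inf` for the Poisson limit).
#' @return Log-probability.
#' @export
nb_log_pmf <- function(y, mu, k) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("'y' must be non-negative integer counts", call. = FALSE)
  if (any(mu < 0)) stop("'mu' must be >= 0", call. = FALSE)
  if (any(k <= 0)) stop("'k' must be > 0", call. = FALSE)
  if (any(is.infinite(k))) {
    out <- stats::dpois(y, lambda = mu, log = TRUE)
    fin <- is.finite(k)
    if (any(fin))
      out[fin] <- stats::dnbinom(y[fin], size = k[fin], mu = mu[fin],
                                 log = TRUE)
    return(out)
  }
  # dnbinom(mu = 0) is a point mass at zero, as required
  stats::dnbinom(y, size = k, mu = mu, log = TRUE)
}

#' Negative-binomial log-likelihood of a delivery data set
#'
#' Sum over site-years and prey of the NB2 log-pmf of each count around its
#' MSFR-predicted mean. Counts are conditionally independent given the
#' parameters; their dependence arises only through the shared
#' handling-time denominator of the response.
#'
#' @param data an [msfr_data] object with counts.
#' @param params an [msfr_params] object.
#' @param k per-prey dispersion vector (recycled if length 1 = shared
#'   dispersion).
#' @return Scalar log-likelihood (0 for an empty data set).
#' @export
log_likelihood <- function(data, params, k) {
  stopifnot(inherits(data, "msfr_data"))
  if (is.null(data$counts))
    stop("data set has no counts; simulate or load them first", call. = FALSE)
  if (nrow(data$counts) == 0L) return(0)
  k <- rep_len(k, params$n_prey)
  mu <- expected_count(data, params)
  ll <- nb_log_pmf(as.vector(data$counts), as.vector(mu),
                   rep(k, each = nrow(mu)))
  bad <- which(is.nan(ll))
  if (length(bad)) {
    cell <- arrayInd(bad[1L], dim(mu))
    stop("non-finite likelihood at site-year '",
         data$site_year_id[cell[1L]], "', prey '", params$prey[cell[2L]],
         "'", call. = FALSE)
  }
  sum(ll)
}

# ---- shifted gamma ---------------------------------------------------------

#' Moment-matched (shifted) gamma distribution
#'
#' `shifted_gamma_from_moments` converts a mean/variance/minimum triple to
#' gamma shape and scale for the distribution of `X = shift + G`,
#' `G ~ Gamma(shape, scale)`: `shape = (mean - shift)^2 / variance`,
#' `scale = variance / (mean - shift)`. The `d/p/q/r` functions take the
#' same moment parameterisation. The shape-exponent prior of the functional
#' response uses mean 2, variance 0.9, minimum 1, whose 95th percentile is
#' about 3.9.
#'
#' @param mean distribution mean; must exceed `shift`.
#' @param variance distribution variance, > 0.
#' @param shift lower bound of support (0 gives an ordinary gamma).
#' @return `shifted_gamma_from_moments`: list with `shape`, `scale`,
#'   `shift`. The d/p/q/r functions follow the usual conventions.
#' @examples
#' shifted_gamma_from_moments(2, 0.9, 1)
#' qsgamma(0.95, 2, 0.9, 1) # ~ 3.9
#' @export
shifted_gamma_from_moments <- function(mean, variance, shift = 0) {
  if (!is.finite(mean) || !is.finite(variance) || variance <= 0)
    stop("'variance' must be finite and > 0", call. = FALSE)
  if (mean <= shift)
    stop("'mean' must exceed 'shift'", call. = FALSE)
  list(shape = (mean - shift)^2 / variance,
       scale = variance / (mean - shift),
       shift = shift)
}

#' @rdname shifted_gamma_from_moments
#' @param x,q quantile; `p` probability; `n` draw count.
#' @param log,lower.tail as in [stats::dgamma].
#' @export
dsgamma <- function(x, mean, variance, shift = 0, log = FALSE) {
  g <- shifted_gamma_from_moments(mean, variance, shift)
  stats::dgamma(x - g$shift, shape = g$shape, scale = g$scale, log = log)
}

#' @rdname shifted_gamma_from_moments
#' @export
psgamma <- function(q, mean, variance, shift = 0, lower.tail = TRUE) {
  g <- shifted_gamma_from_moments(mean, variance, shift)
  stats::pgamma(q - g$shift, shape = g$shape, scale = g$scale,
                lower.tail = lower.tail)
}

#' @rdname shifted_gamma_from_moments
#' @export
qsgamma <- function(p, mean, variance, shift = 0) {
  g <- shifted_gamma_from_moments(mean, variance, shift)
  g$shift + stats::qgamma(p, shape = g$shape, scale = g$scale)
}

#' @rdname shifted_gamma_from_moments
#' @export
rsgamma <- function(n, mean, variance, shift = 0) {
  g <- shifted_gamma_from_moments(mean, variance, shift)
  g$shift + stats::rgamma(n, shape = g$shape, scale = g$scale)
}

# ---- priors ----------------------------------------------------------------

#' Prior specification for one parameter
#'
#' @param family `"gamma"` or `"shifted_gamma"`.
#' @param mean,variance prior moments.
#' @param shift minimum of support for `"shifted_gamma"` (ignored for
#'   `"gamma"`, where it is 0).
#' @return A `prior_spec` object (list with family and hyperparameters).
#' @export
prior_spec <- function(family = c("gamma", "shifted_gamma"),
                       mean, variance, shift = 0) {
  family <- match.arg(family)
  if (family == "gamma") shift <- 0
  shifted_gamma_from_moments(mean, variance, shift) # validates
  structure(list(family = family, mean = mean, variance = variance,
                 shift = shift), class = "prior_spec")
}

prior_logdens <- function(spec, x) {
  if (x <= spec$shift) return(-Inf)
  d <- dsgamma(x, spec$mean, spec$variance, spec$shift, log = TRUE)
  if (is.nan(d)) -Inf else d
}

prior_draw <- function(spec, n = 1L) {
  rsgamma(n, spec$mean, spec$variance, spec$shift)
}

#' Default priors for the MSFR fit
#'
#' One prior per parameter, as a named list keyed
#' `a_<prey>`, `t_<prey>`, `m_<prey>`, `k_<prey>` (or a single `k` when
#' `shared_k = TRUE`):
#' * attack rates `a_i`: gamma with mean 1, variance 0.99 (relatively
#'   uninformative);
#' * handling times `t_i`: gamma with mean 2 h, variance 2 (deliveries to
#'   the nest take a flight regardless of prey size);
#' * shape exponents `m_i`: shifted gamma, minimum 1, mean 2, variance 0.9
#'   (95th percentile 3.9), excluding implausible `m < 1`;
#' * dispersions `k_i`: gamma with mean 1, variance 10, weakly informative.
#'
#' Any entry can be replaced before fitting.
#'
#' @param prey character vector of prey names.
#' @param shared_k if `TRUE` a single dispersion parameter `k` is shared by
#'   all prey.
#' @return Named list of [prior_spec] objects.
#' @export
default_priors <- function(prey, shared_k = FALSE) {
  pri <- list()
  for (p in prey) pri[[paste0("a_", p)]] <- prior_spec("gamma", 1, 0.99)
  for (p in prey) pri[[paste0("t_", p)]] <- prior_spec("gamma", 2, 2)
  for (p in prey) pri[[paste0("m_", p)]] <-
    prior_spec("shifted_gamma", 2, 0.9, shift = 1)
  if (shared_k) pri[["k"]] <- prior_spec("gamma", 1, 10)
  else for (p in prey) pri[[paste0("k_", p)]] <- prior_spec("gamma", 1, 10)
  pri
}

#' Log prior density of a named parameter vector
#'
#' Sum of the per-parameter log densities. Values outside a prior's support
#' give `-Inf` (a value, not an error, so the sampler auto-rejects).
#'
#' @param theta named numeric vector; names must match `priors`.
#' @param priors named list of [prior_spec] objects.
#' @param extra_log_prior optional `function(theta) -> scalar` adding a
#'   joint term (e.g. a user-supplied joint prior on `a_grouse` and
#'   `m_grouse` reconstructed from attack-rate observations).
#' @return Scalar log prior density.
#' @export
log_prior <- function(theta, priors, extra_log_prior = NULL) {
  if (!setequal(names(theta), names(priors)))
    stop("parameter names do not match prior names", call. = FALSE)
  lp <- 0
  for (nm in names(theta)) {
    lp <- lp + prior_logdens(priors[[nm]], theta[[nm]])
    if (lp == -Inf) return(-Inf)
  }
  if (!is.null(extra_log_prior)) lp <- lp + extra_log_prior(theta)
  lp
}

# ---- posterior assembly ----------------------------------------------------

#' Parameter-vector layout for a fit
#'
#' @keywords internal
param_names <- function(prey, shared_k = FALSE) {
  c(paste0("a_", prey), paste0("t_", prey), paste0("m_", prey),
    if (shared_k) "k" else paste0("k_", prey))
}

theta_to_params <- function(theta, prey, shared_k = FALSE) {
  list(params = msfr_params(a = theta[paste0("a_", prey)],
                            t = theta[paste0("t_", prey)],
                            m = theta[paste0("m_", prey)],
                            prey = prey),
       k = if (shared_k) rep(theta[["k"]], length(prey))
           else unname(theta[paste0("k_", prey)]))
}

#' Build the unnormalised log-posterior of an MSFR fit
#'
#' Composes [log_likelihood] and [log_prior] over the packed parameter
#' vector `(a_i, t_i, m_i, k_i)`; the returned closure is what the sampler
#' targets. Parameter values violating support constraints yield `-Inf`.
#'
#' @inheritParams log_likelihood
#' @param priors named list of [prior_spec]s, defaults to
#'   [default_priors] for the data's prey.
#' @param shared_k share one dispersion parameter across prey.
#' @param extra_log_prior optional joint log-prior hook, see [log_prior].
#' @return `function(theta)` mapping a named parameter vector to the
#'   unnormalised log posterior, with attributes `param_names` and
#'   `priors`.
#' @export
make_log_posterior <- function(data, priors = NULL, shared_k = FALSE,
                               extra_log_prior = NULL) {
  stopifnot(inherits(data, "msfr_data"))
  if (is.null(priors)) priors <- default_priors(data$prey, shared_k)
  pn <- param_names(data$prey, shared_k)
  if (!setequal(names(priors), pn))
    stop("priors must cover exactly: ", paste(pn, collapse = ", "),
         call. = FALSE)
  prey <- data$prey
  P <- length(prey)
  if (is.null(data$counts))
    stop("data set has no counts; simulate or load them first",
         call. = FALSE)
  S <- nrow(data$counts)
  # precomputed pieces for a fast closure: the sampler evaluates this
  # hundreds of thousands of times, so no object construction per call
  pri_shape <- vapply(priors[pn], function(s)
    shifted_gamma_from_moments(s$mean, s$variance, s$shift)$shape,
    numeric(1L))
  pri_scale <- vapply(priors[pn], function(s)
    shifted_gamma_from_moments(s$mean, s$variance, s$shift)$scale,
    numeric(1L))
  pri_shift <- vapply(priors[pn], function(s) s$shift, numeric(1L))
  logN <- log(data$densities)            # -Inf at N = 0; exp(m * -Inf) = 0
  yvec <- as.vector(data$counts)
  effort <- data$effort
  ia <- seq_len(P); it <- P + ia; im <- 2L * P + ia
  ik <- if (shared_k) rep.int(3L * P + 1L, P) else 3L * P + ia

  f <- function(theta) {
    if (!is.null(names(theta))) theta <- theta[pn]
    x <- theta - pri_shift
    if (any(x <= 0)) return(-Inf)
    lp <- sum(stats::dgamma(x, shape = pri_shape, scale = pri_scale,
                            log = TRUE))
    if (!is.finite(lp)) return(-Inf)
    if (!is.null(extra_log_prior)) {
      lp <- lp + extra_log_prior(theta[pn])
      if (!is.finite(lp)) return(-Inf)
    }
    if (S == 0L) return(lp)
    av <- theta[ia]; tv <- theta[it]; mv <- theta[im]; kv <- theta[ik]
    W <- exp(logN * rep(mv, each = S)) * rep(av, each = S)
    dim(W) <- c(S, P)
    mu <- (W / (1 + drop(W %*% tv))) * effort
    # overflow of N^m at extreme proposals = outside numeric support
    if (any(!is.finite(mu))) return(-Inf)
    lp + sum(stats::dnbinom(yvec, size = rep(kv, each = S),
                            mu = as.vector(mu), log = TRUE))
  }
  attr(f, "param_names") <- pn
  attr(f, "priors") <- priors
  attr(f, "shared_k") <- shared_k
  f
}
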