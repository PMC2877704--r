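#' Logistic recruitment model
#'
#' Per-capita recruitment of the focal prey in the absence of predation:
#' `recruitment(N) = r (1 - N/K)`, linear in density and zero at the
#' predator-free equilibrium density `K` (208 chicks per km^2 for the
#' grouse system).
#'
#' @param r maximum per-capita recruitment rate, per season, > 0. The
#'   default 1 puts the recruitment line on the same order as seasonal
#'   mortality curves; it is a display/scenario constant, not an estimate.
#' @param K predator-free equilibrium density, > 0.
#' @return A `recruitment_model` object with a `rate(N)` closure.
#' @export
recruitment_model <- function(r = 1, K = 208) {
  check_positive(c(r, K), "r/K")
  structure(list(r = r, K = K,
                 rate = function(N) r * (1 - N / K)),
            class = "recruitment_model")
}

#' Predation scenario for the equilibrium analysis
#'
#' Fixes everything except the focal prey's density: the densities of the
#' alternative prey, the predator density, and the constants converting an
#' hourly per-individual delivery rate to a seasonal per-pair mortality
#' rate.
#'
#' @param alt_densities named numeric vector of alternative-prey densities
#'   (all prey except the focal one).
#' @param focal focal prey name (default `"grouse"`).
#' @param predator_density predator pairs per km^2 (study-site typical
#'   value 0.16).
#' @param effort_scale hunting hours per season; default 336 = 8 h/day x
#'   42-day chick season.
#' @param per_pair_multiplier deliveries-per-individual to per-pair scale
#'   factor (default 1).
#' @param n_grid grid points for the root scan.
#' @param margin grid extends to `K * (1 + margin)`.
#' @return A `scenario` object.
#' @export
scenario <- function(alt_densities, focal = "grouse",
                     predator_density = 0.16, effort_scale = 336,
                     per_pair_multiplier = 1, n_grid = 2000L,
                     margin = 0.05) {
  check_nonnegative(alt_densities, "alt_densities")
  check_nonnegative(predator_density, "predator_density")
  stopifnot(n_grid >= 10L, margin > 0)
  structure(list(alt_densities = alt_densities, focal = focal,
                 predator_density = predator_density,
                 effort_scale = effort_scale,
                 per_pair_multiplier = per_pair_multiplier,
                 n_grid = as.integer(n_grid), margin = margin),
            class = "scenario")
}

full_density_vector <- function(N_focal, params, sc) {
  N <- numeric(params$n_prey)
  names(N) <- params$prey
  alt <- sc$alt_densities
  if (length(alt)) {
    if (is.null(names(alt)) && length(alt) == params$n_prey - 1L)
      names(alt) <- setdiff(params$prey, sc$focal)
    N[names(alt)] <- alt
  }
  N[sc$focal] <- N_focal
  N
}

mortality_at <- function(N_focal, params, sc) {
  per_capita_mortality(full_density_vector(N_focal, params, sc), params,
                       focal = sc$focal,
                       predator_density = sc$predator_density,
                       effort_scale = sc$effort_scale,
                       per_pair_multiplier = sc$per_pair_multiplier)
}

# vectorized mortality over a positive focal-density grid
mortality_over_grid <- function(grid, params, sc) {
  Nmat <- matrix(rep(full_density_vector(1, params, sc), each = length(grid)),
                 length(grid), params$n_prey,
                 dimnames = list(NULL, params$prey))
  Nmat[, sc$focal] <- grid
  F <- msfr_response(Nmat, params)[, sc$focal]
  sc$predator_density * sc$effort_scale * sc$per_pair_multiplier * F / grid
}

#' Per-capita mortality curve over a density grid
#'
#' Seasonal predator-induced per-capita mortality of the focal prey as a
#' function of its own density, with alternative prey fixed by the
#' scenario. When `chains` is supplied, one curve per (thinned) posterior
#' draw is returned — the uncertainty fan around the posterior-mean curve.
#'
#' @param params an [msfr_params] object.
#' @param sc a [scenario].
#' @param grid positive density grid (default 200 points up to
#'   `K * (1 + margin)` requires `recruitment`).
#' @param recruitment optional [recruitment_model], used only to build the
#'   default grid.
#' @param chains optional `msfr_chains`; draws are thinned to `n_draws`.
#' @param n_draws curves to draw from the chain.
#' @return `data.frame(N, mortality)`; with chains, a matrix of curves
#'   (grid x draw) carried in column `mortality_draws`.
#' @export
mortality_curve <- function(params, sc, grid = NULL, recruitment = NULL,
                            chains = NULL, n_draws = 100L) {
  if (is.null(grid)) {
    if (is.null(recruitment))
      stop("supply 'grid' or a recruitment model to derive it from",
           call. = FALSE)
    grid <- seq(recruitment$K * 1e-6, recruitment$K * (1 + sc$margin),
                length.out = 200L)
  }
  check_positive(grid, "grid")
  if (is.null(chains)) {
    return(data.frame(N = grid,
                      mortality = mortality_over_grid(grid, params, sc)))
  }
  idx <- unique(round(seq(1L, nrow(chains$draws),
                          length.out = min(n_draws, nrow(chains$draws)))))
  fan <- vapply(idx, function(i) {
    pk <- theta_to_params(chains$draws[i, ], chains$prey, chains$shared_k)
    mortality_over_grid(grid, pk$params, sc)
  }, numeric(length(grid)))
  out <- data.frame(N = grid)
  out$mortality_draws <- fan
  out
}

#' Locate and classify prey-density equilibria
#'
#' Scans `g(N) = recruitment(N) - mortality(N)` on a grid over
#' `(0, K (1 + margin)]`, brackets every sign change, refines each root by
#' bisection to relative tolerance 1e-8, and classifies stability from the
#' sign of `g` on either side: an equilibrium is stable when the
#' population grows below it (`g > 0`) and shrinks above it (`g < 0`).
#' A "predator pit" is present when at least three interior equilibria
#' exist and the lowest is stable — a stable low-density state separated
#' from the high-density state by an unstable threshold.
#'
#' Grid values that are exactly zero without an accompanying sign change
#' are reported as tangential contacts and do not count towards the pit
#' predicate.
#'
#' @param params an [msfr_params] object.
#' @param sc a [scenario].
#' @param recruitment a [recruitment_model].
#' @return An `equilibrium_set`: `data.frame` `equilibria` with columns
#'   `N`, `stability` (`"stable"`/`"unstable"`/`"tangential"`) and
#'   `residual`, plus `pit_present` and the scenario constants used.
#' @export
find_equilibria <- function(params, sc, recruitment) {
  stopifnot(inherits(recruitment, "recruitment_model"))
  g <- function(N) recruitment$rate(N) - mortality_at(N, params, sc)
  K <- recruitment$K
  grid <- seq(K * 1e-6, K * (1 + sc$margin), length.out = sc$n_grid)
  gv <- recruitment$rate(grid) - mortality_over_grid(grid, params, sc)

  roots <- numeric(0); stab <- character(0)
  sgn <- sign(gv)
  for (i in seq_len(length(grid) - 1L)) {
    if (sgn[i] == 0) next                     # handled as grid root below
    if (sgn[i + 1L] != 0 && sgn[i] != sgn[i + 1L]) {
      r <- stats::uniroot(g, lower = grid[i], upper = grid[i + 1L],
                          tol = K * 1e-8)$root
      roots <- c(roots, r)
      stab <- c(stab, if (sgn[i] > 0) "stable" else "unstable")
    }
  }
  zi <- which(sgn == 0)
  for (i in zi) {
    lo <- if (i > 1L) sgn[i - 1L] else NA_real_
    hi <- if (i < length(sgn)) sgn[i + 1L] else NA_real_
    s <- if (!is.na(lo) && !is.na(hi) && lo > 0 && hi < 0) "stable"
    else if (!is.na(lo) && !is.na(hi) && lo < 0 && hi > 0) "unstable"
    else "tangential"
    roots <- c(roots, grid[i]); stab <- c(stab, s)
  }
  o <- order(roots)
  eq <- data.frame(N = roots[o], stability = stab[o],
                   residual = abs(vapply(roots[o], g, numeric(1L))))
  counted <- eq[eq$stability != "tangential", , drop = FALSE]
  pit <- nrow(counted) >= 3L && counted$stability[1L] == "stable"
  structure(list(equilibria = eq, pit_present = pit,
                 scenario = sc, recruitment = list(r = recruitment$r,
                                                   K = recruitment$K)),
            class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("equilibria (predator pit:", x$pit_present, ")\n")
  print(x$equilibria)
  invisible(x)
}

#' Posterior probability of a predator pit
#'
#' Resamples parameter draws from the posterior chain (with replacement,
#' seeded), runs the equilibrium analysis for each, and reports the
#' fraction of draws whose mortality curve produces a predator pit, along
#' with the distribution of equilibrium counts across draws.
#'
#' @param chains an `msfr_chains` object from an MSFR fit.
#' @param sc a [scenario].
#' @param recruitment a [recruitment_model].
#' @param n_draws posterior resamples.
#' @param seed resampling seed.
#' @param prey,shared_k parameter layout; defaults from the chain.
#' @return List: `probability`, `n_draws`, `equilibrium_counts` (table of
#'   counted-equilibria numbers across draws).
#' @export
pit_probability <- function(chains, sc, recruitment, n_draws = 500L,
                            seed = 1L, prey = chains$prey,
                            shared_k = isTRUE(chains$shared_k)) {
  stopifnot(inherits(chains, "msfr_chains"), nrow(chains$draws) > 0L)
  set.seed(seed)
  idx <- sample.int(nrow(chains$draws), n_draws, replace = TRUE)
  res <- vapply(idx, function(i) {
    pk <- theta_to_params(chains$draws[i, ], prey, shared_k)
    es <- find_equilibria(pk$params, sc, recruitment)
    counted <- es$equilibria$stability != "tangential"
    c(pit = es$pit_present, n_eq = sum(counted))
  }, numeric(2L))
  list(probability = mean(res["pit", ]),
       n_draws = n_draws,
       equilibrium_counts = table(res["n_eq", ]))
}
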