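#' Functional-response parameter set
#'
#' Container for the parameters of the generalised (Holling-family)
#' functional response, one triplet per prey species: attack-rate
#' coefficient `a`, handling time `t` (hours per item, so `1/t` is the
#' asymptotic consumption rate), and shape exponent `m` (`m = 1` gives a
#' hyperbolic Type 2 response, `m > 1` a sigmoidal Type 3 response with
#' density-dependent attack). Densities are treated as opaque prey-specific
#' indices; `a` absorbs any proportionality constant between an index and
#' true abundance, so no unit conversion is attempted.
#'
#' Shape exponents below 1 would imply attack rates that *fall* as a prey
#' becomes more abundant (all else equal), which is biologically
#' implausible; the constructor therefore rejects `m < 1` outright.
#'
#' @param a numeric vector of attack-rate coefficients, one per prey; all > 0.
#' @param t numeric vector of handling times in hours per item; all >= 0.
#' @param m numeric vector of shape exponents; all >= 1.
#' @param prey optional character vector of prey names; defaults to
#'   `names(a)` or `prey1, prey2, ...`.
#'
#' @return An object of class `msfr_params`: a list with elements `a`, `t`,
#'   `m` (named numeric vectors), `prey`, and `n_prey`.
#' @examples
#' table1_msfr_params()
#' msfr_params(a = 2, t = 0.5, m = 1, prey = "vole")
#' @export
msfr_params <- function(a, t, m, prey = NULL) {
  if (is.null(prey)) prey <- names(a)
  a <- as.numeric(a); t <- as.numeric(t); m <- as.numeric(m)
  n <- length(a)
  if (n < 1L) stop("at least one prey species is required", call. = FALSE)
  if (length(t) != n || length(m) != n)
    stop("'a', 't' and 'm' must have one entry per prey species", call. = FALSE)
  check_positive(a, "a")
  check_nonnegative(t, "t")
  if (any(!is.finite(m)) || any(m < 1))
    stop("shape exponent 'm' must be finite and >= 1 for every prey", call. = FALSE)
  if (is.null(prey)) prey <- paste0("prey", seq_len(n))
  if (length(prey) != n) stop("'prey' must name every species", call. = FALSE)
  names(a) <- names(t) <- names(m) <- prey
  structure(list(a = a, t = t, m = m, prey = prey, n_prey = n),
            class = "msfr_params")
}

#' @export
print.msfr_params <- function(x, ...) {
  cat("Multispecies functional response parameters (", x$n_prey,
      " prey)\n", sep = "")
  print(data.frame(prey = x$prey, a = x$a, t = x$t, m = x$m,
                   max_rate = ifelse(x$t > 0, 1 / x$t, Inf),
                   row.names = NULL))
  invisible(x)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("'", name, "' must be finite and > 0", call. = FALSE)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("'", name, "' must be finite and >= 0", call. = FALSE)
  invisible(x)
}

#' Generalised single-species functional response
#'
#' Per-predator consumption rate `F = a N^m / (1 + a t N^m)` at prey
#' density `N`. Special cases: `m = 1, t = 0` linear (Type 1); `m = 1,
#' t > 0` hyperbolic (Type 2); `m > 1` sigmoidal (Type 3). For `t > 0` the
#' rate saturates at the handling-time ceiling `1/t` as `N` grows.
#'
#' @param N prey density index, >= 0 (vectorised).
#' @param a attack-rate coefficient, > 0.
#' @param t handling time, hours per item, >= 0.
#' @param m shape exponent, >= 1.
#' @return Consumption rate in items per hour, same length as `N`.
#' @examples
#' single_species_response(10, a = 0.00164, t = 0.325, m = 1.09)
#' @export
single_species_response <- function(N, a, t, m) {
  check_nonnegative(N, "N")
  check_positive(a, "a")
  check_nonnegative(t, "t")
  if (!is.finite(m) || m < 1) stop("'m' must be finite and >= 1", call. = FALSE)
  w <- a * N^m
  w / (1 + t * w)
}

#' Multispecies functional response
#'
#' Consumption rate of each prey species given the densities of all prey:
#' `F_i = a_i N_i^{m_i} / (1 + sum_j a_j t_j N_j^{m_j})`. All prey share
#' the handling-time denominator, so the total handling-time budget
#' `sum_j t_j F_j` is always below 1: raising the density of one prey
#' depresses consumption of every other prey.
#'
#' @param N numeric vector of prey density indices (one per prey), or a
#'   matrix with one row per observation and one column per prey.
#' @param params an [msfr_params] object.
#' @return Consumption rates in items per hour: a named vector if `N` is a
#'   vector, else a matrix of the same shape as `N`.
#' @examples
#' p <- table1_msfr_params()
#' msfr_response(c(grouse = 100, pipit = 9, vole = 1), p)
#' @export
msfr_response <- function(N, params) {
  stopifnot(inherits(params, "msfr_params"))
  vec <- is.null(dim(N))
  Nm <- if (vec) matrix(N, nrow = 1L) else as.matrix(N)
  if (ncol(Nm) != params$n_prey)
    stop("density vector has ", ncol(Nm), " entries but params describe ",
         params$n_prey, " prey", call. = FALSE)
  check_nonnegative(Nm, "N")
  W <- sweep(Nm, 2L, params$m, `^`)
  W <- sweep(W, 2L, params$a, `*`)          # a_j N_j^m_j
  denom <- 1 + drop(W %*% params$t)
  F <- W / denom
  colnames(F) <- params$prey
  if (vec) F[1L, ] else F
}

#' Per-capita predation mortality index
#'
#' Mortality pressure on a focal prey from a predator population:
#' `predator_density * effort_scale * F_focal / N_focal`. With unit
#' predator density and effort scale this is the raw gradient `F/N` of the
#' functional response. `effort_scale` converts the hourly consumption rate
#' to the seasonal time base of a recruitment rate; the default used by the
#' equilibrium analysis is 336 h (8 h of hunting per day over a 42-day
#' chick season) since no canonical value exists for this conversion.
#'
#' @param N prey density vector (one entry per prey); the focal entry must
#'   be > 0.
#' @param params an [msfr_params] object.
#' @param focal index or name of the focal prey.
#' @param predator_density predators (pairs) per km^2.
#' @param effort_scale hunting hours per season.
#' @param per_pair_multiplier scales deliveries per observed individual to
#'   the per-pair rate (default 1, i.e. the fitted rate is used as-is).
#' @return Mortality index, per season (or per hour when
#'   `effort_scale = 1`).
#' @export
per_capita_mortality <- function(N, params, focal,
                                 predator_density = 1,
                                 effort_scale = 1,
                                 per_pair_multiplier = 1) {
  if (is.character(focal)) focal <- match(focal, params$prey)
  if (is.na(focal) || focal < 1 || focal > params$n_prey)
    stop("'focal' does not identify a prey species", call. = FALSE)
  if (N[focal] <= 0)
    stop("mortality index is undefined at zero focal-prey density (N_",
         params$prey[focal], " = 0)", call. = FALSE)
  check_nonnegative(c(predator_density, effort_scale, per_pair_multiplier),
                    "predator_density/effort_scale/per_pair_multiplier")
  F <- msfr_response(N, params)
  unname(predator_density * effort_scale * per_pair_multiplier *
           F[focal] / N[focal])
}

#' Posterior-mean MSFR parameters for the hen harrier system
#'
#' The multispecies posterior means for hen harriers preying on red grouse
#' chicks, meadow pipits and field voles: the default "truth" of the
#' synthetic-data generator and a convenient realistic parameter set.
#' Handling times imply maximum consumption rates of 0.365 (grouse),
#' 0.597 (pipit) and 0.431 (vole) items per hour.
#'
#' @return An [msfr_params] object for prey `c("grouse", "pipit", "vole")`.
#' @export
table1_msfr_params <- function() {
  msfr_params(a = c(grouse = 0.000673, pipit = 1.904, vole = 3.78),
              t = c(grouse = 2.74, pipit = 1.676, vole = 2.32),
              m = c(grouse = 2.51, pipit = 1.18, vole = 1.14))
}

#' Posterior-mean single-species parameters for grouse
#'
#' Single-species fit treating grouse-chick consumption as a function of
#' grouse density alone; the handling time 0.325 h implies an (extrapolated)
#' asymptotic consumption rate of about 3 items per hour.
#'
#' @return An [msfr_params] object with one prey, `"grouse"`.
#' @export
table1_single_species_params <- function() {
  msfr_params(a = c(grouse = 0.00164), t = 0.325, m = 1.09)
}
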