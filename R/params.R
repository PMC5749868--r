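#' @keywords internal
stop_invalid <- function(...) {
  stop(structure(
    class = c("crispropt_invalid", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @keywords internal
stop_capacity <- function(...) {
  stop(structure(
    class = c("crispropt_capacity", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'", name, "' must be a single finite number")
  as.numeric(x)
}

#' Raw kinetic constants of CRISPR interference
#'
#' Bundles the dimensional constants of effector-target binding and viral DNA
#' degradation: the association rate `k_plus` (per concentration per time), the
#' dissociation rate `k_minus` (per time), the total effector copy number `C`,
#' the viral DNA degradation rate `a` (per time) and the effective interference
#' window `tau` (time), roughly the duration of the first round of viral DNA
#' replication. They reduce to the two dimensionless parameters actually used
#' by the model: the binding efficiency `beta = C * k_plus / k_minus` and the
#' interference efficiency `chi = tau * a`.
#'
#' @param k_plus association rate constant, > 0.
#' @param k_minus dissociation rate constant, > 0.
#' @param C total effector complex copy number, > 0.
#' @param a viral DNA degradation rate constant, > 0.
#' @param tau effective interference time, > 0.
#' @return An object of class `kinetic_constants`.
#' @seealso [crispr_params()] for the dimensionless reduction.
#' @examples
#' k <- kinetic_constants(k_plus = 1, k_minus = 1, C = 1, a = 0.7, tau = 2)
#' crispr_params(beta = with(k, C * k_plus / k_minus), chi = with(k, tau * a),
#'               mu = 0.9, rnt = 5)
#' @export
kinetic_constants <- function(k_plus, k_minus, C, a, tau) {
  vals <- list(k_plus = check_scalar(k_plus, "k_plus"),
               k_minus = check_scalar(k_minus, "k_minus"),
               C = check_scalar(C, "C"),
               a = check_scalar(a, "a"),
               tau = check_scalar(tau, "tau"))
  if (any(unlist(vals) <= 0))
    stop_invalid("all kinetic constants must be strictly positive")
  structure(vals, class = "kinetic_constants")
}

#' Dimensionless model parameters
#'
#' The four dimensionless parameters that fully determine single-virus
#' survival: binding efficiency `beta` (single-target occupancy scale,
#' `C k+ / k-`), interference efficiency `chi` (degradation rate times
#' interference window, `tau * a`), the per-acquisition-interval probability
#' `mu` that a protospacer remains mutation-free, and `rnt`, the expected
#' number of infections over the observation window.
#'
#' @param beta binding efficiency, > 0.
#' @param chi interference efficiency, >= 0.
#' @param mu protospacer non-mutation probability per acquisition interval,
#'   in \[0, 1\].
#' @param rnt expected number of infections, >= 0.
#' @return An object of class `crispr_params`.
#' @examples
#' crispr_params(beta = 1, chi = 1.4, mu = 0.9, rnt = 5)
#' @export
crispr_params <- function(beta, chi, mu, rnt) {
  beta <- check_scalar(beta, "beta"); chi <- check_scalar(chi, "chi")
  mu <- check_scalar(mu, "mu"); rnt <- check_scalar(rnt, "rnt")
  if (beta <= 0) stop_invalid("'beta' must be > 0")
  if (chi < 0) stop_invalid("'chi' must be >= 0")
  if (mu < 0 || mu > 1) stop_invalid("'mu' must lie in [0, 1]")
  if (rnt < 0) stop_invalid("'rnt' must be >= 0")
  structure(list(beta = beta, chi = chi, mu = mu, rnt = rnt),
            class = "crispr_params")
}

#' @export
print.crispr_params <- function(x, ...) {
  cat(sprintf("CRISPR model parameters: beta = %g, chi = %g, mu = %g, rNt = %g\n",
              x$beta, x$chi, x$mu, x$rnt))
  invisible(x)
}

#' CRISPR array model
#'
#' An array is described by its spacer count `S` and the crRNA decay
#' coefficient `delta`: each successively older spacer is `delta` times less
#' likely to charge an effector complex than its younger neighbour. Spacers
#' are indexed by age, position 1 being the most recently acquired.
#' `delta = 1` is the uniform-allocation limit (every spacer gets `C/S`
#' effectors); `delta = 0` is degenerate and rejected.
#'
#' @param S number of spacers, integer >= 1.
#' @param delta crRNA decay coefficient in (0, 1].
#' @return An object of class `crispr_array`.
#' @examples
#' crispr_array(S = 6, delta = 0.7)
#' @export
crispr_array <- function(S, delta) {
  S <- check_scalar(S, "S"); delta <- check_scalar(delta, "delta")
  if (S < 1 || S != round(S)) stop_invalid("'S' must be an integer >= 1")
  if (delta <= 0 || delta > 1) stop_invalid("'delta' must lie in (0, 1]")
  structure(list(S = as.integer(S), delta = delta), class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("CRISPR array: S = %d spacers, crRNA decay delta = %g\n",
              x$S, x$delta))
  invisible(x)
}

#' Default per-spacer non-mutation probabilities
#'
#' Under periodic spacer acquisition the protospacer matching spacer `i`
#' (age-ordered) has had roughly `i - 1/2` acquisition intervals to mutate,
#' assessed mid-interval, so its probability of remaining recognizable is
#' `mu^(i - 1/2)`. Callers may replace this schedule with any vector in
#' \[0, 1\], e.g. to model conserved protospacers that mutate more slowly.
#'
#' @param mu per-interval non-mutation probability in \[0, 1\].
#' @param S number of spacers.
#' @return Numeric vector of length `S`, entries in \[0, 1\].
#' @examples
#' mutation_profile(0.9, 3)
#' @export
mutation_profile <- function(mu, S) {
  mu <- check_scalar(mu, "mu")
  if (mu < 0 || mu > 1) stop_invalid("'mu' must lie in [0, 1]")
  S <- as.integer(check_scalar(S, "S"))
  mu^(seq_len(S) - 0.5)
}

check_mutation_vector <- function(m, S) {
  if (!is.numeric(m) || any(!is.finite(m)))
    stop_invalid("mutation vector must be numeric and finite")
  if (length(m) != S)
    stop_invalid("mutation vector has length ", length(m),
                 " but the array has S = ", S, " spacers")
  if (any(m < 0 | m > 1)) stop_invalid("mutation probabilities must lie in [0, 1]")
  as.numeric(m)
}

#' Viral pool composition
#'
#' Relative abundances of the distinct viral species a cell is exposed to.
#' Fractions must be strictly positive and sum to 1; drop zero-abundance
#' species before construction.
#'
#' @param v numeric vector of species fractions.
#' @return An object of class `viral_pool` with fields `v` and `nu`
#'   (species count).
#' @examples
#' viral_pool(c(0.5, 0.5))
#' @export
viral_pool <- function(v) {
  if (!is.numeric(v) || length(v) < 1L || any(!is.finite(v)))
    stop_invalid("'v' must be a non-empty finite numeric vector")
  if (any(v <= 0)) stop_invalid("species fractions must be strictly positive")
  if (abs(sum(v) - 1) > 1e-12)
    stop_invalid("species fractions must sum to 1 (got ", format(sum(v)), ")")
  structure(list(v = as.numeric(v), nu = length(v)), class = "viral_pool")
}

#' @export
print.viral_pool <- function(x, ...) {
  cat(sprintf("Viral pool: %d species, fractions %s\n", x$nu,
              paste(signif(x$v, 4), collapse = ", ")))
  invisible(x)
}

#' Spacer-to-species assignment
#'
#' Maps every spacer position (age-ordered, youngest first) to the index of
#' the viral species it was acquired from.
#'
#' @param species_of integer vector of length `S`; entries in `1..nu`.
#' @param nu number of species in the pool the assignment refers to.
#' @return An object of class `spacer_assignment`.
#' @examples
#' spacer_assignment(c(1, 2, 2), nu = 2)
#' @export
spacer_assignment <- function(species_of, nu) {
  nu <- as.integer(check_scalar(nu, "nu"))
  if (!is.numeric(species_of) || length(species_of) < 1L)
    stop_invalid("'species_of' must be a non-empty integer vector")
  species_of <- as.integer(species_of)
  if (any(is.na(species_of)) || any(species_of < 1L) || any(species_of > nu))
    stop_invalid("species indices must lie in 1..", nu)
  structure(list(species_of = species_of, nu = nu), class = "spacer_assignment")
}

#' Averaging plan for multi-virus survival
#'
#' Controls how the assignment-averaged survival is computed: `"exact"`
#' enumerates all `nu^S` spacer-to-species assignments, `"montecarlo"` samples
#' assignments position-wise from the pool fractions (the acquisition
#' distribution itself, so the estimator is unweighted), `"auto"` picks exact
#' enumeration when `nu^S <= max_exact` and Monte Carlo otherwise.
#'
#' @param mode one of `"auto"`, `"exact"`, `"montecarlo"`.
#' @param max_exact cap on the number of assignments enumerated exactly.
#' @param n_samples Monte-Carlo sample count.
#' @param seed integer seed; mandatory for reproducible Monte-Carlo runs.
#' @return An object of class `averaging_plan`.
#' @examples
#' averaging_plan("montecarlo", n_samples = 1e5, seed = 42)
#' @export
averaging_plan <- function(mode = c("auto", "exact", "montecarlo"),
                           max_exact = 2^20, n_samples = 2e5, seed = 1L) {
  mode <- match.arg(mode)
  max_exact <- check_scalar(max_exact, "max_exact")
  n_samples <- as.integer(check_scalar(n_samples, "n_samples"))
  if (n_samples < 1L) stop_invalid("'n_samples' must be >= 1")
  seed <- as.integer(check_scalar(seed, "seed"))
  structure(list(mode = mode, max_exact = max_exact,
                 n_samples = n_samples, seed = seed),
            class = "averaging_plan")
}

#' Grid specification for array optimization
#'
#' @param S_min,S_max integer bounds on the spacer count, `1 <= S_min <= S_max`.
#' @param delta_values strictly increasing grid of crRNA decay coefficients in
#'   (0, 1]. The default resolves delta to 0.01 and includes the uniform limit
#'   delta = 1.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(1, 30)
#' @export
grid_spec <- function(S_min = 1L, S_max = 30L,
                      delta_values = c(seq(0.01, 0.99, by = 0.01), 1)) {
  S_min <- as.integer(check_scalar(S_min, "S_min"))
  S_max <- as.integer(check_scalar(S_max, "S_max"))
  if (S_min < 1L || S_min > S_max) stop_invalid("need 1 <= S_min <= S_max")
  if (!is.numeric(delta_values) || length(delta_values) < 1L ||
      any(delta_values <= 0) || any(delta_values > 1) ||
      is.unsorted(delta_values, strictly = TRUE))
    stop_invalid("'delta_values' must be strictly increasing within (0, 1]")
  structure(list(S_min = S_min, S_max = S_max,
                 delta_values = as.numeric(delta_values)),
            class = "grid_spec")
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
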