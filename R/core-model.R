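#' Geometric allocation of effector complexes across spacers
#'
#' Distributes the `C` effector complexes of a cell over the `S` spacers of an
#' array. The share of spacer `i` (age-ordered, youngest = 1) decays
#' geometrically with the crRNA decay coefficient:
#' `C_i = C * delta^(i-1) * (1 - delta) / (1 - delta^S)`, normalised so the
#' shares sum to `C`. At `delta = 1` the analytic limit `C_i = C / S` applies.
#'
#' @param C total effector copy number, > 0.
#' @param arr a [crispr_array()].
#' @return Numeric vector of length `arr$S`; entries sum to `C`.
#' @examples
#' effector_allocation(90, crispr_array(2, 0.5))  # 60, 30
#' @export
effector_allocation <- function(C, arr) {
  C <- check_scalar(C, "C")
  if (C <= 0) stop_invalid("'C' must be > 0")
  if (!inherits(arr, "crispr_array")) arr <- do.call(crispr_array, as.list(arr))
  i <- seq_len(arr$S)
  if (arr$delta == 1) rep(C / arr$S, arr$S)
  else C * arr$delta^(i - 1) * (1 - arr$delta) / (1 - arr$delta^arr$S)
}

#' Steady-state occupancy of a protospacer from raw kinetics
#'
#' The steady state of the binding/dissociation kinetics
#' `dB/dt = k+ (1 - B) C_i - k- B` gives the fraction of time the protospacer
#' is occupied by a matching effector: `B = k+ C_i / (k+ C_i + k-)`. With no
#' effectors carrying the spacer (`Ci = 0`) the occupancy is 0.
#'
#' @param k a [kinetic_constants()] object (only `k_plus` and `k_minus` are
#'   used).
#' @param Ci copy number of effectors charged with this spacer's crRNA, >= 0.
#' @return Occupancy in \[0, 1).
#' @examples
#' k <- kinetic_constants(1, 1, 1, 1, 1)
#' occupancy_from_kinetics(k, 1)  # 0.5
#' @export
occupancy_from_kinetics <- function(k, Ci) {
  if (!inherits(k, "kinetic_constants"))
    stop_invalid("'k' must be a kinetic_constants object")
  if (!is.numeric(Ci) || any(!is.finite(Ci)) || any(Ci < 0))
    stop_invalid("'Ci' must be non-negative and finite")
  k$k_plus * Ci / (k$k_plus * Ci + k$k_minus)
}

#' Per-spacer binding probabilities of a CRISPR array
#'
#' Combines geometric effector allocation with steady-state occupancy into the
#' closed form
#' `B_i = [1 + (1/beta) * delta^(1-i) * (1 - delta^S) / (1 - delta)]^-1`,
#' with the uniform limit `B_i = [1 + S/beta]^-1` at `delta = 1`. For a
#' single-spacer array this reduces to `B = 1 / (1 + 1/beta)` independent of
#' `delta`; at `beta = 1` that is exactly 1/2.
#'
#' @param p a [crispr_params()] (only `beta` is used).
#' @param arr a [crispr_array()].
#' @return Numeric vector of length `arr$S` with entries in (0, 1),
#'   non-increasing in the age index when `delta < 1`.
#' @examples
#' binding_profile(crispr_params(1, 1.4, 0.9, 5), crispr_array(2, 0.5))
#' @export
binding_profile <- function(p, arr) {
  if (!inherits(p, "crispr_params")) stop_invalid("'p' must be a crispr_params object")
  if (!inherits(arr, "crispr_array")) stop_invalid("'arr' must be a crispr_array object")
  i <- seq_len(arr$S)
  if (arr$delta == 1) rep(1 / (1 + arr$S / p$beta), arr$S)
  else 1 / (1 + (1 / p$beta) * arr$delta^(1 - i) *
              (1 - arr$delta^arr$S) / (1 - arr$delta))
}

#' Probability of successful interference
#'
#' With every matching effector binding independently, viral DNA survives the
#' interference window with probability `exp(-chi * sum(B))`, so interference
#' succeeds with probability `I = 1 - exp(-chi * sum(B))`.
#'
#' @param B vector of per-spacer binding probabilities (entries in \[0, 1\]).
#' @param chi interference efficiency, >= 0.
#' @return Probability in \[0, 1).
#' @examples
#' interference_probability(0.5, 1.4)  # about 0.503
#' @export
interference_probability <- function(B, chi) {
  chi <- check_scalar(chi, "chi")
  if (chi < 0) stop_invalid("'chi' must be >= 0")
  if (!is.numeric(B) || any(!is.finite(B)) || any(B < 0 | B > 1))
    stop_invalid("'B' must be a vector of probabilities")
  1 - exp(-chi * sum(B))
}

#' Survival under Poisson-distributed infections
#'
#' Infections arrive as a Poisson process with mean `rnt` over the observation
#' window; each is repelled independently with probability `I`. Averaging the
#' per-infection outcomes over the Poisson count gives
#' `E = exp(-rnt * (1 - I))`.
#'
#' @param I per-infection interference probability in \[0, 1\].
#' @param rnt expected number of infections, >= 0.
#' @return Survival probability in (0, 1\].
#' @examples
#' poisson_survival(0.5, 5)  # exp(-2.5)
#' @export
poisson_survival <- function(I, rnt) {
  I <- check_scalar(I, "I"); rnt <- check_scalar(rnt, "rnt")
  if (I < 0 || I > 1) stop_invalid("'I' must lie in [0, 1]")
  if (rnt < 0) stop_invalid("'rnt' must be >= 0")
  exp(-rnt * (1 - I))
}

# Product of per-spacer failure factors, in log space for long arrays to
# avoid underflow. Factors are >= exp(-chi * B_i) > 0 whenever they arise
# from 1 - m_i * (1 - exp(-chi * B_i)), so the logarithm is always defined.
prod_guard <- function(terms) {
  if (length(terms) > 50L) exp(sum(log(terms))) else prod(terms)
}

# Factorized exponent of the survival formula: product over spacers of
# 1 - m_i * (1 - exp(-chi * B_i)).
failure_product <- function(m, chi, B) {
  prod_guard(1 - m * (1 - exp(-chi * B)))
}

#' Single-virus survival probability (factorized form)
#'
#' The probability that a cell survives the observation window when facing one
#' viral species:
#' `E = exp(-rnt * prod_i (1 - m_i * (1 - exp(-chi * B_i))))`.
#' The `i`-th factor is the probability that effectors charged with spacer `i`
#' fail against a random virion (its protospacer mutated, or binding/cleavage
#' did not complete in time); the product is the probability that the whole
#' array fails, and the exponential averages over the Poisson number of
#' infections. By default `m_i = mu^(i - 1/2)` ([mutation_profile()]).
#'
#' @param p a [crispr_params()].
#' @param arr a [crispr_array()].
#' @param m optional mutation vector of length `arr$S` overriding the default
#'   schedule.
#' @return Survival probability in (0, 1\].
#' @examples
#' survival_single_virus(crispr_params(1, 1.4, 0.9, 5), crispr_array(6, 0.7))
#' @export
survival_single_virus <- function(p, arr, m = NULL) {
  if (!inherits(p, "crispr_params")) stop_invalid("'p' must be a crispr_params object")
  if (!inherits(arr, "crispr_array")) stop_invalid("'arr' must be a crispr_array object")
  m <- if (is.null(m)) mutation_profile(p$mu, arr$S) else check_mutation_vector(m, arr$S)
  B <- binding_profile(p, arr)
  exp(-p$rnt * failure_product(m, p$chi, B))
}

#' Single-virus survival by explicit mutation-variant enumeration
#'
#' Independent oracle for [survival_single_virus()]: enumerates all `2^S`
#' mutation variants of the virus. A variant with intact protospacer set `V`
#' occurs with probability `prod_{i in V} m_i * prod_{i not in V} (1 - m_i)`
#' and escapes interference with probability `exp(-chi * sum_{i in V} B_i)`;
#' the fully mutated variant escapes with probability 1. The weighted escape
#' probability, multiplied by `rnt`, is the Poisson rate of lethal events.
#' Exponential in `S`; use the factorized form beyond `S = 25`.
#'
#' @inheritParams survival_single_virus
#' @return Survival probability in (0, 1\]; equals [survival_single_virus()]
#'   up to floating-point error.
#' @examples
#' p <- crispr_params(1, 1.4, 0.9, 5); a <- crispr_array(4, 0.6)
#' survival_by_variant_enumeration(p, a) - survival_single_virus(p, a)
#' @export
survival_by_variant_enumeration <- function(p, arr, m = NULL) {
  if (!inherits(p, "crispr_params")) stop_invalid("'p' must be a crispr_params object")
  if (!inherits(arr, "crispr_array")) stop_invalid("'arr' must be a crispr_array object")
  S <- arr$S
  if (S > 25L)
    stop_capacity("variant enumeration is limited to S <= 25 (2^S variants); ",
                  "use survival_single_virus() for longer arrays")
  m <- if (is.null(m)) mutation_profile(p$mu, S) else check_mutation_vector(m, S)
  B <- binding_profile(p, arr)
  escape <- 0
  for (code in 0:(2^S - 1)) {
    intact <- bitwAnd(code, 2^(seq_len(S) - 1L)) > 0
    weight <- prod(ifelse(intact, m, 1 - m))
    escape <- escape + weight * exp(-p$chi * sum(B[intact]))
  }
  exp(-p$rnt * escape)
}

#' Ceiling on interference set by protospacer mutation
#'
#' Whatever the binding and cleavage kinetics, interference can succeed only
#' if at least one targeted protospacer has not mutated:
#' `I_max = 1 - prod_i (1 - mu^(i - 1/2))`. (An alternative reading placing
#' the age exponent on `1 - mu` circulates in print; it contradicts the
#' at-least-one-intact meaning under the `mu^(i-1/2)` mutation schedule and is
#' not used here.)
#'
#' @param mu per-interval non-mutation probability in \[0, 1\].
#' @param S number of spacers, >= 1.
#' @return Probability in \[0, 1\].
#' @examples
#' max_interference(0.9, 2)  # about 0.9925
#' @export
max_interference <- function(mu, S) {
  m <- mutation_profile(mu, S)
  1 - prod(1 - m)
}
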