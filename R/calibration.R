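#' Calibrate the interference efficiency from a single-spacer measurement
#'
#' A single-spacer array has occupancy `B = 1/(1 + 1/beta)` independent of
#' `delta`, so an observed interference probability `I_obs` pins down
#' `chi = -log(1 - I_obs) * (1 + 1/beta)` — the unique value with
#' `interference_probability(B, chi) == I_obs`. Binding and interference
#' efficiencies cannot be identified separately from one interference
#' probability, so `beta` enters as an assumption: calibrating the reference
#' measurement `I_obs = 0.5` at `beta = 1` gives `chi = 2 log 2`, about 1.4.
#'
#' @param I_obs measured single-spacer interference probability, strictly in
#'   (0, 1).
#' @param beta assumed binding efficiency, > 0.
#' @return The calibrated interference efficiency `chi` (> 0).
#' @examples
#' calibrate_chi(0.5, beta = 1)  # 2 * log(2)
#' @export
calibrate_chi <- function(I_obs, beta) {
  I_obs <- check_scalar(I_obs, "I_obs")
  beta <- check_scalar(beta, "beta")
  if (I_obs <= 0 || I_obs >= 1) stop_invalid("'I_obs' must lie strictly in (0, 1)")
  if (beta <= 0) stop_invalid("'beta' must be > 0")
  -log(1 - I_obs) * (1 + 1 / beta)
}

#' Burst-minimizing array optimum
#'
#' CRISPR activity in a doomed cell still degrades viral DNA and reduces the
#' burst of progeny virions, limiting secondary infections. Minimizing the
#' expected viral burst leads to the same optimization as cell survival but
#' with the interference efficiency rescaled by the average number of virus
#' replications in a CRISPR-free cell: `chi' = nu_repl * chi` (about 6-7
#' replications for typical phage). The larger effective efficiency shifts the
#' optimum toward somewhat larger arrays.
#'
#' @param p a [crispr_params()]; its `chi` is rescaled internally.
#' @param nu_repl average number of virus replications in an unprotected cell,
#'   >= 1.
#' @param grid a [grid_spec()].
#' @param pool,plan forwarded to [survival_surface()].
#' @return A `crispr_optimum` (see [survival_surface()]) computed at the
#'   rescaled interference efficiency.
#' @examples
#' burst_optimal_array(crispr_params(1, 1.4, 0.9, 5), nu_repl = 7,
#'                     grid_spec(1, 30))
#' @export
burst_optimal_array <- function(p, nu_repl, grid, pool = NULL, plan = NULL) {
  if (!inherits(p, "crispr_params")) stop_invalid("'p' must be a crispr_params object")
  nu_repl <- check_scalar(nu_repl, "nu_repl")
  if (nu_repl < 1) stop_invalid("'nu_repl' must be >= 1")
  q <- crispr_params(p$beta, p$chi * nu_repl, p$mu, p$rnt)
  survival_surface(q, grid, pool = pool, plan = plan)
}
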