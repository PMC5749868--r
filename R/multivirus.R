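#' Probability of a spacer-to-species assignment
#'
#' Spacers are acquired independently, each from species `j` with probability
#' equal to its pool fraction `v_j`, so a particular ordered assignment has
#' probability `prod_k v[species_of[k]]`. Over all `nu^S` assignments these
#' probabilities sum to 1.
#'
#' @param a a [spacer_assignment()].
#' @param pool a [viral_pool()] with `pool$nu == a$nu`.
#' @return Probability in (0, 1\].
#' @examples
#' assignment_probability(spacer_assignment(c(1, 2, 2), 2), viral_pool(c(0.3, 0.7)))
#' @export
assignment_probability <- function(a, pool) {
  if (!inherits(a, "spacer_assignment")) stop_invalid("'a' must be a spacer_assignment")
  if (!inherits(pool, "viral_pool")) stop_invalid("'pool' must be a viral_pool")
  if (a$nu != pool$nu)
    stop_invalid("assignment refers to ", a$nu, " species but the pool has ", pool$nu)
  prod(pool$v[a$species_of])
}

# Poisson rate multiplier for one assignment: sum_j v_j * prod_{i in S_j}
# (1 - m_i (1 - exp(-chi B_i))). A species with no assigned spacers
# contributes v_j (empty product = 1: the cell is defenceless against it).
assignment_failure_rate <- function(fail, species_of, v) {
  rate <- 0
  for (j in seq_along(v)) {
    rate <- rate + v[j] * prod_guard(fail[species_of == j])
  }
  rate
}

#' Survival of a cell with a given spacer-to-species assignment
#'
#' For an array whose spacers target several species, the per-infection escape
#' probability splits over species: the infecting virion is of species `j`
#' with probability `v_j` and escapes with the failure product restricted to
#' the spacers assigned to `j`. A species with no spacer always escapes.
#' Binding probabilities `B_i` come from the full-array profile: effector
#' dilution spans all `S` spacers regardless of which species each targets,
#' and the mutation age schedule `m_i = mu^(i-1/2)` likewise follows the
#' global age index.
#'
#' @param p a [crispr_params()].
#' @param arr a [crispr_array()] with `arr$S == length(a$species_of)`.
#' @param a a [spacer_assignment()].
#' @param pool a [viral_pool()].
#' @param m optional mutation vector overriding the default schedule.
#' @return Survival probability in (0, 1\].
#' @examples
#' p <- crispr_params(1, 1.4, 0.9, 5)
#' survival_given_assignment(p, crispr_array(2, 0.7),
#'                           spacer_assignment(c(1, 2), 2), viral_pool(c(0.5, 0.5)))
#' @export
survival_given_assignment <- function(p, arr, a, pool, m = NULL) {
  if (!inherits(p, "crispr_params")) stop_invalid("'p' must be a crispr_params object")
  if (!inherits(arr, "crispr_array")) stop_invalid("'arr' must be a crispr_array object")
  if (!inherits(a, "spacer_assignment")) stop_invalid("'a' must be a spacer_assignment")
  if (!inherits(pool, "viral_pool")) stop_invalid("'pool' must be a viral_pool")
  if (length(a$species_of) != arr$S)
    stop_invalid("assignment length ", length(a$species_of),
                 " does not match S = ", arr$S)
  if (a$nu != pool$nu)
    stop_invalid("assignment refers to ", a$nu, " species but the pool has ", pool$nu)
  m <- if (is.null(m)) mutation_profile(p$mu, arr$S) else check_mutation_vector(m, arr$S)
  B <- binding_profile(p, arr)
  fail <- 1 - m * (1 - exp(-p$chi * B))
  exp(-p$rnt * assignment_failure_rate(fail, a$species_of, pool$v))
}

# All nu^S assignments as an (nu^S x S) integer matrix, species indices 1..nu,
# ordered with position 1 varying fastest.
enumerate_assignments <- function(nu, S) {
  as.matrix(expand.grid(rep(list(seq_len(nu)), S), KEEP.OUT.ATTRS = FALSE))
}

#' Assignment-averaged survival in a multi-virus pool
#'
#' Averages [survival_given_assignment()] over the distribution of arrays a
#' cell can plausibly hold, each assignment weighted by its acquisition
#' probability ([assignment_probability()]). Exact mode enumerates all `nu^S`
#' assignments; Monte-Carlo mode samples assignments position-wise from the
#' pool fractions (so weights are implicit) and reports the sample mean with
#' its standard error. `"auto"` mode enumerates when `nu^S <= plan$max_exact`
#' and samples otherwise.
#'
#' @param p a [crispr_params()].
#' @param arr a [crispr_array()].
#' @param pool a [viral_pool()].
#' @param plan an [averaging_plan()].
#' @return A list of class `average_survival` with fields `E` (the averaged
#'   survival), `se` (standard error; 0 in exact mode), `mode` (the mode
#'   actually used) and `n` (assignments enumerated or sampled).
#' @examples
#' p <- crispr_params(1, 1.4, 0.9, 5)
#' average_survival(p, crispr_array(4, 0.7), viral_pool(c(0.5, 0.5)),
#'                  averaging_plan("exact"))
#' @export
average_survival <- function(p, arr, pool,
                             plan = averaging_plan()) {
  if (!inherits(p, "crispr_params")) stop_invalid("'p' must be a crispr_params object")
  if (!inherits(arr, "crispr_array")) stop_invalid("'arr' must be a crispr_array object")
  if (!inherits(pool, "viral_pool")) stop_invalid("'pool' must be a viral_pool")
  if (!inherits(plan, "averaging_plan")) stop_invalid("'plan' must be an averaging_plan")

  S <- arr$S; nu <- pool$nu

  # Single-species pool: the average has one term and reduces exactly to the
  # single-virus closed form.
  if (nu == 1L)
    return(structure(list(E = survival_single_virus(p, arr), se = 0,
                          mode = "exact", n = 1L),
                     class = "average_survival"))

  n_assign <- nu^S
  mode <- plan$mode
  if (mode == "auto") mode <- if (n_assign <= plan$max_exact) "exact" else "montecarlo"
  if (mode == "exact" && n_assign > plan$max_exact)
    stop_capacity("exact averaging needs ", format(n_assign), " assignments, above ",
                  "the cap of ", format(plan$max_exact),
                  "; use mode = \"montecarlo\"")

  m <- mutation_profile(p$mu, S)
  B <- binding_profile(p, arr)
  fail <- 1 - m * (1 - exp(-p$chi * B))
  lf <- log(fail)

  if (mode == "exact") {
    assign_mat <- enumerate_assignments(nu, S)
    rate <- 0
    weight <- rep(1, nrow(assign_mat))
    for (j in seq_len(nu)) {
      hit <- assign_mat == j
      rate <- rate + pool$v[j] * exp(hit %*% lf)
      weight <- weight * pool$v[j]^rowSums(hit)
    }
    E <- sum(weight * exp(-p$rnt * rate))
    out <- list(E = as.numeric(E), se = 0, mode = "exact", n = n_assign)
  } else {
    n <- plan$n_samples
    draws <- with_seed(plan$seed,
      matrix(sample.int(nu, n * S, replace = TRUE, prob = pool$v), nrow = n))
    rate <- 0
    for (j in seq_len(nu)) rate <- rate + pool$v[j] * exp((draws == j) %*% lf)
    Ec <- exp(-p$rnt * as.numeric(rate))
    out <- list(E = mean(Ec),
                se = stats::sd(Ec) / sqrt(n),
                mode = "montecarlo", n = n)
  }
  structure(out, class = "average_survival")
}

#' @export
print.average_survival <- function(x, ...) {
  cat(sprintf("Pool-averaged survival: E = %.6g (%s, n = %d%s)\n", x$E, x$mode,
              x$n, if (x$mode == "montecarlo") sprintf(", se = %.2g", x$se) else ""))
  invisible(x)
}
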