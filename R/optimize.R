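# One row of the survival surface for a multi-virus pool: survival at fixed S
# across all delta values. Enumeration (or the Monte-Carlo assignment draw) is
# done once per S and reused across delta, since the assignment distribution
# depends only on (S, pool). The Monte-Carlo seed for the row is
# plan$seed + s_counter, making every cell reproducible in isolation and the
# delta-comparison within a row noise-correlated (common random numbers).
pool_survival_row <- function(p, S, delta_values, pool, plan, s_counter) {
  nu <- pool$nu
  if (nu == 1L)
    return(vapply(delta_values, function(delta)
      survival_single_virus(p, crispr_array(S, delta)), numeric(1)))
  n_assign <- nu^S
  mode <- plan$mode
  if (mode == "auto") mode <- if (n_assign <= plan$max_exact) "exact" else "montecarlo"
  if (mode == "exact" && n_assign > plan$max_exact)
    stop_capacity("exact averaging needs ", format(n_assign),
                  " assignments, above the cap of ", format(plan$max_exact))

  m <- mutation_profile(p$mu, S)
  if (mode == "exact") {
    A <- enumerate_assignments(nu, S)
    hits <- lapply(seq_len(nu), function(j) A == j)
    weight <- rep(1, nrow(A))
    for (j in seq_len(nu)) weight <- weight * pool$v[j]^rowSums(hits[[j]])
  } else {
    n <- plan$n_samples
    A <- with_seed(plan$seed + s_counter,
      matrix(sample.int(nu, n * S, replace = TRUE, prob = pool$v), nrow = n))
    hits <- lapply(seq_len(nu), function(j) A == j)
  }

  vapply(delta_values, function(delta) {
    B <- binding_profile(p, crispr_array(S, delta))
    lf <- log(1 - m * (1 - exp(-p$chi * B)))
    rate <- 0
    for (j in seq_len(nu)) rate <- rate + pool$v[j] * exp(hits[[j]] %*% lf)
    if (mode == "exact") sum(weight * exp(-p$rnt * rate))
    else mean(exp(-p$rnt * rate))
  }, numeric(1))
}

#' Survival surface over array size and crRNA decay coefficient
#'
#' Evaluates the survival probability on the full `(S, delta)` grid and
#' extracts the argmax. Without a pool the single-virus closed form is used;
#' with a pool every cell is the assignment-averaged survival
#' ([average_survival()]), enumerated exactly where `nu^S` fits under the
#' plan's cap and estimated by seeded Monte Carlo otherwise. Ties at the
#' maximum break to the smallest `S`, then the smallest `delta`, biasing
#' toward cheaper arrays.
#'
#' The position of the maximum does not depend on `rnt`: survival is
#' `exp(-rnt * g(S, delta))` for a rate factor `g` free of `rnt`, so `rnt`
#' rescales the surface monotonically without moving the argmax.
#'
#' @param p a [crispr_params()].
#' @param grid a [grid_spec()].
#' @param pool optional [viral_pool()]; omitted means a single viral species.
#' @param plan optional [averaging_plan()] used when `pool` is given. The
#'   default switches to Monte Carlo (20000 samples per cell) above 2^14
#'   assignments.
#' @return An object of class `crispr_optimum`: list with the `surface` matrix
#'   (rows = S, columns = delta), `S_values`, `delta_values`, the argmax
#'   (`S_opt`, `delta_opt`, `E_max`), and the averaging `mode` per S row
#'   (`"closed_form"` for single-virus).
#' @examples
#' opt <- survival_surface(crispr_params(1, 1.4, 0.9, 5), grid_spec(1, 30))
#' c(opt$S_opt, opt$delta_opt)  # 6, 0.69
#' @export
survival_surface <- function(p, grid, pool = NULL, plan = NULL) {
  if (!inherits(p, "crispr_params")) stop_invalid("'p' must be a crispr_params object")
  if (!inherits(grid, "grid_spec")) stop_invalid("'grid' must be a grid_spec object")
  if (!is.null(pool) && !inherits(pool, "viral_pool"))
    stop_invalid("'pool' must be a viral_pool or NULL")
  if (is.null(plan))
    plan <- averaging_plan("auto", max_exact = 2^14, n_samples = 2e4, seed = 1L)
  if (!inherits(plan, "averaging_plan")) stop_invalid("'plan' must be an averaging_plan")

  S_values <- seq.int(grid$S_min, grid$S_max)
  dv <- grid$delta_values
  surface <- matrix(NA_real_, nrow = length(S_values), ncol = length(dv),
                    dimnames = list(S = S_values, delta = signif(dv, 6)))
  modes <- character(length(S_values))
  for (r in seq_along(S_values)) {
    S <- S_values[r]
    if (is.null(pool)) {
      surface[r, ] <- vapply(dv, function(delta)
        survival_single_virus(p, crispr_array(S, delta)), numeric(1))
      modes[r] <- "closed_form"
    } else {
      surface[r, ] <- pool_survival_row(p, S, dv, pool, plan, s_counter = r)
      modes[r] <- if (plan$mode == "auto") {
        if (pool$nu^S <= plan$max_exact) "exact" else "montecarlo"
      } else plan$mode
    }
  }

  best <- which(surface == max(surface), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  structure(list(surface = surface, S_values = S_values, delta_values = dv,
                 S_opt = S_values[best[1L]], delta_opt = dv[best[2L]],
                 E_max = surface[best[1L], best[2L]],
                 mode = modes, params = p, pool = pool),
            class = "crispr_optimum")
}

#' @export
print.crispr_optimum <- function(x, ...) {
  cat(sprintf(paste0("Survival optimum over %d x %d (S, delta) grid:\n",
                     "  S_opt = %d, delta_opt = %g, E_max = %.6g\n"),
              length(x$S_values), length(x$delta_values),
              x$S_opt, x$delta_opt, x$E_max))
  invisible(x)
}

#' @export
as.data.frame.crispr_optimum <- function(x, ...) {
  data.frame(S = rep(x$S_values, times = length(x$delta_values)),
             delta = rep(x$delta_values, each = length(x$S_values)),
             survival = as.vector(x$surface))
}

#' One-dimensional parameter sweep of the array optimum
#'
#' Re-optimizes the array over the inner `(S, delta)` grid for each value of
#' one array-unrelated parameter (`mu`, `beta` or `chi`) and records the
#' optimal spacer count, decay coefficient and maximal survival. Rising
#' mutation pressure (falling `mu`) pushes the optimum toward fewer spacers
#' and lower survival; rising `beta` or `chi` pushes it toward more spacers
#' and higher survival.
#'
#' @param p baseline [crispr_params()]; the swept field is overridden.
#' @param which one of `"mu"`, `"beta"`, `"chi"`.
#' @param values vector of parameter values, each valid for the chosen field.
#' @param inner a [grid_spec()] for the per-value optimization.
#' @param pool optional [viral_pool()] forwarded to [survival_surface()].
#' @param plan optional [averaging_plan()] forwarded to [survival_surface()].
#' @return A data frame of class `crispr_sweep` with columns `parameter`,
#'   `value`, `S_opt`, `delta_opt`, `E_max`, one row per swept value.
#' @examples
#' sweep_optimum(crispr_params(1, 1.4, 0.9, 5), "beta", c(0.5, 1, 2),
#'               grid_spec(1, 15, seq(0.05, 1, by = 0.05)))
#' @export
sweep_optimum <- function(p, which = c("mu", "beta", "chi"), values, inner,
                          pool = NULL, plan = NULL) {
  if (!inherits(p, "crispr_params")) stop_invalid("'p' must be a crispr_params object")
  which <- match.arg(which)
  if (!is.numeric(values) || length(values) < 1L)
    stop_invalid("'values' must be a non-empty numeric vector")
  rows <- lapply(values, function(val) {
    q <- unclass(p); q[[which]] <- val
    q <- do.call(crispr_params, q)  # re-validates the swept value
    opt <- survival_surface(q, inner, pool = pool, plan = plan)
    data.frame(parameter = which, value = val, S_opt = opt$S_opt,
               delta_opt = opt$delta_opt, E_max = opt$E_max)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("crispr_sweep", "data.frame")
  out
}

#' Optimized survival versus viral-pool diversity
#'
#' For each species count `nu` builds the equal-fraction pool
#' `v_j = 1/nu`, optimizes the array over the inner grid and records the
#' optimum. Splitting a pool of fixed total size across more species spreads
#' a bounded effective spacer budget thinner per species, so the maximal
#' survival is non-increasing in `nu`.
#'
#' @param p a [crispr_params()].
#' @param nu_values integer vector of species counts, each >= 1.
#' @param inner a [grid_spec()].
#' @param plan optional [averaging_plan()] forwarded to [survival_surface()].
#' @return A data frame with columns `nu`, `S_opt`, `delta_opt`, `E_max`.
#' @examples
#' diversity_curve(crispr_params(1, 1.4, 0.9, 5), 1:2,
#'                 grid_spec(1, 12, seq(0.1, 1, by = 0.1)))
#' @export
diversity_curve <- function(p, nu_values, inner, plan = NULL) {
  if (!is.numeric(nu_values) || any(nu_values < 1) ||
      any(nu_values != round(nu_values)))
    stop_invalid("'nu_values' must be integers >= 1")
  rows <- lapply(as.integer(nu_values), function(nu) {
    pool <- if (nu == 1L) NULL else viral_pool(rep(1 / nu, nu))
    opt <- survival_surface(p, inner, pool = pool, plan = plan)
    data.frame(nu = nu, S_opt = opt$S_opt, delta_opt = opt$delta_opt,
               E_max = opt$E_max)
  })
  do.call(rbind, rows)
}
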