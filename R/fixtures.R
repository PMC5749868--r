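#' Seeded fixture generator for randomized parameter sets
#'
#' Draws `n_cases` randomized model configurations spanning the physically
#' sensible parameter ranges: `beta` log-uniform on \[0.1, 10\] (occupancy from
#' weak to near-saturated), `chi` uniform on \[0.1, 5\], `mu` uniform on
#' \[0.3, 0.99\], `rnt` uniform on \[1, 20\], a species count `nu` in 1..3 and
#' Dirichlet(1) pool fractions. Each case carries its own sub-seed so any
#' single case can be re-run in isolation. The same master seed always yields
#' the same fixtures (and the same file, if `path` is given).
#'
#' @param seed master integer seed.
#' @param n_cases number of cases to draw (0 gives an empty, still valid,
#'   fixture list).
#' @param path optional file path; when given the fixtures are also written as
#'   JSON.
#' @return A list of cases, each a list with fields `id`, `beta`, `chi`, `mu`,
#'   `rnt`, `S`, `delta`, `pool` and `sub_seed`, invisibly when written to
#'   `path`.
#' @examples
#' fx <- generate_fixtures(seed = 7, n_cases = 3)
#' fx[[1]]$beta
#' @export
generate_fixtures <- function(seed, n_cases, path = NULL) {
  seed <- as.integer(check_scalar(seed, "seed"))
  n_cases <- as.integer(check_scalar(n_cases, "n_cases"))
  if (n_cases < 0L) stop_invalid("'n_cases' must be >= 0")
  cases <- with_seed(seed, lapply(seq_len(n_cases), function(i) {
    nu <- sample.int(3L, 1L)
    w <- stats::rgamma(nu, shape = 1)
    list(id = i,
         beta = 10^stats::runif(1, -1, 1),
         chi = stats::runif(1, 0.1, 5),
         mu = stats::runif(1, 0.3, 0.99),
         rnt = stats::runif(1, 1, 20),
         S = sample.int(12L, 1L),
         delta = stats::runif(1, 0.05, 1),
         pool = w / sum(w),
         sub_seed = sample.int(.Machine$integer.max - 1L, 1L))
  }))
  if (!is.null(path)) {
    jsonlite::write_json(cases, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(cases))
  }
  cases
}
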