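# Shared randomized parameter sets, drawn once per test run from the package's
# own seeded fixture generator.
random_cases <- function(n, seed = 20260101) generate_fixtures(seed, n)

case_params <- function(cs) crispr_params(cs$beta, cs$chi, cs$mu, cs$rnt)
case_array <- function(cs) crispr_array(cs$S, cs$delta)

ref_params <- function() crispr_params(beta = 1, chi = 1.4, mu = 0.9, rnt = 5)
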