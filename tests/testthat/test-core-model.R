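test_that("effector allocation follows the geometric split and conserves copies", {
  expect_equal(effector_allocation(100, crispr_array(1, 0.3)), 100)
  expect_equal(effector_allocation(90, crispr_array(2, 0.5)), c(60, 30))
  expect_equal(effector_allocation(90, crispr_array(3, 1)), rep(30, 3))

  for (delta in c(0.05, 0.3, 0.7, 0.99, 1)) {
    for (S in c(1L, 2L, 7L, 30L, 100L)) {
      Ci <- effector_allocation(250, crispr_array(S, delta))
      expect_equal(sum(Ci), 250, tolerance = 1e-12)
      if (delta < 1 && S > 1) expect_true(all(diff(Ci) < 0))
    }
  }

  expect_error(effector_allocation(0, crispr_array(2, 0.5)), class = "crispropt_invalid")
  expect_error(crispr_array(2, 0), class = "crispropt_invalid")
})

test_that("steady-state occupancy matches binding kinetics", {
  expect_equal(occupancy_from_kinetics(kinetic_constants(1, 1, 1, 1, 1), 1), 0.5)
  expect_equal(occupancy_from_kinetics(kinetic_constants(5, 2, 1, 1, 1), 0), 0)
  expect_equal(occupancy_from_kinetics(kinetic_constants(2, 1, 1, 1, 1), 3), 6 / 7)
  expect_error(occupancy_from_kinetics(kinetic_constants(1, 1, 1, 1, 1), -1),
               class = "crispropt_invalid")
})

test_that("binding profile matches the closed form and its limits", {
  p <- ref_params()
  # single spacer at beta = 1: occupancy exactly 1/2 whatever delta
  for (delta in c(0.1, 0.5, 0.9, 1))
    expect_identical(binding_profile(p, crispr_array(1, delta)), 0.5)
  expect_equal(binding_profile(p, crispr_array(2, 0.5)), c(0.4, 0.25))
  # saturation: overwhelming effector supply occupies every protospacer
  sat <- binding_profile(crispr_params(1e6, 1.4, 0.9, 5), crispr_array(3, 0.9))
  expect_equal(sat, rep(1, 3), tolerance = 1e-4)
})

test_that("binding profile composes allocation with occupancy", {
  for (cs in random_cases(20, seed = 11)) {
    p <- case_params(cs); arr <- case_array(cs)
    C_total <- 37.5
    k <- kinetic_constants(k_plus = p$beta / C_total, k_minus = 1, C = C_total,
                           a = 1, tau = p$chi)
    via_kinetics <- occupancy_from_kinetics(k, effector_allocation(C_total, arr))
    expect_equal(binding_profile(p, arr), via_kinetics, tolerance = 1e-12)
  }
})

test_that("binding profile is monotone in beta, ordered by age, continuous at delta = 1", {
  arr <- crispr_array(5, 0.6)
  B_lo <- binding_profile(crispr_params(0.5, 1.4, 0.9, 5), arr)
  B_hi <- binding_profile(crispr_params(2, 1.4, 0.9, 5), arr)
  expect_true(all(B_hi > B_lo))
  expect_true(all(diff(B_lo) < 0))  # younger spacers are better represented

  p <- ref_params()
  for (S in c(2L, 6L, 40L)) {
    near <- binding_profile(p, crispr_array(S, 1 - 1e-9))
    at <- binding_profile(p, crispr_array(S, 1))
    expect_equal(near, at, tolerance = 1e-6)
    expect_equal(at, rep(1 / (1 + S / p$beta), S))
  }
})

test_that("interference probability follows the exponential kill law", {
  expect_equal(interference_probability(0.5, 1.4), 1 - exp(-0.7))
  expect_equal(interference_probability(c(0.3, 0.2, 0.5), 0), 0)
  expect_equal(interference_probability(c(0.4, 0.25), 1), 1 - exp(-0.65))
  # monotone in chi and in every binding entry
  chis <- seq(0.2, 3, by = 0.4)
  I_chi <- vapply(chis, interference_probability, numeric(1), B = c(0.4, 0.25))
  expect_true(all(diff(I_chi) > 0))
  expect_lt(interference_probability(c(0.4, 0.20), 1.4),
            interference_probability(c(0.4, 0.25), 1.4))
})

test_that("Poisson survival averages per-infection outcomes", {
  expect_equal(poisson_survival(1, 17), 1)
  expect_equal(poisson_survival(0, 5), exp(-5))
  expect_equal(poisson_survival(0.5, 5), exp(-2.5))
})

test_that("single-virus survival matches hand evaluation and limits", {
  p <- ref_params()
  expect_equal(survival_single_virus(p, crispr_array(1, 0.5)),
               exp(-5 * (1 - 0.9^0.5 * (1 - exp(-0.7)))), tolerance = 1e-14)
  # every protospacer mutated: immunity never fires
  p0 <- crispr_params(1, 1.4, 0, 5)
  expect_equal(survival_single_virus(p0, crispr_array(8, 0.4)), exp(-5))
  # no infections at all
  expect_equal(survival_single_virus(crispr_params(1, 1.4, 0.9, 0),
                                     crispr_array(3, 0.7)), 1)
  expect_error(survival_single_virus(p, crispr_array(3, 0.7), m = c(0.9, 0.8)),
               class = "crispropt_invalid")
  # survival strictly decreases with infection pressure while interference is imperfect
  E_rnt <- vapply(c(1, 5, 20), function(rnt)
    survival_single_virus(crispr_params(1, 1.4, 0.9, rnt), crispr_array(6, 0.7)),
    numeric(1))
  expect_true(all(diff(E_rnt) < 0))
})

test_that("variant enumeration expands the two-spacer survival exactly", {
  p <- ref_params()
  arr <- crispr_array(2, 0.5)
  B <- c(0.4, 0.25)  # frozen from the hand-evaluated profile above
  m <- c(0.9^0.5, 0.9^1.5)
  # explicit four-variant average of escape probabilities
  escape <- m[1] * m[2] * exp(-p$chi * sum(B)) +
    m[1] * (1 - m[2]) * exp(-p$chi * B[1]) +
    (1 - m[1]) * m[2] * exp(-p$chi * B[2]) +
    (1 - m[1]) * (1 - m[2])
  expect_equal(survival_by_variant_enumeration(p, arr), exp(-p$rnt * escape),
               tolerance = 1e-14)
  expect_equal(survival_single_virus(p, arr), exp(-p$rnt * escape),
               tolerance = 1e-14)
})

test_that("variant enumeration agrees with the factorized survival", {
  for (cs in random_cases(40, seed = 5)) {
    p <- case_params(cs)
    arr <- crispr_array(min(cs$S, 8L), cs$delta)
    expect_equal(survival_by_variant_enumeration(p, arr),
                 survival_single_virus(p, arr), tolerance = 1e-12)
  }
  # fully mutated virus: enumeration collapses to the undefended cell
  p <- ref_params()
  expect_equal(survival_by_variant_enumeration(p, crispr_array(3, 0.6),
                                               m = rep(0, 3)), exp(-5))
  expect_error(survival_by_variant_enumeration(p, crispr_array(26, 0.5)),
               class = "crispropt_capacity")
})

test_that("mutation ceiling bounds interference", {
  expect_equal(max_interference(1, 7), 1)
  expect_equal(max_interference(0, 4), 0)
  expect_equal(max_interference(0.9, 2), 1 - (1 - 0.9^0.5) * (1 - 0.9^1.5))
  # the mutation-averaged kill probability can never beat the ceiling
  for (cs in random_cases(20, seed = 9)) {
    p <- case_params(cs); arr <- case_array(cs)
    B <- binding_profile(p, arr)
    m <- mutation_profile(p$mu, arr$S)
    kill <- 1 - prod(1 - m * (1 - exp(-p$chi * B)))
    expect_lte(kill, max_interference(p$mu, arr$S) + 1e-12)
  }
})

test_that("uniform allocation rewards extra spacers when protospacers never mutate", {
  p <- ref_params()
  sums <- vapply(1:20, function(S)
    sum(binding_profile(p, crispr_array(S, 1))), numeric(1))
  expect_equal(sums, (1:20) / (1 + (1:20) / p$beta))
  expect_true(all(diff(sums) > 0))
  E <- vapply(1:20, function(S)
    survival_single_virus(p, crispr_array(S, 1), m = rep(1, S)), numeric(1))
  expect_true(all(diff(E) >= 0))
})
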