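# Step-function repulsion, the giant-cluster transition, and two-region
# localization.

test_that("step-model adsorption reduces to the quadratic model at k_max = K_cap", {
  for (cs in c(0.3, 0.8, 1.5)) {
    r <- region_adsorption_step(cs, e_r0 = 0.6, k_max = 150, K_cap = 150)
    full <- adsorption(cs, 0.6)
    expect_equal(r$C_v, full, tolerance = 1e-10)
  }
})

test_that("step-model sums match the independent oracle, giant flag included", {
  r <- region_adsorption_step(2, e_r0 = 0.2, k_max = 5, K_cap = 200)
  expect_equal(r$log_C_v, log(oracle_step_sum(2, 0.2, 5, 200)),
               tolerance = 1e-10)
  expect_equal(r$log_C_v, 65.28304242652812, tolerance = 1e-10)  # frozen
  expect_true(r$giant)
  expect_equal(r$dominant_size, 200L)
  expect_equal(r$mean_size, 197.06435025331442, tolerance = 1e-8)
  # below the transition the largest term is small
  r2 <- region_adsorption_step(0.5, e_r0 = 0.2, k_max = 5, K_cap = 200)
  expect_false(r2$giant)
  expect_equal(r2$C_v, oracle_step_sum(0.5, 0.2, 5, 200), tolerance = 1e-10)
  expect_error(region_adsorption_step(1, 0.2, 5, Inf),
               class = "spovm_domain_error")
  expect_equal(region_adsorption_step(0, 0.2, 5, 100)$C_v, 0)
})

test_that("giant-cluster flag flips exactly once along an increasing grid", {
  grid <- exp(seq(log(0.05), log(10), length.out = 60))
  flags <- vapply(grid, function(cs) {
    region_adsorption_step(cs, e_r0 = 0.2, k_max = 10, K_cap = 400)$giant
  }, TRUE)
  expect_equal(sum(diff(flags) != 0), 1L)
  expect_false(flags[1])
  expect_true(flags[length(flags)])
})

test_that("localization fraction is 1/2 without a binding advantage", {
  sys <- two_region_system(delta_b = 0, e_r0 = 0.2, k_max = 10, K_cap = 300)
  for (cs in c(1e-4, 0.5, 2, 5)) {
    expect_identical(localization_fraction(cs, sys), 0.5)
  }
  expect_error(localization_fraction(0, sys), class = "spovm_domain_error")
})

test_that("fraction exceeds 1/2 for any positive advantage and hits the monomer limit", {
  sys <- two_region_system(delta_b = 0.1, e_r0 = 0.2, k_max = 10, K_cap = 300)
  expect_equal(localization_fraction(1e-6, sys),
               exp(0.1) / (1 + exp(0.1)), tolerance = 1e-6)
  for (cs in c(0.01, 0.5, 1, 3)) {
    expect_gt(localization_fraction(cs, sys), 0.5)
  }
  # term-by-term dominance: region 1 beats region 2 by exp(k delta_b)
  lw1 <- spovmclust:::.step_log_weights(1.2 * exp(0.1), 0.2, 10, 300)
  lw2 <- spovmclust:::.step_log_weights(1.2, 0.2, 10, 300)
  expect_equal(lw1 - lw2, (1:300) * 0.1, tolerance = 1e-9)
})

test_that("area ratio shifts the symmetric fraction as a prior odds factor", {
  sys <- two_region_system(delta_b = 0, e_r0 = 0.2, k_max = 5, K_cap = 100,
                           area_ratio = 3)
  expect_equal(localization_fraction(0.5, sys), 0.75)
})

test_that("localization curve rises from the monomer limit toward near-total localization", {
  sys <- two_region_system(delta_b = 0.02, e_r0 = 0.2, k_max = 10,
                           K_cap = 1000)
  grid <- exp(seq(log(1e-3), log(3), length.out = 40))
  curve <- localization_curve(sys, grid)
  expect_equal(curve$fraction_1[1], exp(0.02) / (1 + exp(0.02)),
               tolerance = 1e-4)
  expect_true(all(diff(curve$total_adsorption) > 0))
  expect_true(all(curve$mean_size_1 >= curve$mean_size_2))
  expect_true(all(curve$fraction_1 > 0.5))
  expect_gt(max(curve$fraction_1), 0.9)
  expect_equal(sum(diff(curve$giant_1) != 0), 1L)
  # a curve with no advantage is flat at 1/2
  flat <- localization_curve(
    two_region_system(delta_b = 0, e_r0 = 0.2, k_max = 10, K_cap = 200),
    c(0.5, 1, 2))
  expect_true(all(flat$fraction_1 == 0.5))
})

test_that("fixed-stoichiometry adsorption follows monomer/q-mer equilibrium", {
  expect_equal(stoichiometric_adsorption(0.7, q = 3, K_q = 0), 0.7)
  expect_equal(stoichiometric_adsorption(0.5, q = 3, K_q = 1), 0.875)
  cs <- 10^seq(-6, -2)
  expect_equal(stoichiometric_adsorption(cs, 3, 5) / cs, rep(1, length(cs)),
               tolerance = 1e-3)
  expect_error(stoichiometric_adsorption(0.5, 1, 1),
               class = "spovm_domain_error")
})
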