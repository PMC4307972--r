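# Direct free-energy minimization versus the closed-form dilute-limit
# cluster distribution.

test_that("configuration energy follows the binding/attraction/repulsion form", {
  p <- interaction_params(eps_b = 1, eps_nn = 0.5, e_r = 0.2)
  expect_equal(total_energy(numeric(0), p), 0)
  expect_equal(total_energy(c(2), p), -2)            # two monomers: binding only
  expect_equal(total_energy(c(0, 0, 1), p), -3.4)    # -3 - 2*0.5 + 3*0.2
  # additivity over clusters
  expect_equal(total_energy(c(2, 1, 1), p),
               total_energy(c(2), p) + total_energy(c(0, 1), p) +
                 total_energy(c(0, 0, 1), p))
  expect_error(total_energy(c(-1), p), class = "spovm_domain_error")
})

test_that("mixing entropy matches direct factorial evaluation", {
  p <- interaction_params()
  expect_equal(cluster_entropy(numeric(0),
                               finite_system(4, 2, 0, p, K = 2)), 0)
  expect_equal(cluster_entropy(numeric(0),
                               finite_system(4, 2, 1, p, K = 2)), log(4))
  expect_equal(cluster_entropy(c(0, 1),
                               finite_system(10, 3, 2, p, K = 3)), log(6))
  # exhaustive: lgamma form vs direct factorials for all small systems
  for (Ls in c(6, 12)) for (ns in 0:3) for (m1 in 0:2) for (m2 in 0:1) {
    nv <- m1 + 2 * m2
    if (nv > min(ns, 4)) next
    sys <- finite_system(Ls, 4, ns, p, K = 4)
    direct <- log(factorial(Ls) /
                    (factorial(Ls - ns + nv) * factorial(ns - nv))) +
      log(factorial(4) / (factorial(m1) * factorial(m2) *
                            factorial(4 - nv)))
    expect_equal(cluster_entropy(c(m1, m2), sys), direct, tolerance = 1e-10)
  }
  expect_error(
    cluster_entropy(c(5), finite_system(10, 3, 2, p, K = 3)),
    class = "spovm_domain_error")
})

test_that("minimizer recovers ideal mixing and the strong-binding limit", {
  # no interactions: membrane occupancy equals bath occupancy
  sys <- finite_system(1e6, 1e3, 1e3, interaction_params(0, 0, 0), K = 1L)
  fit <- minimize_free_energy(sys)
  expect_true(fit$converged)
  expect_equal(fit$n_v / sys$L_v, sys$n_s / sys$L_s, tolerance = 0.01)
  # overwhelming binding pulls essentially all protein onto the membrane
  sys2 <- finite_system(1e8, 1e4, 50, interaction_params(20, 0, 0), K = 1L)
  fit2 <- minimize_free_energy(sys2)
  expect_equal(fit2$n_v, 50, tolerance = 1e-3)
})

test_that("minimizer reproduces the dilute-limit closed form per cluster size", {
  # the bath must dwarf the membrane uptake (n_v << n_s) as well as being
  # dilute (ns* << 1) for the closed form to hold to 0.1% per k
  sys <- finite_system(1e12, 1e4, 1e6, interaction_params(2, 1, 1), K = 20L)
  fit <- minimize_free_energy(sys)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$grad)), 1e-6)
  ns_star <- sys$n_s / sys$L_s
  k <- 1:20
  dE <- -2 * k - (k - 1) * 1 + k * (k - 1) * 1 / 2
  ref <- sys$L_v * ns_star^k * exp(-dE)
  expect_equal(fit$m / ref, rep(1, 20), tolerance = 1e-3)
})

test_that("stationarity residuals vanish at the minimizer", {
  for (er in c(0.5, 2)) {
    sys <- finite_system(1e10, 1e4, 1e4, interaction_params(1, 0.5, er),
                         K = 10L)
    fit <- minimize_free_energy(sys)
    expect_lt(max(abs(fit$grad)), 1e-6)
  }
})

test_that("deviation from the closed form shrinks as the bath gets more dilute", {
  p <- interaction_params(eps_b = 1, eps_nn = 0.5, e_r = 1)
  rep <- dilute_consistency_report(p, ns_star_grid = c(1e-3, 1e-4, 1e-5),
                                   L_s = 1e10, L_v = 1e4, K = 8L)
  devs <- vapply(rep$points, `[[`, 0, "max_deviation")
  expect_true(all(diff(devs) < 0))
  expect_lt(rep$points[[3]]$max_deviation, 1e-3)
  expect_true(all(vapply(rep$points, `[[`, TRUE, "converged")))
  # adsorption prediction agrees too
  expect_lt(rep$points[[3]]$n_v_deviation, 1e-3)
  expect_warning(
    dilute_consistency_report(p, ns_star_grid = 0.05, L_s = 1e6, L_v = 100,
                              K = 4L),
    "dilute")
})
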