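# The adsorption series C_v = sum_k k exp(-k(k-1) e_r / 2) C_s^k and its
# statistics, checked against closed forms and an independent plain-summation
# oracle (helper-oracles.R), plus frozen high-precision reference values.

test_that("cluster weights match closed forms and frozen references", {
  expect_equal(cluster_weights(0, 5, 4), rep(0, 4))
  expect_equal(cluster_weights(0.5, 0, 3), c(0.5, 0.5, 0.375))
  # frozen 50-digit reference for k * exp(-k(k-1)) at C_s = 1
  expect_equal(cluster_weights(1, 2, 4),
               c(1, 0.2706705664732254, 0.0074362565299990755,
                 2.457684941331284e-05),
               tolerance = 1e-12)
  expect_error(cluster_weights(1.2, 0, 3), class = "spovm_divergence_error")
  expect_error(cluster_weights(1, 2, 0), class = "spovm_domain_error")
})

test_that("adsorption reproduces the geometric-series closed form at e_r = 0", {
  for (x in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(adsorption(x, 0), x / (1 - x)^2, tolerance = 1e-10)
    expect_equal(mean_cluster_size(x, 0), 1 / (1 - x), tolerance = 1e-10)
  }
})

test_that("adsorption agrees with the independent summation oracle on a grid", {
  grid <- expand.grid(C_s = c(0.2, 0.8, 1, 2, 5), e_r = c(0.3, 0.7, 1.5, 4))
  for (i in seq_len(nrow(grid))) {
    cs <- grid$C_s[i]; er <- grid$e_r[i]
    expect_equal(adsorption(cs, er), oracle_adsorption(cs, er),
                 tolerance = 1e-8)
    expect_equal(mean_cluster_size(cs, er), oracle_mean_size(cs, er),
                 tolerance = 1e-8)
  }
  # frozen arbitrary-precision references
  expect_equal(adsorption(1, 2), 1.2781314101589673, tolerance = 1e-10)
  expect_equal(mean_cluster_size(1, 2), 1.1233158197845189, tolerance = 1e-10)
})

test_that("limits: monomers at strong repulsion, linearity at low C_s", {
  expect_equal(adsorption(0.3, 1e6), 0.3, tolerance = 1e-10)
  expect_equal(mean_cluster_size(0.3, 1e6), 1, tolerance = 1e-10)
  for (er in c(0.5, 2)) {
    expect_equal(adsorption(1e-8, er) / 1e-8, 1, tolerance = 1e-6)
    expect_equal(mean_cluster_size(1e-10, er), 1, tolerance = 1e-6)
  }
  expect_equal(adsorption(0, 1), 0)
  expect_equal(mean_cluster_size(0, 1), 1)
})

test_that("adsorption is increasing in C_s and decreasing in e_r", {
  cs_grid <- c(0.1, 0.5, 1, 2, 4)
  vals <- vapply(cs_grid, adsorption, 0, e_r = 1)
  expect_true(all(diff(vals) > 0))
  er_grid <- c(0.3, 0.6, 1, 2, 5)
  vals <- vapply(er_grid, function(e) adsorption(1.5, e), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("divergent parameter combinations raise divergence errors", {
  expect_error(adsorption(1.5, 0), class = "spovm_divergence_error")
  expect_error(adsorption(0.5, -0.2), class = "spovm_divergence_error")
  err <- tryCatch(adsorption(2, -1), error = identity)
  expect_match(conditionMessage(err), "C_s = 2")
})

test_that("dominant cluster size is the exact argmax with analytic estimate", {
  expect_equal(dominant_cluster_size(0.1, 1)$k_star, 1L)
  expect_equal(dominant_cluster_size(exp(1), 0.5)$k_star, 3L)
  d <- dominant_cluster_size(exp(10), 1)
  expect_equal(d$k_star, 11L)
  expect_equal(d$estimate, 10)
  # brute-force cross-check at scattered parameters
  for (lncs in c(2, 6, 15)) {
    k <- 1:500
    w <- log(k) - k * (k - 1) * 0.8 / 2 + k * lncs
    expect_equal(dominant_cluster_size(exp(lncs), 0.8)$k_star, which.max(w))
  }
})

test_that("log-adsorption approaches the asymptotic quadratic form", {
  expect_equal(asymptotic_log_adsorption(exp(10), 1), 50)
  expect_equal(asymptotic_log_adsorption(exp(10), 2), 25)
  expect_equal(asymptotic_log_adsorption(1 + 1e-12, 1), 0, tolerance = 1e-10)
  expect_error(asymptotic_log_adsorption(0.9, 1), class = "spovm_domain_error")
  # relative deviation shrinks monotonically along ln C_s = 5, 10, 20, 40
  dev <- vapply(c(5, 10, 20, 40), function(l) {
    abs(adsorption(exp(l), 1, log = TRUE) /
          asymptotic_log_adsorption(exp(l), 1) - 1)
  }, 0)
  expect_true(all(diff(dev) < 0))
})

test_that("denormalization scales by site count and attraction prefactor", {
  g100 <- membrane_geometry(r = 2e-3, a = 400)   # engineered tiny L_v
  p0 <- interaction_params(eps_b = 0, eps_nn = 0, e_r = 1)
  expect_equal(denormalize(0, g100, p0), 0)
  g <- membrane_geometry(1, 4)
  p1 <- interaction_params(eps_b = 0, eps_nn = 1, e_r = 1)
  expect_equal(suppressWarnings(denormalize(2, g, p1)),
               2 * g$L_v * exp(-1))
  expect_warning(denormalize(1, g, p0), "dilute")
})

test_that("cluster_distribution bundles consistent statistics", {
  d <- cluster_distribution(0.8, 0.5, eps_nn = 1)
  k <- seq_len(d$truncation_K)
  expect_true(all(d$weights >= 0))
  # C_v = sum k * (m_k/L_v) / exp(-eps_nn)
  expect_equal(sum(k * d$weights) / exp(-1), d$C_v, tolerance = 1e-12)
  expect_gte(d$mean_size, 1)
  expect_lt(d$dominant_size, d$truncation_K)
})
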