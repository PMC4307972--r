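# Law fitting: prediction, parameter recovery, divergence diagnostics,
# and curvature-versus-tension model discrimination.

test_that("predicted signal composes law, series and nuisance scales", {
  tens <- repulsion_law("tension", c1 = 0.7, c2 = 0.61)
  expect_equal(predict_adsorption(2, 0, tens), 0)
  p1 <- predict_adsorption(0.75, 1, tens, A = 1, c_0 = 1)
  expect_equal(p1, adsorption(1, 0.7 + 0.61 * 0.75), tolerance = 1e-12)
  expect_equal(predict_adsorption(0.75, 1, tens, A = 2), 2 * p1)
  expect_equal(predict_adsorption(0.75, 3, tens, c_0 = 3), p1)
})

test_that("divergence radius exists only for positive curvature laws", {
  expect_equal(divergence_radius(
    repulsion_law("curvature", c1 = 2.67, c2 = 1.1649)),
    0.4362921348314607)
  expect_equal(divergence_radius(
    repulsion_law("curvature", c1 = 2.42, c2 = 1.2277)),
    0.5073140495867768)
  expect_null(divergence_radius(repulsion_law("tension", c1 = 0.7, c2 = 0.61)))
  expect_null(divergence_radius(repulsion_law("curvature", c1 = -1, c2 = 1)))
})

test_that("noiseless radius profiles return the generating parameters", {
  d <- make_radius_profile("tension", 0.7, 0.61, A = 2.5)
  f <- fit_radius_profile(d, "tension", Cs = 1, seed = 11)
  expect_true(f$converged)
  expect_equal(f$c1, 0.7, tolerance = 1e-6)
  expect_equal(f$c2, 0.61, tolerance = 1e-6)
  expect_equal(f$A, 2.5, tolerance = 1e-6)

  d2 <- make_radius_profile("curvature", 2.67, 1.1649, A = 1.5)
  f2 <- fit_radius_profile(d2, "curvature", Cs = 1, seed = 11)
  expect_equal(f2$c1, 2.67, tolerance = 1e-6)
  expect_equal(f2$c2, 1.1649, tolerance = 1e-6)
  expect_equal(f2$divergence_radius, 1.1649 / 2.67, tolerance = 1e-6)
})

test_that("rescaling the data rescales only the amplitude", {
  d <- make_radius_profile("tension", 0.7, 0.61, A = 2)
  d2 <- d; d2$adsorption <- d2$adsorption / 2
  f <- fit_radius_profile(d, "tension", Cs = 1, seed = 3)
  f2 <- fit_radius_profile(d2, "tension", Cs = 1, seed = 3)
  expect_equal(f2$c1, f$c1, tolerance = 1e-6)
  expect_equal(f2$c2, f$c2, tolerance = 1e-6)
  expect_equal(f2$A, f$A / 2, tolerance = 1e-6)
})

test_that("degenerate designs are flagged rather than silently fitted", {
  d <- make_radius_profile("tension")
  d$adsorption <- rep(1, nrow(d))
  f <- fit_radius_profile(d, "tension", seed = 1, n_starts = 2)
  expect_match(paste(f$warnings, collapse = " "), "unconstrained")
  d1 <- d[d$radius_um == 0.75, ]
  f1 <- fit_radius_profile(d1, "tension", seed = 1, n_starts = 2)
  expect_match(paste(f1$warnings, collapse = " "), "identifiable")
})

test_that("noiseless concentration profiles recover all four parameters", {
  spec <- generator_spec(law = repulsion_law("tension", c1 = 0.7, c2 = 0.61),
                         A = 3, c_0 = 2, radii = c(0.75, 3),
                         concentrations = seq(0.2, 5, length.out = 20),
                         noise_cv = 0)
  f <- fit_concentration_profiles(generate_dataset(spec), "tension",
                                  seed = 5)
  expect_equal(f$c1, 0.7, tolerance = 1e-5)
  expect_equal(f$c2, 0.61, tolerance = 1e-5)
  expect_equal(f$A, 3, tolerance = 1e-5)
  expect_equal(f$c_0, 2, tolerance = 1e-5)
})

test_that("data confined to the linear regime is flagged weakly identified", {
  spec <- generator_spec(law = repulsion_law("tension", c1 = 0.7, c2 = 0.61),
                         A = 1, c_0 = 1, radii = c(0.75, 3),
                         concentrations = seq(1e-4, 1e-3, length.out = 5),
                         noise_cv = 0)
  f <- fit_concentration_profiles(generate_dataset(spec), "tension",
                                  seed = 2, n_starts = 4,
                                  c0_box = c(50, 5000))
  expect_match(paste(f$warnings, collapse = " "), "weakly identified")
})

test_that("tension-law cluster adsorption decays exponentially in radius", {
  # once the repulsion is strong enough that dimers dominate the cluster
  # contribution, the cluster part of the signal C_v - C_s behaves as
  # 2 C_s^2 exp(-e_r(r)), i.e. exp(-b r) with b = c2: on an even radius
  # grid its log is affine (vanishing second differences, slope -c2)
  tens <- repulsion_law("tension", c1 = 0.7, c2 = 0.61)
  r <- seq(8, 18, by = 2)
  Cs <- 1.5
  ln_cluster <- log(predict_adsorption(r, Cs, tens) - Cs)
  slopes <- diff(ln_cluster) / diff(r)
  expect_equal(mean(slopes), -0.61, tolerance = 0.01)
  second <- diff(diff(ln_cluster))
  expect_lt(max(abs(second)) / abs(mean(diff(ln_cluster))), 0.01)
})

test_that("model comparison prefers the generating law and flags ties", {
  radii <- c(0.75, 1, 1.5, 2, 3, 4.5, 7, 10, 15, 30)
  spec <- generator_spec(law = repulsion_law("tension", c1 = 0.7, c2 = 0.61),
                         A = 2, radii = radii, concentrations = 3,
                         replicates = 8, noise_cv = 0.05, seed = 42)
  cmp <- compare_models(generate_dataset(spec), Cs = 3, seed = 42,
                        n_starts = 4)
  expect_equal(cmp$ranking[1], "tension")
  expect_gt(cmp$objective_ratio, 1)
  expect_false(cmp$non_identifiable)
  d1 <- make_radius_profile("tension")[1:3, ]
  d1$radius_um <- rep(2, 3)
  cmp1 <- compare_models(d1, Cs = 1, seed = 1, n_starts = 2)
  expect_true(cmp1$non_identifiable)
})
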