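test_that("atlas role statistics match the spec within sampling error", {
  spec <- atlas_spec(n_rois = 10000,
                     odor_roles = tibble::tibble(odor = "odor_a", role = "target",
                                                 valence = "go"),
                     frac_active = c(target = 0.5),
                     mean_amplitude = c(target = -1))
  atlas <- generate_atlas(spec, seed = 7)
  n_active <- sum(atlas$mean_z != 0)        # direct counting oracle
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(n_active / 10000 - 0.5), 3 * se)
  expect_lt(abs(mean(atlas$mean_z[atlas$mean_z != 0]) - (-1)), 0.05)
})

test_that("default atlas reproduces the measured per-role statistics", {
  atlas <- generate_atlas(atlas_spec(n_rois = 4000), seed = 3)
  g <- glance(atlas)
  tgt <- g[g$role == "target", ]
  ctx <- g[g$role == "contextual", ]
  expect_lt(abs(tgt$frac_active - 0.295), 0.03)
  expect_lt(abs(tgt$mean_amplitude - (-0.32)), 0.03)
  expect_lt(abs(ctx$frac_active - 0.435), 0.03)
  expect_lt(abs(ctx$mean_amplitude - (-0.70)), 0.06)
})

test_that("all-zero activation fractions give an all-zero atlas", {
  spec <- atlas_spec(n_rois = 20,
                     frac_active = c(target = 0, contextual = 0, fixed = 0,
                                     novel = 0))
  atlas <- generate_atlas(spec, seed = 1)
  expect_true(all(atlas$mean_z == 0))
})

test_that("atlas generation is deterministic from the seed and validates input", {
  a1 <- generate_atlas(atlas_spec(n_rois = 40), seed = 5)
  a2 <- generate_atlas(atlas_spec(n_rois = 40), seed = 5)
  expect_identical(a1$mean_z, a2$mean_z)
  expect_error(atlas_spec(n_rois = 0), "n_rois")
  expect_error(atlas_spec(frac_active = c(target = 1.2, contextual = 0.4,
                                          fixed = 0.4, novel = 0.4)),
               "\\[0, 1\\]")
  expect_error(atlas_spec(mean_amplitude = c(target = 0.3, contextual = -0.7,
                                             fixed = -0.4, novel = -0.6)),
               "<= 0")
})

test_that("noiseless trials equal the mean pattern exactly", {
  atlas <- small_atlas(20)
  ts <- instantiate_trials(atlas, noise_model(cv = 0, sigma_noise = 0),
                           n_repeats = 3, seed = 1)
  for (t in 1:3) expect_equal(ts$trials[, , t], atlas$mean_z)
})

test_that("trial variance follows the mean-variance law", {
  # every entry mean -2: pooled empirical s.d. must match
  # sqrt(sigma_noise^2 + CV^2 * mu^2) within 1%
  mu <- matrix(-2, nrow = 20, ncol = 50)
  ts <- instantiate_trials(mu, noise_model_wt(), n_repeats = 200, seed = 11)
  expected <- sqrt(1.59^2 + 0.34^2 * 4)
  emp <- sd(as.vector(ts$trials))
  expect_lt(abs(emp - expected) / expected, 0.01)
})

test_that("the variance law holds across a grid of means", {
  nm <- noise_model(cv = 0.3, cv_uncorr = 0.2, sigma_noise = 1.2)
  for (mu in c(-6, -3, -0.5)) {
    m <- matrix(mu, nrow = 10, ncol = 40)
    ts <- instantiate_trials(m, nm, n_repeats = 150, seed = 17 + round(abs(mu)))
    expected <- sqrt(1.2^2 + 0.09 * mu^2)
    expect_lt(abs(sd(as.vector(ts$trials)) - expected) / expected, 0.03)
  }
})

test_that("trial instantiation is bit-reproducible from the seed", {
  atlas <- small_atlas(15)
  t1 <- instantiate_trials(atlas, noise_model_wt(), 4, seed = 9)
  t2 <- instantiate_trials(atlas, noise_model_wt(), 4, seed = 9)
  expect_identical(t1$trials, t2$trials)
  expect_error(noise_model(cv = -0.1), "cv")
  expect_error(instantiate_trials(atlas, noise_model_wt(), 0), "n_repeats")
})

test_that("correlated gain shows up as cross-ROI covariance, not extra variance", {
  mu <- matrix(-3, nrow = 5, ncol = 100)
  nm <- noise_model(cv = 0.4, cv_uncorr = 0.2, sigma_noise = 0)
  ts <- instantiate_trials(mu, nm, n_repeats = 400, seed = 23)
  # within one odor, two ROIs share the per-trial gain
  r1 <- ts$trials[1, 1, ]; r2 <- ts$trials[1, 2, ]
  expect_gt(cor(r1, r2), 0.4)   # cv_corr^2 / cv^2 = 0.75 expected
  ts0 <- instantiate_trials(mu, nm, n_repeats = 400, seed = 23,
                            include_correlated = FALSE)
  expect_lt(abs(cor(ts0$trials[1, 1, ], ts0$trials[1, 2, ])), 0.15)
})

test_that("synthetic behavior tables respect binomial statistics", {
  perf <- c(a = 0.9, b = 0.6, c = 0.5)
  tbl <- generate_behavior(perf, behavioral_noise_sd = 0,
                           n_trials_per_odor = 10000, seed = 2)
  expect_true(all(abs(tbl$performance - perf) < 3 * sqrt(perf * (1 - perf) / 10000)))
  set.seed(99)
  reps <- replicate(200, {
    generate_behavior(c(x = 0.7), 0, n_trials_per_odor = 30)$performance
  })
  expect_lt(abs(sd(reps) - sqrt(0.7 * 0.3 / 30)), 0.03)
  expect_error(generate_behavior(c(1.2)), "\\[0, 1\\]")
})
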