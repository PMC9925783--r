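test_that("a minimal dictionary is exactly the normalized known patterns", {
  atlas <- small_atlas(30, seed = 9)
  d <- build_dictionary(atlas, m_total = 9, seed = 1)
  expect_equal(ncol(d$elements), 9)
  expect_equal(d$known, colnames(d$elements))
  for (k in d$known) {
    raw <- atlas$mean_z[k, ]
    expect_equal(unname(d$elements[, k]), unname(raw / sd(raw)))
  }
  expect_equal(unname(apply(d$elements, 2, sd)), rep(1, 9))
  expect_error(build_dictionary(atlas, m_total = 5), "m_total")
})

test_that("generated elements follow the 20-odor mean and covariance", {
  atlas <- small_atlas(12, seed = 10)
  # draw many raw (pre-normalization) samples through the same eigen route
  all_p <- t(atlas$mean_z)
  mu <- rowMeans(all_p)
  cv <- cov(t(all_p))
  d <- build_dictionary(atlas, m_total = 9 + 4000, seed = 2)
  # undo the per-element normalization by rescaling is not possible in
  # general, so check the correlation structure, which normalization keeps
  synth <- d$elements[, -(1:9)]
  emp <- cor(t(synth))
  expect_gt(cor(emp[upper.tri(emp)], stats::cov2cor(cv)[upper.tri(cv)]), 0.95)
  cor_mu <- cor(rowMeans(synth), mu)
  expect_gt(cor_mu, 0.8)
})

test_that("huge penalties shrink every concentration to zero", {
  atlas <- small_atlas(20, seed = 11)
  d <- build_dictionary(atlas, m_total = 15, seed = 3)
  est <- lasso_solve(d, atlas$mean_z["target_go_1", ], lambda = 1e6)
  expect_true(all(est$concentrations == 0))
})

test_that("an orthogonal dictionary element is recovered with coefficient 1", {
  D <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  colnames(D) <- c("a", "b", "c")
  est <- lasso_solve(D, D[, 2], lambda = 1e-8)
  expect_equal(unname(est$concentrations), c(0, 1, 0), tolerance = 1e-4)
})

test_that("the two-element solution matches a grid-search cost minimizer", {
  set.seed(19)
  for (rep in 1:4) {
    D <- matrix(rnorm(10 * 2), 10, 2)
    s <- rnorm(10)
    lambda <- c(0.01, 0.5, 2)[1 + rep %% 3]
    est <- lasso_solve(D, s, lambda = lambda)
    oracle <- grid_search_lasso2(D, s, lambda)
    expect_equal(unname(est$concentrations), oracle, tolerance = 1e-3)
    expect_lte(lasso_cost(est$concentrations, D, s, lambda),
               lasso_cost(c(0, 0), D, s, lambda) + 1e-8)
    expect_lte(lasso_cost(est$concentrations, D, s, lambda),
               lasso_cost(oracle, D, s, lambda) + 1e-4)
  }
})

test_that("the number of active elements never grows with the penalty", {
  atlas <- small_atlas(25, seed = 12)
  d <- build_dictionary(atlas, m_total = 40, seed = 4)
  obs <- compose_mixture(atlas$mean_z[c("target_go_1", "context_2", "limonene"), ],
                         threshold = -0.42)
  counts <- vapply(c(1e-5, 1e-3, 1e-1, 1, 10, 100), function(lam) {
    sum(lasso_solve(d, obs, lambda = lam)$concentrations != 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("go/no-go readout compares the two pair maxima, ties to no-go", {
  atlas <- small_atlas(15, seed = 13)
  d <- build_dictionary(atlas, m_total = 9, seed = 5)
  cj <- setNames(numeric(9), colnames(d$elements))
  cj[d$go_idx] <- c(0.8, 0.0)
  cj[d$nogo_idx] <- c(0.1, 0.2)
  expect_equal(go_nogo_readout(cj, d), "go")
  cj[d$go_idx] <- c(0.2, 0.1)
  expect_equal(go_nogo_readout(cj, d), "nogo")   # exact tie at 0.2
})

test_that("a target mixture drives the target's concentration above the no-go pair", {
  atlas <- small_atlas(60, seed = 14)
  d <- build_dictionary(atlas, m_total = 200, seed = 6)
  obs <- compose_mixture(
    atlas$mean_z[c("target_go_2", "context_3", "novel_05"), ],
    threshold = -0.42, saturation = saturation_model_measured())
  est <- lasso_solve(d, obs)
  expect_equal(go_nogo_readout(est, d), "go")
  expect_gt(max(est$concentrations[d$go_idx]),
            max(est$concentrations[d$nogo_idx]))
})

test_that("noiseless mixtures with the exact components solve at ceiling", {
  atlas <- small_atlas(40, seed = 15)
  design <- enumerate_design("reduced")
  test_d <- design[design$set == "test", ][1:12, ]
  # dictionary holds every component pattern, observations are noiseless
  ev <- evaluate_lasso(atlas, test_d, sizes = 30, n_dictionaries = 2,
                       cv = 0, lambda = 1e-4, threshold = NULL,
                       saturation = NULL, seed = 7,
                       known_odors = rownames(atlas$mean_z))
  expect_equal(mean(ev$results$fraction_correct), 1)
})

test_that("shuffled-valence mixtures score near chance", {
  atlas <- small_atlas(40, seed = 16)
  design <- enumerate_design("reduced")
  test_d <- design[design$set == "test", ]
  set.seed(20)
  test_d$valence <- sample(test_d$valence)
  ev <- evaluate_lasso(atlas, test_d, sizes = 60, n_dictionaries = 2,
                       cv = 0.25, seed = 8)
  expect_lt(abs(mean(ev$results$fraction_correct) - 0.5),
            3 * sqrt(0.25 / 88))
})
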