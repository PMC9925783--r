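test_that("centering removes training means and round-trips test patterns", {
  toy <- toy_patterns()
  same <- matrix(rep(c(-1, -2, 0), 3), nrow = 3, byrow = TRUE)
  expect_true(all(center_patterns(same)$train == 0))
  cp <- center_patterns(toy$train, toy$train[1:2, ])
  expect_equal(unname(colMeans(cp$train)), rep(0, 5))
  expect_equal(cp$test + rep(cp$means, each = 2), toy$train[1:2, ],
               ignore_attr = TRUE)
  expect_error(center_patterns(toy$train[0, , drop = FALSE]), "empty")
})

test_that("auROC equals exhaustive pair counting, including ties", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(6:14, 1)
    vals <- sample(c(rnorm(n), rep(0.5, 3)))[1:n]   # force some ties
    is_go <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(is_go) || !any(is_go)) next
    expect_equal(glomix:::auroc(vals, is_go), auroc_pairs(vals, is_go))
  }
})

test_that("discriminability folds auROC around one half", {
  resp <- c(-3, -2.5, -0.5, -0.2)
  labs <- c("go", "go", "nogo", "nogo")
  d <- glomerulus_discriminability(resp, labs)
  expect_equal(d$auroc, 0)          # go responses all more negative
  expect_equal(d$discriminability, 1)
  # auROC 0.2 -> discriminability 0.8 by the defining transform
  expect_equal(abs(0.2 - 0.5) + 0.5, 0.8)
  expect_error(glomerulus_discriminability(resp, rep("go", 4)), "Both classes")
})

test_that("discriminability is invariant to label flip and monotone transforms", {
  set.seed(15)
  vals <- rnorm(12)
  is_go <- rep(c(TRUE, FALSE), 6)
  d1 <- glomerulus_discriminability(vals, is_go)$discriminability
  d2 <- glomerulus_discriminability(vals, !is_go)$discriminability
  expect_equal(d1, d2)
  d3 <- glomerulus_discriminability(exp(2 * vals) - 1, is_go)$discriminability
  expect_equal(d1, d3)
})

test_that("best-glomerulus selection finds the separating ROI and threshold", {
  set.seed(16)
  n <- 10
  sep <- c(runif(5, -2.2, -2.0), runif(5, -1.2, -1.0))  # gap [-2, -1.2]
  train <- cbind(sep, matrix(rnorm(n * 4, -1, 0.2), n, 4))
  colnames(train) <- paste0("roi_", 1:5)
  labels <- c(rep("go", 5), rep("nogo", 5))
  cls <- fit_best_glomerulus(train, labels)
  expect_equal(cls$roi, 1L)
  expect_true(cls$threshold > -2.0 && cls$threshold < -1.2)
  expect_equal(unname(predict(cls, train)), labels)
  expect_equal(cls$train_discriminability, 1)
})

test_that("the Youden threshold matches a brute-force sweep", {
  set.seed(17)
  v <- rnorm(14)
  is_go <- rep(c(TRUE, FALSE), 7)
  train <- matrix(v, ncol = 1)
  cls <- fit_best_glomerulus(train, ifelse(is_go, "go", "nogo"))
  sweep_best <- -Inf
  for (th in seq(min(v) - 0.1, max(v) + 0.1, length.out = 2000)) {
    pg <- if (cls$go_if_less) v < th else v > th
    sweep_best <- max(sweep_best, mean(pg[is_go]) - mean(pg[!is_go]))
  }
  pg <- if (cls$go_if_less) v < cls$threshold else v > cls$threshold
  expect_equal(mean(pg[is_go]) - mean(pg[!is_go]), sweep_best)
})

test_that("linear decoders reach 100% training accuracy on separable data", {
  toy <- toy_patterns()
  for (fam in c("svm", "logistic")) {
    dec <- train_linear(toy$train, toy$labels, fam, lambda = 0)
    expect_equal(unname(predict(dec, toy$train)), toy$labels)
  }
})

test_that("a large penalty shrinks every weight to zero", {
  toy <- toy_patterns()
  for (fam in c("svm", "logistic")) {
    dec <- train_linear(toy$train, toy$labels, fam, lambda = 50)
    expect_true(all(dec$weights == 0))
    # prediction then falls to the bias sign alone
    expect_length(unique(predict(dec, toy$train)), 1)
  }
})

test_that("the 1-D logistic boundary sits at the class midpoint", {
  # symmetric two-point classes: the Bayes boundary is the midpoint
  x <- matrix(c(rep(-3, 20), rep(-1, 20)) + rep(c(-0.01, 0.01), 20), ncol = 1)
  labels <- c(rep("go", 20), rep("nogo", 20))
  dec <- train_linear(x, labels, "logistic", lambda = 0.01)
  boundary <- -dec$bias / dec$weights[1]
  expect_equal(boundary, -2, tolerance = 0.1)
})

test_that("linear prediction is the sign of the readout, ties to no-go", {
  dec <- structure(list(weights = c(0, 0, 0), bias = 1, family = "svm",
                        lambda = 0, roi_names = NULL),
                   class = "linear_decoder")
  expect_equal(unname(predict(dec, matrix(rnorm(9), 3))), rep("go", 3))
  dec$bias <- 0
  expect_equal(unname(predict(dec, matrix(rnorm(3), 1))), "nogo")
  dec3 <- structure(list(weights = c(0.5, -1, 2), bias = 0.25, family = "svm",
                         lambda = 0, roi_names = NULL),
                    class = "linear_decoder")
  p <- c(-1, -2, 0.5)
  expect_equal(predict(dec3, p, type = "score"),
               0.5 * -1 + -1 * -2 + 2 * 0.5 + 0.25)  # manual dot product
  expect_error(predict(dec3, c(1, 2)), "ROI count")
})

test_that("NNC returns the valence of the best-matching template", {
  toy <- toy_patterns()
  fit <- nnc_fit(toy$train, toy$labels, selectivity_threshold = 0.5)
  expect_equal(sum(fit$keep), 5)   # threshold 0.5 keeps every ROI
  expect_equal(unname(predict(fit, toy$train)), toy$labels)
  # exhaustive-comparison oracle on a random pattern
  set.seed(18)
  pat <- rnorm(5)
  centered <- pat - fit$means
  dots <- apply(fit$templates, 1, function(tmp) sum(centered * tmp))
  expect_equal(unname(nnc_classify(toy$train, toy$labels, pat)),
               toy$labels[which.max(dots)])
  expect_error(nnc_fit(toy$train, toy$labels, 0.4), "selectivity_threshold")
})

test_that("NNC selectivity filter excludes undiscriminative ROIs or errors", {
  toy <- toy_patterns()
  fit <- nnc_fit(toy$train, toy$labels, selectivity_threshold = 1)
  expect_true(all(fit$keep[1:4]))   # ROIs 1-4 separate perfectly
  expect_false(fit$keep[5])         # ROI 5 carries no label information
})

test_that("noiseless evaluation of a perfect decoder scores 1.0", {
  toy <- toy_patterns()
  dec <- train_linear(toy$train, toy$labels, "svm", 0)
  res <- evaluate_decoder(dec, toy$train, toy$labels, cv = 0,
                          n_instantiations = 5, seed = 1)
  expect_equal(res$fraction_correct, 1)
})

test_that("label-shuffled evaluation sits at chance for every decoder family", {
  atlas <- small_atlas(40, seed = 55)
  d <- enumerate_design("full")
  tr <- compose_design(atlas, d[d$set == "training", ], threshold = -0.42)
  te <- compose_design(atlas, d[d$set == "test", ], threshold = -0.42)
  set.seed(77)
  shuffled <- sample(te$design$valence)
  decoders <- list(
    svm = train_linear(tr$patterns, tr$design$valence, "svm", 0),
    nnc = nnc_fit(tr$patterns, tr$design$valence),
    glom = fit_best_glomerulus(tr$patterns, tr$design$valence)
  )
  for (dec in decoders) {
    res <- evaluate_decoder(dec, te$patterns, shuffled, cv = 0.25,
                            n_instantiations = 20, seed = 91)
    # 176 x 20 outcomes; mixtures are the independent unit
    expect_lt(abs(res$fraction_correct - 0.5), 3 * sqrt(0.25 / 176))
  }
})

test_that("decoder evaluation is reproducible and carries its seed", {
  toy <- toy_patterns()
  dec <- train_linear(toy$train, toy$labels, "svm", 0)
  r1 <- evaluate_decoder(dec, toy$train, toy$labels, cv = 0.4,
                         n_instantiations = 11, seed = 13)
  r2 <- evaluate_decoder(dec, toy$train, toy$labels, cv = 0.4,
                         n_instantiations = 11, seed = 13)
  expect_identical(r1$correct, r2$correct)
  expect_equal(r1$seed, 13)
})

test_that("sparser penalties never add nonzero weights", {
  atlas <- small_atlas(50, seed = 66)
  d <- enumerate_design("full")
  tr <- compose_design(atlas, d[d$set == "training", ], threshold = -0.42)
  for (fam in c("svm", "logistic")) {
    counts <- vapply(seq(0, 1, length.out = 21), function(lam) {
      sum(train_linear(tr$patterns, tr$design$valence, fam, lam)$weights != 0)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0),
                info = paste(fam, paste(counts, collapse = ",")))
  }
})
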