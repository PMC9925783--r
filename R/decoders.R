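#' Center glomerular patterns by training-set means
#'
#' Subtracts the per-ROI mean response of the training set from both the
#' training and the test patterns; the stored means let new patterns be
#' centered identically later.
#'
#' @param train Numeric matrix, training mixtures x ROIs (>= 1 row).
#' @param test Optional numeric matrix sharing the ROI axis.
#' @return List with `train`, `test` (or `NULL`) and `means`.
#' @export
center_patterns <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0) abort("Training set is empty.")
  means <- colMeans(train)
  out_test <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    if (ncol(test) != ncol(train)) abort("Train and test must share the ROI axis.")
    out_test <- sweep(test, 2, means)
  }
  list(train = sweep(train, 2, means), test = out_test, means = means)
}

#' Single-glomerulus discriminability
#'
#' Rank-based area under the ROC curve for one ROI's responses to go vs
#' no-go mixtures (ties count one half), and the orientation-free
#' discriminability `abs(auROC - 0.5) + 0.5`: 1 for perfect separation in
#' either direction, 0.5 for none.
#'
#' @param responses Numeric vector of per-mixture responses of one ROI.
#' @param labels Valence per mixture: `"go"`/`"nogo"` (or logical, TRUE = go).
#' @return A one-row tibble with `auroc` and `discriminability`.
#' @export
glomerulus_discriminability <- function(responses, labels) {
  is_go <- as_go(labels)
  if (all(is_go) || !any(is_go)) abort("Both classes must be present.")
  tibble(auroc = auroc(responses, is_go),
         discriminability = abs(auroc(responses, is_go) - 0.5) + 0.5)
}

as_go <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("go", "nogo"))
  if (length(bad)) abort(paste0("Unknown labels: ", paste(bad, collapse = ", ")))
  labels == "go"
}

# rank-based auROC of go (positive class) vs no-go; ties get half credit
auroc <- function(values, is_go) {
  r <- rank(values)
  n1 <- sum(is_go); n0 <- sum(!is_go)
  (sum(r[is_go]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the best single-glomerulus classifier
#'
#' Selects the ROI with the highest training discriminability (ties go to the
#' lowest ROI index) and places the decision threshold at the point of the
#' ROC curve tangent to a 45-degree line, i.e. the threshold maximizing
#' TPR - FPR (Youden). The orientation - whether more-negative responses
#' signal go - is learned from the training data, not assumed.
#'
#' @param train Numeric matrix, training mixtures x ROIs.
#' @param labels Valence per training mixture (`"go"`/`"nogo"` or logical).
#' @return Object of class `glom_classifier` with `roi`, `threshold`,
#'   `go_if_less` (TRUE if responses below threshold are called go) and
#'   `train_auroc`.
#' @export
fit_best_glomerulus <- function(train, labels) {
  train <- as.matrix(train)
  is_go <- as_go(labels)
  if (sum(is_go) < 2 || sum(!is_go) < 2) abort("Need >= 2 mixtures per class.")
  aucs <- apply(train, 2, auroc, is_go = is_go)
  disc <- abs(aucs - 0.5) + 0.5
  best <- which.max(disc)   # ties -> lowest index
  v <- train[, best]
  go_if_less <- aucs[best] < 0.5
  # Youden sweep: candidate cuts are midpoints between sorted unique values
  u <- sort(unique(v))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  score <- vapply(cand, function(th) {
    pred_go <- if (go_if_less) v < th else v > th
    mean(pred_go[is_go]) - mean(pred_go[!is_go])
  }, numeric(1))
  structure(
    list(roi = unname(best), roi_name = colnames(train)[best],
         threshold = cand[which.max(score)], go_if_less = go_if_less,
         train_auroc = unname(aucs[best]),
         train_discriminability = unname(disc[best])),
    class = "glom_classifier"
  )
}

#' @export
print.glom_classifier <- function(x, ...) {
  cat(sprintf(
    "<glom_classifier> ROI %s, threshold %.3f z (go if %s), training auROC %.3f\n",
    x$roi_name %||% x$roi, x$threshold, if (x$go_if_less) "below" else "above",
    x$train_auroc))
  invisible(x)
}

#' @export
predict.glom_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  v <- newdata[, object$roi]
  pred_go <- if (object$go_if_less) v < object$threshold else v > object$threshold
  ifelse(pred_go, "go", "nogo")
}

#' Train an L1-regularized linear decoder
#'
#' Fits a linear go/no-go readout \eqn{c = \sum_i w_i s_i + w_0} on the mean
#' training patterns, with labels +1 (go) / -1 (no-go) and an L1 penalty of
#' strength `lambda` on the weights (bias unpenalized). `family = "logistic"`
#' minimizes the penalized logistic loss (via glmnet for `lambda > 0`);
#' `family = "svm"` minimizes the penalized squared-hinge loss with a
#' proximal-gradient (FISTA) solver. `lambda = 0` gives the unpenalized fit.
#'
#' @param train Numeric matrix, training mixtures x ROIs.
#' @param labels Valence per training mixture.
#' @param family `"svm"` or `"logistic"`.
#' @param lambda Sparsity penalty (>= 0); larger values zero out more
#'   weights.
#' @return Object of class `linear_decoder` with `weights`, `bias`, `family`,
#'   `lambda`.
#' @export
train_linear <- function(train, labels, family = c("svm", "logistic"),
                         lambda = 0) {
  family <- match.arg(family)
  check_number(lambda, "lambda", lower = 0)
  train <- as.matrix(train)
  y <- ifelse(as_go(labels), 1, -1)
  if (length(unique(y)) < 2) abort("Both classes must be present.")
  if (family == "logistic") {
    if (lambda > 0) {
      x <- train
      one_col <- ncol(x) == 1L
      if (one_col) x <- cbind(x, 0)   # glmnet needs >= 2 columns
      # small-n class warnings are routine for 8-16 training mixtures
      fit <- suppressWarnings(
        glmnet::glmnet(x, factor(y, levels = c(-1, 1)),
                       family = "binomial", alpha = 1,
                       lambda = lambda, standardize = FALSE,
                       thresh = 1e-10, maxit = 1e6))
      w <- as.numeric(coef(fit))[-1]
      if (one_col) w <- w[1]
      b <- as.numeric(coef(fit))[1]
    } else {
      # unpenalized; on separable data weights diverge, the boundary converges
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, train), (y + 1) / 2,
                       family = stats::binomial(),
                       control = list(maxit = 100)))
      b <- fit$coefficients[1]
      w <- fit$coefficients[-1]
      w[is.na(w)] <- 0
      if (is.na(b)) b <- 0
    }
  } else {
    sol <- l1_sqhinge_fit(train, y, lambda)
    w <- sol$w
    b <- sol$b
  }
  structure(
    list(weights = unname(w), bias = unname(b), family = family,
         lambda = lambda, roi_names = colnames(train)),
    class = "linear_decoder"
  )
}

# FISTA on f(w, b) = mean(max(0, 1 - y (Xw + b))^2) + lambda * ||w||_1
l1_sqhinge_fit <- function(X, y, lambda, max_iter = 4000, tol = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  Xb <- cbind(X, 1)                      # last column carries the bias
  L <- 2 * norm(Xb, "2")^2 / n           # Lipschitz constant of the gradient
  if (L == 0) L <- 1
  w <- numeric(p + 1)
  z <- w; tk <- 1
  soft <- function(v, s) sign(v) * pmax(abs(v) - s, 0)
  obj <- function(w) {
    m <- pmax(0, 1 - y * drop(Xb %*% w))
    mean(m^2) + lambda * sum(abs(w[seq_len(p)]))
  }
  prev <- obj(w)
  for (it in seq_len(max_iter)) {
    m <- pmax(0, 1 - y * drop(Xb %*% z))
    grad <- -2 / n * drop(crossprod(Xb, y * m))
    w_new <- z - grad / L
    w_new[seq_len(p)] <- soft(w_new[seq_len(p)], lambda / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- w_new + (tk - 1) / t_new * (w_new - w)
    w <- w_new; tk <- t_new
    if (it %% 25 == 0) {
      cur <- obj(w)
      if (abs(prev - cur) < tol * max(1, abs(prev))) break
      prev <- cur
    }
  }
  list(w = w[seq_len(p)], b = w[p + 1])
}

#' @export
print.linear_decoder <- function(x, ...) {
  cat(sprintf("<linear_decoder> %s, lambda = %.3g, %d/%d nonzero weights\n",
              x$family, x$lambda, sum(x$weights != 0), length(x$weights)))
  invisible(x)
}

#' @export
tidy.linear_decoder <- function(x, ...) {
  tibble(term = c("(bias)", x$roi_names %||% paste0("roi_", seq_along(x$weights))),
         estimate = c(x$bias, x$weights))
}

#' @export
glance.linear_decoder <- function(x, ...) {
  tibble(family = x$family, lambda = x$lambda,
         n_nonzero = sum(x$weights != 0), n_rois = length(x$weights))
}

#' Predict go/no-go from a linear decoder
#'
#' The decision is the sign of the linear readout; an output of exactly zero
#' is called no-go (deterministic conservative tie-break).
#'
#' @param object A `linear_decoder`.
#' @param newdata Numeric matrix (patterns x ROIs) or a single pattern.
#' @param type `"class"` (default) or `"score"`.
#' @param ... Unused.
#' @return Character vector of `"go"`/`"nogo"`, or numeric scores.
#' @export
predict.linear_decoder <- function(object, newdata, type = c("class", "score"),
                                   ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights)) {
    abort("Pattern length does not match the decoder's ROI count.")
  }
  score <- drop(newdata %*% object$weights) + object$bias
  if (type == "score") return(score)
  ifelse(score > 0, "go", "nogo")
}

#' Nearest-neighbor template classifier
#'
#' `nnc_fit()` stores the training mixtures as templates after centering each
#' glomerulus by its training-set mean; ROIs whose training discriminability
#' falls below `selectivity_threshold` are excluded (0.5 keeps all ROIs).
#' Prediction computes the dot product between the centered test pattern and
#' every template and returns the valence of the largest (ties go to the
#' lowest template index). `nnc_classify()` is a one-shot wrapper.
#'
#' @param train Numeric matrix, training mixtures x ROIs.
#' @param labels Valence per training mixture.
#' @param selectivity_threshold Minimum training discriminability for an ROI
#'   to be included, in \[0.5, 1\].
#' @return `nnc_fit()`: object of class `nnc`.
#' @export
nnc_fit <- function(train, labels, selectivity_threshold = 0.5) {
  check_number(selectivity_threshold, "selectivity_threshold", lower = 0.5, upper = 1)
  train <- as.matrix(train)
  is_go <- as_go(labels)
  disc <- apply(train, 2, function(v) abs(auroc(v, is_go) - 0.5) + 0.5)
  keep <- disc >= selectivity_threshold
  if (!any(keep)) abort("No ROI survives the selectivity filter.")
  means <- colMeans(train)
  templates <- sweep(train[, keep, drop = FALSE], 2, means[keep])
  structure(
    list(templates = templates, labels = ifelse(is_go, "go", "nogo"),
         means = means, keep = keep,
         selectivity_threshold = selectivity_threshold),
    class = "nnc"
  )
}

#' @export
print.nnc <- function(x, ...) {
  cat(sprintf("<nnc> %d templates, %d/%d ROIs (selectivity >= %.2f)\n",
              nrow(x$templates), sum(x$keep), length(x$keep),
              x$selectivity_threshold))
  invisible(x)
}

#' @export
predict.nnc <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$keep)) {
    abort("Pattern length does not match the classifier's ROI count.")
  }
  centered <- sweep(newdata[, object$keep, drop = FALSE], 2,
                    object$means[object$keep])
  dots <- centered %*% t(object$templates)
  object$labels[apply(dots, 1, which.max)]   # which.max: ties -> lowest index
}

#' @rdname nnc_fit
#' @param pattern Pattern(s) to classify.
#' @return `nnc_classify()`: character vector of `"go"`/`"nogo"`.
#' @export
nnc_classify <- function(train, labels, pattern, selectivity_threshold = 0.5) {
  predict(nnc_fit(train, labels, selectivity_threshold), pattern)
}

#' Evaluate a decoder on noisy instantiations of a test set
#'
#' For every test mixture, draws `n_instantiations` single-trial patterns
#' under the multiplicative noise model (`mean * (1 + cv * eps)`, independent
#' Gaussian `eps` per glomerulus; population decoders see only the
#' uncorrelated variability) and scores the fraction of instantiations the
#' decoder labels correctly.
#'
#' @param decoder A `linear_decoder`, `nnc` or `glom_classifier`.
#' @param test Numeric matrix, test mixtures x ROIs (mean patterns).
#' @param labels True valence per test mixture.
#' @param cv Coefficient of variation of the instantiation noise
#'   (default 0.25, the uncorrelated variability of the awake WT regime).
#' @param n_instantiations Instantiations per mixture (default 100).
#' @param seed Integer seed.
#' @param design Optional design tibble row-aligned with `test` (columns
#'   `background`, ... ) used for the per-novel-odor breakdown.
#' @return Object of class `decoder_result`: `fraction_correct`,
#'   `per_mixture` tibble, `correct` (mixtures x instantiations logical
#'   matrix), `by_background` (when `design` given), `seed`.
#' @export
evaluate_decoder <- function(decoder, test, labels, cv = 0.25,
                             n_instantiations = 100, seed = NULL,
                             design = NULL) {
  check_number(cv, "cv", lower = 0)
  check_count(n_instantiations, "n_instantiations")
  test <- as.matrix(test)
  labels <- as.character(ifelse(as_go(labels), "go", "nogo"))
  n_mix <- nrow(test)
  correct <- matrix(NA, n_mix, n_instantiations)
  with_seed(seed, {
    for (k in seq_len(n_instantiations)) {
      inst <- test * (1 + cv * matrix(rnorm(length(test)), n_mix, ncol(test)))
      pred <- predict(decoder, inst)
      correct[, k] <- pred == labels
    }
  })
  per_mixture <- tibble(
    mixture = rownames(test) %||% as.character(seq_len(n_mix)),
    valence = labels,
    fraction_correct = rowMeans(correct)
  )
  by_background <- NULL
  if (!is.null(design) && "background" %in% names(design)) {
    by_background <- per_mixture %>%
      dplyr::mutate(background = design$background) %>%
      dplyr::group_by(.data$background) %>%
      dplyr::summarise(fraction_correct = mean(.data$fraction_correct),
                       .groups = "drop")
  }
  structure(
    list(fraction_correct = mean(correct), per_mixture = per_mixture,
         correct = correct, by_background = by_background,
         cv = cv, n_instantiations = n_instantiations, seed = seed),
    class = "decoder_result"
  )
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result> %.1f%% correct (%d mixtures x %d instantiations)\n",
              100 * x$fraction_correct, nrow(x$per_mixture), x$n_instantiations))
  invisible(x)
}

#' @export
tidy.decoder_result <- function(x, ...) x$per_mixture

#' @export
glance.decoder_result <- function(x, ...) {
  tibble(fraction_correct = x$fraction_correct,
         n_mixtures = nrow(x$per_mixture),
         n_instantiations = x$n_instantiations, cv = x$cv)
}

#' @export
autoplot.decoder_result <- function(object, ...) {
  df <- object$by_background %||%
    dplyr::rename(object$per_mixture, background = "mixture")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$background,
                                   y = .data$fraction_correct)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fraction correct") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
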