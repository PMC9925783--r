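#' Build an odor dictionary for sparse deconvolution
#'
#' A dictionary holds one activation pattern per candidate odor. The known
#' elements are the patterns of the nine odors an animal is trained with
#' (4 targets + 4 contextual backgrounds + the fixed background); the
#' remaining elements stand in for other odors the animal may know and are
#' drawn from a multivariate Gaussian whose mean vector and ROI-by-ROI
#' covariance are estimated from the full 20-odor panel, preserving the
#' average activation per glomerulus and the interglomerular correlations.
#' The rank-deficient 20-sample covariance is sampled through its
#' eigendecomposition restricted to non-negative eigenvalues. Every element
#' (known and generated) is normalized to unit variance of its entries
#' across ROIs.
#'
#' @param atlas A `glom_atlas` containing the full odor panel.
#' @param m_total Total number of dictionary elements (>= number of known
#'   odors).
#' @param seed Integer seed for the Gaussian draws.
#' @param known_odors Which odors enter as known elements; defaults to the
#'   trained nine (targets + contextual backgrounds + fixed background).
#' @return Object of class `odor_dictionary`: `elements` (ROIs x m matrix),
#'   `known` (names of known elements), `go_idx`, `nogo_idx`, `seed`.
#' @export
#' @examples
#' atlas <- generate_atlas(atlas_spec(n_rois = 40), seed = 1)
#' d <- build_dictionary(atlas, m_total = 50, seed = 2)
#' ncol(d$elements)
build_dictionary <- function(atlas, m_total = 500, seed = NULL,
                             known_odors = NULL) {
  stopifnot(inherits(atlas, "glom_atlas"))
  roles <- atlas$odor_roles
  if (is.null(known_odors)) {
    known_odors <- roles$odor[roles$role %in% c("target", "contextual", "fixed")]
  }
  check_count(m_total, "m_total", min = length(known_odors))
  all_patterns <- t(atlas$mean_z)                     # ROIs x odors
  known <- all_patterns[, known_odors, drop = FALSE]
  n_extra <- m_total - length(known_odors)
  extras <- NULL
  if (n_extra > 0) {
    mu <- rowMeans(all_patterns)
    cv <- stats::cov(t(all_patterns))                 # ROIs x ROIs, rank-deficient
    eg <- eigen(cv, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-12
    if (!any(pos)) abort("Covariance has no positive eigenvalues.")
    fac <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]),
                                                    nrow = sum(pos))
    extras <- with_seed(seed, {
      z <- matrix(rnorm(sum(pos) * n_extra), sum(pos), n_extra)
      mu + fac %*% z
    })
    colnames(extras) <- sprintf("synthetic_%03d", seq_len(n_extra))
  }
  elements <- cbind(known, extras)
  sds <- apply(elements, 2, sd)
  sds[sds == 0] <- 1
  elements <- sweep(elements, 2, sds, "/")            # unit variance across ROIs
  go_odors <- roles$odor[roles$role == "target" & roles$valence == "go"]
  nogo_odors <- roles$odor[roles$role == "target" & roles$valence == "nogo"]
  structure(
    list(elements = elements, known = known_odors,
         go_idx = match(go_odors, colnames(elements)),
         nogo_idx = match(nogo_odors, colnames(elements)),
         seed = seed),
    class = "odor_dictionary"
  )
}

#' @export
print.odor_dictionary <- function(x, ...) {
  cat(sprintf("<odor_dictionary> %d ROIs x %d elements (%d known)\n",
              nrow(x$elements), ncol(x$elements), length(x$known)))
  invisible(x)
}

#' Sparse deconvolution of an observed glomerular pattern
#'
#' Estimates the concentration of every dictionary element in an observed
#' pattern by minimizing the L1-penalized reconstruction cost
#' \deqn{\sum_i (s_i - \sum_j c_j d_{ij})^2 + \lambda \sum_j |c_j|.}
#' Coefficients are unconstrained in sign unless `nonneg = TRUE`. The solver
#' is glmnet coordinate descent; its objective is `(1/2n) RSS + lambda_g L1`,
#' so the user-facing `lambda` is mapped to `lambda / (2 n)` internally.
#'
#' @param dictionary An [build_dictionary()] result, or a plain ROIs x m
#'   matrix.
#' @param observed Numeric vector of observed z per ROI.
#' @param lambda Sparseness constraint (default 1e-4).
#' @param nonneg Constrain concentrations to be non-negative (default FALSE).
#' @return Object of class `concentration_estimate`: `concentrations` (named
#'   numeric, length m), `residual` (root mean squared reconstruction
#'   error), `lambda`.
#' @export
lasso_solve <- function(dictionary, observed, lambda = 1e-4, nonneg = FALSE) {
  D <- if (inherits(dictionary, "odor_dictionary")) dictionary$elements
       else as.matrix(dictionary)
  check_number(lambda, "lambda", lower = 0)
  if (length(observed) != nrow(D)) {
    abort("Observed pattern length must match the dictionary's ROI axis.")
  }
  n <- nrow(D)
  lam_g <- lambda / (2 * n)
  # a short decreasing path makes the coordinate descent solution accurate
  # at the final (requested) penalty
  lam_path <- sort(unique(c(lam_g * c(100, 10, 3, 1))), decreasing = TRUE)
  fit <- glmnet::glmnet(D, observed, alpha = 1, lambda = lam_path,
                        intercept = FALSE, standardize = FALSE,
                        lower.limits = if (nonneg) 0 else -Inf,
                        thresh = 1e-7, maxit = 1e6)
  cj <- as.numeric(coef(fit, s = lam_g, exact = FALSE))[-1]
  names(cj) <- colnames(D)
  resid <- sqrt(mean((observed - drop(D %*% cj))^2))
  structure(
    list(concentrations = cj, residual = resid, lambda = lambda,
         nonneg = nonneg),
    class = "concentration_estimate"
  )
}

#' @export
print.concentration_estimate <- function(x, ...) {
  nz <- sum(x$concentrations != 0)
  cat(sprintf("<concentration_estimate> %d/%d nonzero, rms residual %.3g\n",
              nz, length(x$concentrations), x$residual))
  invisible(x)
}

#' @export
tidy.concentration_estimate <- function(x, ...) {
  tibble(element = names(x$concentrations) %||%
           as.character(seq_along(x$concentrations)),
         concentration = unname(x$concentrations))
}

#' Go/no-go readout from estimated concentrations
#'
#' Compares the largest concentration assigned to the two go target odors
#' with the largest assigned to the two no-go targets; the larger side wins
#' and an exact tie is called no-go.
#'
#' @param estimate A [lasso_solve()] result (or bare numeric vector).
#' @param dictionary The [build_dictionary()] used, supplying the go/no-go
#'   index pairs.
#' @return `"go"` or `"nogo"`.
#' @export
go_nogo_readout <- function(estimate, dictionary) {
  stopifnot(inherits(dictionary, "odor_dictionary"))
  cj <- if (inherits(estimate, "concentration_estimate")) {
    estimate$concentrations
  } else as.numeric(estimate)
  go_max <- max(cj[dictionary$go_idx])
  nogo_max <- max(cj[dictionary$nogo_idx])
  if (go_max > nogo_max) "go" else "nogo"
}

#' Evaluate Lasso deconvolution over dictionary sizes
#'
#' For each dictionary size, draws `n_dictionaries` random dictionaries and
#' evaluates each on one noisy instantiation of every mixture in the test
#' design (composed from the atlas with the regime's detection threshold and
#' the saturating nonlinearity), reading out go/no-go from the estimated
#' concentrations.
#'
#' @param atlas A `glom_atlas`.
#' @param design Test design tibble (e.g. the reduced test set of 88
#'   mixtures from [enumerate_design()]).
#' @param sizes Dictionary sizes to test (default `c(100, 500, 1000)`).
#' @param n_dictionaries Random dictionaries per size (default 30).
#' @param cv Instantiation noise CV (default 0.25).
#' @param lambda Sparseness constraint (default 1e-4).
#' @param threshold Detection threshold for mixture composition.
#' @param saturation Saturating nonlinearity (default the measured model).
#' @param seed Integer seed.
#' @param known_odors Passed to [build_dictionary()]; `NULL` keeps the
#'   trained nine.
#' @return Object of class `lasso_eval`: tibble `results` (size, dictionary,
#'   fraction_correct) and summary `by_size`.
#' @export
evaluate_lasso <- function(atlas, design, sizes = c(100, 500, 1000),
                           n_dictionaries = 30, cv = 0.25, lambda = 1e-4,
                           threshold = -0.42,
                           saturation = saturation_model_measured(),
                           seed = NULL, known_odors = NULL) {
  stopifnot(inherits(atlas, "glom_atlas"), is.data.frame(design))
  if (nrow(design) == 0) abort("Empty design.")
  check_count(n_dictionaries, "n_dictionaries")
  comp <- compose_design(atlas, design, threshold = threshold,
                         saturation = saturation)
  test <- comp$patterns
  truth <- design$valence
  seeds <- child_seeds(seed, length(sizes) * n_dictionaries * 2)
  si <- 0
  rows <- list()
  for (m in sizes) {
    for (d in seq_len(n_dictionaries)) {
      si <- si + 1
      dict <- build_dictionary(atlas, m_total = m, seed = seeds[2 * si - 1],
                               known_odors = known_odors)
      inst <- with_seed(seeds[2 * si], {
        test * (1 + cv * matrix(rnorm(length(test)), nrow(test), ncol(test)))
      })
      pred <- vapply(seq_len(nrow(inst)), function(i) {
        go_nogo_readout(lasso_solve(dict, inst[i, ], lambda = lambda), dict)
      }, character(1))
      rows[[si]] <- tibble(size = m, dictionary = d,
                           fraction_correct = mean(pred == truth))
    }
  }
  results <- dplyr::bind_rows(rows)
  by_size <- results %>%
    dplyr::group_by(.data$size) %>%
    dplyr::summarise(mean_correct = mean(.data$fraction_correct),
                     sd_correct = sd(.data$fraction_correct), .groups = "drop")
  structure(list(results = results, by_size = by_size, lambda = lambda,
                 cv = cv, seed = seed),
            class = "lasso_eval")
}

#' @export
print.lasso_eval <- function(x, ...) {
  cat(sprintf("<lasso_eval> overall %.1f%% correct over %d runs\n",
              100 * mean(x$results$fraction_correct), nrow(x$results)))
  invisible(x)
}

#' @export
tidy.lasso_eval <- function(x, ...) x$results

#' @export
glance.lasso_eval <- function(x, ...) {
  tibble(mean_correct = mean(x$results$fraction_correct),
         n_runs = nrow(x$results), lambda = x$lambda, cv = x$cv)
}

#' @export
autoplot.lasso_eval <- function(object, ...) {
  ggplot2::ggplot(object$by_size,
                  ggplot2::aes(x = .data$size, y = .data$mean_correct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "dictionary size", y = "fraction correct") +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::theme_minimal()
}
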