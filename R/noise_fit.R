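#' Fit the variance-mean law of trial-to-trial variability
#'
#' Estimates the coefficient of variation CV and the imaging-noise floor
#' sigma_noise by unweighted least squares on the law
#' \eqn{\sigma^2(\mu) = \sigma^2_{noise} + CV^2 \mu^2}, where each data point
#' is one ROI-odor pair with trial mean `mu` and trial s.d. `sigma` (the law
#' is linear in \eqn{\sigma^2_{noise}} and \eqn{CV^2}, so the least-squares
#' minimizer is computed exactly, clamped at zero). When the table carries a
#' trial-count column `n`, `mu` is a noisy trial mean and squaring it
#' attenuates the fitted slope; a method-of-moments measurement-error
#' correction is then applied. Confidence intervals come from a
#' nonparametric bootstrap over ROI-odor pairs (percentile method).
#'
#' @param data Data frame with numeric columns `mu` and `sigma` (one row per
#'   ROI-odor pair), e.g. from [trial_stats()].
#' @param n_boot Bootstrap resamples for the 95% CIs (default 1000; 0 skips
#'   the bootstrap).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `vm_fit` with elements `cv`, `sigma_noise`,
#'   `ci` (tibble), `fit` (the `nls` object) and `data`.
#' @export
#' @examples
#' ts <- instantiate_trials(generate_atlas(atlas_spec(n_rois = 60), seed = 1),
#'                          noise_model_wt(), n_repeats = 20, seed = 2)
#' fit <- fit_variance_mean(trial_stats(ts), n_boot = 50, seed = 3)
#' tidy(fit)
fit_variance_mean <- function(data, n_boot = 1000, seed = NULL) {
  stopifnot(is.data.frame(data), all(c("mu", "sigma") %in% names(data)))
  data <- data[complete.cases(data[c("mu", "sigma")]), ]
  if (nrow(data) < 3 || length(unique(abs(data$mu))) < 3) {
    abort("Need >= 3 ROI-odor pairs with distinct |mu| to fit the variance-mean law.")
  }
  if (all(data$mu == 0)) abort("All means are zero: CV is unidentifiable.")
  n_col <- if ("n" %in% names(data)) data$n else NULL
  est <- vm_point_fit(data$mu, data$sigma, n = n_col)
  ci <- NULL
  if (n_boot > 0) {
    seeds <- child_seeds(seed, 1)
    boots <- with_seed(seeds[1], {
      replicate(n_boot, {
        idx <- sample.int(nrow(data), replace = TRUE)
        tryCatch(vm_point_fit(data$mu[idx], data$sigma[idx], n = n_col[idx]),
                 error = function(e) c(cv = NA_real_, sigma_noise = NA_real_))
      })
    })
    ci <- tibble(
      term = c("cv", "sigma_noise"),
      conf.low = apply(boots, 1, quantile, 0.025, na.rm = TRUE),
      conf.high = apply(boots, 1, quantile, 0.975, na.rm = TRUE)
    )
  }
  structure(
    list(cv = unname(est["cv"]), sigma_noise = unname(est["sigma_noise"]),
         ci = ci, data = as_tibble(data), n_boot = n_boot, seed = seed),
    class = "vm_fit"
  )
}

# single fit of sigma^2 = sigma_noise^2 + cv^2 mu^2 (unweighted).
# When the per-pair trial count `n` is known, `mu` is a noisy trial mean
# (s.e. sigma_tot/sqrt(n)) and regressing on mu^2 attenuates cv^2; a
# method-of-moments measurement-error correction subtracts the estimated
# error variance from the regressor before taking the slope.
vm_point_fit <- function(mu, sigma, n = NULL, sigma_tot = NULL) {
  df <- data.frame(mu2 = mu^2, v = sigma^2)
  if (is.null(n)) {
    # the law is linear in (sigma_noise^2, cv^2), so the least-squares
    # minimizer is exact; clamp at the non-negativity boundary
    slope <- cov(df$mu2, df$v) / var(df$mu2)
    icept <- mean(df$v) - slope * mean(df$mu2)
    if (slope < 0) {
      slope <- 0
      icept <- mean(df$v)
    }
    if (icept < 0) {
      icept <- 0
      slope <- max(sum(df$v * df$mu2) / sum(df$mu2^2), 0)
    }
    return(c(cv = sqrt(slope), sigma_noise = sqrt(icept)))
  }
  if (is.null(sigma_tot)) sigma_tot <- sigma
  me_var <- sigma_tot^2 / n                       # Var(mu_hat)
  x <- df$mu2 - me_var                            # unbiased estimate of mu^2
  lam <- 4 * df$mu2 * me_var + 2 * me_var^2       # Var of the mu^2 noise
  sxx <- var(x)
  denom <- sxx - mean(lam)
  beta <- if (denom > 0.25 * sxx) {
    cov(x, df$v) / denom
  } else {
    cov(x, df$v) / sxx                            # correction unreliable; skip
  }
  beta <- max(beta, 0)
  icept <- max(mean(df$v) - beta * mean(x), 0)
  c(cv = sqrt(beta), sigma_noise = sqrt(icept))
}

#' @export
print.vm_fit <- function(x, ...) {
  cat(sprintf("<vm_fit> CV = %.3f, sigma_noise = %.3f z (%d ROI-odor pairs)\n",
              x$cv, x$sigma_noise, nrow(x$data)))
  invisible(x)
}

#' @export
tidy.vm_fit <- function(x, ...) {
  out <- tibble(term = c("cv", "sigma_noise"),
                estimate = c(x$cv, x$sigma_noise))
  if (!is.null(x$ci)) out <- dplyr::left_join(out, x$ci, by = "term")
  out
}

#' @export
glance.vm_fit <- function(x, ...) {
  tibble(cv = x$cv, sigma_noise = x$sigma_noise, n_pairs = nrow(x$data),
         n_boot = x$n_boot)
}

#' Decompose trial variability into correlated and uncorrelated parts
#'
#' On each odor presentation the whole glomerular population fluctuates
#' together: plotting single-trial responses against the trial-averaged
#' responses across ROIs, the shared gain falls on a line. For every odor
#' presentation an ordinary least-squares line (intercept included) is fitted
#' across the simultaneously recorded ROIs; deviations from that line are the
#' uncorrelated noise. The s.d. of those residuals per ROI-odor pair is then
#' fitted against the mean response with the uncorrelated variance law
#' \eqn{\sigma^2_{uncorr}(\mu) = \sigma^2_{uncorr\,noise} + CV^2_{uncorr}\mu^2}.
#'
#' @param trial_set A [instantiate_trials()] result with >= 2 ROIs and >= 3
#'   repeats.
#' @param fit_on `"variance"` (default) fits the squared law on
#'   \eqn{\sigma^2} vs \eqn{\mu}; `"sd"` fits \eqn{\sigma(\mu)} directly.
#' @param strong_only,strong_z Strong-response ROI preselection, as in
#'   [trial_stats()].
#' @param n_boot,seed Bootstrap settings, as in [fit_variance_mean()].
#' @return Object of class `uncorr_fit` with `cv_uncorr`,
#'   `sigma_uncorr_noise`, `ci`, per-presentation `gains` (slope/intercept of
#'   each line fit) and the residual-s.d. table `pairs`.
#' @export
decompose_uncorrelated <- function(trial_set, fit_on = c("variance", "sd"),
                                   strong_only = TRUE, strong_z = -2,
                                   n_boot = 1000, seed = NULL) {
  stopifnot(inherits(trial_set, "trial_set"))
  fit_on <- match.arg(fit_on)
  tr <- trial_set$trials
  d <- dim(tr)
  if (d[2] < 2) abort("Need >= 2 ROIs: the per-presentation line fit is degenerate.")
  if (d[3] < 3) abort("Need >= 3 repeats to estimate residual s.d.")
  # the per-presentation line fit always runs over ALL simultaneously
  # recorded ROIs; the strong-response filter only selects which ROI-odor
  # pairs enter the subsequent variance-law fit
  keep_roi <- if (strong_only) {
    apply(trial_set$mean_z, 2, function(col) any(col < strong_z))
  } else rep(TRUE, d[2])
  if (sum(keep_roi) < 2) abort("Fewer than 2 ROIs pass the strong-response filter.")
  odors <- rownames(trial_set$mean_z) %||% as.character(seq_len(d[1]))
  gains <- vector("list", d[1])
  resid_sd <- matrix(NA_real_, d[1], d[2])
  for (j in seq_len(d[1])) {
    mu_j <- apply(tr[j, , , drop = FALSE], 2, mean)   # trial-averaged per ROI
    X <- cbind(1, mu_j)
    res <- matrix(NA_real_, d[2], d[3])
    g <- matrix(NA_real_, d[3], 2)
    for (t in seq_len(d[3])) {
      y <- tr[j, , t]
      fit <- lm.fit(X, y)
      res[, t] <- fit$residuals
      g[t, ] <- fit$coefficients
    }
    # hat values of the shared line fit; OLS residuals have variance
    # (1 - h_i) * sigma_i^2, so studentize to keep high-leverage (strongly
    # responding) ROIs unbiased
    h <- 1 / d[2] + (mu_j - mean(mu_j))^2 / sum((mu_j - mean(mu_j))^2)
    resid_sd[j, ] <- apply(res, 1, sd) / sqrt(pmax(1 - h, .Machine$double.eps))
    gains[[j]] <- tibble(odor = odors[j], presentation = seq_len(d[3]),
                         intercept = g[, 1], slope = g[, 2])
  }
  mu_all <- apply(tr, c(1, 2), mean)
  sd_tot <- apply(tr, c(1, 2), sd)
  pairs <- tibble(
    odor = rep(odors, times = d[2]),
    roi = rep(colnames(trial_set$mean_z) %||% as.character(seq_len(d[2])), each = d[1]),
    mu = as.vector(mu_all),
    sigma_uncorr = as.vector(resid_sd),
    sigma_total = as.vector(sd_tot),
    n = d[3],
    keep = rep(unname(keep_roi), each = d[1])
  )
  pairs <- pairs[pairs$keep & !is.na(pairs$sigma_uncorr),
                 setdiff(names(pairs), "keep")]
  est_fun <- function(mu, s, n = NULL, sigma_tot = NULL) {
    if (fit_on == "variance") {
      vm_point_fit(mu, s, n = n, sigma_tot = sigma_tot)
    } else {
      df <- data.frame(mu = mu, s = s)
      fit <- minpack.lm::nlsLM(
        s ~ sqrt(sigma_noise^2 + cv^2 * mu^2), data = df,
        start = list(cv = 0.3, sigma_noise = max(stats::median(df$s), 1e-3)),
        lower = c(0, 0), control = minpack.lm::nls.lm.control(maxiter = 200))
      abs(coef(fit))[c("cv", "sigma_noise")]
    }
  }
  est <- est_fun(pairs$mu, pairs$sigma_uncorr, n = pairs$n,
                 sigma_tot = pairs$sigma_total)
  ci <- NULL
  if (n_boot > 0) {
    boots <- with_seed(child_seeds(seed, 1)[1], {
      replicate(n_boot, {
        idx <- sample.int(nrow(pairs), replace = TRUE)
        tryCatch(est_fun(pairs$mu[idx], pairs$sigma_uncorr[idx],
                         n = pairs$n[idx], sigma_tot = pairs$sigma_total[idx]),
                 error = function(e) c(cv = NA_real_, sigma_noise = NA_real_))
      })
    })
    ci <- tibble(
      term = c("cv_uncorr", "sigma_uncorr_noise"),
      conf.low = apply(boots, 1, quantile, 0.025, na.rm = TRUE),
      conf.high = apply(boots, 1, quantile, 0.975, na.rm = TRUE)
    )
  }
  structure(
    list(cv_uncorr = unname(est["cv"]), sigma_uncorr_noise = unname(est["sigma_noise"]),
         ci = ci, gains = dplyr::bind_rows(gains), pairs = pairs,
         fit_on = fit_on, n_boot = n_boot, seed = seed),
    class = "uncorr_fit"
  )
}

#' @export
print.uncorr_fit <- function(x, ...) {
  cat(sprintf("<uncorr_fit> CV_uncorr = %.3f, sigma_uncorr_noise = %.3f z (%d pairs)\n",
              x$cv_uncorr, x$sigma_uncorr_noise, nrow(x$pairs)))
  invisible(x)
}

#' @export
tidy.uncorr_fit <- function(x, ...) {
  out <- tibble(term = c("cv_uncorr", "sigma_uncorr_noise"),
                estimate = c(x$cv_uncorr, x$sigma_uncorr_noise))
  if (!is.null(x$ci)) out <- dplyr::left_join(out, x$ci, by = "term")
  out
}

#' Detection threshold for glomerular activation
#'
#' Averaging odor-evoked responses over `n` trials leaves a standard error of
#' the mean of \eqn{\sigma_{noise}/\sqrt{n}} from imaging noise alone; mean
#' responses weaker than that cannot be distinguished from no response. The
#' returned value is the magnitude; downstream it is applied as a negative
#' cutoff (responses with z above `-threshold` are set to 0).
#'
#' @param sigma_noise Imaging-noise s.d. in z units (>= 0).
#' @param n_repeats Number of averaged trials (>= 1).
#' @return The threshold magnitude `sigma_noise / sqrt(n_repeats)`.
#' @export
#' @examples
#' detection_threshold(1.83, 16)  # 0.46 in the high-variability regime
detection_threshold <- function(sigma_noise, n_repeats) {
  check_number(sigma_noise, "sigma_noise", lower = 0)
  check_count(n_repeats, "n_repeats")
  sigma_noise / sqrt(n_repeats)
}

#' Saturating mixture nonlinearity
#'
#' When two odor responses sum, the observed mixture response deviates from
#' the linear sum; the deviation is captured by the odd sigmoid
#' \deqn{\sigma(R_o) = \frac{2A}{1 + e^{R_o s}} - A}
#' where `R_o` is the linear sum of the component z-scores, `A` the (negative)
#' asymptote and `s > 0` the saturation rate. `saturation_model()` builds the
#' model, [fit_saturation()] estimates it from (sum, observed) pairs and
#' [apply_saturation()] evaluates it.
#'
#' @param A Asymptote (z-score, negative for activation).
#' @param s Saturation rate (1/z, > 0).
#' @return Object of class `sat_model`.
#' @export
saturation_model <- function(A, s) {
  check_number(A, "A")
  check_number(s, "s", lower = .Machine$double.eps)
  structure(list(A = A, s = s), class = "sat_model")
}

#' @export
print.sat_model <- function(x, ...) {
  cat(sprintf("<sat_model> A = %.4f z, s = %.4f per z\n", x$A, x$s))
  invisible(x)
}

#' Fit the saturating nonlinearity
#'
#' @param data Data frame with columns `r_o` (summed component z-scores) and
#'   `response` (observed mixture z-score); >= 4 pairs spanning negative
#'   `r_o` are required.
#' @param start Optional named list of starting values `A`, `s`.
#' @return A `sat_fit` object: a [saturation_model()] plus the underlying
#'   `nls` fit; non-convergence is raised as an error.
#' @export
#' @examples
#' grid <- tibble::tibble(r_o = seq(-20, 2, length.out = 68))
#' grid$response <- apply_saturation(grid$r_o, saturation_model(-8.0934, 0.2091))
#' tidy(fit_saturation(grid))
fit_saturation <- function(data, start = NULL) {
  stopifnot(is.data.frame(data), all(c("r_o", "response") %in% names(data)))
  data <- data[complete.cases(data[c("r_o", "response")]), ]
  if (nrow(data) < 4 || !any(data$r_o < 0)) {
    abort("Need >= 4 (r_o, response) pairs spanning negative r_o.")
  }
  if (is.null(start)) start <- list(A = min(data$response) - 1e-3, s = 0.1)
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ 2 * A / (1 + exp(r_o * s)) - A, data = data,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(paste0("Saturation fit did not converge: ",
                                     conditionMessage(e)))
  )
  cf <- coef(fit)
  structure(list(A = unname(cf["A"]), s = unname(cf["s"]), fit = fit,
                 data = as_tibble(data)),
            class = c("sat_fit", "sat_model"))
}

#' @export
tidy.sat_fit <- function(x, ...) {
  tibble(term = c("A", "s"), estimate = c(x$A, x$s))
}

#' @rdname saturation_model
#' @param r_o Numeric vector of summed component z-scores.
#' @param model A `sat_model` (or `sat_fit`).
#' @export
apply_saturation <- function(r_o, model) {
  stopifnot(inherits(model, "sat_model"))
  2 * model$A / (1 + exp(r_o * model$s)) - model$A
}

#' The measured saturation model
#'
#' The nonlinearity fitted to mixture measurements: A = -8.0934, s = 0.2091.
#' @return A [saturation_model()].
#' @export
saturation_model_measured <- function() saturation_model(-8.0934, 0.2091)
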