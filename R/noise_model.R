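#' Trial-to-trial noise model for glomerular responses
#'
#' The variability of a glomerular z-score response around its mean \eqn{\mu}
#' has two parts: a multiplicative component proportional to the response,
#' with coefficient of variation CV, and an additive imaging-noise component
#' of s.d. \eqn{\sigma_{noise}} present even without a response, so the
#' total trial variance follows
#' \eqn{\sigma^2(\mu) = \sigma^2_{noise} + CV^2 \mu^2}.
#' The multiplicative part further splits into a gain shared by the whole
#' glomerular population on each trial and fluctuations independent across
#' glomeruli with coefficient `cv_uncorr`; the shared-gain s.d. is
#' \eqn{\sqrt{CV^2 - CV_{uncorr}^2}}.
#'
#' @param cv Total coefficient of variation (>= 0).
#' @param cv_uncorr Uncorrelated coefficient of variation (0 <= cv_uncorr <= cv).
#' @param sigma_noise Additive imaging-noise s.d. in z units (>= 0).
#' @param sigma_uncorr_noise Uncorrelated part of the imaging noise (z units).
#' @param genotype Free-text tag, e.g. `"WT"`.
#' @param threshold_z Detection threshold applied to mean responses
#'   (negative z; responses weaker than this are treated as 0).
#' @return An object of class `noise_model`.
#' @seealso [noise_model_wt()], [noise_model_cntnap2()] for the two measured
#'   regimes, [instantiate_trials()] to draw trials under the model.
#' @export
noise_model <- function(cv, cv_uncorr = cv, sigma_noise = 0,
                        sigma_uncorr_noise = sigma_noise,
                        genotype = "custom", threshold_z = NULL) {
  check_number(cv, "cv", lower = 0)
  check_number(cv_uncorr, "cv_uncorr", lower = 0)
  check_number(sigma_noise, "sigma_noise", lower = 0)
  check_number(sigma_uncorr_noise, "sigma_uncorr_noise", lower = 0)
  if (cv_uncorr > cv + 1e-12) abort("`cv_uncorr` must not exceed `cv`.")
  if (!is.null(threshold_z) && threshold_z > 0) {
    abort("`threshold_z` must be <= 0 (activation is negative z).")
  }
  structure(
    list(cv = cv, cv_uncorr = min(cv_uncorr, cv), sigma_noise = sigma_noise,
         sigma_uncorr_noise = sigma_uncorr_noise, genotype = genotype,
         threshold_z = threshold_z),
    class = "noise_model"
  )
}

#' Measured noise regimes
#'
#' `noise_model_wt()` returns the awake wild-type regime:
#' CV = 0.34, CV_uncorr = 0.25, sigma_noise = 1.59, sigma_uncorr_noise = 1.47,
#' detection threshold -0.42. `noise_model_cntnap2()` returns the
#' higher-variability Cntnap2-knockout-like regime: CV_uncorr = 0.44,
#' sigma_noise = 1.83, sigma_uncorr_noise = 1.65, threshold -0.46 (the total
#' CV keeps the same correlated-gain s.d. as the WT regime).
#'
#' @return A [noise_model()].
#' @export
noise_model_wt <- function() {
  noise_model(cv = 0.34, cv_uncorr = 0.25, sigma_noise = 1.59,
              sigma_uncorr_noise = 1.47, genotype = "WT", threshold_z = -0.42)
}

#' @rdname noise_model_wt
#' @export
noise_model_cntnap2 <- function() {
  # shared-gain s.d. carried over from WT: sqrt(0.34^2 - 0.25^2)
  cv_corr <- sqrt(0.34^2 - 0.25^2)
  noise_model(cv = sqrt(0.44^2 + cv_corr^2), cv_uncorr = 0.44,
              sigma_noise = 1.83, sigma_uncorr_noise = 1.65,
              genotype = "Cntnap2", threshold_z = -0.46)
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model> %s: CV = %.3g, CV_uncorr = %.3g, sigma_noise = %.3g z\n",
    x$genotype, x$cv, x$cv_uncorr, x$sigma_noise))
  invisible(x)
}

#' Instantiate noisy trials from mean response patterns
#'
#' Draws single-trial responses around the mean pattern: each trial is
#' `mean + mean * cv_uncorr * eps` (independent Gaussian `eps` per entry),
#' plus, when `include_correlated`, a shared multiplicative gain per trial
#' (`mean * cv_corr * g`, one Gaussian `g` per odor presentation applied to
#' all ROIs), plus, when `include_imaging_noise`, additive Gaussian imaging
#' noise of s.d. `sigma_noise` independent across ROIs. The total per-entry
#' variance is then `sigma_noise^2 + cv^2 * mean^2`.
#'
#' @param x A `glom_atlas`, or a numeric matrix (odors x ROIs), or a numeric
#'   vector (one pattern).
#' @param noise A [noise_model()].
#' @param n_repeats Number of trials per odor (>= 1).
#' @param seed Integer seed; trials are reproducible from it.
#' @param include_correlated Include the shared per-trial gain component.
#' @param include_imaging_noise Include the additive imaging-noise component.
#' @return An object of class `trial_set`: list with `trials` (odors x ROIs
#'   x repeats array), `mean_z`, `noise`, `seed`.
#' @export
#' @examples
#' atlas <- generate_atlas(atlas_spec(n_rois = 30), seed = 1)
#' ts <- instantiate_trials(atlas, noise_model_wt(), n_repeats = 5, seed = 2)
#' dim(ts$trials)
instantiate_trials <- function(x, noise, n_repeats, seed = NULL,
                               include_correlated = TRUE,
                               include_imaging_noise = TRUE) {
  stopifnot(inherits(noise, "noise_model"))
  check_count(n_repeats, "n_repeats")
  mean_z <- if (inherits(x, "glom_atlas")) x$mean_z else x
  if (is.null(dim(mean_z))) mean_z <- matrix(mean_z, nrow = 1)
  n_odor <- nrow(mean_z)
  n_roi <- ncol(mean_z)
  cv_corr <- if (include_correlated) sqrt(max(noise$cv^2 - noise$cv_uncorr^2, 0)) else 0
  sig <- if (include_imaging_noise) noise$sigma_noise else 0
  trials <- array(0, dim = c(n_odor, n_roi, n_repeats),
                  dimnames = c(dimnames(mean_z), list(NULL)))
  with_seed(seed, {
    for (t in seq_len(n_repeats)) {
      gain <- if (cv_corr > 0) rnorm(n_odor, 0, cv_corr) else numeric(n_odor)
      eps <- matrix(rnorm(n_odor * n_roi, 0, 1), n_odor, n_roi)
      tr <- mean_z * (1 + noise$cv_uncorr * eps + gain)
      if (sig > 0) tr <- tr + matrix(rnorm(n_odor * n_roi, 0, sig), n_odor, n_roi)
      trials[, , t] <- tr
    }
  })
  structure(
    list(trials = trials, mean_z = mean_z, noise = noise, seed = seed,
         include_correlated = include_correlated,
         include_imaging_noise = include_imaging_noise),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<trial_set> %d odors x %d ROIs x %d repeats (%s regime)\n",
              d[1], d[2], d[3], x$noise$genotype))
  invisible(x)
}

#' Tidy a trial set into long format
#'
#' @param x A `trial_set`.
#' @param ... Unused.
#' @return Tibble with columns `odor`, `roi`, `repeat`, `value`.
#' @export
tidy.trial_set <- function(x, ...) {
  long <- as.data.frame.table(x$trials, stringsAsFactors = FALSE)
  names(long) <- c("odor", "roi", "repeat", "value")
  long$`repeat` <- as.integer(factor(long$`repeat`, levels = unique(long$`repeat`)))
  as_tibble(long)
}

#' Per ROI-odor mean and trial s.d.
#'
#' Summarises a trial set into the (mean, s.d.) pairs that the variance-mean
#' law is fitted on. Optionally keeps only strongly responding ROIs (those
#' with a mean z below `strong_z` for at least one odor), mirroring the
#' preselection used when estimating variability from imaging data.
#'
#' @param trial_set A [instantiate_trials()] result.
#' @param strong_only Apply the strong-response ROI filter (default TRUE).
#' @param strong_z Threshold for the filter (default -2).
#' @return Tibble with columns `odor`, `roi`, `mu`, `sigma`, `n`.
#' @export
trial_stats <- function(trial_set, strong_only = TRUE, strong_z = -2) {
  stopifnot(inherits(trial_set, "trial_set"))
  tr <- trial_set$trials
  mu <- apply(tr, c(1, 2), mean)
  sg <- apply(tr, c(1, 2), sd)
  keep_roi <- if (strong_only) {
    apply(trial_set$mean_z, 2, function(col) any(col < strong_z))
  } else rep(TRUE, ncol(mu))
  keep_long <- rep(unname(keep_roi), each = nrow(mu))
  out <- tibble(
    odor = rep(rownames(mu) %||% as.character(seq_len(nrow(mu))), times = ncol(mu)),
    roi = rep(colnames(mu) %||% as.character(seq_len(ncol(mu))), each = nrow(mu)),
    mu = as.vector(mu),
    sigma = as.vector(sg),
    n = dim(tr)[3]
  )
  out[keep_long, ]
}
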