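#' Specify a synthetic intrinsic-imaging movie
#'
#' Geometry and timing for the planted-glomeruli movie generator. Planted
#' glomeruli are 2-D Gaussian spots on a grid; odor activation appears as a
#' negative reflectance step (df/f0) from odor onset, optionally with a
#' slow, spatially broad hemodynamic component and white pixel noise on top.
#'
#' @param width,height Frame size in pixels.
#' @param fps Frame rate (frames per second).
#' @param duration_s Movie length in seconds.
#' @param baseline_s Pre-odor baseline length (odor onset is at
#'   `baseline_s`).
#' @param pixel_um Pixel size in micrometers (default 3.3).
#' @param glom_sigma_um Gaussian spot sigma in micrometers.
#' @param dff_per_z df/f0 amplitude corresponding to one (negative) z unit
#'   of atlas amplitude.
#' @param hemodynamic_amplitude Peak df/f0 of the broad hemodynamic
#'   component (0 disables it).
#' @param pixel_noise_sd S.d. of white pixel noise, as a fraction of the
#'   baseline intensity (0 disables it).
#' @return Object of class `movie_spec`.
#' @export
movie_spec <- function(width = 64, height = 64, fps = 10, duration_s = 15,
                       baseline_s = 5, pixel_um = 3.3, glom_sigma_um = 12,
                       dff_per_z = 0.002, hemodynamic_amplitude = 0,
                       pixel_noise_sd = 0) {
  if (duration_s <= baseline_s + 2) {
    abort("Movie must extend past the baseline plus the response window onset.")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height), fps = fps,
         duration_s = duration_s, baseline_s = baseline_s,
         pixel_um = pixel_um, glom_sigma_um = glom_sigma_um,
         dff_per_z = dff_per_z,
         hemodynamic_amplitude = hemodynamic_amplitude,
         pixel_noise_sd = pixel_noise_sd),
    class = "movie_spec"
  )
}

#' Generate a synthetic intrinsic-imaging movie for one odor
#'
#' Plants one Gaussian spot per atlas ROI on a regular grid and modulates
#' each spot's intensity by a step time course scaled to the atlas amplitude
#' for the chosen odor (activation = intensity decrease). A slow half-sine
#' hemodynamic component covering the whole frame and independent Gaussian
#' pixel noise can be superimposed. Ground-truth ROI masks (spot pixels
#' above half maximum) are returned as a label image.
#'
#' @param atlas A `glom_atlas`; its ROIs (up to the grid capacity) are
#'   planted.
#' @param odor Odor name (a row of the atlas).
#' @param spec A [movie_spec()].
#' @param seed Integer seed for the pixel noise.
#' @return List with `movie` (height x width x frames array of intensities
#'   around a baseline of 1), `masks` (label matrix), `roi_names`, `spec`,
#'   `amplitudes` (the planted atlas z values).
#' @export
generate_movie <- function(atlas, odor, spec = movie_spec(), seed = NULL) {
  stopifnot(inherits(atlas, "glom_atlas"), inherits(spec, "movie_spec"))
  if (!odor %in% rownames(atlas$mean_z)) abort(sprintf("Atlas has no odor `%s`.", odor))
  sig_px <- spec$glom_sigma_um / spec$pixel_um
  spacing <- ceiling(6 * sig_px)
  margin <- ceiling(3 * sig_px)
  xs <- seq(margin, spec$width - margin, by = spacing)
  ys <- seq(margin, spec$height - margin, by = spacing)
  capacity <- length(xs) * length(ys)
  n_glom <- min(ncol(atlas$mean_z), capacity)
  centers <- expand.grid(x = xs, y = ys)[seq_len(n_glom), ]
  amplitudes <- atlas$mean_z[odor, seq_len(n_glom)]

  n_t <- round(spec$duration_s * spec$fps)
  onset <- round(spec$baseline_s * spec$fps)
  px <- matrix(rep(seq_len(spec$width), each = spec$height), spec$height)
  py <- matrix(rep(seq_len(spec$height), times = spec$width), spec$height)
  spatial <- matrix(0, spec$height, spec$width)  # df/f0 map at full activation
  masks <- matrix(0L, spec$height, spec$width)
  for (g in seq_len(n_glom)) {
    spot <- exp(-((px - centers$x[g])^2 + (py - centers$y[g])^2) / (2 * sig_px^2))
    spatial <- spatial + spec$dff_per_z * amplitudes[g] * spot
    masks[spot > 0.5 & masks == 0L] <- g
  }
  hemo_map <- exp(-((px - spec$width / 2)^2 + (py - spec$height / 2)^2) /
                    (2 * (spec$width)^2))  # spatially very broad
  movie <- array(1, dim = c(spec$height, spec$width, n_t))
  tt <- seq_len(n_t)
  step <- as.numeric(tt > onset)
  hemo_t <- ifelse(tt > onset,
                   sin(pmin((tt - onset) / spec$fps / 6, 1) * pi / 2), 0)
  for (t in tt) {
    frame <- 1 + spatial * step[t] -
      spec$hemodynamic_amplitude * hemo_map * hemo_t[t]
    movie[, , t] <- frame
  }
  if (spec$pixel_noise_sd > 0) {
    movie <- movie + with_seed(seed, {
      array(rnorm(length(movie), 0, spec$pixel_noise_sd), dim = dim(movie))
    })
  }
  list(movie = movie, masks = masks,
       roi_names = colnames(atlas$mean_z)[seq_len(n_glom)],
       spec = spec, amplitudes = amplitudes, odor = odor)
}

#' Write / read multi-page TIFF image stacks
#'
#' Thin wrappers storing a height x width x frames array as a 32-bit float
#' multi-page TIFF, and reading one back.
#'
#' @param x Numeric array (height x width x frames) or matrix.
#' @param path File path.
#' @return `read_tiff_stack()` returns the array.
#' @export
write_tiff_stack <- function(x, path) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  pages <- lapply(seq_len(dim(x)[3]), function(t) x[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
  arr
}

#' Generate a synthetic behavioral performance table
#'
#' Stands in for per-novel-odor behavioral performance: each odor's
#' fraction-correct is a binomial draw of `n_trials_per_odor` trials around
#' a noisy copy of the supplied per-odor performance (Gaussian noise of s.d.
#' `behavioral_noise_sd`, clipped to \[0, 1\]).
#'
#' @param performance_by_odor Named numeric vector of per-odor
#'   fraction-correct values in \[0, 1\].
#' @param behavioral_noise_sd S.d. of the animal-level noise (>= 0).
#' @param n_trials_per_odor Trials per odor (default 8, the per-odor cap of
#'   the behavioral design).
#' @param seed Integer seed.
#' @return Tibble with columns `odor`, `n_trials`, `n_correct`,
#'   `performance`.
#' @export
generate_behavior <- function(performance_by_odor, behavioral_noise_sd = 0,
                              n_trials_per_odor = 8, seed = NULL) {
  if (any(performance_by_odor < 0 | performance_by_odor > 1)) {
    abort("Performances must lie in [0, 1].")
  }
  check_number(behavioral_noise_sd, "behavioral_noise_sd", lower = 0)
  check_count(n_trials_per_odor, "n_trials_per_odor")
  n_odor <- length(performance_by_odor)
  with_seed(seed, {
    p <- pmin(pmax(performance_by_odor +
                     rnorm(n_odor, 0, behavioral_noise_sd), 0), 1)
    k <- rbinom(n_odor, n_trials_per_odor, p)
  })
  tibble(
    odor = names(performance_by_odor) %||% paste0("novel_", seq_len(n_odor)),
    n_trials = n_trials_per_odor,
    n_correct = k,
    performance = k / n_trials_per_odor
  )
}
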