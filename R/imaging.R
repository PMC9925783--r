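# Separable Gaussian convolution with reflective padding. "radius sigma" is
# read as the Gaussian standard deviation, converted to pixels by the caller.
gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-half:half)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  reflect_idx <- function(p, n) {   # fold indices back into 1..n repeatedly
    if (n == 1L) return(rep(1L, length(p)))
    r <- (p - 1L) %% (2L * n - 2L)
    ifelse(r < n, r + 1L, 2L * n - 1L - r)
  }
  blur_1d <- function(m) {   # convolve along rows (dim 1), reflective pad
    n <- nrow(m)
    idx <- reflect_idx((1L - half):(n + half), n)
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(k)) {
      out <- out + k[o] * padded[(o - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

#' Convert a raw imaging stack to a per-pixel z-score movie
#'
#' Replays the intrinsic-imaging quantification chain: (1) df/f0 against the
#' mean of the pre-odor baseline window; (2) subtraction of a wide Gaussian
#' low-pass (sigma 40 um) to remove the broad hemodynamic signal;
#' (3) smoothing with a narrow Gaussian (sigma 12 um) to remove high spatial
#' frequency noise; (4) per-pixel z-scoring using the baseline-window mean
#' and s.d. of the filtered signal. Baseline pixels with (near-)zero
#' variance get a machine-epsilon-scaled variance floor instead of emitting
#' non-finite z.
#'
#' @param raw Numeric array height x width x frames of raw intensities.
#' @param fps Frame rate (frames per second).
#' @param onset_s Odor onset time in seconds from movie start.
#' @param baseline_s Length of the pre-odor baseline window (default 5 s).
#' @param pixel_um Pixel size in micrometers (default 3.3).
#' @param wide_um,narrow_um Gaussian sigmas in micrometers (defaults 40
#'   and 12).
#' @return Object of class `zscore_movie`: `z` (same-shaped array), `fps`,
#'   `onset_frame`, `baseline_frames`, `pixel_um`.
#' @export
zscore_movie <- function(raw, fps, onset_s, baseline_s = 5, pixel_um = 3.3,
                         wide_um = 40, narrow_um = 12) {
  stopifnot(is.array(raw), length(dim(raw)) == 3)
  onset_frame <- round(onset_s * fps)
  n_base <- round(baseline_s * fps)
  if (onset_frame < n_base || onset_frame > dim(raw)[3]) {
    abort("Baseline window must fit before the odor onset inside the movie.")
  }
  baseline_frames <- (onset_frame - n_base + 1):onset_frame
  f0 <- apply(raw[, , baseline_frames, drop = FALSE], c(1, 2), mean)
  f0[abs(f0) < .Machine$double.eps] <- .Machine$double.eps
  n_t <- dim(raw)[3]
  filt <- array(0, dim(raw))
  for (t in seq_len(n_t)) {
    dff <- raw[, , t] / f0 - 1
    dff <- dff - gauss_blur(dff, wide_um / pixel_um)
    filt[, , t] <- gauss_blur(dff, narrow_um / pixel_um)
  }
  base <- filt[, , baseline_frames, drop = FALSE]
  mu <- apply(base, c(1, 2), mean)
  s2 <- apply(base, c(1, 2), var)
  floor_ <- max(mean(s2), .Machine$double.eps) * 1e-12 + .Machine$double.eps
  s <- sqrt(pmax(s2, floor_))
  z <- sweep(sweep(filt, c(1, 2), mu), c(1, 2), s, "/")
  structure(
    list(z = z, fps = fps, onset_frame = onset_frame,
         baseline_frames = baseline_frames, pixel_um = pixel_um),
    class = "zscore_movie"
  )
}

#' @export
print.zscore_movie <- function(x, ...) {
  d <- dim(x$z)
  cat(sprintf("<zscore_movie> %d x %d px, %d frames @ %g fps, onset frame %d\n",
              d[1], d[2], d[3], x$fps, x$onset_frame))
  invisible(x)
}

#' Quantify ROI responses from a z-score movie
#'
#' Glomerular activation is the mean z-score across all pixels of an ROI,
#' averaged over the response window (2-9 s after odor onset by default).
#' Supplying a list of movies (repeats of the same stimulus) yields a
#' repeat-resolved table plus the repeat-averaged value.
#'
#' @param zmovie A [zscore_movie()] result, or a list of them (repeats).
#' @param roi_masks Integer label matrix (0 = background, k = ROI k) matching
#'   the movie frame.
#' @param response_window Seconds after odor onset to average (default
#'   `c(2, 9)`).
#' @return Tibble with columns `roi`, `repeat`, `mean_z` plus a
#'   repeat-averaged `mean_z_avg` column.
#' @export
quantify_rois <- function(zmovie, roi_masks, response_window = c(2, 9)) {
  movies <- if (inherits(zmovie, "zscore_movie")) list(zmovie) else zmovie
  stopifnot(all(vapply(movies, inherits, logical(1), "zscore_movie")))
  roi_masks <- as.matrix(roi_masks)
  ids <- sort(setdiff(unique(as.vector(roi_masks)), 0))
  if (!length(ids)) abort("No ROI labels in the mask.")
  rows <- purrr::imap(movies, function(m, rep_i) {
    if (!all(dim(roi_masks) == dim(m$z)[1:2])) {
      abort("ROI mask does not match the movie frame size.")
    }
    fr <- m$onset_frame + seq(round(response_window[1] * m$fps),
                              round(response_window[2] * m$fps))
    fr <- fr[fr >= 1 & fr <= dim(m$z)[3]]
    if (!length(fr)) abort("Response window lies outside the movie.")
    zwin <- apply(m$z[, , fr, drop = FALSE], c(1, 2), mean)
    tibble(
      roi = ids,
      `repeat` = as.integer(rep_i),
      mean_z = vapply(ids, function(k) {
        px <- roi_masks == k
        if (!any(px)) abort(sprintf("ROI %d has an empty mask.", k))
        mean(zwin[px])
      }, numeric(1))
    )
  })
  out <- dplyr::bind_rows(rows)
  avg <- out %>% dplyr::group_by(.data$roi) %>%
    dplyr::summarise(mean_z_avg = mean(.data$mean_z), .groups = "drop")
  dplyr::left_join(out, avg, by = "roi")
}

#' Zero out sub-threshold responses
#'
#' Responses weaker than the detection threshold (z above it, since
#' activation is negative) are set to exactly 0; responses at or below the
#' threshold pass unchanged. Idempotent.
#'
#' @param x A response table (data frame with a `mean_z` or `value` column),
#'   a numeric matrix, or a numeric vector.
#' @param threshold Detection threshold, <= 0 (e.g. -0.42).
#' @return Same shape as the input with sub-threshold entries zeroed.
#' @export
#' @examples
#' apply_detection_threshold(c(-0.40, -0.50), -0.42)
apply_detection_threshold <- function(x, threshold) {
  check_number(threshold, "threshold", upper = 0)
  zero_fun <- function(v) { v[v > threshold] <- 0; v }
  if (is.data.frame(x)) {
    col <- intersect(c("mean_z", "value"), names(x))[1]
    if (is.na(col)) abort("Table needs a `mean_z` or `value` column.")
    x[[col]] <- zero_fun(x[[col]])
    x
  } else {
    zero_fun(x)
  }
}
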