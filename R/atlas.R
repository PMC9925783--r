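#' Default odor panel for the go/no-go mixture task
#'
#' The behavioral task uses 20 odors: four targets (two rewarded "go" odors
#' and two unrewarded "no-go" odors), four contextual background odors that
#' appear in every training mixture, one fixed background (limonene) that is
#' replaced in catch trials, and eleven novel background odors that appear
#' only in catch trials.
#'
#' @return A tibble with columns `odor`, `role`
#'   (`"target"`, `"contextual"`, `"fixed"`, `"novel"`) and `valence`
#'   (`"go"`/`"nogo"` for targets, `NA` otherwise).
#' @export
#' @examples
#' default_odor_roles()
default_odor_roles <- function() {
  tibble(
    odor = c(
      "target_go_1", "target_go_2", "target_nogo_1", "target_nogo_2",
      paste0("context_", 1:4),
      "limonene",
      sprintf("novel_%02d", 1:11)
    ),
    role = c(rep("target", 4), rep("contextual", 4), "fixed", rep("novel", 11)),
    valence = c("go", "go", "nogo", "nogo", rep(NA_character_, 16))
  )
}

#' Specify a synthetic glomerular atlas
#'
#' An atlas spec describes the statistics of the odors-by-ROIs matrix of mean
#' z-score responses for one animal: how many glomerular ROIs are imaged, the
#' fraction of ROIs each odor role activates, and the mean activation
#' amplitude per role. Activation is negative z throughout (the
#' intrinsic-imaging convention: activated glomeruli reflect less light).
#'
#' Defaults are the measured role statistics of awake wild-type mice: targets
#' activate 29.5% of ROIs at a mean of -0.32 z, contextual backgrounds 43.5%
#' at -0.70, the fixed background 37% at -0.41, and novel backgrounds 46.1%
#' at -0.63, over 155 ROIs per animal.
#'
#' @param n_rois Number of glomerular ROIs (default 155).
#' @param odor_roles Tibble with columns `odor`, `role`, `valence`;
#'   see [default_odor_roles()].
#' @param frac_active Named numeric: fraction of ROIs activated per role.
#' @param mean_amplitude Named numeric: mean z-score of active ROIs per role
#'   (all values must be <= 0).
#' @param amplitude_dispersion Optional named numeric giving the s.d. of a
#'   zero-truncated normal amplitude distribution per role. By default active
#'   amplitudes are drawn from a half-normal scaled so its mean equals
#'   `mean_amplitude`, which fixes the spread at `|mean| * sqrt(pi/2 - 1)`.
#' @param seed Integer seed used by [generate_atlas()].
#' @return An object of class `atlas_spec`.
#' @export
atlas_spec <- function(n_rois = 155,
                       odor_roles = default_odor_roles(),
                       frac_active = c(target = 0.295, contextual = 0.435,
                                       fixed = 0.37, novel = 0.461),
                       mean_amplitude = c(target = -0.32, contextual = -0.70,
                                          fixed = -0.41, novel = -0.63),
                       amplitude_dispersion = NULL,
                       seed = NULL) {
  check_count(n_rois, "n_rois")
  stopifnot(is.data.frame(odor_roles), all(c("odor", "role") %in% names(odor_roles)))
  roles <- unique(odor_roles$role)
  missing_frac <- setdiff(roles, names(frac_active))
  if (length(missing_frac)) {
    abort(paste0("`frac_active` missing roles: ", paste(missing_frac, collapse = ", ")))
  }
  if (any(frac_active < 0 | frac_active > 1)) {
    abort("`frac_active` values must lie in [0, 1].")
  }
  if (any(mean_amplitude > 0)) {
    abort("`mean_amplitude` values must be <= 0 (activation is negative z).")
  }
  structure(
    list(
      n_rois = as.integer(n_rois),
      odor_roles = as_tibble(odor_roles),
      frac_active = frac_active,
      mean_amplitude = mean_amplitude,
      amplitude_dispersion = amplitude_dispersion,
      seed = seed
    ),
    class = "atlas_spec"
  )
}

#' Generate a per-animal glomerular atlas
#'
#' Draws an odors-by-ROIs matrix of mean z-score responses. Each ROI is
#' activated by an odor independently with the role's activation probability;
#' active entries get a negative amplitude drawn from a half-normal scaled so
#' that the expected amplitude equals the role's mean amplitude (or from a
#' zero-truncated normal when `amplitude_dispersion` is supplied in the
#' spec). Inactive entries are exactly 0.
#'
#' @param spec An [atlas_spec()].
#' @param animal_id Label stored with the atlas.
#' @param seed Integer seed; overrides `spec$seed` when given.
#' @return An object of class `glom_atlas`: a list with `mean_z`
#'   (odors x ROIs matrix), `odor_roles`, `animal_id` and the generating
#'   `spec`.
#' @export
#' @examples
#' atlas <- generate_atlas(atlas_spec(n_rois = 50), seed = 1)
#' dim(atlas$mean_z)
generate_atlas <- function(spec, animal_id = "animal_1", seed = NULL) {
  stopifnot(inherits(spec, "atlas_spec"))
  seed <- seed %||% spec$seed
  n <- spec$n_rois
  odors <- spec$odor_roles$odor
  mean_z <- matrix(0, nrow = length(odors), ncol = n,
                   dimnames = list(odors, paste0("roi_", seq_len(n))))
  with_seed(seed, {
    for (k in seq_along(odors)) {
      role <- spec$odor_roles$role[k]
      p <- spec$frac_active[[role]]
      mu <- spec$mean_amplitude[[role]]
      active <- runif(n) < p
      n_act <- sum(active)
      if (n_act == 0L || mu == 0) next
      disp <- spec$amplitude_dispersion
      if (is.null(disp)) {
        # half-normal with E|X| = |mu|  =>  scale sd = |mu| * sqrt(pi/2)
        amp <- -abs(rnorm(n_act, mean = 0, sd = abs(mu) * sqrt(pi / 2)))
      } else {
        s <- disp[[role]]
        amp <- rnorm(n_act, mean = mu, sd = s)
        while (any(amp >= 0)) {  # truncate to strictly negative amplitudes
          amp[amp >= 0] <- rnorm(sum(amp >= 0), mean = mu, sd = s)
        }
      }
      mean_z[k, active] <- amp
    }
  })
  structure(
    list(mean_z = mean_z, odor_roles = spec$odor_roles,
         animal_id = animal_id, spec = spec),
    class = "glom_atlas"
  )
}

#' Generate a cohort of synthetic animals
#'
#' @param n_animals Number of animals (default 5, matching the imaged cohort
#'   size).
#' @param spec Shared [atlas_spec()].
#' @param seed Integer seed; one child seed is derived per animal.
#' @return A list of `glom_atlas` objects.
#' @export
generate_atlas_set <- function(n_animals = 5, spec = atlas_spec(), seed = NULL) {
  check_count(n_animals, "n_animals")
  seeds <- child_seeds(seed, n_animals)
  lapply(seq_len(n_animals), function(i) {
    generate_atlas(spec, animal_id = paste0("animal_", i), seed = seeds[i])
  })
}

#' @export
print.glom_atlas <- function(x, ...) {
  cat(sprintf("<glom_atlas> %s: %d odors x %d ROIs\n",
              x$animal_id, nrow(x$mean_z), ncol(x$mean_z)))
  frac <- rowMeans(x$mean_z != 0)
  by_role <- tapply(frac, x$odor_roles$role, mean)
  cat("  mean active fraction by role:\n")
  for (r in names(by_role)) cat(sprintf("    %-10s %.3f\n", r, by_role[[r]]))
  invisible(x)
}

#' Tidy a glomerular atlas into long format
#'
#' @param x A `glom_atlas`.
#' @param ... Unused.
#' @return A tibble with columns `animal`, `odor`, `role`, `roi`, `mean_z`.
#' @export
tidy.glom_atlas <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$mean_z, stringsAsFactors = FALSE))
  names(long) <- c("odor", "roi", "mean_z")
  long$animal <- x$animal_id
  long <- dplyr::left_join(long, x$odor_roles[c("odor", "role")], by = "odor")
  long[, c("animal", "odor", "role", "roi", "mean_z")]
}

#' Per-role summary of an atlas
#'
#' @param x A `glom_atlas`.
#' @param ... Unused.
#' @return A tibble with per-role empirical activation fraction and mean
#'   active amplitude.
#' @export
glance.glom_atlas <- function(x, ...) {
  tidy(x) %>%
    dplyr::group_by(.data$role) %>%
    dplyr::summarise(
      frac_active = mean(.data$mean_z != 0),
      mean_amplitude = mean(.data$mean_z[.data$mean_z != 0]),
      .groups = "drop"
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
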