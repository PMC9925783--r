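#' Enumerate the mixture stimulus designs
#'
#' Every stimulus is a mixture of three odors: one target (4 possible; the
#' target alone sets the go/no-go valence), one contextual background
#' (4 possible), and a third background. In training mixtures the third odor
#' is the fixed background (limonene); in test mixtures it is one of 11
#' novel backgrounds. The full design therefore has 16 training mixtures,
#' 176 test mixtures, 192 in total. The reduced design halves the diversity
#' of training examples: each contextual background is paired with one go
#' and one no-go target (8 training mixtures), and the test set keeps only
#' the 8 complementary target-context combinations, giving 88 test mixtures.
#'
#' @param which `"full"` or `"reduced"`.
#' @param odor_roles Odor panel, see [default_odor_roles()].
#' @return A tibble with columns `set` (`"training"`/`"test"`), `mixture_id`,
#'   `target`, `context`, `background`, `valence`.
#' @export
#' @examples
#' table(enumerate_design("full")$set)     # 16 training, 176 test
#' table(enumerate_design("reduced")$set)  # 8 training, 88 test
enumerate_design <- function(which = c("full", "reduced"),
                             odor_roles = default_odor_roles()) {
  which <- match.arg(which)
  targets <- odor_roles$odor[odor_roles$role == "target"]
  valence <- setNames(odor_roles$valence[odor_roles$role == "target"], targets)
  contexts <- odor_roles$odor[odor_roles$role == "contextual"]
  fixed <- odor_roles$odor[odor_roles$role == "fixed"]
  novels <- odor_roles$odor[odor_roles$role == "novel"]
  stopifnot(length(targets) == 4, length(contexts) == 4, length(fixed) == 1)

  combos <- tidyr::expand_grid(target = targets, context = contexts)
  if (which == "reduced") {
    go <- targets[valence[targets] == "go"]
    nogo <- targets[valence[targets] == "nogo"]
    # each context sees one go and one no-go target; the complementary
    # pairings form the reduced test combinations
    train_combos <- tibble(
      context = rep(contexts, each = 2),
      target = c(go[1], nogo[1], go[2], nogo[2], go[1], nogo[2], go[2], nogo[1])
    )
    test_combos <- dplyr::anti_join(combos, train_combos, by = c("target", "context"))
  } else {
    train_combos <- combos
    test_combos <- combos
  }
  training <- dplyr::mutate(train_combos, set = "training", background = fixed)
  test <- tidyr::expand_grid(test_combos, background = novels) %>%
    dplyr::mutate(set = "test")
  out <- dplyr::bind_rows(training, test) %>%
    dplyr::mutate(
      valence = unname(valence[.data$target]),
      mixture_id = paste(.data$set, .data$target, .data$context,
                         .data$background, sep = "|")
    )
  out[, c("set", "mixture_id", "target", "context", "background", "valence")]
}

#' Compose a virtual odor mixture
#'
#' Virtual mixtures are built from single-odor mean patterns in three steps,
#' in this order: (1) each component pattern is curtailed at the detection
#' threshold (entries with z above the threshold are set to 0); (2) the
#' thresholded components are summed per ROI; (3) the sum is passed through
#' the saturating nonlinearity (when one is supplied). Trial noise is *not*
#' added here; instantiate the returned mean with [instantiate_trials()].
#'
#' @param components Numeric matrix (components x ROIs) or list of equal
#'   length numeric vectors sharing the ROI axis.
#' @param threshold Detection threshold (negative z, e.g. -0.42); `NULL`
#'   skips thresholding.
#' @param saturation A [saturation_model()] or `NULL` to skip saturation.
#' @return Numeric vector of mean mixture z per ROI.
#' @export
compose_mixture <- function(components, threshold = -0.42, saturation = NULL) {
  if (is.list(components) && !is.data.frame(components)) {
    lens <- lengths(components)
    if (length(unique(lens)) != 1L) abort("Components must share the ROI axis.")
    components <- do.call(rbind, components)
  }
  components <- as.matrix(components)
  if (!is.null(threshold)) {
    if (threshold > 0) abort("`threshold` must be <= 0 (activation is negative z).")
    components[components > threshold] <- 0
  }
  total <- colSums(components)
  if (!is.null(saturation)) total <- apply_saturation(total, saturation)
  total
}

#' Compose every mixture of a design from an atlas
#'
#' @param atlas A `glom_atlas` holding the single-odor mean patterns.
#' @param design A design tibble from [enumerate_design()] (or a subset).
#' @param threshold,saturation Passed to [compose_mixture()].
#' @return A list with `patterns` (mixtures x ROIs matrix, rows named by
#'   `mixture_id`) and `design` (the tibble, row-aligned with the matrix).
#' @export
compose_design <- function(atlas, design, threshold = -0.42, saturation = NULL) {
  stopifnot(inherits(atlas, "glom_atlas"), is.data.frame(design))
  odors_needed <- unique(c(design$target, design$context, design$background))
  missing <- setdiff(odors_needed, rownames(atlas$mean_z))
  if (length(missing)) {
    abort(paste0("Atlas lacks odors: ", paste(missing, collapse = ", ")))
  }
  patterns <- t(vapply(seq_len(nrow(design)), function(i) {
    compose_mixture(
      atlas$mean_z[c(design$target[i], design$context[i], design$background[i]), ,
                   drop = FALSE],
      threshold = threshold, saturation = saturation)
  }, numeric(ncol(atlas$mean_z))))
  rownames(patterns) <- design$mixture_id
  colnames(patterns) <- colnames(atlas$mean_z)
  list(patterns = patterns, design = design)
}

#' Similarity between two glomerular patterns
#'
#' The normalized dot product (cosine) between two activation patterns:
#' 1 means the two patterns have the same shape, 0 means orthogonal shapes.
#'
#' @param p,q Numeric vectors over the same ROI axis, each with at least one
#'   nonzero entry.
#' @return A number in \[-1, 1\].
#' @export
similarity <- function(p, q) {
  if (length(p) != length(q)) abort("Patterns must share the ROI axis.")
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) abort("similarity() is undefined for a zero vector.")
  sum(p * q) / (np * nq)
}

#' Serial air-dilution arithmetic
#'
#' Saturated odor vapor is diluted in a cascade: at each stage an odorized
#' flow joins a clean carrier flow, diluting by
#' `odor_flow / (odor_flow + carrier_flow)`; at the final stage the odorized
#' flow enters an already-merged stream of stated total flow, diluting by
#' `final_flow / final_total`.
#'
#' @param stages Data frame or 2-column matrix with columns `odor` and
#'   `carrier` (flows in L/min, one row per stage).
#' @param final_flow,final_total Flows of the last stage (L/min); both `NULL`
#'   to skip it.
#' @return Fraction of saturated vapor (dimensionless).
#' @export
#' @examples
#' # three-stage dilution used on day 1: 0.34% of saturated vapor
#' serial_dilution(data.frame(odor = c(0.5, 0.5), carrier = c(3, 1.5)),
#'                 final_flow = 0.5, final_total = 5.2)
serial_dilution <- function(stages, final_flow = NULL, final_total = NULL) {
  stages <- as.data.frame(stages)
  if (ncol(stages) == 2 && !all(c("odor", "carrier") %in% names(stages))) {
    names(stages) <- c("odor", "carrier")
  }
  if (any(stages$odor <= 0) || any(stages$carrier < 0)) {
    abort("Odor flows must be positive and carrier flows non-negative.")
  }
  frac <- prod(stages$odor / (stages$odor + stages$carrier))
  if (!is.null(final_flow)) {
    if (is.null(final_total) || final_total <= 0) {
      abort("`final_total` must be a positive flow.")
    }
    frac <- frac * final_flow / final_total
  }
  frac
}

#' Air velocity at the animal's nose
#'
#' Converts a volumetric flow through round tubing into linear velocity:
#' `v = Q / (pi r^2)` with SI conversions (L/min to m^3/s, inches to m).
#'
#' @param flow_lpm Flow in liters per minute (> 0).
#' @param id_inch Tube internal diameter in inches (> 0).
#' @return Velocity in m/s.
#' @export
#' @examples
#' nose_velocity(0.7, 1 / 8)  # 1.47 m/s
nose_velocity <- function(flow_lpm, id_inch) {
  check_number(flow_lpm, "flow_lpm", lower = .Machine$double.eps)
  check_number(id_inch, "id_inch", lower = .Machine$double.eps)
  q <- flow_lpm / 1000 / 60                 # m^3/s
  r <- id_inch * 0.0254 / 2                 # m
  q / (pi * r^2)
}
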