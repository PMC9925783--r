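#' Write glomerular response tables as long-format text
#'
#' Atlases and trial sets travel as plain CSV/TSV in long format with
#' columns `animal`, `odor`, `roi`, `value` and, for trial sets, `repeat`.
#' Values use `.` as the decimal separator; a header row is mandatory.
#'
#' @param x A `glom_atlas` or `trial_set`.
#' @param path Output path; a `.tsv` extension selects tab separation.
#' @return The path, invisibly.
#' @export
write_response_table <- function(x, path) {
  if (inherits(x, "glom_atlas")) {
    long <- tidy(x)[, c("animal", "odor", "roi", "mean_z")]
    names(long)[4] <- "value"
  } else if (inherits(x, "trial_set")) {
    long <- tidy(x)
    long$animal <- "animal_1"
    long <- long[, c("animal", "odor", "roi", "repeat", "value")]
  } else {
    abort("`x` must be a glom_atlas or trial_set.")
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(long, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a glomerular response table
#'
#' Reads a long-format CSV/TSV written by [write_response_table()] (or any
#' table with columns `animal`, `odor`, `roi`, `value` and optionally
#' `repeat`). A table without a `repeat` column becomes a `glom_atlas`
#' (role labels attached from `odor_roles`, defaulting to the standard
#' panel; odors not in the panel get role `"unknown"`); with a `repeat`
#' column it becomes a `trial_set` with an `NA` noise model.
#'
#' @param path Input path; `.tsv` selects tab separation.
#' @param odor_roles Sidecar role table (columns `odor`, `role`, optionally
#'   `valence`).
#' @return A `glom_atlas` or `trial_set`.
#' @export
read_response_table <- function(path, odor_roles = default_odor_roles()) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "repeat."] <- "repeat"   # make.names() mangling
  required <- c("animal", "odor", "roi", "value")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))[1]
    abort(sprintf("Non-numeric `value` at row %d.", bad))
  }
  if (any(!is.finite(df$value))) {
    abort(sprintf("Non-finite `value` at row %d.",
                  which(!is.finite(df$value))[1]))
  }
  has_repeat <- "repeat" %in% names(df)
  key_cols <- c("animal", "odor", "roi", if (has_repeat) "repeat")
  if (anyDuplicated(df[key_cols])) {
    abort(sprintf("Duplicate key at row %d.", anyDuplicated(df[key_cols])))
  }
  odors <- unique(df$odor)
  rois <- unique(df$roi)
  roles <- tibble(odor = odors) %>%
    dplyr::left_join(odor_roles, by = "odor")
  roles$role[is.na(roles$role)] <- "unknown"
  if (!"valence" %in% names(roles)) roles$valence <- NA_character_
  if (!has_repeat) {
    mean_z <- matrix(0, length(odors), length(rois),
                     dimnames = list(odors, rois))
    mean_z[cbind(match(df$odor, odors), match(df$roi, rois))] <- df$value
    structure(list(mean_z = mean_z, odor_roles = roles,
                   animal_id = df$animal[1], spec = NULL),
              class = "glom_atlas")
  } else {
    reps <- sort(unique(df$`repeat`))
    trials <- array(0, dim = c(length(odors), length(rois), length(reps)),
                    dimnames = list(odors, rois, NULL))
    trials[cbind(match(df$odor, odors), match(df$roi, rois),
                 match(df$`repeat`, reps))] <- df$value
    structure(list(trials = trials, mean_z = apply(trials, c(1, 2), mean),
                   noise = noise_model(0, 0, 0, 0, genotype = "unknown"),
                   seed = NULL),
              class = "trial_set")
  }
}

#' Read / write generator configuration
#'
#' Generator and experiment parameters travel as YAML (JSON is also
#' accepted on read) with an explicit `seed` field.
#'
#' @param config Named list of parameters; must include `seed`.
#' @param path File path.
#' @return `read_config()` returns the named list.
#' @export
write_config <- function(config, path) {
  if (is.null(config$seed)) abort("Config must carry an explicit `seed`.")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$seed)) abort("Config must carry an explicit `seed`.")
  cfg
}
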