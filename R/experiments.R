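#' Configure a model-comparison experiment
#'
#' Bundles the knobs of an end-to-end synthetic experiment: the noise
#' regime, the stimulus design, which decoders to run, and the simulation
#' sizes. Defaults are modest so a full comparison runs in well under a
#' minute per animal; raise `n_instantiations` and the atlas size for
#' smoother estimates.
#'
#' @param genotype `"WT"` or `"Cntnap2"`; selects the noise regime
#'   ([noise_model_wt()] / [noise_model_cntnap2()]) and its detection
#'   threshold.
#' @param design `"full"` or `"reduced"`, see [enumerate_design()].
#' @param decoders Character subset of
#'   `c("svm", "logistic", "nnc", "glomerulus", "lasso")`.
#' @param n_animals Synthetic animals.
#' @param n_rois ROIs per animal.
#' @param n_instantiations Noisy instantiations per test mixture.
#' @param lambda Linear-decoder sparsity penalty; `NULL` (default) uses
#'   `1 / n_train`, the conventional default strength of linear-classifier
#'   libraries. 0 fits unpenalized.
#' @param lasso_sizes Dictionary sizes for the Lasso.
#' @param n_dictionaries Random dictionaries per size.
#' @param lasso_lambda Sparseness constraint of the deconvolution.
#' @param saturation Saturating nonlinearity used when composing virtual
#'   mixtures.
#' @param seed Integer master seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(genotype = c("WT", "Cntnap2"),
                              design = c("full", "reduced"),
                              decoders = c("svm", "logistic", "nnc", "lasso"),
                              n_animals = 3, n_rois = 155,
                              n_instantiations = 100, lambda = NULL,
                              lasso_sizes = 100, n_dictionaries = 5,
                              lasso_lambda = 1e-4,
                              saturation = saturation_model_measured(),
                              seed = 1) {
  genotype <- match.arg(genotype)
  design <- match.arg(design)
  decoders <- match.arg(decoders,
                        c("svm", "logistic", "nnc", "glomerulus", "lasso"),
                        several.ok = TRUE)
  structure(
    list(genotype = genotype, design = design, decoders = decoders,
         n_animals = n_animals, n_rois = n_rois,
         n_instantiations = n_instantiations, lambda = lambda,
         lasso_sizes = lasso_sizes, n_dictionaries = n_dictionaries,
         lasso_lambda = lasso_lambda, saturation = saturation, seed = seed),
    class = "experiment_config"
  )
}

regime_of <- function(genotype) {
  if (genotype == "WT") noise_model_wt() else noise_model_cntnap2()
}

# compose training/test patterns of a design from one atlas
prepare_session <- function(atlas, design_tbl, noise, saturation) {
  train_d <- design_tbl[design_tbl$set == "training", ]
  test_d <- design_tbl[design_tbl$set == "test", ]
  train <- compose_design(atlas, train_d, threshold = noise$threshold_z,
                          saturation = saturation)
  test <- compose_design(atlas, test_d, threshold = noise$threshold_z,
                         saturation = saturation)
  list(train = train$patterns, train_labels = train_d$valence,
       test = test$patterns, test_labels = test_d$valence,
       train_design = train_d, test_design = test_d)
}

#' Run the decoder comparison end-to-end on synthetic animals
#'
#' Generates one atlas per animal, composes the virtual training and test
#' mixtures of the configured design (thresholded and saturated), trains the
#' configured decoders on the training means, and evaluates each on noisy
#' instantiations of the test set at the regime's uncorrelated variability.
#' The single-glomerulus decoder, when requested, is evaluated at the total
#' CV since a single glomerulus cannot subtract the population-wide gain.
#'
#' @param config An [experiment_config()].
#' @return Object of class `comparison_report`: tibble `performance`
#'   (animal, decoder, fraction_correct), summary `by_decoder`, and the
#'   config.
#' @export
#' @examples
#' \donttest{
#' cfg <- experiment_config(n_animals = 2, n_rois = 60, n_instantiations = 20)
#' run_comparison(cfg)
#' }
run_comparison <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  noise <- regime_of(config$genotype)
  design_tbl <- enumerate_design(config$design)
  atlases <- generate_atlas_set(config$n_animals,
                                atlas_spec(n_rois = config$n_rois),
                                seed = config$seed)
  seeds <- child_seeds(config$seed + 1, config$n_animals)
  rows <- purrr::map2(atlases, seeds, function(atlas, s) {
    ses <- prepare_session(atlas, design_tbl, noise, config$saturation)
    out <- list()
    eval_seeds <- child_seeds(s, 6)
    if ("svm" %in% config$decoders) {
      lam <- config$lambda %||% (1 / nrow(ses$train))
      dec <- train_linear(ses$train, ses$train_labels, "svm", lam)
      out$svm <- evaluate_decoder(dec, ses$test, ses$test_labels,
                                  cv = noise$cv_uncorr,
                                  n_instantiations = config$n_instantiations,
                                  seed = eval_seeds[1],
                                  design = ses$test_design)$fraction_correct
    }
    if ("logistic" %in% config$decoders) {
      lam <- config$lambda %||% (1 / nrow(ses$train))
      dec <- train_linear(ses$train, ses$train_labels, "logistic", lam)
      out$logistic <- evaluate_decoder(dec, ses$test, ses$test_labels,
                                       cv = noise$cv_uncorr,
                                       n_instantiations = config$n_instantiations,
                                       seed = eval_seeds[2],
                                       design = ses$test_design)$fraction_correct
    }
    if ("nnc" %in% config$decoders) {
      dec <- nnc_fit(ses$train, ses$train_labels)
      out$nnc <- evaluate_decoder(dec, ses$test, ses$test_labels,
                                  cv = noise$cv_uncorr,
                                  n_instantiations = config$n_instantiations,
                                  seed = eval_seeds[3],
                                  design = ses$test_design)$fraction_correct
    }
    if ("glomerulus" %in% config$decoders) {
      dec <- fit_best_glomerulus(ses$train, ses$train_labels)
      out$glomerulus <- evaluate_decoder(dec, ses$test, ses$test_labels,
                                         cv = noise$cv,
                                         n_instantiations = config$n_instantiations,
                                         seed = eval_seeds[4],
                                         design = ses$test_design)$fraction_correct
    }
    if ("lasso" %in% config$decoders) {
      le <- evaluate_lasso(atlas, ses$test_design,
                           sizes = config$lasso_sizes,
                           n_dictionaries = config$n_dictionaries,
                           cv = noise$cv_uncorr, lambda = config$lasso_lambda,
                           threshold = noise$threshold_z,
                           saturation = config$saturation,
                           seed = eval_seeds[5])
      out$lasso <- mean(le$results$fraction_correct)
    }
    tibble(animal = atlas$animal_id, decoder = names(out),
           fraction_correct = unlist(out, use.names = FALSE))
  })
  performance <- dplyr::bind_rows(rows)
  by_decoder <- performance %>%
    dplyr::group_by(.data$decoder) %>%
    dplyr::summarise(mean_correct = mean(.data$fraction_correct),
                     sem = sd(.data$fraction_correct) /
                       sqrt(dplyr::n()), .groups = "drop")
  structure(list(performance = performance, by_decoder = by_decoder,
                 config = config),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s design, %s regime\n",
              x$config$design, x$config$genotype))
  print(x$by_decoder)
  invisible(x)
}

#' @export
tidy.comparison_report <- function(x, ...) x$performance

#' @export
glance.comparison_report <- function(x, ...) {
  tidyr::pivot_wider(x$by_decoder[, c("decoder", "mean_correct")],
                     names_from = "decoder", values_from = "mean_correct")
}

#' @export
autoplot.comparison_report <- function(object, ...) {
  ggplot2::ggplot(object$performance,
                  ggplot2::aes(x = .data$decoder, y = .data$fraction_correct)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08),
                        alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction correct") +
    ggplot2::theme_minimal()
}

#' Sweep decoder sparsity / selectivity
#'
#' Trains the linear decoders along a grid of 21 L1 penalties in \[0, 1\]
#' and the NNC along 10 selectivity thresholds in \[0.5, 1\], reporting test
#' performance and the number of ROIs each point actually uses.
#'
#' @param config An [experiment_config()].
#' @param lambda_grid Penalty grid for the linear families.
#' @param selectivity_grid Selectivity grid for the NNC.
#' @return Object of class `glom_sweep`: tibble `curve` with columns
#'   `animal`, `decoder`, `grid_value`, `n_rois_used`, `fraction_correct`.
#' @export
sweep_glomeruli <- function(config,
                            lambda_grid = seq(0, 1, length.out = 21),
                            selectivity_grid = seq(0.5, 1, length.out = 10)) {
  stopifnot(inherits(config, "experiment_config"))
  if (!length(lambda_grid) || !length(selectivity_grid)) abort("Empty grid.")
  noise <- regime_of(config$genotype)
  design_tbl <- enumerate_design(config$design)
  atlases <- generate_atlas_set(config$n_animals,
                                atlas_spec(n_rois = config$n_rois),
                                seed = config$seed)
  seeds <- child_seeds(config$seed + 2, config$n_animals)
  rows <- purrr::map2(atlases, seeds, function(atlas, s) {
    ses <- prepare_session(atlas, design_tbl, noise, config$saturation)
    eval_seeds <- child_seeds(s, 3)
    out <- list()
    for (fam in intersect(config$decoders, c("svm", "logistic"))) {
      pts <- purrr::map(lambda_grid, function(lam) {
        dec <- train_linear(ses$train, ses$train_labels, fam, lam)
        perf <- evaluate_decoder(dec, ses$test, ses$test_labels,
                                 cv = noise$cv_uncorr,
                                 n_instantiations = config$n_instantiations,
                                 seed = eval_seeds[1])$fraction_correct
        tibble(decoder = fam, grid_value = lam,
               n_rois_used = sum(dec$weights != 0), fraction_correct = perf)
      })
      out[[fam]] <- dplyr::bind_rows(pts)
    }
    if ("nnc" %in% config$decoders) {
      pts <- purrr::map(selectivity_grid, function(th) {
        dec <- tryCatch(nnc_fit(ses$train, ses$train_labels, th),
                        error = function(e) NULL)
        if (is.null(dec)) {
          return(tibble(decoder = "nnc", grid_value = th,
                        n_rois_used = 0L, fraction_correct = NA_real_))
        }
        perf <- evaluate_decoder(dec, ses$test, ses$test_labels,
                                 cv = noise$cv_uncorr,
                                 n_instantiations = config$n_instantiations,
                                 seed = eval_seeds[2])$fraction_correct
        tibble(decoder = "nnc", grid_value = th,
               n_rois_used = sum(dec$keep), fraction_correct = perf)
      })
      out$nnc <- dplyr::bind_rows(pts)
    }
    dplyr::mutate(dplyr::bind_rows(out), animal = atlas$animal_id)
  })
  structure(list(curve = dplyr::bind_rows(rows), config = config),
            class = "glom_sweep")
}

#' @export
print.glom_sweep <- function(x, ...) {
  cat(sprintf("<glom_sweep> %d grid points\n", nrow(x$curve)))
  invisible(x)
}

#' @export
tidy.glom_sweep <- function(x, ...) x$curve

#' @export
autoplot.glom_sweep <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$n_rois_used,
                               y = .data$fraction_correct,
                               colour = .data$decoder)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "ROIs used", y = "fraction correct") +
    ggplot2::theme_minimal()
}

#' Correlate per-odor decoder performance with behavior
#'
#' For each decoder result, computes the Pearson correlation between its
#' per-novel-odor performance and the behavioral per-odor performance, and
#' builds the correlation's Monte-Carlo distribution by resampling the
#' stored instantiation-level outcomes (with replacement, per mixture)
#' `n_mc` times.
#'
#' @param results Named list of [evaluate_decoder()] results, each built
#'   with a `design` so the per-background breakdown exists.
#' @param designs Named list (same names) of the test-design tibbles used.
#' @param behavior A [generate_behavior()] table (columns `odor`,
#'   `performance`).
#' @param n_mc Monte-Carlo repeats (default 500).
#' @param seed Integer seed.
#' @return Tibble with columns `decoder`, `mc`, `r`.
#' @export
correlate_with_behavior <- function(results, designs, behavior, n_mc = 500,
                                    seed = NULL) {
  stopifnot(is.list(results), is.data.frame(behavior))
  check_count(n_mc, "n_mc")
  seeds <- child_seeds(seed, length(results))
  out <- purrr::imap(results, function(res, name) {
    design <- designs[[name]]
    shared <- intersect(unique(design$background), behavior$odor)
    if (length(shared) < 3) abort("Need >= 3 shared odors to correlate.")
    beh <- behavior$performance[match(shared, behavior$odor)]
    n_inst <- ncol(res$correct)
    grp <- split(seq_len(nrow(design)), design$background)
    rs <- with_seed(seeds[match(name, names(results))], {
      vapply(seq_len(n_mc), function(i) {
        idx <- sample.int(n_inst, n_inst, replace = TRUE)
        per_odor <- vapply(shared, function(od) {
          mean(res$correct[grp[[od]], idx])
        }, numeric(1))
        if (sd(per_odor) == 0 || sd(beh) == 0) return(NA_real_)
        cor(per_odor, beh)
      }, numeric(1))
    })
    tibble(decoder = name, mc = seq_len(n_mc), r = rs)
  })
  dplyr::bind_rows(out)
}

#' Decoder performance as the uncorrelated variability grows
#'
#' Re-evaluates the configured decoders across a grid of `cv_uncorr` values
#' on the same synthetic animals and flags, per decoder, the first grid
#' value whose performance is significantly below the baseline regime
#' (two-sided t-test across animals at alpha = 0.05).
#'
#' @param config An [experiment_config()].
#' @param cv_grid Grid of uncorrelated CVs (default
#'   `c(0.25, 0.44, 0.65, 0.85, 1.05, 1.25)`).
#' @param baseline_cv Grid value used as the reference (default the first).
#' @return Object of class `cv_sweep`: tibble `curve` (animal, decoder, cv,
#'   fraction_correct) and tibble `knee` (decoder, first significantly
#'   degraded cv, `NA` if none).
#' @export
cv_sensitivity <- function(config,
                           cv_grid = c(0.25, 0.44, 0.65, 0.85, 1.05, 1.25),
                           baseline_cv = cv_grid[1]) {
  stopifnot(inherits(config, "experiment_config"))
  if (!length(cv_grid)) abort("Empty CV grid.")
  noise <- regime_of(config$genotype)
  design_tbl <- enumerate_design(config$design)
  atlases <- generate_atlas_set(config$n_animals,
                                atlas_spec(n_rois = config$n_rois),
                                seed = config$seed)
  seeds <- child_seeds(config$seed + 3, config$n_animals)
  rows <- purrr::map2(atlases, seeds, function(atlas, s) {
    ses <- prepare_session(atlas, design_tbl, noise, config$saturation)
    decs <- list()
    for (fam in intersect(config$decoders, c("svm", "logistic"))) {
      lam <- config$lambda %||% (1 / nrow(ses$train))
      decs[[fam]] <- train_linear(ses$train, ses$train_labels, fam, lam)
    }
    if ("nnc" %in% config$decoders) decs$nnc <- nnc_fit(ses$train, ses$train_labels)
    eval_seeds <- child_seeds(s, length(cv_grid))
    grid_rows <- purrr::imap(decs, function(dec, nm) {
      purrr::map2(cv_grid, eval_seeds, function(cv, es) {
        tibble(decoder = nm, cv = cv,
               fraction_correct = evaluate_decoder(
                 dec, ses$test, ses$test_labels, cv = cv,
                 n_instantiations = config$n_instantiations,
                 seed = es)$fraction_correct)
      }) %>% dplyr::bind_rows()
    })
    dplyr::mutate(dplyr::bind_rows(grid_rows), animal = atlas$animal_id)
  })
  curve <- dplyr::bind_rows(rows)
  knee <- curve %>%
    dplyr::group_by(.data$decoder) %>%
    dplyr::group_modify(function(df, key) {
      base <- df$fraction_correct[df$cv == baseline_cv]
      higher <- sort(unique(df$cv[df$cv > baseline_cv]))
      first_bad <- NA_real_
      for (cv in higher) {
        x <- df$fraction_correct[df$cv == cv]
        p <- tryCatch(t.test(x, base)$p.value, error = function(e) NA_real_)
        if (!is.na(p) && p < 0.05 && mean(x) < mean(base)) {
          first_bad <- cv
          break
        }
      }
      tibble(first_degraded_cv = first_bad)
    }) %>% dplyr::ungroup()
  structure(list(curve = curve, knee = knee, config = config),
            class = "cv_sweep")
}

#' @export
print.cv_sweep <- function(x, ...) {
  cat("<cv_sweep>\n")
  print(x$knee)
  invisible(x)
}

#' @export
tidy.cv_sweep <- function(x, ...) x$curve

#' @export
autoplot.cv_sweep <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$cv, y = .data$fraction_correct,
                               colour = .data$decoder)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "CV (uncorrelated)", y = "fraction correct") +
    ggplot2::theme_minimal()
}
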