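# Pipeline orchestration: one config object drives generate ->
# degrade -> simulate/classify -> fit -> compare, with stage-level
# logging and reproducible outputs (every table carries the config
# hash and master seed).

#' Build a pipeline run configuration
#'
#' Defaults reproduce the study-scale conditions: 288 images per
#' category, 14 simulated human observers, the four matched human
#' degradation levels per type, 80% threshold criterion, 2000
#' bootstrap replicates and Bonferroni correction over the four
#' matched levels. `demo_config()` scales the same design down so the
#' full pipeline completes in minutes on one CPU.
#'
#' @param n_per_class images per category for the test set.
#' @param n_observers simulated human observers.
#' @param n_runs classifier training runs (majority-voted).
#' @param preset degradation preset name (`"human"` or `"cnn"`).
#' @param kinds degradation kinds to run.
#' @param criterion threshold criterion, in (0.5, 1).
#' @param n_boot bootstrap replicates for threshold CIs.
#' @param m_comparisons Bonferroni factor.
#' @param image_params see [synthetic_image_params()].
#' @param human_model,classifier_model [observer_model()]s; the human
#'   model defaults to thresholds near those typical of human
#'   observers on this task, and the classifier trial table comes from
#'   the spectral stand-in classifier, with `classifier_model` unused
#'   unless `classify = FALSE`.
#' @param classify if TRUE (default) run the spectral stand-in
#'   classifier on degraded pixels; if FALSE simulate the classifier
#'   as a second Weibull observer (much faster).
#' @param whiten_input apply spectral whitening before degradation.
#' @param seed master seed.
#' @return a validated `run_config` list.
#' @export
run_config <- function(n_per_class = 288, n_observers = 14, n_runs = 10,
                       preset = "human",
                       kinds = c("lowpass", "highpass", "phase_scramble"),
                       criterion = 0.80, n_boot = 2000, m_comparisons = 4,
                       image_params = synthetic_image_params(),
                       human_model = NULL, classifier_model = NULL,
                       classify = TRUE, whiten_input = FALSE, seed = 1L) {
  levels_per_kind <- degradation_presets(preset)[kinds]
  if (any(vapply(levels_per_kind, length, integer(1)) == 0))
    stop("empty level grid")
  if (criterion <= 0.5 || criterion >= 1)
    stop("criterion must lie in (0.5, 1)")
  if (n_per_class < 1 || n_observers < 1 || n_runs < 1 || n_boot < 10)
    stop("invalid design sizes")
  if (is.null(human_model)) {
    # alphas chosen so the 80% thresholds sit near values typical of
    # human observers on this task (see package vignette)
    f <- (-log(1 - 0.3 / 0.49))^(1 / 3) # criterion factor at beta=3,l=.01
    human_model <- observer_model(
      alpha = c(lowpass = 3.43 / f, highpass = 1 / 6.02 / f,
                phase_scramble = (1 - 0.5844) / f),
      beta = 3, lambda = 0.01)
  }
  if (is.null(classifier_model)) {
    f <- (-log(1 - 0.3 / 0.49))^(1 / 3)
    classifier_model <- observer_model(
      alpha = c(lowpass = 4.38 / f, highpass = 1 / 3.83 / f,
                phase_scramble = (1 - 0.3704) / f),
      beta = 3, lambda = 0.01)
  }
  cfg <- list(n_per_class = n_per_class, n_observers = n_observers,
              n_runs = n_runs, preset = preset, kinds = kinds,
              levels_per_kind = levels_per_kind, criterion = criterion,
              n_boot = n_boot, m_comparisons = m_comparisons,
              image_params = image_params, human_model = human_model,
              classifier_model = classifier_model, classify = classify,
              whiten_input = whiten_input, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Demo-scale pipeline configuration
#'
#' The same design as [run_config()] at a size that completes in
#' minutes on one CPU: 64 images per class at 64 x 64 pixels, 4
#' observers, 2 classifier runs and 200 bootstrap replicates.
#'
#' @param ... overrides passed to [run_config()].
#' @export
demo_config <- function(...) {
  args <- list(n_per_class = 64, n_observers = 4, n_runs = 2,
               n_boot = 200,
               image_params = synthetic_image_params(64, 64))
  override <- list(...)
  args[names(override)] <- override
  do.call(run_config, args)
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields of [run_config()] can be set in a flat YAML map;
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  ok <- names(formals(run_config))
  bad <- setdiff(names(y), ok)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$image_params))
    y$image_params <- do.call(synthetic_image_params, y$image_params)
  do.call(run_config, y)
}

#' @keywords internal
#' @noRd
config_hash <- function(config) {
  stripped <- config[setdiff(names(config),
                             c("human_model", "classifier_model"))]
  rlang::hash(list(stripped, unclass(config$human_model),
                   unclass(config$classifier_model)))
}

#' @keywords internal
#' @noRd
stage_log <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[scenedegrade] %-10s %.1fs", stage,
                    as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Executes generate -> degrade -> simulate/classify -> fit -> compare
#' on synthetic data and writes, under `out_dir`: `fits.csv` (one row
#' per observer-group x kind: Weibull parameters, threshold and CI),
#' `comparisons.csv` (accuracy ratios per kind x level),
#' `agreement.csv` (agreement ratios per kind x level) and
#' `summary.json` (config hash, seed, stage timings). Outputs are a
#' pure function of the configuration and seed: re-running an
#' identical config gives byte-identical CSVs.
#'
#' Human observers are simulated Weibull responders on the degraded
#' stimuli; the artificial classifier is the spectral-feature stand-in
#' trained on an independently generated training set, tested on the
#' degraded pixels (or, with `classify = FALSE`, a second simulated
#' observer).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose log stage timings (default TRUE).
#' @return invisibly, a list with `fits`, `comparisons`, `agreement`
#'   data.frames and the `summary` list.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[3]
  timings <- c()
  tick <- function(stage) {
    timings[stage] <<- round(as.numeric(proc.time()[3] - t0), 2)
    stage_log(verbose, stage, t0)
    t0 <<- proc.time()[3]
  }
  seed <- config$seed

  # --- generate -------------------------------------------------------
  test_set <- gen_two_class_set(config$n_per_class, config$image_params,
                                seed = derive_seed(seed, "test-images"))
  train_set <- if (config$classify)
    gen_two_class_set(config$n_per_class, config$image_params,
                      seed = derive_seed(seed, "train-images"))
  tick("generate")

  # --- degrade + classify --------------------------------------------
  images <- test_set$images
  if (config$whiten_input && config$classify) {
    images <- lapply(images, function(x) stretch_full_range(whiten(x)))
    train_imgs <- lapply(train_set$images,
                         function(x) stretch_full_range(whiten(x)))
  } else if (config$classify) {
    train_imgs <- train_set$images
  }
  labels <- test_set$labels
  cls_rows <- list()
  if (config$classify) {
    models <- lapply(seq_len(config$n_runs), function(r) {
      idx <- with_seed(derive_seed(seed, "run", r), {
        sample(length(train_imgs), round(0.8 * length(train_imgs)))
      })
      train_spectral_classifier(
        train_imgs[idx], train_set$labels[idx],
        augment = list(levels_per_kind = config$levels_per_kind,
                       n_per_image = 2,
                       seed = derive_seed(seed, "augment", r)))
    })
    for (kind in config$kinds) {
      for (lv in config$levels_per_kind[[kind]]) {
        degraded <- lapply(names(images), function(id) {
          degrade_image(images[[id]], kind, lv,
                        derive_seed(seed, "stim", id, kind, lv))
        })
        scores <- vapply(models, function(m) predict_scores(m, degraded),
                         numeric(length(degraded)))
        agg <- aggregate_predictions(scores, labels)
        cls_rows[[paste(kind, lv)]] <- data.frame(
          observer_id = "classifier",
          stimulus_id = sprintf("%s_%s_%g", names(images), kind, lv),
          true_category = ifelse(labels == 1, "animal", "vehicle"),
          degradation_kind = kind, level = lv,
          decision = ifelse(agg$group_decision == 1, "animal", "vehicle"),
          correct = agg$group_decision == labels,
          run_accuracy = mean(agg$run_accuracy),
          stringsAsFactors = FALSE)
      }
    }
    cls_trials <- do.call(rbind, c(cls_rows, list(make.row.names = FALSE)))
  }
  tick("classify")

  # --- simulate human observers --------------------------------------
  design <- do.call(rbind, lapply(config$kinds, function(k) {
    data.frame(kind = k, level = config$levels_per_kind[[k]],
               n_trials = 2L * config$n_per_class)
  }))
  # align simulated trials with the degraded stimuli (same ids and the
  # same true categories) so image-level agreement compares decisions
  # about the same pictures
  align_trials <- function(tt) {
    tt$stimulus_id <- sprintf("%s_%s_%g",
                              rep(names(test_set$images),
                                  times = nrow(design)),
                              tt$degradation_kind, tt$level)
    tt$true_category <- rep(ifelse(labels == 1, "animal", "vehicle"),
                            times = nrow(design))
    tt$decision <- ifelse(tt$correct, tt$true_category,
                          ifelse(tt$true_category == "animal",
                                 "vehicle", "animal"))
    tt
  }
  hum_trials <- do.call(rbind, lapply(seq_len(config$n_observers),
    function(o) {
      align_trials(simulate_observer(
        config$human_model, design,
        seed = derive_seed(seed, "observer", o),
        observer_id = sprintf("human%02d", o)))
    }))
  if (!config$classify) {
    cls_trials <- align_trials(simulate_observer(
      config$classifier_model, design,
      seed = derive_seed(seed, "classifier"),
      observer_id = "classifier"))
  }
  tick("simulate")

  # --- fit ------------------------------------------------------------
  fit_rows <- list()
  for (kind in config$kinds) {
    groups <- list(human = hum_trials, classifier = cls_trials)
    for (g in names(groups)) {
      tr <- groups[[g]]
      tr <- tr[tr$degradation_kind == kind, ]
      fit <- fit_psychometric(data.frame(level = tr$level,
                                         correct = tr$correct), kind)
      if (fit$converged)
        fit <- bootstrap_ci(fit, n_boot = config$n_boot,
                            seed = derive_seed(seed, "boot", g, kind))
      fit_rows[[paste(g, kind)]] <- data.frame(
        observer = g, kind = kind, alpha = fit$alpha, beta = fit$beta,
        lambda = fit$lambda, threshold80 = fit$threshold80,
        ci_low = fit$ci95[1], ci_high = fit$ci95[2],
        n_boot = fit$n_boot, converged = fit$converged,
        stringsAsFactors = FALSE)
    }
  }
  fits <- do.call(rbind, c(fit_rows, list(make.row.names = FALSE)))
  tick("fit")

  # --- compare --------------------------------------------------------
  comp_rows <- list(); agr_rows <- list()
  m <- config$m_comparisons
  for (kind in config$kinds) {
    for (lv in config$levels_per_kind[[kind]]) {
      hh <- hum_trials[hum_trials$degradation_kind == kind &
                         hum_trials$level == lv, ]
      cc <- cls_trials[cls_trials$degradation_kind == kind &
                         cls_trials$level == lv, ]
      pair <- count_pair(sum(cc$correct), nrow(cc),
                         sum(hh$correct), nrow(hh))
      ar <- accuracy_ratio(pair, m_comparisons = m)
      comp_rows[[paste(kind, lv)]] <- data.frame(
        kind = kind, level = lv, ratio = ar$ratio,
        ci_low = ar$ci95[1], ci_high = ar$ci95[2],
        p_raw = ar$p_raw, p_corrected = ar$p_corrected,
        stringsAsFactors = FALSE)
      # per-participant observed agreement with the classifier's
      # image-level decisions, then averaged
      cc <- cc[order(cc$stimulus_id), ]
      obs_per <- vapply(split(hh, hh$observer_id), function(hp) {
        hp <- hp[order(hp$stimulus_id), ]
        observed_agreement(hp$decision, cc$decision, hp$stimulus_id,
                           cc$stimulus_id)$proportion
      }, numeric(1))
      n_img <- nrow(cc)
      agr <- agreement_ratio(round(mean(obs_per) * n_img), n_img, pair,
                             m_comparisons = m)
      agr_rows[[paste(kind, lv)]] <- data.frame(
        kind = kind, level = lv, observed = mean(obs_per),
        expected = agr$expected, ratio = agr$ratio,
        ci_low = agr$ci95[1], ci_high = agr$ci95[2],
        p_raw = agr$p_raw, p_corrected = agr$p_corrected,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, c(comp_rows, list(make.row.names = FALSE)))
  agreement <- do.call(rbind, c(agr_rows, list(make.row.names = FALSE)))
  tick("compare")

  hash <- config_hash(config)
  stamp <- function(df) {
    df$config_hash <- hash
    df$seed <- seed
    df
  }
  fits <- stamp(fits); comparisons <- stamp(comparisons)
  agreement <- stamp(agreement)
  utils::write.csv(fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(agreement, file.path(out_dir, "agreement.csv"),
                   row.names = FALSE)
  summary <- list(config_hash = hash, seed = seed,
                  n_per_class = config$n_per_class,
                  n_observers = config$n_observers,
                  kinds = config$kinds, preset = config$preset,
                  whiten_input = config$whiten_input,
                  stage_seconds = as.list(timings))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fits = fits, comparisons = comparisons,
                 agreement = agreement, summary = summary))
}
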