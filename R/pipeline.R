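#' Pipeline configuration
#'
#' Bundles every stage's settings: cohort generation, descriptor windows,
#' the datasets to build, the model grid and the training budget. The
#' `"smoke"` profile is a small configuration (few subjects, few stimulus
#' repetitions, few epochs) that exercises every stage in minutes; the
#' `"paper"` profile restores the reference protocol (30 phasic repetitions,
#' 2000 epochs, learning rate grid 1e-4..1e-6).
#'
#' @param profile "smoke" or "paper"
#' @param generator a [generator_config()]
#' @param datasets dataset ids to build (subset of [dataset_ids()])
#' @param models models to train: any of "rfc", "rfr", "lstm_cce",
#'   "lstm_bce", "lstm_sw_cce", "lstm_sw_bce"
#' @param modalities any of "eda", "facial"; fusion is added when both are
#'   present
#' @param shift_s,window_s descriptor window settings
#' @param lr,epochs,batch_size recurrent training budget
#' @param seed master seed
#' @param out_dir optional directory; when given, sessions, the manifest and
#'   the report are written there
#' @return list of class `"pipeline_config"`
#' @export
pipeline_config <- function(profile = c("smoke", "paper"),
                            generator = NULL,
                            datasets = c("RPD"),
                            models = c("rfc", "rfr", "lstm_bce"),
                            modalities = c("eda", "facial"),
                            shift_s = 3, window_s = 10L,
                            lr = NULL, epochs = NULL, batch_size = 512L,
                            seed = 1L, out_dir = NULL) {
  profile <- match.arg(profile)
  if (is.null(generator))
    generator <- if (profile == "smoke")
      generator_config(n_subjects = 6L, phasic_reps = 4L,
                       tonic_pause_s = 60, seed = seed)
    else generator_config(seed = seed)
  if (is.null(lr)) lr <- if (profile == "smoke") 1e-3 else 1e-4
  if (is.null(epochs)) epochs <- if (profile == "smoke") 30L else 2000L
  stopifnot(all(datasets %in% dataset_ids()),
            all(models %in% c("rfc", "rfr", "lstm_cce", "lstm_bce",
                              "lstm_sw_cce", "lstm_sw_bce")),
            all(modalities %in% c("eda", "facial")))
  structure(list(profile = profile, generator = generator,
                 datasets = datasets, models = models,
                 modalities = modalities, shift_s = shift_s,
                 window_s = window_s, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Windows per modality for a list of sessions, bound over subjects.
cohort_windows <- function(sessions, modality, shift_s, window_s) {
  bind_windows(lapply(sessions, session_windows, modality = modality,
                      shift_s = shift_s, window_s = window_s))
}

#' Run the full pipeline
#'
#' simulate -> featurize -> build datasets -> train (including the
#' sample-weighting variants) -> fuse -> evaluate. Deterministic given the
#' configuration seed. Returns the evaluation report; when the
#' configuration names an output directory, the per-subject session files,
#' the cohort manifest and the report (CSV + JSON) are written there.
#'
#' @param cfg a [pipeline_config()]
#' @return an `evaluation_report`
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cohort <- generate_cohort(cfg$generator)
  if (!is.null(cfg$out_dir)) {
    dir.create(file.path(cfg$out_dir, "sessions"), recursive = TRUE,
               showWarnings = FALSE)
    for (s in cohort$sessions)
      write_session_csv(s, file.path(cfg$out_dir, "sessions",
                                     paste0(s$subject_id, ".csv")))
    write_cohort_manifest(cohort, file.path(cfg$out_dir, "manifest.json"),
                          session_dir = file.path(cfg$out_dir, "sessions"))
  }
  splits <- split(cohort$manifest$subject_id, cohort$manifest$split)
  need_facial <- "facial" %in% cfg$modalities || any(grepl("sw", cfg$models))
  ws <- list()
  for (mod in unique(c(cfg$modalities, if (need_facial) "facial"))) {
    ws[[mod]] <- list(
      train = cohort_windows(cohort$sessions[splits$train], mod,
                             cfg$shift_s, cfg$window_s),
      test = cohort_windows(cohort$sessions[splits$test], mod,
                            cfg$shift_s, cfg$window_s))
  }

  cells <- list()
  for (ds in cfg$datasets) {
    sets <- lapply(ws, function(w) list(train = build_dataset(w$train, ds),
                                        test = build_dataset(w$test, ds)))
    # the same label stream drives every modality, so the built datasets
    # are aligned window-for-window
    mods <- cfg$modalities
    if (length(mods) == 2L)
      stopifnot(identical(sets[[mods[1]]]$test$code, sets[[mods[2]]]$test$code))
    sw_idx <- if (any(grepl("sw", cfg$models))) {
      sample_weighting(sets[["facial"]]$train,
                       cfg = rf_config("classification", seed = cfg$seed))
    } else NULL

    for (model in cfg$models) {
      task <- if (grepl("cce|rfc", model)) "classification" else "regression"
      preds <- list()
      for (mod in mods) {
        train_set <- sets[[mod]]$train
        if (grepl("sw", model)) train_set <- augment_windows(train_set, sw_idx)
        fit <- if (grepl("^rf", model)) {
          train_rf(train_set, rf_config(task, seed = cfg$seed))
        } else {
          train_recurrent(train_set, default_arch(ds, task),
                          lr = cfg$lr, epochs = cfg$epochs,
                          batch_size = cfg$batch_size, seed = cfg$seed)
        }
        preds[[mod]] <- predict_windows(fit, sets[[mod]]$test, modality = mod)
        cells[[length(cells) + 1L]] <-
          list(dataset = ds, model = model, modality = mod,
               pred = preds[[mod]], truth = sets[[mod]]$test,
               arch = if (grepl("^rf", model)) NA else model_id(fit),
               lr = if (grepl("^rf", model)) NA else cfg$lr)
      }
      if (length(mods) == 2L) {
        fused <- fuse_predictions(preds[[mods[1]]], preds[[mods[2]]])
        cells[[length(cells) + 1L]] <-
          list(dataset = ds, model = model, modality = "DF",
               pred = fused, truth = sets[[mods[1]]]$test)
      }
    }
  }
  report <- evaluation_report(cells)
  if (!is.null(cfg$out_dir))
    write_report(report, file.path(cfg$out_dir, "report.csv"),
                 file.path(cfg$out_dir, "report.json"))
  report
}
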