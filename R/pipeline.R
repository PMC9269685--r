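#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run: the session design (or a
#' directory of existing recordings), harmonization side, filter settings,
#' transverse-plane convention, output directory and seed. Can be read from
#' a YAML file with [read_run_config()].
#'
#' @param design A [session_design()] (used when simulating) or `NULL` when
#'   reading recordings from `input_dir`.
#' @param input_dir Directory of recording CSVs named
#'   `<sensor>__<trial_id>.csv` (only when `design` is `NULL`).
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param side Leading side for harmonization.
#' @param cutoff,filter_order Butterworth settings for segmentation.
#' @param transverse Transverse-plane convention for LPOE.
#' @param simulate Logical; simulate recordings from `design` (default) or
#'   read them from `input_dir`.
#' @return A `run_config` object.
#' @export
run_config <- function(design = session_design(), input_dir = NULL,
                       out_dir = tempfile("transferkin_run_"), seed = 1,
                       side = "left", cutoff = 15, filter_order = 4,
                       transverse = "body", simulate = is.null(input_dir)) {
  if (!simulate) {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop("input_dir does not exist: ", input_dir, call. = FALSE)
    }
  }
  structure(
    list(design = design, input_dir = input_dir, out_dir = out_dir,
         seed = seed, side = side, cutoff = cutoff,
         filter_order = filter_order, transverse = transverse,
         simulate = simulate),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys mirror the [run_config()] arguments; the
#' `design` block accepts `n_subjects`, `trials_per_subject`,
#' `between_subject_sd`, `within_subject_sd`, `score_flip_prob` and a
#' `sensors` block of noise parameters per sensor name.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  design <- session_design()
  if (!is.null(y$design)) {
    d <- y$design
    sensors <- if (is.null(d$sensors)) {
      list(KINECT_AZURE = sensor_noise(jitter_sd = 2),
           KINECT_V2 = sensor_noise(jitter_sd = 3))
    } else {
      lapply(d$sensors, function(s) {
        sensor_noise(
          jitter_sd = s$jitter_sd %||% 0,
          pelvis_lag = s$pelvis_lag %||% 0,
          dropout_prob = s$dropout_prob %||% 0
        )
      })
    }
    design <- session_design(
      n_subjects = d$n_subjects %||% 7,
      trials_per_subject = d$trials_per_subject %||% 10,
      between_subject_sd = unlist(d$between_subject_sd) %||%
        c(dswp = 5.2, lpoe = 5.3, le = 5.0, tf = 7.0),
      within_subject_sd = unlist(d$within_subject_sd) %||%
        c(dswp = 1.5, lpoe = 1.6, le = 1.5, tf = 2.1),
      sensors = sensors,
      score_flip_prob = d$score_flip_prob %||% 0.08
    )
  }
  run_config(
    design = design,
    input_dir = y$input_dir %||% NULL,
    out_dir = y$out_dir %||% tempfile("transferkin_run_"),
    seed = y$seed %||% 1,
    side = y$side %||% "left",
    cutoff = y$cutoff %||% 15,
    filter_order = y$filter_order %||% 4,
    transverse = y$transverse %||% "body"
  )
}

#' Run the full transfer-analysis pipeline
#'
#' Executes the stages in order -- simulate (or load) recordings,
#' harmonize, segment, extract features, reliability report, score
#' agreement/accuracy -- writing per-stage outputs and a JSON manifest
#' (seed, config hash, package version, per-trial status) under
#' `config$out_dir`. A trial failing any stage is recorded with its error
#' message and excluded from downstream statistics, never silently
#' dropped; the run itself only aborts on configuration errors.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @return The run manifest (list), invisibly the same as written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$simulate) {
    session <- simulate_session(config$design, seed = config$seed,
                                render = "recordings")
    recordings <- session$recordings
    score_truth <- session$score_truth
    score_pred <- session$score_pred
    utils::write.csv(session$features_true,
                     file.path(config$out_dir, "features_true.csv"),
                     row.names = FALSE)
  } else {
    files <- list.files(config$input_dir, pattern = "\\.csv(\\.gz)?$",
                        full.names = TRUE)
    files <- files[grepl("__", basename(files))]
    recordings <- list()
    for (f in files) {
      key <- sub("\\.csv(\\.gz)?$", "", basename(f))
      parts <- strsplit(key, "__", fixed = TRUE)[[1]]
      recordings[[paste(parts[1], parts[2], sep = "/")]] <-
        tryCatch(read_recording(f, parts[1]), error = function(e) e)
    }
    score_truth <- NULL; score_pred <- NULL
  }

  trial_status <- list()
  feature_sets <- list()
  for (key in names(recordings)) {
    rec <- recordings[[key]]
    res <- tryCatch({
      if (inherits(rec, "error")) stop(conditionMessage(rec))
      ct <- harmonize(rec, side = config$side)
      seg <- detect_phases(ct$pelvis_x, rec$sensor$nominal_rate,
                           cutoff = config$cutoff,
                           order = config$filter_order)
      extract_features(ct, seg, transverse = config$transverse)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      trial_status[[key]] <- list(key = key, status = "failed",
                                  reason = conditionMessage(res))
    } else {
      trial_status[[key]] <- list(key = key, status = "ok", reason = NA)
      feature_sets[[key]] <- res
    }
  }

  features <- if (length(feature_sets)) features_df(feature_sets) else NULL
  report <- NULL
  if (!is.null(features)) {
    utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    report <- tryCatch(
      reliability_report(features),
      error = function(e) { warning(conditionMessage(e)); NULL }
    )
    if (!is.null(report)) write_reliability_report(report, config$out_dir)
  }

  agreement <- NULL; accuracy <- NULL
  if (!is.null(score_pred) && length(score_pred) >= 2) {
    pair <- utils::combn(names(score_pred), 2, simplify = FALSE)[[1]]
    agreement <- percent_agreement(score_pred[[pair[1]]],
                                   score_pred[[pair[2]]])
    utils::write.csv(agreement$per_item,
                     file.path(config$out_dir, "agreement.csv"),
                     row.names = FALSE)
  }
  if (!is.null(score_pred) && !is.null(score_truth)) {
    accuracy <- lapply(score_pred, accuracy_vs_truth, truth = score_truth)
    acc_df <- do.call(rbind, Map(function(a, sn) {
      cbind(sensor = sn, a$by_stratum)
    }, accuracy, names(accuracy)))
    utils::write.csv(acc_df, file.path(config$out_dir, "accuracy.csv"),
                     row.names = FALSE)
  }

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  tmp <- tempfile()
  writeLines(jsonlite::toJSON(unclass_deep(cfg_for_hash),
                              auto_unbox = TRUE, digits = NA, na = "null",
                              force = TRUE), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  manifest <- list(
    package_version = as.character(utils::packageVersion("transferkin")),
    seed = config$seed,
    config_hash = cfg_hash,
    n_trials = length(trial_status),
    n_failed = sum(vapply(trial_status, function(s)
      s$status == "failed", logical(1))),
    trials = unname(trial_status)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(manifest = manifest, features = features,
                 reliability = report, agreement = agreement,
                 accuracy = accuracy, out_dir = config$out_dir))
}

# strip S3 classes recursively so jsonlite can serialize the config
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
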