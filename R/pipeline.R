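# Orchestration: run configuration (round-tripping through YAML/JSON),
# per-subject feature extraction across the three families, and the
# end-to-end protocol (age-match -> split -> select -> evaluate -> resample)
# with Table-style report writing.

#' Run configuration bundling every stage's parameters
#'
#' @param preprocess A [preprocess_config()].
#' @param gabor A [gabor_bank_config()].
#' @param blob A [blob_detect_config()].
#' @param synth A [synth_config()].
#' @param ratio Controls per case for age matching.
#' @param age_min,age_max Inclusive age bounds (years).
#' @param variance_threshold PCA explained-variance fraction.
#' @param adaboost_rounds Boosting rounds for the local-feature classifier.
#' @param cv_folds Folds for method selection.
#' @param n_resample Resampling runs (0 disables resampling).
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       gabor = gabor_bank_config(),
                       blob = blob_detect_config(),
                       synth = synth_config(),
                       ratio = 3L, age_min = 5L, age_max = 14L,
                       variance_threshold = 0.95, adaboost_rounds = 50L,
                       cv_folds = 10L, n_resample = 50L, seed = 1L) {
  structure(list(preprocess = preprocess, gabor = gabor, blob = blob,
                 synth = synth, ratio = as.integer(ratio),
                 age_min = as.integer(age_min), age_max = as.integer(age_max),
                 variance_threshold = variance_threshold,
                 adaboost_rounds = as.integer(adaboost_rounds),
                 cv_folds = as.integer(cv_folds),
                 n_resample = as.integer(n_resample), seed = as.integer(seed)),
            class = "run_config")
}

config_constructors <- function() list(
  preprocess = preprocess_config, gabor = gabor_bank_config,
  blob = blob_detect_config, synth = synth_config
)

#' Write / read a run configuration (YAML or JSON)
#'
#' The round trip is lossless; unknown keys in the file are rejected.
#'
#' @param config A [run_config()].
#' @param path Target path; `.yaml`/`.yml` selects YAML, `.json` JSON.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- lapply(config, function(v) if (is.list(v)) unclass(v) else v)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(plain, path, precision = 15L)
  else jsonlite::write_json(plain, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  plain <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  template <- run_config()
  unknown <- setdiff(names(plain), names(template))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  ctors <- config_constructors()
  args <- list()
  for (nm in names(plain)) {
    if (nm %in% names(ctors)) {
      sub <- plain[[nm]]
      known <- names(formals(ctors[[nm]]))
      bad <- setdiff(names(sub), known)
      if (length(bad))
        stop("unknown config keys in ", nm, ": ", paste(bad, collapse = ", "),
             call. = FALSE)
      args[[nm]] <- do.call(ctors[[nm]], sub)
    } else {
      args[[nm]] <- plain[[nm]]
    }
  }
  do.call(run_config, args)
}

#' Preprocess one sample and extract all three feature families
#'
#' Runs geometric normalization, histogram equalization, face interception
#' (resampled to the texture crop size for the Gabor energies) and eye-patch
#' segmentation, then extracts the pairwise-distance vector, the texture
#' energy matrix and the five local features.
#'
#' @param sample A [cohort_sample()].
#' @param config A [run_config()].
#' @return List with `ggf` (length 2278), `gtf` (flattened length 4096),
#'   `lf` (named fused vector) and the preprocessed `image`/`landmarks`.
#' @export
extract_sample_features <- function(sample, config = run_config()) {
  norm <- normalize_geometry(sample$image, sample$landmarks, config$preprocess)
  eq <- equalize_gray(norm$image)
  crop <- crop_face_region(eq, norm$landmarks)
  tex <- resample_bilinear(unclass(crop), config$preprocess$texture_crop_size,
                           config$preprocess$texture_crop_size)
  lf <- local_features(eq, norm$landmarks, gabor = config$gabor,
                       blob = config$blob, prep = config$preprocess)
  list(ggf = ggf_extract(norm$landmarks),
       gtf = as.vector(gtf_extract(tex, config$gabor,
                                   input_size = config$preprocess$texture_crop_size)),
       lf = lf$vector,
       image = eq, landmarks = norm$landmarks)
}

#' Extract feature matrices for a whole cohort
#'
#' @param cohort A [cohort()].
#' @param config A [run_config()].
#' @param verbose Print a progress line every 25 subjects.
#' @return List of matrices `ggf`, `gtf`, `lf` (subjects in rows, cohort
#'   order) with subject ids as row names.
#' @export
extract_features <- function(cohort, config = run_config(), verbose = FALSE) {
  n <- length(cohort)
  if (n == 0L) stop("cannot extract features from an empty cohort", call. = FALSE)
  ggf <- gtf <- lf <- NULL
  for (i in seq_len(n)) {
    f <- extract_sample_features(cohort[[i]], config)
    if (is.null(ggf)) {
      ggf <- matrix(0, n, length(f$ggf))
      gtf <- matrix(0, n, length(f$gtf))
      lf <- matrix(0, n, length(f$lf), dimnames = list(NULL, names(f$lf)))
    }
    ggf[i, ] <- f$ggf; gtf[i, ] <- f$gtf; lf[i, ] <- f$lf
    if (verbose && i %% 25 == 0) message("  extracted ", i, "/", n)
  }
  ids <- cohort_ids(cohort)
  rownames(ggf) <- rownames(gtf) <- rownames(lf) <- ids
  colnames(ggf) <- sprintf("gg_%04d", seq_len(ncol(ggf)) - 1)
  colnames(gtf) <- sprintf("gt_%04d", seq_len(ncol(gtf)) - 1)
  list(ggf = ggf, gtf = gtf, lf = lf)
}

#' Run the full classification protocol on a cohort
#'
#' Age-matches the cohort, splits it evenly into training and testing sides,
#' extracts the three feature families, ranks the three pipelines by
#' cross-validation on the training side, retrains each on the full training
#' side and evaluates it on the held-out testing side, and (optionally)
#' repeats the split/train/test cycle `n_resample` times.
#'
#' @param cohort A [cohort()] (e.g. from [gen_cohort()] or [read_cohort()]).
#' @param config A [run_config()].
#' @param out_dir Optional directory for CSV/JSON reports.
#' @param verbose Print stage progress.
#' @return List with `selection` (CV ranking), `test` (per-method
#'   [confusion_metrics()] on the testing side), `resampling` (per-method
#'   [resample_evaluate()] summaries, when requested), and the cohorts used.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("age-matched selection")
  matched <- select_age_matched(cohort, ratio = config$ratio,
                                age_min = config$age_min,
                                age_max = config$age_max, seed = config$seed)
  if (length(matched) == 0L)
    stop("age-matched selection left no usable subjects ",
         "(each age group needs >= 2 cases and ", config$ratio,
         " controls per case)", call. = FALSE)
  say("feature extraction (", length(matched), " subjects)")
  feats <- extract_features(matched, config, verbose = verbose)
  labels <- cohort_labels(matched)
  split <- split_train_test(matched, seed = config$seed)
  tr <- match(cohort_ids(split$train), cohort_ids(matched))
  te <- match(cohort_ids(split$test), cohort_ids(matched))
  say("method selection by ", config$cv_folds, "-fold CV")
  train_feats <- lapply(feats, function(m) m[tr, , drop = FALSE])
  selection <- select_method(train_feats, labels[tr], k = config$cv_folds,
                             seed = config$seed,
                             variance_threshold = config$variance_threshold,
                             rounds = config$adaboost_rounds)
  keys <- c("Global geometrical features" = "ggf",
            "Global texture features" = "gtf",
            "Fusion of local features" = "lf")
  say("testing-side evaluation")
  test_results <- lapply(keys, function(kk) {
    predictor <- fit_method(kk, feats[[kk]][tr, , drop = FALSE], labels[tr],
                            variance_threshold = config$variance_threshold,
                            rounds = config$adaboost_rounds,
                            seed = config$seed)
    confusion_metrics(predictor(feats[[kk]][te, , drop = FALSE]), labels[te])
  })
  resampling <- NULL
  if (config$n_resample > 0) {
    say("resampling x ", config$n_resample)
    resampling <- lapply(keys, function(kk)
      resample_evaluate(matched, feats[[kk]], kk, n_runs = config$n_resample,
                        base_seed = config$seed,
                        variance_threshold = config$variance_threshold,
                        rounds = config$adaboost_rounds))
  }
  report <- list(selection = selection, test = test_results,
                 resampling = resampling, matched = matched, split = split,
                 features = feats, config = config)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Table-2/Table-3 shaped CSVs plus a JSON summary.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- names(report$test)
  test_tab <- data.frame(
    feature = feats,
    method = ifelse(feats == "Fusion of local features", "AdaBoost", "PCA + SVM"),
    sensitivity = vapply(report$test, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(report$test, `[[`, numeric(1), "specificity"),
    row.names = NULL
  )
  utils::write.csv(test_tab, file.path(out_dir, "test_performance.csv"),
                   row.names = FALSE)
  utils::write.csv(report$selection, file.path(out_dir, "method_selection.csv"),
                   row.names = FALSE)
  if (!is.null(report$resampling)) {
    res_tab <- data.frame(
      feature = names(report$resampling),
      mean_sensitivity = vapply(report$resampling, `[[`, numeric(1), "mean_sensitivity"),
      sd_sensitivity = vapply(report$resampling, `[[`, numeric(1), "sd_sensitivity"),
      mean_specificity = vapply(report$resampling, `[[`, numeric(1), "mean_specificity"),
      sd_specificity = vapply(report$resampling, `[[`, numeric(1), "sd_specificity"),
      row.names = NULL
    )
    utils::write.csv(res_tab, file.path(out_dir, "resampling_summary.csv"),
                     row.names = FALSE)
    for (nm in names(report$resampling))
      utils::write.csv(report$resampling[[nm]]$runs,
                       file.path(out_dir, paste0("resampling_runs_",
                                                 gsub("[^a-z]+", "_", tolower(nm)),
                                                 ".csv")),
                       row.names = FALSE)
  }
  summary <- list(
    n_matched = length(report$matched),
    n_train = length(report$split$train), n_test = length(report$split$test),
    seed = report$config$seed,
    best_method = report$selection$feature[1],
    test = lapply(report$test, function(m)
      list(tp = m$tp, fn = m$fn, tn = m$tn, fp = m$fp,
           sensitivity = m$sensitivity, specificity = m$specificity))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
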