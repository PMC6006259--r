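# Cohort assembly and evaluation protocol: age-matched 1:3 case-control
# selection, even random train/test splits within age groups, sensitivity and
# specificity with one-decimal half-away-from-zero rounding, the repeated
# resampling harness, and the two comparison statistics (one-sample t,
# Pearson correlation).

#' Age-matched case-control selection
#'
#' Drops subjects outside `[age_min, age_max]`, then within each one-year age
#' group keeps the largest even number of cases whose matched controls
#' (`ratio` per case) are available, and samples that many controls uniformly
#' without replacement (seeded). Groups lacking a usable case count are
#' dropped entirely. The result satisfies the split invariants: per group,
#' controls = ratio x cases with cases even.
#'
#' @param cohort A [cohort()].
#' @param ratio Controls per case.
#' @param age_min,age_max Inclusive age bounds in years.
#' @param seed Integer seed for the control sampling and case trimming.
#' @return The selected [cohort()] (possibly empty, with a warning).
#' @export
select_age_matched <- function(cohort, ratio = 3L, age_min = 5L, age_max = 14L,
                               seed = 1L) {
  ages <- cohort_ages(cohort)
  labels <- cohort_labels(cohort)
  rng <- local_rng(seed)
  keep <- integer(0)
  in_range <- which(ages >= age_min & ages <= age_max)
  for (a in sort(unique(ages[in_range]))) {
    grp <- in_range[ages[in_range] == a]
    cases <- grp[labels[grp] == "case"]
    controls <- grp[labels[grp] == "control"]
    # largest even case count with ratio-matched controls available
    n_case <- min(length(cases), floor(length(controls) / ratio))
    n_case <- n_case - (n_case %% 2)
    if (n_case < 2) next
    cases_kept <- if (n_case < length(cases))
      cases[rng$sample_n(length(cases), n_case)] else cases
    controls_kept <- if (ratio * n_case < length(controls))
      controls[rng$sample_n(length(controls), ratio * n_case)] else controls
    keep <- c(keep, cases_kept, controls_kept)
  }
  if (length(keep) == 0L)
    warning("age matching produced an empty cohort", call. = FALSE)
  cohort[sort(keep)]
}

#' Even random train/test split within age groups
#'
#' Within each age group and class, half the subjects are assigned to the
#' training side and half to the testing side by a seeded shuffle; class
#' counts per side are therefore equal and seed-independent.
#'
#' @param cohort An age-matched [cohort()] with even per-group class counts.
#' @param seed Integer seed.
#' @return List with `train` and `test` cohorts.
#' @export
split_train_test <- function(cohort, seed = 1L) {
  ages <- cohort_ages(cohort)
  labels <- cohort_labels(cohort)
  rng <- local_rng(seed)
  train <- integer(0); test <- integer(0)
  for (a in sort(unique(ages))) {
    for (cl in c("case", "control")) {
      idx <- which(ages == a & labels == cl)
      if (length(idx) == 0L) next
      if (length(idx) %% 2 != 0)
        stop("cannot split evenly: age group ", a, " has an odd number of ",
             cl, " subjects", call. = FALSE)
      idx <- idx[rng$sample_perm(length(idx))]
      half <- length(idx) / 2
      train <- c(train, idx[seq_len(half)])
      test <- c(test, idx[half + seq_len(half)])
    }
  }
  list(train = cohort[sort(train)], test = cohort[sort(test)])
}

#' Confusion counts and sensitivity/specificity
#'
#' Sensitivity = 100 TP / (TP + FN) and specificity = 100 TN / (TN + FP),
#' each reported as a percentage rounded half away from zero to one decimal
#' (11/16 gives 68.8, 39/48 gives 81.3).
#'
#' @param predictions,labels Character vectors of `"case"` / `"control"`,
#'   equal length.
#' @return An `evaluation_result` list with `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(predictions, labels) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length", call. = FALSE)
  if (!all(c(predictions, labels) %in% c("case", "control")))
    stop("entries must be 'case' or 'control'", call. = FALSE)
  pos <- labels == "case"
  if (!any(pos)) stop("sensitivity undefined: no positive labels", call. = FALSE)
  if (all(pos)) stop("specificity undefined: no negative labels", call. = FALSE)
  tp <- sum(pos & predictions == "case")
  fn <- sum(pos & predictions == "control")
  tn <- sum(!pos & predictions == "control")
  fp <- sum(!pos & predictions == "case")
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = round_half_up(100 * tp / (tp + fn), 1),
                 specificity = round_half_up(100 * tn / (tn + fp), 1)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> TP %d FN %d TN %d FP %d | sens %.1f%% spec %.1f%%\n",
              x$tp, x$fn, x$tn, x$fp, x$sensitivity, x$specificity))
  invisible(x)
}

#' Repeated train/test resampling of a classification pipeline
#'
#' Re-splits the cohort `n_runs` times (run `r` uses seed `base_seed + r`),
#' retrains the pipeline on each training side from scratch, evaluates on the
#' matching testing side, and summarizes sensitivity and specificity as mean
#' and sample standard deviation (n - 1 denominator) over runs.
#'
#' @param cohort An age-matched [cohort()].
#' @param features Matrix of per-subject feature rows aligned with the cohort
#'   (e.g. the fused local feature matrix).
#' @param method `"ggf"`, `"gtf"` or `"lf"` naming a built-in pipeline, or a
#'   list with functions `train(X, labels)` returning an object and
#'   `predict(model, X)` returning labels.
#' @param n_runs Number of resampling runs.
#' @param base_seed Base seed; run `r` reseeds with `base_seed + r`.
#' @param ... Passed on to the built-in trainer ([fit_method()]).
#' @return A `resampling_summary` with per-run data frame `runs` (run, seed,
#'   tp, fn, tn, fp, sensitivity, specificity) and `mean_sensitivity`,
#'   `sd_sensitivity`, `mean_specificity`, `sd_specificity`.
#' @export
resample_evaluate <- function(cohort, features, method, n_runs = 50L,
                              base_seed = 1L, ...) {
  ids <- cohort_ids(cohort)
  labels <- cohort_labels(cohort)
  if (!is.null(features)) {
    features <- as.matrix(features)
    stopifnot(nrow(features) == length(ids))
  }
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    seed_r <- base_seed + r
    sp <- split_train_test(cohort, seed = seed_r)
    tr_idx <- match(cohort_ids(sp$train), ids)
    te_idx <- match(cohort_ids(sp$test), ids)
    if (is.list(method)) {
      model <- method$train(features[tr_idx, , drop = FALSE], labels[tr_idx])
      pred <- method$predict(model, features[te_idx, , drop = FALSE])
    } else {
      predictor <- fit_method(method, features[tr_idx, , drop = FALSE],
                              labels[tr_idx], seed = seed_r, ...)
      pred <- predictor(features[te_idx, , drop = FALSE])
    }
    m <- confusion_metrics(pred, labels[te_idx])
    rows[[r]] <- data.frame(run = r, seed = seed_r, tp = m$tp, fn = m$fn,
                            tn = m$tn, fp = m$fp,
                            sensitivity = m$sensitivity,
                            specificity = m$specificity)
  }
  runs <- do.call(rbind, rows)
  structure(list(runs = runs,
                 mean_sensitivity = mean(runs$sensitivity),
                 sd_sensitivity = stats::sd(runs$sensitivity),
                 mean_specificity = mean(runs$specificity),
                 sd_specificity = stats::sd(runs$specificity),
                 n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed)),
            class = "resampling_summary")
}

#' @export
print.resampling_summary <- function(x, ...) {
  cat(sprintf(
    "<resampling_summary> %d runs | sens %.1f +/- %.1f%% | spec %.1f +/- %.1f%%\n",
    x$n_runs, x$mean_sensitivity, x$sd_sensitivity,
    x$mean_specificity, x$sd_specificity))
  invisible(x)
}

#' One-sample t-test
#'
#' Two-sided test of the sample mean against a reference value:
#' `t = (mean - mu0) / (sd / sqrt(n))` with `n - 1` degrees of freedom.
#'
#' @param values Numeric sample, `n >= 2`, non-constant.
#' @param mu0 Reference value.
#' @return List with `t`, `p`, `df`, `mean`, `sd`, `n`.
#' @export
one_sample_t <- function(values, mu0) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) < 1e-15)
    stop("degenerate sample: zero standard deviation", call. = FALSE)
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean = mean(values),
       sd = stats::sd(values), n = length(values))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric samples, `n >= 3`, both non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15)
    stop("degenerate sample: constant input", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}
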