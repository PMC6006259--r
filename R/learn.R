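# Classification machinery: PCA reduction with automatic dimension choice,
# an SVM over the reduced global features (hyperparameters picked by
# stratified k-fold cross-validation), and discrete AdaBoost over decision
# stumps providing the score-level fusion of the local features.

# Labels are "case" (positive, internally +1) and "control" (negative, -1).
label_to_pm1 <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'", call. = FALSE)
  ifelse(labels == "case", 1, -1)
}

#' Fit a PCA model with automatic dimension selection
#'
#' Centers the data and retains the smallest number of leading principal
#' components whose cumulative explained-variance fraction reaches
#' `variance_threshold`. The retained dimension is a data-dependent output,
#' not a tuning constant.
#'
#' @param features Numeric matrix, subjects in rows.
#' @param variance_threshold Fraction of total variance to retain.
#' @return A `pca_model` with fields `center`, `rotation` (columns = retained
#'   components), `sdev`, `var_explained`, `k`.
#' @export
pca_fit <- function(features, variance_threshold = 0.95) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("PCA needs at least 2 subjects", call. = FALSE)
  if (!all(is.finite(features))) stop("non-finite feature values", call. = FALSE)
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  if (total < 1e-24)
    stop("degenerate data: all subjects identical, PCA undefined", call. = FALSE)
  frac <- pc$sdev^2 / total
  k <- which(cumsum(frac) >= variance_threshold - 1e-12)[1]
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev, var_explained = frac, k = as.integer(k)),
            class = "pca_model")
}

#' Project features onto a fitted PCA model
#'
#' @param model A [pca_fit()] result.
#' @param features Matrix (or vector) with the model's original width.
#' @return Matrix of scores, `k` columns.
#' @export
pca_transform <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != length(model$center))
    stop("feature dimension does not match the PCA model", call. = FALSE)
  sweep(features, 2, model$center) %*% model$rotation
}

# --- AdaBoost over decision stumps ------------------------------------------

# Best stump for one feature column under weights w and labels y in {-1,+1}.
# A stump predicts polarity * sign(x - threshold), with sign(0) counted as -1.
# `ord` is the precomputed sort order of x.
best_stump_for_feature <- function(x, y, w, ord = order(x)) {
  xs <- x[ord]; ys <- y[ord]; ws <- w[ord]
  # error of (threshold below all, polarity +1): predict +1 everywhere
  err_plus_all <- sum(ws[ys == -1])
  # moving the threshold past point i flips its prediction to -1
  csum <- cumsum(ws * ys)          # sum over first i of w*y
  # polarity +1, threshold after position i: err = err_plus_all + csum[i]
  distinct <- c(xs[-1] != xs[-length(xs)], TRUE)
  errs_plus <- err_plus_all + csum
  errs_minus <- 1 - errs_plus      # weights sum to 1
  cand <- which(distinct)
  all_err <- c(err_plus_all, errs_plus[cand], 1 - err_plus_all, errs_minus[cand])
  all_pol <- c(1, rep(1, length(cand)), -1, rep(-1, length(cand)))
  all_thr <- c(min(xs) - 1,
               ifelse(cand < length(xs), (xs[cand] + xs[pmin(cand + 1, length(xs))]) / 2,
                      xs[length(xs)] + 1),
               min(xs) - 1,
               ifelse(cand < length(xs), (xs[cand] + xs[pmin(cand + 1, length(xs))]) / 2,
                      xs[length(xs)] + 1))
  best <- which.min(all_err)
  list(threshold = all_thr[best], polarity = all_pol[best], error = all_err[best])
}

stump_predict <- function(x, threshold, polarity) {
  polarity * ifelse(x > threshold, 1, -1)
}

#' Train a discrete AdaBoost ensemble of decision stumps
#'
#' Standard discrete AdaBoost: at each round the depth-1 stump minimizing the
#' weighted 0-1 error is selected, weighted by
#' `alpha = 0.5 log((1 - eps) / eps)`, and sample weights are re-normalized
#' exponentially. Boosting stops early when no stump beats chance (weighted
#' error >= 0.5) or when the training set is fit exactly.
#'
#' @param features Numeric matrix, subjects in rows (the fused local feature
#'   vectors in the standard pipeline).
#' @param labels Character vector of `"case"` / `"control"`.
#' @param rounds Maximum number of boosting rounds.
#' @return A `fusion_model` with per-round stumps, weights `alpha`, and the
#'   per-round weighted errors.
#' @export
adaboost_train <- function(features, labels, rounds = 50L) {
  X <- as.matrix(features)
  y <- label_to_pm1(labels)
  if (length(unique(y)) < 2)
    stop("both classes must be present to train", call. = FALSE)
  n <- nrow(X)
  w <- rep(1 / n, n)
  ords <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  stumps <- list(); alphas <- numeric(0); eps_hist <- numeric(0)
  score <- numeric(n)
  for (t in seq_len(rounds)) {
    best <- NULL
    for (j in seq_len(ncol(X))) {
      s <- best_stump_for_feature(X[, j], y, w, ords[[j]])
      if (is.null(best) || s$error < best$error) {
        best <- s; best$feature <- j
      }
    }
    if (best$error >= 0.5 - 1e-12) break
    eps <- max(best$error, 1e-12)
    alpha <- 0.5 * log((1 - eps) / eps)
    h <- stump_predict(X[, best$feature], best$threshold, best$polarity)
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <-
      best[c("feature", "threshold", "polarity")]
    alphas <- c(alphas, alpha)
    eps_hist <- c(eps_hist, eps)
    score <- score + alpha * h
    if (all(sign(score) == y)) break  # training error 0, nothing left to fit
  }
  structure(list(stumps = stumps, alpha = alphas, weighted_errors = eps_hist,
                 n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "fusion_model")
}

#' Ensemble score and label from a trained fusion model
#'
#' The score is the weighted stump vote `sum_t alpha_t h_t(x)`; the label is
#' `"case"` for a strictly positive score and `"control"` otherwise (a score
#' of exactly zero resolves to the control class, favoring specificity in a
#' screening setting).
#'
#' @param model A [adaboost_train()] result.
#' @param features Matrix (or single vector) of fused local features.
#' @return List with numeric `score` and character `label`, one entry per row.
#' @export
fuse_scores <- function(model, features) {
  if (!inherits(model, "fusion_model"))
    stop("model must be a trained fusion_model", call. = FALSE)
  if (is.list(features) && !is.null(features$vector))
    features <- features$vector
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  X <- as.matrix(features)
  if (ncol(X) != model$n_features)
    stop("feature width does not match the trained model", call. = FALSE)
  score <- numeric(nrow(X))
  for (t in seq_along(model$stumps)) {
    s <- model$stumps[[t]]
    score <- score + model$alpha[t] *
      stump_predict(X[, s$feature], s$threshold, s$polarity)
  }
  list(score = score, label = ifelse(score > 0, "case", "control"))
}

# --- Cross-validation plans and the SVM over reduced global features --------

#' Stratified k-fold cross-validation plan
#'
#' Folds partition the indices; sizes differ by at most one within each
#' class, so class proportions are preserved as closely as the counts allow.
#' The fold count drops (with a warning) when the rarer class has fewer than
#' `k` members.
#'
#' @param labels Character label vector.
#' @param k Requested number of folds.
#' @param seed Integer seed for the shuffle.
#' @return A `cv_plan`: list with `folds` (list of validation index vectors),
#'   `k`, `seed`.
#' @export
cv_plan <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  min_class <- min(table(labels))
  if (min_class < k) {
    k <- max(2L, as.integer(min_class))
    warning("reducing fold count to ", k,
            " (rarer class has too few members)", call. = FALSE)
  }
  rng <- local_rng(seed)
  assign_fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_perm(length(idx))]
    assign_fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(folds = split(seq_along(labels), assign_fold),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "cv_plan")
}

# Seeded RNG helper confined to a closure (never touches the global stream).
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sample_perm = function(n) with_state(function() sample.int(n)),
    sample_n = function(n, size) with_state(function() sample.int(n, size)),
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    rpois = function(n, lambda) with_state(function() stats::rpois(n, lambda)),
    rint = function(n, lo, hi) with_state(function() lo + sample.int(hi - lo + 1, n, replace = TRUE) - 1L)
  )
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(st, X) {
  sweep(sweep(X, 2, st$center), 2, st$scale, "/")
}

default_svm_grid <- function() {
  rbind(
    data.frame(kernel = "linear", cost = c(0.1, 1, 10), gamma = NA),
    expand.grid(kernel = "radial", cost = c(1, 10), gamma = c(0.25, 1, 4),
                stringsAsFactors = FALSE)
  )
}

balanced_accuracy <- function(pred, truth) {
  pos <- truth == "case"; neg <- !pos
  sens <- if (any(pos)) mean(pred[pos] == "case") else NA_real_
  spec <- if (any(neg)) mean(pred[neg] == "control") else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

svm_fit_raw <- function(X, y, kernel, cost, gamma) {
  yf <- factor(y, levels = c("case", "control"))
  if (kernel == "linear")
    e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE)
  else
    e1071::svm(X, yf, kernel = "radial", cost = cost,
               gamma = gamma / ncol(X), scale = FALSE)
}

#' Train the global-feature SVM with CV-based hyperparameter selection
#'
#' Standardizes the (PCA-reduced) features, evaluates a small grid of linear
#' and RBF kernels by mean cross-validated balanced accuracy under a
#' stratified fold plan, breaks ties toward the simpler model (linear kernel,
#' then smaller cost, then smaller gamma), and refits the winner on the full
#' training set.
#'
#' @param features Numeric matrix of reduced features, subjects in rows.
#' @param labels Character `"case"` / `"control"` vector.
#' @param cv A [cv_plan()] (built from `labels` if omitted).
#' @param grid Data frame with columns `kernel`, `cost`, `gamma` (gamma as a
#'   multiple of the `1/ncol` default; `NA` for linear).
#' @param seed Seed used when `cv` is omitted.
#' @return A `global_classifier` with the fitted SVM, standardization
#'   statistics, chosen hyperparameters and the CV table.
#' @export
svm_train <- function(features, labels, cv = NULL, grid = default_svm_grid(),
                      seed = 1L) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to train", call. = FALSE)
  if (is.null(cv)) cv <- cv_plan(labels, k = 10L, seed = seed)
  st <- standardize_fit(X)
  Xs <- standardize_apply(st, X)
  res <- grid
  res$cv_balanced_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    accs <- vapply(cv$folds, function(val) {
      tr <- setdiff(seq_len(nrow(Xs)), val)
      if (length(unique(labels[tr])) < 2) return(NA_real_)
      fit <- svm_fit_raw(Xs[tr, , drop = FALSE], labels[tr],
                         grid$kernel[g], grid$cost[g], grid$gamma[g])
      pred <- as.character(predict(fit, Xs[val, , drop = FALSE]))
      balanced_accuracy(pred, labels[val])
    }, numeric(1))
    res$cv_balanced_accuracy[g] <- mean(accs, na.rm = TRUE)
  }
  # ties resolve to the simpler model: linear first, then smaller cost/gamma
  ord <- order(-res$cv_balanced_accuracy,
               res$kernel != "linear", res$cost, res$gamma)
  best <- res[ord[1], ]
  fit <- svm_fit_raw(Xs, labels, best$kernel, best$cost, best$gamma)
  structure(list(fit = fit, standardize = st, kernel = best$kernel,
                 cost = best$cost, gamma = best$gamma,
                 cv_balanced_accuracy = best$cv_balanced_accuracy,
                 cv_table = res),
            class = "global_classifier")
}

#' Predict labels from a trained global classifier
#'
#' @param object A [svm_train()] result.
#' @param newdata Matrix of features with the training width.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.global_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  Xs <- standardize_apply(object$standardize, as.matrix(newdata))
  as.character(predict(object$fit, Xs))
}

# Fit one pipeline (pca+svm for global families, adaboost for local) on a
# training set and return a closure predicting labels for new rows.
fit_method <- function(method, X, labels, variance_threshold = 0.95,
                       rounds = 50L, seed = 1L) {
  if (method %in% c("ggf", "gtf")) {
    pca <- pca_fit(X, variance_threshold)
    clf <- svm_train(pca_transform(pca, X), labels, seed = seed)
    function(Xnew) predict(clf, pca_transform(pca, Xnew))
  } else if (method == "lf") {
    model <- adaboost_train(X, labels, rounds = rounds)
    function(Xnew) fuse_scores(model, Xnew)$label
  } else stop("unknown method: ", method, call. = FALSE)
}

#' Rank the three feature/classifier pipelines by cross-validation
#'
#' Evaluates the global geometric (PCA + SVM), global texture (PCA + SVM) and
#' fused local (AdaBoost) pipelines under one shared stratified fold plan and
#' ranks them by mean CV balanced accuracy. Within each fold the full
#' pipeline (PCA, standardization, hyperparameter search or boosting) is
#' refit on the fold's training part.
#'
#' @param features Named list with matrices `ggf`, `gtf`, `lf` (same row
#'   order).
#' @param labels Character label vector matching the rows.
#' @param k Folds for the shared plan.
#' @param seed Seed for the fold shuffle.
#' @param variance_threshold Passed to [pca_fit()].
#' @param rounds Passed to [adaboost_train()].
#' @return Data frame with one row per method (ranked, best first):
#'   `feature`, `method`, `cv_sensitivity`, `cv_specificity`,
#'   `cv_balanced_accuracy`.
#' @export
select_method <- function(features, labels, k = 10L, seed = 1L,
                          variance_threshold = 0.95, rounds = 50L) {
  stopifnot(all(c("ggf", "gtf", "lf") %in% names(features)))
  labels <- as.character(labels)
  cv <- cv_plan(labels, k = k, seed = seed)
  methods <- data.frame(
    feature = c("Global geometrical features", "Global texture features",
                "Fusion of local features"),
    method = c("PCA + SVM", "PCA + SVM", "AdaBoost"),
    key = c("ggf", "gtf", "lf"), stringsAsFactors = FALSE
  )
  out <- methods
  out$cv_sensitivity <- out$cv_specificity <- out$cv_balanced_accuracy <- NA_real_
  for (m in seq_len(nrow(methods))) {
    X <- as.matrix(features[[methods$key[m]]])
    pred_all <- rep(NA_character_, length(labels))
    for (val in cv$folds) {
      tr <- setdiff(seq_along(labels), val)
      predictor <- fit_method(methods$key[m], X[tr, , drop = FALSE],
                              labels[tr],
                              variance_threshold = variance_threshold,
                              rounds = rounds, seed = cv$seed)
      pred_all[val] <- predictor(X[val, , drop = FALSE])
    }
    pos <- labels == "case"
    out$cv_sensitivity[m] <- mean(pred_all[pos] == "case")
    out$cv_specificity[m] <- mean(pred_all[!pos] == "control")
    out$cv_balanced_accuracy[m] <-
      (out$cv_sensitivity[m] + out$cv_specificity[m]) / 2
  }
  out$key <- NULL
  out[order(-out$cv_balanced_accuracy), ]
}
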