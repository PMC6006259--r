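test_that("age matching keeps even cases with ratio-matched controls", {
  # one age group: 5 cases, 20 controls, ratio 3 -> 4 cases + 12 controls
  co <- stub_cohort(rep(c("case", "control"), c(5, 20)), rep(8, 25))
  m <- select_age_matched(co, ratio = 3, seed = 7)
  lab <- cohort_labels(m)
  expect_equal(sum(lab == "case"), 4L)
  expect_equal(sum(lab == "control"), 12L)

  # a group with no cases is dropped entirely
  co2 <- stub_cohort(rep("control", 10), rep(9, 10))
  expect_warning(m2 <- select_age_matched(co2, seed = 1), "empty")
  expect_length(m2, 0L)

  # 2 cases with only 5 controls cannot reach 1:3 -> group dropped
  co3 <- stub_cohort(rep(c("case", "control"), c(2, 5)), rep(10, 7))
  expect_warning(m3 <- select_age_matched(co3, seed = 1), "empty")
  expect_length(m3, 0L)

  # ages outside the window are excluded before matching
  co4 <- stub_cohort(rep(c("case", "control"), c(4, 12)),
                     c(3, 8, 8, 16, rep(8, 10), 3, 17))
  m4 <- select_age_matched(co4, seed = 1)
  expect_true(all(cohort_ages(m4) == 8))
  expect_equal(sum(cohort_labels(m4) == "case"), 2L)
})

test_that("age matching satisfies the split invariants on random cohorts", {
  set.seed(61)
  for (rep in 1:8) {
    n <- 60
    co <- stub_cohort(sample(c("case", "control"), n, TRUE, c(0.3, 0.7)),
                      sample(3:17, n, TRUE))
    m <- suppressWarnings(select_age_matched(co, seed = rep))
    if (length(m) == 0) next
    ages <- cohort_ages(m); lab <- cohort_labels(m)
    expect_true(all(ages >= 5 & ages <= 14))
    for (a in unique(ages)) {
      nc <- sum(lab == "case" & ages == a)
      expect_equal(nc %% 2, 0)
      expect_gt(nc, 0)
      expect_equal(sum(lab == "control" & ages == a), 3 * nc)
    }
  }
})

test_that("train/test splits halve every age-class cell", {
  co <- stub_cohort(rep(c("case", "control"), c(4, 12)), rep(9, 16))
  sp <- split_train_test(co, seed = 5)
  expect_equal(sum(cohort_labels(sp$train) == "case"), 2L)
  expect_equal(sum(cohort_labels(sp$train) == "control"), 6L)
  expect_equal(sum(cohort_labels(sp$test) == "case"), 2L)
  expect_equal(length(sp$train), length(sp$test))
  # no overlap
  expect_length(intersect(cohort_ids(sp$train), cohort_ids(sp$test)), 0L)

  # different seeds: different memberships, identical counts
  sp2 <- split_train_test(co, seed = 6)
  expect_equal(length(sp2$train), length(sp$train))
  expect_false(identical(cohort_ids(sp2$train), cohort_ids(sp$train)))

  # study-scale cohort: 32 cases + 96 controls -> 16 + 48 per side
  big <- stub_cohort(rep(rep(c("case", "control"), c(4, 12)), 8),
                     rep(5:12, each = 16))
  spb <- split_train_test(big, seed = 1)
  expect_equal(sum(cohort_labels(spb$train) == "case"), 16L)
  expect_equal(sum(cohort_labels(spb$train) == "control"), 48L)
  expect_equal(sum(cohort_labels(spb$test) == "case"), 16L)

  odd <- stub_cohort(rep(c("case", "control"), c(3, 9)), rep(7, 12))
  expect_error(split_train_test(odd, seed = 1), "odd")
})

test_that("confusion metrics reproduce the published rounding exactly", {
  mk <- function(tp, fn, tn, fp) {
    confusion_metrics(
      rep(c("case", "control", "control", "case"), c(tp, fn, tn, fp)),
      rep(c("case", "control"), c(tp + fn, tn + fp)))
  }
  expect_equal(mk(11, 5, 42, 6)$sensitivity, 68.8)
  expect_equal(mk(11, 5, 42, 6)$specificity, 87.5)
  expect_equal(mk(4, 12, 39, 9)$sensitivity, 25)
  expect_equal(mk(4, 12, 39, 9)$specificity, 81.3)
  expect_equal(mk(6, 10, 42, 6)$sensitivity, 37.5)
  expect_equal(mk(8, 0, 20, 0)$sensitivity, 100)
  expect_equal(mk(8, 0, 20, 0)$specificity, 100)

  expect_error(confusion_metrics(c("case"), c("case")), "specificity undefined")
  expect_error(confusion_metrics(c("control"), c("control")),
               "sensitivity undefined")

  # order of samples is irrelevant
  set.seed(62)
  pred <- sample(c("case", "control"), 40, TRUE)
  lab <- sample(c("case", "control"), 40, TRUE)
  o <- sample(40)
  a <- confusion_metrics(pred, lab); b <- confusion_metrics(pred[o], lab[o])
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$tp, b$tp)
})

test_that("resampling reports per-run values consistent with its summary", {
  co <- stub_cohort(rep(rep(c("case", "control"), c(2, 6)), 2),
                    rep(c(7, 9), each = 8))
  # features encode the truth; the pipeline reads them back
  feats <- matrix(ifelse(cohort_labels(co) == "case", 1, 0), ncol = 1)
  oracle <- list(train = function(X, y) NULL,
                 predict = function(model, X)
                   ifelse(X[, 1] > 0.5, "case", "control"))
  rs <- resample_evaluate(co, feats, oracle, n_runs = 6, base_seed = 3)
  expect_equal(rs$mean_sensitivity, 100)
  expect_equal(rs$sd_specificity, 0)
  expect_equal(nrow(rs$runs), 6L)
  expect_equal(mean(rs$runs$sensitivity), rs$mean_sensitivity)
  expect_equal(stats::sd(rs$runs$specificity), rs$sd_specificity)

  # a single run equals the matching one-shot split evaluation
  rs1 <- resample_evaluate(co, feats, oracle, n_runs = 1, base_seed = 11)
  sp <- split_train_test(co, seed = 12)     # base_seed + run index
  te <- match(cohort_ids(sp$test), cohort_ids(co))
  direct <- confusion_metrics(oracle$predict(NULL, feats[te, , drop = FALSE]),
                              cohort_labels(co)[te])
  expect_equal(rs1$runs$tp, direct$tp)
  expect_equal(rs1$runs$sensitivity, direct$sensitivity)
})

test_that("a label-blind pipeline scores near chance under resampling", {
  lab <- rep(rep(c("case", "control"), c(4, 12)), 2)
  co <- stub_cohort(lab, rep(c(7, 9), each = 16))
  # a label-blind rule that flags exactly half of each class as "case":
  # under random test-side sampling its expected sensitivity is 50%
  heads <- stats::ave(seq_along(lab), lab, FUN = seq_along) %% 2
  feats <- matrix(heads, ncol = 1)
  coin <- list(train = function(X, y) NULL,
               predict = function(model, X)
                 ifelse(X[, 1] == 1, "case", "control"))
  rs <- resample_evaluate(co, feats, coin, n_runs = 40, base_seed = 5)
  se <- rs$sd_sensitivity / sqrt(40)
  expect_lt(abs(rs$mean_sensitivity - 50), 3 * max(se, 5))
})

test_that("the one-sample t-test matches its closed form and printed use", {
  r <- one_sample_t(c(1, 2, 3), 2)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # a sample with mean 57.4, SD 21.9, n = 48 against 68.8
  set.seed(64)
  x <- rnorm(48)
  x <- (x - mean(x)) / stats::sd(x) * 21.9 + 57.4
  r2 <- one_sample_t(x, 68.8)
  t_manual <- (57.4 - 68.8) / (21.9 / sqrt(48))
  p_manual <- 2 * stats::pt(-abs(t_manual), 47)
  expect_equal(r2$t, t_manual, tolerance = 1e-10)
  expect_equal(r2$p, p_manual, tolerance = 1e-10)
  expect_equal(round(r2$p, 3), 0.001)

  # arbitrary sample vs the textbook formula
  y <- rexp(20, 0.3)
  r3 <- one_sample_t(y, 3)
  expect_equal(r3$t, (mean(y) - 3) / (stats::sd(y) / sqrt(20)),
               tolerance = 1e-10)
  expect_equal(r3$p, 2 * stats::pt(-abs(r3$t), 19), tolerance = 1e-10)

  expect_error(one_sample_t(rep(4, 6), 2), "degenerate")
  expect_error(one_sample_t(5, 2), "at least 2")
})

test_that("Pearson correlation matches the covariance formula and t transform", {
  set.seed(65)
  x <- rnorm(25); y <- 0.6 * x + rnorm(25, 0, 0.8)
  r <- pearson_r(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, r_manual, tolerance = 1e-12)
  t_manual <- r_manual * sqrt(23 / (1 - r_manual^2))
  expect_equal(r$p, 2 * stats::pt(-abs(t_manual), 23), tolerance = 1e-10)

  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 7)$r, -1)
  expect_error(pearson_r(x, rep(1, 25)), "degenerate")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})
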