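# Shared fixtures and independent oracles, all built in code.

template_lm <- function() landmark_set(template_landmarks())

# A quick stub sample for cohort-protocol tests (tiny image, template points).
stub_sample <- function(id, label, age) {
  cohort_sample(face_image(matrix(128, 4, 4)), template_lm(), label, age, id)
}

stub_cohort <- function(labels, ages) {
  cohort(mapply(stub_sample, sprintf("s%03d", seq_along(labels)),
                labels, ages, SIMPLIFY = FALSE))
}

# Brute-force pairwise distance oracle: explicit double loop.
pairwise_dist_oracle <- function(pts) {
  n <- nrow(pts)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out <- c(out, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
  }
  out
}

# Dense direct 2-D correlation with reflect padding: shift-and-add over the
# kernel support, no FFT anywhere.
direct_conv_reflect <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  h <- nrow(img); w <- ncol(img)
  ri <- c((ph + 1):2, 1:h, (h - 1):(h - ph))
  ci <- c((pw + 1):2, 1:w, (w - 1):(w - pw))
  pad <- img[ri, ci]
  acc <- matrix(0 + 0i, h, w)
  for (u in seq_len(kh)) {
    for (v in seq_len(kw)) {
      acc <- acc + Conj(kern[u, v]) * pad[(u):(u + h - 1), (v):(v + w - 1)]
    }
  }
  acc
}

# Draw a dark Gaussian spot (matching the generator's nevus model) onto a
# matrix; sigma = radius / sqrt(2) gives a LoG response maximum at `radius`.
plant_spot <- function(img, cx, cy, radius, depth = 90) {
  sigma <- radius / sqrt(2)
  d2 <- outer((seq_len(nrow(img)) - 1 - cy)^2,
              (seq_len(ncol(img)) - 1 - cx)^2, "+")
  img - depth * exp(-d2 / (2 * sigma^2))
}

# Exhaustive best single decision stump (unweighted error), used as the
# baseline in the boosting test.
best_single_stump_error <- function(X, y) {
  n <- length(y)
  best <- Inf
  for (j in seq_len(ncol(X))) {
    cuts <- c(sort(unique(X[, j])) - 1e-9, max(X[, j]) + 1)
    for (thr in cuts) {
      for (pol in c(-1, 1)) {
        pred <- pol * ifelse(X[, j] > thr, 1, -1)
        best <- min(best, mean(pred != y))
      }
    }
  }
  best
}
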