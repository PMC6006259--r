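# Seeded synthetic frontal "faces": schematic 640 x 640 renders with ground
# truth 68-point landmarks and planted class differences in landmark geometry
# (ocular ratio, forehead width, nasal bridge), inner-canthal oriented texture
# (epicanthus-like ridge) and dark circular blobs (nevi). Schematic stimuli
# exercise every pipeline operator without any patient imagery.

#' Synthetic cohort configuration
#'
#' Effect sizes give the planted case-minus-control differences: a shift of
#' the ocular distance ratio (dimensionless), of the forehead width and nasal
#' bridge length (pixels in the 640 frame), Poisson rates of planted nevi per
#' class, and the contrast of the epicanthal ridge element (8-bit intensity
#' units, cases only).
#'
#' @param n_cases,n_controls Cohort composition.
#' @param age_range Inclusive integer age range in years.
#' @param ocular_ratio_shift Added to the case ocular distance ratio.
#' @param forehead_shift Pixels added to the case forehead width.
#' @param nasal_shift Pixels added to the case nasal bridge length (negative
#'   values shorten it).
#' @param nevi_rate_case,nevi_rate_control Expected planted blob counts.
#' @param nevi_radius_range Planted blob radii are uniform in this range
#'   (pixels).
#' @param epicanthus_strength Ridge contrast for cases (0 disables).
#' @param landmark_jitter_sd Isotropic Gaussian jitter on every landmark.
#' @param intensity_noise_sd Gaussian pixel noise (8-bit units).
#' @param age_balance If `TRUE` (and the control:case ratio is a whole
#'   number), cases are spread over the age range in even-sized groups with
#'   ratio-matched controls at the same ages, emulating an age-matched
#'   case-control study; otherwise ages are independent uniform draws.
#' @param seed Master seed of the cohort.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cases = 32L, n_controls = 96L,
                         age_range = c(5L, 14L),
                         ocular_ratio_shift = 0.05, forehead_shift = 10,
                         nasal_shift = -8, nevi_rate_case = 4,
                         nevi_rate_control = 1, nevi_radius_range = c(4, 12),
                         epicanthus_strength = 60, landmark_jitter_sd = 2,
                         intensity_noise_sd = 4, age_balance = TRUE,
                         seed = 1L) {
  stopifnot(n_cases >= 0, n_controls >= 0, length(age_range) == 2,
            age_range[1] <= age_range[2], nevi_rate_case >= 0,
            nevi_rate_control >= 0, landmark_jitter_sd >= 0,
            intensity_noise_sd >= 0, nevi_radius_range[1] > 0,
            nevi_radius_range[2] >= nevi_radius_range[1])
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 age_range = as.integer(age_range),
                 ocular_ratio_shift = ocular_ratio_shift,
                 forehead_shift = forehead_shift, nasal_shift = nasal_shift,
                 nevi_rate_case = nevi_rate_case,
                 nevi_rate_control = nevi_rate_control,
                 nevi_radius_range = nevi_radius_range,
                 epicanthus_strength = epicanthus_strength,
                 landmark_jitter_sd = landmark_jitter_sd,
                 intensity_noise_sd = intensity_noise_sd,
                 age_balance = isTRUE(age_balance),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Canonical frontal 68-point landmark template
#'
#' A schematic frontal face layout in the 640 x 640 frame honoring the
#' region index map (outline arc, brow arcs, nasal bridge column and subnasal
#' row, eye rings, mouth ellipses).
#'
#' @return A 68 x 2 coordinate matrix (not yet a [landmark_set()]).
#' @export
template_landmarks <- function() {
  pts <- matrix(NA_real_, 68, 2)
  phi <- pi + (0:16) * pi / 16
  pts[1:17, ] <- cbind(320 + 200 * cos(phi), 280 - 220 * sin(phi))
  brow_y <- c(206, 200, 198, 200, 206)
  pts[18:22, ] <- cbind(seq(160, 280, length.out = 5), brow_y)       # 17-21
  pts[23:27, ] <- cbind(seq(360, 480, length.out = 5), rev(brow_y))  # 22-26
  pts[28:31, ] <- cbind(320, seq(250, 340, length.out = 4))          # 27-30
  pts[32:36, ] <- cbind(seq(280, 360, length.out = 5), 370)          # 31-35
  pts[37:42, ] <- cbind(c(185, 210, 240, 265, 240, 210),             # 36-41
                        c(260, 250, 250, 260, 270, 270))
  pts[43:48, ] <- cbind(c(375, 400, 430, 455, 430, 400),             # 42-47
                        c(260, 250, 250, 260, 270, 270))
  ang_out <- pi + (0:11) * 2 * pi / 12
  pts[49:60, ] <- cbind(320 + 60 * cos(ang_out), 440 - 22 * sin(ang_out))
  ang_in <- pi + (0:7) * 2 * pi / 8
  pts[61:68, ] <- cbind(320 + 35 * cos(ang_in), 440 - 9 * sin(ang_in))
  pts
}

#' Generate one synthetic landmark set
#'
#' Starts from the canonical template, scales mildly with age about the face
#' center, applies the class-dependent shifts to the ocular-ratio points
#' (39, 42 via the outer-corner distance), brow endpoints (17, 26) and nasal
#' points (30, 33), and adds isotropic Gaussian jitter.
#'
#' @param class_label `"case"` or `"control"`.
#' @param age_years Integer age.
#' @param config A [synth_config()].
#' @param rng A seeded generator from `local_rng()`; pass a fresh one per
#'   sample for reproducibility.
#' @return A [landmark_set()].
#' @export
gen_landmarks <- function(class_label, age_years, config = synth_config(),
                          rng = local_rng(config$seed)) {
  pts <- template_landmarks()
  s_age <- 0.75 + 0.02 * age_years     # mild linear growth with age
  ctr <- c(320, 320)
  pts <- sweep(sweep(pts, 2, ctr) * s_age, 2, ctr, "+")
  if (class_label == "case") {
    pts[17 + 1, 1] <- pts[17 + 1, 1] - config$forehead_shift / 2
    pts[26 + 1, 1] <- pts[26 + 1, 1] + config$forehead_shift / 2
    pts[30 + 1, 2] <- pts[30 + 1, 2] - config$nasal_shift / 2
    pts[33 + 1, 2] <- pts[33 + 1, 2] + config$nasal_shift / 2
    outer_d <- sqrt(sum((pts[36 + 1, ] - pts[45 + 1, ])^2))
    dx <- config$ocular_ratio_shift * outer_d / 2
    pts[39 + 1, 1] <- pts[39 + 1, 1] - dx
    pts[42 + 1, 1] <- pts[42 + 1, 1] + dx
  }
  if (config$landmark_jitter_sd > 0)
    pts <- pts + matrix(rng$rnorm(136, 0, config$landmark_jitter_sd), 68, 2)
  landmark_set(pmin(pmax(pts, 0), 639))
}

# Subtract a Gaussian spot of amplitude `depth` and scale sigma at (cx, cy).
subtract_spot <- function(img, cx, cy, sigma, depth) {
  half <- ceiling(3.5 * sigma)
  xs <- max(0, floor(cx - half)):min(ncol(img) - 1, ceiling(cx + half))
  ys <- max(0, floor(cy - half)):min(nrow(img) - 1, ceiling(cy + half))
  if (length(xs) == 0 || length(ys) == 0) return(img)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] - depth * exp(-d2 / (2 * sigma^2))
  img
}

fill_ellipse <- function(img, cx, cy, rx, ry, value) {
  xs <- max(0, floor(cx - rx)):min(ncol(img) - 1, ceiling(cx + rx))
  ys <- max(0, floor(cy - ry)):min(nrow(img) - 1, ceiling(cy + ry))
  inside <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, "+") <= 1
  block <- img[ys + 1, xs + 1]
  block[inside] <- value
  img[ys + 1, xs + 1] <- block
  img
}

# Dark oriented ridge through (cx, cy) at angle theta, Gaussian profile
# across the ridge, circular window of radius `win`.
subtract_ridge <- function(img, cx, cy, theta, strength, width = 1.5,
                           win = 8) {
  xs <- max(0, floor(cx - win)):min(ncol(img) - 1, ceiling(cx + win))
  ys <- max(0, floor(cy - win)):min(nrow(img) - 1, ceiling(cy + win))
  gx <- outer(rep(1, length(ys)), xs - cx)
  gy <- outer(ys - cy, rep(1, length(xs)))
  u <- -sin(theta) * gx + cos(theta) * gy   # distance across the ridge
  r2 <- gx^2 + gy^2
  mask <- exp(-u^2 / (2 * width^2)) * (r2 <= win^2)
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] - strength * mask
  img
}

#' Render a synthetic face image for one landmark set
#'
#' Draws a skin-toned face region bounded by the outline/brow polygon on a
#' dark background, dark brows, eye and mouth ellipses and a nasal line at
#' the landmark positions; plants a Poisson number of dark Gaussian blobs
#' (class rate) uniformly inside the face polygon with radii uniform in
#' `nevi_radius_range`; adds an oriented ridge at each inner eye corner for
#' cases when `epicanthus_strength > 0`; and finishes with Gaussian pixel
#' noise.
#'
#' @param landmarks A [landmark_set()].
#' @param class_label `"case"` or `"control"`.
#' @param config A [synth_config()].
#' @param rng A seeded generator from `local_rng()`.
#' @param size Canvas side length in pixels.
#' @return List with `image` (a [face_image()]) and `ground_truth` (list with
#'   the planted blob table and ridge strength).
#' @export
gen_face_image <- function(landmarks, class_label, config = synth_config(),
                           rng = local_rng(config$seed), size = 640L) {
  lm <- as_landmark_set(landmarks)
  img <- matrix(120, size, size)
  poly <- face_polygon(lm)
  g <- expand.grid(y = 0:(size - 1), x = 0:(size - 1))
  inside <- points_in_polygon(g$x, g$y, poly)
  img[matrix(c(g$y[inside] + 1, g$x[inside] + 1), ncol = 2)] <- 190
  # smooth illumination shading (random phase), as on real photographs
  ph <- rng$runif(2, 0, 2 * pi)
  shade <- 14 * outer(sin(2 * pi * (0:(size - 1)) / size + ph[1]),
                      rep(1, size)) +
    14 * outer(rep(1, size), sin(2 * pi * (0:(size - 1)) / size + ph[2]))
  img <- img + shade

  # brows: dark spots strung along the five brow points
  for (reg in c("right_brow", "left_brow")) {
    bp <- region_points(lm, reg)
    for (i in seq_len(nrow(bp) - 1)) {
      mid <- (bp[i, ] + bp[i + 1, ]) / 2
      img <- subtract_spot(img, mid[1], mid[2], 4, 70)
      img <- subtract_spot(img, bp[i, 1], bp[i, 2], 4, 70)
    }
    img <- subtract_spot(img, bp[5, 1], bp[5, 2], 4, 70)
  }
  # eyes: dark ellipses over each eye ring
  for (reg in c("right_eye", "left_eye")) {
    ep <- region_points(lm, reg)
    img <- fill_ellipse(img, mean(range(ep[, 1])), mean(range(ep[, 2])),
                        diff(range(ep[, 1])) / 2, diff(range(ep[, 2])) / 2, 55)
  }
  # nasal bridge line and nostrils
  nb <- landmark_points(lm, 27:30)
  for (i in seq_len(nrow(nb))) img <- subtract_spot(img, nb[i, 1], nb[i, 2], 2.2, 35)
  sn <- landmark_points(lm, c(31, 35))
  for (i in 1:2) img <- subtract_spot(img, sn[i, 1], sn[i, 2], 2, 60)
  # mouth
  mp <- region_points(lm, "mouth")
  img <- fill_ellipse(img, mean(range(mp[, 1])), mean(range(mp[, 2])),
                      diff(range(mp[, 1])) / 2, diff(range(mp[, 2])) / 2, 95)

  # planted nevi
  rate <- if (class_label == "case") config$nevi_rate_case else config$nevi_rate_control
  n_blobs <- if (rate > 0) rng$rpois(1, rate) else 0L
  blob_tab <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
  if (n_blobs > 0) {
    bb <- c(range(poly[, 1]), range(poly[, 2]))
    boxes <- organ_boxes(lm)
    got <- 0L; tries <- 0L
    while (got < n_blobs && tries < 500L * n_blobs) {
      tries <- tries + 1L
      cx <- rng$runif(1, bb[1], bb[2]); cy <- rng$runif(1, bb[3], bb[4])
      r <- rng$runif(1, config$nevi_radius_range[1], config$nevi_radius_range[2])
      # skin placement only: clear of the organ boxes and the face boundary
      grown <- boxes + matrix(c(-r, r, -r, r), nrow(boxes), 4, byrow = TRUE)
      if (in_any_box(cx, cy, grown)) next
      if (!points_in_polygon(cx, cy, poly)) next
      if (polygon_edge_distance(cx, cy, poly) < r + 2) next
      blob_tab <- rbind(blob_tab, data.frame(x = cx, y = cy, radius = r))
      img <- subtract_spot(img, cx, cy, r / sqrt(2), 90)
      got <- got + 1L
    }
  }
  # epicanthal ridge at the inner canthi (cases)
  if (class_label == "case" && config$epicanthus_strength > 0) {
    ic <- landmark_points(lm, c(39, 42))
    img <- subtract_ridge(img, ic[1, 1], ic[1, 2], pi / 4,
                          config$epicanthus_strength)
    img <- subtract_ridge(img, ic[2, 1], ic[2, 2], 3 * pi / 4,
                          config$epicanthus_strength)
  }
  if (config$intensity_noise_sd > 0)
    img <- img + matrix(rng$rnorm(size * size, 0, config$intensity_noise_sd),
                        size, size)
  list(image = face_image(pmin(pmax(img, 0), 255)),
       ground_truth = list(blobs = blob_tab,
                           epicanthus_strength =
                             if (class_label == "case") config$epicanthus_strength else 0))
}

#' Generate a full synthetic cohort with ground truth
#'
#' Ages are uniform integers over `age_range`. One master generator (seeded
#' by `config$seed`) draws ages and one sub-seed per sample; each sample is
#' then generated from its own sub-stream, so cohorts are reproducible and
#' earlier samples do not depend on how many follow them.
#'
#' @param config A [synth_config()].
#' @return List with `cohort` (a [cohort()]) and `ground_truth` (named list
#'   per subject: planted ocular ratio, blob table, ridge strength).
#' @export
gen_cohort <- function(config = synth_config()) {
  n <- config$n_cases + config$n_controls
  labels <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  ids <- sprintf("%s_%03d", ifelse(labels == "case", "case", "ctrl"),
                 c(seq_len(config$n_cases), seq_len(config$n_controls)))
  master <- local_rng(config$seed)
  if (n == 0) return(list(cohort = cohort(list()), ground_truth = list()))
  ages <- cohort_ages_draw(config, master)
  sub_seeds <- master$sample_n(.Machine$integer.max - 1L, n)
  samples <- vector("list", n)
  gt <- vector("list", n)
  for (i in seq_len(n)) {
    rng <- local_rng(sub_seeds[i])
    lm <- gen_landmarks(labels[i], ages[i], config, rng)
    rendered <- gen_face_image(lm, labels[i], config, rng)
    samples[[i]] <- cohort_sample(rendered$image, lm, labels[i], ages[i], ids[i])
    gt[[i]] <- c(list(label = labels[i], age_years = ages[i],
                      ocular_ratio = lf_ocular_ratio(lm)),
                 rendered$ground_truth)
  }
  names(gt) <- ids
  list(cohort = cohort(samples), ground_truth = gt)
}

# Age assignment for a synthetic cohort. Balanced mode lays case ages out in
# pairs cycling over a shuffled age range (so per-age case counts stay even)
# and gives each case's age group its ratio of controls; leftover controls
# get uniform ages. Falls back to independent uniform draws when the ratio
# is not a whole number.
cohort_ages_draw <- function(config, master) {
  ages_avail <- config$age_range[1]:config$age_range[2]
  n_cases <- config$n_cases; n_controls <- config$n_controls
  ratio <- if (n_cases > 0) n_controls / n_cases else NA_real_
  if (!config$age_balance || n_cases == 0 || !isTRUE(ratio == round(ratio))) {
    return(master$rint(n_cases + n_controls, config$age_range[1],
                       config$age_range[2]))
  }
  shuffled <- ages_avail[master$sample_perm(length(ages_avail))]
  pair_ages <- rep_len(shuffled, ceiling(n_cases / 2))
  case_ages <- rep(pair_ages, each = 2)[seq_len(n_cases)]
  control_ages <- rep(case_ages, ratio)
  extra <- n_controls - length(control_ages)
  if (extra > 0)
    control_ages <- c(control_ages,
                      master$rint(extra, config$age_range[1],
                                  config$age_range[2]))
  c(case_ages, control_ages[seq_len(n_controls)])
}
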