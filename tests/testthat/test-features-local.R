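set_points <- function(numbers, coords) {
  pts <- template_landmarks()
  pts[numbers + 1, ] <- coords
  landmark_set(pts)
}

test_that("the three geometric local features follow their point pairs", {
  expect_equal(lf_forehead(set_points(c(17, 26),
                                      rbind(c(100, 150), c(400, 150)))), 300)
  expect_equal(lf_forehead(set_points(c(17, 26),
                                      rbind(c(250, 200), c(250, 200)))), 0)
  expect_equal(lf_forehead(set_points(c(17, 26), rbind(c(0, 0), c(3, 4)))), 5)

  expect_equal(lf_nasal_bridge(set_points(c(30, 33),
                                          rbind(c(320, 300), c(320, 360)))), 60)
  expect_equal(lf_nasal_bridge(set_points(c(30, 33),
                                          rbind(c(1, 2), c(4, 6)))), 5)

  expect_equal(lf_ocular_ratio(set_points(c(39, 42, 36, 45),
                                          rbind(c(275, 260), c(325, 260),
                                                c(250, 260), c(350, 260)))),
               0.5)
  expect_equal(lf_ocular_ratio(set_points(c(39, 42, 36, 45),
                                          rbind(c(300, 260), c(340, 260),
                                                c(240, 260), c(400, 260)))),
               0.25)
  # random corner placement vs direct arithmetic
  set.seed(41)
  p <- matrix(runif(8, 100, 500), 4, 2)
  lm <- set_points(c(39, 42, 36, 45), p)
  manual <- sqrt(sum((p[1, ] - p[2, ])^2)) / sqrt(sum((p[3, ] - p[4, ])^2))
  expect_equal(lf_ocular_ratio(lm), manual, tolerance = 1e-12)
})

test_that("the ocular ratio is invariant under rigid motion and scaling", {
  set.seed(42)
  pts <- template_landmarks() + matrix(rnorm(136, 0, 3), 68, 2)
  pts <- pmax(pts, 1)
  base <- lf_ocular_ratio(landmark_set(pts))
  th <- 0.4
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  moved <- sweep(pts %*% t(R), 2, c(40, 200), "+")
  moved <- sweep(moved, 2, pmin(0, apply(moved, 2, min)) - 0)  # keep >= 0
  expect_equal(lf_ocular_ratio(landmark_set(pmax(moved, 0))), base,
               tolerance = 1e-9)
  expect_equal(lf_ocular_ratio(landmark_set(pts * 1.7)), base,
               tolerance = 1e-12)
})

test_that("epicanthus energies have bank length and respond to orientation", {
  zeroes <- face_image(matrix(0, 32, 64))
  v <- lf_epicanthus(zeroes, zeroes)
  expect_length(v, 80L)
  expect_true(all(v == 0))

  # a dark ridge extending along psi concentrates scale-summed energy in the
  # channel whose carrier is perpendicular to it (theta = psi + 90 degrees)
  cfg <- gabor_bank_config()
  xs <- outer(rep(1, 32), 0:63); ys <- outer(0:31, rep(1, 64))
  for (k_or in c(3, 5)) {
    psi <- (k_or - 1) * pi / 8
    u <- -sin(psi) * (xs - 32) + cos(psi) * (ys - 16)
    ridge <- face_image(pmax(150 - 120 * exp(-u^2 / (2 * 1.5^2)), 0))
    v <- lf_epicanthus(ridge, zeroes, cfg)
    per_orient <- rowsum(v[1:40], rep(1:8, 5))   # scale-summed, right eye
    expect_equal(which.max(per_orient), ((k_or - 1 + 4) %% 8) + 1)
  }

  expect_error(lf_epicanthus(zeroes, face_image(matrix(0, 16, 16))),
               "share one size")
})

test_that("planted dark spots are detected at the right scale", {
  img <- matrix(200, 300, 300)
  sp <- rbind(c(80, 60, 4 * sqrt(2)), c(200, 150, 10), c(120, 240, 5))
  for (i in 1:3) img <- plant_spot(img, sp[i, 1], sp[i, 2], sp[i, 3])
  blobs <- detect_blobs(face_image(pmax(img, 0)))
  expect_equal(nrow(blobs), 3L)
  for (i in 1:3) {
    d <- sqrt((blobs$x - sp[i, 1])^2 + (blobs$y - sp[i, 2])^2)
    j <- which.min(d)
    expect_lt(d[j], 3)
    expect_lt(abs(blobs$radius[j] - sp[i, 3]) / sp[i, 3], 0.3)
  }
})

test_that("blank images yield no blobs and zero nevi vectors", {
  expect_equal(nrow(detect_blobs(face_image(matrix(180, 200, 200)))), 0L)
  v <- lf_nevi(face_image(matrix(180, 640, 640)), template_lm())
  expect_equal(unname(v), c(0, 0, 0, 0))
})

test_that("nevus counting respects the face-outline mask", {
  lm <- template_lm()
  img <- matrix(185, 640, 640)
  # spots far outside the outline polygon (image corners)
  img <- plant_spot(img, 40, 40, 8)
  img <- plant_spot(img, 600, 610, 8)
  v_out <- lf_nevi(face_image(pmax(img, 0)), lm)
  expect_equal(unname(v_out["count"]), 0)

  # the same spots inside the cheeks are counted with sane sizes
  img2 <- matrix(185, 640, 640)
  img2 <- plant_spot(img2, 250, 400, 8)
  img2 <- plant_spot(img2, 400, 340, 6)
  v_in <- lf_nevi(face_image(pmax(img2, 0)), lm)
  expect_equal(unname(v_in["count"]), 2)
  expect_gt(v_in["max_radius"], 6 * 0.7)
  expect_equal(unname(v_in["total_area"]),
               sum(pi * c(8, 6)^2), tolerance = 0.6 * sum(pi * c(8, 6)^2))
})

test_that("blob counts are monotone as the response threshold drops", {
  set.seed(44)
  img <- matrix(200, 300, 300)
  for (i in 1:5)
    img <- plant_spot(img, runif(1, 40, 260), runif(1, 40, 260),
                      runif(1, 4, 10), depth = runif(1, 30, 90))
  img <- face_image(pmin(pmax(img, 0), 255))
  counts <- vapply(c(0.15, 0.08, 0.04, 0.01), function(thr) {
    nrow(detect_blobs(img, blob_detect_config(response_threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the fused local vector keeps the fixed order and width", {
  skin <- face_image(matrix(185, 640, 640))
  lf <- local_features(skin, template_lm())
  v <- lf$vector
  expect_length(v, 87L)
  expect_equal(names(v)[1:5],
               c("lf_forehead", "lf_nevi_count", "lf_nevi_mean_r",
                 "lf_nevi_max_r", "lf_nevi_area"))
  expect_equal(names(v)[86:87], c("lf_nasal", "lf_ocular"))
  expect_equal(unname(v["lf_forehead"]), lf_forehead(template_lm()))
})
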