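# The five local dysmorphology features: forehead width, nasal bridge length,
# ocular distance ratio (landmark geometry), epicanthus texture energy (Gabor
# bank over the eye patches, no block partition), and multiple facial nevi
# (scale-normalized Laplacian-of-Gaussian blob detection inside the face
# outline).

dist2 <- function(a, b) sqrt(sum((a - b)^2))

#' Local geometric features from the landmark model
#'
#' `lf_forehead()` is the Euclidean distance between the outer brow endpoints
#' (point numbers 17 and 26); `lf_nasal_bridge()` the distance between nose
#' tip and subnasal center (points 30 and 33); `lf_ocular_ratio()` the
#' inner-canthal over outer-canthal distance, d(39,42) / d(36,45) — larger
#' values suggest hypertelorism or epicanthal folds.
#'
#' @param landmarks A [landmark_set()].
#' @return A single non-negative number (pixels for the distances, a
#'   dimensionless ratio for `lf_ocular_ratio`).
#' @export
lf_forehead <- function(landmarks) {
  p <- landmark_points(landmarks, c(17, 26))
  dist2(p[1, ], p[2, ])
}

#' @rdname lf_forehead
#' @export
lf_nasal_bridge <- function(landmarks) {
  p <- landmark_points(landmarks, c(30, 33))
  dist2(p[1, ], p[2, ])
}

#' @rdname lf_forehead
#' @export
lf_ocular_ratio <- function(landmarks) {
  p <- landmark_points(landmarks, c(39, 42, 36, 45))
  outer_d <- dist2(p[3, ], p[4, ])
  if (outer_d < 1e-9)
    stop("degenerate geometry: outer eye corners coincide", call. = FALSE)
  dist2(p[1, ], p[2, ]) / outer_d
}

#' Epicanthus texture energy over the eye patches
#'
#' Applies the Gabor bank to each fixed-size eye patch without any block
#' partition and records the total squared-magnitude response per filter;
#' right-eye energies first, then left. Oriented structure at the inner eye
#' corner (an epicanthal fold) concentrates energy in the matching
#' orientation channels.
#'
#' @param eye_patch_right,eye_patch_left Patches from [segment_eye_region()],
#'   both of identical size.
#' @param config A [gabor_bank_config()].
#' @return Numeric vector of length `2 * n_scales * n_orientations`.
#' @export
lf_epicanthus <- function(eye_patch_right, eye_patch_left,
                          config = gabor_bank_config()) {
  r <- if (inherits(eye_patch_right, "face_image")) unclass(eye_patch_right) else as.matrix(eye_patch_right)
  l <- if (inherits(eye_patch_left, "face_image")) unclass(eye_patch_left) else as.matrix(eye_patch_left)
  if (!identical(dim(r), dim(l)))
    stop("eye patches must share one size", call. = FALSE)
  bank <- lapply(build_gabor_bank(config), shrink_kernel, d = dim(r))
  energy <- function(img) vapply(conv2_multi(img, bank),
                                 function(resp) sum(Mod(resp)^2), numeric(1))
  c(energy(r), energy(l))
}

# Truncate a kernel symmetrically so its support fits reflect padding of a
# small patch (support must stay below the patch size).
shrink_kernel <- function(kern, d) {
  kh <- nrow(kern); kw <- ncol(kern)
  mh <- 2 * (ceiling(d[1] / 2) - 1) + 1  # largest odd size < d, >= 1
  mw <- 2 * (ceiling(d[2] / 2) - 1) + 1
  if (kh <= mh && kw <= mw) return(kern)
  ch <- (kh + 1) / 2; cw <- (kw + 1) / 2
  hh <- (min(kh, mh) - 1) / 2; hw <- (min(kw, mw) - 1) / 2
  out <- kern[(ch - hh):(ch + hh), (cw - hw):(cw + hw), drop = FALSE]
  key <- attr(kern, "cache_key")
  if (!is.null(key))
    attr(out, "cache_key") <- sprintf("%s|shrunk%dx%d", key, 2 * hh + 1, 2 * hw + 1)
  out
}

#' Blob-detection configuration for nevus counting
#'
#' @param min_radius,max_radius Radius range of detectable blobs, pixels in
#'   the normalized 640 frame.
#' @param n_scales Number of logarithmically spaced detection scales.
#' @param response_threshold Minimum scale-normalized response (image
#'   intensities taken in `[0, 1]`).
#' @param overlap_threshold Blobs overlapping a stronger detection by more
#'   than this fraction (of the smaller blob's area) are pruned.
#' @return A `blob_detect_config` list.
#' @export
blob_detect_config <- function(min_radius = 3, max_radius = 25, n_scales = 10L,
                               response_threshold = 0.05,
                               overlap_threshold = 0.5) {
  stopifnot(min_radius > 0, max_radius > min_radius, n_scales >= 1,
            response_threshold >= 0,
            overlap_threshold > 0, overlap_threshold <= 1)
  structure(list(min_radius = min_radius, max_radius = max_radius,
                 n_scales = as.integer(n_scales),
                 response_threshold = response_threshold,
                 overlap_threshold = overlap_threshold),
            class = "blob_detect_config")
}

# Scale-normalized LoG kernel (sigma^2 * Laplacian of Gaussian). Positive
# response peak for a dark blob on a light background.
log_kernel <- function(sigma) {
  half <- max(ceiling(3 * sigma), 2L)
  ax <- -half:half
  ones <- rep(1, length(ax))
  r2 <- outer(ax^2, ones) + outer(ones, ax^2)
  g <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  structure(sigma^2 * (r2 / sigma^4 - 2 / sigma^2) * g,  # +LoG: dark blobs
            cache_key = sprintf("log|%.10g", sigma))
}

#' Detect dark circular blobs by multi-scale Laplacian of Gaussian
#'
#' Filters the image (rescaled to `[0, 1]`) with scale-normalized LoG kernels
#' at logarithmically spaced sigmas, keeps local maxima over the 3 x 3 x 3
#' space-scale neighborhood above the response threshold, and prunes weaker
#' overlapping detections. Blob radius is `sqrt(2) * sigma` of the maximizing
#' scale.
#'
#' @param image A [face_image()] or numeric matrix (8-bit intensities).
#' @param config A [blob_detect_config()].
#' @return Data frame with columns `x`, `y` (0-based center), `radius`
#'   (pixels) and `response`, strongest first; zero rows when nothing is found.
#' @export
detect_blobs <- function(image, config = blob_detect_config()) {
  img <- if (inherits(image, "face_image")) unclass(image) else as.matrix(image)
  img <- img / 255
  sigmas <- exp(seq(log(config$min_radius / sqrt(2)),
                    log(config$max_radius / sqrt(2)),
                    length.out = config$n_scales))
  h <- nrow(img); w <- ncol(img)
  kerns <- lapply(sigmas, log_kernel)
  for (kern in kerns)
    if (nrow(kern) >= 2 * h || ncol(kern) >= 2 * w)
      stop("blob scale too large for image", call. = FALSE)
  # pack pairs of real kernels into one complex kernel: one inverse FFT
  # yields both responses (real part first kernel, -imaginary part second)
  n_s <- length(sigmas)
  pairs <- split(seq_len(n_s), ceiling(seq_len(n_s) / 2))
  packed <- lapply(pairs, function(ix) {
    if (length(ix) == 1L) return(kerns[[ix]])
    k1 <- kerns[[ix[1]]]; k2 <- kerns[[ix[2]]]
    d1 <- dim(k1); d2 <- dim(k2)
    big <- matrix(0, max(d1[1], d2[1]), max(d1[2], d2[2]))
    center_into <- function(big, k) {
      r0 <- (nrow(big) - nrow(k)) / 2; c0 <- (ncol(big) - ncol(k)) / 2
      big[r0 + seq_len(nrow(k)), c0 + seq_len(ncol(k))] <-
        big[r0 + seq_len(nrow(k)), c0 + seq_len(ncol(k))] + k
      big
    }
    structure(center_into(big, k1) + 1i * center_into(big, k2),
              cache_key = paste(attr(k1, "cache_key"),
                                attr(k2, "cache_key"), sep = "+"))
  })
  resp <- conv2_multi(img, packed)
  slices <- vector("list", n_s)
  for (p in seq_along(pairs)) {
    ix <- pairs[[p]]
    slices[[ix[1]]] <- Re(resp[[p]])
    if (length(ix) == 2L) slices[[ix[2]]] <- -Im(resp[[p]])
  }
  peaks <- local_maxima_3d(slices, config$response_threshold)
  if (nrow(peaks) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                      response = numeric(0)))
  blobs <- data.frame(x = peaks[, "col"] - 1, y = peaks[, "row"] - 1,
                      radius = sqrt(2) * sigmas[peaks[, "scale"]],
                      response = peaks[, "value"])
  blobs <- blobs[order(-blobs$response), , drop = FALSE]
  keep <- prune_overlaps(blobs, config$overlap_threshold)
  rownames(blobs) <- NULL
  blobs[keep, , drop = FALSE]
}

# Strict local maxima over the 3x3x3 space-scale neighborhood of a list of
# per-scale response matrices. Only pixels at or above the threshold are
# examined, which keeps the scan cheap on mostly flat responses.
local_maxima_3d <- function(slices, threshold) {
  nr <- nrow(slices[[1]]); nc <- ncol(slices[[1]]); ns <- length(slices)
  res <- NULL
  for (k in seq_len(ns)) {
    sl <- slices[[k]]
    cand <- which(sl >= threshold, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    v <- sl[cand]
    keep <- rep(TRUE, nrow(cand))
    for (dk in -1:1) {
      kk <- k + dk
      if (kk < 1 || kk > ns) next
      nb_sl <- slices[[kk]]
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0 && dk == 0) next
        rr <- cand[, 1] + dy; cc <- cand[, 2] + dx
        ok <- keep & rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        if (!any(ok)) next
        keep[ok] <- v[ok] > nb_sl[rr[ok] + (cc[ok] - 1) * nr]
      }
    }
    if (any(keep))
      res <- rbind(res, cbind(row = cand[keep, 1], col = cand[keep, 2],
                              scale = k, value = v[keep]))
  }
  if (is.null(res)) matrix(numeric(0), 0, 4,
                           dimnames = list(NULL, c("row", "col", "scale", "value")))
  else res
}

# Greedy overlap pruning: blobs ordered strongest first; drop a blob whose
# circle overlaps an already kept one by more than `threshold` of the smaller
# circle's area.
prune_overlaps <- function(blobs, threshold) {
  n <- nrow(blobs)
  keep <- logical(n)
  for (i in seq_len(n)) {
    kept <- which(keep)
    keep[i] <- length(kept) == 0L ||
      all(circle_overlap(blobs$x[i], blobs$y[i], blobs$radius[i],
                         blobs$x[kept], blobs$y[kept],
                         blobs$radius[kept]) <= threshold)
  }
  keep
}

# Intersection area of circle 1 with each of circles 2 (vectorized), as a
# fraction of the smaller circle's area.
circle_overlap <- function(x1, y1, r1, x2, y2, r2) {
  d <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  r_small <- pmin(r1, r2); r_big <- pmax(r1, r2)
  out <- numeric(length(d))
  partial <- d < r1 + r2 & d > r_big - r_small
  out[d <= r_big - r_small] <- 1
  if (any(partial)) {
    dd <- d[partial]; rr2 <- rep_len(r2, length(d))[partial]
    a1 <- r1^2 * acos(pmin(pmax((dd^2 + r1^2 - rr2^2) / (2 * dd * r1), -1), 1))
    a2 <- rr2^2 * acos(pmin(pmax((dd^2 + rr2^2 - r1^2) / (2 * dd * rr2), -1), 1))
    a3 <- 0.5 * sqrt(pmax((-dd + r1 + rr2) * (dd + r1 - rr2) *
                            (dd - r1 + rr2) * (dd + r1 + rr2), 0))
    out[partial] <- (a1 + a2 - a3) / (pi * pmin(r1, rr2)^2)
  }
  out
}

# Clamp a 0-based [lo, hi] range to [0, n - 1] and grow it to a multiple of
# 32 pixels where room allows, so repeated detections on equally sized frames
# share FFT plans and cached kernel transforms.
snap_range <- function(lo, hi, n) {
  lo <- max(lo, 0); hi <- min(hi, n - 1)
  want <- min(32 * ceiling((hi - lo + 1) / 32), n)
  hi <- min(lo + want - 1, n - 1)
  lo <- max(hi - want + 1, 0)
  c(lo, hi)
}

# Face-region polygon: outline 0-16 (right jaw to left jaw) closed back over
# the brows (left brow 26..22, right brow 21..17).
face_polygon <- function(landmarks) {
  rbind(region_points(landmarks, "outline"),
        region_points(landmarks, "left_brow")[5:1, ],
        region_points(landmarks, "right_brow")[5:1, ])
}

# Bounding boxes (x0, x1, y0, y1) of the facial organs -- eye+brow pairs,
# nose, mouth -- expanded by `margin` of each box dimension (at least
# `min_pad` px). Nevus detection excludes these: a dark iris, brow or
# nostril is a blob but not a nevus.
organ_boxes <- function(landmarks, margin = 0.3, min_pad = 6) {
  groups <- list(c("right_eye", "right_brow"), c("left_eye", "left_brow"),
                 "nose", "mouth")
  t(vapply(groups, function(regs) {
    pts <- do.call(rbind, lapply(regs, region_points, landmarks = landmarks))
    px <- max(margin * diff(range(pts[, 1])), min_pad)
    py <- max(margin * diff(range(pts[, 2])), min_pad)
    c(min(pts[, 1]) - px, max(pts[, 1]) + px,
      min(pts[, 2]) - py, max(pts[, 2]) + py)
  }, numeric(4)))
}

in_any_box <- function(x, y, boxes) {
  hit <- logical(length(x))
  for (b in seq_len(nrow(boxes)))
    hit <- hit | (x >= boxes[b, 1] & x <= boxes[b, 2] &
                    y >= boxes[b, 3] & y <= boxes[b, 4])
  hit
}

# Minimum distance from each point to the boundary of a closed polygon.
polygon_edge_distance <- function(px, py, poly) {
  n <- nrow(poly)
  dmin <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 < 1e-12) rep(0, length(px))
         else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / len2, 0), 1)
    dmin <- pmin(dmin, sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2))
    j <- i
  }
  dmin
}

#' Multiple facial nevi feature via blob detection
#'
#' Runs dark-blob detection restricted to the face-outline polygon (outline
#' points closed over the brow line) and merges the detections into a fixed
#' length-4 vector: count, mean radius, max radius, and total blob area
#' (pixels squared). All zeros when no blob is found. Detections centered in
#' the facial-organ boxes (eyes with brows, nose, mouth) or closer to the
#' face boundary than 80% of their radius are discarded: irises, brows,
#' nostrils and boundary-curvature responses are blobs but not nevi.
#'
#' @param face A preprocessed [face_image()] (normalized and equalized).
#' @param landmarks The matching [landmark_set()].
#' @param config A [blob_detect_config()].
#' @return Named numeric vector `c(count, mean_radius, max_radius, total_area)`.
#' @export
lf_nevi <- function(face, landmarks, config = blob_detect_config()) {
  img <- unclass(as_face_image(face))
  poly <- face_polygon(landmarks)
  # restrict the filtering to the polygon's bounding box plus kernel support
  margin <- ceiling(3 * config$max_radius / sqrt(2)) + 1
  xr <- snap_range(floor(min(poly[, 1])) - margin,
                   ceiling(max(poly[, 1])) + margin, ncol(img))
  yr <- snap_range(floor(min(poly[, 2])) - margin,
                   ceiling(max(poly[, 2])) + margin, nrow(img))
  x0 <- xr[1]; y0 <- yr[1]
  sub <- img[(yr[1] + 1):(yr[2] + 1), (xr[1] + 1):(xr[2] + 1), drop = FALSE]
  blobs <- detect_blobs(sub, config)
  if (nrow(blobs) > 0) {
    blobs$x <- blobs$x + x0
    blobs$y <- blobs$y + y0
    ok <- points_in_polygon(blobs$x, blobs$y, poly) &
      !in_any_box(blobs$x, blobs$y, organ_boxes(landmarks)) &
      polygon_edge_distance(blobs$x, blobs$y, poly) >= 0.8 * blobs$radius
    blobs <- blobs[ok, , drop = FALSE]
  }
  if (nrow(blobs) == 0L)
    return(c(count = 0, mean_radius = 0, max_radius = 0, total_area = 0))
  c(count = nrow(blobs), mean_radius = mean(blobs$radius),
    max_radius = max(blobs$radius), total_area = sum(pi * blobs$radius^2))
}

#' Assemble the five local features for one subject
#'
#' Computes V_L1..V_L5 from a preprocessed sample and returns them as a named
#' list plus the fixed-order fused vector used by the AdaBoost classifier
#' (forehead, nevi, epicanthus, nasal bridge, ocular ratio).
#'
#' @param face A normalized, equalized [face_image()].
#' @param landmarks The matching [landmark_set()].
#' @param gabor A [gabor_bank_config()].
#' @param blob A [blob_detect_config()].
#' @param prep A [preprocess_config()].
#' @return List with elements `forehead`, `nasal_bridge`, `ocular_ratio`,
#'   `epicanthus`, `nevi`, and `vector` (the fused numeric vector).
#' @export
local_features <- function(face, landmarks, gabor = gabor_bank_config(),
                           blob = blob_detect_config(),
                           prep = preprocess_config()) {
  pr <- segment_eye_region(face, landmarks, "right", prep)
  pl <- segment_eye_region(face, landmarks, "left", prep)
  lf <- list(
    forehead = lf_forehead(landmarks),
    nasal_bridge = lf_nasal_bridge(landmarks),
    ocular_ratio = lf_ocular_ratio(landmarks),
    epicanthus = lf_epicanthus(pr, pl, gabor),
    nevi = lf_nevi(face, landmarks, blob)
  )
  lf$vector <- local_feature_vector(lf)
  lf
}

#' Fixed-order fused local feature vector
#'
#' Concatenates the five local features in the order forehead, nevi,
#' epicanthus, nasal bridge, ocular ratio, with stable column names.
#'
#' @param lf A list as returned by [local_features()].
#' @return Named numeric vector.
#' @export
local_feature_vector <- function(lf) {
  epi <- lf$epicanthus
  names(epi) <- sprintf("lf_epi_%02d", seq_along(epi) - 1)
  c(lf_forehead = lf$forehead,
    lf_nevi_count = unname(lf$nevi["count"]),
    lf_nevi_mean_r = unname(lf$nevi["mean_radius"]),
    lf_nevi_max_r = unname(lf$nevi["max_radius"]),
    lf_nevi_area = unname(lf$nevi["total_area"]),
    epi,
    lf_nasal = lf$nasal_bridge,
    lf_ocular = lf$ocular_ratio)
}
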