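# Preprocessing: geometric normalization into a fixed 640 x 640 frame,
# landmark-driven face-area interception, histogram equalization, and
# eye-region segmentation for the epicanthus texture feature.

#' Preprocessing configuration
#'
#' @param target_size Side length in pixels of the normalized square frame.
#' @param texture_crop_size Side length of the face crop used for global
#'   texture features.
#' @param eye_patch_margin Fractional margin added on every side of the
#'   eye-ring bounding box before resampling.
#' @param eye_patch_size Height and width in pixels of the resampled eye patch.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = 640L, texture_crop_size = 128L,
                              eye_patch_margin = 0.2,
                              eye_patch_size = c(32L, 64L)) {
  stopifnot(target_size > 0, texture_crop_size > 0,
            eye_patch_margin >= 0, eye_patch_margin < 1,
            length(eye_patch_size) == 2, all(eye_patch_size > 0))
  structure(list(target_size = as.integer(target_size),
                 texture_crop_size = as.integer(texture_crop_size),
                 eye_patch_margin = eye_patch_margin,
                 eye_patch_size = as.integer(eye_patch_size)),
            class = "preprocess_config")
}

# Similarity transform bringing the inter-eye segment horizontal and the
# input frame into the target square: rotate by -theta about the eye midpoint,
# scale by target/max(W, H), center the scaled frame. Returns the forward map
# p' = s R (p - m) + s m + t and its pieces.
eye_alignment_transform <- function(width, height, landmarks, target) {
  ec <- eye_centers(landmarks)
  d <- ec$left - ec$right
  if (sqrt(sum(d^2)) < 1e-9)
    stop("degenerate geometry: coincident eye centers", call. = FALSE)
  theta <- atan2(d[2], d[1])
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
              2, 2, byrow = TRUE)  # rotation by -theta
  s <- target / max(width, height)
  t <- c((target - s * width) / 2, (target - s * height) / 2)
  list(R = R, s = s, t = t, m = (ec$left + ec$right) / 2)
}

.grid_cache <- new.env(parent = emptyenv())

# Column-major grid of 0-based (x, y) output pixel centers, cached per size.
output_grid <- function(n) {
  key <- as.character(n)
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    g <- cbind(rep(0:(n - 1), each = n), rep(0:(n - 1), n))
    .grid_cache[[key]] <- g
  }
  g
}

apply_similarity <- function(pts, tr) {
  centered <- sweep(pts, 2, tr$m)
  rot <- centered %*% t(tr$R)
  sweep(tr$s * sweep(rot, 2, tr$m, "+"), 2, tr$t, "+")
}

#' Geometric normalization of an image and its landmarks
#'
#' Rotates about the midpoint of the two eye centers so the inter-eye segment
#' is horizontal (right eye on the image left), rescales isotropically so the
#' input frame fits the target square, and pads with black. Landmarks receive
#' the identical similarity transform. Bilinear interpolation.
#'
#' @param image A [face_image()].
#' @param landmarks A [landmark_set()] in the same coordinate frame.
#' @param config A [preprocess_config()].
#' @return List with elements `image` (target_size square [face_image()]) and
#'   `landmarks` (transformed [landmark_set()]).
#' @export
normalize_geometry <- function(image, landmarks, config = preprocess_config()) {
  image <- as_face_image(image)
  landmarks <- as_landmark_set(landmarks)
  n <- config$target_size
  tr <- eye_alignment_transform(ncol(image), nrow(image), landmarks, n)
  # inverse map output pixel centers into the input frame
  q <- output_grid(n)
  unscaled <- sweep(sweep(q, 2, tr$t) / tr$s, 2, tr$m)
  src <- sweep(unscaled %*% tr$R, 2, tr$m, "+")  # R is orthonormal: t(R^-1)=R
  vals <- bilinear_sample(unclass(image), src[, 1], src[, 2], fill = 0)
  out <- face_image(matrix(pmin(pmax(vals, 0), 255), n, n),
                    c(applied_steps(image), "geometric_normalization"))
  new_lm <- apply_similarity(unclass(landmarks), tr)
  list(image = out, landmarks = landmark_set(pmax(new_lm, 0)))
}

#' Face-area interception from landmarks
#'
#' Crops the axis-aligned bounding box of the face outline (points 0-16)
#' extended to include the brows (17-26), grown by a fractional margin on each
#' side and clamped to the frame.
#'
#' @param image A geometrically normalized [face_image()].
#' @param landmarks The matching [landmark_set()].
#' @param margin Fraction of the box width/height added per side.
#' @return A [face_image()] crop carrying an `origin` attribute with the 0-based
#'   (x, y) of its top-left pixel in the input frame.
#' @export
crop_face_region <- function(image, landmarks, margin = 0.1) {
  image <- as_face_image(image)
  pts <- rbind(region_points(landmarks, "outline"),
               region_points(landmarks, "right_brow"),
               region_points(landmarks, "left_brow"))
  x0 <- min(pts[, 1]); x1 <- max(pts[, 1])
  y0 <- min(pts[, 2]); y1 <- max(pts[, 2])
  bw <- x1 - x0; bh <- y1 - y0
  x0 <- max(floor(x0 - margin * bw), 0)
  x1 <- min(ceiling(x1 + margin * bw), ncol(image) - 1)
  y0 <- max(floor(y0 - margin * bh), 0)
  y1 <- min(ceiling(y1 + margin * bh), nrow(image) - 1)
  if (x1 <= x0 || y1 <= y0)
    stop("degenerate geometry: face bounding box has zero area", call. = FALSE)
  out <- face_image(unclass(image)[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)],
                    c(applied_steps(image), "face_interception"))
  attr(out, "origin") <- c(x = x0, y = y0)
  out
}

#' Gray-scale normalization by histogram equalization
#'
#' Applies the cumulative-histogram mapping `floor(255 * cdf(v))` on 8-bit
#' intensities (inputs are rounded to integers first). The mapping is monotone
#' non-decreasing, so pixel rank order is preserved.
#'
#' @param image A [face_image()].
#' @return The equalized [face_image()].
#' @export
equalize_gray <- function(image) {
  image <- as_face_image(image)
  v <- as.integer(round(unclass(image)))
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(v)
  mapping <- floor(255 * cdf)
  face_image(matrix(mapping[v + 1L], nrow(image), ncol(image)),
             c(applied_steps(image), "histogram_equalization"))
}

#' Segment one eye region into a fixed-size patch
#'
#' Takes the bounding box of the six eye-ring points, expands it by
#' `eye_patch_margin` of its width/height on every side, clamps to the frame,
#' and resamples the box to `eye_patch_size` bilinearly.
#'
#' @param image A normalized [face_image()].
#' @param landmarks The matching [landmark_set()].
#' @param side `"right"` or `"left"` (subject's side).
#' @param config A [preprocess_config()].
#' @return A [face_image()] patch of exactly `eye_patch_size` pixels.
#' @export
segment_eye_region <- function(image, landmarks, side = c("right", "left"),
                               config = preprocess_config()) {
  side <- match.arg(side)
  image <- as_face_image(image)
  pts <- region_points(landmarks, paste0(side, "_eye"))
  x0 <- min(pts[, 1]); x1 <- max(pts[, 1])
  y0 <- min(pts[, 2]); y1 <- max(pts[, 2])
  mx <- config$eye_patch_margin * (x1 - x0)
  my <- config$eye_patch_margin * (y1 - y0)
  x0 <- max(floor(x0 - mx), 0); x1 <- min(ceiling(x1 + mx), ncol(image) - 1)
  y0 <- max(floor(y0 - my), 0); y1 <- min(ceiling(y1 + my), nrow(image) - 1)
  if (x1 <= x0 || y1 <= y0)
    stop("degenerate geometry: eye box collapses after clamping", call. = FALSE)
  box <- unclass(image)[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
  patch <- resample_bilinear(box, config$eye_patch_size[1],
                             config$eye_patch_size[2])
  face_image(pmin(pmax(patch, 0), 255),
             c(applied_steps(image), paste0("eye_patch_", side)))
}
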