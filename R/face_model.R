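# The 68-point landmark model. Point numbers follow the standard scheme and
# are 0-based (p0..p67): 0-16 face outline, 17-21 right brow, 22-26 left brow,
# 27-35 nasal bridge, 36-41 right eye, 42-47 left eye, 48-67 mouth. "Right"
# and "left" are the subject's sides, so the right eye sits on the left of the
# image. Coordinates are pixels, x rightward, y downward, origin top-left.

#' Fixed landmark index ranges per facial region
#'
#' A named list of 0-based point numbers for each of the seven facial regions
#' of the 68-point model.
#'
#' @format Named list of integer vectors with elements `outline`, `right_brow`,
#'   `left_brow`, `nose`, `right_eye`, `left_eye`, `mouth`.
#' @export
landmark_regions <- list(
  outline    = 0:16,
  right_brow = 17:21,
  left_brow  = 22:26,
  nose       = 27:35,
  right_eye  = 36:41,
  left_eye   = 42:47,
  mouth      = 48:67
)

#' Construct a 68-point landmark set
#'
#' @param points A 68 x 2 numeric matrix of (x, y) pixel coordinates; row `i`
#'   holds point number `i - 1`.
#' @return A `landmark_set` object (the validated matrix).
#' @examples
#' lm <- landmark_set(template_landmarks())
#' region_points(lm, "mouth")
#' @export
landmark_set <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 68L || ncol(points) != 2L)
    stop("a landmark set requires exactly 68 (x, y) points", call. = FALSE)
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  if (any(points < 0))
    stop("landmark coordinates must be non-negative", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(points, class = c("landmark_set", "matrix", "array"))
}

as_landmark_set <- function(x) {
  if (inherits(x, "landmark_set")) x else landmark_set(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> 68 points,",
      sprintf("x in [%.1f, %.1f], y in [%.1f, %.1f]\n",
              min(x[, 1]), max(x[, 1]), min(x[, 2]), max(x[, 2])))
  invisible(x)
}

#' Retrieve landmark coordinates by point number
#'
#' @param landmarks A [landmark_set()].
#' @param numbers 0-based point numbers (0-67).
#' @return Matrix of the requested (x, y) rows, order preserved.
#' @export
landmark_points <- function(landmarks, numbers) {
  landmarks <- as_landmark_set(landmarks)
  if (any(numbers < 0 | numbers > 67))
    stop("point numbers must lie in 0..67", call. = FALSE)
  unclass(landmarks)[numbers + 1L, , drop = FALSE]
}

#' Landmarks of one facial region
#'
#' @param landmarks A [landmark_set()].
#' @param region One of `"outline"`, `"right_brow"`, `"left_brow"`, `"nose"`,
#'   `"right_eye"`, `"left_eye"`, `"mouth"`.
#' @return Matrix of the region's points in index order.
#' @export
region_points <- function(landmarks, region) {
  if (length(region) != 1L || !region %in% names(landmark_regions))
    stop("unknown region: ", paste(region, collapse = ", "), call. = FALSE)
  landmark_points(landmarks, landmark_regions[[region]])
}

#' Eye centers as centroids of the six eye-ring points
#'
#' @param landmarks A [landmark_set()].
#' @return List with `right` and `left`, each a length-2 (x, y) vector.
#' @export
eye_centers <- function(landmarks) {
  list(
    right = colMeans(region_points(landmarks, "right_eye")),
    left  = colMeans(region_points(landmarks, "left_eye"))
  )
}

#' Construct a face image raster
#'
#' @param pixels Numeric matrix of 8-bit intensities (0-255); rows are image
#'   rows (y), columns are x.
#' @param applied_steps Character vector of preprocessing step identifiers
#'   already applied.
#' @return A `face_image` object.
#' @export
face_image <- function(pixels, applied_steps = character(0)) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop("face image pixels must be finite numbers", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("face image intensities must lie in [0, 255]", call. = FALSE)
  structure(pixels, applied_steps = as.character(applied_steps),
            class = c("face_image", "matrix", "array"))
}

as_face_image <- function(x) {
  if (inherits(x, "face_image")) x else face_image(x)
}

#' @export
print.face_image <- function(x, ...) {
  cat(sprintf("<face_image> %d x %d px (w x h), steps: %s\n",
              ncol(x), nrow(x),
              if (length(attr(x, "applied_steps")))
                paste(attr(x, "applied_steps"), collapse = " -> ")
              else "none"))
  invisible(x)
}

#' Record of preprocessing steps applied to an image
#'
#' @param image A [face_image()].
#' @return Character vector of step identifiers.
#' @export
applied_steps <- function(image) {
  attr(image, "applied_steps") %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

add_step <- function(image, step) {
  attr(image, "applied_steps") <- c(applied_steps(image), step)
  image
}

#' Bundle one subject's image, landmarks, label and age
#'
#' @param image A [face_image()].
#' @param landmarks A [landmark_set()].
#' @param label `"case"` or `"control"`.
#' @param age_years Non-negative integer age.
#' @param subject_id Unique identifier string.
#' @return A `cohort_sample` object.
#' @export
cohort_sample <- function(image, landmarks, label, age_years, subject_id) {
  label <- match.arg(label, c("case", "control"))
  age_years <- as.integer(age_years)
  if (is.na(age_years) || age_years < 0)
    stop("age_years must be a non-negative integer", call. = FALSE)
  structure(
    list(image = as_face_image(image), landmarks = as_landmark_set(landmarks),
         label = label, age_years = age_years,
         subject_id = as.character(subject_id)),
    class = "cohort_sample"
  )
}

#' Assemble samples into a cohort
#'
#' @param samples List of [cohort_sample()] objects with unique subject ids.
#' @return A `cohort` object (list of samples).
#' @export
cohort <- function(samples) {
  stopifnot(all(vapply(samples, inherits, logical(1), "cohort_sample")))
  ids <- vapply(samples, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    stop("duplicate subject_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(unname(samples), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<cohort> %d samples (%d case, %d control), ages %s\n",
              length(x), sum(lab == "case"), sum(lab == "control"),
              if (length(x)) paste(range(cohort_ages(x)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
`[.cohort` <- function(x, i) {
  structure(unclass(x)[i], class = "cohort")
}

#' Cohort accessor helpers
#'
#' `cohort_labels()`, `cohort_ages()` and `cohort_ids()` extract the per-sample
#' label, age and subject-id vectors in cohort order.
#'
#' @param x A [cohort()].
#' @return Atomic vector, one entry per sample.
#' @export
cohort_labels <- function(x) vapply(x, `[[`, character(1), "label")

#' @rdname cohort_labels
#' @export
cohort_ages <- function(x) vapply(x, `[[`, integer(1), "age_years")

#' @rdname cohort_labels
#' @export
cohort_ids <- function(x) vapply(x, `[[`, character(1), "subject_id")
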