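# On-disk interchange: PNG rasters, JSON / "pts" landmark sidecars, and the
# cohort manifest CSV (subject_id, image_path, landmark_path, label, age_years).

#' Read a face photograph from PNG
#'
#' RGB(A) input is converted to grayscale with the standard luma transform
#' 0.299 R + 0.587 G + 0.114 B; intensities are rescaled to 0-255.
#'
#' @param path Path to a PNG file.
#' @return A [face_image()].
#' @export
read_face_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    gray <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  } else {
    gray <- arr
  }
  face_image(pmin(pmax(gray * 255, 0), 255))
}

#' Write a face image to PNG
#'
#' @param image A [face_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_face_png <- function(image, path) {
  png::writePNG(unclass(as_face_image(image)) / 255, path)
  invisible(path)
}

#' Read landmarks from a JSON sidecar
#'
#' Expects a top-level key `points` holding 68 `[x, y]` pairs.
#'
#' @param path Path to the JSON file.
#' @return A [landmark_set()].
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$points))
    stop("landmark JSON must contain a 'points' key", call. = FALSE)
  landmark_set(matrix(as.numeric(t(obj$points)), ncol = 2, byrow = TRUE))
}

#' @rdname read_landmarks_json
#' @param landmarks A [landmark_set()] to serialize.
#' @export
write_landmarks_json <- function(landmarks, path) {
  landmarks <- as_landmark_set(landmarks)
  jsonlite::write_json(
    list(points = unname(apply(unclass(landmarks), 1, as.numeric,
                               simplify = FALSE))),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' Read landmarks in the plain-text "pts" format
#'
#' The format carries a `version:` line, an `n_points:` line, and the points
#' between braces, one `x y` pair per line.
#'
#' @param path Path to the pts file.
#' @return A [landmark_set()].
#' @export
read_landmarks_pts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  np_line <- grep("^n_points:", lines, value = TRUE)
  if (length(np_line) != 1L)
    stop("pts file must declare n_points", call. = FALSE)
  n <- as.integer(sub("^n_points:\\s*", "", np_line))
  open <- match("{", lines)
  pts <- lines[(open + 1):(open + n)]
  coords <- do.call(rbind, lapply(strsplit(pts, "\\s+"), as.numeric))
  landmark_set(coords)
}

#' @rdname read_landmarks_pts
#' @param landmarks A [landmark_set()] to serialize.
#' @export
write_landmarks_pts <- function(landmarks, path) {
  landmarks <- as_landmark_set(landmarks)
  writeLines(c("version: 1", sprintf("n_points: %d", nrow(landmarks)), "{",
               sprintf("%.6f %.6f", landmarks[, 1], landmarks[, 2]), "}"),
             path)
  invisible(path)
}

#' Write a cohort to disk as PNGs, JSON sidecars and a manifest CSV
#'
#' @param cohort A [cohort()].
#' @param dir Output directory (created if absent).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    img <- file.path(dir, paste0(s$subject_id, ".png"))
    lmk <- file.path(dir, paste0(s$subject_id, ".json"))
    write_face_png(s$image, img)
    write_landmarks_json(s$landmarks, lmk)
    data.frame(subject_id = s$subject_id, image_path = basename(img),
               landmark_path = basename(lmk), label = s$label,
               age_years = s$age_years, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                   manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest CSV
#'
#' Samples whose image or landmark file is missing are skipped with a warning.
#'
#' @param manifest Path to a manifest CSV with columns `subject_id`,
#'   `image_path`, `landmark_path`, `label`, `age_years`; relative paths are
#'   resolved against the manifest directory.
#' @return A [cohort()].
#' @export
read_cohort <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  samples <- list()
  for (i in seq_len(nrow(tab))) {
    ip <- resolve(tab$image_path[i]); lp <- resolve(tab$landmark_path[i])
    if (!file.exists(ip) || !file.exists(lp)) {
      warning("skipping subject ", tab$subject_id[i],
              ": missing image or landmark file", call. = FALSE)
      next
    }
    lmk <- if (grepl("\\.pts$", lp)) read_landmarks_pts(lp) else read_landmarks_json(lp)
    samples <- c(samples, list(cohort_sample(
      read_face_png(ip), lmk, tab$label[i], tab$age_years[i], tab$subject_id[i]
    )))
  }
  cohort(samples)
}
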