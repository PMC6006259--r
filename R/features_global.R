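# Global features: the pairwise landmark-distance vector (GGF) and the Gabor
# filter-bank joint spatial-frequency block-energy matrix (GTF).

#' Global geometric feature vector: all pairwise landmark distances
#'
#' Euclidean distances d_ij between every unordered pair of landmarks, i < j,
#' in lexicographic (i, j) order. For the 68-point model this yields
#' 68 * 67 / 2 = 2278 distance features.
#'
#' @param landmarks A [landmark_set()], or any n x 2 point matrix with n >= 2.
#' @return Numeric vector of length n (n - 1) / 2.
#' @export
ggf_extract <- function(landmarks) {
  pts <- if (inherits(landmarks, "landmark_set")) unclass(landmarks)
         else as.matrix(landmarks)
  if (nrow(pts) < 2L)
    stop("at least 2 points are required for pairwise distances", call. = FALSE)
  # stats::dist stacks the lower triangle column-wise: exactly the
  # lexicographic (i, j), i < j ordering of pairs
  as.vector(stats::dist(pts))
}

#' Gabor filter-bank configuration
#'
#' The bank holds `n_scales * n_orientations` complex kernels. Wavelengths
#' follow a geometric progression (half-octave steps by default); orientations
#' are uniform on `[0, pi)`. The envelope width is `sigma_ratio * wavelength`
#' (about one octave of frequency bandwidth) and kernels are truncated at
#' three envelope standard deviations.
#'
#' @param n_scales Number of scales.
#' @param n_orientations Number of orientations.
#' @param wavelengths Pixels per cycle, strictly increasing, one per scale.
#' @param sigma_ratio Envelope sigma as a fraction of the wavelength.
#' @param dc_corrected If `TRUE`, each kernel's real part is corrected to sum
#'   to zero so a constant image yields (numerically) no response.
#' @return A `gabor_bank_config` list.
#' @export
gabor_bank_config <- function(n_scales = 5L, n_orientations = 8L,
                              wavelengths = 4 * sqrt(2)^(0:(n_scales - 1)),
                              sigma_ratio = 0.56, dc_corrected = TRUE) {
  stopifnot(n_scales >= 1, n_orientations >= 1)
  if (length(wavelengths) != n_scales)
    stop("need one wavelength per scale", call. = FALSE)
  if (any(wavelengths <= 0) || any(diff(wavelengths) <= 0))
    stop("wavelengths must be positive and strictly increasing", call. = FALSE)
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 wavelengths = wavelengths, sigma_ratio = sigma_ratio,
                 dc_corrected = isTRUE(dc_corrected)),
            class = "gabor_bank_config")
}

#' Build the Gabor filter bank
#'
#' @param config A [gabor_bank_config()].
#' @return List of `n_scales * n_orientations` complex kernel matrices in
#'   scale-major order (all orientations of scale 1, then scale 2, ...). Each
#'   carries `scale`, `orientation`, `wavelength` and `theta` attributes.
#' @export
build_gabor_bank <- function(config = gabor_bank_config()) {
  bank <- vector("list", config$n_scales * config$n_orientations)
  k <- 0L
  for (s in seq_len(config$n_scales)) {
    lambda <- config$wavelengths[s]
    sigma <- config$sigma_ratio * lambda
    half <- max(ceiling(3 * sigma), 1L)
    ax <- -half:half
    for (o in seq_len(config$n_orientations)) {
      theta <- (o - 1) * pi / config$n_orientations
      ones <- rep(1, length(ax))
      # xr = x cos(theta) + y sin(theta); x varies along columns, y along rows
      xr <- outer(ones, ax) * cos(theta) + outer(ax, ones) * sin(theta)
      env <- exp(-(outer(ax^2, ax^2, "+")) / (2 * sigma^2))
      kern <- env * exp(2i * pi * xr / lambda)
      if (config$dc_corrected) {
        kern <- kern - env * (sum(Re(kern)) / sum(env))
      }
      k <- k + 1L
      bank[[k]] <- structure(
        kern, scale = s, orientation = o, wavelength = lambda, theta = theta,
        cache_key = sprintf("gabor|%.8g|%.8g|%d|%d|%d", lambda,
                            config$sigma_ratio, o, config$n_orientations,
                            config$dc_corrected))
    }
  }
  bank
}

#' Global texture feature: joint spatial-frequency energy matrix
#'
#' Filters a 128 x 128 (more generally `texture_crop_size` square) image with
#' every kernel of the bank, partitions each squared-magnitude response into
#' an 8 x 8 grid of equal blocks, and records the per-block energy. The result
#' is a 64 x 64 matrix: rows are the 64 spatial blocks (row-major), columns
#' the frequency channels in scale-major order; channels beyond the bank size
#' are structural zero padding, giving a flattened length of 4096.
#'
#' @param image A [face_image()] or matrix, square, matching `input_size`.
#' @param config A [gabor_bank_config()].
#' @param input_size Required side length in pixels.
#' @param n_blocks Blocks per image side.
#' @return A 64 x 64 numeric matrix of non-negative block energies.
#' @export
gtf_extract <- function(image, config = gabor_bank_config(),
                        input_size = 128L, n_blocks = 8L) {
  img <- if (inherits(image, "face_image")) unclass(image) else as.matrix(image)
  if (nrow(img) != input_size || ncol(img) != input_size)
    stop("global texture extraction expects a ", input_size, " x ",
         input_size, " image", call. = FALSE)
  bank <- build_gabor_bank(config)
  n_channels <- n_blocks^2
  out <- matrix(0, n_blocks^2, n_channels)
  block <- input_size / n_blocks
  bi <- rep(seq_len(n_blocks), each = block)   # block row of each pixel row
  responses <- conv2_multi(img, bank)
  for (f in seq_along(bank)) {
    resp <- Mod(responses[[f]])^2
    # sum within each block of the n_blocks x n_blocks grid, row-major rows
    agg <- rowsum(t(rowsum(resp, bi)), bi)     # n_blocks x n_blocks, [bx, by]
    out[, f] <- as.vector(agg)                 # bx fastest = row-major blocks
  }
  out
}
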