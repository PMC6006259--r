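# Shared numeric helpers. Image rasters are numeric matrices indexed
# [row = y + 1, col = x + 1]; coordinates are 0-based, x rightward, y downward,
# pixel centers at integer positions.

#' Round half away from zero
#'
#' Rounding used for reported percentages (so 68.75 -> 68.8), unlike base
#' [round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Bilinear sampling of an image at continuous coordinates
#'
#' @param img Numeric matrix raster.
#' @param x,y Vectors of 0-based sample coordinates (x = column, y = row).
#' @param fill Value returned outside the image frame.
#' @return Numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp corner indices; weights of out-of-range corners are zeroed below
  gx0 <- pmin(pmax(x0, 0), w - 1); gx1 <- pmin(pmax(x0 + 1, 0), w - 1)
  gy0 <- pmin(pmax(y0, 0), h - 1); gy1 <- pmin(pmax(y0 + 1, 0), h - 1)
  idx <- function(gy, gx) gy + 1 + gx * h
  v00 <- img[idx(gy0, gx0)]; v10 <- img[idx(gy0, gx1)]
  v01 <- img[idx(gy1, gx0)]; v11 <- img[idx(gy1, gx1)]
  out <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
  outside <- x < 0 | x > (w - 1) | y < 0 | y > (h - 1)
  out[outside] <- fill
  out
}

#' Resample an image to a target size by bilinear interpolation
#'
#' Maps output pixel centers linearly onto the input frame (edge-aligned
#' pixel-area convention).
#'
#' @param img Numeric matrix.
#' @param height,width Output dimensions in pixels.
#' @return Numeric matrix `height x width`.
#' @keywords internal
resample_bilinear <- function(img, height, width) {
  sy <- nrow(img) / height; sx <- ncol(img) / width
  xs <- (seq_len(width) - 0.5) * sx - 0.5
  ys <- (seq_len(height) - 0.5) * sy - 0.5
  g <- expand.grid(y = ys, x = xs)
  # clamp to frame so edge pixels replicate instead of fading to fill
  x <- pmin(pmax(g$x, 0), ncol(img) - 1)
  y <- pmin(pmax(g$y, 0), nrow(img) - 1)
  matrix(bilinear_sample(img, x, y), nrow = height, ncol = width)
}

#' Test points for inclusion in a closed polygon
#'
#' Even-odd ray-casting rule; points exactly on an edge may fall either side.
#'
#' @param px,py Coordinates of the query points.
#' @param poly Two-column matrix of polygon vertices (closed implicitly).
#' @return Logical vector.
#' @keywords internal
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# FFT-based 2-D filtering with reflect padding. All kernels must have odd
# dimensions. conv2_multi() pads the image once by the largest kernel
# half-width, transforms it once, and reuses cached kernel FFTs (keyed by an
# optional "cache_key" attribute on the kernel), which makes filter banks and
# scale stacks cheap to apply across many images of identical size.

.conv_cache <- new.env(parent = emptyenv())

conv2_multi <- function(img, kernels) {
  halves <- vapply(kernels, function(k) {
    stopifnot(nrow(k) %% 2 == 1, ncol(k) %% 2 == 1)
    c((nrow(k) - 1) / 2, (ncol(k) - 1) / 2)
  }, numeric(2))
  P <- max(halves)
  pad <- pad_reflect(img, P, P)
  # grow to 5-smooth sizes (zero rows/cols appended outside the reflect
  # border never reach the extracted region) so the FFTs stay fast
  H <- good_fft_size(nrow(pad)); W <- good_fft_size(ncol(pad))
  if (H > nrow(pad) || W > ncol(pad)) {
    grown <- matrix(0, H, W)
    grown[seq_len(nrow(pad)), seq_len(ncol(pad))] <- pad
    pad <- grown
  }
  ifft_scale <- H * W
  img_fft <- fft(pad)
  h <- nrow(img); w <- ncol(img)
  lapply(seq_along(kernels), function(i) {
    kern <- kernels[[i]]
    ph <- halves[1, i]; pw <- halves[2, i]
    key <- attr(kern, "cache_key")
    kfft <- NULL
    if (!is.null(key)) {
      full_key <- paste(key, H, W, sep = "|")
      kfft <- .conv_cache[[full_key]]
    }
    if (is.null(kfft)) {
      kpad <- matrix(0 + 0i, H, W)
      kpad[seq_len(nrow(kern)), seq_len(ncol(kern))] <-
        Conj(kern[nrow(kern):1, ncol(kern):1])
      kfft <- fft(kpad)
      if (!is.null(key)) .conv_cache[[full_key]] <- kfft
    }
    full <- fft(img_fft * kfft, inverse = TRUE) / ifft_scale
    full[(P + ph + 1):(P + ph + h), (P + pw + 1):(P + pw + w), drop = FALSE]
  })
}

# Smallest integer >= n whose prime factors are all in {2, 3, 5}.
good_fft_size <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
    m <- m + 1
  }
}

# Single-kernel correlation with reflect padding; returns a complex matrix
# the size of `img`.
conv2_reflect <- function(img, kernel) {
  conv2_multi(img, list(kernel))[[1]]
}

pad_reflect <- function(img, ph, pw) {
  h <- nrow(img); w <- ncol(img)
  if (ph >= h || pw >= w)
    stop("kernel support exceeds image size", call. = FALSE)
  ri <- c(if (ph > 0) (ph + 1):2 else integer(0), 1:h,
          if (ph > 0) (h - 1):(h - ph) else integer(0))
  ci <- c(if (pw > 0) (pw + 1):2 else integer(0), 1:w,
          if (pw > 0) (w - 1):(w - pw) else integer(0))
  img[ri, ci, drop = FALSE]
}
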