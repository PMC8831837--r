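#' Intensity images
#'
#' An `IntensityImage` is a plain numeric matrix of finite intensities,
#' indexed `[row, col]`. Throughout the package, points are continuous
#' 1-based pixel coordinates `c(x, y)` with `x` the column (rightward) and
#' `y` the row (downward); pixel `(1, 1)` is the top-left pixel centre.
#'
#' @param pixels numeric matrix of intensities.
#' @param min_dim minimum number of rows and columns required.
#' @return The validated matrix (invisibly for the checker).
#' @export
as_intensity_image <- function(pixels, min_dim = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("intensity image must be a non-empty numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("intensity image contains non-finite values", call. = FALSE)
  if (nrow(pixels) < min_dim || ncol(pixels) < min_dim)
    stop(sprintf("intensity image must be at least %dx%d", min_dim, min_dim),
         call. = FALSE)
  pixels
}

# Keys cubic convolution kernel, a = -1/2 (classic bicubic).
cubic_kernel <- function(t) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  i2 <- at > 1 & at < 2
  w[i1] <- (1.5 * at[i1] - 2.5) * at[i1]^2 + 1
  w[i2] <- ((-0.5 * at[i2] + 2.5) * at[i2] - 4) * at[i2] + 2
  w
}

#' Bicubic interpolation of image intensities
#'
#' Samples an image at arbitrary sub-pixel positions with the Keys cubic
#' convolution kernel. The kernel reproduces constants exactly, so sampling
#' a flat image returns the flat value at every query point.
#'
#' @param image numeric matrix.
#' @param x,y numeric vectors of equal length; continuous 1-based pixel
#'   coordinates (x = column, y = row).
#' @param boundary `"clamp"` extends the image by edge replication;
#'   `"zero"` treats everything outside the grid as zero intensity.
#' @return numeric vector of interpolated intensities.
#' @export
interp_bicubic <- function(image, x, y, boundary = c("clamp", "zero")) {
  boundary <- match.arg(boundary)
  stopifnot(length(x) == length(y))
  nr <- nrow(image); nc <- ncol(image)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- numeric(length(x))
  inside <- rep(TRUE, length(x))
  if (boundary == "zero") {
    # fully outside queries contribute nothing; border queries blend with 0
    inside <- x > -1 & x < nc + 2 & y > -1 & y < nr + 2
  }
  for (dy in -1:2) {
    wy <- cubic_kernel(fy - dy)
    ry <- y0 + dy
    for (dx in -1:2) {
      wx <- cubic_kernel(fx - dx)
      cx <- x0 + dx
      if (boundary == "clamp") {
        rr <- pmin(pmax(ry, 1L), nr)
        cc <- pmin(pmax(cx, 1L), nc)
        out <- out + wy * wx * image[cbind(rr, cc)]
      } else {
        ok <- inside & ry >= 1 & ry <= nr & cx >= 1 & cx <= nc
        if (any(ok))
          out[ok] <- out[ok] + wy[ok] * wx[ok] * image[cbind(ry[ok], cx[ok])]
      }
    }
  }
  out
}

# Normalized 1-D Gaussian kernel truncated at 3 sigma (at least 1 tap).
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  blur_axis <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(blur_axis(t(blur_axis(image))))
}

# Smooth a numeric vector with a truncated, renormalized Gaussian.
gaussian_smooth_vec <- function(v, sigma) {
  n <- length(v)
  if (sigma <= 0 || n < 3L) return(v)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - r); hi <- min(n, i + r)
    w <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
    out[i] <- sum(w * v[lo:hi]) / sum(w)
  }
  out
}

# Quadratic (parabolic) sub-sample refinement of an extremum at index j.
# Returns the refined fractional index. Plateaus fall back to the plateau
# centroid to keep the result symmetric.
parabolic_refine <- function(values, j) {
  n <- length(values)
  if (j <= 1L || j >= n) return(as.numeric(j))
  d1 <- values[j - 1L]; d2 <- values[j]; d3 <- values[j + 1L]
  denom <- d1 - 2 * d2 + d3
  if (abs(denom) < 1e-12 * max(abs(c(d1, d2, d3)), 1e-300)) {
    tol <- 1e-12 * max(abs(d2), 1e-300)
    lo <- j; hi <- j
    while (lo > 1L && abs(values[lo - 1L] - d2) <= tol) lo <- lo - 1L
    while (hi < n && abs(values[hi + 1L] - d2) <= tol) hi <- hi + 1L
    return((lo + hi) / 2)
  }
  delta <- 0.5 * (d1 - d3) / denom
  as.numeric(j) + max(-0.5, min(0.5, delta))
}
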