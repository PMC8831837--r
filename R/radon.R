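#' Discrete Radon transform
#'
#' Integrates image intensity along every line `rho = x*cos(theta) +
#' y*sin(theta)`, with the origin at the image centre, `x` rightward and `y`
#' downward, and `theta` the angle between the line normal and the x axis.
#' Each pixel's intensity is accumulated into the two offset bins bracketing
#' its exact normal offset, with linear weights, so the transform is exactly
#' linear in the image and preserves total intensity per orientation.
#'
#' @param image numeric matrix of finite intensities (at least 8x8).
#' @param theta_axis orientations in degrees, each in `[0, 180)`.
#' @return A `sinogram` object: list with `values` (rho x theta matrix),
#'   `rho_axis` (integer offsets, symmetric about 0) and `theta_axis`.
#' @examples
#' img <- matrix(0, 32, 32); img[16, ] <- 1
#' s <- radon_transform(img, theta_axis = 0:179)
#' max(s$values)  # the row sum, 32
#' @export
radon_transform <- function(image, theta_axis = 0:179) {
  image <- as_intensity_image(image)
  theta_axis <- as.numeric(theta_axis)
  if (length(theta_axis) == 0L)
    stop("theta_axis must be non-empty", call. = FALSE)
  if (any(theta_axis < 0 | theta_axis >= 180))
    stop("theta_axis values must lie in [0, 180) degrees", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  xs <- rep(seq_len(nc), each = nr) - cx
  ys <- rep(seq_len(nr), times = nc) - cy
  g <- as.vector(image)
  rmax <- ceiling(sqrt(max(abs(xs))^2 + max(abs(ys))^2)) + 1L
  rho_axis <- seq(-rmax, rmax)
  nbin <- length(rho_axis)
  values <- matrix(0, nbin, length(theta_axis))
  for (k in seq_along(theta_axis)) {
    th <- theta_axis[k] * pi / 180
    rho <- xs * cos(th) + ys * sin(th)
    pos <- rho + rmax + 1          # fractional bin index
    lo <- floor(pos)
    frac <- pos - lo
    acc <- numeric(nbin)
    a <- tapply_sum(lo, g * (1 - frac), nbin)
    b <- tapply_sum(lo + 1L, g * frac, nbin)
    values[, k] <- a + b
  }
  structure(list(values = values, rho_axis = rho_axis,
                 theta_axis = theta_axis),
            class = "sinogram")
}

# Sum weights into integer bins 1..nbin (out-of-range dropped).
tapply_sum <- function(bin, w, nbin) {
  ok <- bin >= 1L & bin <= nbin
  out <- numeric(nbin)
  if (any(ok)) {
    s <- rowsum(w[ok], group = bin[ok])
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d offsets x %d orientations (rho %g..%g px)\n",
              length(x$rho_axis), length(x$theta_axis),
              min(x$rho_axis), max(x$rho_axis)))
  invisible(x)
}

#' Distance-based weight mask
#'
#' Isotropic Gaussian weights of Euclidean distance from a window centre,
#' normalized to 1 at the centre so every weight lies in `[0, 1]` and weights
#' decay monotonically with distance. Used to emphasize intensities close to
#' the current centerline point when forming directional line integrals.
#'
#' @param window_shape integer `c(rows, cols)`.
#' @param center `c(x, y)` sub-pixel centre within the window (1-based).
#' @param bandwidth Gaussian scale in pixels (> 0); default 4, half the
#'   caliber of a typical temporal arteriole at this image scale.
#' @return list with `weights` (rows x cols matrix) and `center`.
#' @export
distance_weights <- function(window_shape, center = (window_shape[c(2, 1)] + 1) / 2,
                             bandwidth = 4) {
  if (length(window_shape) != 2L || any(window_shape < 1))
    stop("window_shape must be two positive integers", call. = FALSE)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be a positive number of pixels", call. = FALSE)
  nr <- window_shape[1L]; nc <- window_shape[2L]
  dx <- matrix(rep(seq_len(nc), each = nr), nr, nc) - center[1L]
  dy <- matrix(rep(seq_len(nr), times = nc), nr, nc) - center[2L]
  w <- exp(-(dx^2 + dy^2) / (2 * bandwidth^2))
  list(weights = w, center = center)
}

# 1-D Gaussian distance weights along a ray parameterized by t (pixels).
ray_weights <- function(t, bandwidth) exp(-t^2 / (2 * bandwidth^2))

#' Directional line-integral profiles about a point
#'
#' Forms one oriented segment per orientation through `center`, samples the
#' image along it by bicubic interpolation (edge-clamped), and weights the
#' samples by a Gaussian of distance from the centre. With the default 179
#' directions the orientations are 1..179 degrees in 1-degree steps, which
#' covers the half-circle without the 0/180 duplicate.
#'
#' The reported `integrals` are weight-normalized (sum of weighted samples
#' divided by the sum of weights), so on a constant image of value `c` every
#' integral equals `c` exactly.
#'
#' @param image numeric matrix.
#' @param center `c(x, y)` sub-pixel point.
#' @param n_directions number of orientations (>= 3); default 179.
#' @param half_length half the segment length in pixels; default 10.
#' @param bandwidth Gaussian distance-weight scale (px).
#' @param spacing sample spacing along the segment (px).
#' @return list with `center`, `theta_deg`, `profiles` (orientation x sample
#'   matrix of raw interpolated intensities), `weights`, and `integrals`
#'   (weight-normalized line integral per orientation).
#' @export
directional_profiles <- function(image, center, n_directions = 179L,
                                 half_length = 10, bandwidth = 4,
                                 spacing = 1) {
  image <- as_intensity_image(image)
  if (n_directions < 3L)
    stop("n_directions must be at least 3", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  if (center[1L] < 1 || center[1L] > nc || center[2L] < 1 || center[2L] > nr)
    stop("center lies outside the image", call. = FALSE)
  theta_deg <- seq_len(n_directions) * (180 / (n_directions + 1L))
  if (n_directions == 179L) theta_deg <- as.numeric(1:179)
  t_axis <- seq(-half_length, half_length, by = spacing)
  w <- ray_weights(t_axis, bandwidth)
  th <- theta_deg * pi / 180
  # all sample positions at once: orientation-major
  px <- outer(cos(th), t_axis) + center[1L]
  py <- outer(sin(th), t_axis) + center[2L]
  vals <- interp_bicubic(image, as.vector(px), as.vector(py), boundary = "clamp")
  profiles <- matrix(vals, nrow = n_directions)
  integrals <- as.vector(profiles %*% w) / sum(w)
  list(center = center, theta_deg = theta_deg, t_axis = t_axis,
       profiles = profiles, weights = w, integrals = integrals)
}
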