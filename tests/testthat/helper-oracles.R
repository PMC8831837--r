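# Brute-force Radon oracle: for every orientation, assign each pixel's full
# intensity to the offset bin nearest its exact normal offset. Deliberately
# naive (pixel-by-pixel enumeration, nearest-bin histogram); independent of
# the package's accumulation scheme.
oracle_radon <- function(img, thetas) {
  nr <- nrow(img); nc <- ncol(img)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  rmax <- ceiling(sqrt(max(abs(seq_len(nc) - cx))^2 +
                       max(abs(seq_len(nr) - cy))^2)) + 1L
  rho_axis <- seq(-rmax, rmax)
  vals <- matrix(0, length(rho_axis), length(thetas))
  for (k in seq_along(thetas)) {
    th <- thetas[k] * pi / 180
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      rho <- (j - cx) * cos(th) + (i - cy) * sin(th)
      b <- which.min(abs(rho_axis - rho))
      vals[b, k] <- vals[b, k] + img[i, j]
    }
  }
  list(values = vals, rho_axis = rho_axis, theta_axis = thetas)
}

# A histogram oracle is only defined to one-bin resolution, so sinograms are
# compared after both are smoothed with a unit-bin Gaussian along rho.
sinogram_rel_error <- function(s, o, sigma = 1) {
  sm <- function(m) apply(m, 2, function(col) {
    k <- exp(-((-3:3)^2) / (2 * sigma^2)); k <- k / sum(k)
    as.vector(stats::filter(c(rep(col[1], 3), col, rep(col[length(col)], 3)),
                            k, sides = 2))[4:(length(col) + 3)]
  })
  A <- sm(s$values); B <- sm(o$values)
  norm(A - B, "F") / norm(B, "F")
}

# perpendicular distance of trace points from an infinite line through
# `origin` at `angle_deg` (screen convention, y down)
line_deviation <- function(points, origin, angle_deg) {
  d <- c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180))
  rel <- sweep(points, 2, origin)
  abs(rel[, 1] * d[2] - rel[, 2] * d[1])
}

hausdorff <- function(a, b) {
  dmat <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}
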