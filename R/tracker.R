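#' Tracking parameters
#'
#' Bundle of tunables for centerline tracking and the downstream width and
#' angle measurements. Defaults are in pixels at the native fundus scale.
#'
#' @param step_length distance advanced per tracking step (px).
#' @param max_steps hard cap on the number of steps.
#' @param target_bias weight in `[0, 1]` given to alignment with the
#'   direction toward the target when scoring candidate directions; the
#'   remainder weights the normalized Radon response.
#' @param smoothing_sigma Gaussian scale (in points) for trace smoothing.
#' @param profile_half_length half-length of the directional integral
#'   segments (px).
#' @param weight_bandwidth Gaussian distance-weight scale (px).
#' @param recenter_halfwidth maximum perpendicular re-centering shift (px).
#' @param noise_floor minimum intensity dynamic range around the seed for a
#'   vessel to count as detectable (intensity units; images are in [0, 1]).
#' @param tangent_window length of the tangent-parallel integration segment
#'   used for edge profiles (px).
#' @param max_offset perpendicular search range for vessel edges (px).
#' @param min_contrast minimum centre-to-background contrast, as a fraction
#'   of the profile dynamic range, for an edge measurement to be accepted.
#' @param max_arclength proximal arclength span used for width (px).
#' @param sample_spacing arclength spacing of width samples (px).
#' @param edge_method `"gradient"` (steepest transition of the parallel
#'   integral profile) or `"halfmax"` (half-maximum crossing).
#' @param fit_span proximal arclength span used for straight-ray fits (px).
#' @param parallel_tol minimum inter-line angle for an intersection (degrees).
#' @return list of class `tracking_params`.
#' @export
tracking_params <- function(step_length = 2, max_steps = 2000L,
                            target_bias = 0.3, smoothing_sigma = 2,
                            profile_half_length = 10, weight_bandwidth = 4,
                            recenter_halfwidth = 3, noise_floor = 0.02,
                            tangent_window = 7, max_offset = 15,
                            min_contrast = 0.1, max_arclength = 100,
                            sample_spacing = 2, edge_method = "gradient",
                            fit_span = 50, parallel_tol = 0.5) {
  stopifnot(step_length > 0, max_steps >= 1,
            target_bias >= 0, target_bias <= 1, smoothing_sigma >= 0)
  structure(list(step_length = step_length, max_steps = as.integer(max_steps),
                 target_bias = target_bias, smoothing_sigma = smoothing_sigma,
                 profile_half_length = profile_half_length,
                 weight_bandwidth = weight_bandwidth,
                 recenter_halfwidth = recenter_halfwidth,
                 noise_floor = noise_floor, tangent_window = tangent_window,
                 max_offset = max_offset, min_contrast = min_contrast,
                 max_arclength = max_arclength,
                 sample_spacing = sample_spacing,
                 edge_method = match.arg(edge_method, c("gradient", "halfmax")),
                 fit_span = fit_span, parallel_tol = parallel_tol),
            class = "tracking_params")
}

new_trace <- function(points, converged, confidence) {
  pts <- matrix(points, ncol = 2, dimnames = list(NULL, c("x", "y")))
  seg <- if (nrow(pts) > 1)
    sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  else numeric(0)
  structure(list(points = pts, arclength = c(0, cumsum(seg)),
                 converged = converged, confidence = confidence),
            class = "centerline_trace")
}

#' @export
print.centerline_trace <- function(x, ...) {
  cat(sprintf("centerline trace: %d points, arclength %.1f px, %s\n",
              nrow(x$points), max(x$arclength),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# Perpendicular re-centering: profile the (bright-vessel) intensity along the
# normal and move to the sub-pixel maximum, with the shift limited to
# +/- halfwidth. The probe window extends 4 px beyond the allowed shift so
# the profile always reaches background on both sides of the caliber, and
# the profile is matched-filtered (Gaussian, 1.5 px) because flat-topped
# calibers otherwise present two interpolation humps whose raw maximum
# snaps to one edge.
recenter_point <- function(image, p, direction, halfwidth) {
  n <- c(-direction[2L], direction[1L])
  ds <- 0.25
  hw_win <- halfwidth + 4
  s <- seq(-hw_win, hw_win, by = ds)
  # short tangent averaging stabilizes the profile under pixel noise
  tt <- c(-1, 0, 1)
  qx <- as.vector(outer(s * n[1L], tt * direction[1L], "+")) + p[1L]
  qy <- as.vector(outer(s * n[2L], tt * direction[2L], "+")) + p[2L]
  v <- interp_bicubic(image, qx, qy, boundary = "clamp")
  prof <- rowMeans(matrix(v, nrow = length(s)))
  sm <- gaussian_smooth_vec(prof, sigma = 1.5 / ds)
  allowed <- which(abs(s) <= halfwidth)
  j <- allowed[which.max(sm[allowed])]
  sj <- parabolic_refine(sm, j)
  shift <- max(-halfwidth, min(halfwidth, s[1L] + (sj - 1) * ds))
  list(point = p + shift * n, profile = prof, range = diff(range(prof)))
}

#' Track a vessel centerline between a seed and a target point
#'
#' Iterative Radon-guided ridge following on a bright-vessel intensity image
#' (fundus images are inverted at ingest so vessels are bright). At each
#' step, 179 weighted directional line integrals are formed about the
#' current point; each candidate direction is scored by a convex combination
#' of its normalized integral response and its alignment with the direction
#' toward the target, restricted to the forward cone (within 90 degrees of
#' the previous direction). After each step the point is re-centred at the
#' sub-pixel maximum of the perpendicular intensity profile. Tracking stops
#' when the point comes within one step of the target (converged) or when
#' `max_steps` is reached.
#'
#' @param image bright-vessel intensity matrix.
#' @param seed `c(x, y)` start point, on or within ~3 px of the vessel.
#' @param target `c(x, y)` distal stopping point.
#' @param params a [tracking_params()] list.
#' @return A `centerline_trace`: sub-pixel `points`, cumulative `arclength`,
#'   per-point Radon `confidence`, and a `converged` flag.
#' @export
track_centerline <- function(image, seed, target, params = tracking_params()) {
  image <- as_intensity_image(image)
  nr <- nrow(image); nc <- ncol(image)
  in_bounds <- function(p) p[1L] >= 1 && p[1L] <= nc && p[2L] >= 1 && p[2L] <= nr
  if (!in_bounds(seed) || !in_bounds(target))
    stop("seed and target must lie inside the image", call. = FALSE)
  to_target <- target - seed
  dist_target <- sqrt(sum(to_target^2))
  d_prev <- if (dist_target > 0) to_target / dist_target else c(1, 0)

  rc <- recenter_point(image, seed, d_prev, params$recenter_halfwidth)
  if (rc$range < params$noise_floor)
    stop("no detectable vessel contrast at the seed point", call. = FALSE)
  p <- rc$point

  if (sqrt(sum((p - target)^2)) <= params$step_length)
    return(new_trace(p, converged = TRUE, confidence = rc$range))

  pts <- matrix(NA_real_, params$max_steps + 1L, 2L)
  conf <- numeric(params$max_steps + 1L)
  pts[1L, ] <- p
  conf[1L] <- rc$range
  npts <- 1L
  converged <- FALSE
  margin <- params$profile_half_length + 2

  for (step in seq_len(params$max_steps)) {
    dp <- directional_profiles(image, p,
                               half_length = params$profile_half_length,
                               bandwidth = params$weight_bandwidth)
    th <- dp$theta_deg * pi / 180
    dirs <- cbind(cos(th), sin(th))
    # orient each axis into the forward cone of the previous direction
    flip <- (dirs %*% d_prev) < 0
    dirs[flip, ] <- -dirs[flip, ]
    resp <- dp$integrals
    rng <- diff(range(resp))
    resp_n <- if (rng > 0) (resp - min(resp)) / rng else rep(0, length(resp))
    u_t <- target - p
    u_t <- u_t / max(sqrt(sum(u_t^2)), 1e-12)
    align <- as.vector(dirs %*% u_t)
    score <- (1 - params$target_bias) * resp_n + params$target_bias * align
    best <- max(score)
    cand <- which(score >= best - 1e-12)
    if (length(cand) > 1L) {
      prev_align <- as.vector(dirs[cand, , drop = FALSE] %*% d_prev)
      cand <- cand[which.max(prev_align)]
    }
    d <- dirs[cand[1L], ]
    p_new <- p + params$step_length * d
    rc <- recenter_point(image, p_new, d, params$recenter_halfwidth)
    p_new <- rc$point
    if (p_new[1L] < margin || p_new[1L] > nc - margin + 1 ||
        p_new[2L] < margin || p_new[2L] > nr - margin + 1) {
      # leaving the tractable region: stop short of the border
      break
    }
    npts <- npts + 1L
    pts[npts, ] <- p_new
    conf[npts] <- resp[cand[1L]]
    d_prev <- (p_new - p) / max(sqrt(sum((p_new - p)^2)), 1e-12)
    p <- p_new
    if (sqrt(sum((p - target)^2)) <= params$step_length) {
      converged <- TRUE
      # finish on the (re-centred) target so forward and reverse traces
      # cover the same span
      rt <- recenter_point(image, target, d_prev, params$recenter_halfwidth)
      if (sqrt(sum((rt$point - p)^2)) > 1e-9 && npts < params$max_steps + 1L) {
        npts <- npts + 1L
        pts[npts, ] <- rt$point
        conf[npts] <- conf[npts - 1L]
      }
      break
    }
  }
  new_trace(pts[seq_len(npts), , drop = FALSE], converged,
            conf[seq_len(npts)])
}

#' Gaussian smoothing of a centerline trace
#'
#' Convolves the x and y coordinate sequences with a truncated, renormalized
#' Gaussian kernel along the point index. The first and last points are kept
#' fixed so the trace still spans seed to target. Because the same
#' unit-mass kernel is applied to both coordinates, exactly collinear traces
#' remain collinear.
#'
#' @param trace a `centerline_trace`.
#' @param sigma kernel scale in points; `0` returns the trace unchanged.
#' @return the smoothed `centerline_trace` with recomputed arclength.
#' @export
smooth_centerline <- function(trace, sigma = 2) {
  stopifnot(inherits(trace, "centerline_trace"), sigma >= 0)
  pts <- trace$points
  if (nrow(pts) < 2L || sigma == 0) return(trace)
  sx <- gaussian_smooth_vec(pts[, 1L], sigma)
  sy <- gaussian_smooth_vec(pts[, 2L], sigma)
  sx[c(1L, length(sx))] <- pts[c(1L, nrow(pts)), 1L]
  sy[c(1L, length(sy))] <- pts[c(1L, nrow(pts)), 2L]
  out <- new_trace(cbind(sx, sy), trace$converged, trace$confidence)
  out
}

# Linear interpolation of trace points at given arclength positions.
trace_point_at <- function(trace, s) {
  al <- trace$arclength
  pts <- trace$points
  s <- pmin(pmax(s, 0), max(al))
  ix <- findInterval(s, al, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), nrow(pts) - 1L)
  seg <- al[ix + 1L] - al[ix]
  f <- ifelse(seg > 0, (s - al[ix]) / seg, 0)
  cbind(x = pts[ix, 1L] + f * (pts[ix + 1L, 1L] - pts[ix, 1L]),
        y = pts[ix, 2L] + f * (pts[ix + 1L, 2L] - pts[ix, 2L]))
}

# Unit tangent of the trace at arclength s, by central difference over a
# window of +/- half_window arclength.
trace_tangent_at <- function(trace, s, half_window = 3) {
  smax <- max(trace$arclength)
  a <- trace_point_at(trace, max(0, s - half_window))
  b <- trace_point_at(trace, min(smax, s + half_window))
  d <- c(b[1L, 1L] - a[1L, 1L], b[1L, 2L] - a[1L, 2L])
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) stop("tangent undefined at this position", call. = FALSE)
  d / nd
}
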