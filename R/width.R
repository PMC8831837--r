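#' Perpendicular edge profile from parallel line integrals
#'
#' At one centerline position, integrates image intensity along short
#' segments parallel to the local vessel direction, one segment per signed
#' perpendicular offset. The resulting offset-vs-integral profile has its
#' steepest transitions at the two vessel edges.
#'
#' @param image numeric matrix (any polarity; edge detection adapts).
#' @param trace a `centerline_trace`.
#' @param position_index index of an interior trace point.
#' @param max_offset perpendicular search half-range (px).
#' @param tangent_window length of the tangent-parallel segment (px).
#' @param offset_spacing offset grid spacing (px).
#' @return list with `offsets` (strictly increasing, symmetric about 0),
#'   `integrals` (weight-normalized parallel line integrals), plus the
#'   `center`, `tangent` and `normal` used, for reconstructing edge points.
#' @export
edge_profile <- function(image, trace, position_index, max_offset = 15,
                         tangent_window = 7, offset_spacing = 0.5) {
  stopifnot(inherits(trace, "centerline_trace"))
  npt <- nrow(trace$points)
  if (position_index <= 1L || position_index >= npt)
    stop("position_index must be interior to the trace (tangent undefined at endpoints)",
         call. = FALSE)
  s <- trace$arclength[position_index]
  center <- trace$points[position_index, ]
  tangent <- trace_tangent_at(trace, s)
  edge_profile_at(image, center, tangent, max_offset, tangent_window,
                  offset_spacing)
}

edge_profile_at <- function(image, center, tangent, max_offset = 15,
                            tangent_window = 7, offset_spacing = 0.5) {
  image <- as_intensity_image(image)
  normal <- c(-tangent[2L], tangent[1L])
  offsets <- seq(-max_offset, max_offset, by = offset_spacing)
  t_axis <- seq(-tangent_window / 2, tangent_window / 2, by = 1)
  qx <- as.vector(outer(offsets * normal[1L], t_axis * tangent[1L], "+")) + center[1L]
  qy <- as.vector(outer(offsets * normal[2L], t_axis * tangent[2L], "+")) + center[2L]
  v <- interp_bicubic(image, qx, qy, boundary = "clamp")
  integrals <- rowMeans(matrix(v, nrow = length(offsets)))
  structure(list(offsets = offsets, integrals = integrals, center = center,
                 tangent = tangent, normal = normal),
            class = "edge_profile")
}

#' Locate the two vessel edges on a perpendicular profile
#'
#' Finds, on each side of offset zero, the steepest transition of the
#' parallel-integral profile (extremum of its first difference) with
#' parabolic sub-sample refinement. The profile polarity is detected from
#' the centre vs the outer background, so dark-vessel and bright-vessel
#' images are handled alike. With `method = "halfmax"` the edge is instead
#' placed where the profile crosses halfway between the centre level and
#' that side's background level; on ideal band profiles the two criteria
#' agree to within half a pixel.
#'
#' @param profile an `edge_profile`.
#' @param min_contrast minimum centre-to-background contrast as a fraction
#'   of the profile's dynamic range.
#' @param method `"gradient"` or `"halfmax"`.
#' @return `c(top, bottom)`: the negative-side and positive-side edge
#'   offsets in pixels.
#' @export
detect_edges <- function(profile, min_contrast = 0.1,
                         method = c("gradient", "halfmax")) {
  method <- match.arg(method)
  off <- profile$offsets
  P <- profile$integrals
  n <- length(P)
  if (n < 7L || min(off) >= 0 || max(off) <= 0)
    stop("profile must span both sides of zero with at least 7 offsets",
         call. = FALSE)
  rng <- diff(range(P))
  nout <- max(2L, floor(n / 5))
  bg <- mean(c(P[seq_len(nout)], P[seq(n - nout + 1L, n)]))
  c0 <- P[which.min(abs(off))]
  contrast <- abs(c0 - bg)
  if (rng < 1e-12 || contrast < min_contrast * rng)
    stop("low-contrast profile: no detectable vessel edges", call. = FALSE)
  sgn <- if (c0 >= bg) 1 else -1   # work with a bright-centre profile
  Q <- sgn * P
  dQ <- diff(Q) / diff(off)
  mid <- (off[-1L] + off[-n]) / 2
  left <- which(mid < 0)
  right <- which(mid > 0)
  if (method == "gradient") {
    jl <- left[which.max(dQ[left])]
    jr <- right[which.min(dQ[right])]
    sl <- parabolic_refine(dQ, jl)
    sr <- parabolic_refine(-dQ, jr)
    top <- approx_index(mid, sl)
    bottom <- approx_index(mid, sr)
  } else {
    half_level <- function(side_idx) {
      bg_side <- mean(Q[side_idx][seq_len(min(3L, length(side_idx)))])
      (max(Q) + bg_side) / 2
    }
    li <- seq_len(which.min(abs(off)))
    ri <- seq(which.min(abs(off)), n)
    top <- crossing_offset(off[li], Q[li], half_level(li), from_left = TRUE)
    bottom <- crossing_offset(off[ri], Q[ri], half_level(rev(ri)), from_left = FALSE)
  }
  if (!is.finite(top) || !is.finite(bottom) || top >= bottom)
    stop("edge localization failed on this profile", call. = FALSE)
  c(top = top, bottom = bottom)
}

# Fractional index -> offset value on a uniform grid.
approx_index <- function(grid, frac_idx) {
  step <- grid[2L] - grid[1L]
  grid[1L] + (frac_idx - 1) * step
}

# Offset where values cross `level`; nearest crossing to the centre end.
crossing_offset <- function(off, vals, level, from_left) {
  above <- vals >= level
  idx <- which(above[-1L] != above[-length(above)])
  if (length(idx) == 0L) return(NA_real_)
  j <- if (from_left) max(idx) else min(idx)
  f <- (level - vals[j]) / (vals[j + 1L] - vals[j])
  off[j] + f * (off[j + 1L] - off[j])
}

#' Vessel width along the proximal centerline span
#'
#' Samples centerline positions every `sample_spacing` pixels of arclength
#' over the proximal span (capped at `max_arclength`, 100 px by default
#' since angles and widths are read near the optic disc). At each position
#' the two edges are localized on the perpendicular profile and the width is
#' the Euclidean distance between the reconstructed top-edge and bottom-edge
#' points, which lie on the same perpendicular line. Low-contrast positions
#' are skipped and counted.
#'
#' @param image numeric matrix.
#' @param trace a `centerline_trace` (converged, or arclength >= 10 px).
#' @param max_arclength proximal span to use (px).
#' @param params a [tracking_params()] list.
#' @return list of class `width_measurement`: `per_position_widths`,
#'   `mean_width`, `n_positions`, `n_skipped`, `arclength_used`,
#'   `edge_points` (top/bottom image coordinates per position).
#' @export
vessel_width <- function(image, trace, max_arclength = NULL,
                         params = tracking_params()) {
  stopifnot(inherits(trace, "centerline_trace"))
  if (is.null(max_arclength)) max_arclength <- params$max_arclength
  total <- max(trace$arclength)
  if (!trace$converged && total < 10)
    stop("trace too short and not converged; refusing width measurement",
         call. = FALSE)
  span <- min(total, max_arclength)
  s_axis <- seq(0, span, by = params$sample_spacing)
  s_axis <- s_axis[s_axis > 0 & s_axis < total]  # interior tangents only
  widths <- numeric(0)
  tops <- NULL; bottoms <- NULL
  n_skipped <- 0L
  for (s in s_axis) {
    ctr <- trace_point_at(trace, s)[1L, ]
    tg <- trace_tangent_at(trace, s)
    prof <- edge_profile_at(image, ctr, tg, params$max_offset,
                            params$tangent_window)
    edges <- tryCatch(
      detect_edges(prof, params$min_contrast, params$edge_method),
      error = function(e) NULL)
    if (is.null(edges)) { n_skipped <- n_skipped + 1L; next }
    pt_top <- ctr + edges[1L] * prof$normal
    pt_bot <- ctr + edges[2L] * prof$normal
    widths <- c(widths, sqrt(sum((pt_bot - pt_top)^2)))
    tops <- rbind(tops, pt_top); bottoms <- rbind(bottoms, pt_bot)
  }
  if (length(widths) < 3L)
    stop("fewer than 3 valid width positions on this vessel", call. = FALSE)
  structure(list(per_position_widths = widths, mean_width = mean(widths),
                 n_positions = length(widths), n_skipped = n_skipped,
                 arclength_used = span,
                 edge_points = list(top = tops, bottom = bottoms)),
            class = "width_measurement")
}

#' @export
print.width_measurement <- function(x, ...) {
  cat(sprintf("vessel width: %.2f px (mean of %d positions, %d skipped, %g px span)\n",
              x$mean_width, x$n_positions, x$n_skipped, x$arclength_used))
  invisible(x)
}

#' Aggregate superior and inferior arm widths into a temporal width
#'
#' The temporal artery/vein width (TAW/TVW) is the mean of the superior and
#' inferior arm widths. When the superior arm could not be measured (for
#' example when an adjacent vein overlaps the artery) the inferior width
#' alone is used and flagged.
#'
#' @param superior,inferior `width_measurement` objects or `NULL`.
#' @return list of class `temporal_width`: `superior`, `inferior`, `value`
#'   (px), and flags `inferior_only` / `superior_only`.
#' @export
aggregate_temporal_width <- function(superior = NULL, inferior = NULL) {
  sup <- if (!is.null(superior)) superior$mean_width else NULL
  inf <- if (!is.null(inferior)) inferior$mean_width else NULL
  if (is.null(sup) && is.null(inf))
    stop("no width measurement available for either arm", call. = FALSE)
  value <- mean(c(sup, inf))
  structure(list(superior = sup, inferior = inf, value = value,
                 inferior_only = is.null(sup), superior_only = is.null(inf)),
            class = "temporal_width")
}
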