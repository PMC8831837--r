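#' Fit a straight ray to the proximal span of a vessel centerline
#'
#' Total-least-squares line through the trace points whose arclength lies
#' within `fit_span` of the proximal end (the end nearest the optic disc,
#' i.e. the start of the trace). The direction is oriented distally, from
#' the proximal end toward the far end of the fitted span.
#'
#' @param trace_points n x 2 matrix of ordered `(x, y)` points, proximal
#'   first, or a `centerline_trace`.
#' @param fit_span proximal arclength span used for the fit (px); `Inf`
#'   uses every point.
#' @return list of class `vessel_ray`: `anchor` (centroid of fitted points),
#'   unit `direction` (distal), `fit_residual` (RMS perpendicular distance),
#'   `distal_ref` (far end of the fitted span).
#' @export
fit_vessel_ray <- function(trace_points, fit_span = 50) {
  if (inherits(trace_points, "centerline_trace"))
    trace_points <- trace_points$points
  pts <- matrix(as.numeric(trace_points), ncol = 2)
  if (nrow(pts) < 2L) stop("need at least 2 points to fit a ray", call. = FALSE)
  if (fit_span <= 0) stop("fit_span must be positive", call. = FALSE)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  al <- c(0, cumsum(seg))
  keep <- al <= fit_span
  if (sum(keep) < 2L) keep[seq_len(2L)] <- TRUE
  sub <- pts[keep, , drop = FALSE]
  ctr <- colMeans(sub)
  X <- sweep(sub, 2L, ctr)
  cv <- crossprod(X) / nrow(X)
  if (sum(cv) < 1e-18 && max(abs(X)) < 1e-9)
    stop("degenerate fit: all points coincident", call. = FALSE)
  ev <- eigen(cv, symmetric = TRUE)
  # an exactly collinear point set has a zero minor eigenvalue up to
  # round-off; clamp it so the reported residual is exactly zero
  if (ev$values[2L] < 1e-12 * ev$values[1L]) ev$values[2L] <- 0
  dir <- ev$vectors[, 1L]
  # orient proximal -> distal along the point order
  chord <- sub[nrow(sub), ] - sub[1L, ]
  if (sum(dir * chord) < 0) dir <- -dir
  resid <- sqrt(max(ev$values[2L], 0))
  structure(list(anchor = ctr, direction = dir / sqrt(sum(dir^2)),
                 fit_residual = resid, distal_ref = sub[nrow(sub), ]),
            class = "vessel_ray")
}

#' Intersect two vessel rays
#'
#' Unique intersection point of the two infinite lines; it may fall outside
#' the image (vessel arms need not meet at the optic-disc centre).
#'
#' @param a,b `vessel_ray` objects.
#' @param parallel_tol minimum inter-line angle in degrees.
#' @return `c(x, y)` intersection point.
#' @export
intersect_rays <- function(a, b, parallel_tol = 0.5) {
  da <- a$direction; db <- b$direction
  cross <- da[1L] * db[2L] - da[2L] * db[1L]
  if (abs(cross) < sin(parallel_tol * pi / 180))
    stop("rays are (nearly) parallel: no reliable intersection", call. = FALSE)
  dp <- b$anchor - a$anchor
  t <- (dp[1L] * db[2L] - dp[2L] * db[1L]) / cross
  a$anchor + t * da
}

#' Inter-arm vessel angle at the ray intersection
#'
#' Both arm directions are re-anchored at the intersection point and
#' oriented distally (toward each arm's far reference point); the angle is
#' the inverse cosine of their dot product, reported in degrees on
#' (0, 180) without folding obtuse angles to acute.
#'
#' @param a,b `vessel_ray` objects (superior and inferior arms).
#' @param parallel_tol passed to [intersect_rays()].
#' @return list of class `angle_measurement`: `angle_deg`, `vertex`,
#'   `ray_superior`, `ray_inferior`.
#' @export
vessel_angle <- function(a, b, parallel_tol = 0.5) {
  vertex <- intersect_rays(a, b, parallel_tol)
  orient <- function(r) {
    d <- r$direction
    if (sum(d * (r$distal_ref - vertex)) < 0) d <- -d
    d
  }
  da <- orient(a); db <- orient(b)
  cosang <- max(-1, min(1, sum(da * db)))
  structure(list(angle_deg = acos(cosang) * 180 / pi, vertex = vertex,
                 ray_superior = a, ray_inferior = b),
            class = "angle_measurement")
}

#' @export
print.angle_measurement <- function(x, ...) {
  cat(sprintf("vessel angle: %.2f deg at vertex (%.1f, %.1f)\n",
              x$angle_deg, x$vertex[1L], x$vertex[2L]))
  invisible(x)
}

#' Disc-centre chord angle (baseline method)
#'
#' The older semi-automatic convention: the angle subtended at the
#' optic-disc centre by chords to a point on each arm. Kept as a baseline;
#' when the true arm intersection is displaced from the disc centre this
#' chord angle is biased, which motivates the intersection-based method.
#'
#' @param disc_center `c(x, y)` optic-disc centre.
#' @param point_superior,point_inferior points on the two arms.
#' @return angle in degrees.
#' @export
disc_chord_angle <- function(disc_center, point_superior, point_inferior) {
  u <- point_superior - disc_center
  v <- point_inferior - disc_center
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9)
    stop("chord point coincides with the disc centre", call. = FALSE)
  cosang <- max(-1, min(1, sum(u * v) / (nu * nv)))
  acos(cosang) * 180 / pi
}

track_arm <- function(image, entry, params) {
  trace <- track_centerline(image, entry$seed, entry$target, params)
  smooth_centerline(trace, params$smoothing_sigma)
}

#' Measure one eye: temporal angles and widths
#'
#' Composes the full per-image pipeline. For each annotated arm (superior /
#' inferior x artery / vein) the centerline is tracked from its seed to its
#' target and smoothed. Per vessel type, the temporal angle (TAA / TVA) is
#' computed when both arms are present, by fitting proximal rays and
#' intersecting them; the temporal width (TAW / TVW) aggregates the arm
#' widths, falling back to the inferior arm alone when the superior arm is
#' flagged as overlapped or fails its width measurement.
#'
#' @param image bright-vessel intensity matrix (see [read_fundus_image()]).
#' @param annotation an annotation list: see [annotation()] /
#'   [read_annotation()].
#' @param params a [tracking_params()] list.
#' @return list of class `eye_measurement` with `taa`, `tva`, `taw`, `tvw`
#'   (numbers or `NA`), `flags` (character), and per-arm `details`
#'   (traces, width and angle objects).
#' @export
measure_eye <- function(image, annotation, params = tracking_params()) {
  image <- as_intensity_image(image)
  arms <- annotation$vessels
  if (length(arms) == 0L)
    stop("annotation contains no vessel arms", call. = FALSE)
  details <- list()
  flags <- character(0)
  get_arm <- function(vessel, arm) {
    for (e in arms)
      if (identical(e$vessel, vessel) && identical(e$arm, arm)) return(e)
    NULL
  }
  result <- list(taa = NA_real_, tva = NA_real_,
                 taw = NA_real_, tvw = NA_real_,
                 taw_inferior_only = FALSE, tvw_inferior_only = FALSE)
  for (vessel in c("artery", "vein")) {
    traces <- list()
    widths <- list()
    for (arm in c("superior", "inferior")) {
      e <- get_arm(vessel, arm)
      if (is.null(e)) next
      tr <- tryCatch(track_arm(image, e, params), error = function(err) {
        flags <<- c(flags, sprintf("%s %s: tracking failed (%s)",
                                   arm, vessel, conditionMessage(err)))
        NULL
      })
      if (is.null(tr)) next
      traces[[arm]] <- tr
      overlapped <- isTRUE(e$overlapped)
      if (overlapped) {
        flags <- c(flags, sprintf("%s %s: overlapped, width skipped", arm, vessel))
      } else {
        w <- tryCatch(vessel_width(image, tr, params = params),
                      error = function(err) {
                        flags <<- c(flags, sprintf("%s %s: width failed (%s)",
                                                   arm, vessel,
                                                   conditionMessage(err)))
                        NULL
                      })
        if (!is.null(w)) widths[[arm]] <- w
      }
    }
    details[[vessel]] <- list(traces = traces, widths = widths)
    if (length(traces) == 2L) {
      ang <- tryCatch({
        rs <- fit_vessel_ray(traces$superior, params$fit_span)
        ri <- fit_vessel_ray(traces$inferior, params$fit_span)
        vessel_angle(rs, ri, params$parallel_tol)
      }, error = function(err) {
        flags <<- c(flags, sprintf("%s angle failed (%s)", vessel,
                                   conditionMessage(err)))
        NULL
      })
      if (!is.null(ang)) {
        details[[vessel]]$angle <- ang
        if (vessel == "artery") result$taa <- ang$angle_deg
        else result$tva <- ang$angle_deg
      }
    }
    if (length(widths) > 0L) {
      tw <- aggregate_temporal_width(widths$superior, widths$inferior)
      details[[vessel]]$temporal_width <- tw
      if (vessel == "artery") {
        result$taw <- tw$value; result$taw_inferior_only <- tw$inferior_only
      } else {
        result$tvw <- tw$value; result$tvw_inferior_only <- tw$inferior_only
      }
    }
  }
  if (all(is.na(c(result$taa, result$tva, result$taw, result$tvw))))
    stop("no measurable vessel pair in this image", call. = FALSE)
  structure(c(result, list(flags = flags, details = details,
                           stage = annotation$stage)),
            class = "eye_measurement")
}

#' @export
print.eye_measurement <- function(x, ...) {
  fmt <- function(v, unit) if (is.na(v)) "absent" else sprintf("%.2f %s", v, unit)
  cat("eye measurement\n")
  cat("  TAA:", fmt(x$taa, "deg"), " TVA:", fmt(x$tva, "deg"), "\n")
  cat("  TAW:", fmt(x$taw, "px"),
      if (isTRUE(x$taw_inferior_only)) "(inferior only)" else "",
      " TVW:", fmt(x$tvw, "px"),
      if (isTRUE(x$tvw_inferior_only)) "(inferior only)" else "", "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
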