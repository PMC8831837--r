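#' Phantom specification
#'
#' Describes a synthetic fundus-like image: dark curvilinear vessels of
#' known width on a brighter background, an optional mock optic disc,
#' Gaussian blur, and i.i.d. Gaussian pixel noise. Rendering is fully
#' deterministic given `seed`.
#'
#' Each arm is a list with `points` (n x 2 polyline of `(x, y)` vertices),
#' `width` (px), `label`, and optionally `vessel` ("artery"/"vein") and
#' `arm` ("superior"/"inferior") for annotation emission.
#'
#' @param image_size `c(rows, cols)`; default 600 x 800 (half the native
#'   1600 x 1200 capture scale, for speed; full size is just a parameter).
#' @param background_level background intensity in [0, 1].
#' @param vessel_contrast intensity drop at the vessel centre.
#' @param vessel_profile `"rect"` (ideal band, anti-aliased) or
#'   `"gaussian"` (soft cross-section whose FWHM equals the width).
#' @param arms list of arm descriptions (see Details).
#' @param disc_center,disc_radius mock optic disc (set radius 0 to omit).
#' @param noise_sigma Gaussian pixel-noise standard deviation.
#' @param blur_sigma Gaussian blur scale (px) applied before noise.
#' @param seed integer RNG seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(600L, 800L), background_level = 0.75,
                         vessel_contrast = 0.45,
                         vessel_profile = c("rect", "gaussian"),
                         arms = list(), disc_center = c(120, 300),
                         disc_radius = 40, noise_sigma = 0,
                         blur_sigma = 0.5, seed = 1L) {
  vessel_profile <- match.arg(vessel_profile)
  if (vessel_contrast <= 0) stop("vessel_contrast must be > 0", call. = FALSE)
  for (a in arms) {
    if (is.null(a$width) || a$width <= 0)
      stop("every arm needs a positive width", call. = FALSE)
    p <- matrix(as.numeric(a$points), ncol = 2)
    if (any(p[, 1L] < 1 | p[, 1L] > image_size[2L] |
            p[, 2L] < 1 | p[, 2L] > image_size[1L]))
      stop("arm polyline extends outside the image", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 background_level = background_level,
                 vessel_contrast = vessel_contrast,
                 vessel_profile = vessel_profile, arms = arms,
                 disc_center = disc_center, disc_radius = disc_radius,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Minimum distance from every pixel to a polyline, computed segment-wise
# within padded bounding boxes. Returns a full-image distance matrix
# (Inf far away).
polyline_distance <- function(image_size, pts, pad) {
  nr <- image_size[1L]; nc <- image_size[2L]
  D <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    x0 <- max(1L, floor(min(a[1L], b[1L]) - pad))
    x1 <- min(nc, ceiling(max(a[1L], b[1L]) + pad))
    y0 <- max(1L, floor(min(a[2L], b[2L]) - pad))
    y1 <- min(nr, ceiling(max(a[2L], b[2L]) + pad))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    gx <- matrix(rep(xs, each = length(ys)), length(ys)) - a[1L]
    gy <- matrix(rep(ys, times = length(xs)), length(ys)) - a[2L]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) pmin(pmax((gx * ab[1L] + gy * ab[2L]) / len2, 0), 1) else 0
    dx <- gx - t * ab[1L]
    dy <- gy - t * ab[2L]
    d <- sqrt(dx^2 + dy^2)
    D[ys, xs] <- pmin(D[ys, xs], d)
  }
  D
}

#' Render a phantom image with ground truth
#'
#' Vessels are drawn as dark bands: with the `"rect"` profile the intensity
#' drop equals `vessel_contrast` times the pixel's coverage by the band
#' (anti-aliased, so a width-6 band is exactly 6 px across between its
#' half-coverage edges); with `"gaussian"` the drop is a Gaussian of the
#' perpendicular distance whose FWHM equals the nominal width. The mock
#' disc brightens a circular region. Blur is applied before noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (raw dark-vessel intensities), `bright`
#'   (inverted copy, the polarity the tracker consumes) and `truth`
#'   (`phantom_truth`: per-arm widths, axes, annotation seeds/targets, and
#'   any true inter-arm angles attached by [phantom_eye_spec()]).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$image_size[1L]; nc <- spec$image_size[2L]
  img <- matrix(spec$background_level, nr, nc)
  if (spec$disc_radius > 0) {
    xs <- matrix(rep(seq_len(nc), each = nr), nr) - spec$disc_center[1L]
    ys <- matrix(rep(seq_len(nr), times = nc), nr) - spec$disc_center[2L]
    d <- sqrt(xs^2 + ys^2)
    img <- img + 0.12 * pmin(pmax(spec$disc_radius + 0.5 - d, 0), 1)
  }
  drop <- matrix(0, nr, nc)
  for (a in spec$arms) {
    pts <- matrix(as.numeric(a$points), ncol = 2)
    hw <- a$width / 2
    pad <- hw + 3
    D <- polyline_distance(spec$image_size, pts, pad)
    contrib <- if (spec$vessel_profile == "rect") {
      spec$vessel_contrast * pmin(pmax(hw + 0.5 - D, 0), 1)
    } else {
      sg <- a$width / (2 * sqrt(2 * log(2)))
      spec$vessel_contrast * exp(-D^2 / (2 * sg^2))
    }
    contrib[!is.finite(contrib)] <- 0
    drop <- pmax(drop, contrib)
  }
  img <- img - drop
  img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sigma > 0) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(spec$seed)
    img <- img + matrix(stats::rnorm(nr * nc, sd = spec$noise_sigma), nr, nc)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  truth <- phantom_truth(spec)
  list(image = img, bright = max(img) - img, truth = truth)
}

phantom_truth <- function(spec) {
  arms <- lapply(spec$arms, function(a) {
    pts <- matrix(as.numeric(a$points), ncol = 2)
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    list(label = a$label, vessel = a$vessel, arm = a$arm, width = a$width,
         axis = pts, arclength = sum(seg),
         seed = pts[1L, ], target = pts[nrow(pts), ],
         overlapped = isTRUE(a$overlapped))
  })
  structure(list(arms = arms, disc_center = spec$disc_center,
                 disc_radius = spec$disc_radius,
                 true_angle_artery = attr(spec, "true_angle_artery"),
                 true_angle_vein = attr(spec, "true_angle_vein"),
                 vertex_artery = attr(spec, "vertex_artery"),
                 vertex_vein = attr(spec, "vertex_vein")),
            class = "phantom_truth")
}

# straight arm from `start`, direction angle_deg (screen convention:
# y down, so negative angles head up-screen), length len
straight_arm <- function(start, angle_deg, len, width, label,
                         vessel = NULL, arm = NULL, n = 2L) {
  th <- angle_deg * pi / 180
  t <- seq(0, len, length.out = max(2L, n))
  list(points = cbind(start[1L] + t * cos(th), start[2L] + t * sin(th)),
       width = width, label = label, vessel = vessel, arm = arm)
}

#' Phantom of one eye: artery and/or vein arm pairs of known angle
#'
#' Builds a [phantom_spec()] whose superior and inferior arms of each
#' vessel type radiate temporally (rightward) from a vertex, separated by
#' the requested inter-arm angle, so the ground-truth TAA/TVA are the
#' design angles. The vein vertex is displaced nasally so the two vessel
#' trees stay spatially separate, as the arcades do in real fundus images.
#'
#' @param angle_artery,angle_vein design inter-arm angles (degrees);
#'   `NULL` omits that vessel type.
#' @param width_artery,width_vein arm widths (px).
#' @param arm_length arm length (px).
#' @param vertex_artery artery vertex; default just temporal of the disc
#'   centre.
#' @param vein_vertex_offset displacement of the vein vertex from the
#'   artery vertex.
#' @param ... further arguments passed to [phantom_spec()].
#' @return a `phantom_spec` with true angles recorded in its attributes.
#' @export
phantom_eye_spec <- function(angle_artery = 120, angle_vein = NULL,
                             width_artery = 4, width_vein = 6,
                             arm_length = 260,
                             vertex_artery = c(130, 300),
                             vein_vertex_offset = c(-55, 0), ...) {
  arms <- list()
  if (!is.null(angle_artery)) {
    h <- angle_artery / 2
    arms <- c(arms, list(
      straight_arm(vertex_artery, -h, arm_length, width_artery,
                   "artery_superior", "artery", "superior"),
      straight_arm(vertex_artery, h, arm_length, width_artery,
                   "artery_inferior", "artery", "inferior")))
  }
  if (!is.null(angle_vein)) {
    vv <- vertex_artery + vein_vertex_offset
    h <- angle_vein / 2
    arms <- c(arms, list(
      straight_arm(vv, -h, arm_length, width_vein,
                   "vein_superior", "vein", "superior"),
      straight_arm(vv, h, arm_length, width_vein,
                   "vein_inferior", "vein", "inferior")))
  }
  spec <- phantom_spec(arms = arms, ...)
  attr(spec, "true_angle_artery") <- angle_artery
  attr(spec, "true_angle_vein") <- angle_vein
  attr(spec, "vertex_artery") <- vertex_artery
  if (!is.null(angle_vein))
    attr(spec, "vertex_vein") <- vertex_artery + vein_vertex_offset
  spec
}

#' Annotation derived from phantom ground truth
#'
#' Emits an annotation directly consumable by [measure_eye()]: for each arm
#' the seed is placed `seed_offset` px along the arm from its vertex (just
#' outside the mock disc margin) and the target at the distal end.
#'
#' @param truth a `phantom_truth`.
#' @param stage ROP stage label for the emitted annotation.
#' @param seed_offset arclength from the proximal end to the seed (px).
#' @return an [annotation()] list.
#' @export
truth_annotation <- function(truth, stage = "none", seed_offset = 60) {
  vessels <- lapply(truth$arms, function(a) {
    pts <- a$axis
    tr <- new_trace(pts, TRUE, numeric(nrow(pts)))
    sd <- trace_point_at(tr, min(seed_offset, max(tr$arclength) / 2))[1L, ]
    list(vessel = a$vessel, arm = a$arm, seed = as.numeric(sd),
         target = as.numeric(a$target), overlapped = a$overlapped)
  })
  vessels <- Filter(function(v) !is.null(v$vessel), vessels)
  annotation(stage = stage, vessels = vessels)
}
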