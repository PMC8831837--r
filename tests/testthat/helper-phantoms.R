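# Shared phantom builders. Noise levels quoted as fractions of the default
# vessel contrast (0.45), e.g. 5% -> sigma 0.0225.

default_params <- vesselrt::tracking_params()

# one straight artery pair at a known inter-arm angle
eye_phantom <- function(angle = 110, width = 5, noise = 0, seed = 1, ...) {
  vesselrt::render_phantom(
    vesselrt::phantom_eye_spec(angle_artery = angle, width_artery = width,
                               noise_sigma = noise, seed = seed, ...))
}

# a single straight vessel through the image centre at `angle_deg`
line_phantom <- function(angle_deg, width = 5, noise = 0, seed = 1,
                         size = c(600, 600), half_len = 120) {
  th <- angle_deg * pi / 180
  ctr <- (size[c(2, 1)] + 1) / 2
  p1 <- ctr - half_len * c(cos(th), sin(th))
  p2 <- ctr + half_len * c(cos(th), sin(th))
  spec <- vesselrt::phantom_spec(
    image_size = size, disc_radius = 0, noise_sigma = noise, seed = seed,
    arms = list(list(points = rbind(p1, p2), width = width, label = "arm",
                     vessel = "artery", arm = "inferior")))
  out <- vesselrt::render_phantom(spec)
  out$p1 <- p1; out$p2 <- p2; out$ctr <- ctr; out$angle <- angle_deg
  out
}

track_and_smooth <- function(bright, seed, target, params = default_params) {
  vesselrt::smooth_centerline(
    vesselrt::track_centerline(bright, seed, target, params),
    params$smoothing_sigma)
}

measured_eye_angle <- function(rp, vessel = "artery",
                               params = default_params) {
  ann <- vesselrt::truth_annotation(rp$truth)
  arms <- Filter(function(v) v$vessel == vessel, ann$vessels)
  trs <- lapply(arms, function(v)
    track_and_smooth(rp$bright, v$seed, v$target, params))
  sup <- trs[[which(vapply(arms, function(v) v$arm, "") == "superior")]]
  inf <- trs[[which(vapply(arms, function(v) v$arm, "") == "inferior")]]
  vesselrt::vessel_angle(vesselrt::fit_vessel_ray(sup, params$fit_span),
                         vesselrt::fit_vessel_ray(inf, params$fit_span))
}
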