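# analytic band profile: background `hi`, band of half-width `hw` at level
# `lo`, linear 1-px transitions centred on the edges
band_profile <- function(offsets, hw, lo = 0.3, hi = 0.75) {
  ramp <- pmin(pmax(abs(offsets) - hw + 0.5, 0), 1)
  lo + (hi - lo) * ramp
}

make_profile <- function(offsets, integrals) {
  structure(list(offsets = offsets, integrals = integrals,
                 center = c(0, 0), tangent = c(1, 0), normal = c(0, 1)),
            class = "edge_profile")
}

test_that("edge profile of an ideal dark band is dark inside, flat outside", {
  lp <- line_phantom(0, width = 6, noise = 0)
  # trace straight along the known axis
  pts <- cbind(seq(lp$p1[1] + 20, lp$p2[1] - 20, by = 2), lp$ctr[2])
  tr <- vesselrt:::new_trace(pts, TRUE, numeric(nrow(pts)))
  prof <- edge_profile(lp$image, tr, position_index = 25L)
  inside <- abs(prof$offsets) < 2
  outside <- abs(prof$offsets) > 5
  expect_lt(max(prof$integrals[inside]), min(prof$integrals[outside]))
  # symmetric vessel -> even profile
  sym_err <- max(abs(prof$integrals - rev(prof$integrals)))
  expect_lt(sym_err, 0.02 * diff(range(prof$integrals)))
  # flat image -> flat profile
  flatp <- edge_profile(matrix(0.4, 400, 400), tr, 25L)
  expect_lt(diff(range(flatp$integrals)), 1e-9)
  expect_error(edge_profile(lp$image, tr, 1L), "interior")
})

test_that("edge detection localizes analytic transitions to sub-pixel accuracy", {
  off <- seq(-10, 10, by = 0.5)
  e <- detect_edges(make_profile(off, band_profile(off, 3)))
  expect_equal(unname(e), c(-3, 3), tolerance = 0.25)

  # asymmetric background levels: each side localized independently
  P <- band_profile(off, 3)
  P[off > 0] <- band_profile(off[off > 0], 4, lo = 0.3, hi = 0.9)
  e2 <- detect_edges(make_profile(off, P))
  expect_equal(e2[["top"]], -3, tolerance = 0.25)
  expect_equal(e2[["bottom"]], 4, tolerance = 0.25)

  # flat profile has no edges
  expect_error(detect_edges(make_profile(off, rep(0.5, length(off)))),
               "low-contrast")
  # gradient and half-max criteria agree on ideal bands
  eh <- detect_edges(make_profile(off, band_profile(off, 3)), method = "halfmax")
  expect_lt(max(abs(eh - e)), 0.5)
})

test_that("width is recovered within half a pixel across calibers under noise", {
  for (w in c(3, 4, 5, 6, 8)) {
    rp <- eye_phantom(angle = 110, width = w, noise = 0.05 * 0.45,
                      seed = 100 + w)
    v <- truth_annotation(rp$truth)$vessels[[1]]
    tr <- track_and_smooth(rp$bright, v$seed, v$target)
    wm <- vessel_width(rp$image, tr)
    expect_lt(abs(wm$mean_width - w), 0.5)
    expect_equal(wm$mean_width, mean(wm$per_position_widths))
  }
})

test_that("width respects ordering, the 100 px cap, and the halfmax cross-check", {
  lp4 <- line_phantom(15, width = 4)
  lp8 <- line_phantom(15, width = 8, seed = 2)
  tr4 <- track_and_smooth(lp4$bright, lp4$p1 + c(8, 2), lp4$p2)
  tr8 <- track_and_smooth(lp8$bright, lp8$p1 + c(8, 2), lp8$p2)
  w4 <- vessel_width(lp4$image, tr4)
  w8 <- vessel_width(lp8$image, tr8)
  expect_lt(w4$mean_width, w8$mean_width)
  expect_lte(w4$arclength_used, 100)
  expect_gt(max(tr4$arclength), 100)  # the trace itself is longer than the cap

  hm <- tracking_params(edge_method = "halfmax")
  wh <- vessel_width(lp4$image, tr4, params = hm)
  expect_lt(abs(wh$mean_width - w4$mean_width), 0.5)
})

test_that("measured width scales with the image and is rotation invariant", {
  # upscale x2: same vessel rendered at twice the scale
  mk <- function(scale) {
    th <- 25 * pi / 180
    ctr <- c(300, 300) * scale / ifelse(scale > 1, 1.2, 1)  # keep inside
    p1 <- ctr - 110 * scale * c(cos(th), sin(th))
    p2 <- ctr + 110 * scale * c(cos(th), sin(th))
    spec <- phantom_spec(image_size = c(600, 600) * scale, disc_radius = 0,
                         arms = list(list(points = rbind(p1, p2),
                                          width = 4 * scale, label = "a")),
                         noise_sigma = 0)
    list(rp = render_phantom(spec), p1 = p1, p2 = p2)
  }
  s1 <- mk(1); s2 <- mk(2)
  t1 <- track_and_smooth(s1$rp$bright, s1$p1 + c(8, 4), s1$p2)
  t2 <- track_and_smooth(s2$rp$bright, s2$p1 + c(8, 4), s2$p2)
  w1 <- vessel_width(s1$rp$image, t1)
  w2 <- vessel_width(s2$rp$image, t2)
  expect_lt(abs(w2$mean_width / w1$mean_width - 2), 0.1)

  ws <- vapply(seq(0, 170, by = 10), function(a) {
    lp <- line_phantom(a, width = 5)
    u <- (lp$p2 - lp$p1) / sqrt(sum((lp$p2 - lp$p1)^2))
    tr <- track_and_smooth(lp$bright, lp$p1 + 10 * u, lp$p2)
    vessel_width(lp$image, tr)$mean_width
  }, numeric(1))
  expect_lte(diff(range(ws)), 0.3)
})

test_that("temporal width aggregation averages arms and flags fallbacks", {
  wm <- function(w) structure(list(mean_width = w), class = "width_measurement")
  both <- aggregate_temporal_width(wm(4), wm(5))
  expect_equal(both$value, 4.5)
  expect_false(both$inferior_only)
  inf_only <- aggregate_temporal_width(NULL, wm(4.8))
  expect_equal(inf_only$value, 4.8)
  expect_true(inf_only$inferior_only)
  expect_error(aggregate_temporal_width(NULL, NULL), "no width")
})

test_that("too-short or low-contrast vessels are refused", {
  flat <- matrix(0.5, 300, 300)
  pts <- cbind(seq(50, 250, by = 2), 150)
  tr <- vesselrt:::new_trace(pts, TRUE, numeric(nrow(pts)))
  expect_error(vessel_width(flat, tr), "fewer than 3")
  short <- vesselrt:::new_trace(pts[1:3, ], FALSE, numeric(3))
  expect_error(vessel_width(flat, short), "too short")
})
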