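test_that("representative frame selection follows the marker rules", {
  mk <- select_representative_frames(c(8.0, 5.0, 2.7, 4.9, 7.8), c(0, 4),
                                     pr = 0, dr = 4)
  expect_equal(unclass(mk)[c("pr", "ps", "mla", "ds", "dr")],
               list(pr = 0L, ps = 1L, mla = 2L, ds = 3L, dr = 4L))
  # no PR: midpoint between the proximal lesion edge and the MLA
  areas <- c(9, 8, 7, 6, 5, 4, 3.1, 4.5, 5.5, 6.5, 7.5)
  mk2 <- select_representative_frames(areas, c(0, 10))
  expect_equal(mk2$mla, 6L)
  expect_equal(mk2$ps, 3L)
  expect_true(is.na(mk2$pr))
  # floor rule for odd gaps
  a3 <- c(5, 4, 3, 2, 1, 2.5)
  mk3 <- select_representative_frames(a3, c(0, 5), pr = 0)
  expect_equal(mk3$mla, 4L)
  expect_equal(mk3$ps, 2L)
  # shifting all frame ids shifts all markers equally
  for (shift in c(5L, 17L, 230L)) {
    mks <- select_representative_frames(areas, c(0, 10) + shift)
    expect_equal(mks$mla, mk2$mla + shift)
    expect_equal(mks$ps, mk2$ps + shift)
    expect_equal(mks$ds, mk2$ds + shift)
  }
  expect_error(select_representative_frames(numeric(0), c(0, -1)), "empty")
  expect_message(select_representative_frames(c(3, 2, 2, 4), c(0, 3)), "tie")
})

test_that("layered geometry partitions the wall annulus", {
  # concentric circles: annulus band areas
  cs <- cross_section(1L, 0, circle_contour(1.5, 192L),
                      circle_contour(2.0, 192L), list(), 0.2, 0.3)
  g <- build_layered_geometry(cs)
  expect_equal(g$areas$media, pi * (2.2^2 - 2.0^2), tolerance = 5e-3)
  expect_equal(g$areas$adventitia, pi * (2.5^2 - 2.2^2), tolerance = 5e-3)
  expect_equal(g$areas$intima_fibrous, pi * (2.0^2 - 1.5^2), tolerance = 1e-3)

  # lipid crescent: fibrous + lipid partition the intima to 0.1%
  sp <- section_spec(lumen_radius = 1.5, wall_thickness = 0.5,
                     eccentricity = 0, lipid_arc = 90, cap_thickness = 150,
                     seed = 3)
  cs2 <- make_section(sp)
  g2 <- build_layered_geometry(cs2)
  intima <- polygon_area(cs2$iel) - polygon_area(cs2$lumen)
  expect_equal(g2$areas$intima_fibrous + g2$areas$intima_lipid +
                 g2$areas$intima_calcium, intima, tolerance = 1e-3)
  expect_gt(g2$areas$intima_lipid, 0)
})

test_that("regions protruding past the IEL are clipped to the intima", {
  lumen <- circle_contour(1.5, 192L)
  iel <- circle_contour(2.0, 192L)
  # lipid blob centered on the IEL: half of it sticks out
  blob <- circle_contour(0.35, 64L, center = c(2.0, 0))
  cs <- cross_section(1L, 0, lumen, iel,
                      list(plaque_region("lipid", blob)), 0.2, 0.2)
  expect_warning(g <- build_layered_geometry(cs), "clipped")
  oracle <- shapely_clip_area(blob, lumen, iel)
  expect_equal(g$areas$intima_lipid, oracle, tolerance = 5e-3)
})

test_that("calcium takes precedence where regions overlap", {
  lumen <- circle_contour(1.5, 192L)
  iel <- circle_contour(2.1, 192L)
  lip <- circle_contour(0.25, 64L, center = c(1.8, 0))
  cal <- circle_contour(0.25, 64L, center = c(1.85, 0.1))
  cs <- cross_section(1L, 0, lumen, iel,
                      list(plaque_region("lipid", lip),
                           plaque_region("calcium", cal)), 0.2, 0.2)
  expect_message(g <- build_layered_geometry(cs), "calcium")
  expect_equal(g$areas$intima_calcium, abs(polygon_area(cal)),
               tolerance = 5e-3)
  both <- g$areas$intima_lipid + g$areas$intima_calcium
  # union area, not sum of areas: the overlap is counted once
  expect_lt(both, abs(polygon_area(lip)) + abs(polygon_area(cal)) - 1e-3)
})

test_that("plaque burden follows the area formula and stays in [0, 100)", {
  lum <- circle_contour(sqrt(2.7 / pi), 256L)
  iel <- circle_contour(sqrt(8.74 / pi), 256L)
  expect_equal(compute_plaque_burden(lum, iel), 100 * (8.74 - 2.7) / 8.74,
               tolerance = 1e-3)
  same <- circle_contour(1.8)
  expect_equal(compute_plaque_burden(same, same), 0)
  set.seed(5)
  for (k in 1:20) {
    r1 <- runif(1, 0.5, 1.5); r2 <- r1 + runif(1, 0.05, 1.5)
    pb <- compute_plaque_burden(circle_contour(r1, 64L), circle_contour(r2, 64L))
    expect_gte(pb, 0); expect_lt(pb, 100)
    expect_equal(pb, 100 * (1 - polygon_area(circle_contour(r1, 64L)) /
                              polygon_area(circle_contour(r2, 64L))))
  }
  expect_error(compute_plaque_burden(circle_contour(2), circle_contour(1)),
               "not nested|smaller")
})

test_that("cap thickness is the minimum lumen-lipid distance in micrometres", {
  lum <- circle_contour(1.50, 256L)
  lip <- plaque_region("lipid", circle_contour(1.65, 256L))
  expect_equal(measure_cap_thickness(lum, lip), 150, tolerance = 1e-2)
  touching <- plaque_region("lipid", circle_contour(0.4, 64L, center = c(1.9, 0)))
  expect_lt(measure_cap_thickness(lum, touching), 1.5)
  expect_true(is.na(measure_cap_thickness(lum, NULL)))
  # eccentric pool: brute-force all-pairs over densified vertices
  pool <- ellipse_contour(0.5, 0.3, 256L, angle = 0.4, center = c(2.2, 0.3))
  lum2 <- resample_contour(circle_contour(1.5, 64L), 2048L)
  pool_d <- resample_contour(pool, 2048L)
  brute <- min(sqrt(outer(lum2[, 1], pool_d[, 1], "-")^2 +
                      outer(lum2[, 2], pool_d[, 2], "-")^2)) * 1000
  expect_equal(measure_cap_thickness(circle_contour(1.5, 64L),
                                     plaque_region("lipid", pool)),
               brute, tolerance = 1e-3)
})

test_that("partial IEL arcs are completed by ellipse fitting", {
  # circle with a 90-degree gap
  t <- seq(0, 1.5 * pi, length.out = 80L)
  arc <- cbind(1.9 * cos(t), 1.9 * sin(t))
  rec <- complete_partial_iel(arc)
  rr <- sqrt(rowSums(unclass(rec)^2))
  expect_lt(max(abs(rr - 1.9)) / 1.9, 0.01)
  # noiseless half ellipse
  t2 <- seq(0, pi, length.out = 60L)
  half <- cbind(2.0 * cos(t2), 1.6 * sin(t2))
  fit <- attr(complete_partial_iel(half), "fit")
  expect_equal(fit$a, 2.0, tolerance = 0.01)
  expect_equal(fit$b, 1.6, tolerance = 0.01)
  # noisy arc: residual RMS bounded, parameters agree with an independent fit
  set.seed(9)
  t3 <- seq(-0.2, 1.25 * pi, length.out = 150L)
  noisy <- cbind(1.8 * cos(t3) + rnorm(150, 0, 0.02),
                 1.4 * sin(t3) + rnorm(150, 0, 0.02))
  fit3 <- attr(complete_partial_iel(noisy), "fit")
  ind <- skimage_ellipse_fit(noisy)
  expect_equal(fit3$center, ind[1:2], tolerance = 0.02)
  expect_equal(c(fit3$a, fit3$b), ind[3:4], tolerance = 0.03)
  # residual RMS <= 2 sigma against the fitted ellipse
  th <- atan2(noisy[, 2] - fit3$center[2], noisy[, 1] - fit3$center[1])
  rec3 <- complete_partial_iel(noisy, n = 2048L)
  resid <- sapply(seq_len(nrow(noisy)), function(i)
    min(sqrt((rec3[, 1] - noisy[i, 1])^2 + (rec3[, 2] - noisy[i, 2])^2)))
  expect_lt(sqrt(mean(resid^2)), 2 * 0.02)
  # arcs under 180 degrees are refused with the fallback named
  short <- cbind(2 * cos(seq(0, 2, length.out = 30L)),
                 2 * sin(seq(0, 2, length.out = 30L)))
  expect_error(complete_partial_iel(short), "adjacent")
})

test_that("cross-sections survive a JSON round trip", {
  cs <- make_section(section_spec(lipid_arc = 80, calcium_arc = 30, seed = 5))
  tf <- tempfile(fileext = ".json")
  write_cross_section(cs, tf)
  back <- read_cross_section(tf)
  expect_equal(back$frame_id, cs$frame_id)
  expect_equal(unclass(back$lumen), unclass(cs$lumen), tolerance = 1e-12)
  expect_equal(unclass(back$iel), unclass(cs$iel), tolerance = 1e-12)
  expect_equal(length(back$regions), length(cs$regions))
  expect_equal(back$media_thickness, cs$media_thickness)
})
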