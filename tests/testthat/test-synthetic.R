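test_that("generated sections are deterministic and honor their spec", {
  sp <- section_spec(lumen_radius = 1.1, wall_thickness = 0.7,
                     eccentricity = 0.5, lipid_arc = 120, cap_thickness = 180,
                     calcium_arc = 45, seed = 99)
  a <- make_section(sp); b <- make_section(sp)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  other <- make_section(section_spec(lumen_radius = 1.1, wall_thickness = 0.7,
                                     eccentricity = 0.5, lipid_arc = 120,
                                     cap_thickness = 180, calcium_arc = 45,
                                     seed = 100))
  expect_false(identical(unclass(a$lumen), unclass(other$lumen)))
  # generation does not disturb the session RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(make_section(sp)); r2 <- runif(1)
  expect_identical(r1, r2)

  # degenerate spec: concentric fibrous-only "normal segment"
  norm <- make_section(section_spec(lumen_radius = 1.3, wall_thickness = 0.3,
                                    eccentricity = 0, lipid_arc = 0,
                                    calcium_arc = 0, seed = 2))
  expect_length(norm$regions, 0L)
  rl <- sqrt(rowSums(unclass(norm$lumen)^2))
  expect_lt(stats::sd(rl) / mean(rl), 0.03)

  # impossible specs are refused with the violated constraint named
  expect_error(section_spec(cap_thickness = 900, wall_thickness = 0.6),
               "cap_thickness")
  expect_error(section_spec(eccentricity = 1.2), "eccentricity")
})

test_that("the requested cap thickness is reproduced by measurement", {
  for (cap in c(80, 150, 250)) {
    sp <- section_spec(lumen_radius = 1.0, wall_thickness = 0.75,
                       eccentricity = 0.4, lipid_arc = 100,
                       cap_thickness = cap, seed = 17)
    cs <- make_section(sp)
    lip <- Filter(function(r) r$label == "lipid", cs$regions)[[1]]
    expect_equal(measure_cap_thickness(cs$lumen, lip), cap, tolerance = 5 / cap)
  }
})

test_that("synthetic tracings attain their stated bounds and period", {
  tr <- make_pressure_tracing(systolic = 120, diastolic = 80, hr = 60,
                              n_beats = 2L, gradient = 0, noise_sd = 0, seed = 1)
  expect_equal(max(tr$pa), 120, tolerance = 0.5 / 120)
  expect_equal(min(tr$pa), 80, tolerance = 0.5 / 80)
  expect_identical(tr$pa, tr$pd)     # no stenosis, no noise
  for (hr in c(60, 75, 100)) {
    tr2 <- make_pressure_tracing(hr = hr, n_beats = 3L, gradient = 0.1, seed = 3)
    beat <- extract_representative_beat(tr2)
    expect_equal(max(beat$time) - min(beat$time), 60 / hr,
                 tolerance = 1.2 * 0.01 / (60 / hr))
  }
  expect_error(make_pressure_tracing(gradient = 1.2), "gradient")
  expect_error(make_pressure_tracing(systolic = 70, diastolic = 80), "systolic")
})

test_that("pullback curves are monotone with the stated plateau", {
  flat <- make_ofr_pullback(drop = 0)
  expect_true(all(flat$value == 1))
  pb <- make_ofr_pullback(length = 50, lesion_center = 25, drop = 0.2, width = 2)
  expect_equal(pb$value[1], 0.80, tolerance = 0.005 / 0.8)
  expect_equal(pb$value[length(pb$value)], 1.0, tolerance = 0.005)
  expect_true(all(diff(pb$value) >= 0))   # exhaustive pairwise monotonicity
  expect_error(make_ofr_pullback(width = 0), "width")
})

test_that("cohorts have the stated group structure and parameter spread", {
  entries <- make_cohort(cohort_spec(n_normal = 2L, n_diseased = 3L, seed = 5))
  expect_length(entries, 5L)
  labs <- vapply(entries, function(e) e$label, "")
  expect_setequal(labs[1:2], c("PR", "DR"))
  expect_true(all(labs[3:5] %in% c("PS", "MLA", "DS")))
  for (e in entries[3:5]) {
    has_lipid <- any(vapply(e$section$regions, function(r) r$label, "") == "lipid")
    expect_true(has_lipid)
  }
  for (e in entries[1:2]) expect_length(e$section$regions, 0L)
  expect_identical(serialize(make_cohort(cohort_spec(seed = 5)), NULL),
                   serialize(make_cohort(cohort_spec(seed = 5)), NULL))

  # plaque burden across many samples spans the configured morphology range
  big <- make_cohort(cohort_spec(n_normal = 50L, n_diseased = 50L, seed = 8))
  burden <- vapply(big, function(e)
    compute_plaque_burden(e$section$lumen, e$section$iel), 0)
  labs <- vapply(big, function(e) e$label, "")
  normal <- burden[labs %in% c("PR", "DR")]
  diseased <- burden[!labs %in% c("PR", "DR")]
  expect_gt(min(diseased), max(normal))
  expect_lt(max(normal), 45)
  expect_gt(max(diseased), 55)
  expect_gt(max(normal) - min(normal), 3)    # ranges are actually explored
  expect_gt(max(diseased) - min(diseased), 8)
})

test_that("every generated object passes the pipeline validators", {
  for (seed in c(1, 23, 77)) {
    e <- make_cohort(cohort_spec(n_normal = 1L, n_diseased = 1L, seed = seed))
    for (x in e) {
      expect_s3_class(x$section, "cross_section")
      g <- build_layered_geometry(x$section)
      expect_gt(g$areas$intima_fibrous, 0)
    }
    tr <- make_pressure_tracing(noise_sd = 1, seed = seed)
    expect_s3_class(tr, "pressure_tracing")
    expect_s3_class(make_ofr_pullback(drop = 0.3), "ofr_pullback")
  }
})
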