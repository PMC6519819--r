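# Beam/phantom/panel geometry: corner rays, surface planes, footprints and
# projected areas.

test_that("corner rays and source position follow the gantry", {
  rays <- beam_corner_rays(beam_setup(0, 6.3))
  expect_equal(rays[[1]]$origin, c(0, 0, 105))
  corners <- t(vapply(rays, function(r) {
    # corner = origin + t * direction with z = 0 at the isocenter plane
    r$origin + r$direction * (-r$origin[3] / r$direction[3])
  }, numeric(3)))
  expect_equal(sort(corners[, 1]), c(-3.15, -3.15, 3.15, 3.15))
  expect_equal(sort(corners[, 2]), c(-3.15, -3.15, 3.15, 3.15))
  expect_equal(corners[, 3], rep(0, 4))

  s30 <- source_position(beam_setup(30, 6.3))
  expect_equal(s30, 105 * c(-sin(pi / 6), 0, cos(pi / 6)), tolerance = 1e-12)
  expect_equal(s30[3], 90.93267, tolerance = 1e-6)
  # gantry angles normalize to [0, 360)
  expect_equal(beam_setup(-30, 6.3)$gantry_angle, 330)
})

test_that("surface planes sit at half-thickness along the tilted normal", {
  p0 <- surface_plane(phantom_setup(0), "entrance")
  expect_equal(p0$point, c(0, 0, 5))
  expect_equal(p0$normal, c(0, 0, 1))

  p30 <- surface_plane(phantom_setup(30), "entrance")
  expect_equal(p30$point, c(0, 2.5, 4.330127), tolerance = 1e-6)
  p30x <- surface_plane(phantom_setup(30), "exit")
  expect_equal(p30x$point, -p30$point)
  expect_equal(p30x$normal, p30$normal)
})

test_that("ray/plane intersection returns the point or a distinct miss", {
  pl <- plane3(c(0, 0, 5), c(0, 0, 1))
  hit <- ray_plane_intersection(ray3(c(0, 0, 105), c(0, 0, -1)), pl)
  expect_equal(hit, c(0, 0, 5))
  expect_null(ray_plane_intersection(ray3(c(0, 0, 105), c(1, 0, 0)), pl))
  # behind the origin is also a miss
  expect_null(ray_plane_intersection(ray3(c(0, 0, 0), c(0, 0, 1)),
                                     plane3(c(0, 0, -5), c(0, 0, 1))))
  # central axis at gantry 30 meets the tilt-30 exit plane 111.67 cm out
  b <- beam_setup(30, 12.6)
  cax <- ray3(source_position(b), beam_direction(b))
  px <- ray_plane_intersection(cax, surface_plane(phantom_setup(30), "exit"))
  expect_equal(sqrt(sum((px - cax$origin)^2)), 111.6667, tolerance = 1e-4)
})

test_that("entrance footprint area matches the obliquity approximation", {
  cond <- tiny_condition(tilt = 10, fs = 6.3, gantry = 0)
  fp <- footprint_polygon(cond, "entrance")
  a_planar <- attr(projected_area(fp), "planar_area")
  # central-ray distance to the entrance plane, then inverse-square scaling
  # and 1/cos obliquity
  t_cax <- 105 - 5 / cos(10 * pi / 180)  # approximate
  approx_area <- (6.3 * t_cax / 105)^2 / cos(10 * pi / 180)
  expect_lt(abs(a_planar - approx_area) / approx_area, 0.03)
})

test_that("degenerate and clipped footprints behave", {
  expect_error(footprint_polygon(tiny_condition(fs = 0), "entrance"),
               "degenerate")
  # a footprint fully inside the face is unchanged by clipping
  cond <- tiny_condition(tilt = 10, fs = 6.3, gantry = 0)
  a_unclipped <- projected_area(footprint_polygon(cond, "entrance"))
  a_clipped <- projected_area(footprint_polygon(cond, "entrance",
                                                clip_to_phantom = TRUE))
  expect_equal(as.numeric(a_unclipped), as.numeric(a_clipped))
  # a large oblique footprint is reduced by clipping
  big <- tiny_condition(tilt = 30, fs = 12.6, gantry = 330)
  expect_lt(projected_area(footprint_polygon(big, "exit", TRUE)),
            projected_area(footprint_polygon(big, "exit", FALSE)))
})

test_that("projected areas obey the study symmetries and orderings", {
  # no tilt -> the surface normal is orthogonal to the field axis
  flat <- tiny_condition(tilt = 0, fs = 6.3, gantry = 0)
  expect_equal(as.numeric(projected_area(footprint_polygon(flat, "entrance"))), 0)

  for (tilt in c(10, 20, 30)) for (fs in c(6.3, 12.6)) {
    for (which in c("entrance", "exit")) {
      a30 <- projected_area(footprint_polygon(
        tiny_condition(tilt, fs, 30), which))
      a330 <- projected_area(footprint_polygon(
        tiny_condition(tilt, fs, 330), which))
      expect_lt(abs(a30 - a330), 1e-9)
    }
  }

  # beam divergence: exit footprint always projects at least as large
  grid <- expand.grid(tilt = c(10, 20, 30), fs = c(6.3, 12.6),
                      g = c(0, 30, 330))
  for (i in seq_len(nrow(grid))) {
    cond <- tiny_condition(grid$tilt[i], grid$fs[i], grid$g[i])
    expect_gte(projected_area(footprint_polygon(cond, "exit")),
               projected_area(footprint_polygon(cond, "entrance")))
  }

  # monotone in tilt for fixed beam and plane
  for (fs in c(6.3, 12.6)) for (g in c(0, 330)) {
    areas <- vapply(5:30, function(tilt) {
      as.numeric(projected_area(footprint_polygon(
        tiny_condition(tilt, fs, g), "entrance")))
    }, numeric(1))
    expect_true(all(diff(areas) >= 0))
  }

  # quadratic field-size scaling at gantry 0, small tilt, unclipped
  a63 <- projected_area(footprint_polygon(tiny_condition(10, 6.3, 0), "entrance"))
  a126 <- projected_area(footprint_polygon(tiny_condition(10, 12.6, 0), "entrance"))
  expect_gt(a126 / a63, 3.8)
  expect_lt(a126 / a63, 4.4)
})

test_that("projection via vertex shoelace equals planar area times |n.y|", {
  grid <- expand.grid(tilt = c(5, 17, 30), fs = c(6.3, 12.6), g = c(0, 30))
  for (i in seq_len(nrow(grid))) {
    fp <- footprint_polygon(tiny_condition(grid$tilt[i], grid$fs[i], grid$g[i]),
                            "exit")
    a_proj <- estreamlab:::shoelace_area(fp$vertices[, c(1, 3)])
    a_cos <- estreamlab:::shoelace_area(fp$local) * abs(fp$plane$normal[2])
    expect_lt(abs(a_proj - a_cos), 1e-9 * max(1, a_cos))
    expect_equal(as.numeric(projected_area(fp)), a_proj)
  }
})

test_that("condition enumeration is complete, ordered and stable", {
  conds <- enumerate_conditions()
  expect_equal(nrow(conds), 72)
  expect_equal(nrow(dplyr::distinct(conds, condition_id)), 72)
  single <- enumerate_conditions(study_config(tilt_angles = 10,
                                              field_sizes = 6.3,
                                              gantry_angles = 0,
                                              distances = 10))
  expect_equal(nrow(single), 2)
  expect_setequal(single$panel, c("front", "end"))
  expect_identical(conds, enumerate_conditions())
})

test_that("projected_area_table reports both clip conventions per condition", {
  at <- projected_area_table()
  expect_equal(nrow(at), 36)
  expect_true(all(at$area_clipped_cm2 <= at$area_cm2 + 1e-12))
  expect_true(all(at$plane[at$panel == "front"] == "entrance"))
  expect_true(all(at$plane[at$panel == "end"] == "exit"))
})
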