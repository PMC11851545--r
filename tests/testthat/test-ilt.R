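make_box_ilt <- function(L = 0.06, lo = 0.02, hi = 0.04, h = 1e-3,
                         dirs = "outer") {
  z <- seq(0, L, by = 2.5e-3)
  H <- matrix(0, length(z), length(dirs))
  H[z >= lo & z <= hi, ] <- h
  ilt_map(z, H, dirs)
}

test_that("sectioning counts, labels and spacing contracts", {
  geom <- vessel_geometry(0.06, 0.01)
  ilt0 <- make_box_ilt(h = 0)
  sk <- section_geometry(geom, ilt0)
  expect_identical(nrow(sk), 13L)                 # 60 mm / 5 mm, inclusive
  expect_true(all(sk$group == "non-ILT"))
  expect_equal(diff(sk$z_mm), rep(5, 12))
  ilt <- make_box_ilt(lo = 0.02, hi = 0.04)
  sk2 <- section_geometry(geom, ilt)
  expect_identical(sk2$group[sk2$z_mm >= 20 & sk2$z_mm <= 40],
                   rep("ILT", 5L))
  expect_identical(sk2$group[sk2$z_mm < 20 | sk2$z_mm > 40],
                   rep("non-ILT", 8L))
  expect_error(section_geometry(geom, ilt, spacing = 0.07), "spacing")
  ## every section in exactly one group
  expect_true(all(sk2$group %in% c("ILT", "non-ILT")))
})

test_that("thrombus area reproduces the annulus closed form", {
  geom <- vessel_geometry(0.06, 0.01)
  z <- seq(0, 0.06, by = 5e-3)
  ## uniform 5 mm thickness: pi (15^2 - 10^2) mm^2
  ilt <- ilt_map(z, matrix(5e-3, length(z), 1), "outer")
  expect_equal(thrombus_area(0.03, geom, ilt), pi * (15^2 - 10^2),
               tolerance = 1e-6)
  expect_equal(thrombus_area(0.03, geom, ilt), 392.70, tolerance = 1e-4)
  ## zero thickness: zero area
  expect_identical(thrombus_area(0.03, geom, make_box_ilt(h = 0)), 0)
  ## two-direction map: hand-computed half-annulus sums to < 0.1%
  H <- cbind(upper = rep(2e-3, length(z)), lower = rep(1e-3, length(z)))
  ilt2 <- ilt_map(z, H, c("upper", "lower"))
  hand <- pi / 2 * ((12^2 - 10^2) + (11^2 - 10^2))
  expect_lt(abs(thrombus_area(0.03, geom, ilt2) / hand - 1), 1e-3)
  ## monotone in h
  areas <- sapply(c(1, 2, 4) * 1e-3, function(h)
    thrombus_area(0.03, geom, ilt_map(z, matrix(h, length(z), 1), "outer")))
  expect_true(all(diff(areas) > 0))
  ## thickness beyond the lumen radius is a data error
  big <- ilt_map(z, matrix(0.02, length(z), 1), "outer")
  expect_error(thrombus_area(0.03, geom, big), "exceeds")
})

test_that("area-NO regression recovers exact and degenerate cases", {
  tab <- data.frame(TAcNO = c(1, 2, 3), area_mm2 = c(5, 3, 1), group = "ILT")
  fit <- correlate_area_no(tab)
  expect_equal(fit$slope, -2)
  expect_equal(fit$r_squared, 1)
  expect_identical(fit$n, 3L)
  ## response independent of x: R^2 = 0, p = 1
  flat <- data.frame(TAcNO = 1:6, area_mm2 = rep(4, 6), group = "ILT")
  f0 <- correlate_area_no(flat)
  expect_equal(f0$r_squared, 0)
  expect_gte(f0$p_value, 0.999)
  expect_error(correlate_area_no(tab[1:2, ]), "at least 3")
  degen <- data.frame(TAcNO = rep(2, 4), area_mm2 = 1:4, group = "ILT")
  expect_error(correlate_area_no(degen), "degenerate")
})

test_that("group comparison handles identical fields and single sections", {
  tab <- data.frame(TAcNO = rep(7, 6), area_mm2 = c(1, 1, 1, 0, 0, 0),
                    group = rep(c("ILT", "non-ILT"), each = 3))
  g <- compare_ilt_groups(tab)
  expect_equal(g$difference, 0)
  single <- data.frame(TAcNO = c(4, 9), area_mm2 = c(2, 0),
                       group = c("ILT", "non-ILT"))
  g1 <- compare_ilt_groups(single)
  expect_equal(g1$mean_ilt, 4)
  expect_equal(g1$mean_non_ilt, 9)
  empty <- data.frame(TAcNO = c(4, 5), area_mm2 = c(2, 3), group = "ILT")
  expect_warning(g2 <- compare_ilt_groups(empty), "empty")
  expect_false(g2$complete)
})

test_that("directional analysis: symmetry, contracts and degenerate lines", {
  ## symmetric planar bulge, symmetric ILT => both directions agree
  geom <- vessel_geometry(0.06, 0.01, bulge_amplitude = 0.004,
                          bulge_width = 0.012)
  mesh <- build_mesh(geom, list(nz = 33, nr = 21, nw = 5), mode = "planar-2D")
  fl <- solve_steady(mesh, fluid_properties(), 0.1)
  no <- solve_no(mesh, fl)
  z <- seq(0, 0.06, by = 5e-3)
  H <- matrix(1e-3, length(z), 2, dimnames = list(NULL, c("upper", "lower")))
  ilt <- ilt_map(z, H, c("upper", "lower"))
  da <- directional_analysis(no, geom, ilt, section_z = c(0.02, 0.03, 0.04))
  expect_equal(da$per_section$upper, da$per_section$lower, tolerance = 5e-3)
  expect_error(directional_analysis(no, geom, ilt, section_z = c(0.02, 0.03, 0.04),
                                    line_fraction = 0), "zero-length")
  ## sections outside the thrombus support are rejected
  gap <- make_box_ilt(lo = 0.02, hi = 0.04, dirs = c("upper", "lower"))
  expect_error(directional_analysis(no, geom, gap, section_z = c(0.005, 0.025, 0.045)),
               "inside the ILT region")
  ## axisymmetric solutions lack a second direction
  no_ax <- fx_no_steady()
  ilt_ax <- make_box_ilt(L = 0.08)
  expect_error(directional_analysis(no_ax, tube_geom(), ilt_ax),
               "two wall directions")
})

test_that("representative sections fit inside a sufficient ILT region", {
  ilt <- make_box_ilt(L = 0.06, lo = 0.005, hi = 0.055)
  z <- representative_sections(ilt)
  expect_identical(length(z), 3L)
  expect_equal(diff(z), rep(0.02, 2))
  narrow <- make_box_ilt(lo = 0.025, hi = 0.035)
  expect_error(representative_sections(narrow), "no placement")
})
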