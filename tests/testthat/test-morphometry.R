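test_that("cell length follows the through-stack convention", {
  st <- cuboid_stack(n = 100)
  expect_equal(cell_length(st, "cub"), 13.0)
  st1 <- cuboid_stack(n = 1)
  expect_equal(cell_length(st1, "cub"), 0.13)
  expect_error(cell_length(st, "nope"), "not found")
})

test_that("width of a straight slab needs a single segment", {
  st <- slab_stack(w = 10, t = 0.7, n = 3)
  w <- suppressMessages(cell_width(st, "slab", "nonnuclear"))
  expect_equal(as.numeric(w), 10, tolerance = 1e-6)
  expect_error(cell_width(st, "slab", "nuclear"), "no nucleus")
})

test_that("width of a circular-arc cell lies between chord and arc length", {
  # radius 20 um spanning 28.65 degrees: arc length 10, chord 9.9585
  arc <- 10; R <- 20
  poly <- arc_ribbon_poly(R = R, arc = arc, t = 0.7)
  st <- section_stack(list(section(0, list(contour("IW_CELL", "c", poly)))))
  w <- as.numeric(suppressMessages(cell_width(st, "c", "nonnuclear")))
  chord <- 2 * R * sin(arc / (2 * R))
  expect_gte(w, chord - 0.01)
  expect_lte(w, arc + 0.01)
  expect_gt(w, 9.96)
})

test_that("nuclear width and thickness are taken at the largest nuclear section", {
  g <- generate_cell(demo_cell_spec())
  st <- g$stack
  wn <- cell_width(st, "c1", "nuclear")
  expect_equal(as.numeric(wn), g$truth$cell$nuclear_width,
               tolerance = 0.021)
  # the chosen section is the nucleus centre, where its profile peaks
  nuc_z <- sort(unique(vapply(stack_contours(st, label = "NUCLEUS"),
                              `[[`, integer(1), "section")))
  expect_equal(attr(wn, "sections"), nuc_z[which.max(vapply(nuc_z,
    function(z) {
      ct <- Filter(function(h) h$section == z,
                   stack_contours(st, label = "NUCLEUS"))[[1]]
      polygon_area(ct$contour$points)
    }, numeric(1)))])
  tn <- cell_thickness(st, "c1", "nuclear")
  expect_equal(as.numeric(tn), g$truth$cell$nuclear_thickness,
               tolerance = 0.05 * g$truth$cell$nuclear_thickness)
})

test_that("thickness of a uniform slab and of a curved shell is recovered", {
  st <- slab_stack(w = 10, t = 0.70, n = 3)
  expect_equal(as.numeric(suppressMessages(
    cell_thickness(st, "slab", "nonnuclear"))), 0.70, tolerance = 1e-6)
  # curved shell of constant radial thickness 0.62
  poly <- arc_ribbon_poly(R = 20, arc = 10, t = 0.62)
  stc <- section_stack(list(section(0, list(contour("IW_CELL", "c", poly)))))
  expect_equal(as.numeric(suppressMessages(
    cell_thickness(stc, "c", "nonnuclear"))), 0.62, tolerance = 0.02)
})

test_that("thickness sampling skips sections holding the nucleus or a vacuole", {
  g <- generate_cell(demo_cell_spec())
  st <- g$stack
  th <- suppressMessages(cell_thickness(st, "c1", "nonnuclear"))
  zs <- attr(th, "sections")
  busy <- sort(unique(vapply(
    c(stack_contours(st, label = "NUCLEUS"),
      stack_contours(st, label = "GV")),
    `[[`, integer(1), "section")))
  expect_length(intersect(zs, busy), 0L)
  expect_equal(as.numeric(th), g$truth$cell$nonnuclear_thickness,
               tolerance = 0.05 * g$truth$cell$nonnuclear_thickness)
})

test_that("cell volume subtracts vacuole volumes from the envelope", {
  # cuboid 10 x 5 x 2.6: 130 um^3, against the voxel-count oracle
  st <- cuboid_stack(w = 10, d = 5, n = 20)
  v <- cell_volume(st, "cub")
  expect_equal(as.numeric(v), 130, tolerance = 130 * 0.001)
  vox <- voxel_volume(st, "cub")
  expect_lt(abs(as.numeric(v) - vox) / vox, 0.02)
  expect_equal(attr(v, "envelope"), as.numeric(v))  # no vacuoles

  # subtraction arithmetic: envelope 100, vacuoles 30 -> 70
  n <- 10
  secs <- lapply(0:(n - 1L), function(z)
    section(z, list(
      contour("IW_CELL", "c", rect_poly(20, 20 + 100 / (n * 0.13), 20, 21)),
      contour("GV", "g",
              rect_poly(22, 22 + 30 / (n * 0.13 * 0.8), 20.1, 20.9)))))
  st2 <- section_stack(secs, field_width = 141)
  expect_equal(as.numeric(cell_volume(st2, "c")), 70, tolerance = 1e-9)

  # vacuole traced outside the envelope -> inconsistency error
  secs3 <- lapply(0:4, function(z)
    section(z, list(contour("IW_CELL", "c", rect_poly(30, 32, 20, 22)),
                    contour("GV", "g", rect_poly(28, 34, 18, 24)))))
  expect_error(cell_volume(section_stack(secs3), "c"), "negative")
})

test_that("vacuole volume is the section sum of contour areas", {
  # one circular contour r = 1 -> pi * 0.13
  st <- section_stack(list(section(0, list(
    contour("GV", "g", ngon_poly(256, 1, 70, 20))))))
  expect_equal(gv_volume(st, "g"), pi * 0.13, tolerance = 1e-3)
  # rasterized sphere r = 1 -> 4 pi / 3 within 5%
  sph <- sphere_stack(r = 1)
  expect_equal(gv_volume(sph, "gv1"), 4 * pi / 3,
               tolerance = 0.05 * 4 * pi / 3)
  expect_error(gv_volume(st, "nope"), "not found")
  # additivity over disjoint vacuoles
  st2 <- section_stack(list(section(0, list(
    contour("GV", "a", ngon_poly(64, 0.8, 60, 20)),
    contour("GV", "b", ngon_poly(64, 0.5, 70, 20))))))
  expect_equal(gv_volume(st2, "a") + gv_volume(st2, "b"),
               (pi * 0.8^2 + pi * 0.5^2) * 0.13 *
                 (32 / pi) * sin(pi / 32), tolerance = 1e-9)
  # open contour -> error
  st3 <- section_stack(list(section(0, list(
    contour("GV", "g", rbind(c(1, 1), c(2, 1), c(2, 2)), closed = FALSE)))))
  expect_error(gv_volume(st3, "g"), "open contour")
})

test_that("overlap honours the 45-degree rule with an inclusive boundary", {
  # junction parallel to the axis, extent 0.30 -> 0.30
  st0 <- angled_junction_stack(ol = 0.30, angle_deg = 0)
  olp <- suppressMessages(overlap_profile(st0, "slab"))
  expect_equal(olp$samples$ol[1], 0.30, tolerance = 0.02)
  # 50 degrees -> not counted
  st50 <- angled_junction_stack(ol = 0.30, angle_deg = 50)
  expect_equal(suppressMessages(
    overlap_profile(st50, "slab"))$samples$ol[1], 0)
  # exactly 45 degrees -> counted (inclusive)
  st45 <- angled_junction_stack(ol = 0.30, angle_deg = 45)
  ol45 <- suppressMessages(overlap_profile(st45, "slab"))$samples$ol[1]
  expect_gt(ol45, 0.30)  # ramp length = 0.3 * sqrt(2) along 45 degrees
})

test_that("overlap at B-pores measures, not asserts", {
  # generated pore: zero on both flanks
  g <- generate_cell(demo_cell_spec())
  pid <- g$truth$bpores$bpore_id[1]
  r <- overlap_at_bpore(g$stack, "c1", pid)
  expect_equal(r$before, 0)
  expect_equal(r$after, 0)
  expect_false(r$partial)

  # deliberately inconsistent fixture: overlap 0.2 flanks the pore marker
  mk_sec <- function(z, pore = FALSE) {
    cts <- list(contour("IW_CELL", "c", rect_poly(30, 40, 20, 20.7)))
    if (pore) {
      cts <- c(cts, list(
        contour("BPORE_OPENING", "bp", rect_poly(40.05, 40.2, 20.2, 20.5)),
        contour("ADJACENT_IW_CELL", "adj",
                rect_poly(40.3, 42, 20, 20.7))))
    } else {
      cts <- c(cts, list(
        contour("ADJACENT_IW_CELL", "adj",
                rect_poly(39.8, 42, 20.7, 20.95))))
    }
    section(z, cts)
  }
  st <- section_stack(lapply(0:4, function(z) mk_sec(z, pore = z == 2)))
  r2 <- overlap_at_bpore(st, "c", "bp")
  expect_equal(r2$before, 0.2, tolerance = 0.02)
  expect_equal(r2$after, 0.2, tolerance = 0.02)

  # pore on the first section: "before" side flagged missing
  st3 <- section_stack(lapply(0:3, function(z) mk_sec(z, pore = z == 0)))
  r3 <- overlap_at_bpore(st3, "c", "bp")
  expect_true(r3$partial)
  expect_true(is.na(r3$before))
  expect_equal(r3$after, 0.2, tolerance = 0.02)
})

test_that("measurements are invariant under rigid in-plane motion", {
  g <- generate_cell(demo_cell_spec())
  st <- g$stack
  st2 <- transform_stack(st, angle = 0.4, dx = 6, dy = 9)
  expect_equal(cell_length(st2, "c1"), cell_length(st, "c1"))
  expect_equal(as.numeric(suppressMessages(cell_width(st2, "c1",
                                                      "nonnuclear"))),
               as.numeric(suppressMessages(cell_width(st, "c1",
                                                      "nonnuclear"))),
               tolerance = 0.01)
  expect_equal(as.numeric(suppressMessages(cell_thickness(st2, "c1",
                                                          "nonnuclear"))),
               as.numeric(suppressMessages(cell_thickness(st, "c1",
                                                          "nonnuclear"))),
               tolerance = 0.01)
  expect_equal(as.numeric(cell_volume(st2, "c1")),
               as.numeric(cell_volume(st, "c1")), tolerance = 1e-6)
  expect_equal(gv_volume(st2, "c1_gv1"), gv_volume(st, "c1_gv1"),
               tolerance = 1e-9)
  o1 <- suppressMessages(overlap_profile(st, "c1"))
  o2 <- suppressMessages(overlap_profile(st2, "c1"))
  expect_equal(o2$ol_mean, o1$ol_mean, tolerance = 0.005)
})
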