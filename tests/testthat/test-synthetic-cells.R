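test_that("generation is deterministic for a fixed spec and seed", {
  sp <- demo_cell_spec(seed = 13)
  g1 <- generate_cell(sp)
  g2 <- generate_cell(sp)
  f1 <- tempfile(); f2 <- tempfile()
  write_stack(g1$stack, f1); write_stack(g2$stack, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(g1$truth, g2$truth)
  # a different seed moves the lateral wobble
  g3 <- generate_cell(demo_cell_spec(seed = 14))
  expect_false(identical(g1$stack, g3$stack))
})

test_that("opening flags map to the stated vacuole types in ground truth", {
  sp <- cell_spec("c1", "HIGH", length = 26, nonnuclear_width = 6,
                  nuclear_width = 9, nuclear_thickness = 5,
                  nonnuclear_thickness = 0.7,
                  gvs = list(
                    gv_spec(30, 1, 0.8, 1, s_center = 1),
                    gv_spec(60, 1, 0.8, 1, s_center = -1,
                            has_basal_opening = TRUE),
                    gv_spec(160, 1, 0.8, 1, s_center = 0,
                            has_basal_opening = TRUE, has_ipore = TRUE)),
                  seed = 3)
  g <- generate_cell(sp)
  expect_equal(g$truth$gvs$gv_type, c("I", "II", "IV"))
})

test_that("ground truth marks connection heights against the 0.3 um threshold", {
  sp <- cell_spec("c1", "LOW", length = 15, nonnuclear_width = 6,
                  nuclear_width = 9, nuclear_thickness = 5,
                  nonnuclear_thickness = 0.7,
                  connections = list(
                    connection_spec(1, 20, 22, -1, height = 0.25),
                    connection_spec(1, 40, 42, 1, height = 0.35)),
                  seed = 2)
  g <- generate_cell(sp)
  side <- vapply(g$truth$connections$height, function(h)
    classify_connection("IW", "process", "JCT_ECM", height = h,
                        pixel_size = NULL), integer(1))
  expect_equal(side, c(0L, 1L))  # one below, one above threshold
})

test_that("spec violations are rejected", {
  expect_error(generate_cell(cell_spec("c", "NON", length = 15,
    nonnuclear_width = 4, nuclear_width = 8,
    gvs = list(gv_spec(40, 3, 1, 1)), seed = 1)),
    "larger than the cell envelope")
  expect_error(generate_cell(cell_spec("c", "NON", length = 15,
    nonnuclear_width = 6, nuclear_width = 8,
    gvs = list(gv_spec(5, 1, 0.8, 1.5)), seed = 1)),
    "exceeds the cell span")
  expect_error(generate_cell(cell_spec("c", "NON", length = 15,
    nonnuclear_width = 6, nuclear_width = 8,
    gvs = list(gv_spec(40, 1, 0.8, 1, gv_id = "c")), seed = 1)),
    "overlapping object_ids")
  expect_error(generate_dataset(n_cells_per_area = 0), ">= 1")
})

test_that("the table1 fixture reproduces the published count structure", {
  ds <- generate_dataset(preset = "table1_fixture", seed = 1,
                         rasterize = FALSE)
  tg <- ds$truth$gvs
  expect_equal(nrow(ds$truth$cells), 45L)
  expect_equal(as.vector(table(ds$truth$cells$flow_area)), c(15L, 15L, 15L))
  expect_equal(nrow(tg), 234L)
  expect_equal(as.vector(tapply(tg$gv_id, tg$flow_area, length)[
    c("HIGH", "LOW", "NON")]), c(105L, 66L, 63L))
  expect_equal(sum(tg$n_ipores), 41L)
  expect_equal(as.vector(tapply(tg$n_ipores, tg$flow_area, sum)[
    c("HIGH", "LOW", "NON")]), c(20L, 15L, 6L))
  expect_equal(as.vector(tapply(tg$n_ipores > 0, tg$flow_area, sum)[
    c("HIGH", "LOW", "NON")]), c(20L, 14L, 6L))
  expect_equal(as.vector(table(tg$gv_type)), c(67L, 127L, 7L, 33L))
  bp <- ds$truth$bpores
  expect_equal(nrow(bp), 12L)
  expect_equal(as.vector(tapply(bp$bpore_id, bp$flow_area, length)[
    c("HIGH", "LOW", "NON")]), c(3L, 2L, 7L))
  expect_equal(length(unique(bp$cell_id)), 9L)
})

test_that("dataset generation is seed-reproducible and seeds differ", {
  d1 <- generate_dataset(n_cells_per_area = 2, seed = 9, rasterize = FALSE)
  d2 <- generate_dataset(n_cells_per_area = 2, seed = 9, rasterize = FALSE)
  d3 <- generate_dataset(n_cells_per_area = 2, seed = 10, rasterize = FALSE)
  expect_identical(d1$truth, d2$truth)
  expect_false(identical(d1$truth$cells$length, d3$truth$cells$length))
})

test_that("population draws agree with the truncated population means", {
  # Monte-Carlo oracle for the truncated-normal dimension means
  pop <- vm_population()
  ds <- generate_dataset(n_cells_per_area = 50, seed = 4, rasterize = FALSE)
  set.seed(1234)
  for (ai in 1:3) {
    area <- pop$areas[ai]
    p <- pop$length
    oracle <- mean(pmin(p$max, pmax(p$min,
                                    rnorm(2e5, p$mean[ai], p$sd[ai]))))
    drawn <- ds$truth$cells$length[ds$truth$cells$flow_area == area]
    # allow for the vacuole-capacity floor plus Monte-Carlo error at n = 50
    se <- p$sd[ai] / sqrt(length(drawn))
    expect_lt(abs(mean(drawn) - oracle), 3 * se + 3)
  }
  # vacuole counts: Poisson clamped to [1, 15]
  gp <- pop$gvs_per_cell
  for (ai in 1:3) {
    k <- table(factor(ds$truth$gvs$cell_id,
                      levels = ds$truth$cells$cell_id[
                        ds$truth$cells$flow_area == pop$areas[ai]]))
    oracle <- mean(pmin(gp$max, pmax(gp$min, rpois(2e5, gp$mean[ai]))))
    expect_lt(abs(mean(k) - oracle), 3 * sqrt(gp$mean[ai] / 50) + 0.2)
  }
})

test_that("analytic vacuole volumes match a voxel-count of the rasterization", {
  sp <- cell_spec("c1", "HIGH", length = 16, nonnuclear_width = 7,
                  nuclear_width = 9, nuclear_thickness = 5,
                  nonnuclear_thickness = 0.7,
                  gvs = list(gv_spec(25, 0.8, 0.6, 0.9, s_center = 1.2),
                             gv_spec(90, 1.6, 1.2, 1.6, s_center = -0.8)),
                  seed = 11)
  g <- generate_cell(sp)
  for (i in 1:2) {
    va <- g$truth$gvs$volume[i]
    vv <- voxel_volume(g$stack, g$truth$gvs$gv_id[i])
    expect_lt(abs(vv - va) / va, 0.05)
  }
})

test_that("B-pore construction separates the junction and keeps flanks joined", {
  g <- generate_cell(demo_cell_spec())
  st <- g$stack
  pore <- ds_id <- g$truth$bpores$bpore_id[1]
  zp <- g$truth$bpores$z_start[1]:g$truth$bpores$z_end[1]
  env <- Filter(function(h) h$section %in% zp,
                stack_contours(st, object_id = "c1"))
  adj <- Filter(function(h) h$section %in% zp,
                stack_contours(st, label = "ADJACENT_IW_CELL"))
  adj <- Filter(function(h) grepl("adjR", h$contour$object_id), adj)
  # on pore sections the borders separate by a clear gap
  for (i in seq_along(env)) {
    d <- min(vapply(seq_len(nrow(adj[[i]]$contour$points)), function(k)
      min(sqrt(rowSums(sweep(env[[i]]$contour$points, 2,
                             adj[[i]]$contour$points[k, ])^2))),
      numeric(1)))
    expect_gt(d, 0.1)
  }
  # junction annotation present on the flanking sections
  for (z in c(min(zp) - 1L, max(zp) + 1L)) {
    expect_gt(length(Filter(function(h)
      h$section == z && grepl("adjR", h$contour$object_id),
      stack_contours(st, label = "ADJACENT_IW_CELL"))), 0L)
  }
  # and ground truth records zero overlap at the pore site
  expect_true(all(g$truth$ol$ol[g$truth$ol$side == "right" &
                                abs(g$truth$ol$section - zp[1]) <= 4] == 0))
})
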