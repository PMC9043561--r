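test_that("the seven connection categories map to their type codes", {
  expect_equal(classify_connection("IW", "process", "JCT_ECM",
                                   height = 0.5), 1L)
  expect_equal(classify_connection("IW", "process", "JCT_CELL_BODY",
                                   height = 0.5), 2L)
  expect_equal(classify_connection("IW", "tongue", "JCT_GROOVE",
                                   height = 0.5), 3L)
  expect_equal(classify_connection("IW", "process", "JCT_CELL_PROCESS",
                                   height = 0.35), 4L)
  expect_equal(classify_connection("JCT", "process", "IW_CELL_BODY",
                                   height = 0.5), 5L)
  expect_equal(classify_connection("JCT", "tongue", "IW_GROOVE",
                                   height = 0.5), 6L)
  expect_equal(classify_connection("IW", "apposition", "JCT_CELL_BODY",
                                   contact_area = 0.8), 7L)
  expect_error(classify_connection("JCT", "apposition", "JCT_ECM",
                                   contact_area = 1), "unknown")
})

test_that("counting thresholds are inclusive at the stated boundaries", {
  h <- function(x) classify_connection("IW", "process", "JCT_ECM",
                                       height = x, pixel_size = NULL)
  expect_equal(vapply(c(0.29, 0.30, 0.31), h, integer(1)), c(0L, 1L, 1L))
  a <- function(x) classify_connection("IW", "apposition", "JCT_CELL_BODY",
                                       contact_area = x, pixel_size = NULL)
  expect_equal(vapply(c(0.49, 0.50), a, integer(1)), c(0L, 7L))
  # pixel-quantum rounding keeps values measured a hair under threshold
  expect_equal(h2 <- classify_connection("IW", "process", "JCT_ECM",
                                         height = 0.2995,
                                         pixel_size = 0.0101), 1L)
})

test_that("vacuole typing is the bijection on the two opening flags", {
  expect_equal(classify_gv(FALSE, FALSE), "I")
  expect_equal(classify_gv(TRUE, FALSE), "II")
  expect_equal(classify_gv(FALSE, TRUE), "III")
  expect_equal(classify_gv(TRUE, TRUE), "IV")
  combos <- expand.grid(b = c(FALSE, TRUE), i = c(FALSE, TRUE))
  expect_length(unique(classify_gv(combos$b, combos$i)), 4L)
})

test_that("beneath-vacuole counting uses span intersection and the dilated footprint", {
  # vacuole on sections 10-20 around x = 70; margin 0.5
  secs <- lapply(0:30, function(z) {
    cts <- list(contour("IW_CELL", "c", rect_poly(60, 80, 20, 20.7)))
    if (z >= 10 && z <= 20)
      cts <- c(cts, list(contour("GV", "g", ngon_poly(32, 1, 70, 20.6))))
    section(z, cts)
  })
  st <- section_stack(secs)
  conn <- function(id, z, x) data.frame(
    connection_id = id, type_code = 1L, z_start = z, z_end = z,
    anchor_x = x, anchor_y = 20, anchor_section = z,
    stringsAsFactors = FALSE)
  cons <- rbind(conn("a", 12, 70.2), conn("b", 15, 69.5),
                conn("c", 15, 74),    # 3 um outside footprint
                conn("d", 25, 70))    # outside the span
  n <- connections_beneath_gv(st, "g", cons)
  expect_equal(as.integer(n), 2L)
  expect_setequal(attr(n, "connection_ids"), c("a", "b"))
  # section mode counts laterally distant connections too
  expect_equal(as.integer(connections_beneath_gv(st, "g", cons,
                                                 mode = "section")), 3L)
})

test_that("connection ratio and percent-under-vacuole arithmetic", {
  expect_equal(connection_ratio(2, 10), 0.2)
  expect_equal(connection_ratio(0, 5), 0)
  expect_error(connection_ratio(1, 0), "undefined")
  expect_equal(percent_under_gvs(4, 10), 40)
  expect_equal(percent_under_gvs(0, 10), 0)
  expect_equal(percent_under_gvs(4, 10) + percent_under_gvs(6, 10), 100)
  expect_error(percent_under_gvs(0, 0), "zero connections")
})

test_that("generated connections are recovered with exact types and counts", {
  g <- generate_cell(demo_cell_spec())
  cc <- cell_connectivity(g$stack, "c1")
  tr <- g$truth$connections
  expect_equal(nrow(cc$connections), nrow(tr))
  mm <- merge(tr, cc$connections, by = "connection_id",
              suffixes = c(".t", ".m"))
  expect_equal(mm$type_code.m, mm$type_code.t)
  # per-type totals sum to the grand total
  tot <- sum(unlist(cc$summary[paste0("type", 1:7)]))
  expect_equal(tot, cc$summary$total)
  expect_equal(cc$summary$cell_matrix_total + cc$summary$cell_cell_total,
               cc$summary$total)
  # vacuole records: types, pore counts and beneath counts match truth
  gm <- merge(g$truth$gvs, cc$gvs, by = "gv_id", suffixes = c(".t", ".m"))
  expect_equal(gm$gv_type.m, gm$gv_type.t)
  expect_equal(gm$n_ipores.m, gm$n_ipores.t)
  expect_equal(gm$n_connections_beneath.m, gm$n_connections_beneath.t)
  expect_equal(gm$connections_per_volume,
               gm$n_connections_beneath.t / gm$volume.m)
})

test_that("a structural annotation is required to classify a trace", {
  st <- section_stack(list(section(0, list(
    contour("IW_CELL", "c", rect_poly(30, 40, 20, 20.7)),
    contour("CONNECTION_ENDPOINT", "x",
            rect_poly(34, 34.2, 19.5, 20))))))
  expect_error(extract_connections(st, "c"), "structural annotation")
})

test_that("B-pore validation accepts generator pores and flags fabricated ones", {
  g <- generate_cell(demo_cell_spec())
  pid <- g$truth$bpores$bpore_id[1]
  v <- validate_bpore(g$stack, pid, "c1")
  expect_true(v$valid)
  expect_length(v$warnings, 0L)

  # pore marker with non-zero flanking overlap: valid, but with a warning
  mk_sec <- function(z, pore = FALSE) {
    cts <- list(contour("IW_CELL", "c", rect_poly(30, 40, 20, 20.7)))
    if (pore) {
      cts <- c(cts, list(
        contour("BPORE_OPENING", "bp", rect_poly(40.05, 40.2, 20.2, 20.5)),
        contour("ADJACENT_IW_CELL", "adj", rect_poly(40.3, 42, 20, 20.7))))
    } else {
      cts <- c(cts, list(
        contour("ADJACENT_IW_CELL", "adj",
                rect_poly(39.8, 42, 20.7, 20.95))))
    }
    section(z, cts)
  }
  st <- section_stack(lapply(0:4, function(z) mk_sec(z, pore = z == 2)))
  v2 <- validate_bpore(st, "bp", "c")
  expect_true(v2$valid)
  expect_match(v2$warnings, "non-zero overlap")

  # a "pore" inside a single cell's own border is invalid
  st3 <- section_stack(lapply(0:4, function(z) section(z, list(
    contour("IW_CELL", "c", rect_poly(30, 40, 20, 20.7)),
    contour("ADJACENT_IW_CELL", "adj", rect_poly(40, 42, 20, 20.7)),
    contour("BPORE_OPENING", "bp", rect_poly(34, 34.4, 20.2, 20.5))))))
  v3 <- validate_bpore(st3, "bp", "c")
  expect_false(v3$valid)
  expect_match(v3$warnings, "inside a single cell")
})
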