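make_records <- function(n_cells, n_gvs, n_gv_ip, n_ip, area) {
  cells <- data.frame(cell_id = sprintf("%s%02d", area, seq_len(n_cells)),
                      flow_area = area, stringsAsFactors = FALSE)
  gvs <- NULL
  if (n_gvs > 0) {
    owner <- rep_len(cells$cell_id, n_gvs)
    nip <- integer(n_gvs)
    if (n_gv_ip > 0) {
      nip[seq_len(n_gv_ip)] <- 1L
      extra <- n_ip - n_gv_ip
      if (extra > 0) nip[seq_len(extra)] <- nip[seq_len(extra)] + 1L
    }
    gvs <- data.frame(gv_id = sprintf("%s_gv%03d", area, seq_len(n_gvs)),
                      cell_id = owner, n_ipores = nip,
                      stringsAsFactors = FALSE)
  }
  list(cells = cells, gvs = gvs)
}

test_that("flow-area summary reproduces the per-area count arithmetic", {
  hi <- make_records(15, 105, 20, 20, "HIGH")
  lo <- make_records(15, 66, 14, 15, "LOW")
  no <- make_records(15, 63, 6, 6, "NON")
  cells <- rbind(hi$cells, lo$cells, no$cells)
  gvs <- rbind(hi$gvs, lo$gvs, no$gvs)
  sm <- summarize_flow_areas(cells, gvs)
  expect_equal(round(sm$mean_gvs_per_cell, 1), c(7.0, 4.4, 4.2, 5.2))
  expect_equal(round(sm$pct_gvs_with_ipores, 1), c(19.0, 21.2, 9.5, 17.1))
  expect_equal(sm$n_ipores, c(20L, 15L, 6L, 41L))
  # counts conservation: per-area rows sum to the overall row
  for (cl in c("n_cells", "n_gvs", "n_ipores", "n_gvs_with_ipores",
               "n_bpores", "n_cells_with_bpore"))
    expect_equal(sum(sm[[cl]][1:3]), sm[[cl]][4])
  expect_error(summarize_flow_areas(data.frame(cell_id = "x",
                                               flow_area = NA)),
               "flow-area label")
})

test_that("an area without vacuoles reports zero percentage, flagged", {
  cells <- data.frame(cell_id = c("a", "b"), flow_area = c("HIGH", "LOW"),
                      stringsAsFactors = FALSE)
  gvs <- data.frame(gv_id = "g1", cell_id = "a", n_ipores = 1L,
                    stringsAsFactors = FALSE)
  sm <- summarize_flow_areas(cells, gvs)
  non <- sm[sm$flow_area == "NON", ]
  expect_equal(non$pct_gvs_with_ipores, 0)
  expect_false(non$pct_defined)
})

test_that("vacuole type distribution percentages match the count quotients", {
  types <- c(rep("I", 67), rep("II", 127), rep("III", 7), rep("IV", 33))
  gd <- gv_type_distribution(types)
  expect_equal(gd$n, c(67L, 127L, 7L, 33L))
  expect_equal(gd$pct_printed, c(28.6, 54.3, 3.0, 14.1))
  expect_equal(sum(gd$n), 234L)
  empty <- gv_type_distribution(character(0))
  expect_equal(empty$n, rep(0L, 4))
  expect_equal(empty$pct, rep(0, 4))
})

test_that("ANOVA handles identical groups and clear separation", {
  r <- compare_by_flow_area(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"),
                                                    each = 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(31)
  x <- c(rnorm(15), rnorm(15, 100))
  g <- rep(c("a", "b"), each = 15)
  expect_lt(compare_by_flow_area(x, g)$p_value, 1e-6)
  expect_warning(compare_by_flow_area(rep(1, 9), rep(c("a", "b", "c"), 3)),
                 "degenerate")
  expect_error(compare_by_flow_area(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("ANOVA and Tukey match the closed-form oracle on seeded fixtures", {
  set.seed(101)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    n <- sample(5:20, k, replace = TRUE)
    x <- unlist(lapply(seq_len(k), function(i)
      rnorm(n[i], mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))))
    g <- rep(letters[seq_len(k)], times = n)
    got <- compare_by_flow_area(x, g)
    ora <- anova_oracle(x, g)
    expect_equal(got$statistic, unname(ora$f), tolerance = 1e-10)
    expect_equal(got$p_value, unname(ora$p), tolerance = 1e-10)
    expect_equal(stats::setNames(got$pairwise$p_adj,
                                 got$pairwise$comparison),
                 ora$tukey[got$pairwise$comparison], tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis and Wilcoxon match hand oracles on seeded fixtures", {
  set.seed(202)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    n <- sample(c(5:15, 25), k, replace = TRUE)
    tie <- rep %% 2 == 0
    x <- unlist(lapply(seq_len(k), function(i) {
      v <- rnorm(n[i], mean = runif(1, -1, 1))
      if (tie) round(v, 1) else v
    }))
    g <- rep(letters[seq_len(k)], times = n)
    got <- compare_ratios_by_gv_type(x, g)
    ora <- kruskal_oracle(x, g)
    expect_equal(got$statistic, ora$h, tolerance = 1e-10)
    expect_equal(got$p_value, ora$p, tolerance = 1e-10)
    for (i in seq_len(nrow(got$pairwise))) {
      pr <- strsplit(got$pairwise$comparison[i], "-")[[1]]
      expect_equal(got$pairwise$p_value[i],
                   wilcox_oracle(x[g == pr[1]], x[g == pr[2]]),
                   tolerance = 1e-10)
    }
  }
})

test_that("ratio comparison reports medians/IQR and a generated effect", {
  r0 <- compare_ratios_by_gv_type(rep(1:5, 4), rep(c("I", "II", "III",
                                                     "IV"), each = 5))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_named(r0$group_summary,
               c("group", "n", "median", "iqr_low", "iqr_high"))
  # stochastically lower type-IV ratios at n = 30/group
  set.seed(77)
  x <- c(rlnorm(30, log(0.3), 0.5), rlnorm(30, log(0.05), 0.5))
  g <- rep(c("I", "IV"), each = 30)
  r1 <- compare_ratios_by_gv_type(x, g)
  expect_lt(r1$pairwise$p_value[1], 0.05)
  expect_lt(r1$group_summary$median[r1$group_summary$group == "IV"],
            r1$group_summary$median[r1$group_summary$group == "I"])
  expect_warning(compare_ratios_by_gv_type(c(1, 2, 3, NA),
                                           factor(c("a", "a", "b", "c"),
                                                  levels = c("a", "b",
                                                             "c"))),
                 "empty group")
})

test_that("report rendering is deterministic and reports gaps", {
  hi <- make_records(15, 105, 20, 20, "HIGH")
  lo <- make_records(15, 66, 14, 15, "LOW")
  no <- make_records(15, 63, 6, 6, "NON")
  cells <- rbind(hi$cells, lo$cells, no$cells)
  gvs <- rbind(hi$gvs, lo$gvs, no$gvs)
  sm <- summarize_flow_areas(cells, gvs)
  res <- list(table1 = as.data.frame(sm),
              gv_types = gv_type_distribution(
                c(rep("I", 67), rep("II", 127), rep("III", 7),
                  rep("IV", 33))))
  d1 <- tempfile(); d2 <- tempfile()
  render_report(res, d1)
  render_report(res, d2)
  t1 <- utils::read.csv(file.path(d1, "table1.csv"))
  overall <- t1[t1$flow_area == "Overall", ]
  expect_equal(overall$n_cells, 45L)
  expect_equal(overall$n_gvs, 234L)
  expect_equal(round(overall$mean_gvs_per_cell, 1), 5.2)
  expect_equal(overall$n_ipores, 41L)
  expect_equal(round(overall$pct_gvs_with_ipores, 1), 17.1)
  # byte-identical re-run
  for (f in c("table1.csv", "gv_types.csv", "summary.txt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # gaps listed for missing components
  expect_match(paste(readLines(file.path(d1, "summary.txt")),
                     collapse = " "), "missing components")
  # empty tables give headers-only files
  d3 <- tempfile()
  render_report(list(table1 = sm[0, ]), d3)
  expect_length(readLines(file.path(d3, "table1.csv")), 1L)
})
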