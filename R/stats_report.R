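# Flow-area summary tables and comparison statistics: one-way ANOVA with
# Tukey HSD for per-cell metrics, Kruskal-Wallis with pairwise Wilcoxon
# rank-sum for beneath-vacuole connection ratios by vacuole type.

.vm_area_levels <- c("HIGH", "LOW", "NON")

.vm_sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Flow-area summary of giant vacuoles and pores
#'
#' One row per flow area plus an overall row: cell and vacuole counts, mean
#' vacuoles per cell (with SEM), I-pore counts and per-cell means, vacuoles
#' with at least one I-pore (count and percentage of vacuoles), B-pore counts
#' (deduplicated by pore id) and cells carrying at least one B-pore. All
#' columns are exact counts or full-precision means; the print method rounds
#' to the conventional one decimal.
#'
#' @param cells Data frame with `cell_id` and `flow_area` (one row per cell).
#' @param gvs Data frame with `gv_id`, `cell_id` and either `n_ipores` or
#'   `has_ipore`; `NULL` for none.
#' @param bpores Data frame with `bpore_id` and `cell_id`; `NULL` for none.
#' @return Data frame of class `vm_flow_summary`. Areas with no vacuoles get
#'   a zero percentage flagged by `pct_defined = FALSE`.
#' @export
summarize_flow_areas <- function(cells, gvs = NULL, bpores = NULL) {
  if (any(is.na(cells$flow_area)) ||
      !all(cells$flow_area %in% .vm_area_levels))
    stop("every cell must carry a HIGH/LOW/NON flow-area label")
  if (!is.null(gvs) && nrow(gvs)) {
    gvs <- merge(gvs, cells[, c("cell_id", "flow_area")], by = "cell_id",
                 suffixes = c(".x", ""))
    if (!"n_ipores" %in% names(gvs))
      gvs$n_ipores <- as.integer(gvs$has_ipore)
  }
  if (!is.null(bpores) && nrow(bpores)) {
    bpores <- bpores[!duplicated(bpores$bpore_id), , drop = FALSE]
    bpores <- merge(bpores, cells[, c("cell_id", "flow_area")],
                    by = "cell_id", suffixes = c(".x", ""))
  }
  row_for <- function(area) {
    cc <- cells[cells$flow_area %in% area, , drop = FALSE]
    gg <- if (!is.null(gvs) && nrow(gvs))
      gvs[gvs$flow_area %in% area, , drop = FALSE] else NULL
    bb <- if (!is.null(bpores) && nrow(bpores))
      bpores[bpores$flow_area %in% area, , drop = FALSE] else NULL
    n_gv_per_cell <- vapply(cc$cell_id, function(id)
      if (is.null(gg)) 0L else sum(gg$cell_id == id), integer(1))
    n_gvs <- sum(n_gv_per_cell)
    n_ip <- if (is.null(gg)) 0L else sum(gg$n_ipores)
    n_gv_ip <- if (is.null(gg)) 0L else sum(gg$n_ipores > 0L)
    data.frame(
      flow_area = if (length(area) > 1L) "Overall" else area,
      n_cells = nrow(cc),
      n_gvs = n_gvs,
      mean_gvs_per_cell = mean(n_gv_per_cell),
      sem_gvs_per_cell = .vm_sem(n_gv_per_cell),
      n_ipores = n_ip,
      ipores_per_cell = n_ip / nrow(cc),
      n_gvs_with_ipores = n_gv_ip,
      pct_gvs_with_ipores = if (n_gvs > 0) 100 * n_gv_ip / n_gvs else 0,
      pct_defined = n_gvs > 0,
      n_bpores = if (is.null(bb)) 0L else nrow(bb),
      n_cells_with_bpore = if (is.null(bb)) 0L
                           else length(unique(bb$cell_id)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(lapply(.vm_area_levels, row_for),
                          list(row_for(.vm_area_levels))))
  rownames(out) <- NULL
  class(out) <- c("vm_flow_summary", "data.frame")
  out
}

#' @export
print.vm_flow_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$mean_gvs_per_cell <- round(y$mean_gvs_per_cell, 1)
  y$sem_gvs_per_cell <- round(y$sem_gvs_per_cell, 1)
  y$ipores_per_cell <- round(y$ipores_per_cell, 1)
  y$pct_gvs_with_ipores <- round(y$pct_gvs_with_ipores, 1)
  y$pct_defined <- NULL
  print(y, row.names = FALSE)
  invisible(x)
}

#' Giant-vacuole type distribution
#'
#' @param gv_types Character vector of types (`"I"`-`"IV"`), or a data frame
#'   with a `gv_type` column.
#' @return Data frame with counts and percentages (full precision, plus a
#'   `pct_printed` column rounded to one decimal).
#' @export
gv_type_distribution <- function(gv_types) {
  if (is.data.frame(gv_types)) gv_types <- gv_types$gv_type
  lv <- c("I", "II", "III", "IV")
  n <- vapply(lv, function(t) sum(gv_types == t), integer(1))
  tot <- sum(n)
  pct <- if (tot > 0) 100 * n / tot else rep(0, 4)
  data.frame(gv_type = lv, n = as.integer(n), pct = pct,
             pct_printed = round(pct, 1), row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- comparison statistics ---------------------------------------------------

#' One-way ANOVA with Tukey HSD across flow areas
#'
#' @param values Numeric vector of a per-cell metric.
#' @param groups Group labels (flow areas), same length.
#' @return `list` of class `vm_comparison` with `test = "anova"`, the F
#'   statistic, p-value, per-group means, and the Tukey pairwise table.
#' @export
compare_by_flow_area <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  if (stats::var(values) < .Machine$double.eps) {
    warning("all values identical across groups; comparison degenerate")
    return(structure(list(test = "anova", statistic = NaN, p_value = NaN,
                          groups = levels(groups), pairwise = NULL,
                          group_means = tapply(values, groups, mean)),
                     class = "vm_comparison"))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL,
                         stringsAsFactors = FALSE)
  structure(list(test = "anova", statistic = tab[1, "F value"],
                 p_value = tab[1, "Pr(>F)"], groups = levels(groups),
                 pairwise = pairwise,
                 group_means = tapply(values, groups, mean),
                 group_sem = tapply(values, groups, .vm_sem)),
            class = "vm_comparison")
}

# two-sided Wilcoxon rank-sum: exact when both groups are small and tie-free,
# normal approximation with continuity correction otherwise
.vm_wilcox_pair <- function(x, y) {
  exact <- length(x) <= 20 && length(y) <= 20 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                      correct = TRUE))$p.value
}

#' Kruskal-Wallis with pairwise Wilcoxon rank-sum across vacuole types
#'
#' Ties are midranked; empty groups are dropped with a warning. Pairwise
#' Wilcoxon p-values are reported unadjusted (post-hoc convention), exact for
#' small tie-free groups and normal-approximated with continuity correction
#' when any group exceeds n = 20. Per-group medians and interquartile ranges
#' accompany the tests.
#'
#' @param values Numeric vector (e.g. beneath-vacuole connection ratios).
#' @param groups Group labels (e.g. vacuole types).
#' @return `list` of class `vm_comparison` with `test = "kruskal_wallis"`,
#'   the H statistic, p-value, pairwise table and group summaries.
#' @export
compare_ratios_by_gv_type <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- if (is.factor(groups)) groups[keep] else factor(groups[keep])
  sizes <- table(groups)
  if (any(sizes == 0L)) {
    warning("dropping empty group(s): ",
            paste(names(sizes)[sizes == 0L], collapse = ", "))
    groups <- droplevels(groups)
  }
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  kw <- stats::kruskal.test(values, groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  pairwise <- data.frame(
    comparison = apply(pairs, 2, paste, collapse = "-"),
    p_value = apply(pairs, 2, function(pr)
      .vm_wilcox_pair(values[groups == pr[1]], values[groups == pr[2]])),
    stringsAsFactors = FALSE)
  med <- tapply(values, groups, stats::median)
  iqr <- tapply(values, groups, function(v)
    stats::quantile(v, c(0.25, 0.75), names = FALSE))
  group_summary <- data.frame(
    group = lv, n = as.integer(table(groups)[lv]), median = as.numeric(med),
    iqr_low = vapply(iqr, `[`, numeric(1), 1),
    iqr_high = vapply(iqr, `[`, numeric(1), 2),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(test = "kruskal_wallis",
                 statistic = unname(kw$statistic),
                 p_value = kw$p.value, groups = lv, pairwise = pairwise,
                 group_summary = group_summary),
            class = "vm_comparison")
}

#' @export
print.vm_comparison <- function(x, ...) {
  lab <- if (x$test == "anova") "One-way ANOVA" else "Kruskal-Wallis"
  st <- if (x$test == "anova") "F" else "H"
  cat(sprintf("%s: %s = %.4g, p = %.4g\n", lab, st, x$statistic,
              x$p_value))
  if (!is.null(x$pairwise)) {
    cat(if (x$test == "anova") "Tukey HSD pairwise:\n"
        else "Pairwise Wilcoxon rank-sum (unadjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

# ---- report rendering --------------------------------------------------------

.vm_flatten_comparison <- function(name, cmp) {
  main <- data.frame(metric = name, test = cmp$test,
                     statistic = cmp$statistic, p_value = cmp$p_value,
                     comparison = "overall", stringsAsFactors = FALSE)
  if (is.null(cmp$pairwise)) return(main)
  pw <- cmp$pairwise
  pcol <- if ("p_adj" %in% names(pw)) pw$p_adj else pw$p_value
  rbind(main,
        data.frame(metric = name, test = paste0(cmp$test, "_posthoc"),
                   statistic = NA_real_, p_value = pcol,
                   comparison = pw$comparison, stringsAsFactors = FALSE))
}

#' Render the analysis report to CSV tables
#'
#' Writes machine-readable tables (flow-area summary, vacuole type
#' distribution, per-cell dimensions, connections by type, beneath-vacuole
#' connection data, overlap data, and the statistical tests) plus a plain-text
#' summary, with deterministic row ordering. Missing components are skipped
#' and listed as gaps in the summary.
#'
#' @param results Named list with any of `table1`, `gv_types`, `dimensions`,
#'   `connections_by_type`, `gv_connections`, `overlap` (data frames) and
#'   `stats` (named list of `vm_comparison` objects).
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  gaps <- character(0)
  emit <- function(name, df) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  for (nm in c("table1", "gv_types", "dimensions", "connections_by_type",
               "gv_connections", "overlap")) {
    df <- results[[nm]]
    if (is.null(df)) { gaps <- c(gaps, nm); next }
    df <- as.data.frame(df)
    ord <- do.call(order, df[, intersect(c("flow_area", "cell_id", "gv_id",
                                           "gv_type", "section"),
                                         names(df)), drop = FALSE])
    if (length(ord)) df <- df[ord, , drop = FALSE]
    emit(nm, df)
  }
  if (!is.null(results$stats)) {
    st <- do.call(rbind, lapply(names(results$stats), function(nm)
      .vm_flatten_comparison(nm, results$stats[[nm]])))
    st <- st[order(st$metric, st$test, st$comparison), , drop = FALSE]
    emit("stats", st)
  } else gaps <- c(gaps, "stats")
  summary_path <- file.path(dir, "summary.txt")
  con <- file(summary_path, "wb")
  lines <- c("vacuomorph analysis report",
             paste0("tables: ", paste(basename(files), collapse = ", ")),
             if (length(gaps)) paste0("missing components: ",
                                      paste(gaps, collapse = ", "))
             else "all components present")
  writeLines(lines, con)
  close(con)
  invisible(c(files, summary_path))
}
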