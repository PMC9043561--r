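# Population-level dataset generation: draws per-cell parameters from
# flow-area-specific distributions, lays out giant vacuoles, connections and
# pores inside each cell, and (optionally) rasterizes every cell.

#' Default per-flow-area population parameters
#'
#' Dimension distributions are normal with the reported per-area means and a
#' standard deviation of SEM * sqrt(15) (the reported cohorts had 15 cells per
#' area); per-cell giant-vacuole and connection counts are Poisson with the
#' reported per-area means; giant-vacuole type proportions follow the overall
#' type distribution apportioned per area so that the per-area
#' vacuoles-with-pore fractions are respected. Sizes of vacuoles are a
#' modelling choice (log-normal radii, pore-bearing types drawn larger), since
#' only medians/IQRs of derived ratios are reported for them.
#'
#' @return A named list of population parameters, one element per quantity,
#'   each with components for the HIGH, LOW and NON flow areas.
#' @export
vm_population <- function() {
  list(
    areas = c("HIGH", "LOW", "NON"),
    length = list(mean = c(70.76, 108.56, 79.68),
                  sd = c(4.78, 9.68, 6.38) * sqrt(15), min = 30, max = 135),
    nuclear_width = list(mean = c(10.05, 12.41, 9.06),
                         sd = c(0.73, 1.03, 0.82) * sqrt(15),
                         min = 6, max = 18),
    nonnuclear_width = list(mean = c(5.72, 6.90, 4.18),
                            sd = c(0.56, 0.45, 0.30) * sqrt(15),
                            min = 2.8, max = 11),
    nuclear_thickness = list(mean = c(6.19, 4.50, 7.07),
                             sd = c(0.67, 0.38, 1.08) * sqrt(15),
                             min = 2.6, max = 9),
    nonnuclear_thickness = list(mean = c(0.68, 0.62, 0.75),
                                sd = c(0.08, 0.04, 0.07) * sqrt(15),
                                min = 0.45, max = 1.05),
    gvs_per_cell = list(mean = c(7.0, 4.4, 4.2), min = 1, max = 15),
    # per-area type proportions (I, II, III, IV); rows sum to 1
    gv_type_prob = rbind(
      HIGH = c(25, 60, 2, 18) / 105,
      LOW  = c(12, 40, 3, 11) / 66,
      NON  = c(30, 27, 2, 4) / 63),
    gv_radius = list(meanlog = log(0.9), sdlog = 0.35, pore_scale = 1.5,
                     min = 0.5, max = 2.2),
    # mean connections per cell by type (rows) and flow area (columns)
    connections = cbind(
      HIGH = c(18.5, 1.2, 0.1, 3.3, 2.8, 0.4, 0.3),
      LOW  = c(15.7, 2.9, 0.7, 9.9, 13.5, 0.5, 1.8),
      NON  = c(33.1, 4.5, 0.5, 9.0, 10.1, 0.5, 1.4)),
    height = list(min = 0.35, max = 1.2),
    contact_area = list(min = 0.55, max = 1.6),
    frac_under_gv = c(0.446, 0.412, 0.316),
    overlap = list(mean = c(0.18, 0.29, 0.23),
                   sd = c(0.03, 0.05, 0.03) * sqrt(15),
                   min = 0.06, max = 0.6),
    p_bpore = c(0.2, 0.133, 0.267),
    curvature_radius = 120
  )
}

.vm_rtnorm <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

# sample k elements of x (safe for length-1 x)
.vm_sample <- function(x, k = 1L) x[sample.int(length(x), k)]

# lay out GVs, connections and pores for one cell; returns a vm_cell_spec.
# `plan` carries everything drawn/fixed upstream.
.vm_assemble_spec <- function(plan, tsec = 0.13) {
  n <- as.integer(round(plan$length / tsec))
  w <- plan$nonnuclear_width
  g <- length(plan$gv_types)
  zc_n <- floor(n / 2)
  cns <- max(4, round(min(5, 0.12 * plan$length) / tsec))

  # z-disjoint slots for the vacuoles, outside the nuclear span
  blocks <- rbind(c(10, zc_n - cns - 10), c(zc_n + cns + 10, n - 11))
  blocks <- blocks[blocks[, 2] - blocks[, 1] > 20, , drop = FALSE]
  gvs <- list()
  gv_ids <- character(0)
  if (g > 0) {
    if (!nrow(blocks)) stop("cell too short to place giant vacuoles")
    cap <- blocks[, 2] - blocks[, 1]
    alloc <- round(cap / sum(cap) * g)
    alloc[1] <- g - sum(alloc[-1])
    slot_list <- list()
    for (bi in seq_len(nrow(blocks))) {
      k <- alloc[bi]
      if (k <= 0) next
      edges <- round(seq(blocks[bi, 1], blocks[bi, 2], length.out = k + 1))
      for (j in seq_len(k))
        slot_list[[length(slot_list) + 1L]] <- c(edges[j], edges[j + 1])
    }
    for (i in seq_len(g)) {
      slot <- slot_list[[i]]
      half <- (slot[2] - slot[1]) / 2
      cmax <- half * tsec - 0.45
      ty <- plan$gv_types[i]
      b <- plan$gv_radii[i]
      b <- min(b, cmax / 1.15, (w / 2 - 0.45) / 1.35)
      b <- max(b, 0.5)
      a <- 1.3 * b
      cz <- min(cmax, 1.5 * b)
      if (cz < 1.1 * b) cz <- 1.1 * b
      if (cz > cmax) stop("giant-vacuole slot too small; cell too short")
      smax <- w / 2 - a - 0.25
      sc <- stats::runif(1, -smax, smax)
      gid <- paste0(plan$cell_id, "_gv", i)
      gvs[[i]] <- gv_spec(center_section = round(mean(slot)),
                          semi_lateral = a, semi_radial = b, semi_axial = cz,
                          s_center = sc,
                          has_basal_opening = ty %in% c("II", "IV"),
                          has_ipore = ty %in% c("III", "IV"),
                          n_ipores = plan$gv_ipores[i], gv_id = gid)
      gv_ids[i] <- gid
    }
  }

  # connection placement: under-GV anchors live inside a vacuole's footprint
  # and span; free anchors use sections clear of every vacuole span
  types <- rep(1:7, times = plan$conn_counts)
  types <- .vm_sample(types, length(types))
  n_conn <- length(types)
  n_under <- min(round(plan$frac_under * n_conn), sum(types != 7L))
  under_pool <- which(types != 7L)
  under_idx <- if (n_under > 0 && g > 0)
    sort(.vm_sample(under_pool, n_under)) else integer(0)
  gv_spans <- if (g > 0) t(vapply(gvs, function(gv) {
    czs <- gv$semi_axial / tsec
    c(floor(gv$center_section - czs), ceiling(gv$center_section + czs))
  }, numeric(2))) else matrix(numeric(0), 0, 2)
  blocked <- rep(FALSE, n)
  if (g > 0) for (i in seq_len(g)) {
    lo <- max(0, gv_spans[i, 1] - 3); hi <- min(n - 1, gv_spans[i, 2] + 3)
    blocked[(lo:hi) + 1L] <- TRUE
  }
  free_z <- which(!blocked) - 1L
  free_z <- free_z[free_z >= 4 & free_z <= n - 5]
  conns <- list()
  gv_assign <- if (length(under_idx)) {
    pool <- rep_len(seq_len(g), length(under_idx))
    .vm_sample(pool, length(pool))
  } else integer(0)
  ui <- 0L
  for (i in seq_len(n_conn)) {
    ty <- types[i]
    cid <- paste0(plan$cell_id, "_cn", i)
    if (i %in% under_idx) {
      ui <- ui + 1L
      gi <- gv_assign[ui]
      gv <- gvs[[gi]]
      span <- gv_spans[gi, ]
      inner <- round(span + c(1, -1) * max(2, diff(span) * 0.2))
      zc <- .vm_sample(seq(inner[1], inner[2]))
      sa <- gv$s_center + stats::runif(1, -0.6, 0.6) * gv$semi_lateral
      conns[[i]] <- connection_spec(ty, max(span[1] + 1, zc - 1),
                                    min(span[2] - 1, zc + 1), sa,
                                    height = stats::runif(1, plan$h_rng[1],
                                                          plan$h_rng[2]),
                                    under_gv = gv_ids[gi],
                                    connection_id = cid)
    } else {
      zpool <- free_z[free_z > 2 & free_z < n - 3]
      zc <- if (length(zpool)) .vm_sample(zpool) else 5L
      if (ty == 7L) {
        area <- stats::runif(1, plan$a_rng[1], plan$a_rng[2])
        lmax <- max(0.8, 0.6 * w - 0.5)
        k <- max(3L, as.integer(ceiling(area / (tsec * lmax))))
        len <- area / (k * tsec)
        smax <- w / 2 - len / 2 - 0.3
        sa <- stats::runif(1, -smax, smax)
        conns[[i]] <- connection_spec(ty, zc - (k - 1L) %/% 2L,
                                      zc + k %/% 2L, sa,
                                      contact_area = area,
                                      connection_id = cid)
      } else {
        sa <- stats::runif(1, -(w / 2 - 0.8), w / 2 - 0.8)
        conns[[i]] <- connection_spec(ty, zc - 1L, zc + 1L, sa,
                                      height = stats::runif(1, plan$h_rng[1],
                                                            plan$h_rng[2]),
                                      connection_id = cid)
      }
    }
  }

  # B-pore sites, spaced along z
  bp <- list()
  if (plan$n_bpores > 0) {
    zcand <- seq(30, n - 32)
    for (j in seq_len(plan$n_bpores)) {
      if (!length(zcand)) break
      zpick <- .vm_sample(zcand)
      zcand <- zcand[abs(zcand - zpick) > 12]
      bp[[j]] <- list(side = .vm_sample(c(-1, 1)), z = as.integer(zpick))
    }
  }

  cell_spec(cell_id = plan$cell_id, flow_area = plan$flow_area,
            length = plan$length, nuclear_width = plan$nuclear_width,
            nonnuclear_width = plan$nonnuclear_width,
            nuclear_thickness = plan$nuclear_thickness,
            nonnuclear_thickness = plan$nonnuclear_thickness,
            curvature_radius = plan$curvature_radius,
            gvs = gvs, connections = conns,
            overlap_left = plan$ol[1], overlap_right = plan$ol[2],
            bpores = bp, seed = plan$seed)
}

# draw one cell's plan from the population
.vm_draw_plan <- function(pop, ai, cell_id, flow_area, gv_count = NULL,
                          gv_types = NULL, gv_ipores = NULL,
                          n_bpores = NULL) {
  if (is.null(gv_count)) {
    gp <- pop$gvs_per_cell
    gv_count <- min(gp$max, max(gp$min, stats::rpois(1, gp$mean[ai])))
  }
  if (is.null(gv_types)) {
    gv_types <- sample(c("I", "II", "III", "IV"), gv_count, replace = TRUE,
                       prob = pop$gv_type_prob[ai, ])
  }
  if (is.null(gv_ipores))
    gv_ipores <- as.integer(gv_types %in% c("III", "IV"))
  gr <- pop$gv_radius
  radii <- stats::rlnorm(gv_count, gr$meanlog, gr$sdlog)
  radii[gv_types %in% c("III", "IV")] <-
    radii[gv_types %in% c("III", "IV")] * gr$pore_scale
  radii <- pmin(gr$max, pmax(gr$min, radii))
  conn_counts <- stats::rpois(7, pop$connections[, ai])
  if (is.null(n_bpores))
    n_bpores <- stats::rbinom(1, 1, pop$p_bpore[ai])
  len <- .vm_rtnorm(1, pop$length$mean[ai], pop$length$sd[ai],
                    pop$length$min, pop$length$max)
  len <- max(len, 16 + 3.4 * gv_count)
  wnn <- .vm_rtnorm(1, pop$nonnuclear_width$mean[ai],
                    pop$nonnuclear_width$sd[ai],
                    pop$nonnuclear_width$min, pop$nonnuclear_width$max)
  wnu <- max(wnn + 1,
             .vm_rtnorm(1, pop$nuclear_width$mean[ai],
                        pop$nuclear_width$sd[ai],
                        pop$nuclear_width$min, pop$nuclear_width$max))
  list(cell_id = cell_id, flow_area = flow_area, length = len,
       nuclear_width = wnu, nonnuclear_width = wnn,
       nuclear_thickness = .vm_rtnorm(1, pop$nuclear_thickness$mean[ai],
                                      pop$nuclear_thickness$sd[ai],
                                      pop$nuclear_thickness$min,
                                      pop$nuclear_thickness$max),
       nonnuclear_thickness = .vm_rtnorm(1, pop$nonnuclear_thickness$mean[ai],
                                         pop$nonnuclear_thickness$sd[ai],
                                         pop$nonnuclear_thickness$min,
                                         pop$nonnuclear_thickness$max),
       curvature_radius = pop$curvature_radius,
       gv_types = gv_types, gv_ipores = gv_ipores, gv_radii = radii,
       conn_counts = conn_counts,
       frac_under = pop$frac_under_gv[ai],
       h_rng = c(pop$height$min, pop$height$max),
       a_rng = c(pop$contact_area$min, pop$contact_area$max),
       ol = .vm_rtnorm(2, pop$overlap$mean[ai], pop$overlap$sd[ai],
                       pop$overlap$min, pop$overlap$max),
       n_bpores = n_bpores,
       seed = sample.int(2^20, 1))
}

# fixed per-cell allocations reproducing the published per-area counts:
# 105/66/63 vacuoles across 15 cells each, type totals 67/127/7/33,
# vacuoles-with-pores 20/14/6 (one low-flow type-IV vacuole carries 2 pores),
# B-pores 3/2/7 on 3/2/4 cells.
.vm_table1_allocation <- function() {
  gv_counts <- list(
    HIGH = c(1, 2, 3, 4, 5, 6, 7, 7, 8, 8, 9, 10, 10, 10, 15),
    LOW  = c(1, 2, 2, 3, 3, 4, 4, 4, 5, 5, 5, 5, 6, 6, 11),
    NON  = c(1, 2, 2, 3, 3, 3, 4, 4, 4, 5, 5, 5, 6, 7, 9))
  type_pool <- list(
    HIGH = c(rep("I", 25), rep("II", 60), rep("III", 2), rep("IV", 18)),
    LOW  = c(rep("I", 12), rep("II", 40), rep("III", 3), rep("IV", 11)),
    NON  = c(rep("I", 30), rep("II", 27), rep("III", 2), rep("IV", 4)))
  bpores <- list(HIGH = c(1, 1, 1, rep(0, 12)),
                 LOW  = c(1, 1, rep(0, 13)),
                 NON  = c(2, 3, 1, 1, rep(0, 11)))
  list(gv_counts = gv_counts, type_pool = type_pool, bpores = bpores)
}

#' Generate a multi-cell synthetic dataset
#'
#' Draws `n_cells_per_area` cells for each flow-type area from the population
#' distributions (or from the fixed `table1_fixture` allocation, which
#' reproduces the published per-area giant-vacuole, I-pore and B-pore counts
#' over 15 cells per area exactly) and optionally rasterizes each cell into a
#' contour stack.
#'
#' @param population Population parameters; see [vm_population()].
#' @param n_cells_per_area Cells per flow area (>= 1); forced to 15 by the
#'   `table1_fixture` preset.
#' @param seed Integer seed; a fixed seed reproduces the dataset exactly.
#' @param preset `"population"` or `"table1_fixture"`.
#' @param rasterize Build the contour stacks (set `FALSE` to obtain only the
#'   specs and ground-truth tables, which is much faster).
#' @param acquisition An [acquisition_params()].
#' @return A list of class `vm_dataset`: `stacks` (named list of `vm_stack`,
#'   or `NULL`), `truth` (list of data frames `cells`, `gvs`, `connections`,
#'   `bpores`, `ol`), and `specs`.
#' @export
generate_dataset <- function(population = vm_population(),
                             n_cells_per_area = 15, seed = 1,
                             preset = c("population", "table1_fixture"),
                             rasterize = TRUE,
                             acquisition = acquisition_params()) {
  preset <- match.arg(preset)
  if (preset == "table1_fixture") n_cells_per_area <- 15L
  if (!is.numeric(n_cells_per_area) || n_cells_per_area < 1)
    stop("`n_cells_per_area` must be >= 1")
  n_cells_per_area <- as.integer(n_cells_per_area)
  pop <- population
  tsec <- acquisition$section_thickness

  specs <- .vm_with_seed(as.integer(seed), {
    out <- list()
    alloc <- if (preset == "table1_fixture") .vm_table1_allocation() else NULL
    for (ai in seq_along(pop$areas)) {
      area <- pop$areas[ai]
      if (preset == "table1_fixture") {
        # deterministic type allocation: deal the area's type pool across
        # cells in a fixed interleaved order
        pool <- alloc$type_pool[[area]]
        pool <- pool[order(rep_len(seq_len(15), length(pool)))]
      }
      ptr <- 0L
      for (ci in seq_len(n_cells_per_area)) {
        cid <- sprintf("%s_%02d", tolower(area), ci)
        if (preset == "table1_fixture") {
          gk <- alloc$gv_counts[[area]][ci]
          tys <- pool[(ptr + 1L):(ptr + gk)]
          ptr <- ptr + gk
          ips <- as.integer(tys %in% c("III", "IV"))
          plan <- .vm_draw_plan(pop, ai, cid, area, gv_count = gk,
                                gv_types = tys, gv_ipores = ips,
                                n_bpores = alloc$bpores[[area]][ci])
        } else {
          plan <- .vm_draw_plan(pop, ai, cid, area)
        }
        out[[cid]] <- .vm_assemble_spec(plan, tsec = tsec)
      }
    }
    out
  })

  if (preset == "table1_fixture") {
    # the low-flow area has 15 I-pores on 14 pore-bearing vacuoles: give the
    # first type-IV vacuole of the area a second pore
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      if (sp$flow_area != "LOW") next
      iv <- which(vapply(sp$gvs, function(g)
        g$has_ipore && g$has_basal_opening, logical(1)))
      if (length(iv)) {
        sp$gvs[[iv[1]]]$n_ipores <- 2L
        specs[[nm]] <- sp
        break
      }
    }
  }

  truth <- list(cells = list(), gvs = list(), connections = list(),
                bpores = list(), ol = list())
  stacks <- if (rasterize) list() else NULL
  for (nm in names(specs)) {
    gc_out <- generate_cell(specs[[nm]], acquisition = acquisition)
    if (rasterize) stacks[[nm]] <- gc_out$stack
    for (k in names(truth))
      truth[[k]][[nm]] <- gc_out$truth[[if (k == "cells") "cell" else k]]
  }
  truth <- lapply(truth, function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (length(lst)) {
      df <- do.call(rbind, lst)
      rownames(df) <- NULL
      df
    } else NULL
  })

  structure(list(stacks = stacks, truth = truth, specs = specs,
                 preset = preset, seed = seed),
            class = "vm_dataset")
}

#' @export
print.vm_dataset <- function(x, ...) {
  cat("Synthetic inner-wall cell dataset (preset: ", x$preset, ")\n", sep = "")
  cat(sprintf("  cells: %d  giant vacuoles: %d  connections: %d  B-pores: %d\n",
              nrow(x$truth$cells),
              if (is.null(x$truth$gvs)) 0L else nrow(x$truth$gvs),
              if (is.null(x$truth$connections)) 0L
              else nrow(x$truth$connections),
              if (is.null(x$truth$bpores)) 0L else nrow(x$truth$bpores)))
  cat(if (is.null(x$stacks)) "  stacks: not rasterized\n"
      else sprintf("  stacks: %d rasterized\n", length(x$stacks)))
  invisible(x)
}

#' Write a dataset's stacks and ground-truth tables to a directory
#'
#' Stacks are written in the native JSON schema, ground truth as plain CSV
#' tables alongside them.
#'
#' @param dataset A `vm_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "vm_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(dataset$stacks)) {
    for (nm in names(dataset$stacks))
      write_stack(dataset$stacks[[nm]], file.path(dir, paste0(nm, ".json")))
  }
  for (k in names(dataset$truth)) {
    if (is.null(dataset$truth[[k]])) next
    utils::write.csv(dataset$truth[[k]],
                     file.path(dir, paste0("truth_", k, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
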