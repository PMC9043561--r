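# Per-cell geometric measurements on a contour stack: length, segmented-line
# width, thickness, giant-vacuole-subtracted volume, and adjacent-cell
# overlap length under the 45-degree rule.

# envelope contour of `cell_id` on section z (NULL if absent)
.vm_envelope_on <- function(stack, cell_id, z) {
  for (sec in stack$sections) {
    if (sec$index != z) next
    for (ct in sec$contours)
      if (ct$label == "IW_CELL" && ct$object_id == cell_id) return(ct)
  }
  NULL
}

# all sections of a cell, with its envelope contours, as an index
.vm_cell_index <- function(stack, cell_id) {
  env <- list(); zs <- integer(0)
  nuc_z <- integer(0); other <- list()
  for (sec in stack$sections) {
    for (ct in sec$contours) {
      if (ct$label == "IW_CELL" && ct$object_id == cell_id) {
        zs <- c(zs, sec$index)
        env[[as.character(sec$index)]] <- ct
      }
    }
  }
  if (!length(zs)) stop("cell '", cell_id, "' not found in stack")
  list(z = sort(zs), env = env)
}

# ids of GV objects whose centroid lies inside the cell envelope
.vm_cell_gv_ids <- function(stack, cell_id, idx = NULL) {
  if (is.null(idx)) idx <- .vm_cell_index(stack, cell_id)
  hits <- stack_contours(stack, label = "GV")
  ids <- character(0)
  seen <- character(0)
  for (h in hits) {
    oid <- h$contour$object_id
    if (oid %in% seen) next
    seen <- c(seen, oid)
    env <- idx$env[[as.character(h$section)]]
    if (is.null(env)) next
    if (.vm_point_in_poly(colMeans(h$contour$points), env$points))
      ids <- c(ids, oid)
  }
  ids
}

# sections carrying a given label (restricted to objects in `ids` if given)
.vm_label_sections <- function(stack, label, ids = NULL) {
  hits <- stack_contours(stack, label = label)
  if (!is.null(ids))
    hits <- Filter(function(h) h$contour$object_id %in% ids, hits)
  sort(unique(vapply(hits, `[[`, integer(1), "section")))
}

# "every `interval` sections" sampling from the first section of the span,
# substituting the nearest eligible section within +/- `slack`
.vm_sample_sections <- function(span_z, eligible, interval = 40L,
                                slack = 5L) {
  anchors <- span_z[seq(1L, length(span_z), by = interval)]
  out <- integer(0)
  skipped <- integer(0)
  for (z in anchors) {
    if (z %in% eligible) { out <- c(out, z); next }
    near <- eligible[abs(eligible - z) <= slack]
    if (length(near)) {
      out <- c(out, near[which.min(abs(near - z))])
    } else {
      skipped <- c(skipped, z)
    }
  }
  if (length(skipped))
    message("no eligible section within ", slack, " of sampled section(s) ",
            paste(skipped, collapse = ", "), "; sample(s) skipped")
  unique(out)
}

#' Cell length along the stack axis
#'
#' The through-stack convention: (last section - first section + 1) times the
#' section thickness.
#'
#' @param stack A `vm_stack`.
#' @param cell_id Cell object id.
#' @return Length in um.
#' @export
cell_length <- function(stack, cell_id) {
  idx <- .vm_cell_index(stack, cell_id)
  (max(idx$z) - min(idx$z) + 1L) * stack$acquisition$section_thickness
}

#' Cell width by segmented line
#'
#' Width is the length of a polyline of at most three segments spanning the
#' cell's lateral extent along the inner-wall curvature (breakpoints chosen to
#' minimise the maximal deviation of the profile midline from the polyline).
#' Nuclear width is measured once, on the section with the largest nuclear
#' cross-sectional area; non-nuclear width is the mean over sections sampled
#' every `interval` sections on nucleus-free sections (nearest eligible
#' section within 5 substituted).
#'
#' @param stack A `vm_stack`.
#' @param cell_id Cell object id.
#' @param mode `"nuclear"` or `"nonnuclear"`.
#' @param interval Sampling interval in sections.
#' @return Width in um, with attribute `"sections"` giving the sections used.
#' @export
cell_width <- function(stack, cell_id, mode = c("nuclear", "nonnuclear"),
                       interval = 40L) {
  mode <- match.arg(mode)
  idx <- .vm_cell_index(stack, cell_id)
  width_on <- function(z) {
    mid <- .vm_midline(idx$env[[as.character(z)]]$points)
    if (is.null(mid)) return(NA_real_)
    .vm_segline_width(mid$pts)
  }
  if (mode == "nuclear") {
    z <- .vm_max_nucleus_csa(stack, cell_id, idx)
    w <- width_on(z)
    return(structure(w, sections = z))
  }
  nuc_z <- .vm_label_sections(stack, "NUCLEUS")
  eligible <- setdiff(idx$z, nuc_z)
  if (!length(eligible)) stop("no nucleus-free section available for width")
  zs <- .vm_sample_sections(idx$z, eligible, interval)
  vals <- vapply(zs, width_on, numeric(1))
  structure(mean(vals, na.rm = TRUE), sections = zs)
}

# section with the largest nuclear cross-sectional area belonging to the cell
.vm_max_nucleus_csa <- function(stack, cell_id, idx = NULL) {
  if (is.null(idx)) idx <- .vm_cell_index(stack, cell_id)
  hits <- stack_contours(stack, label = "NUCLEUS")
  hits <- Filter(function(h) {
    env <- idx$env[[as.character(h$section)]]
    !is.null(env) &&
      .vm_point_in_poly(colMeans(h$contour$points), env$points)
  }, hits)
  if (!length(hits)) stop("cell '", cell_id, "' has no nucleus annotation")
  areas <- vapply(hits, function(h) .vm_shoelace(h$contour$points),
                  numeric(1))
  hits[[which.max(areas)]]$section
}

#' Cell thickness (basal-to-apical height)
#'
#' Operationalizes the chord construction: the chord joining the two lateral
#' cell borders is bisected, the bisector's intersection with the profile
#' midline fixes the measurement locus, and thickness is the profile extent
#' perpendicular to the local midline axis there. Nuclear thickness is
#' measured once at the largest-nuclear-CSA section; non-nuclear thickness is
#' the mean over sections sampled every `interval` sections where neither the
#' nucleus nor any giant vacuole is present.
#'
#' @inheritParams cell_width
#' @return Thickness in um with attribute `"sections"`.
#' @export
cell_thickness <- function(stack, cell_id,
                           mode = c("nuclear", "nonnuclear"),
                           interval = 40L) {
  mode <- match.arg(mode)
  idx <- .vm_cell_index(stack, cell_id)
  thick_on <- function(z) {
    poly <- idx$env[[as.character(z)]]$points
    mid <- .vm_midline(poly)
    if (is.null(mid)) return(NA_real_)
    m <- nrow(mid$pts)
    chord_mid <- (mid$pts[1, ] + mid$pts[m, ]) / 2
    d2 <- (mid$pts[, 1] - chord_mid[1])^2 + (mid$pts[, 2] - chord_mid[2])^2
    li <- which.min(d2)
    locus <- mid$pts[li, ]
    nrm <- c(-mid$tangents[li, 2], mid$tangents[li, 1])
    .vm_extent_along(poly, locus, nrm)
  }
  if (mode == "nuclear") {
    z <- .vm_max_nucleus_csa(stack, cell_id, idx)
    return(structure(thick_on(z), sections = z))
  }
  gv_ids <- .vm_cell_gv_ids(stack, cell_id, idx)
  busy <- union(.vm_label_sections(stack, "NUCLEUS"),
                .vm_label_sections(stack, "GV", gv_ids))
  eligible <- setdiff(idx$z, busy)
  if (!length(eligible))
    stop("no nucleus- and vacuole-free section available for thickness")
  zs <- .vm_sample_sections(idx$z, eligible, interval)
  vals <- vapply(zs, thick_on, numeric(1))
  structure(mean(vals, na.rm = TRUE), sections = zs)
}

#' Giant-vacuole volume by section summation
#'
#' Sum of per-section contour areas times the section thickness.
#'
#' @param stack A `vm_stack`.
#' @param gv_id Vacuole object id.
#' @return Volume in cubic um.
#' @export
gv_volume <- function(stack, gv_id) {
  hits <- stack_contours(stack, object_id = gv_id)
  if (!length(hits)) stop("giant vacuole '", gv_id, "' not found")
  a <- vapply(hits, function(h) {
    if (!h$contour$closed)
      stop("giant vacuole '", gv_id, "' has an open contour on section ",
           h$section)
    .vm_shoelace(h$contour$points)
  }, numeric(1))
  sum(a) * stack$acquisition$section_thickness
}

#' Cell volume with giant vacuoles subtracted
#'
#' The traced envelope encompasses the vacuole lumina, so cell volume is the
#' section-summed envelope volume minus the summed vacuole volumes.
#'
#' @param stack A `vm_stack`.
#' @param cell_id Cell object id.
#' @return Volume in cubic um (with attribute `"envelope"`, the unsubtracted
#'   envelope volume).
#' @export
cell_volume <- function(stack, cell_id) {
  idx <- .vm_cell_index(stack, cell_id)
  areas <- vapply(idx$z, function(z) {
    ct <- idx$env[[as.character(z)]]
    if (!ct$closed)
      stop("cell '", cell_id, "' has an open envelope on section ", z)
    .vm_shoelace(ct$points)
  }, numeric(1))
  env_vol <- sum(areas) * stack$acquisition$section_thickness
  gvv <- sum(vapply(.vm_cell_gv_ids(stack, cell_id, idx),
                    function(id) gv_volume(stack, id), numeric(1)))
  vol <- env_vol - gvv
  if (vol < -1e-6)
    stop("negative cell volume: vacuoles traced outside the envelope of '",
         cell_id, "'")
  structure(max(0, vol), envelope = env_vol)
}

# ---- overlap length ---------------------------------------------------------

# overlap length between the cell envelope and one adjacent-cell contour on
# one section: boundary points of the adjacent contour within `tol` of the
# envelope are projected onto the envelope; each near-straight piece of the
# projected contact polyline contributes its extent when it lies within 45
# degrees of the local inner-wall axis.
.vm_measure_ol <- function(env_poly, adj_poly, mid, tol = 0.02,
                           angle_limit = 45) {
  pts <- .vm_resample_boundary(adj_poly, step = 0.01)
  n <- nrow(env_poly)
  i2 <- c(2:n, 1L)
  ax <- env_poly[, 1]; ay <- env_poly[, 2]
  dx <- env_poly[i2, 1] - ax; dy <- env_poly[i2, 2] - ay
  L2 <- pmax(dx * dx + dy * dy, .Machine$double.eps)
  proj <- t(apply(pts, 1L, function(p) {
    tt <- pmin(1, pmax(0, ((p[1] - ax) * dx + (p[2] - ay) * dy) / L2))
    qx <- ax + tt * dx; qy <- ay + tt * dy
    dd <- (p[1] - qx)^2 + (p[2] - qy)^2
    k <- which.min(dd)
    c(sqrt(dd[k]), qx[k], qy[k], k, tt[k])
  }))
  # a junction exists only where the two membranes run parallel: require the
  # local adjacent-boundary direction to agree with the envelope edge the
  # point projects onto (within 25 degrees); a foot sitting exactly on an
  # envelope vertex may match either incident edge
  m <- nrow(pts)
  iq <- c(2:m, 1L)
  at <- pts[iq, , drop = FALSE] - pts
  atl <- pmax(sqrt(rowSums(at^2)), .Machine$double.eps)
  k <- proj[, 4]
  cpar <- function(j) {
    abs(at[, 1] * dx[j] + at[, 2] * dy[j]) / (atl * sqrt(L2[j]))
  }
  lim <- cos(25 * pi / 180)
  par_ok <- cpar(k) >= lim
  tt <- proj[, 5]
  el <- sqrt(L2[k])
  nxt <- ifelse(k == n, 1L, k + 1L)
  prv <- ifelse(k == 1L, n, k - 1L)
  par_ok <- par_ok | ((1 - tt) * el < 0.01 & cpar(nxt) >= lim) |
    (tt * el < 0.01 & cpar(prv) >= lim)
  keep <- proj[, 1] <= tol & par_ok
  if (sum(keep) < 2L) return(0)
  ki <- which(keep)
  runs <- split(ki, cumsum(c(1, diff(ki) > 3)))
  total <- 0
  for (run in runs) {
    feet <- proj[run, 2:3, drop = FALSE]
    if (nrow(feet) >= 2L) {
      dup <- c(FALSE, rowSums(abs(diff(feet))) < 1e-9)
      feet <- feet[!dup, , drop = FALSE]
    }
    if (nrow(feet) < 2L) next
    sp <- .vm_dp_indices(feet, tol = 0.02)
    for (si in seq_len(length(sp) - 1L)) {
      a <- feet[sp[si], ]; b <- feet[sp[si + 1L], ]
      seg <- b - a
      len <- sqrt(sum(seg^2))
      if (len < 0.025) next
      axis <- .vm_axis_at(mid, (a + b) / 2)
      cosang <- abs(sum(seg * axis)) / len
      ang <- acos(pmin(1, cosang)) * 180 / pi
      if (ang <= angle_limit + 1e-6) total <- total + len
    }
  }
  total
}

# adjacent-cell objects split by side of the cell (along the midline axis)
.vm_adjacent_sides <- function(stack, cell_id, idx) {
  hits <- stack_contours(stack, label = "ADJACENT_IW_CELL")
  if (!length(hits)) return(list())
  ids <- unique(vapply(hits, function(h) h$contour$object_id, character(1)))
  z0 <- idx$z[which.max(vapply(idx$z, function(z)
    nrow(idx$env[[as.character(z)]]$points), integer(1)))]
  env <- idx$env[[as.character(z0)]]$points
  mid <- .vm_midline(env)
  axis <- mid$axis
  # deterministic orientation so side labels are reproducible
  if (axis[1] < 0 || (axis[1] == 0 && axis[2] < 0)) axis <- -axis
  ctr <- colMeans(env)
  sides <- lapply(ids, function(id) {
    h <- Filter(function(x) x$contour$object_id == id, hits)
    cents <- t(vapply(h, function(x) colMeans(x$contour$points), numeric(2)))
    pr <- mean((cents[, 1] - ctr[1]) * axis[1] +
               (cents[, 2] - ctr[2]) * axis[2])
    sign(pr)
  })
  names(sides) <- ids
  sides
}

#' Overlap-length profile of a cell
#'
#' Overlap with each adjacent inner-wall cell is measured every `interval`
#' sections over the full cell span, on both sides; junction segments steeper
#' than 45 degrees to the local inner-wall axis contribute zero (the
#' 45-degree boundary itself is counted). Sampled sections with no
#' adjacent-cell annotation on a side are excluded (with a message).
#'
#' @param stack A `vm_stack`.
#' @param cell_id Cell object id.
#' @param interval Sampling interval in sections.
#' @param angle_limit Axis-angle limit in degrees.
#' @return `list(samples = data.frame(section, side, ol), ol_mean = mean)`.
#' @export
overlap_profile <- function(stack, cell_id, interval = 40L,
                            angle_limit = 45) {
  idx <- .vm_cell_index(stack, cell_id)
  sides <- .vm_adjacent_sides(stack, cell_id, idx)
  if (!length(sides)) {
    message("no adjacent-cell annotation: overlap undefined for '",
            cell_id, "'")
    return(list(samples = data.frame(section = integer(0),
                                     side = character(0), ol = numeric(0)),
                ol_mean = NA_real_))
  }
  zs <- idx$z[seq(1L, length(idx$z), by = interval)]
  rows <- list()
  for (z in zs) {
    env <- idx$env[[as.character(z)]]
    mid <- .vm_midline(env$points)
    if (is.null(mid)) next
    for (id in names(sides)) {
      cts <- .vm_contours_on(stack, id, z)
      if (!length(cts)) {
        message("adjacent cell '", id, "' absent on sampled section ", z,
                "; sample excluded")
        next
      }
      ol <- sum(vapply(cts, function(ct)
        .vm_measure_ol(env$points, ct$points, mid,
                       angle_limit = angle_limit), numeric(1)))
      rows[[length(rows) + 1L]] <-
        data.frame(section = z,
                   side = if (sides[[id]] < 0) "left" else "right",
                   ol = ol, stringsAsFactors = FALSE)
    }
  }
  samples <- if (length(rows)) do.call(rbind, rows)
             else data.frame(section = integer(0), side = character(0),
                             ol = numeric(0))
  list(samples = samples,
       ol_mean = if (nrow(samples)) mean(samples$ol) else NA_real_)
}

#' Overlap length on the sections flanking a B-pore
#'
#' Measures overlap on the nearest junction-bearing section before and after
#' the pore span, on the pore's side of the cell. A pore at the stack
#' boundary yields a partial result with the missing side flagged `NA`.
#'
#' @param stack A `vm_stack`.
#' @param cell_id Cell object id.
#' @param bpore_id B-pore object id.
#' @param angle_limit Axis-angle limit in degrees.
#' @return `list(before, after, sections, partial)`.
#' @export
overlap_at_bpore <- function(stack, cell_id, bpore_id, angle_limit = 45) {
  idx <- .vm_cell_index(stack, cell_id)
  ph <- stack_contours(stack, object_id = bpore_id)
  if (!length(ph)) stop("B-pore '", bpore_id, "' not found")
  pz <- range(vapply(ph, `[[`, integer(1), "section"))
  pc <- colMeans(ph[[1]]$contour$points)
  sides <- .vm_adjacent_sides(stack, cell_id, idx)
  if (!length(sides)) stop("no adjacent-cell annotation near B-pore")
  # the adjacent cell on the pore's side: nearest object on the pore section
  dists <- vapply(names(sides), function(id) {
    cts <- .vm_contours_on(stack, id, ph[[1]]$section)
    if (!length(cts)) return(Inf)
    min(vapply(cts, function(ct)
      .vm_dist_to_poly(pc, ct$points), numeric(1)))
  }, numeric(1))
  adj_id <- names(sides)[which.min(dists)]

  measure_at <- function(z) {
    env <- idx$env[[as.character(z)]]
    if (is.null(env)) return(NA_real_)
    cts <- .vm_contours_on(stack, adj_id, z)
    if (!length(cts)) return(NA_real_)
    mid <- .vm_midline(env$points)
    if (is.null(mid)) return(NA_real_)
    sum(vapply(cts, function(ct)
      .vm_measure_ol(env$points, ct$points, mid,
                     angle_limit = angle_limit), numeric(1)))
  }
  find_flank <- function(dir) {
    z <- if (dir < 0) pz[1] - 1L else pz[2] + 1L
    while (z >= min(idx$z) && z <= max(idx$z)) {
      if (length(.vm_contours_on(stack, adj_id, z)))
        return(list(z = z, ol = measure_at(z)))
      z <- z + dir
    }
    NULL
  }
  bef <- find_flank(-1L); aft <- find_flank(1L)
  list(before = if (is.null(bef)) NA_real_ else bef$ol,
       after = if (is.null(aft)) NA_real_ else aft$ol,
       sections = c(before = if (is.null(bef)) NA_integer_ else bef$z,
                    after = if (is.null(aft)) NA_integer_ else aft$z),
       partial = is.null(bef) || is.null(aft))
}

#' Measure every cell of a dataset
#'
#' Runs the full per-cell morphometry (length, widths, thicknesses,
#' vacuole-subtracted volume, mean overlap length) over a named list of
#' stacks.
#'
#' @param stacks Named list of `vm_stack`, one reconstructed cell each; names
#'   are the cell ids.
#' @param cells Optional data frame with `cell_id` and `flow_area` labels.
#' @param interval Sampling interval in sections.
#' @return A data frame with one row per cell.
#' @export
measure_cells <- function(stacks, cells = NULL, interval = 40L) {
  rows <- lapply(names(stacks), function(nm) {
    st <- stacks[[nm]]
    wnuc <- tryCatch(cell_width(st, nm, "nuclear", interval),
                     error = function(e) NA_real_)
    tnuc <- tryCatch(cell_thickness(st, nm, "nuclear", interval),
                     error = function(e) NA_real_)
    olp <- suppressMessages(overlap_profile(st, nm, interval))
    data.frame(
      cell_id = nm,
      length = cell_length(st, nm),
      nuclear_width = as.numeric(wnuc),
      nonnuclear_width = as.numeric(
        suppressMessages(cell_width(st, nm, "nonnuclear", interval))),
      nuclear_thickness = as.numeric(tnuc),
      nonnuclear_thickness = as.numeric(
        suppressMessages(cell_thickness(st, nm, "nonnuclear", interval))),
      volume = as.numeric(cell_volume(st, nm)),
      ol_mean = olp$ol_mean,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cells))
    out <- merge(cells[, c("cell_id", "flow_area")], out, by = "cell_id",
                 sort = TRUE)
  out
}
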