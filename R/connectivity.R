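# Classification of inner-wall/juxtacanalicular connections (types 1-7),
# giant-vacuole types (I-IV), beneath-vacuole connection counting, and B-pore
# validation.

#' Classify a giant vacuole from its opening flags
#'
#' Type I: neither basal opening nor I-pore; Type II: basal opening only;
#' Type III: I-pore only; Type IV: both. Vectorised.
#'
#' @param has_basal_opening,has_ipore Logical vectors.
#' @return Character vector of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
classify_gv <- function(has_basal_opening, has_ipore) {
  c("I", "II", "III", "IV")[1L + as.integer(has_basal_opening) +
                            2L * as.integer(has_ipore)]
}

#' Classify a candidate connection
#'
#' Maps the structural category of a candidate (origin cell, geometry kind,
#' target structure) to a type code 1-7 and applies the counting thresholds:
#' projections (types 1-6) need a height of at least 0.3 um from the cell
#' body, body-body appositions (type 7) a contact area of at least 0.5 um^2
#' (both boundaries inclusive). Measured values are rounded to the pixel
#' quantum before comparison to avoid rasterization flutter at the boundary.
#'
#' @param origin `"IW"` or `"JCT"`.
#' @param kind `"process"`, `"tongue"` or `"apposition"`.
#' @param target One of `"JCT_ECM"`, `"JCT_CELL_BODY"`, `"JCT_CELL_PROCESS"`,
#'   `"JCT_GROOVE"`, `"IW_CELL_BODY"`, `"IW_GROOVE"`.
#' @param height Projection height in um (types 1-6).
#' @param contact_area Contact area in um^2 (type 7).
#' @param height_threshold,area_threshold Counting thresholds.
#' @param pixel_size Pixel quantum for rounding (um); pass `NULL` to compare
#'   unrounded values.
#' @return Integer type code 1-7, or `0L` for a candidate below threshold
#'   (rejected).
#' @export
classify_connection <- function(origin, kind, target,
                                height = NA_real_,
                                contact_area = NA_real_,
                                height_threshold = 0.3,
                                area_threshold = 0.5,
                                pixel_size = 0.0101) {
  taxo <- .vm_conn_taxonomy()
  hit <- which(taxo$origin == origin & taxo$kind == kind &
               taxo$target == target)
  if (length(hit) != 1L)
    stop("unknown connection category: ", origin, " ", kind, " -> ", target)
  ty <- taxo$type_code[hit]
  if (ty == 7L) {
    if (is.na(contact_area)) stop("type 7 candidate needs `contact_area`")
    a <- if (is.null(pixel_size)) contact_area
         else round(contact_area / pixel_size^2) * pixel_size^2
    if (a < area_threshold - 1e-9) return(0L)
  } else {
    if (is.na(height)) stop("projection candidate needs `height`")
    h <- if (is.null(pixel_size)) height
         else .vm_snap(height, pixel_size)
    if (h < height_threshold - 1e-9) return(0L)
  }
  ty
}

#' Extract connection candidates from a stack
#'
#' Connection-endpoint contours are grouped by object id; the structural
#' category is read from the contour annotation (`meta`), while the
#' quantitative geometry is measured from the traces: projection height is the
#' largest distance from the connection's vertices to the cell envelope on the
#' same section, contact area is the section-summed apposition length times
#' the section thickness, and the anchor is the vertex closest to the
#' envelope.
#'
#' @param stack A `vm_stack`.
#' @param cell_id Cell object id.
#' @param height_threshold,area_threshold Counting thresholds passed to
#'   [classify_connection()].
#' @return Data frame with one row per candidate (including rejected ones,
#'   `type_code == 0`).
#' @export
extract_connections <- function(stack, cell_id, height_threshold = 0.3,
                                area_threshold = 0.5) {
  idx <- .vm_cell_index(stack, cell_id)
  hits <- stack_contours(stack, label = "CONNECTION_ENDPOINT")
  if (!length(hits))
    return(data.frame(connection_id = character(0), origin = character(0),
                      kind = character(0), target = character(0),
                      type_code = integer(0), height = numeric(0),
                      contact_area = numeric(0), z_start = integer(0),
                      z_end = integer(0), anchor_x = numeric(0),
                      anchor_y = numeric(0), anchor_section = integer(0),
                      stringsAsFactors = FALSE))
  ids <- unique(vapply(hits, function(h) h$contour$object_id, character(1)))
  px <- stack$acquisition$pixel_size
  tsec <- stack$acquisition$section_thickness
  rows <- lapply(ids, function(id) {
    hh <- Filter(function(h) h$contour$object_id == id, hits)
    metas <- lapply(hh, function(h) h$contour$meta)
    m <- metas[[1]]
    if (is.null(m$origin) || is.null(m$kind) || is.null(m$target))
      stop("connection '", id, "' lacks a structural annotation")
    if (!all(vapply(metas, function(x) identical(x[c("origin", "kind",
                                                     "target")],
                                                 m[c("origin", "kind",
                                                     "target")]),
                    logical(1))))
      stop("connection '", id, "' has inconsistent annotations")
    zs <- vapply(hh, `[[`, integer(1), "section")
    height <- NA_real_; area <- NA_real_
    anchor <- c(NA_real_, NA_real_); anchor_z <- NA_integer_
    if (m$kind == "apposition") {
      lens <- vapply(hh, function(h) .vm_poly_diameter(h$contour$points),
                     numeric(1))
      area <- sum(lens) * tsec
      k <- which.max(lens)
      anchor <- colMeans(hh[[k]]$contour$points)
      anchor_z <- zs[k]
    } else {
      best <- -Inf; bestd <- Inf
      for (h in hh) {
        env <- idx$env[[as.character(h$section)]]
        if (is.null(env)) next
        d <- .vm_dist_to_poly(h$contour$points, env$points)
        if (max(d) > best) best <- max(d)
        if (min(d) < bestd) {
          bestd <- min(d)
          anchor <- h$contour$points[which.min(d), ]
          anchor_z <- h$section
        }
      }
      height <- best
    }
    ty <- classify_connection(m$origin, m$kind, m$target, height = height,
                              contact_area = area,
                              height_threshold = height_threshold,
                              area_threshold = area_threshold,
                              pixel_size = px)
    data.frame(connection_id = id, origin = m$origin, kind = m$kind,
               target = m$target, type_code = ty, height = height,
               contact_area = area, z_start = min(zs), z_end = max(zs),
               anchor_x = anchor[1], anchor_y = anchor[2],
               anchor_section = anchor_z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$connection_id), , drop = FALSE]
}

#' Count connections beneath a giant vacuole
#'
#' A connection is beneath the vacuole when its section span intersects the
#' vacuole's span and (in the default footprint mode) its anchor lies within
#' the vacuole's lateral footprint dilated by `margin`; each connection is
#' counted once per vacuole. `mode = "section"` counts every connection on
#' the vacuole's sections regardless of lateral position.
#'
#' @param stack A `vm_stack`.
#' @param gv_id Vacuole object id.
#' @param connections Data frame from [extract_connections()] (rejected
#'   candidates are ignored).
#' @param margin Footprint dilation in um.
#' @param mode `"footprint"` or `"section"`.
#' @return Integer count with attribute `"connection_ids"`.
#' @export
connections_beneath_gv <- function(stack, gv_id, connections, margin = 0.5,
                                   mode = c("footprint", "section")) {
  mode <- match.arg(mode)
  hits <- stack_contours(stack, object_id = gv_id)
  if (!length(hits)) stop("giant vacuole '", gv_id, "' not found")
  zs <- range(vapply(hits, `[[`, integer(1), "section"))
  cn <- connections[connections$type_code > 0L, , drop = FALSE]
  if (!nrow(cn)) return(structure(0L, connection_ids = character(0)))
  span_ok <- cn$z_start <= zs[2] & cn$z_end >= zs[1]
  if (mode == "footprint") {
    xr <- range(unlist(lapply(hits, function(h) h$contour$points[, 1])))
    lat_ok <- cn$anchor_x >= xr[1] - margin & cn$anchor_x <= xr[2] + margin
    sel <- span_ok & lat_ok
  } else {
    sel <- span_ok
  }
  structure(sum(sel), connection_ids = cn$connection_id[sel])
}

#' Connections-per-volume ratio of a giant vacuole
#'
#' @param n_connections Connections counted beneath the vacuole.
#' @param volume Vacuole volume in cubic um (> 0).
#' @return Ratio in 1/um^3.
#' @export
connection_ratio <- function(n_connections, volume) {
  if (!is.numeric(volume) || volume <= 0)
    stop("ratio undefined: vacuole volume must be > 0")
  n_connections / volume
}

#' Percentage of a cell's connections lying beneath giant vacuoles
#'
#' @param n_under Connections beneath at least one vacuole.
#' @param n_total All counted connections of the cell (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
percent_under_gvs <- function(n_under, n_total) {
  if (n_total <= 0)
    stop("percentage undefined for a cell with zero connections")
  100 * n_under / n_total
}

#' Extract giant-vacuole records from a stack
#'
#' Vacuoles are the GV objects whose centroids lie inside the cell envelope;
#' opening annotations (I-pores, basal openings) are attributed to the nearest
#' vacuole whose span covers their section. Types follow [classify_gv()];
#' beneath-vacuole connection counts and per-volume ratios are attached when
#' `connections` is supplied.
#'
#' @param stack A `vm_stack`.
#' @param cell_id Cell object id.
#' @param connections Optional data frame from [extract_connections()].
#' @param margin Footprint dilation for beneath-counting (um).
#' @param mode Beneath-counting mode, see [connections_beneath_gv()].
#' @return Data frame with one row per vacuole.
#' @export
extract_gvs <- function(stack, cell_id, connections = NULL, margin = 0.5,
                        mode = c("footprint", "section")) {
  mode <- match.arg(mode)
  idx <- .vm_cell_index(stack, cell_id)
  ids <- .vm_cell_gv_ids(stack, cell_id, idx)
  if (!length(ids))
    return(data.frame(gv_id = character(0), cell_id = character(0),
                      volume = numeric(0), has_basal_opening = logical(0),
                      has_ipore = logical(0), n_ipores = integer(0),
                      gv_type = character(0), z_start = integer(0),
                      z_end = integer(0),
                      n_connections_beneath = integer(0),
                      connections_per_volume = numeric(0),
                      stringsAsFactors = FALSE))
  spans <- lapply(ids, function(id) {
    h <- stack_contours(stack, object_id = id)
    range(vapply(h, `[[`, integer(1), "section"))
  })
  names(spans) <- ids

  # attribute each opening annotation to its vacuole
  assign_openings <- function(label) {
    res <- stats::setNames(integer(length(ids)), ids)
    for (h in stack_contours(stack, label = label)) {
      cen <- colMeans(h$contour$points)
      cand <- ids[vapply(ids, function(id)
        h$section >= spans[[id]][1] && h$section <= spans[[id]][2],
        logical(1))]
      if (!length(cand)) next
      d <- vapply(cand, function(id) {
        cts <- .vm_contours_on(stack, id, h$section)
        if (!length(cts)) return(Inf)
        min(vapply(cts, function(ct) .vm_dist_to_poly(cen, ct$points),
                   numeric(1)))
      }, numeric(1))
      if (min(d) > 0.5) next
      pick <- cand[which.min(d)]
      res[pick] <- res[pick] + 1L
    }
    res
  }
  n_ip <- assign_openings("IPORE_OPENING")
  n_bo <- assign_openings("BASAL_OPENING")

  vols <- vapply(ids, function(id) gv_volume(stack, id), numeric(1))
  nb <- rep(NA_integer_, length(ids))
  if (!is.null(connections))
    nb <- vapply(ids, function(id)
      as.integer(connections_beneath_gv(stack, id, connections,
                                        margin = margin, mode = mode)),
      integer(1))
  data.frame(
    gv_id = ids, cell_id = cell_id, volume = vols,
    has_basal_opening = n_bo > 0L, has_ipore = n_ip > 0L,
    n_ipores = as.integer(n_ip),
    gv_type = classify_gv(n_bo > 0L, n_ip > 0L),
    z_start = vapply(spans, `[`, numeric(1), 1)[ids],
    z_end = vapply(spans, `[`, numeric(1), 2)[ids],
    n_connections_beneath = nb,
    connections_per_volume = ifelse(vols > 0, nb / vols, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Validate a B-pore annotation
#'
#' A valid B-pore lies between two distinct cells, the borders clearly
#' separate over the pore span (no contact between the reconstructed cell and
#' the adjacent cell near the pore), and the junction re-forms on sections
#' before and after. A warning (not an error) is attached when the flanking
#' overlap length is non-zero.
#'
#' @param stack A `vm_stack`.
#' @param bpore_id Pore object id.
#' @param cell_id Optional reconstructed-cell id (defaults to the only
#'   IW_CELL object).
#' @return `list(valid, warnings)`.
#' @export
validate_bpore <- function(stack, bpore_id, cell_id = NULL) {
  if (is.null(cell_id)) {
    cand <- object_ids(stack, label = "IW_CELL")
    if (length(cand) != 1L)
      stop("`cell_id` required when the stack holds several cells")
    cell_id <- cand
  }
  ph <- stack_contours(stack, object_id = bpore_id)
  if (!length(ph)) stop("B-pore '", bpore_id, "' not found")
  idx <- .vm_cell_index(stack, cell_id)
  pz <- vapply(ph, `[[`, integer(1), "section")
  pc <- colMeans(ph[[1]]$contour$points)
  warnings <- character(0)

  # inside the reconstructed cell's own border? then it is no B-pore
  envs <- lapply(pz, function(z) idx$env[[as.character(z)]])
  inside <- any(vapply(envs, function(e)
    !is.null(e) && .vm_point_in_poly(pc, e$points), logical(1)))
  if (inside)
    return(list(valid = FALSE,
                warnings = "pore lies inside a single cell's border"))

  # nearest adjacent cell: the pore must sit between two distinct cells
  adj <- stack_contours(stack, label = "ADJACENT_IW_CELL")
  near <- Filter(function(h) h$section %in% pz &&
                   min(.vm_dist_to_poly(pc, h$contour$points)) < 1.5, adj)
  if (!length(near))
    return(list(valid = FALSE,
                warnings = "pore is not adjacent to two distinct cells"))
  adj_id <- near[[1]]$contour$object_id

  # separation over the pore span
  px <- stack$acquisition$pixel_size
  sep <- vapply(pz, function(z) {
    env <- idx$env[[as.character(z)]]
    cts <- .vm_contours_on(stack, adj_id, z)
    if (is.null(env) || !length(cts)) return(NA_real_)
    min(vapply(cts, function(ct) {
      pts <- .vm_resample_boundary(ct$points, step = 0.05)
      min(.vm_dist_to_poly(pts, env$points))
    }, numeric(1)))
  }, numeric(1))
  if (any(!is.na(sep) & sep <= px))
    return(list(valid = FALSE,
                warnings = "cell borders do not separate over the pore span"))

  # junction re-forms before and after
  rejoin <- function(dir) {
    z <- if (dir < 0) min(pz) - 1L else max(pz) + 1L
    for (k in 0:6) {
      zz <- z + dir * k
      if (zz < min(idx$z) || zz > max(idx$z)) return(FALSE)
      env <- idx$env[[as.character(zz)]]
      cts <- .vm_contours_on(stack, adj_id, zz)
      if (is.null(env) || !length(cts)) next
      d <- min(vapply(cts, function(ct) {
        pts <- .vm_resample_boundary(ct$points, step = 0.05)
        min(.vm_dist_to_poly(pts, env$points))
      }, numeric(1)))
      if (d <= 3 * px) return(TRUE)
    }
    FALSE
  }
  ok_before <- rejoin(-1L); ok_after <- rejoin(1L)
  if (!ok_before || !ok_after)
    return(list(valid = FALSE,
                warnings = "junction does not re-form around the pore"))

  flank <- overlap_at_bpore(stack, cell_id, bpore_id)
  if (isTRUE(flank$before > 1e-9) || isTRUE(flank$after > 1e-9))
    warnings <- c(warnings,
                  sprintf("non-zero overlap flanks the pore (%.3f / %.3f um)",
                          flank$before, flank$after))
  list(valid = TRUE, warnings = warnings)
}

#' Full connectivity work-up of one cell
#'
#' Extracts and classifies every connection, builds the vacuole records with
#' beneath-vacuole counts and ratios, collects validated B-pores, and
#' summarises per-type totals.
#'
#' @param stack A `vm_stack`.
#' @param cell_id Cell object id.
#' @param margin Footprint dilation for beneath-counting (um).
#' @param mode Beneath-counting mode.
#' @param height_threshold,area_threshold Counting thresholds.
#' @return `list(connections, gvs, bpores, summary)`; `summary` is a one-row
#'   data frame with per-type totals, cell-matrix (type 1) and cell-cell
#'   (types 2-7) totals, and the percentage of connections beneath vacuoles
#'   (`NA` for a cell with no counted connections).
#' @export
cell_connectivity <- function(stack, cell_id, margin = 0.5,
                              mode = c("footprint", "section"),
                              height_threshold = 0.3, area_threshold = 0.5) {
  mode <- match.arg(mode)
  conns <- extract_connections(stack, cell_id,
                               height_threshold = height_threshold,
                               area_threshold = area_threshold)
  gvs <- extract_gvs(stack, cell_id, connections = conns, margin = margin,
                     mode = mode)
  counted <- conns[conns$type_code > 0L, , drop = FALSE]
  under_ids <- unique(unlist(lapply(gvs$gv_id, function(id)
    attr(connections_beneath_gv(stack, id, conns, margin = margin,
                                mode = mode), "connection_ids"))))
  totals <- vapply(1:7, function(ty) sum(counted$type_code == ty),
                   integer(1))
  pore_ids <- object_ids(stack, label = "BPORE_OPENING")
  bp <- lapply(pore_ids, function(id) {
    v <- validate_bpore(stack, id, cell_id)
    zs <- vapply(stack_contours(stack, object_id = id), `[[`, integer(1),
                 "section")
    data.frame(bpore_id = id, cell_id = cell_id, valid = v$valid,
               z_start = min(zs), z_end = max(zs),
               stringsAsFactors = FALSE)
  })
  bpores <- if (length(bp)) do.call(rbind, bp)
            else data.frame(bpore_id = character(0), cell_id = character(0),
                            valid = logical(0), z_start = integer(0),
                            z_end = integer(0), stringsAsFactors = FALSE)
  n_total <- nrow(counted)
  smry <- data.frame(cell_id = cell_id, t(stats::setNames(
    as.integer(totals), paste0("type", 1:7))),
    cell_matrix_total = totals[1],
    cell_cell_total = sum(totals[2:7]),
    total = n_total,
    n_under_gvs = length(under_ids),
    percent_under_gvs = if (n_total > 0)
      percent_under_gvs(length(under_ids), n_total) else NA_real_,
    stringsAsFactors = FALSE)
  list(connections = conns, gvs = gvs, bpores = bpores, summary = smry)
}

#' Connectivity work-up over a dataset
#'
#' @param stacks Named list of single-cell `vm_stack` objects.
#' @param cells Optional data frame with `cell_id` and `flow_area`.
#' @param ... Passed to [cell_connectivity()].
#' @return `list(connections, gvs, bpores, cells)` of row-bound per-cell
#'   results (flow-area labels merged in when supplied).
#' @export
classify_cells <- function(stacks, cells = NULL, ...) {
  res <- lapply(names(stacks), function(nm)
    cell_connectivity(stacks[[nm]], nm, ...))
  names(res) <- names(stacks)
  bind <- function(part) {
    out <- do.call(rbind, lapply(res, `[[`, part))
    rownames(out) <- NULL
    out
  }
  out <- list(connections = bind("connections"), gvs = bind("gvs"),
              bpores = bind("bpores"), cells = bind("summary"))
  if (!is.null(cells)) {
    lab <- cells[, c("cell_id", "flow_area")]
    for (k in names(out)) {
      if (nrow(out[[k]]) && "cell_id" %in% names(out[[k]]))
        out[[k]] <- merge(lab, out[[k]], by = "cell_id", sort = TRUE)
    }
  }
  out
}
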