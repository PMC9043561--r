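# Parametric synthetic inner-wall cells rasterized into contour stacks with
# exact ground truth.
#
# Geometry model: each cell is a thin, gently curved ribbon (the endothelial
# monolayer seen in cross-section), extruded through the stack along z. In
# ribbon coordinates (s = arc length along the inner-wall axis, h = radial
# apical-basal offset) the envelope runs from h = -t/2 (basal) to h = +t/2
# plus apical bulges: an ellipsoidal nuclear bulge and ellipsoidal giant
# vacuoles whose lumina stay inside the cell trace, as in manual tracing where
# the cell outline encompasses its vacuoles. Connections are finger-like
# processes (types 1-6) or flat appositions (type 7) on the basal side;
# adjacent cells are ribbons overlapping the apical surface by the prescribed
# overlap length, with explicit B-pore gaps. All vertices are snapped to the
# acquisition pixel grid; ground truth records the analytic pre-rasterization
# values (overlap length records the drawn, snapped extent since its recovery
# tolerance is below one pixel).

# evaluate `code` under a local RNG stream, restoring the caller's state
.vm_with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# ---- spec constructors -----------------------------------------------------

#' Giant-vacuole specification
#'
#' An ellipsoidal vacuole bulging apically out of the cell ribbon, tangent to
#' the basal membrane at its central section.
#'
#' @param center_section z index of the central section.
#' @param semi_lateral,semi_radial,semi_axial Ellipsoid semi-axes (um) along
#'   the inner-wall axis, the apical-basal direction, and z.
#' @param s_center Lateral placement (um) along the ribbon midline.
#' @param has_basal_opening,has_ipore Opening flags; the four combinations
#'   yield giant-vacuole types I-IV.
#' @param n_ipores Number of intracellular pores (defaults to `has_ipore`).
#' @param gv_id Optional object identifier.
#' @return A `vm_gv_spec`.
#' @export
gv_spec <- function(center_section, semi_lateral, semi_radial, semi_axial,
                    s_center = 0, has_basal_opening = FALSE,
                    has_ipore = FALSE, n_ipores = NULL, gv_id = NULL) {
  if (semi_lateral <= 0 || semi_radial <= 0 || semi_axial <= 0)
    stop("giant-vacuole semi-axes must be positive")
  if (is.null(n_ipores)) n_ipores <- as.integer(has_ipore)
  if ((n_ipores > 0) != isTRUE(has_ipore))
    stop("`n_ipores` inconsistent with `has_ipore`")
  structure(list(center_section = as.integer(center_section),
                 semi_lateral = semi_lateral, semi_radial = semi_radial,
                 semi_axial = semi_axial, s_center = s_center,
                 has_basal_opening = isTRUE(has_basal_opening),
                 has_ipore = isTRUE(has_ipore),
                 n_ipores = as.integer(n_ipores), gv_id = gv_id),
            class = "vm_gv_spec")
}

#' Connection specification
#'
#' One inner-wall/juxtacanalicular connection. Types 1-6 are projections with
#' a height measured from the cell body; type 7 is a body-body apposition with
#' a contact area.
#'
#' @param type_code Integer 1-7 (Fig.-3-style taxonomy).
#' @param z_start,z_end Section span.
#' @param s_anchor Lateral anchor (um) along the ribbon midline.
#' @param height Projection height in um (types 1-6).
#' @param contact_area Contact area in um^2 (type 7).
#' @param under_gv Optional id of the giant vacuole this connection lies
#'   beneath.
#' @param connection_id Optional object identifier.
#' @return A `vm_connection_spec`.
#' @export
connection_spec <- function(type_code, z_start, z_end, s_anchor,
                            height = NULL, contact_area = NULL,
                            under_gv = NULL, connection_id = NULL) {
  type_code <- as.integer(type_code)
  if (!(type_code %in% 1:7)) stop("`type_code` must be 1-7")
  if (z_end < z_start) stop("connection span reversed")
  if (type_code <= 6L) {
    if (is.null(height) || height < 0) stop("types 1-6 need a height >= 0")
  } else {
    if (is.null(contact_area) || contact_area < 0)
      stop("type 7 needs a contact_area >= 0")
  }
  structure(list(type_code = type_code, z_start = as.integer(z_start),
                 z_end = as.integer(z_end), s_anchor = s_anchor,
                 height = height, contact_area = contact_area,
                 under_gv = under_gv, connection_id = connection_id),
            class = "vm_connection_spec")
}

#' Cell specification
#'
#' Full parametric description of one inner-wall cell: dimensions, nucleus,
#' giant vacuoles, connections, adjacent-cell overlap, and B-pores.
#'
#' @param cell_id Cell identifier.
#' @param flow_area `"HIGH"`, `"LOW"` or `"NON"` flow-type label.
#' @param length Cell length along z (um); rounded to whole sections.
#' @param nuclear_width,nonnuclear_width Ribbon widths (um) at the nuclear
#'   bulge and away from it.
#' @param nuclear_thickness,nonnuclear_thickness Apical-basal heights (um).
#' @param curvature_radius Radius (um) of the inner-wall arc; `Inf` gives a
#'   straight ribbon.
#' @param gvs List of [gv_spec()] objects.
#' @param connections List of [connection_spec()] objects.
#' @param overlap_left,overlap_right Adjacent-cell overlap length (um) per
#'   side; forced to zero around B-pores.
#' @param bpores List of `list(side = -1 or 1, z = section)` B-pore sites.
#' @param seed Integer seed for the (small) stochastic rasterization details.
#' @return A `vm_cell_spec`.
#' @export
cell_spec <- function(cell_id, flow_area = c("HIGH", "LOW", "NON"),
                      length = 70, nuclear_width = 10,
                      nonnuclear_width = 5.7, nuclear_thickness = 6,
                      nonnuclear_thickness = 0.7, curvature_radius = 120,
                      gvs = list(), connections = list(),
                      overlap_left = 0.2, overlap_right = 0.2,
                      bpores = list(), seed = 1L) {
  flow_area <- match.arg(flow_area)
  if (length <= 0 || nuclear_width <= 0 || nonnuclear_width <= 0 ||
      nuclear_thickness <= 0 || nonnuclear_thickness <= 0)
    stop("cell dimensions must be positive")
  if (nuclear_width < nonnuclear_width)
    stop("`nuclear_width` must be >= `nonnuclear_width`")
  if (overlap_left < 0 || overlap_right < 0) stop("overlap must be >= 0")
  stopifnot(all(vapply(gvs, inherits, logical(1), "vm_gv_spec")),
            all(vapply(connections, inherits, logical(1),
                       "vm_connection_spec")))
  structure(list(cell_id = as.character(cell_id), flow_area = flow_area,
                 length = length, nuclear_width = nuclear_width,
                 nonnuclear_width = nonnuclear_width,
                 nuclear_thickness = nuclear_thickness,
                 nonnuclear_thickness = nonnuclear_thickness,
                 curvature_radius = curvature_radius, gvs = gvs,
                 connections = connections, overlap_left = overlap_left,
                 overlap_right = overlap_right, bpores = bpores,
                 seed = as.integer(seed)),
            class = "vm_cell_spec")
}

# connection taxonomy: structural category per type code
.vm_conn_taxonomy <- function() {
  data.frame(
    type_code = 1:7,
    origin = c("IW", "IW", "IW", "IW", "JCT", "JCT", "IW"),
    kind = c("process", "process", "tongue", "process", "process", "tongue",
             "apposition"),
    target = c("JCT_ECM", "JCT_CELL_BODY", "JCT_GROOVE", "JCT_CELL_PROCESS",
               "IW_CELL_BODY", "IW_GROOVE", "JCT_CELL_BODY"),
    stringsAsFactors = FALSE
  )
}

# ---- single-cell rasterization ----------------------------------------------

#' Rasterize a cell specification into a contour stack
#'
#' Deterministic for a fixed spec (the spec's `seed` drives the only random
#' element, a gentle lateral wobble of the whole assembly along z). Ground
#' truth records the analytic, pre-rasterization values of every quantity the
#' measurement modules recover.
#'
#' @param spec A [cell_spec()].
#' @param acquisition An [acquisition_params()]; vertices are snapped to its
#'   pixel grid.
#' @param field_width,field_height Imaging field (um).
#' @param sampling_interval Section interval at which ground-truth overlap
#'   samples are recorded (matching the measurement convention).
#' @return `list(stack = vm_stack, truth = list(cell, gvs, connections,
#'   bpores, ol))` where the truth components are data frames.
#' @export
generate_cell <- function(spec, acquisition = acquisition_params(),
                          field_width = 141, field_height = 65,
                          sampling_interval = 40L) {
  stopifnot(inherits(spec, "vm_cell_spec"))
  px <- acquisition$pixel_size
  tsec <- acquisition$section_thickness
  n <- max(1L, as.integer(round(spec$length / tsec)))
  t <- spec$nonnuclear_thickness
  Tn <- spec$nuclear_thickness
  w <- spec$nonnuclear_width
  wn <- spec$nuclear_width
  R <- spec$curvature_radius
  xc <- field_width / 2
  y0 <- 18

  # --- object-id bookkeeping
  gv_ids <- vapply(seq_along(spec$gvs), function(i) {
    id <- spec$gvs[[i]]$gv_id
    if (is.null(id)) paste0(spec$cell_id, "_gv", i) else id
  }, character(1))
  cn_ids <- vapply(seq_along(spec$connections), function(i) {
    id <- spec$connections[[i]]$connection_id
    if (is.null(id)) paste0(spec$cell_id, "_cn", i) else id
  }, character(1))
  all_ids <- c(spec$cell_id, gv_ids, cn_ids)
  if (anyDuplicated(all_ids))
    stop("overlapping object_ids in cell spec '", spec$cell_id, "'")

  # --- per-section profiles
  zv <- 0:(n - 1)
  zc_n <- floor(n / 2)
  cns <- max(4, round(min(5, 0.12 * spec$length) / tsec))
  nk <- sqrt(pmax(0, 1 - ((zv - zc_n) / cns)^2))
  nk_eff <- pmax(0, (nk - 0.25) / 0.75)
  aw <- w / 2 + (wn - w) / 2 * nk_eff
  a_n <- 0.30 * wn                      # nuclear bulge lateral semi-axis
  Hn <- Tn * nk                         # nuclear bulge height profile
  nuc_present <- nk > 0.25 & (Hn / 2 - 0.04) > 0.05

  # --- validate giant vacuoles against the envelope
  for (i in seq_along(spec$gvs)) {
    g <- spec$gvs[[i]]
    if (abs(g$s_center) + g$semi_lateral > w / 2 - 0.2)
      stop("giant vacuole '", gv_ids[i],
           "' is larger than the cell envelope")
    czs <- g$semi_axial / tsec
    if (g$center_section - czs < 1 || g$center_section + czs > n - 2)
      stop("giant vacuole '", gv_ids[i], "' exceeds the cell span")
  }
  for (i in seq_along(spec$connections)) {
    cn <- spec$connections[[i]]
    if (cn$z_start < 0 || cn$z_end > n - 1)
      stop("connection '", cn_ids[i], "' exceeds the cell span")
  }

  # --- lateral wobble (the only seeded element)
  phase <- .vm_with_seed(spec$seed, stats::runif(1, 0, 2 * pi))
  x0z <- xc + 0.15 * sin(2 * pi * zv / 400 + phase)

  map_sh <- function(s, h, z) {
    x0 <- x0z[z + 1L]
    if (is.finite(R)) {
      phi <- s / R
      m <- cbind(x0 + (R + h) * sin(phi), y0 + (R + h) * cos(phi) - R)
    } else {
      m <- cbind(x0 + s, y0 + h)
    }
    .vm_snap(m, px)
  }
  dedupe <- function(m) {
    if (nrow(m) < 2L) return(m)
    keep <- c(TRUE, rowSums(abs(diff(m))) > px / 4)
    m <- m[keep, , drop = FALSE]
    if (nrow(m) > 1L && sum(abs(m[1, ] - m[nrow(m), ])) < px / 4)
      m <- m[-nrow(m), , drop = FALSE]
    m
  }

  # effective per-section overlap per side, honouring B-pore neighbourhoods
  pore_span <- 2L
  ol_base <- c(spec$overlap_left, spec$overlap_right)
  pore_z <- lapply(c(-1, 1), function(sd) {
    zz <- unlist(lapply(spec$bpores,
                        function(b) if (b$side == sd) b$z else NULL))
    if (is.null(zz)) integer(0) else as.integer(zz)
  })
  ol_eff <- function(side, z) {
    si <- if (side < 0) 1L else 2L
    zp <- pore_z[[si]]
    if (length(zp) && any(z >= zp - 4L & z <= zp + pore_span - 1L + 4L))
      return(0)
    ol_base[si]
  }
  is_pore_sec <- function(side, z) {
    si <- if (side < 0) 1L else 2L
    zp <- pore_z[[si]]
    length(zp) && any(z >= zp & z <= zp + pore_span - 1L)
  }

  taxo <- .vm_conn_taxonomy()
  conn_geo <- lapply(seq_along(spec$connections), function(i) {
    cn <- spec$connections[[i]]
    tx <- taxo[cn$type_code, ]
    nspan <- cn$z_end - cn$z_start + 1L
    list(spec = cn, id = cn_ids[i],
         meta = list(origin = tx$origin, kind = tx$kind, target = tx$target),
         len_per_sec = if (cn$type_code == 7L)
           cn$contact_area / (nspan * tsec) else NA_real_,
         zc = as.integer(round((cn$z_start + cn$z_end) / 2)))
  })

  sections <- vector("list", n)
  adj_ext <- 2.3
  for (z in zv) {
    awz <- aw[z + 1L]
    cts <- list()

    # active bulges on this section
    bulges <- list()
    if (nuc_present[z + 1L])
      bulges[[length(bulges) + 1L]] <-
        list(kind = "nuc", sc = 0, A = a_n * nk[z + 1L], H = Hn[z + 1L])
    gv_active <- list()
    for (i in seq_along(spec$gvs)) {
      g <- spec$gvs[[i]]
      kz2 <- 1 - ((z - g$center_section) * tsec / g$semi_axial)^2
      if (kz2 <= 0.0025) next
      kz <- sqrt(kz2)
      ak <- g$semi_lateral * kz
      bk <- g$semi_radial * kz
      if (ak < 5 * px || bk < 3 * px) next
      gv_active[[length(gv_active) + 1L]] <-
        list(i = i, id = gv_ids[i], sc = g$s_center, ak = ak, bk = bk,
             hc = -t / 2 + g$semi_radial, g = g)
      bulges[[length(bulges) + 1L]] <-
        list(kind = "gv", sc = g$s_center, A = ak, H = NA,
             hc = -t / 2 + g$semi_radial, bk = bk)
    }

    # envelope top boundary
    svals <- c(seq(-awz, awz, by = 1.0), awz)
    for (b in bulges) {
      grid <- seq(b$sc - b$A, b$sc + b$A, length.out = 21)
      svals <- c(svals, grid, b$sc - b$A - 2.5 * px, b$sc + b$A + 2.5 * px)
    }
    svals <- sort(unique(pmin(awz, pmax(-awz, svals))))
    top <- rep(t / 2, length(svals))
    for (b in bulges) {
      u2 <- 1 - ((svals - b$sc) / b$A)^2
      inb <- u2 > 0
      if (!any(inb)) next
      prof <- if (b$kind == "nuc") {
        -t / 2 + b$H * sqrt(u2[inb])
      } else {
        b$hc + b$bk * sqrt(u2[inb])
      }
      top[inb] <- pmax(top[inb], prof)
    }

    # envelope bottom boundary (extra vertices beneath connection anchors
    # keep measured projection heights exact)
    sbot <- c(seq(-awz, awz, by = 0.8), awz)
    for (cg in conn_geo) {
      cn <- cg$spec
      if (z >= cn$z_start && z <= cn$z_end) sbot <- c(sbot, cn$s_anchor)
    }
    sbot <- sort(unique(pmin(awz, pmax(-awz, sbot))), decreasing = TRUE)

    env_sh <- rbind(cbind(svals, top), cbind(sbot, -t / 2))
    env_xy <- dedupe(map_sh(env_sh[, 1], env_sh[, 2], z))
    cts[[length(cts) + 1L]] <- contour("IW_CELL", spec$cell_id, env_xy)

    # nucleus: flat-based apical dome strictly inside the envelope
    if (nuc_present[z + 1L]) {
      H <- Hn[z + 1L]; An <- a_n * nk[z + 1L]
      u <- seq(-1, 1, length.out = 31)
      sdome <- 0.97 * An * u
      hdome <- -t / 2 + 0.02 + (H - 0.06) * sqrt(pmax(0, 1 - u^2))
      dome <- rbind(cbind(sdome, hdome),
                    c(0.97 * An, -t / 2 + 0.02),
                    c(-0.97 * An, -t / 2 + 0.02))
      pts <- dedupe(map_sh(dome[, 1], dome[, 2], z))
      if (nrow(pts) >= 3L)
        cts[[length(cts) + 1L]] <- contour("NUCLEUS",
                                           paste0(spec$cell_id, "_nuc"), pts)
    }

    # giant vacuoles and their opening annotations
    for (ga in gv_active) {
      th <- seq(0, 2 * pi, length.out = 49)[-49]
      pts <- dedupe(map_sh(ga$sc + ga$ak * cos(th),
                           ga$hc + ga$bk * sin(th), z))
      if (nrow(pts) >= 3L)
        cts[[length(cts) + 1L]] <- contour("GV", ga$id, pts)
      g <- ga$g
      if (z == g$center_section) {
        if (g$has_basal_opening) {
          bo <- rbind(c(ga$sc - 0.15, -t / 2 - 0.04),
                      c(ga$sc + 0.15, -t / 2 - 0.04),
                      c(ga$sc + 0.15, -t / 2 + 0.04),
                      c(ga$sc - 0.15, -t / 2 + 0.04))
          cts[[length(cts) + 1L]] <-
            contour("BASAL_OPENING", paste0(ga$id, "_bo"),
                    dedupe(map_sh(bo[, 1], bo[, 2], z)))
        }
        if (g$n_ipores >= 1L) {
          tp <- ga$hc + ga$bk
          ip <- rbind(c(ga$sc - 0.1, tp - 0.03), c(ga$sc + 0.1, tp - 0.03),
                      c(ga$sc + 0.1, tp + 0.03), c(ga$sc - 0.1, tp + 0.03))
          cts[[length(cts) + 1L]] <-
            contour("IPORE_OPENING", paste0(ga$id, "_ip1"),
                    dedupe(map_sh(ip[, 1], ip[, 2], z)))
        }
      }
      if (g$n_ipores >= 2L && z == g$center_section + 2L) {
        tp <- ga$hc + ga$bk
        ip <- rbind(c(ga$sc + 0.1, tp - 0.03), c(ga$sc + 0.3, tp - 0.03),
                    c(ga$sc + 0.3, tp + 0.03), c(ga$sc + 0.1, tp + 0.03))
        cts[[length(cts) + 1L]] <-
          contour("IPORE_OPENING", paste0(ga$id, "_ip2"),
                  dedupe(map_sh(ip[, 1], ip[, 2], z)))
      }
    }

    # adjacent cells and B-pores
    for (side in c(-1, 1)) {
      sd_id <- paste0(spec$cell_id, if (side < 0) "_adjL" else "_adjR")
      ol <- ol_eff(side, z)
      pore <- is_pore_sec(side, z)
      if (pore) {
        s1 <- awz + 0.25; s2 <- awz + adj_ext
        h1 <- -t / 2; h2 <- t / 2
        po <- rbind(c(awz + 0.03, -0.08), c(awz + 0.22, -0.08),
                    c(awz + 0.22, 0.08), c(awz + 0.03, 0.08))
        po[, 1] <- side * po[, 1]
        zp <- pore_z[[if (side < 0) 1L else 2L]]
        zp0 <- zp[which(z >= zp & z <= zp + pore_span - 1L)[1]]
        cts[[length(cts) + 1L]] <-
          contour("BPORE_OPENING",
                  paste0(spec$cell_id, "_bp",
                         if (side < 0) "L" else "R", zp0),
                  dedupe(map_sh(po[, 1], po[, 2], z)))
      } else if (ol > 0) {
        s1 <- awz - ol; s2 <- awz + adj_ext
        h1 <- t / 2; h2 <- t / 2 + 0.25
      } else {
        s1 <- awz; s2 <- awz + adj_ext
        h1 <- -t / 2; h2 <- t / 2
      }
      sgrid <- sort(unique(c(seq(s1, s2, by = 0.8), s2)))
      strip <- rbind(cbind(sgrid, h1), cbind(rev(sgrid), h2))
      strip[, 1] <- side * strip[, 1]
      pts <- dedupe(map_sh(strip[, 1], strip[, 2], z))
      if (nrow(pts) >= 3L)
        cts[[length(cts) + 1L]] <- contour("ADJACENT_IW_CELL", sd_id, pts)
    }

    # connections
    for (cg in conn_geo) {
      cn <- cg$spec
      if (z < cn$z_start || z > cn$z_end) next
      if (cn$type_code == 7L) {
        len <- cg$len_per_sec
        sh <- rbind(c(cn$s_anchor - len / 2, -t / 2),
                    c(cn$s_anchor + len / 2, -t / 2),
                    c(cn$s_anchor + len / 2, -t / 2 - 0.045),
                    c(cn$s_anchor - len / 2, -t / 2 - 0.045))
      } else {
        wd <- if (cg$meta$kind == "tongue") 0.4 else 0.16
        H <- cn$height
        sh <- rbind(c(cn$s_anchor - wd / 2, -t / 2),
                    c(cn$s_anchor + wd / 2, -t / 2),
                    c(cn$s_anchor + wd / 2, -t / 2 - H),
                    c(cn$s_anchor, -t / 2 - H),
                    c(cn$s_anchor - wd / 2, -t / 2 - H))
      }
      pts <- dedupe(map_sh(sh[, 1], sh[, 2], z))
      if (nrow(pts) >= 3L)
        cts[[length(cts) + 1L]] <-
          contour("CONNECTION_ENDPOINT", cg$id, pts, meta = cg$meta)
      # companion target structure at the central section
      if (z == cg$zc) {
        H <- if (cn$type_code == 7L) 0.045 else cn$height
        tg <- rbind(c(cn$s_anchor - 0.2, -t / 2 - H - 0.12),
                    c(cn$s_anchor + 0.2, -t / 2 - H - 0.12),
                    c(cn$s_anchor + 0.2, -t / 2 - H - 0.02),
                    c(cn$s_anchor - 0.2, -t / 2 - H - 0.02))
        lab <- if (cn$type_code == 1L) "JCT_ECM_ANCHOR" else "JCT_CELL"
        oid <- if (cn$type_code == 1L) paste0(cg$id, "_ecm")
               else paste0(spec$cell_id, "_jct")
        pts <- dedupe(map_sh(tg[, 1], tg[, 2], z))
        if (nrow(pts) >= 3L)
          cts[[length(cts) + 1L]] <- contour(lab, oid, pts)
      }
    }

    sections[[z + 1L]] <- section(z, cts)
  }

  stack <- section_stack(sections, acquisition = acquisition,
                         field_width = field_width,
                         field_height = field_height, validate = FALSE)

  # ---- analytic ground truth -------------------------------------------------

  # envelope area per section: ribbon plus apical bulge lenses
  lens_area <- function(A, B, tau) {
    # area of an ellipse-profile bulge of semi-axes (A, B) above the chord at
    # relative height tau = (cut - base)/B; tau < 1 required
    if (tau >= 1) return(0)
    if (tau <= -1) return(pi * A * B)
    if (tau >= 0) {
      q <- sqrt(1 - tau^2)
      A * B * (asin(q) - q * tau)
    } else {
      A * B * (pi / 2 - 2 * tau)
    }
  }
  env_area <- numeric(n)
  for (z in zv) {
    Aenv <- 2 * aw[z + 1L] * t
    if (nuc_present[z + 1L]) {
      H <- Hn[z + 1L]
      if (H > t)
        Aenv <- Aenv + lens_area(a_n * nk[z + 1L], H, t / H)
    }
    for (i in seq_along(spec$gvs)) {
      g <- spec$gvs[[i]]
      kz2 <- 1 - ((z - g$center_section) * tsec / g$semi_axial)^2
      if (kz2 <= 0.0025) next
      kz <- sqrt(kz2)
      ak <- g$semi_lateral * kz; bk <- g$semi_radial * kz
      if (ak < 5 * px || bk < 3 * px) next
      Aenv <- Aenv + lens_area(ak, bk, (t - g$semi_radial) / bk)
    }
    env_area[z + 1L] <- Aenv
  }
  gv_vol <- vapply(spec$gvs, function(g)
    4 / 3 * pi * g$semi_lateral * g$semi_radial * g$semi_axial, numeric(1))
  cell_volume <- sum(env_area) * tsec - sum(gv_vol)

  # drawn overlap length at the measurement sections
  zsamp <- seq(0L, n - 1L, by = sampling_interval)
  ol_rows <- list()
  for (side in c(-1, 1)) {
    for (z in zsamp) {
      ol <- ol_eff(side, z)
      val <- 0
      if (ol > 0 && !is_pore_sec(side, z)) {
        awz <- aw[z + 1L]
        p <- map_sh(side * c(awz - ol, awz), c(t / 2, t / 2), z)
        val <- sqrt(sum((p[2, ] - p[1, ])^2))
      }
      ol_rows[[length(ol_rows) + 1L]] <-
        data.frame(cell_id = spec$cell_id, section = z,
                   side = if (side < 0) "left" else "right", ol = val,
                   stringsAsFactors = FALSE)
    }
  }
  ol_df <- do.call(rbind, ol_rows)

  n_beneath <- vapply(gv_ids, function(id)
    sum(vapply(spec$connections,
               function(cn) identical(cn$under_gv, id), logical(1))),
    integer(1))

  truth <- list(
    cell = data.frame(
      cell_id = spec$cell_id, flow_area = spec$flow_area,
      length = n * tsec, nuclear_width = wn, nonnuclear_width = w,
      nuclear_thickness = Tn, nonnuclear_thickness = t,
      volume = cell_volume, ol_mean = mean(ol_df$ol),
      n_sections = n, n_connections = length(spec$connections),
      stringsAsFactors = FALSE),
    gvs = if (length(spec$gvs)) data.frame(
      gv_id = gv_ids, cell_id = spec$cell_id, flow_area = spec$flow_area,
      volume = gv_vol,
      has_basal_opening = vapply(spec$gvs, `[[`, logical(1),
                                 "has_basal_opening"),
      has_ipore = vapply(spec$gvs, `[[`, logical(1), "has_ipore"),
      n_ipores = vapply(spec$gvs, `[[`, integer(1), "n_ipores"),
      gv_type = classify_gv(
        vapply(spec$gvs, `[[`, logical(1), "has_basal_opening"),
        vapply(spec$gvs, `[[`, logical(1), "has_ipore")),
      n_connections_beneath = unname(n_beneath),
      stringsAsFactors = FALSE) else NULL,
    connections = if (length(spec$connections)) data.frame(
      connection_id = cn_ids, cell_id = spec$cell_id,
      flow_area = spec$flow_area,
      type_code = vapply(spec$connections, `[[`, integer(1), "type_code"),
      height = vapply(spec$connections, function(cn)
        if (is.null(cn$height)) NA_real_ else cn$height, numeric(1)),
      contact_area = vapply(spec$connections, function(cn)
        if (is.null(cn$contact_area)) NA_real_ else cn$contact_area,
        numeric(1)),
      z_start = vapply(spec$connections, `[[`, integer(1), "z_start"),
      z_end = vapply(spec$connections, `[[`, integer(1), "z_end"),
      s_anchor = vapply(spec$connections, `[[`, numeric(1), "s_anchor"),
      under_gv = vapply(spec$connections, function(cn)
        if (is.null(cn$under_gv)) NA_character_ else cn$under_gv,
        character(1)),
      stringsAsFactors = FALSE) else NULL,
    bpores = if (length(spec$bpores)) data.frame(
      bpore_id = vapply(spec$bpores, function(b)
        paste0(spec$cell_id, "_bp", if (b$side < 0) "L" else "R", b$z),
        character(1)),
      cell_id = spec$cell_id, flow_area = spec$flow_area,
      side = vapply(spec$bpores, function(b)
        if (b$side < 0) "left" else "right", character(1)),
      z_start = vapply(spec$bpores, function(b) as.integer(b$z), integer(1)),
      z_end = vapply(spec$bpores, function(b)
        as.integer(b$z + pore_span - 1L), integer(1)),
      stringsAsFactors = FALSE) else NULL,
    ol = ol_df
  )
  list(stack = stack, truth = truth)
}
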