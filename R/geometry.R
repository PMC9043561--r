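# Internal planar-geometry utilities shared by the measurement modules.
# All coordinates are micrometres; polygons are vertex matrices (n x 2),
# implicitly closed.

# snap coordinates to the pixel grid
.vm_snap <- function(x, px) round(x / px) * px

.vm_polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                    pts[-nrow(pts), , drop = FALSE])^2)))
}

# densely resample a closed polygon boundary; original vertices are retained
.vm_resample_boundary <- function(poly, step = 0.05, closed = TRUE) {
  n <- nrow(poly)
  idx <- if (closed) c(seq_len(n), 1L) else seq_len(n)
  out <- vector("list", length(idx) - 1L)
  for (i in seq_len(length(idx) - 1L)) {
    a <- poly[idx[i], ]; b <- poly[idx[i + 1L], ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  if (!closed) out[[length(out) + 1L]] <- poly[n, , drop = FALSE]
  do.call(rbind, out)
}

# minimum distance from each query point to a polygon boundary (vectorised
# over edges for each point)
.vm_dist_to_poly <- function(pts, poly, closed = TRUE) {
  pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  i2 <- if (closed) c(2:n, 1L) else 2:n
  i1 <- if (closed) 1:n else 1:(n - 1L)
  ax <- poly[i1, 1]; ay <- poly[i1, 2]
  bx <- poly[i2, 1]; by <- poly[i2, 2]
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  L2[L2 == 0] <- .Machine$double.eps
  apply(pts, 1L, function(p) {
    t <- ((p[1] - ax) * dx + (p[2] - ay) * dy) / L2
    t <- pmin(1, pmax(0, t))
    qx <- ax + t * dx; qy <- ay + t * dy
    sqrt(min((p[1] - qx)^2 + (p[2] - qy)^2))
  })
}

# point-in-polygon (even-odd rule) for a single point
.vm_point_in_poly <- function(p, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  x <- poly[, 1]; y <- poly[, 2]
  cross <- ((y > p[2]) != (y[j] > p[2])) &
    (p[1] < (x[j] - x) * (p[2] - y) / (y[j] - y) + x)
  (sum(cross, na.rm = TRUE) %% 2L) == 1L
}

# largest pairwise distance between vertices (diameter of the vertex set)
.vm_poly_diameter <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  h <- tryCatch(grDevices::chull(pts), error = function(e) seq_len(nrow(pts)))
  q <- pts[h, , drop = FALSE]
  d2 <- outer(q[, 1], q[, 1], "-")^2 + outer(q[, 2], q[, 2], "-")^2
  sqrt(max(d2))
}

# Douglas-Peucker split indices (returned sorted, including endpoints)
.vm_dp_indices <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(seq_len(n))
  keep <- c(1L, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    L <- sqrt(sum(ab^2))
    mid <- (i + 1L):(j - 1L)
    if (L < .Machine$double.eps) {
      d <- sqrt(rowSums(sweep(pts[mid, , drop = FALSE], 2, a)^2))
    } else {
      d <- abs((pts[mid, 1] - a[1]) * ab[2] - (pts[mid, 2] - a[2]) * ab[1]) / L
    }
    k <- which.max(d)
    if (d[k] > tol) {
      kk <- mid[k]
      keep <- c(keep, kk)
      stack[[length(stack) + 1L]] <- c(i, kk)
      stack[[length(stack) + 1L]] <- c(kk, j)
    }
  }
  sort(unique(keep))
}

# ---- ribbon midline --------------------------------------------------------

# Extract the midline (medial polyline) of a thin, elongated "ribbon" polygon
# such as an endothelial-cell profile. Robust to one-sided bulges (nucleus,
# giant vacuoles): the flatter boundary side is taken as the basal reference
# and bulge bins are offset from it by half the ribbon thickness.
#
# Returns list(pts, tangents, t_est, axis) or NULL when the profile is too
# small to bin.
.vm_midline <- function(poly, bin = 0.15, smooth_win = 2, step = 0.05) {
  B <- .vm_resample_boundary(poly, step = step)
  ctr <- colMeans(B)
  X <- sweep(B, 2, ctr)
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)$vectors
  e1 <- ev[, 1]; e2 <- ev[, 2]

  detilt <- function(u, v) {
    br <- seq(min(u) - 1e-9, max(u) + 1e-9, by = bin)
    if (length(br) < 4L) return(NULL)
    g <- findInterval(u, br)
    vmin <- tapply(v, g, min); vmax <- tapply(v, g, max)
    um <- tapply(u, g, mean)
    ok <- !is.na(vmin)
    if (sum(ok) < 3L) return(NULL)
    rs <- function(y) {
      f <- stats::lm.fit(cbind(1, um[ok]), y[ok])
      list(slope = f$coefficients[2], sd = stats::sd(f$residuals))
    }
    lo <- rs(vmin); hi <- rs(vmax)
    basal_min <- lo$sd <= hi$sd
    slope <- if (basal_min) lo$slope else hi$slope
    list(angle = atan(slope), basal_min = basal_min,
         fit_sd = min(lo$sd, hi$sd))
  }
  # the lateral axis is the principal axis whose perpendicular boundary
  # (basal membrane) fits a line best; a tall nuclear bulge can otherwise
  # flip the principal axis to the apical-basal direction
  u <- as.numeric(X %*% e1); v <- as.numeric(X %*% e2)
  dt <- detilt(u, v)
  if (is.null(dt) || dt$fit_sd > 0.2) {
    dt_alt <- detilt(v, -u)
    if (!is.null(dt_alt) && (is.null(dt) || dt_alt$fit_sd < dt$fit_sd)) {
      tmp <- u; u <- v; v <- -tmp
      e1n <- e2; e2 <- -e1; e1 <- e1n
      dt <- dt_alt
    }
  }
  if (is.null(dt)) return(NULL)
  ca <- cos(dt$angle); sa <- sin(dt$angle)
  u2 <- ca * u + sa * v
  v2 <- -sa * u + ca * v
  f1 <- ca * e1 + sa * e2          # in-plane axis after de-tilt
  f2 <- -sa * e1 + ca * e2

  br <- seq(min(u2) - 1e-9, max(u2) + 1e-9, by = bin)
  g <- findInterval(u2, br)
  vmin <- tapply(v2, g, min); vmax <- tapply(v2, g, max)
  um <- tapply(u2, g, mean)
  o <- order(um)
  um <- as.numeric(um[o]); vmin <- as.numeric(vmin[o]); vmax <- as.numeric(vmax[o])
  h <- vmax - vmin
  # ribbon thickness from a low quantile of interior bin heights: robust even
  # when a nuclear or vacuolar bulge covers most of the lateral extent
  # (the partial bins at the ends may cover only part of the cap)
  h_int <- if (length(h) > 4L) h[-c(1L, length(h))] else h
  t_est <- stats::quantile(h_int, 0.1, names = FALSE)
  bulge <- h > 1.12 * t_est
  vmid <- ifelse(bulge,
                 if (dt$basal_min) vmin + t_est / 2 else vmax - t_est / 2,
                 (vmin + vmax) / 2)

  # exact lateral extremes: the boundary point at mid-ribbon height with the
  # extreme lateral coordinate, i.e. where the midline meets the end cap
  # (robust to the radial tilt of the caps on a curved ribbon)
  cap <- function(side) {
    # basal reference from the nearest full (interior) bin: the extreme bin
    # may cover only part of the end cap
    ebin <- if (side > 0) max(1L, length(um) - 1L) else min(2L, length(um))
    vm_end <- if (dt$basal_min) vmin[ebin] + t_est / 2
              else vmax[ebin] - t_est / 2
    band <- which(abs(v2 - vm_end) <= 0.3 * t_est)
    if (!length(band)) band <- seq_along(u2)
    # cap region = band points near the lateral extreme (the cap may lean a
    # little on a curved ribbon); take the one at mid-ribbon height
    lim <- max(side * u2[band])
    capr <- band[side * u2[band] >= lim - 0.12]
    k <- capr[which.min(abs(v2[capr] - vm_end))]
    c(u2[k], v2[k])
  }
  lo_end <- cap(-1); hi_end <- cap(1)
  # drop the partial, cap-dominated extreme bins; the cap endpoints represent
  # the lateral extremes exactly
  if (length(um) > 4L) {
    um <- um[-c(1L, length(um))]
    vmid <- vmid[-c(1L, length(vmid))]
  }
  um <- c(lo_end[1], um, hi_end[1])
  vmid <- c(lo_end[2], vmid, hi_end[2])

  # running-mean smoothing of the medial offset over a fixed window
  if (length(um) > 2L && smooth_win > 0) {
    vs <- vmid
    for (i in seq_along(um)) {
      sel <- abs(um - um[i]) <= smooth_win / 2
      vs[i] <- mean(vmid[sel])
    }
    vs[1] <- vmid[1]; vs[length(vs)] <- vmid[length(vs)]
    vmid <- vs
  }

  pts <- cbind(ctr[1] + um * f1[1] + vmid * f2[1],
               ctr[2] + um * f1[2] + vmid * f2[2])
  m <- nrow(pts)
  tang <- matrix(0, m, 2)
  tang[1, ] <- pts[2, ] - pts[1, ]
  tang[m, ] <- pts[m, ] - pts[m - 1, ]
  if (m > 2L) {
    tang[2:(m - 1), ] <- pts[3:m, , drop = FALSE] -
      pts[1:(m - 2), , drop = FALSE]
    # the cap endpoint sits laterally close to the first bin centre, so the
    # one-sided difference there can point almost anywhere; use the adjacent
    # interior tangent for the local axis at the ends
    tang[1, ] <- tang[2, ]
    tang[m, ] <- tang[m - 1, ]
  }
  tang <- tang / pmax(sqrt(rowSums(tang^2)), .Machine$double.eps)
  list(pts = pts, tangents = tang, t_est = t_est, axis = f1,
       basal_min = dt$basal_min, frame = list(ctr = ctr, f1 = f1, f2 = f2))
}

# local axis direction (unit vector) of the midline nearest to point p
.vm_axis_at <- function(mid, p) {
  d2 <- (mid$pts[, 1] - p[1])^2 + (mid$pts[, 2] - p[2])^2
  mid$tangents[which.min(d2), ]
}

# ---- segmented-line width --------------------------------------------------

# Length of a <= `nseg`-segment polyline through the midline points,
# breakpoints chosen to minimise the maximal deviation of the midline from
# the polyline (dynamic programme over candidate breakpoints).
.vm_segline_width <- function(mid_pts, nseg = 3L, cand_step = 0.4) {
  m <- nrow(mid_pts)
  if (m <= 2L) return(.vm_polyline_length(mid_pts))
  # candidate breakpoints subsampled along the midline
  s <- c(0, cumsum(sqrt(rowSums((mid_pts[-1, , drop = FALSE] -
                                 mid_pts[-m, , drop = FALSE])^2))))
  want <- seq(0, s[m], by = cand_step)
  cand <- unique(c(1L, vapply(want, function(w) which.min(abs(s - w)),
                              integer(1)), m))
  cand <- sort(cand)
  nc <- length(cand)
  segerr <- function(i, j) {
    a <- mid_pts[i, ]; b <- mid_pts[j, ]
    ab <- b - a; L <- sqrt(sum(ab^2))
    ks <- i:j
    if (L < .Machine$double.eps)
      return(max(sqrt(rowSums(sweep(mid_pts[ks, , drop = FALSE], 2, a)^2))))
    max(abs((mid_pts[ks, 1] - a[1]) * ab[2] -
            (mid_pts[ks, 2] - a[2]) * ab[1]) / L)
  }
  E <- matrix(Inf, nc, nc)
  for (ii in 1:(nc - 1L)) for (jj in (ii + 1L):nc)
    E[ii, jj] <- segerr(cand[ii], cand[jj])
  best <- Inf; bi <- c(1L, nc, nc)
  for (ii in 2:(nc - 1L)) {
    for (jj in ii:(nc - 1L)) {
      e <- max(E[1, ii], E[ii, jj], E[jj, nc])
      if (e < best) { best <- e; bi <- c(ii, jj, nc) }
    }
  }
  bp <- cand[unique(c(1L, bi))]
  .vm_polyline_length(mid_pts[bp, , drop = FALSE])
}

# ---- profile extent along a line -------------------------------------------

# Extent of a polygon along the line through `origin` in unit direction
# `normal` (the intersection chord length); 0 if the line misses the polygon.
.vm_extent_along <- function(poly, origin, normal) {
  tangent <- c(-normal[2], normal[1])
  d <- (poly[, 1] - origin[1]) * tangent[1] +
       (poly[, 2] - origin[2]) * tangent[2]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  cross <- which(d * d[j] < 0 | (d == 0))
  if (!length(cross)) return(0)
  svals <- numeric(0)
  for (i in cross) {
    k <- j[i]
    if (d[i] == 0) {
      q <- poly[i, ]
    } else if (d[k] == 0) {
      next  # counted when the loop reaches k
    } else {
      t <- d[i] / (d[i] - d[k])
      q <- poly[i, ] + t * (poly[k, ] - poly[i, ])
    }
    svals <- c(svals, (q[1] - origin[1]) * normal[1] +
                      (q[2] - origin[2]) * normal[2])
  }
  if (length(svals) < 2L) return(0)
  max(svals) - min(svals)
}
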