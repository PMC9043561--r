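# Programmatic fixtures shared across the test files. Everything is built in
# code; no binary data.

# rectangle polygon (implicitly closed)
rect_poly <- function(x0, x1, y0, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

# regular n-gon of circumradius r
ngon_poly <- function(n, r = 1, cx = 0, cy = 0, phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# a cuboid cell: w x d rectangle envelope on n sections
cuboid_stack <- function(w = 10, d = 5, n = 20, cell_id = "cub",
                         x0 = 30, y0 = 20) {
  secs <- lapply(0:(n - 1L), function(z)
    section(z, list(contour("IW_CELL", cell_id,
                            rect_poly(x0, x0 + w, y0, y0 + d)))))
  section_stack(secs)
}

# slab cell (thin rectangle ribbon) on n sections, optionally with extras
# added per section via `extra(z)` returning a list of contours
slab_stack <- function(w = 10, t = 0.7, n = 5, cell_id = "slab",
                       x0 = 30, y0 = 20, extra = NULL) {
  secs <- lapply(0:(n - 1L), function(z) {
    cts <- list(contour("IW_CELL", cell_id,
                        rect_poly(x0, x0 + w, y0, y0 + t)))
    if (!is.null(extra)) cts <- c(cts, extra(z))
    section(z, cts)
  })
  section_stack(secs)
}

# curved ribbon: circular-arc midline of radius R spanning `arc` um of arc
# length, constant radial thickness t, densely sampled boundary
arc_ribbon_poly <- function(R = 20, arc = 10, t = 0.7, cx = 70, cy = 20,
                            n_s = 200) {
  phi <- seq(-arc / (2 * R), arc / (2 * R), length.out = n_s)
  cen <- c(cx, cy - R)
  outer_b <- cbind(cen[1] + (R + t / 2) * sin(phi),
                   cen[2] + (R + t / 2) * cos(phi))
  inner_b <- cbind(cen[1] + (R - t / 2) * sin(rev(phi)),
                   cen[2] + (R - t / 2) * cos(rev(phi)))
  rbind(outer_b, inner_b)
}

# sphere rasterized as per-section circles (GV object only)
sphere_stack <- function(r = 1, label = "GV", object_id = "gv1",
                         tsec = 0.13, nv = 180, cx = 70, cy = 20) {
  acq <- acquisition_params(section_thickness = tsec)
  kmax <- floor(r / tsec)
  secs <- list()
  z <- 0L
  for (k in -kmax:kmax) {
    rho2 <- r^2 - (k * tsec)^2
    if (rho2 <= 0) next
    secs[[length(secs) + 1L]] <-
      section(z, list(contour(label, object_id,
                              ngon_poly(nv, sqrt(rho2), cx, cy))))
    z <- z + 1L
  }
  section_stack(secs, acquisition = acq)
}

# voxel-count volume oracle: counts pixel centres inside each contour of the
# object, independent of the shoelace/section-sum implementation
voxel_volume <- function(stack, object_id) {
  px <- stack$acquisition$pixel_size
  tsec <- stack$acquisition$section_thickness
  total <- 0
  for (h in stack_contours(stack, object_id = object_id)) {
    p <- h$contour$points
    xs <- seq(floor(min(p[, 1]) / px) * px, max(p[, 1]) + px, by = px)
    ys <- seq(floor(min(p[, 2]) / px) * px, max(p[, 2]) + px, by = px)
    inside <- 0L
    for (y in ys) {
      # even-odd crossings along a horizontal scan line
      n <- nrow(p)
      j <- c(n, seq_len(n - 1L))
      crossings <- numeric(0)
      for (i in seq_len(n)) {
        yi <- p[i, 2]; yj <- p[j[i], 2]
        if ((yi > y) != (yj > y)) {
          crossings <- c(crossings,
                         p[i, 1] + (y - yi) / (yj - yi) *
                           (p[j[i], 1] - p[i, 1]))
        }
      }
      crossings <- sort(crossings)
      if (length(crossings) >= 2L) {
        for (ci in seq(1L, length(crossings) - 1L, by = 2L)) {
          inside <- inside +
            sum(xs >= crossings[ci] & xs <= crossings[ci + 1L])
        }
      }
    }
    total <- total + inside * px^2
  }
  total * tsec
}

# rigid in-plane transform of a whole stack
transform_stack <- function(stack, angle = 0, dx = 0, dy = 0,
                            pivot = c(70, 30)) {
  ca <- cos(angle); sa <- sin(angle)
  secs <- lapply(stack$sections, function(sec) {
    cts <- lapply(sec$contours, function(ct) {
      p <- sweep(ct$points, 2, pivot)
      q <- cbind(ca * p[, 1] - sa * p[, 2], sa * p[, 1] + ca * p[, 2])
      q <- sweep(q, 2, pivot + c(dx, dy), "+")
      contour(ct$label, ct$object_id, q, closed = ct$closed, meta = ct$meta)
    })
    section(sec$index, cts)
  })
  section_stack(secs, acquisition = stack$acquisition,
                field_width = stack$field_width + abs(dx) + 40,
                field_height = stack$field_height + abs(dy) + 40,
                validate = FALSE)
}

# slab cell with an adjacent-cell strip whose junction runs at `angle_deg`
# to the slab axis over lateral extent `ol`, on every section
angled_junction_stack <- function(ol = 0.3, angle_deg = 0, w = 10, t = 0.7,
                                  n = 3, x0 = 30, y0 = 20) {
  xr <- x0 + w
  slope <- tan(angle_deg * pi / 180)
  # envelope top has a ramp over [xr - ol, xr] rising with the given slope
  env <- rbind(c(x0, y0 + t), c(xr - ol, y0 + t),
               c(xr, y0 + t + ol * slope),
               c(xr, y0), c(x0, y0))
  # adjacent strip sits on the ramp and continues beyond the cell
  adj <- rbind(c(xr - ol, y0 + t), c(xr, y0 + t + ol * slope),
               c(xr + 2, y0 + t + ol * slope),
               c(xr + 2, y0 + t + ol * slope + 0.25),
               c(xr - ol, y0 + t + 0.25))
  secs <- lapply(0:(n - 1L), function(z)
    section(z, list(contour("IW_CELL", "slab", env),
                    contour("ADJACENT_IW_CELL", "adj", adj))))
  section_stack(secs)
}

# a small generated cell used by several connectivity tests
demo_cell_spec <- function(seed = 7) {
  cell_spec("c1", "HIGH", length = 20, nuclear_width = 9,
            nonnuclear_width = 5.7, nuclear_thickness = 5,
            nonnuclear_thickness = 0.7,
            gvs = list(gv_spec(30, 1.3, 1.0, 1.3, s_center = 0.8,
                               has_basal_opening = TRUE, has_ipore = TRUE),
                       gv_spec(120, 0.9, 0.7, 1.0, s_center = -1.0)),
            connections = list(
              connection_spec(1, 59, 61, 0.5, height = 0.5),
              connection_spec(3, 90, 92, 1.5, height = 0.45),
              connection_spec(4, 99, 101, -1.2, height = 0.35),
              connection_spec(6, 105, 107, 0.0, height = 0.7),
              connection_spec(7, 70, 74, 0.2, contact_area = 0.8),
              connection_spec(5, 28, 32, 0.8, height = 0.6,
                              under_gv = "c1_gv1")),
            overlap_left = 0.2, overlap_right = 0.3,
            bpores = list(list(side = 1, z = 110)), seed = seed)
}

# minimal Reconstruct series fixture written as text files; returns the
# series path
write_reconstruct_fixture <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("reconstruct")
    dir.create(dir)
  }
  ser <- file.path(dir, "demo.ser")
  writeLines('<?xml version="1.0"?><Series index="0" />', ser)
  sec0 <- file.path(dir, "demo.0")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<Section index="0" alignLocked="true">',
    ' <Transform dim="0" xcoef="0 1 0 0 0 0" ycoef="0 0 1 0 0 0">',
    '  <Image mag="0.0101" filename="demo.0.tif" />',
    '  <Contour name="IW_CELL" closed="True" border="1 0 0"',
    '   points="100 100, 600 100, 600 200, 100 200, "/>',
    '  <ZContour name="ztrace" closed="False" points="0 0 0"/>',
    ' </Transform>',
    '</Section>'), sec0)
  ser
}

# hand ANOVA/Tukey oracle from sums of squares and ptukey
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  gm <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  ssb <- sum(n * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  msb <- ssb / (k - 1); msw <- ssw / (N - k)
  f <- msb / msw
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  lv <- levels(groups)
  prs <- utils::combn(lv, 2)
  tuk <- apply(prs, 2, function(pr) {
    d <- gm[pr[2]] - gm[pr[1]]
    se <- sqrt(msw / 2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
    stats::ptukey(abs(d) / se, k, N - k, lower.tail = FALSE)
  })
  list(f = f, p = p,
       tukey = stats::setNames(tuk, apply(prs, 2, function(pr)
         paste(pr[2], pr[1], sep = "-"))))
}

# hand Kruskal-Wallis oracle with midranks and tie correction
kruskal_oracle <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  ties <- table(values)
  h <- h / (1 - sum(ties^3 - ties) / (N^3 - N))
  p <- stats::pchisq(h, nlevels(groups) - 1, lower.tail = FALSE)
  list(h = h, p = p)
}

# hand two-sided Wilcoxon rank-sum oracle mirroring the exact/approximate
# convention (exact via pwilcox for small tie-free samples; otherwise normal
# approximation with continuity correction and tie-corrected variance)
wilcox_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  exact <- m <= 20 && n <= 20 && !any(duplicated(c(x, y)))
  if (exact) {
    if (w > m * n / 2) {
      p <- 2 * stats::pwilcox(w - 1, m, n, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(w, m, n)
    }
    return(min(1, p))
  }
  mu <- m * n / 2
  ties <- table(r)
  sig <- sqrt((m * n / 12) *
              ((m + n + 1) - sum(ties^3 - ties) /
                 ((m + n) * (m + n - 1))))
  z <- w - mu
  z <- z - sign(z) * 0.5
  2 * stats::pnorm(-abs(z) / sig)
}
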