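# Data model for labeled serial-section contour stacks.
#
# A stack holds ordered sections; each section holds closed 2D contours traced
# in physical micrometres. The origin is the lower-left corner of the imaging
# field; z is the 0-based section index.

#' Structure labels recognised in a contour stack
#'
#' The tracing vocabulary: the reconstructed inner-wall cell envelope, its
#' nucleus, giant vacuoles, juxtacanalicular (JCT) cells and matrix anchors,
#' adjacent inner-wall cells, pore/opening annotations, and connection
#' endpoints.
#'
#' @export
VM_LABELS <- c(
  "IW_CELL", "NUCLEUS", "GV", "JCT_CELL", "JCT_ECM_ANCHOR",
  "ADJACENT_IW_CELL", "IPORE_OPENING", "BASAL_OPENING", "BPORE_OPENING",
  "CONNECTION_ENDPOINT"
)

#' Acquisition geometry of a serial block-face stack
#'
#' @param pixel_size In-plane pixel size in micrometres per pixel.
#' @param section_thickness Section thickness in micrometres.
#'
#' @details Defaults match the acquisition used for the reference material:
#'   0.0101 um pixels and 0.13 um sections.
#'
#' @return A list of class `vm_acquisition`.
#' @export
acquisition_params <- function(pixel_size = 0.0101, section_thickness = 0.13) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  if (!is.numeric(section_thickness) || length(section_thickness) != 1L ||
      section_thickness <= 0)
    stop("`section_thickness` must be a single positive number")
  structure(list(pixel_size = pixel_size,
                 section_thickness = section_thickness),
            class = "vm_acquisition")
}

#' Create a labeled contour
#'
#' @param label One of [VM_LABELS].
#' @param object_id Identifier grouping the contours of one 3D object.
#' @param points Numeric matrix (n x 2) of ordered vertices in micrometres.
#' @param closed Logical; closed contours need at least 3 non-collinear
#'   vertices.
#' @param meta Optional named list of annotation metadata (e.g. the structural
#'   category of a connection, which mirrors the tracer's qualitative call and
#'   cannot be derived from the trace geometry alone).
#'
#' @return A list of class `vm_contour`.
#' @export
contour <- function(label, object_id, points, closed = TRUE, meta = NULL) {
  if (!is.character(label) || length(label) != 1L || !(label %in% VM_LABELS))
    stop("unknown contour label: ", paste(label, collapse = ", "))
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("`points` must be an n x 2 numeric matrix")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (closed) {
    if (nrow(points) < 3L)
      stop("closed contour '", object_id, "' has fewer than 3 vertices")
    if (.vm_shoelace(points) <= .Machine$double.eps * max(1, sum(abs(points))))
      stop("closed contour '", object_id, "' is degenerate (collinear vertices)")
  }
  structure(list(label = label, object_id = as.character(object_id),
                 closed = isTRUE(closed), meta = meta, points = points),
            class = "vm_contour")
}

#' Create a section
#'
#' @param index 0-based z index.
#' @param contours List of [contour()] objects.
#' @return A list of class `vm_section`.
#' @export
section <- function(index, contours = list()) {
  if (!is.numeric(index) || length(index) != 1L || index < 0 ||
      index != round(index))
    stop("`index` must be a single non-negative integer")
  if (!all(vapply(contours, inherits, logical(1), "vm_contour")))
    stop("`contours` must be a list of vm_contour objects")
  structure(list(index = as.integer(index), contours = contours),
            class = "vm_section")
}

#' Assemble a serial-section stack
#'
#' @param sections List of [section()] objects with strictly increasing
#'   indices.
#' @param acquisition An [acquisition_params()] object.
#' @param field_width,field_height Imaging field dimensions in micrometres.
#' @param validate Run [validate_stack()] on the result.
#'
#' @return A list of class `vm_stack`.
#' @export
section_stack <- function(sections = list(),
                          acquisition = acquisition_params(),
                          field_width = 141, field_height = 65,
                          validate = TRUE) {
  stopifnot(inherits(acquisition, "vm_acquisition"))
  if (!all(vapply(sections, inherits, logical(1), "vm_section")))
    stop("`sections` must be a list of vm_section objects")
  stk <- structure(list(acquisition = acquisition,
                        field_width = field_width,
                        field_height = field_height,
                        sections = sections),
                   class = "vm_stack")
  if (validate) validate_stack(stk)
  stk
}

#' Validate stack invariants
#'
#' Checks strictly increasing section indices, label consistency within each
#' `object_id`, closed-contour non-degeneracy, and that all vertices lie
#' within the imaging field.
#'
#' @param stack A `vm_stack`.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_stack <- function(stack) {
  stopifnot(inherits(stack, "vm_stack"))
  idx <- vapply(stack$sections, `[[`, integer(1), "index")
  if (length(idx) > 1L && any(diff(idx) <= 0))
    stop("section indices must be strictly increasing")
  seen <- new.env(parent = emptyenv())
  for (sec in stack$sections) {
    for (ct in sec$contours) {
      if (ct$closed && nrow(ct$points) < 3L)
        stop("section ", sec$index, ": closed contour '", ct$object_id,
             "' has fewer than 3 vertices")
      prev <- seen[[ct$object_id]]
      if (is.null(prev)) {
        assign(ct$object_id, ct$label, envir = seen)
      } else if (!identical(prev, ct$label)) {
        stop("object '", ct$object_id, "' carries inconsistent labels ('",
             prev, "' vs '", ct$label, "')")
      }
      p <- ct$points
      tol <- 1e-6
      if (any(p[, 1] < -tol | p[, 1] > stack$field_width + tol |
              p[, 2] < -tol | p[, 2] > stack$field_height + tol))
        stop("section ", sec$index, ": contour '", ct$object_id,
             "' has vertices outside the imaging field")
    }
  }
  invisible(TRUE)
}

#' @export
print.vm_stack <- function(x, ...) {
  n_sec <- length(x$sections)
  n_ct <- sum(vapply(x$sections, function(s) length(s$contours), integer(1)))
  labs <- table(unlist(lapply(x$sections, function(s)
    vapply(s$contours, `[[`, character(1), "label"))))
  cat("Serial-section contour stack\n")
  cat(sprintf("  sections: %d  contours: %d\n", n_sec, n_ct))
  cat(sprintf("  pixel %g um, section %g um, field %g x %g um\n",
              x$acquisition$pixel_size, x$acquisition$section_thickness,
              x$field_width, x$field_height))
  if (length(labs))
    cat("  labels:", paste(sprintf("%s=%d", names(labs), labs),
                           collapse = ", "), "\n")
  invisible(x)
}

# ---- accessors -------------------------------------------------------------

#' Extract contours from a stack
#'
#' @param stack A `vm_stack`.
#' @param label Optional label filter.
#' @param object_id Optional object filter.
#' @return A list with one element per matching contour: `section` (z index)
#'   and `contour`.
#' @export
stack_contours <- function(stack, label = NULL, object_id = NULL) {
  out <- list()
  for (sec in stack$sections) {
    for (ct in sec$contours) {
      if (!is.null(label) && !(ct$label %in% label)) next
      if (!is.null(object_id) && !(ct$object_id %in% object_id)) next
      out[[length(out) + 1L]] <- list(section = sec$index, contour = ct)
    }
  }
  out
}

#' Section indices on which an object appears
#'
#' @param stack A `vm_stack`.
#' @param object_id Object identifier.
#' @return Sorted integer vector of z indices (possibly empty).
#' @export
object_sections <- function(stack, object_id) {
  sort(unique(vapply(stack_contours(stack, object_id = object_id),
                     `[[`, integer(1), "section")))
}

#' Object ids present in a stack, optionally filtered by label
#' @param stack A `vm_stack`.
#' @param label Optional label filter.
#' @return Character vector of unique object ids, in order of appearance.
#' @export
object_ids <- function(stack, label = NULL) {
  unique(vapply(stack_contours(stack, label = label),
                function(x) x$contour$object_id, character(1)))
}

# contours of one object on one section (list of vm_contour)
.vm_contours_on <- function(stack, object_id, index) {
  hits <- stack_contours(stack, object_id = object_id)
  lapply(Filter(function(x) x$section == index, hits), `[[`, "contour")
}

# fast per-stack index: section index -> list of contours, plus lookup tables
.vm_index_stack <- function(stack) {
  secs <- stack$sections
  idx <- vapply(secs, `[[`, integer(1), "index")
  list(sections = secs, index = idx,
       lookup = stats::setNames(seq_along(secs), as.character(idx)))
}

# ---- polygon area ----------------------------------------------------------

.vm_shoelace <- function(points) {
  n <- nrow(points)
  x <- points[, 1]; y <- points[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Absolute area of a closed polygon (shoelace formula)
#'
#' Orientation-independent: the polygon may be traced clockwise or
#' counter-clockwise.
#'
#' @param points Numeric matrix (n x 2), n >= 3, of ordered vertices in
#'   micrometres. The polygon is implicitly closed.
#' @return Area in square micrometres.
#' @export
polygon_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("polygon needs at least 3 vertices")
  .vm_shoelace(points)
}

# ---- native JSON I/O -------------------------------------------------------

#' Write a stack to the native JSON schema
#'
#' One JSON document per stack: a header with acquisition parameters and field
#' dimensions, then `sections[]` of `contours[]` with label, object_id,
#' closed flag, optional meta, and `[x, y]` vertex lists. Coordinates are
#' serialized with 6 decimal places, so a write/read round trip moves a vertex
#' by at most 5e-7 um.
#'
#' @param stack A valid `vm_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  validate_stack(stack)
  doc <- list(
    schema = "vacuomorph-stack-v1",
    pixel_size = stack$acquisition$pixel_size,
    section_thickness = stack$acquisition$section_thickness,
    field = list(width = stack$field_width, height = stack$field_height),
    sections = lapply(stack$sections, function(sec) {
      list(index = sec$index,
           contours = lapply(sec$contours, function(ct) {
             out <- list(label = ct$label, object_id = ct$object_id,
                         closed = ct$closed,
                         points = round(unname(ct$points), 6))
             if (!is.null(ct$meta)) out$meta <- ct$meta
             out
           }))
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}

#' Read a contour stack
#'
#' @param path Path to a native JSON stack, or to a Reconstruct series
#'   (`.ser`) file when `format = "reconstruct_xml"`.
#' @param format `"native"` or `"reconstruct_xml"`.
#' @return A validated `vm_stack`.
#' @export
read_stack <- function(path, format = c("native", "reconstruct_xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "reconstruct_xml") return(.vm_read_reconstruct(path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed native stack file '", path, "': ",
                             conditionMessage(e)))
  if (is.null(doc$pixel_size) || is.null(doc$section_thickness))
    stop("malformed native stack file '", path,
         "': missing acquisition header")
  acq <- acquisition_params(doc$pixel_size, doc$section_thickness)
  fw <- if (!is.null(doc$field$width)) doc$field$width else 141
  fh <- if (!is.null(doc$field$height)) doc$field$height else 65
  secs <- lapply(doc$sections, function(s) {
    cts <- lapply(seq_along(s$contours), function(i) {
      c0 <- s$contours[[i]]
      pts <- do.call(rbind, lapply(c0$points, function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      tryCatch(
        contour(c0$label, c0$object_id, pts,
                closed = isTRUE(c0$closed), meta = c0$meta),
        error = function(e) stop("section ", s$index, ", contour ", i, ": ",
                                 conditionMessage(e)))
    })
    section(s$index, cts)
  })
  section_stack(secs, acquisition = acq, field_width = fw, field_height = fh)
}

# ---- Reconstruct serial-section XML (read-only, polygon traces) ------------

.vm_read_reconstruct <- function(series_path) {
  ser <- tryCatch(xml2::read_xml(series_path),
                  error = function(e) stop("malformed Reconstruct series '",
                                           series_path, "': ",
                                           conditionMessage(e)))
  if (xml2::xml_name(ser) != "Series")
    stop("'", series_path, "' is not a Reconstruct series file")
  base <- sub("\\.ser$", "", series_path)
  files <- Sys.glob(paste0(base, ".*"))
  files <- files[grepl("\\.[0-9]+$", files)]
  if (!length(files)) stop("no Reconstruct section files found next to '",
                           series_path, "'")
  ord <- order(as.integer(sub(".*\\.", "", files)))
  files <- files[ord]
  secs <- list()
  skipped <- 0L
  for (f in files) {
    xs <- xml2::read_xml(f)
    z <- as.integer(xml2::xml_attr(xs, "index"))
    mags <- as.numeric(xml2::xml_attr(xml2::xml_find_all(xs, ".//Image"),
                                      "mag"))
    mag <- if (length(mags) && is.finite(mags[1])) mags[1] else 1
    kids <- xml2::xml_name(xml2::xml_find_all(xs, ".//Transform/*"))
    skipped <- skipped + sum(!kids %in% c("Image", "Contour"))
    cts <- list()
    for (node in xml2::xml_find_all(xs, ".//Contour")) {
      closed <- !identical(xml2::xml_attr(node, "closed"), "False")
      ptxt <- xml2::xml_attr(node, "points")
      if (is.na(ptxt)) { skipped <- skipped + 1L; next }
      toks <- strsplit(trimws(unlist(strsplit(ptxt, ","))), "[[:space:]]+")
      toks <- Filter(function(t) length(t) >= 2 && nzchar(t[1]), toks)
      pts <- do.call(rbind, lapply(toks, function(t)
        as.numeric(t[1:2]))) * mag
      nm <- xml2::xml_attr(node, "name")
      lab <- if (nm %in% VM_LABELS) nm else "IW_CELL"
      cts[[length(cts) + 1L]] <- contour(lab, object_id = nm, points = pts,
                                         closed = closed)
    }
    secs[[length(secs) + 1L]] <- section(z, cts)
  }
  if (skipped > 0L)
    warning(skipped, " non-polygon Reconstruct entities ignored")
  ord <- order(vapply(secs, `[[`, integer(1), "index"))
  fw <- max(1, vapply(secs, function(s) {
    m <- vapply(s$contours,
                function(ct) if (nrow(ct$points)) max(ct$points[, 1]) else 0,
                numeric(1))
    if (length(m)) max(m) else 0
  }, numeric(1)))
  fh <- max(1, unlist(lapply(secs, function(s)
    lapply(s$contours, function(ct) max(ct$points[, 2])))))
  section_stack(secs[ord],
                field_width = ceiling(max(fw) + 1),
                field_height = ceiling(max(fh) + 1))
}
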