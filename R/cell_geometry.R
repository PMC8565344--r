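#' Cell geometry from a closed outline polygon
#'
#' Builds the geometry descriptor used for cell assignment and for the
#' standardized-cell transform: area centroid, principal (long) axis, and the
#' cell length/width measured as the extent of the outline along the two
#' principal axes.
#'
#' @param polygon two-column matrix or data.frame of vertices (micrometre).
#'   The polygon is treated as closed; a repeated last vertex is dropped.
#' @param cell_id identifier.
#' @return an object of class `cell_geometry` with fields `polygon`
#'   (open ring, counter-clockwise), `centroid`, `long_axis` (unit vector),
#'   `length`, `width`, `cell_id`.
#' @export
cell_geometry <- function(polygon, cell_id = "cell1") {
  p <- as.matrix(polygon)
  if (ncol(p) != 2L) stop("polygon must have two columns", call. = FALSE)
  storage.mode(p) <- "double"
  if (nrow(p) > 1L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3L)
    stop("validation error: polygon of cell '", cell_id,
         "' has fewer than 3 distinct vertices", call. = FALSE)
  if (any(!is.finite(p))) stop("non-finite polygon vertex", call. = FALSE)
  if (.polygon_self_intersects(p))
    stop("validation error: polygon of cell '", cell_id,
         "' is self-intersecting", call. = FALSE)

  a2 <- .polygon_signed_area2(p)
  if (abs(a2) < 1e-12)
    stop("validation error: degenerate polygon for cell '", cell_id, "'",
         call. = FALSE)
  if (a2 < 0) { p <- p[rev(seq_len(nrow(p))), , drop = FALSE]; a2 <- -a2 }
  centroid <- .polygon_centroid(p, a2)

  # principal axis from the second moments of the polygon interior
  mom <- .polygon_second_moments(p, centroid)
  ev <- eigen(mom, symmetric = TRUE)
  axis_long <- ev$vectors[, 1L]
  if (axis_long[1L] < 0 || (axis_long[1L] == 0 && axis_long[2L] < 0))
    axis_long <- -axis_long
  axis_short <- c(-axis_long[2L], axis_long[1L])

  ctr <- sweep(p, 2L, centroid)
  proj_l <- ctr %*% axis_long
  proj_s <- ctr %*% axis_short
  len <- diff(range(proj_l))
  wid <- diff(range(proj_s))
  if (wid <= 0)
    stop("degenerate cell '", cell_id, "': zero width", call. = FALSE)

  structure(list(polygon = p, centroid = as.numeric(centroid),
                 long_axis = as.numeric(axis_long),
                 length = as.numeric(len), width = as.numeric(wid),
                 cell_id = as.character(cell_id)),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Cell '%s': length %.3f um, width %.3f um, centroid (%.3f, %.3f)\n",
              x$cell_id, x$length, x$width, x$centroid[1], x$centroid[2]))
  invisible(x)
}

.polygon_signed_area2 <- function(p) {
  i <- seq_len(nrow(p)); j <- c(i[-1L], 1L)
  sum(p[i, 1L] * p[j, 2L] - p[j, 1L] * p[i, 2L])
}

.polygon_centroid <- function(p, a2 = .polygon_signed_area2(p)) {
  i <- seq_len(nrow(p)); j <- c(i[-1L], 1L)
  cr <- p[i, 1L] * p[j, 2L] - p[j, 1L] * p[i, 2L]
  c(sum((p[i, 1L] + p[j, 1L]) * cr), sum((p[i, 2L] + p[j, 2L]) * cr)) / (3 * a2)
}

# second area moments about the centroid (for the principal axis)
.polygon_second_moments <- function(p, ctr) {
  q <- sweep(p, 2L, ctr)
  i <- seq_len(nrow(q)); j <- c(i[-1L], 1L)
  cr <- q[i, 1L] * q[j, 2L] - q[j, 1L] * q[i, 2L]
  sxx <- sum(cr * (q[i, 1L]^2 + q[i, 1L] * q[j, 1L] + q[j, 1L]^2)) / 12
  syy <- sum(cr * (q[i, 2L]^2 + q[i, 2L] * q[j, 2L] + q[j, 2L]^2)) / 12
  sxy <- sum(cr * (2 * q[i, 1L] * q[i, 2L] + q[i, 1L] * q[j, 2L] +
                     q[j, 1L] * q[i, 2L] + 2 * q[j, 1L] * q[j, 2L])) / 24
  matrix(c(sxx, sxy, sxy, syy), 2L, 2L)
}

# segment-pair test, skipping adjacent edges
.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n <= 3L) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1L), , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (.segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

.segments_cross <- function(a, b, c, d) {
  o <- function(p, q, r) {
    v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    sign(v)
  }
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  (o1 != o2 && o3 != o4)
}

#' Read cell outlines from delimited text
#'
#' Expects a header `cell_id,vertex,x,y` with one closed polygon per cell
#' (micrometre coordinates, vertices in ring order).  Mesh formats from
#' upstream segmentation tools are supported through this polygon contract:
#' reduce a mesh to its outline ring and write it in this format.
#'
#' @param path file to read.
#' @param sep field separator.
#' @return list of [cell_geometry()] objects.
#' @export
read_cell_outlines <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "vertex", "x", "y")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- unique(as.character(raw$cell_id))
  lapply(ids, function(id) {
    sub <- raw[as.character(raw$cell_id) == id, , drop = FALSE]
    sub <- sub[order(sub$vertex), , drop = FALSE]
    cell_geometry(cbind(sub$x, sub$y), cell_id = id)
  })
}

#' Write cell outlines to delimited text
#' @param cells list of `cell_geometry`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cell_outlines <- function(cells, path) {
  rows <- do.call(rbind, lapply(cells, function(cg) {
    data.frame(cell_id = cg$cell_id, vertex = seq_len(nrow(cg$polygon)),
               x = sprintf("%.17g", cg$polygon[, 1L]),
               y = sprintf("%.17g", cg$polygon[, 2L]))
  }))
  utils::write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# vectorized point-in-polygon (closed ring implied)
points_in_cell <- function(x, y, cell) {
  as.logical(mgcv::in.out(rbind(cell$polygon, cell$polygon[1L, ]),
                          cbind(as.numeric(x), as.numeric(y))))
}

#' Assign tracks to cells by majority inclusion
#'
#' A track is assigned to the cell containing the majority of its
#' localizations; it stays unassigned (`NA`) when no single cell contains at
#' least 50% of them.  Whole tracks are assigned, never clipped.
#'
#' @param ts a `track_set`.
#' @param cells list of `cell_geometry` in the same coordinate frame.
#' @return named character vector, `track_id -> cell_id` (`NA` if unassigned).
#' @export
assign_tracks_to_cells <- function(ts, cells) {
  stopifnot(inherits(ts, "track_set"))
  per <- split_tracks(ts)
  out <- vapply(per, function(tr) {
    frac <- vapply(cells, function(cg)
      mean(points_in_cell(tr$x, tr$y, cg)), numeric(1))
    i <- which.max(frac)
    if (length(i) == 0L || frac[i] < 0.5) NA_character_
    else cells[[i]]$cell_id
  }, character(1))
  out
}

#' Map localizations into the standardized cell
#'
#' Affine standardization: the cell centroid goes to the origin, the long
#' principal axis to the horizontal, and the two axes are rescaled
#' independently so the cell spans the standard 3 x 1 micrometre frame
#' (x in \[-1.5, 1.5\], y in \[-0.5, 0.5\]).  With `mirror = TRUE`,
#' coordinates are additionally folded into the first quadrant (absolute
#' values), the convention used when a map is mirrored for display.
#'
#' @param points data.frame with `x`, `y` (micrometre), e.g. the `tracks`
#'   table of a `track_set`.
#' @param cell the `cell_geometry` the points belong to.
#' @param mirror fold coordinates into one quadrant.
#' @param std_length,std_width dimensions of the standardized cell.
#' @return `points` with `x`, `y` replaced by standardized coordinates.  The
#'   non-mirrored map is a bijection; its inverse parameters are attached as
#'   attribute `"transform"`.
#' @export
normalize_to_standard_cell <- function(points, cell, mirror = FALSE,
                                       std_length = 3, std_width = 1) {
  stopifnot(inherits(cell, "cell_geometry"))
  if (cell$width <= 0 || cell$length <= 0)
    stop("degenerate cell: zero extent", call. = FALSE)
  u <- cell$long_axis
  v <- c(-u[2L], u[1L])
  dx <- points$x - cell$centroid[1L]
  dy <- points$y - cell$centroid[2L]
  xs <- (dx * u[1L] + dy * u[2L]) * (std_length / cell$length)
  ys <- (dx * v[1L] + dy * v[2L]) * (std_width / cell$width)
  if (mirror) { xs <- abs(xs); ys <- abs(ys) }
  out <- points
  out$x <- xs
  out$y <- ys
  attr(out, "transform") <- list(centroid = cell$centroid, long_axis = u,
                                 scale = c(std_length / cell$length,
                                           std_width / cell$width),
                                 mirrored = mirror)
  out
}

#' Invert the standardized-cell transform
#'
#' Maps standardized coordinates back to the original frame.  Only defined
#' for non-mirrored output (the quadrant fold is not invertible).
#'
#' @param points standardized points carrying the `"transform"` attribute, or
#'   any data.frame with `x`, `y` if `cell` is supplied.
#' @param cell optional `cell_geometry` to take the transform from.
#' @inheritParams normalize_to_standard_cell
#' @return data.frame with original-frame `x`, `y`.
#' @export
denormalize_from_standard_cell <- function(points, cell = NULL,
                                           std_length = 3, std_width = 1) {
  tr <- attr(points, "transform")
  if (is.null(tr)) {
    stopifnot(inherits(cell, "cell_geometry"))
    tr <- list(centroid = cell$centroid, long_axis = cell$long_axis,
               scale = c(std_length / cell$length, std_width / cell$width),
               mirrored = FALSE)
  }
  if (isTRUE(tr$mirrored))
    stop("mirrored coordinates cannot be inverted", call. = FALSE)
  u <- tr$long_axis
  v <- c(-u[2L], u[1L])
  xl <- points$x / tr$scale[1L]
  yl <- points$y / tr$scale[2L]
  out <- points
  out$x <- tr$centroid[1L] + xl * u[1L] + yl * v[1L]
  out$y <- tr$centroid[2L] + xl * u[2L] + yl * v[2L]
  attr(out, "transform") <- NULL
  out
}

#' Standardize all tracks of a set into the standard cell frame
#'
#' Convenience wrapper: assigns tracks to cells, drops unassigned tracks and
#' maps each track through its cell's standardization.
#'
#' @param ts a `track_set`.
#' @param cells list of `cell_geometry`.
#' @param assignment optional precomputed [assign_tracks_to_cells()] result.
#' @param mirror fold coordinates into one quadrant.
#' @return a `track_set` in standardized coordinates (unassigned tracks
#'   removed); the cell of each track is recorded in column `cell_id`.
#' @export
standardize_tracks <- function(ts, cells, assignment = NULL, mirror = FALSE) {
  stopifnot(inherits(ts, "track_set"))
  if (is.null(assignment)) assignment <- assign_tracks_to_cells(ts, cells)
  by_id <- stats::setNames(cells, vapply(cells, `[[`, "", "cell_id"))
  per <- split_tracks(ts)
  pieces <- lapply(names(per), function(id) {
    cid <- assignment[[id]]
    if (is.na(cid)) return(NULL)
    std <- normalize_to_standard_cell(per[[id]], by_id[[cid]], mirror = mirror)
    std$cell_id <- cid
    attr(std, "transform") <- NULL
    std
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L)
    stop("no track could be assigned to a cell", call. = FALSE)
  out <- ts
  out$tracks <- do.call(rbind, pieces)
  rownames(out$tracks) <- NULL
  out$source <- paste0(ts$source, " [standardized]")
  out
}
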