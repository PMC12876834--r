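# Polygon geometry in raster coordinates (0-based, y-down; pixel (r, c)
# covers [c-1, c] x [r-1, r], center (c-0.5, r-0.5)). No geometry package in
# the supported stack provides these, so they are implemented and
# oracle-tested here.

#' Even-odd point-in-polygon test
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly n x 2 matrix of (x, y) vertices (open ring; closure implied).
#' @return logical vector, TRUE where the point lies inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon to a logical mask
#'
#' Scanline even-odd fill: a pixel is foreground when its center lies inside
#' the polygon.
#'
#' @param poly n x 2 vertex matrix, or a list of such matrices whose union is
#'   rasterized.
#' @param h,w mask dimensions in pixels.
#' @return logical h x w matrix.
#' @export
rasterize_polygon <- function(poly, h, w) {
  if (is.list(poly)) {
    m <- matrix(FALSE, h, w)
    for (p in poly) m <- m | rasterize_polygon(p, h, w)
    return(m)
  }
  stopifnot(is.matrix(poly), ncol(poly) == 2)
  m <- matrix(FALSE, h, w)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  ylo <- max(1L, floor(min(y1) + 0.5) + 1L)
  yhi <- min(h, ceiling(max(y1) - 0.5))
  if (ylo > yhi) return(m)
  for (r in ylo:yhi) {
    yc <- r - 0.5
    cr <- ((y1 <= yc) & (y2 > yc)) | ((y2 <= yc) & (y1 > yc))
    if (!any(cr)) next
    xs <- sort(x1[cr] + (yc - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      lo <- max(1L, floor(xs[k] + 0.5) + 1L)
      hi <- min(w, ceiling(xs[k + 1] - 0.5))
      if (lo <= hi) m[r, lo:hi] <- TRUE
    }
  }
  m
}

# Shoelace area (always >= 0).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle.
# Returns a vertex matrix (possibly with 0 rows when disjoint).
clip_polygon_rect <- function(poly, xmin, ymin, xmax, ymax) {
  clip_halfplane <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    out
  }
  ix <- function(p, q, t) p + t * (q - p)
  pts <- poly
  pts <- clip_halfplane(pts, function(p) p[1] >= xmin, function(p, q)
    ix(p, q, (xmin - p[1]) / (q[1] - p[1])))
  pts <- clip_halfplane(pts, function(p) p[1] <= xmax, function(p, q)
    ix(p, q, (xmax - p[1]) / (q[1] - p[1])))
  pts <- clip_halfplane(pts, function(p) p[2] >= ymin, function(p, q)
    ix(p, q, (ymin - p[2]) / (q[2] - p[2])))
  pts <- clip_halfplane(pts, function(p) p[2] <= ymax, function(p, q)
    ix(p, q, (ymax - p[2]) / (q[2] - p[2])))
  pts
}

# Intersection area of a polygon with a rectangle.
polygon_rect_intersection_area <- function(poly, xmin, ymin, xmax, ymax) {
  cl <- clip_polygon_rect(poly, xmin, ymin, xmax, ymax)
  if (is.null(nrow(cl)) || nrow(cl) < 3) return(0)
  polygon_area(cl)
}

#' Trace the boundary polygons of a binary mask
#'
#' Uses marching-squares iso-contours at level 0.5 on the pixel-center grid
#' (mask padded with background so boundary blobs close). Each connected
#' boundary becomes one polygon in mask pixel coordinates.
#'
#' @param mask logical or 0/1 matrix.
#' @return list of n x 2 (x, y) vertex matrices; empty list for an empty mask.
#' @export
mask_to_polygons <- function(mask) {
  if (!any(mask)) return(list())
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask * 1
  # grid of pixel centers of the padded mask, in original coordinates
  xs <- (0:(w + 1)) - 0.5
  ys <- (0:(h + 1)) - 0.5
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(pad), levels = 0.5)
  lapply(cl, function(cc) cbind(x = cc$x, y = cc$y))
}
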