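# Physical-scale normalization and tile extraction. The reference workflow
# extracts 512 x 512 tiles at 0.5 um/px from glomerular region annotations
# drawn at scanner resolution (0.2208-0.2506 um/px), so every path through
# here rescales first and grids second.

#' Tiling configuration
#'
#' @param tile_px tile side in pixels (default 512).
#' @param target_mpp target resolution in um/px (default 0.5).
#' @param stride_px grid stride in pixels; defaults to `tile_px`
#'   (non-overlapping). Strides smaller than `tile_px` overlap.
#' @param pad_value RGB triple in \[0,1\] used where a tile extends past the
#'   image bounds.
#' @return object of class `tiling_config`.
#' @export
tiling_config <- function(tile_px = 512L, target_mpp = 0.5,
                          stride_px = tile_px, pad_value = c(1, 1, 1)) {
  if (tile_px <= 0) stop("tile_px must be positive")
  if (target_mpp <= 0) stop("target_mpp must be positive")
  if (stride_px <= 0) stop("stride_px must be positive")
  structure(list(tile_px = as.integer(tile_px), target_mpp = target_mpp,
                 stride_px = as.integer(stride_px),
                 pad_value = as.numeric(pad_value)),
            class = "tiling_config")
}

#' Rescale an image between physical resolutions
#'
#' Output dimensions are `round(dim * src_mpp / dst_mpp)`; interpolation is
#' bilinear. Coordinates in the source frame map to the target frame by the
#' same factor `src_mpp / dst_mpp`.
#'
#' @param image numeric matrix or H x W x C array.
#' @param src_mpp,dst_mpp source and destination resolution (um/px, > 0).
#' @return rescaled image; the input unchanged when `src_mpp == dst_mpp`.
#' @export
rescale_to_mpp <- function(image, src_mpp, dst_mpp) {
  if (src_mpp <= 0 || dst_mpp <= 0)
    stop("pixel spacings must be positive")
  if (src_mpp == dst_mpp) return(image)
  s <- src_mpp / dst_mpp
  oh <- as.integer(round(dim(image)[1] * s))
  ow <- as.integer(round(dim(image)[2] * s))
  resize_bilinear(image, oh, ow)
}

new_tile <- function(pixels, origin, region, label = NA_character_,
                     masks = NULL) {
  structure(list(pixels = pixels, origin = origin,
                 region_id = region$region_id, case_id = region$case_id,
                 slide_id = region$slide_id, label = label, masks = masks),
            class = "tile")
}

# Cut a (possibly padded) window [oy, oy+t) x [ox, ox+t) out of an image.
cut_window <- function(img, ox, oy, t, pad_value) {
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- array(rep(pad_value, each = t * t), c(t, t, 3))
  rs <- max(oy + 1, 1):min(oy + t, h)
  cs <- max(ox + 1, 1):min(ox + t, w)
  if (length(rs) > 0 && length(cs) > 0 && rs[1] <= rs[length(rs)])
    out[rs - oy, cs - ox, ] <- img[rs, cs, , drop = FALSE]
  out
}

cut_window_mask <- function(m, ox, oy, t) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, t, t)
  rs <- max(oy + 1, 1):min(oy + t, h)
  cs <- max(ox + 1, 1):min(ox + t, w)
  if (length(rs) > 0 && length(cs) > 0 && rs[1] <= rs[length(rs)])
    out[rs - oy, cs - ox] <- m[rs, cs]
  out
}

#' Extract labeled tiles from a region annotation
#'
#' Rescales image (bilinear) and any masks (nearest-neighbour) to
#' `cfg$target_mpp`, then grids the region's bounding box from its top-left
#' with stride `cfg$stride_px`, keeping tiles whose center lies inside the
#' polygon. Tiles extending past the image are padded with `cfg$pad_value`.
#' A region whose bounding box fits inside one tile yields exactly one tile
#' centered on the bounding box. Tiles are ordered by (origin_y, origin_x);
#' origins are recorded in target-resolution pixel space.
#'
#' @param image H x W x 3 array at `src_mpp`.
#' @param region a [region_annotation()] with vertices at `src_mpp`.
#' @param cfg a [tiling_config()].
#' @param src_mpp source resolution of `image` (um/px).
#' @param masks optional named list of logical masks at `src_mpp`,
#'   co-extracted per tile (nearest-neighbour, padded with `FALSE`).
#' @return list of `tile` objects (possibly empty, with a warning, when the
#'   region lies outside the image).
#' @export
extract_tiles <- function(image, region, cfg = tiling_config(), src_mpp,
                          masks = NULL) {
  s <- src_mpp / cfg$target_mpp
  img <- rescale_to_mpp(image, src_mpp, cfg$target_mpp)
  h <- dim(img)[1]; w <- dim(img)[2]
  sm <- NULL
  if (!is.null(masks))
    sm <- lapply(masks, function(m) {
      if (s == 1) m else
        matrix(as.logical(resize_nearest(m * 1, h, w) > 0.5), h, w)
    })
  poly <- region$polygon * s
  xmin <- min(poly[, 1]); xmax <- max(poly[, 1])
  ymin <- min(poly[, 2]); ymax <- max(poly[, 2])
  if (xmax < 0 || ymax < 0 || xmin > w || ymin > h) {
    warning("region '", region$region_id, "' lies outside the image; ",
            "no tiles extracted")
    return(list())
  }
  t <- cfg$tile_px
  if ((xmax - xmin) <= t && (ymax - ymin) <= t) {
    ox <- as.integer(round((xmin + xmax) / 2 - t / 2))
    oy <- as.integer(round((ymin + ymax) / 2 - t / 2))
    origins <- cbind(ox, oy)
  } else {
    x0 <- floor(xmin); y0 <- floor(ymin)
    oxs <- seq(x0, max(x0, ceiling(xmax) - 1), by = cfg$stride_px)
    oys <- seq(y0, max(y0, ceiling(ymax) - 1), by = cfg$stride_px)
    grid <- expand.grid(ox = oxs, oy = oys)  # row-major in y: oy varies slower
    grid <- grid[order(grid$oy, grid$ox), ]
    keep <- point_in_polygon(grid$ox + t / 2, grid$oy + t / 2, poly)
    origins <- as.matrix(grid[keep, , drop = FALSE])
  }
  tiles <- vector("list", nrow(origins))
  for (i in seq_len(nrow(origins))) {
    ox <- unname(origins[i, 1]); oy <- unname(origins[i, 2])
    tm <- if (is.null(sm)) NULL else
      lapply(sm, cut_window_mask, ox = ox, oy = oy, t = t)
    tiles[[i]] <- new_tile(cut_window(img, ox, oy, t, cfg$pad_value),
                           origin = c(x = ox, y = oy), region = region,
                           masks = tm)
  }
  tiles
}

#' Label tiles by intersection with foamy-podocyte polygons
#'
#' A tile is labeled `"foamy"` iff its square window intersects any
#' foamy-podocyte polygon with positive area (exact polygon clipping, no
#' minimum-overlap threshold), else `"not_foamy"`. Tile origins and polygon
#' coordinates must be in the same target-resolution pixel space.
#'
#' @param tiles list of `tile` objects.
#' @param podocyte_regions list of [region_annotation()] polygons.
#' @param tile_px tile side in pixels.
#' @return `tiles` with `label` filled in.
#' @export
label_tiles <- function(tiles, podocyte_regions, tile_px = 512L) {
  for (i in seq_along(tiles)) {
    ox <- tiles[[i]]$origin[["x"]]; oy <- tiles[[i]]$origin[["y"]]
    hit <- FALSE
    for (r in podocyte_regions) {
      if (polygon_rect_intersection_area(
        r$polygon, ox, oy, ox + tile_px, oy + tile_px) > 1e-9) {
        hit <- TRUE; break
      }
    }
    tiles[[i]]$label <- if (hit) "foamy" else "not_foamy"
  }
  tiles
}

#' Square region templates around glomerulus centers
#'
#' Emits square polygons of physical side `side_um` centered on each point,
#' in pixel coordinates at resolution `mpp` — the "position a box around each
#' glomerulus" annotation workflow.
#'
#' @param glomerulus_centers n x 2 matrix of (x, y) centers in um.
#' @param side_um physical side of the squares (um, > 0).
#' @param mpp resolution of the target pixel frame (um/px).
#' @return list of [region_annotation()] squares (class
#'   `"glomerulus_template"`).
#' @export
make_region_templates <- function(glomerulus_centers, side_um, mpp = 0.5) {
  if (side_um <= 0) stop("side_um must be positive")
  if (is.null(dim(glomerulus_centers)))
    glomerulus_centers <- matrix(glomerulus_centers, ncol = 2)
  n <- nrow(glomerulus_centers)
  if (n == 0) return(list())
  half <- side_um / (2 * mpp)
  lapply(seq_len(n), function(i) {
    cx <- glomerulus_centers[i, 1] / mpp
    cy <- glomerulus_centers[i, 2] / mpp
    region_annotation(
      cbind(c(cx - half, cx + half, cx + half, cx - half),
            c(cy - half, cy - half, cy + half, cy + half)),
      "glomerulus_template", region_id = sprintf("template%03d", i))
  })
}
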