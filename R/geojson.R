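# QuPath-dialect GeoJSON interchange: FeatureCollection of Polygon /
# MultiPolygon features carrying a `classification` with a `name`. We write
# what QuPath writes (objectType "annotation") and read liberally.

#' Create a region annotation
#'
#' @param polygon n x 2 matrix of (x, y) vertices at source resolution
#'   (0-based, y-down, open ring).
#' @param class_name annotation class, e.g. `"glomerulus"` or
#'   `"foamy_podocyte"`.
#' @param case_id,slide_id,region_id provenance identifiers.
#' @return object of class `region_annotation`.
#' @export
region_annotation <- function(polygon, class_name,
                              case_id = NA_character_,
                              slide_id = NA_character_,
                              region_id = NA_character_) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) >= 2 &&
      all(polygon[1, ] == polygon[nrow(polygon), ]))
    polygon <- polygon[-nrow(polygon), , drop = FALSE]
  if (nrow(polygon) < 3) stop("polygon needs at least 3 vertices")
  colnames(polygon) <- c("x", "y")
  structure(list(polygon = polygon, class_name = class_name,
                 case_id = case_id, slide_id = slide_id,
                 region_id = region_id),
            class = "region_annotation")
}

ring_closed <- function(poly) {
  rbind(poly, poly[1, , drop = FALSE])
}

feature_from_region <- function(r) {
  ring <- ring_closed(r$polygon)
  coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
  list(type = "Feature",
       geometry = list(type = "Polygon", coordinates = list(coords)),
       properties = list(
         objectType = "annotation",
         classification = list(name = r$class_name, color = c(50L, 50L, 200L)),
         case_id = r$case_id, slide_id = r$slide_id, region_id = r$region_id))
}

#' Write region annotations to a QuPath-style GeoJSON file
#'
#' @param regions list of [region_annotation()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(regions, path) {
  fc <- list(type = "FeatureCollection",
             features = lapply(regions, feature_from_region))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read region annotations from a GeoJSON file
#'
#' Accepts the QuPath dialect: a FeatureCollection whose features carry a
#' `classification` object with a `name` (matched case-insensitively and
#' lower-cased). MultiPolygon geometries are split into one region per part;
#' polygon holes are ignored. Features without geometry are skipped with a
#' warning; features without classification get class `"unclassified"`.
#'
#' @param path GeoJSON file.
#' @return list of [region_annotation()] objects.
#' @export
read_annotations <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("failed to parse GeoJSON file '", path, "': ",
                         conditionMessage(e)))
  feats <- doc$features %||% list()
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom) || is.null(geom$type)) {
      warning("feature ", i, " in '", path, "' has no geometry; skipped")
      next
    }
    cls <- f$properties$classification$name
    if (is.null(cls)) {
      # QuPath sometimes stores a bare string
      cls <- if (is.character(f$properties$classification))
        f$properties$classification else NULL
    }
    if (is.null(cls) || !nzchar(cls)) {
      warning("feature ", i, " in '", path,
              "' has no classification; using 'unclassified'")
      cls <- "unclassified"
    }
    cls <- tolower(cls)
    ring_to_mat <- function(ring)
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    polys <- switch(geom$type,
      Polygon = list(ring_to_mat(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates,
                            function(pp) ring_to_mat(pp[[1]])),
      { warning("feature ", i, " has unsupported geometry type '",
                geom$type, "'; skipped"); NULL })
    for (k in seq_along(polys)) {
      rid <- f$properties$region_id %||% sprintf("feature%03d%s", i,
        if (length(polys) > 1) sprintf("_part%d", k) else "")
      out[[length(out) + 1]] <- region_annotation(
        polys[[k]], cls,
        case_id = f$properties$case_id %||% NA_character_,
        slide_id = f$properties$slide_id %||% NA_character_,
        region_id = rid)
    }
  }
  out
}

#' Polygonize a synthetic glomerulus into region annotations
#'
#' Traces the glomerulus mask (class `"glomerulus"`) and each connected foamy
#' lesion (class `"foamy_podocyte"`) into polygons in the image's pixel
#' coordinates at source resolution.
#'
#' @param glom a `synthetic_glomerulus`.
#' @return list of [region_annotation()] objects.
#' @export
regions_from_glomerulus <- function(glom) {
  regs <- lapply(mask_to_polygons(glom$glomerulus_mask), function(p)
    region_annotation(p, "glomerulus", glom$case_id, glom$slide_id,
                      glom$glomerulus_id))
  pods <- mask_to_polygons(glom$podocyte_mask)
  for (k in seq_along(pods))
    regs[[length(regs) + 1]] <- region_annotation(
      pods[[k]], "foamy_podocyte", glom$case_id, glom$slide_id,
      sprintf("%s_pod%02d", glom$glomerulus_id, k))
  regs
}

#' Export a synthetic case's annotations as GeoJSON
#'
#' Writes one QuPath-dialect GeoJSON file per glomerulus image (each image has
#' its own coordinate frame), named `{case}_{glomerulus}.geojson`.
#'
#' @param case a `synthetic_case`.
#' @param path output directory (created if missing).
#' @return character vector of written file paths, invisibly.
#' @export
export_annotations <- function(case, path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create directory '", path, "'")
  files <- character(0)
  for (g in case$glomeruli) {
    f <- file.path(path, sprintf("%s_%s.geojson", g$case_id, g$glomerulus_id))
    write_annotations(regions_from_glomerulus(g), f)
    files <- c(files, f)
  }
  invisible(files)
}
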