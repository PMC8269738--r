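# Readers and writers: 16-bit TIFF images (VIS 3-channel + UV 1-channel),
# region-set JSON, radiation CSV, tidy score/reflectance CSV.

#' Write / read a scene's images as 16-bit TIFF
#'
#' A scene is stored as two files: `<id>_vis.tif` (3-channel) and
#' `<id>_uv.tif` (1-channel), values scaled from reflectance \[0, 1\] to the
#' 16-bit range, plus `<id>_regions.json`.
#'
#' @param scene a [render_scene()] object.
#' @param dir output directory.
#' @param id file stem.
#' @return list of the paths written.
#' @export
write_scene <- function(scene, dir, id) {
  vis <- file.path(dir, paste0(id, "_vis.tif"))
  uv <- file.path(dir, paste0(id, "_uv.tif"))
  rj <- file.path(dir, paste0(id, "_regions.json"))
  tiff::writeTIFF(scene$image[, , 1:3], vis, bits.per.sample = 16)
  tiff::writeTIFF(scene$image[, , 4], uv, bits.per.sample = 16)
  write_region_set(scene$regions, rj)
  list(vis = vis, uv = uv, regions = rj)
}

#' @rdname write_scene
#' @param vis_path,uv_path TIFF paths as written by `write_scene()`.
#' @return `read_scene_image()`: H x W x 4 array (R, G, B, UV) in \[0, 1\]
#'   (quantised to 16 bits).
#' @export
read_scene_image <- function(vis_path, uv_path) {
  vis <- tiff::readTIFF(vis_path)
  uv <- tiff::readTIFF(uv_path)
  if (length(dim(vis)) != 3 || dim(vis)[3] != 3) {
    nc_abort("VIS TIFF must have 3 channels", "nestcamo_parse_error")
  }
  if (!all(dim(uv) == dim(vis)[1:2])) {
    nc_abort("UV TIFF geometry does not match VIS", "nestcamo_parse_error")
  }
  out <- array(0, c(dim(vis)[1:2], 4))
  out[, , 1:3] <- vis
  out[, , 4] <- uv
  dimnames(out) <- list(NULL, NULL, BAND_NAMES)
  out
}

#' Write / read region annotations as JSON
#'
#' Polygons are vertex lists in 0-based pixel coordinates (x right, y down),
#' implicitly closed. The schema has keys `egg_polygons` (list of arrays of
#' `[x, y]` pairs), `standard_polygon`, `nest_centre`, `px_per_cm`.
#'
#' @param regions a [region_set()].
#' @param path JSON file path.
#' @export
write_region_set <- function(regions, path) {
  obj <- list(
    egg_polygons = lapply(regions$egg_polygons, function(p) unname(as.matrix(p))),
    standard_polygon = unname(as.matrix(regions$standard_polygon)),
    nest_centre = regions$nest_centre,
    px_per_cm = regions$px_per_cm
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_region_set
#' @return `read_region_set()`: a [region_set()].
#' @export
read_region_set <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    nc_abort(paste0("malformed region JSON: ",
                                    conditionMessage(e)),
                             "nestcamo_parse_error")
                  })
  for (key in c("egg_polygons", "standard_polygon", "nest_centre",
                "px_per_cm")) {
    if (is.null(obj[[key]])) {
      nc_abort(paste0("region JSON missing key: ", key),
               "nestcamo_parse_error")
    }
  }
  polys <- obj$egg_polygons
  if (is.array(polys) && length(dim(polys)) == 3) {
    polys <- lapply(seq_len(dim(polys)[1]), function(i) polys[i, , ])
  }
  region_set(egg_polygons = polys,
             standard_polygon = obj$standard_polygon,
             nest_centre = obj$nest_centre,
             px_per_cm = obj$px_per_cm)
}

#' Write / read radiation records as CSV
#'
#' Columns: `treatment`, `day`, `timestamp` (ISO 8601, UTC),
#' `irradiance_wm2`, `illuminance_lux`, `uv_index`.
#'
#' @param records tibble from [simulate_radiation()].
#' @param path CSV path.
#' @export
write_radiation_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_radiation_csv
#' @return `read_radiation_csv()`: tibble with the schema above.
#' @export
read_radiation_csv <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = list(timestamp = readr::col_character()))
  missing <- setdiff(c("treatment", "day", "timestamp", "irradiance_wm2",
                       "illuminance_lux", "uv_index"), names(rec))
  if (length(missing)) {
    nc_abort(paste0("radiation CSV missing column(s): ",
                    paste(missing, collapse = ", ")), "nestcamo_parse_error")
  }
  rec
}
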