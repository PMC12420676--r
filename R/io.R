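# Shared readers and writers.  Tiles and label masks are PNG (8-bit RGB
# and 16-bit grayscale respectively); tables are CSV; polygon overlays
# are QuPath-style GeoJSON FeatureCollections with `classification` and
# `measurements` properties in pixel coordinates.

#' Write / read an RGB tile as 8-bit PNG
#'
#' @param image height x width x 3 array in 0..1.
#' @param path file path.
#' @return `read_tile_png` returns the RGB array.
#' @export
write_tile_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname write_tile_png
#' @export
read_tile_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write / read an instance label mask as RGB PNG
#'
#' Label ids are byte-packed across the three 8-bit channels
#' (id = 65536*R + 256*G + B), lossless up to 16,777,215 instances.
#'
#' @param mask integer matrix.
#' @param path file path.
#' @return `read_mask_png` returns the integer matrix.
#' @export
write_mask_png <- function(mask, path) {
  if (max(mask) > 16777215) stopf("too many labels to store")
  r <- mask %/% 65536L
  g <- (mask %/% 256L) %% 256L
  b <- mask %% 256L
  png::writePNG(array(c(r, g, b) / 255, c(dim(mask), 3)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 2) return(matrix(as.integer(round(m * 255)),
                                         nrow(m), ncol(m)))
  id <- round(m[, , 1] * 255) * 65536 + round(m[, , 2] * 255) * 256 +
    round(m[, , 3] * 255)
  matrix(as.integer(id), dim(m)[1], dim(m)[2])
}

#' Write / read a cell table CSV
#'
#' Columns: `cell_id, x_um, y_um, area_um2, nucleolus_diam_um,
#' nucleolus_contrast, label, binary_label`.
#'
#' @param cells data frame from [classify_cells()].
#' @param path file path.
#' @export
write_cells_csv <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a ground-truth CSV (`cell_id,x_um,y_um,label`)
#'
#' @param truth a `ground_truth` object or compatible data frame.
#' @param path file path.
#' @export
write_truth_csv <- function(truth, path) {
  df <- if (inherits(truth, "ground_truth"))
    truth$planted[, c("cell_id", "x_um", "y_um", "label")]
  else truth
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write / read a profile CSV
#'
#' @param profiles rows from [profile_roi()].
#' @param path file path.
#' @export
write_profile_csv <- function(profiles, path) {
  write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write / read a cohort CSV
#'
#' Columns: `sample_id, grade, dens_g3, dens_other, time_days, event`
#' (plus `quadrant` if present).
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if ("quadrant" %in% names(out))
    out$quadrant <- factor(out$quadrant, QUADRANT_LEVELS)
  out
}

#' Write segmented/classified cells as QuPath-style GeoJSON
#'
#' A FeatureCollection of Polygon features in pixel coordinates.
#' `properties$classification$name` carries the class (empty string at
#' the segmentation stage); `properties$measurements$score` carries the
#' detection score d.
#'
#' @param instances a `nucleus_set`.
#' @param path file path.
#' @param classes optional character vector of per-instance class names.
#' @export
write_cells_geojson <- function(instances, path, classes = NULL) {
  n <- length(instances)
  feats <- lapply(seq_len(n), function(i) {
    inst <- instance_at(instances, i)
    ring <- rbind(inst$polygon, inst$polygon[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(v) c(ring[v, 1], ring[v, 2])))),
         properties = list(
           classification = list(
             name = if (is.null(classes)) "" else classes[i]),
           measurements = list(score = inst$score)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a QuPath-style cells GeoJSON
#'
#' @param path file path.
#' @return list with `polygons` (list of vertex matrices, the closing
#'   vertex removed), `scores` and `classes`.
#' @export
read_cells_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  polys <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) unlist(v)))
    m[-nrow(m), , drop = FALSE]
  })
  scores <- vapply(feats, function(f)
    as.numeric(f$properties$measurements$score %||% NA), numeric(1))
  classes <- vapply(feats, function(f)
    as.character(f$properties$classification$name %||% ""), character(1))
  list(polygons = polys, scores = scores, classes = classes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' All numeric parameters with their defaults; round-trips losslessly
#' through JSON.
#'
#' @param pixel_size um per pixel (0.25 corresponds to a x40 scan).
#' @param n_rays,prob_threshold,iou_threshold,stride segmentation
#'   parameters.
#' @param rules classifier thresholds, a [grade_rules()] object.
#' @param roi_perimeter_um ROI perimeter (4000 um = 1 mm^2 square).
#' @param cuts quadrant density cut-offs `c(g3, other)`.
#' @param g3_criterion_pct %G3 criterion for flagging high grade.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = 0.25, n_rays = 32,
                            prob_threshold = 0.5, iou_threshold = 0.5,
                            stride = 2, rules = grade_rules(),
                            roi_perimeter_um = 4000,
                            cuts = c(g3 = 533, other = 4133),
                            g3_criterion_pct = 11.4, seed = 1L) {
  num <- c(pixel_size, n_rays, prob_threshold, iou_threshold, stride,
           roi_perimeter_um, cuts, g3_criterion_pct)
  if (any(num <= 0)) stopf("all numeric parameters must be positive")
  structure(list(pixel_size = pixel_size, n_rays = as.integer(n_rays),
                 prob_threshold = prob_threshold,
                 iou_threshold = iou_threshold, stride = as.integer(stride),
                 rules = unclass(rules),
                 roi_perimeter_um = roi_perimeter_um,
                 cuts = c(g3 = unname(cuts[1]), other = unname(cuts[2])),
                 g3_criterion_pct = g3_criterion_pct,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(pixel_size = x$pixel_size, n_rays = x$n_rays,
                  prob_threshold = x$prob_threshold,
                  iou_threshold = x$iou_threshold, stride = x$stride,
                  rules = do.call(grade_rules, as.list(x$rules)),
                  roi_perimeter_um = x$roi_perimeter_um,
                  cuts = c(g3 = x$cuts[[1]], other = x$cuts[[2]]),
                  g3_criterion_pct = x$g3_criterion_pct, seed = x$seed)
}
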