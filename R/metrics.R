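# ROI handling and tissue-profile statistics: densities of G3 and Other
# cells per mm^2 and the percentage of G3 cells.

#' Square ROI from a perimeter
#'
#' Axis-aligned square of side `perimeter_um / 4` centred at `center`;
#' the reference ROI has a 4000 um perimeter, i.e. area 1 mm^2.
#'
#' @param perimeter_um perimeter in micrometres (> 0).
#' @param center (x, y) centre in micrometres.
#' @param id ROI identifier.
#' @return object of class `roi` with fields `xmin, xmax, ymin, ymax`
#'   (um), `area_mm2`, `boundary` (4 x 2 vertex matrix, um) and `id`.
#' @export
roi_from_perimeter <- function(perimeter_um, center = c(0, 0), id = "roi1") {
  if (perimeter_um <= 0) stopf("perimeter must be positive")
  side <- perimeter_um / 4
  xmin <- center[1] - side / 2; ymin <- center[2] - side / 2
  xmax <- xmin + side; ymax <- ymin + side
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 side_um = side, area_mm2 = side^2 / 1e6,
                 boundary = cbind(x = c(xmin, xmax, xmax, xmin),
                                  y = c(ymin, ymin, ymax, ymax)),
                 id = id),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi '%s': side %.1f um, area %.4f mm^2\n",
              x$id, x$side_um, x$area_mm2))
  invisible(x)
}

#' Profile the cells of an ROI
#'
#' Membership is by centroid with a half-open convention: a cell belongs
#' to the ROI iff `xmin <= x < xmax` and `ymin <= y < ymax` (min edges
#' inclusive), so adjacent tiling ROIs never double count.  An ROI with
#' zero cells yields a flagged profile with undefined `pct_g3`, not an
#' error.
#'
#' @param cells data frame with `x_um`, `y_um` and `binary_label`
#'   columns (as produced by [classify_cells()]).
#' @param roi a [roi_from_perimeter()] object.
#' @param verify when `TRUE`, warn if the in-ROI cell count per mm^2 is
#'   outside the 400-1200 verification band (sparse dystrophic tiles
#'   legitimately run below it).
#' @return one-row data frame of class `roi_profile`: `roi_id, area_mm2,
#'   n_total, n_g3, n_other, dens_g3, dens_other, pct_g3, empty`.
#' @export
profile_roi <- function(cells, roi, verify = FALSE) {
  stopifnot(inherits(roi, "roi"))
  inside <- cells$x_um >= roi$xmin & cells$x_um < roi$xmax &
    cells$y_um >= roi$ymin & cells$y_um < roi$ymax
  sub <- cells[inside, , drop = FALSE]
  n_total <- nrow(sub)
  n_g3 <- sum(sub$binary_label == "G3")
  n_other <- n_total - n_g3
  if (verify) {
    dens <- n_total / roi$area_mm2
    if (dens < 400 || dens > 1200)
      warnf("ROI '%s' has %.0f cells/mm^2, outside the 400-1200 band",
            roi$id, dens)
  }
  out <- data.frame(roi_id = roi$id, area_mm2 = roi$area_mm2,
                    n_total = n_total, n_g3 = n_g3, n_other = n_other,
                    dens_g3 = n_g3 / roi$area_mm2,
                    dens_other = n_other / roi$area_mm2,
                    pct_g3 = if (n_total > 0) 100 * n_g3 / n_total
                             else NA_real_,
                    empty = n_total == 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_profile", "data.frame")
  out
}

#' Range of the G3 percentage over a set of profiles
#'
#' @param profiles data frame of profiles (rows from [profile_roi()]).
#' @return named numeric `c(min, max)` over the defined `pct_g3` values.
#' @export
profile_range <- function(profiles) {
  v <- profiles$pct_g3[!is.na(profiles$pct_g3)]
  if (!length(v)) stopf("all profiles are empty")
  c(min = min(v), max = max(v))
}
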