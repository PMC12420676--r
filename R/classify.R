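# Deterministic rule-based cell grading by nucleolar prominence.
#
# The WHO/ISUP verbal criteria (nucleolus visible at x100 vs x400
# magnification) are operationalised as physical size/contrast
# thresholds: a nucleolus "clearly visible at x100" must be at least
# D100 um across with high contrast, one "noticeable at x400" at least
# D400 um with moderate contrast.  All thresholds are configuration
# values; the defaults are stated in grade_rules().

#' Grading rule thresholds
#'
#' @param D100 minimum nucleolus equivalent diameter (um) for the
#'   "clearly visible at x100" (G3) rule.
#' @param D400 minimum nucleolus diameter (um) for the "noticeable at
#'   x400" (G2) rule.
#' @param C_hi minimum nucleolus/nucleoplasm darkness contrast for G3.
#' @param C_lo minimum contrast for G2.
#' @param small_nucleus_diam upper bound (um) on the nucleus equivalent
#'   diameter for the small-nucleus G1 rule; low-grade nuclei average
#'   about 6 um, high-grade about 9 um, so the bound sits between.
#' @return object of class `grade_rules`.
#' @export
grade_rules <- function(D100 = 1.5, D400 = 0.7, C_hi = 0.25, C_lo = 0.10,
                        small_nucleus_diam = 7.5) {
  stopifnot(D100 >= D400, C_hi >= C_lo, small_nucleus_diam > 0)
  structure(list(D100 = D100, D400 = D400, C_hi = C_hi, C_lo = C_lo,
                 small_nucleus_diam = small_nucleus_diam),
            class = "grade_rules")
}

darkness_matrix <- function(image) {
  1 - (image[, , 1] + image[, , 2] + image[, , 3]) / 3
}

#' Detect nucleoli inside a nucleus mask
#'
#' Nucleoli are connected clusters of intra-nuclear pixels whose darkness
#' exceeds the nucleoplasm reference (median darkness over the mask) by
#' at least `min_contrast`.  Returned blobs are sorted by diameter
#' descending.
#'
#' @param image RGB array or darkness matrix.
#' @param nucleus_mask logical matrix (same shape) marking the nucleus,
#'   or integer vector of linear pixel indices.
#' @param pixel_size um per pixel.
#' @param min_contrast detection threshold on darkness above the
#'   nucleoplasm median.
#' @param min_px minimum blob size in pixels.
#' @return data frame with columns `diam_um` and `contrast`, one row per
#'   blob, sorted by diameter descending.
#' @export
detect_nucleoli <- function(image, nucleus_mask, pixel_size,
                            min_contrast = 0.08, min_px = 2L) {
  dm <- if (length(dim(image)) == 3) darkness_matrix(image) else image
  if (is.logical(nucleus_mask)) idx <- which(nucleus_mask)
  else idx <- as.integer(nucleus_mask)
  if (length(idx) < 4) stopf("nucleus mask must cover at least 4 pixels")
  h <- nrow(dm)
  ys <- (idx - 1L) %% h + 1L
  xs <- (idx - 1L) %/% h + 1L
  y0 <- min(ys); x0 <- min(xs)
  sub <- matrix(FALSE, max(ys) - y0 + 1L, max(xs) - x0 + 1L)
  sub[cbind(ys - y0 + 1L, xs - x0 + 1L)] <- TRUE
  dsub <- dm[y0:max(ys), x0:max(xs), drop = FALSE]
  ref <- median(dsub[sub])
  blobmask <- sub & (dsub >= ref + min_contrast)
  if (!any(blobmask))
    return(data.frame(diam_um = numeric(0), contrast = numeric(0)))
  lab <- cpp_cc(blobmask)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  rows <- lapply(ids, function(b) {
    px <- lab == b
    n <- sum(px)
    if (n < min_px) return(NULL)
    bg <- median(dsub[sub & !blobmask])
    data.frame(diam_um = 2 * sqrt(n / pi) * pixel_size,
               contrast = mean(dsub[px]) - bg)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(diam_um = numeric(0), contrast = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(-out$diam_um), , drop = FALSE]
}

#' Extract per-cell features
#'
#' Area = pixel count x pixel_size^2; equivalent diameter =
#' 2*sqrt(area/pi); nucleolus fields come from the largest detected blob
#' (zero diameter and contrast when none).
#'
#' @param image RGB array or darkness matrix.
#' @param pixels linear pixel indices of the instance, or a logical mask.
#' @param pixel_size um per pixel.
#' @param min_contrast passed to [detect_nucleoli()].
#' @return object of class `cell_features` (a one-row list).
#' @export
extract_features <- function(image, pixels, pixel_size,
                             min_contrast = 0.08) {
  dm <- if (length(dim(image)) == 3) darkness_matrix(image) else image
  idx <- if (is.logical(pixels)) which(pixels) else as.integer(pixels)
  if (length(idx) == 0) stopf("zero-area instance")
  area <- length(idx) * pixel_size^2
  blobs <- if (length(idx) >= 4)
    detect_nucleoli(dm, idx, pixel_size, min_contrast)
  else data.frame(diam_um = numeric(0), contrast = numeric(0))
  structure(list(
    nucleus_area = area,
    nucleus_equiv_diam = 2 * sqrt(area / pi),
    nucleus_mean_darkness = mean(dm[idx]),
    nucleolus_diam = if (nrow(blobs)) blobs$diam_um[1] else 0,
    nucleolus_contrast = if (nrow(blobs)) blobs$contrast[1] else 0,
    n_nucleoli = nrow(blobs)), class = "cell_features")
}

#' Assign a cell grade from its features
#'
#' Rule order: G3 iff nucleolus_diam >= D100 and contrast >= C_hi
#' (boundaries inclusive); else G2 iff nucleolus_diam >= D400 and
#' contrast >= C_lo; else G1 iff the nucleus equivalent diameter is at
#' most the small-nucleus bound; else Other.  When several nucleoli are
#' present the largest governs.  Total and deterministic.
#'
#' @param f a `cell_features` object (or list with the same fields).
#' @param rules a [grade_rules()] object.
#' @return one of `"G1"`, `"G2"`, `"G3"`, `"Other"`.
#' @export
assign_grade <- function(f, rules = grade_rules()) {
  if (f$nucleolus_diam >= rules$D100 && f$nucleolus_contrast >= rules$C_hi)
    return("G3")
  if (f$nucleolus_diam >= rules$D400 && f$nucleolus_contrast >= rules$C_lo)
    return("G2")
  if (f$nucleus_equiv_diam <= rules$small_nucleus_diam) return("G1")
  "Other"
}

#' Collapse a grade label to the binary G3-vs-Other task
#'
#' G3 maps to G3; G1, G2 and Other map to Other (all stromal and tumour
#' cells lacking prominent nucleoli).
#'
#' @param label character vector of grade labels.
#' @return character vector over `{"G3", "Other"}`.
#' @export
binarize_label <- function(label) {
  bad <- setdiff(unique(label), CLASS_LEVELS)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  ifelse(label == "G3", "G3", "Other")
}

#' Class-distribution summary
#'
#' Counts and percentages per class, percentages reported to two
#' decimals with half-up rounding.
#'
#' @param x either a character vector of labels or a named vector of
#'   non-negative counts.
#' @return data frame with columns `class`, `count`, `pct`.
#' @export
class_distribution <- function(x) {
  counts <- if (is.numeric(x)) x
  else {
    tab <- table(factor(x, levels = unique(c(CLASS_LEVELS, unique(x)))))
    tab[tab > 0 | names(tab) %in% CLASS_LEVELS]
  }
  if (any(counts < 0)) stopf("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stopf("total count must be positive")
  data.frame(class = if (is.null(names(counts)))
    paste0("class", seq_along(counts)) else names(counts),
    count = as.integer(counts),
    pct = round_half_up(100 * as.numeric(counts) / total, 2),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify every instance of a segmented or ground-truth mask
#'
#' @param image RGB array.
#' @param mask integer label matrix (0 = background).
#' @param pixel_size um per pixel.
#' @param rules a [grade_rules()] object.
#' @param min_contrast nucleolus detection threshold.
#' @return data frame of cell records: `cell_id, x_um, y_um, area_um2,
#'   nucleolus_diam_um, nucleolus_contrast, label, binary_label`.
#' @export
classify_cells <- function(image, mask, pixel_size, rules = grade_rules(),
                           min_contrast = 0.08) {
  dm <- darkness_matrix(image)
  ids <- sort(setdiff(unique(as.vector(mask)), 0L))
  fg <- which(mask > 0)
  by_id <- split(fg, mask[fg])
  h <- nrow(mask)
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    idx <- by_id[[as.character(id)]]
    f <- extract_features(dm, idx, pixel_size, min_contrast)
    lab <- assign_grade(f, rules)
    ys <- (idx - 1L) %% h
    xs <- (idx - 1L) %/% h
    rows[[k]] <- data.frame(
      cell_id = id,
      x_um = mean(xs) * pixel_size, y_um = mean(ys) * pixel_size,
      area_um2 = f$nucleus_area,
      nucleolus_diam_um = f$nucleolus_diam,
      nucleolus_contrast = f$nucleolus_contrast,
      label = lab, binary_label = binarize_label(lab),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
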