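# Star-convex nucleus instance segmentation.
#
# The learned probability/distance predictor of the original
# segmentation network is replaced by a deterministic classical stage:
# object probability is a rescaled, smoothed nuclear-stain darkness, and
# radial distances are obtained by ray casting on the thresholded
# foreground.  Candidate polygons (one per qualifying pixel) are then
# reduced by greedy IoU non-maximum suppression, exactly as in the
# star-convex representation this module implements.

#' Compute object-probability and radial-distance maps
#'
#' Darkness (1 - mean RGB) is smoothed and linearly rescaled between
#' `darkness_low` (background) and `darkness_high` (confident nucleus) to
#' a per-pixel object probability in 0..1.  Radial distances along
#' `n_rays` fixed directions (ray k at angle 2*pi*k/n_rays; angle 0 = +x,
#' measured toward +y, image convention) are computed by ray marching on
#' the thresholded foreground and stored sparsely for foreground pixels.
#'
#' @param image RGB array (height x width x 3, values in 0..1).
#' @param n_rays number of rays (>= 3).
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param darkness_low,darkness_high darkness rescaling anchors.
#' @param fg_prob probability level defining the ray-casting foreground.
#' @return object of class `prob_dist_maps` with fields `prob` (matrix),
#'   `dist` (n_fg x n_rays matrix, pixels), `fg_idx` (linear indices of
#'   foreground pixels, column-major), `n_rays`, `shape`.
#' @export
compute_maps <- function(image, n_rays = 32, smooth_sigma = 1,
                         darkness_low = 0.10, darkness_high = 0.30,
                         fg_prob = 0.5) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stopf("image must be an RGB array (h x w x 3)")
  if (n_rays < 3) stopf("n_rays must be >= 3")
  d <- 1 - (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  sm <- cpp_blur(d, smooth_sigma)
  prob <- pmin(pmax((sm - darkness_low) / (darkness_high - darkness_low),
                    0), 1)
  fg <- prob >= fg_prob
  fg_idx <- which(fg)
  h <- nrow(prob)
  py <- (fg_idx - 1L) %% h          # 0-based row
  px <- (fg_idx - 1L) %/% h         # 0-based col
  rmax <- sqrt(nrow(prob)^2 + ncol(prob)^2)
  dist <- if (length(fg_idx))
    cpp_radial_dist(fg, as.integer(px), as.integer(py), as.integer(n_rays),
                    0.5, rmax)
  else matrix(0, 0, n_rays)
  structure(list(prob = prob, dist = dist, fg_idx = fg_idx,
                 n_rays = as.integer(n_rays),
                 shape = dim(prob)),
            class = "prob_dist_maps")
}

#' Polygon from a centre and radial distances
#'
#' Vertex k lies at `center + radii[k] * (cos(theta_k), sin(theta_k))`
#' with `theta_k = 2*pi*k/n_rays` (k = 0..n_rays-1).
#'
#' @param center numeric (x, y) in pixels.
#' @param radii positive radial distances, length `n_rays`.
#' @param n_rays number of rays; defaults to `length(radii)`.
#' @return n_rays x 2 matrix of vertex coordinates.
#' @export
polygon_from_rays <- function(center, radii, n_rays = length(radii)) {
  if (length(radii) != n_rays) stopf("radii must have length n_rays")
  if (any(radii <= 0)) stopf("all radii must be positive")
  theta <- 2 * pi * (0:(n_rays - 1)) / n_rays
  cbind(x = center[1] + radii * cos(theta),
        y = center[2] + radii * sin(theta))
}

#' Intersection-over-union of two simple polygons
#'
#' Exact area computation via signed triangle-fan decomposition and
#' convex clipping; symmetric; degenerate (zero-area) polygons give 0.
#'
#' @param a,b vertex matrices (n x 2).
#' @return IoU in 0..1.
#' @export
polygon_iou <- function(a, b) {
  cpp_polygon_iou(as.matrix(a), as.matrix(b))
}

# container for a set of star-convex instances; matrix-oriented so that
# tens of thousands of candidates stay cheap
new_nucleus_set <- function(centers, radii, scores, ids = seq_along(scores)) {
  structure(list(centers = centers, radii = radii, scores = scores,
                 ids = as.integer(ids)),
            class = "nucleus_set")
}

#' @export
length.nucleus_set <- function(x) length(x$scores)

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("nucleus_set: %d instances, %d rays\n",
              length(x$scores), ncol(x$radii)))
  invisible(x)
}

#' Materialise one instance of a nucleus set
#'
#' @param x a `nucleus_set`.
#' @param i index.
#' @return list with `center`, `radii`, `score`, `id` and `polygon`.
#' @export
instance_at <- function(x, i) {
  list(center = x$centers[i, ], radii = x$radii[i, ], score = x$scores[i],
       id = x$ids[i],
       polygon = polygon_from_rays(x$centers[i, ], x$radii[i, ]))
}

#' Polygon candidates from probability/distance maps
#'
#' One candidate per (optionally grid-subsampled) pixel whose probability
#' is at least `prob_threshold`; candidate score is the probability at
#' that pixel.  Output is sorted by score descending, ties broken by
#' (row, column) scan order.
#'
#' @param maps a [compute_maps()] result.
#' @param prob_threshold probability threshold in (0, 1].
#' @param stride candidate grid stride in pixels.
#' @return a `nucleus_set`.
#' @export
candidates <- function(maps, prob_threshold = 0.5, stride = 2) {
  stopifnot(inherits(maps, "prob_dist_maps"))
  if (prob_threshold <= 0 || prob_threshold > 1)
    stopf("prob_threshold must be in (0, 1]")
  h <- maps$shape[1]
  py <- (maps$fg_idx - 1L) %% h
  px <- (maps$fg_idx - 1L) %/% h
  keep <- maps$prob[maps$fg_idx] >= prob_threshold &
    py %% stride == 0L & px %% stride == 0L
  py <- py[keep]; px <- px[keep]
  sc <- maps$prob[maps$fg_idx][keep]
  radii <- maps$dist[keep, , drop = FALSE]
  radii[radii <= 0] <- 0.25
  ord <- order(-sc, py, px)
  new_nucleus_set(cbind(px, py)[ord, , drop = FALSE],
                  radii[ord, , drop = FALSE], sc[ord])
}

#' Greedy non-maximum suppression
#'
#' Accept the highest-scoring candidate, suppress every candidate whose
#' IoU with an accepted instance exceeds `iou_threshold`, repeat.  The
#' output is a subset of the input with pairwise IoU <= threshold.
#'
#' @param cands a `nucleus_set` sorted by score descending.
#' @param iou_threshold overlap threshold in (0, 1).
#' @return a `nucleus_set` with ids renumbered 1..K in score order.
#' @export
nms <- function(cands, iou_threshold = 0.5) {
  stopifnot(inherits(cands, "nucleus_set"))
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stopf("iou_threshold must be in (0, 1)")
  if (is.unsorted(-cands$scores))
    stopf("candidates must be sorted by score descending")
  if (length(cands) == 0) return(cands)
  keep <- cpp_nms(cands$centers, cands$radii, iou_threshold)
  new_nucleus_set(cands$centers[keep, , drop = FALSE],
                  cands$radii[keep, , drop = FALSE],
                  cands$scores[keep])
}

#' Rasterise instances to a label image
#'
#' Each pixel (by pixel-centre inclusion) is assigned to the
#' highest-score covering instance; labels 1..K follow score order;
#' background is 0.  Instances falling fully outside the image are
#' dropped with a warning.
#'
#' @param instances a `nucleus_set` (NMS-filtered).
#' @param shape image shape `c(height, width)`.
#' @return integer label matrix.
#' @export
rasterize <- function(instances, shape) {
  stopifnot(inherits(instances, "nucleus_set"))
  n <- length(instances)
  if (n == 0) return(matrix(0L, shape[1], shape[2]))
  ord <- order(-instances$scores)
  polys <- lapply(ord, function(i)
    polygon_from_rays(instances$centers[i, ], instances$radii[i, ]))
  outside <- vapply(polys, function(p)
    all(p[, 1] < 0) || all(p[, 1] > shape[2] - 1) ||
    all(p[, 2] < 0) || all(p[, 2] > shape[1] - 1), logical(1))
  if (any(outside)) {
    warnf("%d instance(s) fully outside the image were dropped",
          sum(outside))
    polys <- polys[!outside]
  }
  cpp_rasterize(polys, shape[1], shape[2])
}

#' Segment a tile end to end
#'
#' Convenience wrapper: [compute_maps()], [candidates()], [nms()],
#' [rasterize()].  Deterministic: identical input gives identical masks.
#'
#' @param image RGB array.
#' @param n_rays number of rays.
#' @param prob_threshold candidate probability threshold.
#' @param iou_threshold NMS overlap threshold.
#' @param stride candidate grid stride.
#' @param smooth_sigma probability-map smoothing sigma (pixels).
#' @return list with `instances` (a `nucleus_set`) and `mask` (label
#'   matrix).
#' @export
segment_tile <- function(image, n_rays = 32, prob_threshold = 0.5,
                         iou_threshold = 0.5, stride = 2,
                         smooth_sigma = 1) {
  maps <- compute_maps(image, n_rays = n_rays, smooth_sigma = smooth_sigma)
  cands <- candidates(maps, prob_threshold, stride)
  inst <- nms(cands, iou_threshold)
  list(instances = inst, mask = rasterize(inst, maps$shape))
}
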