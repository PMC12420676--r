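# Shared fixtures and small independent oracles used across test files.

# quarter-mm^2 test tile at 0.5 um/px: same cell densities per mm^2 as
# the reference 1 mm^2 ROI at a quarter of the cost
small_tile <- function(n_cells = 150, seed = 1,
                       mix = c(G1 = 0.45, G2 = 0.15, G3 = 0.1,
                               Other = 0.3)) {
  make_tile(tile_spec(width_px = 1000, height_px = 1000, pixel_size = 0.5,
                      n_cells = n_cells, class_mix = mix, seed = seed))
}

# synthetic image helpers -------------------------------------------------

blank_white_tile <- function(h = 100, w = 100) {
  array(1, dim = c(h, w, 3))
}

# dark disc of given radius (pixels) centred in a white image
disc_tile <- function(h = 64, w = 64, cx = 32, cy = 32, r = 10,
                      darkness = 0.7) {
  d <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w))
    if ((x - 1 - cx)^2 + (y - 1 - cy)^2 <= r^2) d[y, x] <- darkness
  array(rep(1 - d, 3), dim = c(h, w, 3))
}

# independent oracles ------------------------------------------------------

# O(n^2) all-pairs concordance AUC
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# exhaustive cutpoint scan for Youden's J
youden_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, Inf)
  best <- list(J = -Inf, threshold = NA)
  for (th in cand) {
    sens <- mean(scores[labels] > th)
    spec <- mean(scores[!labels] <= th)
    if (sens + spec - 1 > best$J + 1e-12)
      best <- list(J = sens + spec - 1, threshold = th)
  }
  best
}

# brute-force greedy NMS using polygon_iou directly on materialised
# polygons (quadratic reference implementation)
nms_bruteforce <- function(cands, iou_threshold) {
  n <- length(cands)
  polys <- lapply(seq_len(n), function(i) instance_at(cands, i)$polygon)
  keep <- logical(n)
  acc <- integer(0)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in acc)
      if (polygon_iou(polys[[i]], polys[[j]]) > iou_threshold) {
        ok <- FALSE; break
      }
    if (ok) { keep[i] <- TRUE; acc <- c(acc, i) }
  }
  keep
}

# hand product-limit estimator (independent of km_fit internals)
km_bruteforce <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(et))
  for (k in seq_along(et)) {
    n_i <- sum(times >= et[k])
    d_i <- sum(times == et[k] & events == 1)
    s <- s * (1 - d_i / n_i)
    surv[k] <- s
  }
  list(event_times = et, survival = surv)
}

# mask-level instance matching at an IoU threshold (greedy, best first)
match_instances <- function(truth_mask, pred_mask, iou = 0.5) {
  t <- as.vector(truth_mask); p <- as.vector(pred_mask)
  nt <- max(t); np <- max(p)
  if (np == 0 || nt == 0)
    return(list(matched = 0L, n_true = nt, n_pred = np, fp = np))
  ta <- tabulate(t, nt); pa <- tabulate(p, np)
  sel <- t > 0 & p > 0
  ov <- table(factor(t[sel]), factor(p[sel]))
  pairs <- which(ov > 0, arr.ind = TRUE)
  tid <- as.integer(rownames(ov))[pairs[, 1]]
  pid <- as.integer(colnames(ov))[pairs[, 2]]
  inter <- ov[pairs]
  ious <- inter / (ta[tid] + pa[pid] - inter)
  ord <- order(-ious)
  used_t <- logical(nt); used_p <- logical(np)
  matched <- 0L
  for (k in ord) {
    if (ious[k] < iou) break
    i <- tid[k]; j <- pid[k]
    if (!used_t[i] && !used_p[j]) {
      used_t[i] <- TRUE; used_p[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(matched = matched, n_true = nt, n_pred = np,
       fp = np - sum(used_p))
}
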