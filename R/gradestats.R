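# Grade-level statistics: ROC/AUC for the low (G1/G2) vs high (G3/G4)
# binary grading task, Youden's J cutpoint, and one-way ANOVA with
# Tukey's multiple comparisons for the per-grade density/percentage
# comparisons.

#' Area under the ROC curve
#'
#' Computed as the normalised pairwise concordance
#' `P(score_pos > score_neg) + 0.5 * P(tie)` via midranks, which equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores.
#' @param labels logical (or coercible) positive-class indicator.
#' @return AUC in 0..1.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Optimal threshold by Youden's J index
#'
#' Candidate thresholds are the midpoints between adjacent distinct
#' scores plus -Inf and +Inf; positives are called when
#' `score > threshold`.  The threshold maximising
#' J = sensitivity + specificity - 1 is returned; ties on J resolve to
#' the smallest threshold.
#'
#' @inheritParams roc_auc
#' @return object of class `threshold_result` with fields `threshold`,
#'   `J`, `sensitivity`, `specificity`, `auc`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, Inf)
  best <- list(J = -Inf, threshold = NA_real_, sens = NA_real_,
               spec = NA_real_)
  for (th in cand) {
    sens <- sum(scores[labels] > th) / n_pos
    spec <- sum(scores[!labels] <= th) / n_neg
    J <- sens + spec - 1
    if (J > best$J + 1e-12) # strict improvement keeps smallest threshold
      best <- list(J = J, threshold = th, sens = sens, spec = spec)
  }
  structure(list(threshold = best$threshold, J = best$J,
                 sensitivity = best$sens, specificity = best$spec,
                 auc = roc_auc(scores, labels)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "threshold %.4g | J = %.3f (sens %.3f, spec %.3f) | AUC = %.3f\n",
    x$threshold, x$J, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Low-vs-high grade discrimination from ROI profiles
#'
#' Labels grades 1-2 as low and 3-4 as high and evaluates a profile
#' score (percentage of G3 cells by default, or their density) by ROC
#' AUC and the Youden cutpoint.
#'
#' @param profiles data frame with the score column and `sample_id` (or
#'   aligned row order with `grades`).
#' @param grades integer vector of expert grades in 1..4, aligned with
#'   `profiles` rows.
#' @param score which profile column to use as score.
#' @return a `threshold_result` with an added `score` field.
#' @export
grade_binary_eval <- function(profiles, grades,
                              score = c("pct_g3", "dens_g3")) {
  score <- match.arg(score)
  if (!all(grades %in% 1:4)) stopf("grades must be in 1..4")
  if (nrow(profiles) != length(grades))
    stopf("profiles and grades must align")
  high <- grades >= 3
  if (!any(high) || all(high))
    stopf("both low (1-2) and high (3-4) grades must be present")
  res <- youden_threshold(profiles[[score]], high)
  res$score <- score
  res
}

#' One-way ANOVA with Tukey's multiple comparisons
#'
#' Classical one-way F test followed by Tukey HSD adjusted pairwise
#' comparisons (studentized-range distribution).  If every group is
#' constant, the degenerate case is flagged: p = 1 when all means agree,
#' otherwise p = 0 with `zero_variance = TRUE` (no infinite F is
#' reported).
#'
#' @param values numeric response values, or a named list of per-group
#'   vectors (then `groups` is ignored).
#' @param groups group membership, aligned with `values`.
#' @return object of class `anova_result` with fields `F`, `df_between`,
#'   `df_within`, `p`, `tukey` (data frame `group_i, group_j, mean_diff,
#'   adjusted_p`) and `zero_variance`.
#' @export
anova_tukey <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2) stopf("need at least 2 groups")
  if (any(tabulate(g) < 2)) stopf("each group needs n >= 2")
  k <- nlevels(g); n <- length(values)
  means <- tapply(values, g, mean)
  ssw <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  if (ssw < 1e-12 * max(1, sum(values^2))) {
    same <- max(means) - min(means) < 1e-12
    return(structure(list(F = if (same) 0 else NA_real_,
                          df_between = k - 1, df_within = n - k,
                          p = if (same) 1 else 0,
                          tukey = NULL, zero_variance = !same),
                     class = "anova_result"))
  }
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(group_i = vapply(pairs, `[`, "", 1),
                      group_j = vapply(pairs, `[`, "", 2),
                      mean_diff = tk[, "diff"],
                      adjusted_p = tk[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(F = tab[1, "F value"], df_between = tab[1, "Df"],
                 df_within = tab[2, "Df"], p = tab[1, "Pr(>F)"],
                 tukey = tukey, zero_variance = FALSE),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (isTRUE(x$zero_variance)) " [zero within-group variance]"
              else ""))
  if (!is.null(x$tukey)) {
    cat("Tukey HSD:\n")
    print(x$tukey, digits = 4)
  }
  invisible(x)
}

#' Boxplot summary statistics (numbers, not graphics)
#'
#' Median, quartiles and the 5th/95th percentiles per group, matching
#' the 5-95 percentile boxplot convention.
#'
#' @inheritParams anova_tukey
#' @return data frame with one row per group.
#' @export
boxplot_stats <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  do.call(rbind, lapply(levels(g), function(lv) {
    v <- values[g == lv]
    q <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE,
                  type = 7)
    data.frame(group = lv, n = length(v), p05 = q[1], q1 = q[2],
               median = q[3], q3 = q[4], p95 = q[5],
               stringsAsFactors = FALSE)
  }))
}
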