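# Prognostic quadrant analysis: dual density cut-offs, Kaplan-Meier
# product-limit curves and medians, the k-sample log-rank (Mantel-Cox)
# test and Fisher's exact test of the quadrant-by-grade association.
#
# The published quadrant definitions are inconsistent at the Other-cell
# boundary (">" in one quadrant, ">=" in its complement), which cannot
# partition the plane; a uniform strict-greater positivity rule is used
# for both axes instead.

#' Assign the tissue-pattern quadrant from dual density cut-offs
#'
#' G3-positive iff `dens_g3 > cuts[1]`; Other-positive iff
#' `dens_other > cuts[2]` (uniform strict-greater convention, so points
#' exactly on a cut-off are negative for that axis).  The four quadrants
#' partition the density plane.
#'
#' @param dens_g3,dens_other densities in cells/mm^2 (vectorised).
#' @param cuts cut-offs `c(g3, other)`, default `c(533, 4133)`.
#' @return factor over `"G3+/O-", "G3+/O+", "G3-/O-", "G3-/O+"`.
#' @export
assign_quadrant <- function(dens_g3, dens_other,
                            cuts = c(g3 = 533, other = 4133)) {
  if (any(dens_g3 < 0) || any(dens_other < 0))
    stopf("densities must be non-negative")
  g3p <- dens_g3 > cuts[[1]]
  otp <- dens_other > cuts[[2]]
  q <- ifelse(g3p, ifelse(otp, "G3+/O+", "G3+/O-"),
              ifelse(otp, "G3-/O+", "G3-/O-"))
  factor(q, levels = QUADRANT_LEVELS)
}

#' Kaplan-Meier product-limit fit
#'
#' `S(t) = prod over event times ti <= t of (1 - d_i / n_i)`; subjects
#' censored exactly at an event time are counted at risk at that time.
#'
#' @param times positive follow-up times.
#' @param events event indicator (1 = event, 0 = censored).
#' @return object of class `km_curve` with fields `event_times`,
#'   `n_at_risk`, `n_events`, `survival` (aligned with `event_times`),
#'   `median` (NA when not reached), `n`.
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0) stopf("empty input")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  if (any(times <= 0)) stopf("times must be positive")
  et <- sort(unique(times[events == 1]))
  n_at_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_events <- vapply(et, function(t) sum(times == t & events == 1),
                     numeric(1))
  surv <- cumprod(1 - n_events / n_at_risk)
  med <- if (length(et) && any(surv <= 0.5)) et[which(surv <= 0.5)[1]]
         else NA_real_
  structure(list(event_times = et, n_at_risk = n_at_risk,
                 n_events = n_events, survival = surv, median = med,
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: n = %d, %d events, median = %s\n",
              x$n, sum(x$n_events),
              if (is.na(x$median)) "not reached"
              else format(x$median)))
  invisible(x)
}

#' Median survival of a Kaplan-Meier curve
#'
#' Smallest event time with `S(t) <= 0.5` (inclusive convention);
#' `NA` (printed as "not reached") when the curve never drops to 0.5.
#'
#' @param curve a [km_fit()] result.
#' @return numeric days, or `NA_real_` when not reached.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  curve$median
}

#' Evaluate the survival function of a KM curve at arbitrary times
#'
#' @param curve a [km_fit()] result.
#' @param t times at which to evaluate.
#' @return survival probabilities (1 before the first event).
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- sum(curve$event_times <= tt)
    if (i == 0) 1 else curve$survival[i]
  }, numeric(1))
}

#' k-sample log-rank (Mantel-Cox) test
#'
#' Observed-minus-expected event counts with the hypergeometric
#' variance-covariance summed over distinct event times; ties are
#' processed together at the shared event time.  The statistic is
#' compared with a chi-square with k - 1 degrees of freedom.
#'
#' @param groups list of `list(times=, events=)` per group, or see
#'   `times`, `events`, `group`.
#' @param times,events,group alternative flat interface.
#' @return object of class `logrank_result` with `chi2`, `df`, `p`,
#'   `observed`, `expected`.
#' @export
logrank_test <- function(groups = NULL, times = NULL, events = NULL,
                         group = NULL) {
  if (is.null(groups)) {
    g <- factor(group)
    groups <- lapply(levels(g), function(lv)
      list(times = times[g == lv], events = events[g == lv]))
    names(groups) <- levels(g)
  }
  k <- length(groups)
  if (k < 2) stopf("need at least 2 non-empty groups")
  if (any(vapply(groups, function(x) length(x$times) == 0, logical(1))))
    stopf("need at least 2 non-empty groups")
  all_t <- unlist(lapply(groups, `[[`, "times"))
  all_e <- unlist(lapply(groups, `[[`, "events"))
  gid <- rep(seq_len(k), vapply(groups, function(x) length(x$times),
                                numeric(1)))
  if (sum(all_e) == 0)
    stopf("no events observed; log-rank test undefined")
  et <- sort(unique(all_t[all_e == 1]))
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in et) {
    at_risk <- all_t >= t
    n <- sum(at_risk)
    ni <- vapply(seq_len(k), function(j) sum(at_risk & gid == j),
                 numeric(1))
    d <- sum(all_t == t & all_e == 1)
    di <- vapply(seq_len(k), function(j)
      sum(all_t == t & all_e == 1 & gid == j), numeric(1))
    O <- O + di
    E <- E + d * ni / n
    if (n > 1) {
      f <- d * (n - d) / (n - 1)
      V <- V + f * (diag(ni / n, k) - tcrossprod(ni / n))
    }
  }
  u <- (O - E)[-k]
  Vs <- V[-k, -k, drop = FALSE]
  chi2 <- tryCatch(drop(t(u) %*% solve(Vs, u)), error = function(e) {
    # generalized inverse for singular variance (degenerate groups)
    s <- svd(Vs)
    pos <- s$d > max(s$d) * 1e-10
    drop(t(u) %*% s$v[, pos, drop = FALSE] %*%
           ((t(s$u[, pos, drop = FALSE]) %*% u) / s$d[pos]))
  })
  chi2 <- max(chi2, 0)
  structure(list(chi2 = chi2, df = k - 1,
                 p = pchisq(chi2, k - 1, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank (Mantel-Cox): chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Fisher's exact test for a contingency table
#'
#' 2x2 tables use direct hypergeometric enumeration with the
#' probability-mass two-sided definition (sum of table probabilities not
#' exceeding the observed one).  Larger tables delegate to the exact
#' network algorithm when the total is at most `exact_max`, otherwise a
#' seeded Monte-Carlo p with its standard error is returned.  Zero
#' margin rows/columns are dropped with a warning.
#'
#' @param table non-negative integer matrix.
#' @param exact_max largest table total for the exact r x c algorithm.
#' @param B Monte-Carlo replicates for large tables.
#' @param mc_seed seed for the Monte-Carlo branch.
#' @return list with `p`, `method` and (Monte-Carlo only) `se`.
#' @export
fisher_exact <- function(table, exact_max = 200, B = 1e5, mc_seed = 1L) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("table must contain non-negative integers")
  if (sum(tab) == 0) stopf("table total must be positive")
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warnf("dropping %d zero-margin row(s)/column(s)", sum(zr) + sum(zc))
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stopf("table must be at least 2 x 2 after dropping zero margins")
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); kk <- sum(tab[, 1])
    support <- max(0, kk - n2):min(kk, m)
    probs <- dhyper(support, m, n2, kk)
    p_obs <- dhyper(tab[1, 1], m, n2, kk)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    return(list(p = min(p, 1), method = "exact 2x2 enumeration"))
  }
  if (sum(tab) <= exact_max) {
    p <- tryCatch(fisher.test(tab, workspace = 2e7)$p.value,
                  error = function(e) NULL)
    if (!is.null(p))
      return(list(p = p, method = "exact network (r x c)"))
    warnf("exact network algorithm failed; falling back to Monte-Carlo")
  }
  p <- with_seed(mc_seed,
                 fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value)
  list(p = p, method = sprintf("Monte-Carlo (B = %d)", as.integer(B)),
       se = sqrt(p * (1 - p) / B))
}

#' Full cohort survival analysis
#'
#' Assigns quadrants from the dual cut-offs, fits per-quadrant and
#' overall Kaplan-Meier curves with medians, runs the k-sample log-rank
#' test across populated quadrants (skipped with a flag when fewer than
#' two are populated) and Fisher's exact test on the quadrant-by-grade
#' table.
#'
#' @param samples cohort data frame with columns `dens_g3, dens_other,
#'   time_days, event, grade`.
#' @param cuts density cut-offs `c(g3, other)`.
#' @return object of class `cohort_report`.
#' @export
cohort_analysis <- function(samples, cuts = c(g3 = 533, other = 4133)) {
  need <- c("dens_g3", "dens_other", "time_days", "event", "grade")
  if (!all(need %in% names(samples)))
    stopf("samples must have columns %s", paste(need, collapse = ", "))
  q <- assign_quadrant(samples$dens_g3, samples$dens_other, cuts)
  populated <- levels(q)[table(q) > 0]
  km <- lapply(setNames(populated, populated), function(lv) {
    i <- q == lv
    km_fit(samples$time_days[i], samples$event[i])
  })
  medians <- vapply(km, km_median, numeric(1))
  overall <- km_fit(samples$time_days, samples$event)
  lr <- NULL; lr_skipped <- length(populated) < 2
  if (!lr_skipped)
    lr <- logrank_test(times = samples$time_days, events = samples$event,
                       group = droplevels(q))
  grade_tab <- table(quadrant = q, grade = factor(samples$grade))
  grade_tab <- grade_tab[rowSums(grade_tab) > 0, , drop = FALSE]
  fisher <- if (nrow(grade_tab) >= 2 && ncol(grade_tab) >= 2)
    fisher_exact(grade_tab) else NULL
  scatter <- data.frame(sample_id = samples$sample_id,
                        dens_g3 = samples$dens_g3,
                        dens_other = samples$dens_other,
                        quadrant = q, event = samples$event,
                        stringsAsFactors = FALSE)
  structure(list(cuts = cuts, quadrant_counts = table(q),
                 km_per_quadrant = km, medians = medians,
                 overall_median = km_median(overall), overall_km = overall,
                 logrank = lr, logrank_skipped = lr_skipped,
                 fisher = fisher, grade_table = grade_tab,
                 scatter = scatter),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: cuts G3 > %g, Other > %g cells/mm^2\n",
              x$cuts[[1]], x$cuts[[2]]))
  print(x$quadrant_counts)
  cat("medians (days):\n")
  print(round(x$medians, 1))
  cat(sprintf("overall median: %s\n",
              if (is.na(x$overall_median)) "not reached"
              else format(x$overall_median)))
  if (x$logrank_skipped) cat("log-rank: skipped (<2 populated quadrants)\n")
  else print(x$logrank)
  if (!is.null(x$fisher))
    cat(sprintf("Fisher quadrant x grade: p = %.4g (%s)\n",
                x$fisher$p, x$fisher$method))
  invisible(x)
}
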