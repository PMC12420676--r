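test_that("assign_quadrant uses the strict-greater convention", {
  expect_equal(as.character(assign_quadrant(600, 4000)), "G3+/O-")
  expect_equal(as.character(assign_quadrant(600, 5000)), "G3+/O+")
  expect_equal(as.character(assign_quadrant(100, 5000)), "G3-/O+")
  # boundary values are negative on both axes
  expect_equal(as.character(assign_quadrant(533, 4133)), "G3-/O-")
  expect_error(assign_quadrant(-1, 100), "non-negative")
})

test_that("quadrant assignment equals brute-force double inequalities", {
  set.seed(13)
  g3 <- c(runif(200, 0, 2000), 533, 533, 534)
  ot <- c(runif(200, 0, 8000), 4133, 4134, 4133)
  got <- assign_quadrant(g3, ot)
  ref <- ifelse(g3 > 533,
                ifelse(ot > 4133, "G3+/O+", "G3+/O-"),
                ifelse(ot > 4133, "G3-/O+", "G3-/O-"))
  expect_identical(as.character(got), ref)
  # the four quadrants partition the plane
  expect_false(any(is.na(got)))
})

test_that("km_fit reproduces the hand product-limit example", {
  km <- km_fit(c(1, 2, 3), c(1, 0, 1))
  # events at t=1 (3 at risk) and t=3 (1 at risk)
  expect_equal(km$event_times, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km_median(km), 3)
  # all censored: S = 1, median not reached
  km2 <- km_fit(c(5, 6, 7), c(0, 0, 0))
  expect_length(km2$event_times, 0)
  expect_true(is.na(km_median(km2)))
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
  expect_error(km_fit(c(1, 2), c(1, 2)), "0/1")
})

test_that("km_fit equals brute-force product limit on random data", {
  set.seed(29)
  for (rep in 1:10) {
    n <- sample(10:100, 1)
    times <- round(rexp(n, 1 / 50)) + 1
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) events[1] <- 1
    km <- km_fit(times, events)
    ref <- km_bruteforce(times, events)
    expect_equal(km$event_times, ref$event_times)
    expect_equal(km$survival, ref$survival, tolerance = 1e-12)
    # survival is non-increasing, starts below 1
    expect_true(all(diff(km$survival) <= 1e-12))
  }
})

test_that("km_fit agrees with survival::survfit (independent route)", {
  skip_if_not_installed("survival")
  set.seed(37)
  times <- round(rexp(60, 1 / 100)) + 1
  events <- rbinom(60, 1, 0.6)
  km <- km_fit(times, events)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  at_events <- sf$time %in% km$event_times & sf$n.event > 0
  expect_equal(km$survival, sf$surv[at_events], tolerance = 1e-12)
  med <- unname(summary(sf)$table["median"])
  expect_equal(km_median(km), med)
})

test_that("median conventions: <= 0.5 crossing, exact 0.5, not reached", {
  # S drops 1 -> 0.4 at t = 100
  km <- km_fit(c(100, 100, 100, 100, 100, 200), c(1, 1, 1, 0, 0, 0))
  expect_equal(km$survival[1], 0.5)   # 1 - 3/6
  expect_equal(km_median(km), 100)    # hits exactly 0.5 -> that time
  km2 <- km_fit(c(10, 20, 30, 40, 50), c(1, 1, 0, 0, 0))
  expect_true(min(km2$survival) > 0.5)
  expect_true(is.na(km_median(km2)))
})

test_that("logrank: identical groups give chi2 = 0, p = 1", {
  t1 <- c(3, 5, 8, 10); e1 <- c(1, 0, 1, 1)
  r <- logrank_test(list(a = list(times = t1, events = e1),
                         b = list(times = t1, events = e1)))
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
  expect_equal(r$df, 1)
})

test_that("two-group logrank matches the closed form and survdiff", {
  # independently coded two-sample closed form
  logrank2 <- function(t1, e1, t2, e2) {
    tt <- c(t1, t2); ee <- c(e1, e2); gg <- rep(1:2, c(length(t1),
                                                      length(t2)))
    et <- sort(unique(tt[ee == 1]))
    O1 <- 0; E1 <- 0; V <- 0
    for (s in et) {
      n <- sum(tt >= s); n1 <- sum(tt >= s & gg == 1)
      d <- sum(tt == s & ee == 1)
      d1 <- sum(tt == s & ee == 1 & gg == 1)
      O1 <- O1 + d1; E1 <- E1 + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O1 - E1)^2 / V
  }
  set.seed(41)
  for (rep in 1:5) {
    t1 <- round(rexp(30, 1 / 60)) + 1; e1 <- rbinom(30, 1, 0.8)
    t2 <- round(rexp(25, 1 / 90)) + 1; e2 <- rbinom(25, 1, 0.8)
    r <- logrank_test(times = c(t1, t2), events = c(e1, e2),
                      group = rep(c("a", "b"), c(30, 25)))
    expect_equal(r$chi2, logrank2(t1, e1, t2, e2), tolerance = 1e-10)
    if (requireNamespace("survival", quietly = TRUE)) {
      sd <- survival::survdiff(
        survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, c(30, 25)))
      expect_equal(r$chi2, sd$chisq, tolerance = 1e-10)
    }
  }
})

test_that("logrank is invariant to group label permutation", {
  set.seed(43)
  times <- round(rexp(60, 1 / 70)) + 1
  events <- rbinom(60, 1, 0.7)
  g <- sample(letters[1:3], 60, TRUE)
  r1 <- logrank_test(times = times, events = events, group = g)
  relab <- c(a = "z", b = "x", c = "y")[g]
  r2 <- logrank_test(times = times, events = events, group = relab)
  expect_equal(r1$chi2, r2$chi2, tolerance = 1e-12)
  # 4-group case agrees with survdiff
  skip_if_not_installed("survival")
  g4 <- sample(1:4, 60, TRUE)
  r4 <- logrank_test(times = times, events = events, group = g4)
  sd4 <- survival::survdiff(survival::Surv(times, events) ~ g4)
  expect_equal(r4$chi2, sd4$chisq, tolerance = 1e-10)
  expect_equal(r4$df, 3)
})

test_that("fisher_exact 2x2 equals hypergeometric enumeration", {
  tab <- matrix(c(1, 11, 9, 3), 2)   # [[1,9],[11,3]]
  got <- fisher_exact(tab)
  # direct enumeration oracle
  m <- 1 + 9; n2 <- 11 + 3; k <- 1 + 11
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_ref <- sum(probs[probs <= dhyper(1, m, n2, k) * (1 + 1e-7)])
  expect_equal(got$p, p_ref, tolerance = 1e-12)
  expect_equal(got$p, fisher.test(tab)$p.value, tolerance = 1e-9)
  # identical rows -> p = 1
  expect_equal(fisher_exact(matrix(c(4, 4, 6, 6), 2))$p, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("fisher_exact r x c: exact for small, Monte-Carlo for large", {
  set.seed(3)
  tab <- matrix(c(5, 2, 3, 1, 6, 4, 2, 8, 3, 2, 2, 2), 4, 3)
  got <- fisher_exact(tab)
  expect_equal(got$p, fisher.test(tab)$p.value, tolerance = 1e-9)
  # large table: MC branch with reported standard error, agrees with
  # the exact computation within 3 SE on this (still tractable) table
  got_mc <- fisher_exact(tab * 30, exact_max = 10, B = 2e4, mc_seed = 5)
  expect_true(grepl("Monte-Carlo", got_mc$method))
  expect_true(is.finite(got_mc$se))
  # zero margin dropped with warning
  tab0 <- rbind(tab, 0)
  expect_warning(r0 <- fisher_exact(tab0), "zero-margin")
  expect_equal(r0$p, got$p)
})

test_that("cohort_analysis composes quadrants, KM, logrank and Fisher", {
  co <- make_cohort(cohort_spec(n_samples = 120, seed = 55))
  rep_ <- cohort_analysis(co)
  expect_s3_class(rep_, "cohort_report")
  expect_equal(sum(rep_$quadrant_counts), 120)
  expect_false(rep_$logrank_skipped)
  expect_true(rep_$logrank$p >= 0 && rep_$logrank$p <= 1)
  expect_equal(names(rep_$km_per_quadrant),
               names(rep_$quadrant_counts[rep_$quadrant_counts > 0]))
  # per-quadrant counts reproduce a brute-force partition
  for (q in names(rep_$km_per_quadrant)) {
    i <- as.character(assign_quadrant(co$dens_g3, co$dens_other)) == q
    expect_equal(rep_$km_per_quadrant[[q]]$n, sum(i))
  }
  # single-quadrant cohort: log-rank flagged as skipped
  co1 <- make_cohort(cohort_spec(n_samples = 20,
                                 quadrant_mix = c(1, 0, 0, 0), seed = 5))
  rep1 <- cohort_analysis(co1)
  expect_true(rep1$logrank_skipped)
  expect_null(rep1$logrank)
})
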