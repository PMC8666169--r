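test_that("summary-derived tables round from unrounded products", {
  # syncope score, diagram-caption specificity: 36 events, 2 missed
  t1 <- nf_from_summary(perf_summary(0.93, 0.56, 0.03647, "low risk"))
  expect_equal(t1$tp + t1$fn, 36)
  expect_equal(t1$tp, 34)   # round(0.93 * 36.47) on the unrounded product
  expect_equal(t1$fn, 2)
  expect_equal(t1$tp + t1$fp + t1$fn + t1$tn, 1000)

  # tabulated-specificity variant leaves the event margin unchanged
  t2 <- nf_from_summary(perf_summary(0.93, 0.53, 0.03647))
  expect_equal(t2$tp, 34)
  expect_equal(t2$fn, 2)

  # cardiovascular score at the 20% cut-point
  t3 <- nf_from_summary(perf_summary(0.40, 0.88, 0.09, ">=20%"))
  expect_equal(t3$tp + t3$fn, 90)
  expect_equal(t3$tp, 36)
  expect_equal(t3$fn, 54)
  expect_equal(t3$fp + t3$tn, 910)

  # perfect rule at 50% prevalence
  t4 <- nf_from_summary(perf_summary(1, 1, 0.5), 100)
  expect_equal(unlist(t4[c("tp", "fp", "fn", "tn")]),
               c(tp = 50, fp = 0, fn = 0, tn = 50))
})

test_that("half-away-from-zero rounding is used, not banker's rounding", {
  # prevalence 0.0365 * 1000 = 36.5 must give 37 events (round() gives 36);
  # the non-event margin also lands on .5 here, so the clamp warning fires
  t <- suppressWarnings(nf_from_summary(perf_summary(1, 1, 0.0365)))
  expect_equal(t$tp + t$fn, 37)
})

test_that("count-built tables store cells verbatim and conserve population", {
  t <- nf_table(34, 426, 2, 538)
  expect_equal(t$population, 1000)
  expect_equal(t$tp + t$fp, 460)      # at risk
  expect_equal(nf_table(0, 0, 0, 1)$population, 1)
  expect_equal(nf_table(36, 110, 54, 800)$population, 1000)
  expect_error(nf_table(-1, 0, 0, 1), "non-negative")
  expect_error(nf_table(0, 0, 0, 0), "positive")
})

test_that("input validation rejects out-of-range proportions and populations", {
  expect_error(perf_summary(1.2, 0.5, 0.1), "sensitivity")
  expect_error(perf_summary(0.9, -0.1, 0.1), "specificity")
  expect_error(perf_summary(0.9, 0.5, 0), "prevalence")
  expect_error(perf_summary(0.9, 0.5, 1), "prevalence")
  expect_error(nf_from_summary(perf_summary(0.9, 0.5, 0.1), 0), "population")
})

test_that("rescaling uses largest-remainder allocation", {
  t <- nf_table(34, 426, 2, 538)
  expect_identical(as.data.frame(nf_rescale(t, 1000)), as.data.frame(t))
  expect_equal(unlist(as.data.frame(nf_rescale(nf_table(1, 1, 1, 1), 8)))[1:4],
               c(tp = 2, fp = 2, fn = 2, tn = 2))

  # each cell within 1 of its exact share, exact total — over random tables
  set.seed(42)
  for (i in 1:25) {
    cells <- rpois(4, lambda = c(30, 400, 5, 500))
    if (sum(cells) == 0) next
    t <- nf_table(cells[1], cells[2], cells[3], cells[4])
    for (newpop in c(10, 100, 997)) {
      r <- nf_rescale(t, newpop)
      got <- c(r$tp, r$fp, r$fn, r$tn)
      exact <- cells * newpop / sum(cells)
      expect_equal(sum(got), newpop)
      expect_true(all(abs(got - exact) < 1))
    }
  }
})

test_that("metrics match their defining ratios and flag zero denominators", {
  m <- nf_metrics(nf_table(36, 110, 54, 800))
  expect_equal(m$overtreat_ratio, 110 / 36)
  expect_equal(round(m$overtreat_ratio), 3)
  expect_equal(m$missed_fraction, 54 / 90)
  expect_equal(m$ppv, 36 / 146)
  expect_equal(m$at_risk, 146)

  m2 <- nf_metrics(nf_table(34, 426, 2, 538))
  expect_equal(m2$npv, 538 / 540)
  expect_equal(m2$sensitivity, 34 / 36)

  # no events: sensitivity undefined but flagged, not an error
  m3 <- nf_metrics(nf_table(0, 0, 0, 100))
  expect_true(is.na(m3$sensitivity))
  expect_equal(m3$specificity, 1)
  expect_true("sensitivity" %in% m3$undefined)
  expect_true("overtreat_ratio" %in% m3$undefined)
})

test_that("summary round-trips through the table up to integer rounding", {
  set.seed(7)
  for (i in 1:30) {
    s <- perf_summary(runif(1), runif(1), runif(1, 0.01, 0.99))
    t <- nf_from_summary(s, 1000)
    m <- nf_metrics(t)
    events <- t$tp + t$fn
    if (events > 0) {
      expect_lte(abs(m$sensitivity - s$sensitivity), 1 / events)
    }
    non_events <- t$fp + t$tn
    if (non_events > 0) {
      expect_lte(abs(m$specificity - s$specificity), 1 / non_events)
    }
    expect_equal(t$population, 1000)
  }
})

test_that("cells stay non-negative and conserved even at rounding edges", {
  set.seed(11)
  cases <- rbind(
    expand.grid(sens = c(0, 1e-6, 0.5, 1), spec = c(0, 1),
                prev = c(1e-6, 0.5, 1 - 1e-6), pop = c(1, 3, 1000)),
    data.frame(sens = runif(50), spec = runif(50),
               prev = runif(50, 1e-4, 1 - 1e-4),
               pop = sample(1:2000, 50, replace = TRUE))
  )
  for (i in seq_len(nrow(cases))) {
    t <- suppressWarnings(
      nf_from_summary(perf_summary(cases$sens[i], cases$spec[i],
                                   cases$prev[i]), cases$pop[i]))
    expect_gte(min(t$tp, t$fp, t$fn, t$tn), 0)
    expect_equal(t$population, cases$pop[i])
  }
})

test_that("double half-rounding across the margin is clamped with a flag", {
  # events = round(36.5) = 37 leaves 963 non-events, but a perfect
  # specificity rounds to round(963.5) = 964: fp would be -1 without the
  # clamp
  expect_warning(t <- nf_from_summary(perf_summary(1, 1, 0.0365), 1000),
                 "clamped")
  expect_true("clamped" %in% t$flags)
  expect_equal(t$fp, 0)
  expect_equal(t$population, 1000)
  expect_equal(t$tp + t$fn, 37)
})
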