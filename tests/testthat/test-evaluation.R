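ref_from <- function(classes) {
  data.frame(image_id = sprintf("i%05d", seq_along(classes)),
             label = as.integer(classes), stringsAsFactors = FALSE)
}
calls_from <- function(ref, referrable) {
  data.frame(image_id = ref$image_id, referrable = referrable,
             stringsAsFactors = FALSE)
}

test_that("referral mapping sends classes 2-4 to referrable, the rest not", {
  expect_identical(to_referrable(0:6),
                   c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(to_referrable(9), "invalid")
})

test_that("confusion counts honour the cohort composition", {
  comp <- testset_composition()
  ref <- ref_from(rep(0:6, times = as.integer(comp)))
  perfect <- calls_from(ref, to_referrable(ref$label))
  cc <- confusion_counts(perfect, ref)
  expect_equal(cc, list(tp = 2237L, fp = 0L, tn = 4090L, fn = 0L))
  never <- calls_from(ref, FALSE)
  cn <- confusion_counts(never, ref)
  expect_equal(cn$tp, 0L)
  expect_equal(cn$tn, 4090L)
  expect_equal(cn$fn, 2237L)
  single <- ref_from(3L)
  expect_equal(confusion_counts(calls_from(single, TRUE), single),
               list(tp = 1L, fp = 0L, tn = 0L, fn = 0L))
  expect_error(confusion_counts(perfect[-1, ], ref), "incomplete AUT output")
})

test_that("overall metrics are the defining ratios", {
  m <- overall_metrics(list(tp = 1927, fn = 310, tn = 3618, fp = 472))
  expect_equal(round(m$accuracy, 6), 0.876403)
  expect_equal(m$sensitivity, 1927 / 2237)
  expect_equal(m$specificity, 3618 / 4090)
  expect_equal(overall_metrics(list(tp = 1, fp = 0, tn = 1, fn = 0)),
               list(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_equal(overall_metrics(list(tp = 0, fp = 1, tn = 0, fn = 1)),
               list(sensitivity = 0, specificity = 0, accuracy = 0))
  expect_error(overall_metrics(list(tp = 0, fp = 1, tn = 1, fn = 0)),
               "sensitivity")
})

test_that("per-class capability decomposes correct decisions by class", {
  ref <- ref_from(rep(0:6, each = 10))
  perfect <- calls_from(ref, to_referrable(ref$label))
  expect_true(all(per_class_capability(perfect, ref) == 1))
  flawed <- perfect
  flawed$referrable[ref$label == 5][1] <- TRUE  # one class-5 false positive
  cap <- per_class_capability(flawed, ref)
  expect_equal(unname(cap[["5"]]), 0.9)
  absent <- ref_from(rep(c(0L, 2L), each = 5))
  cap2 <- per_class_capability(calls_from(absent, to_referrable(absent$label)),
                               absent)
  expect_true(is.na(cap2[["6"]]))
})

test_that("reconstruction reproduces the benchmark overall metrics to 6 decimals", {
  comp <- testset_composition()
  bm <- aut_overall_benchmarks()
  profs <- aut_capability_profiles()
  for (i in seq_len(nrow(bm))) {
    rec <- reconstruct_overall(profs[[bm$aut_id[i]]]$capability, comp)
    expect_equal(round(rec$sensitivity, 6), bm$sensitivity[i])
    expect_equal(round(rec$specificity, 6), bm$specificity[i])
    expect_equal(round(rec$accuracy, 6), bm$accuracy[i])
  }
  ones <- stats::setNames(rep(1, 7), 0:6)
  expect_equal(reconstruct_overall(ones, comp),
               list(sensitivity = 1, specificity = 1, accuracy = 1))
  missing_cap <- stats::setNames(c(NA, rep(1, 6)), 0:6)
  expect_error(reconstruct_overall(missing_cap, comp), "missing capability")
})

test_that("overall metrics equal the per-class reconstruction to 1e-12", {
  comp <- cohort_composition(c(87, 26, 112, 58, 54, 260, 36))
  cohort <- toy_cohort(rep(0:6, times = as.integer(comp)))
  ref <- data.frame(image_id = cohort$image_id, label = cohort$true_class,
                    stringsAsFactors = FALSE)
  for (s in 1:5) {
    calls <- simulate_aut(aut_capability_profiles()$AUT3, cohort, seed = s)
    m <- overall_metrics(confusion_counts(calls, ref))
    r <- reconstruct_overall(per_class_capability(calls, ref), comp)
    expect_equal(m$sensitivity, r$sensitivity, tolerance = 1e-12)
    expect_equal(m$specificity, r$specificity, tolerance = 1e-12)
    expect_equal(m$accuracy, r$accuracy, tolerance = 1e-12)
  }
})

test_that("correcting one wrong call never degrades any overall metric", {
  set.seed(71)
  ref <- ref_from(sample(0:6, 300, replace = TRUE))
  calls <- calls_from(ref, ifelse(stats::runif(300) < 0.8,
                                  to_referrable(ref$label),
                                  !to_referrable(ref$label)))
  before <- overall_metrics(confusion_counts(calls, ref))
  wrong <- which(calls$referrable != to_referrable(ref$label))
  for (w in wrong[1:10]) {
    fixed <- calls
    fixed$referrable[w] <- !fixed$referrable[w]
    after <- overall_metrics(confusion_counts(fixed, ref))
    expect_gte(after$sensitivity, before$sensitivity)
    expect_gte(after$specificity, before$specificity)
    expect_gte(after$accuracy, before$accuracy)
  }
})

test_that("evaluation against raw labels uses the same code path", {
  cohort <- generate_cohort(cohort_composition(c(30, 10, 40, 20, 20, 90, 15)),
                            seed = 81)
  cohort <- simulate_raw_labels(cohort, seed = 81)
  raw_ref <- data.frame(image_id = cohort$image_id, label = cohort$raw_label,
                        stringsAsFactors = FALSE)
  calls <- simulate_aut(aut_capability_profiles()$AUT1, cohort, seed = 81)
  rep_raw <- metrics_report("AUT1", calls, raw_ref)
  expect_s3_class(rep_raw, "metrics_report")
  expect_equal(rep_raw$tp + rep_raw$fp + rep_raw$tn + rep_raw$fn, nrow(cohort))
})

test_that("compare_auts flags the argmax per metric, homogeneity and ties", {
  comp <- testset_composition()
  scaled <- cohort_composition(as.integer(comp) * 5L)
  cohort <- toy_cohort(rep(0:6, times = as.integer(scaled)))
  ref <- data.frame(image_id = cohort$image_id, label = cohort$true_class,
                    stringsAsFactors = FALSE)
  reports <- lapply(aut_capability_profiles(), function(p)
    metrics_report(p$aut_id, simulate_aut(p, cohort, seed = 91), ref))
  cmp <- compare_auts(reports)
  expect_equal(cmp$best[["accuracy"]], "AUT1")
  expect_equal(cmp$best[["sensitivity"]], "AUT1")
  expect_false(any(cmp$homogeneous))  # no AUT is homogeneous across classes

  one <- compare_auts(reports[1])
  expect_equal(nrow(one$overall), 1L)

  twin <- compare_auts(list(reports[[1]], reports[[1]]))
  expect_true(all(grepl(",", twin$best)))

  other_ref <- ref; other_ref$label <- rev(other_ref$label)
  r_alt <- metrics_report("X", simulate_aut(aut_capability_profiles()$AUT2,
                                            cohort, seed = 91), other_ref)
  expect_error(compare_auts(list(reports[[1]], r_alt)), "incomparable")
})
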