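test_that("fleiss_kappa matches the direct-formula oracle", {
  perfect <- rbind(c(3, 0), c(0, 3), c(3, 0), c(0, 3))
  expect_equal(fleiss_kappa(perfect), 1)
  tab <- rbind(c(3, 0), c(0, 3), c(2, 1), c(1, 2))
  expect_equal(fleiss_kappa(tab), fleiss_oracle(tab), tolerance = 1e-12)
  # enumerated small tables: all 3-rater 2-category tables on 4 items
  for (a in 0:3) for (b in 0:3) for (c0 in 0:3) for (d in 0:3) {
    t4 <- rbind(c(a, 3 - a), c(b, 3 - b), c(c0, 3 - c0), c(d, 3 - d))
    expect_equal(fleiss_kappa(t4), fleiss_oracle(t4), tolerance = 1e-12)
  }
  expect_error(fleiss_kappa(rbind(c(1, 0), c(0, 1))), "2 raters")
  expect_error(fleiss_kappa(matrix(c(3, 0), nrow = 1)), "2 items")
})

test_that("fleiss_kappa is near zero for independent uniform raters", {
  set.seed(41)
  reps <- 20L
  kappas <- vapply(seq_len(reps), function(r) {
    labels <- matrix(sample(0:6, 3 * 2000, replace = TRUE), ncol = 3)
    counts <- t(apply(labels, 1, function(v) tabulate(v + 1L, nbins = 7L)))
    fleiss_kappa(counts)
  }, numeric(1))
  se <- stats::sd(kappas) / sqrt(reps)
  expect_lt(abs(mean(kappas)), 3 * se)
})

test_that("fleiss_kappa is invariant to item order and category relabeling", {
  set.seed(42)
  labels <- matrix(sample(0:6, 3 * 200, replace = TRUE), ncol = 3)
  counts <- t(apply(labels, 1, function(v) tabulate(v + 1L, nbins = 7L)))
  k0 <- fleiss_kappa(counts)
  expect_equal(fleiss_kappa(counts[sample(nrow(counts)), ]), k0,
               tolerance = 1e-12)
  expect_equal(fleiss_kappa(counts[, sample(7)]), k0, tolerance = 1e-12)
})

test_that("cohen_kappa matches the oracle, including exhaustive small cases", {
  expect_equal(cohen_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  expect_equal(cohen_kappa(c(0, 1, 0, 1), c(2, 2, 2, 2)), 0)
  ab <- c(rep(0, 45), rep(0, 15), rep(1, 25), rep(1, 15))
  bb <- c(rep(0, 45), rep(1, 15), rep(0, 25), rep(1, 15))
  expect_equal(cohen_kappa(ab, bb), cohen_oracle(ab, bb), tolerance = 1e-12)
  expect_equal(cohen_kappa(ab, bb), cohen_kappa(bb, ab), tolerance = 1e-12)
  # exhaustive: every pair of binary label vectors of length 2..6
  for (n in 2:6) {
    grid <- as.matrix(expand.grid(rep(list(0:1), n)))
    worst <- 0
    for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
      a <- grid[i, ]; b <- grid[j, ]
      worst <- max(worst, abs(suppressWarnings(cohen_kappa(a, b)) -
                                suppressWarnings(cohen_oracle(a, b))))
    }
    expect_lt(worst, 1e-12)
  }
  expect_error(cohen_kappa(1:3, 1:4), "equal")
})

test_that("annotator accuracy is counted against the reference standard", {
  ref <- data.frame(image_id = sprintf("i%02d", 1:10),
                    label = rep(2L, 10), stringsAsFactors = FALSE)
  ev <- data.frame(image_id = rep(ref$image_id, 2),
                   annotator_id = rep(c("a", "b"), each = 10),
                   round = 1L,
                   label = c(rep(2L, 10), c(rep(2L, 7), rep(3L, 3))),
                   order_index = rep(1:10, 2), stringsAsFactors = FALSE)
  acc <- annotator_accuracy(ev, ref)
  expect_equal(acc$per_annotator$accuracy[acc$per_annotator$annotator_id == "a"], 1)
  expect_equal(acc$per_annotator$accuracy[acc$per_annotator$annotator_id == "b"], 0.7)
  expect_equal(acc$min, 0.7)
  expect_error(annotator_accuracy(ev, ref[1:5, ]), "reference")
})

test_that("panel accuracy against adjudicated labels recovers the diagonal", {
  cohort <- generate_cohort(cohort_composition(c(60, 20, 80, 40, 40, 180, 25)),
                            seed = 51)
  juniors <- lapply(1:3, function(i) make_annotator(paste0("jr", i), 0.83))
  seniors <- lapply(1:3, function(i) make_annotator(paste0("sr", i), 1))
  b <- assign_batches(cohort, juniors, 1, seed = 51)
  r1 <- round_one(cohort, b, juniors, seed = 51)
  preq <- r1$partition$image_id[r1$partition$pool == "prequalified"]
  sampled <- sample_prequalified(preq, 0.10, seed = 51)
  arb <- r1$partition$image_id[r1$partition$pool == "arbitration"]
  partition <- r1$partition
  partition$pool[partition$image_id %in% sampled] <- "prequalified_sampled"
  r2 <- round_two(c(sampled, arb), seniors, "sr3", cohort, seed = 51)
  fin <- resolve_final(partition, r1$events, r2$labels)
  acc <- annotator_accuracy(r1$events, fin)
  n_reads <- nrow(cohort)
  for (a in acc$per_annotator$accuracy)
    expect_true(within_3se(a, 0.83, n_reads) ||
                  a > 0.83)  # unanimous-but-wrong images bias accuracy upward
})

test_that("intra-rater repeatability matches analytic and ANOVA oracles", {
  x <- rep(0:6, 4)
  expect_equal(intra_rater(x, x), 1)
  expect_equal(intra_rater(x, x, method = "icc"), 1)

  set.seed(43)
  n <- 10000L
  a <- sample(0:6, n, replace = TRUE)
  b <- sample(0:6, n, replace = TRUE)
  expect_true(within_3se(intra_rater(a, b), 1 / 7, n))

  first <- c(0, 2, 2, 5, 6, 3)
  second <- c(1, 2, 3, 5, 6, 4)
  expect_equal(intra_rater(first, second, method = "icc"),
               icc_oracle(first, second), tolerance = 1e-10)
  expect_error(intra_rater(1, 1), "2 items")
})

test_that("degenerate single-category input returns the conventional kappa", {
  expect_equal(suppressWarnings(cohen_kappa(rep(1, 5), rep(1, 5))), 1)
  one_cat <- rbind(c(3, 0), c(3, 0))
  expect_equal(fleiss_kappa(one_cat), 1)
})
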