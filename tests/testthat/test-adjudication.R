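make_panel <- function(n, accuracy, prefix = "jr") {
  lapply(seq_len(n), function(i)
    make_annotator(sprintf("%s%02d", prefix, i), accuracy))
}

test_that("batch assignment partitions the cohort and respects workload bounds", {
  cohort <- generate_cohort(testset_composition(), seed = 21)
  juniors <- make_panel(15, 0.83)
  b <- assign_batches(cohort, juniors, n_groups = 5,
                      workload_bounds = c(1000, 1500), seed = 21)
  expect_setequal(b$assignment$image_id, cohort$image_id)
  loads <- table(b$assignment$group)
  expect_true(all(loads >= 1000 & loads <= 1500))
  expect_true(all(lengths(b$groups) == 3L))
  expect_identical(sort(unlist(b$groups, use.names = FALSE)),
                   sort(vapply(juniors, `[[`, character(1), "annotator_id")))

  one <- assign_batches(toy_cohort(rep(0L, 10)), make_panel(3, 1), 1, seed = 1)
  expect_true(all(one$assignment$group == "group1"))
  expect_equal(nrow(one$assignment), 10L)

  expect_identical(assign_batches(cohort, juniors, 5, seed = 3)$assignment,
                   assign_batches(cohort, juniors, 5, seed = 3)$assignment)
  expect_error(assign_batches(cohort, juniors, 5,
                              workload_bounds = c(1, 100), seed = 1),
               "workload")
  expect_error(assign_batches(cohort, make_panel(4, 1), 5, seed = 1),
               "annotators")
})

test_that("round one partitions images by unanimity", {
  cohort <- toy_cohort(rep(0:6, 10))
  juniors <- make_panel(3, 1)
  b <- assign_batches(cohort, juniors, 1, seed = 2)
  r1 <- round_one(cohort, b, juniors, seed = 2)
  expect_true(all(r1$partition$pool == "prequalified"))
  expect_equal(nrow(r1$events), 3L * nrow(cohort))
  # every image's final unanimous label equals the truth for perfect readers
  votes <- split(r1$events$label, r1$events$image_id)
  expect_true(all(vapply(votes, function(v) length(unique(v)) == 1L,
                         logical(1))))
})

test_that("unanimity probability matches the analytic sum of cubed row entries", {
  n <- 100000L
  cohort <- toy_cohort(rep(2L, n))
  juniors <- make_panel(3, 0.83)
  b <- assign_batches(cohort, juniors, 1, seed = 8)
  r1 <- round_one(cohort, b, juniors, seed = 8)
  p_unanimous <- mean(r1$partition$pool == "prequalified")
  row2 <- adjacent_confusion(0.83, 0.7)["2", ]
  expect_true(within_3se(p_unanimous, sum(row2^3), n))
})

test_that("prequalified sampling uses the floor rule deterministically", {
  pool <- sprintf("img%04d", seq_len(3694))
  s <- sample_prequalified(pool, 0.10, seed = 5)
  expect_length(s, 369L)
  expect_true(all(s %in% pool) && !anyDuplicated(s))
  expect_length(sample_prequalified(pool[1:9], 0.10, seed = 5), 0L)
  expect_identical(sample_prequalified(pool, 0.10, seed = 5), s)
  expect_error(sample_prequalified(pool, 1.2, seed = 1), "sample_rate")
})

test_that("senior consensus is modal with leader tie-break", {
  expect_equal(senior_consensus(c(4L, 4L, 1L), 3L), 4L)
  expect_equal(senior_consensus(c(0L, 5L, 6L), 2L), 5L)
  # exhaustive check of every 3-vote pattern against the oracle
  all_match <- TRUE
  for (leader in 1:3) {
    for (v1 in 0:6) for (v2 in 0:6) for (v3 in 0:6) {
      votes <- c(v1, v2, v3)
      all_match <- all_match &&
        identical(senior_consensus(votes, leader),
                  consensus_oracle(votes, leader))
    }
  }
  expect_true(all_match)
})

test_that("round two resolves through senior profiles", {
  cohort <- toy_cohort(rep(0:6, 5))
  seniors <- make_panel(3, 1, "sr")
  r2 <- round_two(cohort$image_id, seniors, "sr03", cohort, seed = 4)
  expect_identical(r2$labels$label, cohort$true_class)
  expect_error(round_two(cohort$image_id, seniors, "nobody", cohort, seed = 4),
               "leader")
})

test_that("provenance classification follows the vote-count rule", {
  expect_equal(classify_provenance(c(2L, 2L, 2L), 2L), "unanimous")
  expect_equal(classify_provenance(c(2L, 2L, 3L), 3L), "minority")
  expect_equal(classify_provenance(c(2L, 2L, 3L), 2L), "majority")
  expect_equal(classify_provenance(c(1L, 2L, 3L), 5L), "arbitration_only")
  # exhaustive consistency: re-derivation matches for all 3-vote patterns
  all_match <- TRUE
  for (v1 in 0:6) for (v2 in 0:6) for (v3 in 0:6) for (f in 0:6) {
    k <- sum(c(v1, v2, v3) == f)
    expected <- c("arbitration_only", "minority", "majority", "unanimous")[k + 1L]
    all_match <- all_match &&
      identical(classify_provenance(c(v1, v2, v3), f), expected)
  }
  expect_true(all_match)
})

test_that("final resolution honours pools and records provenance", {
  partition <- data.frame(
    image_id = c("a", "b", "c"),
    pool = c("prequalified", "prequalified_sampled", "arbitration"),
    stringsAsFactors = FALSE)
  r1 <- data.frame(
    image_id = rep(c("a", "b", "c"), each = 3),
    annotator_id = rep(c("j1", "j2", "j3"), 3),
    round = 1L,
    label = c(4L, 4L, 4L,  2L, 2L, 2L,  1L, 2L, 2L),
    order_index = rep(1:3, 3), stringsAsFactors = FALSE)
  r2 <- data.frame(image_id = c("b", "c"), label = c(2L, 1L),
                   stringsAsFactors = FALSE)
  fin <- resolve_final(partition, r1, r2)
  expect_identical(fin$label, c(4L, 2L, 1L))
  expect_identical(fin$provenance, c("unanimous", "unanimous", "minority"))
  expect_error(resolve_final(partition, r1, r2[1, , drop = FALSE]),
               "unresolved")
})

test_that("inspection escalates when sampled disagreement exceeds the threshold", {
  mk <- function(n, n_bad) {
    ids <- sprintf("s%03d", seq_len(n))
    list(r1 = data.frame(image_id = ids, label = rep(2L, n),
                         stringsAsFactors = FALSE),
         r2 = data.frame(image_id = ids,
                         label = c(rep(3L, n_bad), rep(2L, n - n_bad)),
                         stringsAsFactors = FALSE))
  }
  pol <- workflow_policy(escalation_threshold = 0.05,
                         escalation_action = "double_sample")
  z <- mk(100, 0)
  expect_equal(inspect_and_escalate(z$r1, z$r2, pol)$decision, "none")
  e <- mk(100, 8)
  expect_equal(inspect_and_escalate(e$r1, e$r2, pol)$decision, "double_sample")
  hi <- mk(369, 19)   # rate 0.0515 crosses the 0.05 boundary
  expect_equal(inspect_and_escalate(hi$r1, hi$r2, pol)$decision, "double_sample")
  lo <- mk(369, 18)   # rate 0.0488 does not
  expect_equal(inspect_and_escalate(lo$r1, lo$r2, pol)$decision, "none")
  empty <- data.frame(image_id = character(0), label = integer(0))
  expect_warning(res <- inspect_and_escalate(empty, empty, pol), "empty")
  expect_equal(res$decision, "none")
})

test_that("pools partition the cohort and provenance counts are conserved", {
  cohort <- generate_cohort(cohort_composition(c(80, 30, 90, 50, 50, 180, 40)),
                            seed = 31)
  juniors <- make_panel(3, 0.83)
  seniors <- make_panel(3, 0.93, "sr")
  b <- assign_batches(cohort, juniors, 1, seed = 31)
  r1 <- round_one(cohort, b, juniors, seed = 31)
  preq <- r1$partition$image_id[r1$partition$pool == "prequalified"]
  arb <- r1$partition$image_id[r1$partition$pool == "arbitration"]
  expect_setequal(c(preq, arb), cohort$image_id)
  expect_length(intersect(preq, arb), 0L)
  sampled <- sample_prequalified(preq, 0.10, seed = 31)
  partition <- r1$partition
  partition$pool[partition$image_id %in% sampled] <- "prequalified_sampled"
  expect_setequal(partition$pool,
                  c("prequalified", "prequalified_sampled", "arbitration"))
  r2 <- round_two(c(sampled, arb), seniors, "sr03", cohort, seed = 31)
  fin <- resolve_final(partition, r1$events, r2$labels)
  expect_equal(nrow(fin), nrow(cohort))
  ps <- provenance_summary(fin)
  expect_equal(sum(ps$n), nrow(cohort))
  # oracle re-derivation of provenance from stored votes and finals
  votes <- split(r1$events$label, r1$events$image_id)
  for (i in seq_len(nrow(fin))) {
    id <- fin$image_id[i]
    if (partition$pool[partition$image_id == id] == "prequalified") next
    expect_identical(fin$provenance[i],
                     classify_provenance(votes[[id]], fin$label[i]))
  }
})

test_that("round-1 reads are blinded: removing one reader leaves others unchanged", {
  cohort <- toy_cohort(rep(0:6, 20))
  panel_a <- make_panel(3, 0.8)
  panel_b <- c(panel_a[1:2], list(make_annotator("jr99", 0.6)))
  b_a <- list(assignment = data.frame(image_id = cohort$image_id,
                                      group = "group1",
                                      stringsAsFactors = FALSE),
              groups = list(group1 = c("jr01", "jr02", "jr03")))
  b_b <- b_a; b_b$groups$group1 <- c("jr01", "jr02", "jr99")
  r_a <- round_one(cohort, b_a, panel_a, seed = 77)
  r_b <- round_one(cohort, b_b, panel_b, seed = 77)
  for (aid in c("jr01", "jr02")) {
    expect_identical(r_a$events$label[r_a$events$annotator_id == aid],
                     r_b$events$label[r_b$events$annotator_id == aid])
  }
})
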