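#!/usr/bin/env Rscript
# Stage 1: annotator qualification and cohort simulation.
#
# Recruits a junior annotator panel through the qualification exam and
# simulates the label-level test-set cohort with raw hospital labels.
# Writes results/cohort.csv, results/exam_results.csv, results/juniors.csv.

suppressPackageStartupMessages(library(drtestset))

seed <- 1L
dir.create("results", showWarnings = FALSE)

# --- qualification exam: 100 items, 18/45/32/6% renormalized, pass >= 80%
spec <- exam_spec()
pool <- generate_cohort(cohort_composition(rep(150, 7)),
                        seed = substream_seed(seed, "exam_pool"))
exam <- build_exam(spec, pool, seed = seed)

n_candidates <- 47L
set.seed(substream_seed(seed, "candidates"))
accs <- runif(n_candidates, 0.75, 0.90)
cand <- data.frame(candidate_id = sprintf("cand%02d", 1:n_candidates),
                   true_accuracy = accs)
cand$exam_accuracy <- vapply(seq_len(n_candidates), function(j) {
  prof <- make_annotator(cand$candidate_id[j], accs[j],
                         seed = substream_seed(seed, paste0("exam/", cand$candidate_id[j])))
  score_exam(simulate_reads(prof, exam$items), exam$key)
}, numeric(1))
cand$admitted <- vapply(cand$exam_accuracy, admit, logical(1), spec = spec)

juniors <- head(cand[cand$admitted, ], 15)
stopifnot(nrow(juniors) == 15)
cat(sprintf("qualification: %d of %d candidates admitted (exam accuracy %.2f-%.2f); panel of 15 selected\n",
            sum(cand$admitted), n_candidates,
            min(cand$exam_accuracy[cand$admitted]),
            max(cand$exam_accuracy[cand$admitted])))

# --- cohort: reference composition, raw labels at 61.64% diagonal
cohort <- generate_cohort(testset_composition(), seed = seed)
cohort <- simulate_raw_labels(cohort, seed = seed)
cat(sprintf("cohort: %d images; raw-label accuracy %.4f\n", nrow(cohort),
            mean(cohort$raw_label == cohort$true_class)))
print(composition_summary(testset_composition()))

write_labels(cohort, "results/cohort.csv")
write.csv(cand, "results/exam_results.csv", row.names = FALSE)
write.csv(juniors[c("candidate_id", "true_accuracy")], "results/juniors.csv",
          row.names = FALSE)
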