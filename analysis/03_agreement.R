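#!/usr/bin/env Rscript
# Stage 3: rater-agreement statistics.
#
# Computes Fleiss kappa over the round-1 panel, per-annotator accuracy
# against the adjudicated reference, the raw-label accuracy and Cohen
# kappa, and intra-rater repeatability from seeded repeat readings.
# Writes results/agreement.csv.

suppressPackageStartupMessages(library(drtestset))

seed <- 1L
cohort <- read_labels("results/cohort.csv")
events <- read_labels("results/annotation_events.csv")
fin <- read_labels("results/final_labels.csv")
finals <- data.frame(image_id = fin$image_id, label = fin$final_label)
r1 <- events[events$round == 1L, ]

# repeat readings: each junior re-reads 200 of their images
panel <- read.csv("results/juniors.csv")
repeats <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
  aid <- panel$candidate_id[i]
  mine <- r1[r1$annotator_id == aid, ]
  set.seed(substream_seed(seed, paste0("repeat_pick/", aid)))
  idx <- sample.int(nrow(mine), min(200L, nrow(mine)))
  prof <- make_annotator(aid, panel$true_accuracy[i],
                         seed = substream_seed(seed, paste0("repeat/", aid)))
  recs <- cohort[match(mine$image_id[idx], cohort$image_id), ]
  data.frame(first = mine$label[idx], second = simulate_reads(prof, recs))
}))

report <- agreement_report(r1, finals, cohort, repeats)
print(report)

acc <- report$annotator_accuracy
write.csv(data.frame(
  metric = c("fleiss_kappa_round1", "annotator_accuracy_min",
             "annotator_accuracy_mean", "annotator_accuracy_max",
             "raw_label_accuracy", "raw_cohen_kappa",
             "intra_rater_percent", "intra_rater_icc"),
  value = round(c(report$fleiss_kappa, acc$min, acc$mean, acc$max,
                  report$raw_label_accuracy, report$raw_cohen_kappa,
                  report$intra_rater_percent, report$intra_rater_icc), 6)),
  "results/agreement.csv", row.names = FALSE)
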