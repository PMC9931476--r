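#!/usr/bin/env Rscript
# Stage 2: two-round reference-standard adjudication.
#
# Reads the simulated cohort and admitted panel from stage 1, runs blinded
# triple annotation in 5 groups, 10% sampled inspection, senior arbitration
# and provenance classification. Writes results/annotation_events.csv,
# results/final_labels.csv, results/provenance.csv.

suppressPackageStartupMessages(library(drtestset))

seed <- 1L
cohort <- read_labels("results/cohort.csv")
panel <- read.csv("results/juniors.csv")
juniors <- lapply(seq_len(nrow(panel)), function(i)
  make_annotator(panel$candidate_id[i], panel$true_accuracy[i]))
seniors <- lapply(1:3, function(j)
  make_annotator(sprintf("senior%d", j), c(0.92, 0.92, 0.95)[j],
                 seniority = if (j == 3) "leader" else "senior"))
policy <- workflow_policy()

batches <- assign_batches(cohort, juniors, n_groups = 5,
                          workload_bounds = c(1000, 1500), seed = seed)
r1 <- round_one(cohort, batches, juniors, seed = seed)
preq <- r1$partition$image_id[r1$partition$pool == "prequalified"]
arb <- r1$partition$image_id[r1$partition$pool == "arbitration"]
sampled <- sample_prequalified(preq, policy$sample_rate, seed = seed)
cat(sprintf("round 1: %d prequalified, %d arbitration; %d sampled for inspection\n",
            length(preq), length(arb), length(sampled)))

r2 <- round_two(c(sampled, arb), seniors, "senior3", cohort, seed = seed)
unanimous <- vapply(split(r1$events$label, r1$events$image_id), `[`,
                    integer(1), 1L)
insp <- inspect_and_escalate(
  data.frame(image_id = sampled, label = unname(unanimous[sampled])),
  r2$labels, policy)
cat(sprintf("inspection: disagreement rate %.4f -> %s\n",
            insp$disagreement_rate, insp$decision))

partition <- r1$partition
partition$pool[partition$image_id %in% sampled] <- "prequalified_sampled"
finals <- resolve_final(partition, r1$events, r2$labels, policy)
prov <- provenance_summary(finals, r1$events)
print(prov)

write_labels(rbind(r1$events, r2$events), "results/annotation_events.csv")
write_labels(data.frame(image_id = finals$image_id,
                        final_label = finals$label,
                        provenance = finals$provenance),
             "results/final_labels.csv")
write.csv(prov, "results/provenance.csv", row.names = FALSE)
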