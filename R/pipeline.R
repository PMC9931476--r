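# End-to-end orchestration: qualification -> cohort -> adjudication ->
# agreement -> evaluation, with every stochastic stage drawing from a
# substream of one root seed and all artifacts written as delimited text.

#' Build a run configuration
#'
#' Defaults reproduce the full-scale study conditions: the 6327-image
#' reference composition, 47 exam candidates, 15 admitted juniors in 5
#' groups of 3 with workloads in 1000-1500 images, a 3-member senior panel
#' with leader, 10% sampled inspection, raw labels at 61.64% accuracy, and
#' the five benchmark AUT capability profiles.
#'
#' @param seed Root integer seed (mandatory); every stochastic stage
#'   derives its stream from it via [substream_seed()].
#' @param composition Per-class cohort counts (classes 0-6).
#' @param n_sites,n_cameras Numbers of uniform site/camera strata.
#' @param exam_n_items,exam_composition,pass_threshold,strict_admission
#'   Qualification-exam settings, see [exam_spec()].
#' @param exam_pool_per_class Images per class in the exam item pool.
#' @param n_candidates Number of exam candidates.
#' @param candidate_accuracy Range `c(lo, hi)` of candidate true accuracies,
#'   drawn uniformly; equal bounds give identical candidates.
#' @param adjacency_weight Adjacency weight of every reader's error model.
#' @param group_size,n_groups,workload_bounds Junior panel structure.
#' @param senior_accuracies Accuracies of the senior panel, leader last.
#' @param sample_rate,escalation_threshold,escalation_action,max_escalations
#'   Inspection policy, see [workflow_policy()].
#' @param raw_diagonal Diagonal of the raw hospital-label confusion.
#' @param auts Named list of 7-element AUT capability vectors; defaults to
#'   [aut_capability_profiles()].
#' @param intra_rater_n Repeat readings per junior for intra-rater
#'   repeatability (0 disables).
#' @param output_dir Directory for run artifacts (`NULL` keeps results in
#'   memory only).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed,
                       composition = c(873, 262, 1118, 579, 540, 2600, 355),
                       n_sites = 11, n_cameras = 13,
                       exam_n_items = 100,
                       exam_composition = c(18, 45, 32, 6),
                       pass_threshold = 0.80,
                       strict_admission = FALSE,
                       exam_pool_per_class = 150,
                       n_candidates = 47,
                       candidate_accuracy = c(0.75, 0.90),
                       adjacency_weight = 0.7,
                       group_size = 3,
                       n_groups = 5,
                       workload_bounds = c(1000, 1500),
                       senior_accuracies = c(0.92, 0.92, 0.95),
                       sample_rate = 0.10,
                       escalation_threshold = 0.05,
                       escalation_action = "double_sample",
                       max_escalations = 2,
                       raw_diagonal = 0.6164,
                       auts = NULL,
                       intra_rater_n = 200,
                       output_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("a root seed is mandatory",
                                           call. = FALSE)
  if (is.null(auts))
    auts <- lapply(aut_capability_profiles(), function(p)
      as.numeric(p$capability))
  auts <- lapply(auts, as.numeric)
  structure(list(
    seed = as.integer(seed),
    composition = as.integer(composition),
    n_sites = as.integer(n_sites), n_cameras = as.integer(n_cameras),
    exam_n_items = as.integer(exam_n_items),
    exam_composition = as.numeric(exam_composition),
    pass_threshold = as.numeric(pass_threshold),
    strict_admission = isTRUE(strict_admission),
    exam_pool_per_class = as.integer(exam_pool_per_class),
    n_candidates = as.integer(n_candidates),
    candidate_accuracy = as.numeric(candidate_accuracy),
    adjacency_weight = as.numeric(adjacency_weight),
    group_size = as.integer(group_size),
    n_groups = as.integer(n_groups),
    workload_bounds = as.numeric(workload_bounds),
    senior_accuracies = as.numeric(senior_accuracies),
    sample_rate = as.numeric(sample_rate),
    escalation_threshold = as.numeric(escalation_threshold),
    escalation_action = as.character(escalation_action),
    max_escalations = as.integer(max_escalations),
    raw_diagonal = as.numeric(raw_diagonal),
    auts = auts,
    intra_rater_n = as.integer(intra_rater_n),
    output_dir = if (is.null(output_dir)) NULL else as.character(output_dir)
  ), class = "run_config")
}

#' Full-scale preset configuration
#' @inheritParams run_config
#' @return A [run_config()] at the full 6327-image study conditions.
#' @export
full_scale_config <- function(seed, output_dir = NULL) {
  run_config(seed = seed, output_dir = output_dir)
}

#' Minimal perfect-actor preset
#'
#' A 70-image cohort (10 per class) read by error-free annotators, seniors
#' and a single error-free AUT: final labels must equal truth, provenance
#' must be 100% unanimous and every metric must be 1.
#'
#' @inheritParams run_config
#' @return A [run_config()].
#' @export
minimal_config <- function(seed, output_dir = NULL) {
  run_config(
    seed = seed,
    composition = rep(10, 7),
    exam_pool_per_class = 60,
    n_candidates = 3,
    candidate_accuracy = c(1, 1),
    n_groups = 1,
    workload_bounds = c(0, Inf),
    senior_accuracies = c(1, 1, 1),
    raw_diagonal = 1,
    auts = list(PERFECT = rep(1, 7)),
    intra_rater_n = 10,
    output_dir = output_dir
  )
}

uniform_strata <- function(n_sites, n_cameras) {
  strata_spec(
    site_props = stats::setNames(rep(1 / n_sites, n_sites),
                                 sprintf("site%02d", seq_len(n_sites))),
    camera_props = stats::setNames(rep(1 / n_cameras, n_cameras),
                                   sprintf("camera%02d", seq_len(n_cameras))))
}

run_qualification <- function(cfg, strata) {
  espec <- exam_spec(cfg$exam_n_items, cfg$exam_composition,
                     cfg$pass_threshold, cfg$strict_admission)
  pool <- generate_cohort(
    cohort_composition(rep(cfg$exam_pool_per_class, 7)), strata,
    seed = substream_seed(cfg$seed, "exam_pool"))
  exam <- build_exam(espec, pool, seed = cfg$seed)
  lo <- cfg$candidate_accuracy[1]; hi <- cfg$candidate_accuracy[2]
  accs <- if (lo == hi) rep(lo, cfg$n_candidates) else
    with_stream(substream_seed(cfg$seed, "candidates"),
                stats::runif(cfg$n_candidates, lo, hi))
  cand_ids <- sprintf("cand%02d", seq_len(cfg$n_candidates))
  answers <- matrix(NA_integer_, nrow = espec$n_items,
                    ncol = cfg$n_candidates, dimnames = list(NULL, cand_ids))
  for (j in seq_len(cfg$n_candidates)) {
    prof <- make_annotator(cand_ids[j], accs[j], cfg$adjacency_weight,
                           "junior",
                           seed = substream_seed(cfg$seed,
                                                 paste0("exam/", cand_ids[j])))
    answers[, j] <- simulate_reads(prof, exam$items)
  }
  scores <- apply(answers, 2L, score_exam, key = exam$key)
  admitted <- vapply(scores, admit, logical(1), spec = espec)
  results <- data.frame(candidate_id = cand_ids, true_accuracy = accs,
                        exam_accuracy = scores, admitted = admitted,
                        stringsAsFactors = FALSE)
  need <- cfg$n_groups * cfg$group_size
  picked <- which(admitted)[seq_len(min(need, sum(admitted)))]
  if (length(picked) < need)
    stop(sprintf("qualification stage: only %d of %d candidates admitted, need %d",
                 sum(admitted), cfg$n_candidates, need), call. = FALSE)
  juniors <- lapply(picked, function(j)
    make_annotator(cand_ids[j], accs[j], cfg$adjacency_weight, "junior"))
  # agreement among the admitted panel on the shared exam items
  exam_counts <- t(apply(answers[, picked, drop = FALSE], 1L, function(v)
    tabulate(v + 1L, nbins = 7L)))
  colnames(exam_counts) <- 0:6
  list(exam_spec = espec, exam = exam, results = results, juniors = juniors,
       exam_fleiss = fleiss_kappa(exam_counts))
}

run_adjudication <- function(cfg, cohort, juniors, policy) {
  batches <- assign_batches(cohort, juniors, cfg$n_groups,
                            workload_bounds = cfg$workload_bounds,
                            seed = cfg$seed, policy = policy)
  r1 <- round_one(cohort, batches, juniors, seed = cfg$seed)
  seniors <- lapply(seq_along(cfg$senior_accuracies), function(j)
    make_annotator(sprintf("senior%d", j), cfg$senior_accuracies[j],
                   cfg$adjacency_weight,
                   if (j == length(cfg$senior_accuracies)) "leader" else "senior"))
  leader_id <- seniors[[length(seniors)]]$annotator_id
  preq <- r1$partition$image_id[r1$partition$pool == "prequalified"]
  arb <- r1$partition$image_id[r1$partition$pool == "arbitration"]
  sampled <- sample_prequalified(preq, policy$sample_rate, cfg$seed)
  r2 <- round_two(c(sampled, arb), seniors, leader_id, cohort, cfg$seed)
  r2_labels <- r2$labels
  r2_events <- r2$events
  unanimous_of <- stats::setNames(
    vapply(split(r1$events$label, r1$events$image_id), `[`, integer(1), 1L),
    names(split(r1$events$label, r1$events$image_id)))
  escalations <- character(0)
  cycle <- 0L
  repeat {
    s1 <- data.frame(image_id = sampled,
                     label = unname(unanimous_of[sampled]),
                     stringsAsFactors = FALSE)
    insp <- inspect_and_escalate(s1, r2_labels, policy)
    if (insp$decision == "none") break
    cycle <- cycle + 1L
    remaining <- setdiff(preq, sampled)
    action <- if (cycle > policy$max_escalations) "full_review" else insp$decision
    if (action == "full_review" || length(remaining) == 0L) {
      extra <- remaining
    } else {
      extra <- sample_prequalified(remaining, policy$sample_rate, cfg$seed,
                                   label = sprintf("sample/cycle%d", cycle))
      if (length(extra) == 0L) extra <- remaining
    }
    escalations <- c(escalations,
                     sprintf("cycle %d: rate %.4f -> %s (%d images)",
                             cycle, insp$disagreement_rate, action,
                             length(extra)))
    if (length(extra) == 0L) break
    r2x <- round_two(extra, seniors, leader_id, cohort, cfg$seed)
    r2_labels <- rbind(r2_labels, r2x$labels)
    r2_events <- rbind(r2_events, r2x$events)
    sampled <- c(sampled, extra)
    if (action == "full_review") break
  }
  partition <- r1$partition
  partition$pool[partition$image_id %in% sampled] <- "prequalified_sampled"
  finals <- resolve_final(partition, r1$events, r2_labels, policy)
  list(batches = batches, round1 = r1, seniors = seniors,
       sampled = sampled, arbitration = arb, round2_labels = r2_labels,
       round2_events = r2_events, partition = partition, finals = finals,
       inspection = insp, escalations = escalations)
}

run_repeat_readings <- function(cfg, cohort, adj, juniors) {
  if (cfg$intra_rater_n <= 0L) return(NULL)
  ev <- adj$round1$events
  out <- lapply(juniors, function(prof) {
    aid <- prof$annotator_id
    mine <- ev[ev$annotator_id == aid, , drop = FALSE]
    n <- min(cfg$intra_rater_n, nrow(mine))
    if (n < 2L) return(NULL)
    idx <- with_stream(substream_seed(cfg$seed, paste0("repeat_pick/", aid)),
                       sample.int(nrow(mine), n))
    recs <- cohort[match(mine$image_id[idx], cohort$image_id), , drop = FALSE]
    prof$seed <- substream_seed(cfg$seed, paste0("repeat/", aid))
    data.frame(annotator_id = aid, image_id = mine$image_id[idx],
               first = mine$label[idx], second = simulate_reads(prof, recs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Execute the full test-set construction and evaluation pipeline
#'
#' Runs qualification, cohort generation, two-round adjudication,
#' agreement statistics and AUT evaluation in order. All randomness stems
#' from the configured root seed, so rerunning an identical configuration
#' reproduces byte-identical artifacts.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with every stage's results: `qualification`,
#'   `cohort`, `adjudication`, `agreement`, `reports`, `comparison`,
#'   `provenance`, and `paths` of written artifacts when `output_dir` is
#'   set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  strata <- uniform_strata(cfg$n_sites, cfg$n_cameras)
  policy <- workflow_policy(group_size = cfg$group_size,
                            sample_rate = cfg$sample_rate,
                            senior_panel_size = length(cfg$senior_accuracies),
                            escalation_threshold = cfg$escalation_threshold,
                            escalation_action = cfg$escalation_action,
                            max_escalations = cfg$max_escalations)
  qual <- run_qualification(cfg, strata)
  cohort <- generate_cohort(cohort_composition(cfg$composition), strata,
                            seed = cfg$seed)
  cohort <- simulate_raw_labels(
    cohort, adjacent_confusion(cfg$raw_diagonal, cfg$adjacency_weight),
    seed = cfg$seed)
  adj <- run_adjudication(cfg, cohort, qual$juniors, policy)
  repeats <- run_repeat_readings(cfg, cohort, adj, qual$juniors)
  agree <- agreement_report(adj$round1$events, adj$finals, cohort, repeats)
  reports <- lapply(names(cfg$auts), function(id) {
    prof <- aut_profile(id, cfg$auts[[id]])
    calls <- simulate_aut(prof, cohort, seed = cfg$seed)
    metrics_report(id, calls, adj$finals)
  })
  names(reports) <- names(cfg$auts)
  comparison <- compare_auts(reports)
  prov <- provenance_summary(adj$finals, adj$round1$events)
  res <- list(config = cfg, qualification = qual, cohort = cohort,
              adjudication = adj, agreement = agree, repeats = repeats,
              reports = reports, comparison = comparison, provenance = prov)
  if (!is.null(cfg$output_dir)) res$paths <- write_artifacts(res, cfg)
  invisible(res)
}

write_artifacts <- function(res, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$output_dir, f)
  write_labels(res$cohort, p("cohort.csv"))
  events <- rbind(res$adjudication$round1$events,
                  res$adjudication$round2_events)
  write_labels(events, p("annotation_events.csv"))
  finals <- res$adjudication$finals
  write_labels(data.frame(image_id = finals$image_id,
                          final_label = finals$label,
                          provenance = finals$provenance,
                          stringsAsFactors = FALSE),
               p("final_labels.csv"))
  utils::write.csv(res$provenance, p("provenance.csv"), row.names = FALSE)
  ag <- res$agreement
  agree_tab <- data.frame(
    metric = c("fleiss_kappa_round1", "fleiss_kappa_exam",
               "annotator_accuracy_min", "annotator_accuracy_mean",
               "annotator_accuracy_max", "raw_label_accuracy",
               "raw_cohen_kappa", "intra_rater_percent", "intra_rater_icc"),
    value = round(c(ag$fleiss_kappa, res$qualification$exam_fleiss,
                    ag$annotator_accuracy$min, ag$annotator_accuracy$mean,
                    ag$annotator_accuracy$max,
                    ag$raw_label_accuracy %||% NA,
                    ag$raw_cohen_kappa %||% NA,
                    ag$intra_rater_percent %||% NA,
                    ag$intra_rater_icc %||% NA), 6),
    stringsAsFactors = FALSE)
  utils::write.csv(agree_tab, p("agreement.csv"), row.names = FALSE, na = "")
  ov <- res$comparison$overall
  ov[-1] <- lapply(ov[-1], round, 6)
  utils::write.csv(ov, p("aut_overall.csv"), row.names = FALSE)
  pc <- res$comparison$per_class
  pc$capability <- round(pc$capability, 6)
  utils::write.csv(pc, p("aut_per_class.csv"), row.names = FALSE)
  write_run_config(cfg, p("config.yaml"))
  writeLines(c(sprintf("seed: %d", cfg$seed),
               sprintf("config_hash: %d", config_hash(cfg)),
               sprintf("cohort_size: %d", nrow(res$cohort)),
               sprintf("escalations: %d",
                       length(res$adjudication$escalations))),
             p("manifest.txt"))
  writeLines(pipeline_summary_lines(res), p("summary.txt"))
  vapply(c("cohort.csv", "annotation_events.csv", "final_labels.csv",
           "provenance.csv", "agreement.csv", "aut_overall.csv",
           "aut_per_class.csv", "config.yaml", "manifest.txt",
           "summary.txt"), p, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_summary_lines <- function(res) {
  adj <- res$adjudication
  pools <- table(factor(adj$round1$partition$pool,
                        levels = c("prequalified", "arbitration")))
  c(sprintf("cohort: %d images, %d classes", nrow(res$cohort), 7L),
    sprintf("round 1: %d prequalified, %d arbitration, %d sampled for inspection",
            pools[["prequalified"]], pools[["arbitration"]],
            length(adj$sampled)),
    sprintf("inspection disagreement rate: %.4f",
            adj$inspection$disagreement_rate),
    "provenance (%):",
    sprintf("  %s: %.2f", res$provenance$provenance,
            res$provenance$percentage),
    sprintf("Fleiss kappa (round 1): %.4f", res$agreement$fleiss_kappa),
    sprintf("annotator accuracy: mean %.3f [%.3f, %.3f]",
            res$agreement$annotator_accuracy$mean,
            res$agreement$annotator_accuracy$min,
            res$agreement$annotator_accuracy$max),
    sprintf("raw labels: accuracy %.4f, Cohen kappa %.4f",
            res$agreement$raw_label_accuracy, res$agreement$raw_cohen_kappa),
    "AUT overall metrics:",
    sprintf("  %s: sens %.6f spec %.6f acc %.6f",
            res$comparison$overall$aut_id,
            res$comparison$overall$sensitivity,
            res$comparison$overall$specificity,
            res$comparison$overall$accuracy),
    sprintf("best: sensitivity %s, specificity %s, accuracy %s",
            res$comparison$best[["sensitivity"]],
            res$comparison$best[["specificity"]],
            res$comparison$best[["accuracy"]]))
}
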