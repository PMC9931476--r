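# Two-round reference-standard workflow: blinded triple annotation,
# prequalified/arbitration pool partition, 10% sampled inspection, senior
# review with leader tie-break, escalation, and provenance classification.

#' Configure the adjudication workflow
#'
#' @param group_size Readers per junior group (odd, >= 3; default 3).
#' @param sample_rate Fraction of the prequalified pool sampled for
#'   second-round inspection (default 0.10; sample size uses floor).
#' @param senior_panel_size Members of the senior panel, leader included
#'   (default 3).
#' @param escalation_threshold Disagreement rate on the inspected sample
#'   above which escalation triggers (default 0.05).
#' @param escalation_action `"double_sample"` (draw a second sample of the
#'   same size) or `"full_review"` (send the whole remaining prequalified
#'   pool to round two).
#' @param max_escalations Escalation cycles before forcing a full review
#'   (default 2).
#' @return An object of class `workflow_policy`.
#' @export
workflow_policy <- function(group_size = 3L, sample_rate = 0.10,
                            senior_panel_size = 3L,
                            escalation_threshold = 0.05,
                            escalation_action = c("double_sample", "full_review"),
                            max_escalations = 2L) {
  escalation_action <- match.arg(escalation_action)
  group_size <- as.integer(group_size)
  if (group_size < 3L || group_size %% 2L == 0L)
    stop("group_size must be odd and at least 3", call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0 || sample_rate >= 1)
    stop("sample_rate must lie in (0, 1)", call. = FALSE)
  structure(list(group_size = group_size, sample_rate = sample_rate,
                 senior_panel_size = as.integer(senior_panel_size),
                 escalation_threshold = escalation_threshold,
                 escalation_action = escalation_action,
                 max_escalations = as.integer(max_escalations)),
            class = "workflow_policy")
}

#' Assign images to annotator groups
#'
#' Non-excluded images are shuffled under the seed and split into
#' `n_groups` contiguous, near-equal blocks; junior annotators are shuffled
#' and partitioned into groups of `group_size`. Every image in a group is
#' read by all of that group's annotators, so each annotator's workload is
#' the block size.
#'
#' @param cohort Cohort data.frame.
#' @param junior_profiles List of junior [make_annotator()] profiles.
#' @param n_groups Number of groups.
#' @param workload_bounds Optional `c(min, max)` per-annotator workload;
#'   an assignment violating the bounds is an error.
#' @param seed Integer seed.
#' @param policy A [workflow_policy()].
#' @return List with `assignment` (data.frame `image_id`, `group`) and
#'   `groups` (list of annotator-id vectors per group).
#' @export
assign_batches <- function(cohort, junior_profiles, n_groups,
                           workload_bounds = NULL, seed,
                           policy = workflow_policy()) {
  n_groups <- as.integer(n_groups)
  need <- n_groups * policy$group_size
  if (length(junior_profiles) < need)
    stop(sprintf("assignment error: %d groups of %d need %d annotators, have %d",
                 n_groups, policy$group_size, need, length(junior_profiles)),
         call. = FALSE)
  active <- cohort[!cohort$excluded, , drop = FALSE]
  n <- nrow(active)
  sizes <- rep(n %/% n_groups, n_groups)
  if (n %% n_groups > 0) sizes[seq_len(n %% n_groups)] <- sizes[seq_len(n %% n_groups)] + 1L
  if (!is.null(workload_bounds) &&
      (min(sizes) < workload_bounds[1] || max(sizes) > workload_bounds[2]))
    stop(sprintf(
      "assignment error: per-annotator workload %d-%d outside bounds [%d, %d]",
      min(sizes), max(sizes), workload_bounds[1], workload_bounds[2]),
      call. = FALSE)
  ids <- vapply(junior_profiles, `[[`, character(1), "annotator_id")
  res <- with_stream(substream_seed(seed, "batches"), {
    img_ord <- sample(active$image_id)
    ann_ord <- sample(ids)[seq_len(need)]
    list(img = img_ord, ann = ann_ord)
  })
  group <- rep(sprintf("group%d", seq_len(n_groups)), times = sizes)
  groups <- split(res$ann, rep(seq_len(n_groups), each = policy$group_size))
  names(groups) <- sprintf("group%d", seq_len(n_groups))
  list(assignment = data.frame(image_id = res$img, group = group,
                               stringsAsFactors = FALSE),
       groups = groups)
}

#' First annotation round: blinded triple reads and pool partition
#'
#' Each group's annotators independently read the group's images, every
#' reader drawing from their own substream of the root seed (so removing
#' one reader never changes another's labels). Images with fully concordant
#' reads form the prequalified pool; the rest form the arbitration pool.
#'
#' @param cohort Cohort data.frame.
#' @param batches Result of [assign_batches()].
#' @param junior_profiles Named-by-id list or plain list of junior profiles.
#' @param seed Root integer seed; reader substreams are derived from it.
#' @return List with `events` (image_id, annotator_id, round, label,
#'   order_index) and `partition` (image_id, pool).
#' @export
round_one <- function(cohort, batches, junior_profiles, seed) {
  ids <- vapply(junior_profiles, `[[`, character(1), "annotator_id")
  names(junior_profiles) <- ids
  asg <- batches$assignment
  rows <- match(asg$image_id, cohort$image_id)
  if (any(is.na(rows)))
    stop("incomplete round: assigned images missing from cohort", call. = FALSE)
  events <- vector("list", 0L)
  for (g in names(batches$groups)) {
    gi <- asg$image_id[asg$group == g]
    grec <- cohort[match(gi, cohort$image_id), , drop = FALSE]
    for (aid in batches$groups[[g]]) {
      prof <- junior_profiles[[aid]]
      if (is.null(prof))
        stop(sprintf("incomplete round: no profile for annotator %s", aid),
             call. = FALSE)
      prof$seed <- substream_seed(seed, paste0("round1/", aid))
      events[[length(events) + 1L]] <- data.frame(
        image_id = gi, annotator_id = aid, round = 1L,
        label = simulate_reads(prof, grec),
        order_index = seq_along(gi), stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, events)
  votes <- split(events$label, events$image_id)
  sizes <- lengths(votes)
  if (length(unique(sizes)) != 1L)
    stop("incomplete round: unequal read counts per image", call. = FALSE)
  unanimous <- vapply(votes, function(v) all(v == v[1L]), logical(1))
  partition <- data.frame(
    image_id = names(votes),
    pool = ifelse(unanimous, "prequalified", "arbitration"),
    stringsAsFactors = FALSE)
  partition <- partition[match(asg$image_id, partition$image_id), , drop = FALSE]
  rownames(partition) <- NULL
  list(events = events, partition = partition)
}

#' Sample the prequalified pool for second-round inspection
#'
#' Draws `floor(sample_rate * pool size)` images uniformly without
#' replacement (so a pool of 3694 at 10% yields 369 samples).
#'
#' @param prequalified_ids Character vector of prequalified image ids.
#' @param sample_rate Sampling fraction in (0, 1).
#' @param seed Integer seed.
#' @param label Substream label, varied across escalation cycles.
#' @return Character vector of sampled ids (possibly empty).
#' @export
sample_prequalified <- function(prequalified_ids, sample_rate = 0.10, seed,
                                label = "sample") {
  if (sample_rate <= 0 || sample_rate >= 1)
    stop("sample_rate must lie in (0, 1)", call. = FALSE)
  m <- floor(sample_rate * length(prequalified_ids))
  if (m == 0L) return(character(0))
  with_stream(substream_seed(seed, label),
              prequalified_ids[sample.int(length(prequalified_ids), m)])
}

#' Consensus rule of the senior panel
#'
#' The panel's decision is the modal label of the independent senior reads;
#' when every read differs the leader's label stands (a deterministic
#' surrogate for the panel discussion). Supplied as a separate function so
#' alternative consensus rules can be plugged into [round_two()].
#'
#' @param labels Integer vector of one image's senior reads, in panel order.
#' @param leader_index Position of the leader within `labels`.
#' @return The consensus class code.
#' @export
senior_consensus <- function(labels, leader_index) {
  tab <- table(labels)
  top <- max(tab)
  if (top == 1L) return(labels[leader_index])
  modes <- as.integer(names(tab)[tab == top])
  if (length(modes) == 1L) return(modes)
  # even-sized panels can tie between two modes; the leader's label wins
  # if among them, else the lowest severity code (stable tie-break)
  if (labels[leader_index] %in% modes) labels[leader_index] else min(modes)
}

#' Second annotation round: senior review and arbitration
#'
#' Each senior reads the submitted images independently through their own
#' confusion rows and substream; the final label per image comes from the
#' consensus rule.
#'
#' @param image_ids Images submitted to round two.
#' @param senior_profiles List of senior [make_annotator()] profiles.
#' @param leader_id Annotator id of the team leader (must be on the panel).
#' @param cohort Cohort data.frame.
#' @param seed Root integer seed.
#' @param consensus Consensus function, by default [senior_consensus()].
#' @return List with `labels` (image_id, label) and `events` (round-2 reads).
#' @export
round_two <- function(image_ids, senior_profiles, leader_id, cohort, seed,
                      consensus = senior_consensus) {
  ids <- vapply(senior_profiles, `[[`, character(1), "annotator_id")
  leader_index <- match(leader_id, ids)
  if (is.na(leader_index))
    stop("policy error: leader is not a member of the senior panel",
         call. = FALSE)
  if (length(image_ids) == 0L)
    return(list(labels = data.frame(image_id = character(0),
                                    label = integer(0),
                                    stringsAsFactors = FALSE),
                events = data.frame(image_id = character(0),
                                    annotator_id = character(0),
                                    round = integer(0), label = integer(0),
                                    order_index = integer(0),
                                    stringsAsFactors = FALSE)))
  recs <- cohort[match(image_ids, cohort$image_id), , drop = FALSE]
  if (any(is.na(recs$image_id)))
    stop("round two submitted images missing from cohort", call. = FALSE)
  reads <- matrix(NA_integer_, nrow = length(image_ids),
                  ncol = length(senior_profiles))
  events <- vector("list", length(senior_profiles))
  for (j in seq_along(senior_profiles)) {
    prof <- senior_profiles[[j]]
    prof$seed <- substream_seed(seed, paste0("round2/", ids[j]))
    reads[, j] <- simulate_reads(prof, recs)
    events[[j]] <- data.frame(image_id = image_ids, annotator_id = ids[j],
                              round = 2L, label = reads[, j],
                              order_index = seq_along(image_ids),
                              stringsAsFactors = FALSE)
  }
  final <- vapply(seq_along(image_ids),
                  function(i) consensus(reads[i, ], leader_index), integer(1))
  list(labels = data.frame(image_id = image_ids, label = final,
                           stringsAsFactors = FALSE),
       events = do.call(rbind, events))
}

#' Classify the provenance of a final label
#'
#' Given one image's round-1 votes and its final label: `unanimous` if all
#' votes equal the final label; `majority` if the final label holds a
#' majority of votes but not all; `minority` if exactly one vote (more
#' generally, a sub-majority share) matches; `arbitration_only` if no vote
#' matches.
#'
#' @param round1_votes Integer vector of the image's round-1 labels.
#' @param final The final class code.
#' @return One of `"unanimous"`, `"majority"`, `"minority"`,
#'   `"arbitration_only"`.
#' @export
classify_provenance <- function(round1_votes, final) {
  g <- length(round1_votes)
  k <- sum(round1_votes == final)
  if (k == g) "unanimous"
  else if (k >= ceiling(g / 2)) "majority"
  else if (k >= 1L) "minority"
  else "arbitration_only"
}

#' Resolve final reference-standard labels
#'
#' Unsampled prequalified images keep their unanimous round-1 label
#' (provenance `unanimous`); sampled and arbitration images take the
#' round-2 label, classified by [classify_provenance()] against the
#' round-1 votes — a round-2 overturn of a unanimous sample can therefore
#' yield `arbitration_only`.
#'
#' @param partition Pool assignment with `pool` in
#'   `{prequalified, prequalified_sampled, arbitration}`.
#' @param round1_events Round-1 events table.
#' @param round2_labels Round-2 labels (`image_id`, `label`).
#' @param policy A [workflow_policy()].
#' @return Final-label data.frame: `image_id`, `label`, `provenance`.
#' @export
resolve_final <- function(partition, round1_events, round2_labels,
                          policy = workflow_policy()) {
  votes <- split(round1_events$label, round1_events$image_id)
  r2 <- stats::setNames(round2_labels$label, round2_labels$image_id)
  lab <- integer(nrow(partition))
  prov <- character(nrow(partition))
  for (i in seq_len(nrow(partition))) {
    id <- partition$image_id[i]
    v <- votes[[id]]
    if (is.null(v))
      stop(sprintf("unresolved image %s: no round-1 votes", id), call. = FALSE)
    if (partition$pool[i] == "prequalified") {
      lab[i] <- v[1L]
      prov[i] <- "unanimous"
    } else {
      if (!id %in% names(r2))
        stop(sprintf("unresolved image %s: no round-2 label", id),
             call. = FALSE)
      lab[i] <- r2[[id]]
      prov[i] <- classify_provenance(v, lab[i])
    }
  }
  data.frame(image_id = partition$image_id, label = lab, provenance = prov,
             stringsAsFactors = FALSE)
}

#' Inspect the sampled prequalified annotations and decide on escalation
#'
#' The disagreement rate is the fraction of sampled images whose round-2
#' label differs from the unanimous round-1 label; escalation triggers when
#' it exceeds the policy threshold.
#'
#' @param sampled_round1 data.frame `image_id`, `label` (unanimous round-1).
#' @param sampled_round2 data.frame `image_id`, `label` (round-2 result).
#' @param policy A [workflow_policy()].
#' @return List with `decision` (`"none"`, `"double_sample"` or
#'   `"full_review"`), `disagreement_rate` and `n_sampled`.
#' @export
inspect_and_escalate <- function(sampled_round1, sampled_round2,
                                 policy = workflow_policy()) {
  if (nrow(sampled_round1) == 0L) {
    warning("empty inspection sample: no escalation decision possible")
    return(list(decision = "none", disagreement_rate = NA_real_,
                n_sampled = 0L))
  }
  m <- match(sampled_round1$image_id, sampled_round2$image_id)
  if (any(is.na(m)))
    stop("inspection sets are not aligned by image", call. = FALSE)
  rate <- mean(sampled_round1$label != sampled_round2$label[m])
  decision <- if (rate > policy$escalation_threshold)
    policy$escalation_action else "none"
  list(decision = decision, disagreement_rate = rate,
       n_sampled = nrow(sampled_round1))
}

#' Summarize final-label provenance
#'
#' @param finals Final-label data.frame from [resolve_final()].
#' @param round1_events Optional round-1 events; required when
#'   `distinguish_split = TRUE`.
#' @param distinguish_split If `TRUE`, images whose round-1 votes were all
#'   distinct are reported as `minority_split` rather than pooled with
#'   `minority` (the share attributable to fully divergent groups).
#' @return data.frame with `provenance`, `n`, `percentage`.
#' @export
provenance_summary <- function(finals, round1_events = NULL,
                               distinguish_split = FALSE) {
  prov <- finals$provenance
  if (distinguish_split) {
    if (is.null(round1_events))
      stop("round1_events needed to distinguish split votes", call. = FALSE)
    votes <- split(round1_events$label, round1_events$image_id)
    split_ids <- names(votes)[vapply(votes, function(v)
      length(unique(v)) == length(v), logical(1))]
    prov[finals$image_id %in% split_ids & prov == "minority"] <- "minority_split"
  }
  levs <- c("unanimous", "majority", "minority",
            if (distinguish_split) "minority_split", "arbitration_only")
  tab <- table(factor(prov, levels = levs))
  data.frame(provenance = names(tab), n = as.integer(tab),
             percentage = round(100 * as.integer(tab) / nrow(finals), 2),
             stringsAsFactors = FALSE)
}
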