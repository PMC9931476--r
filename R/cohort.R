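# Label-level cohort simulation: image records, raw hospital labels,
# confusion-matrix annotators and binary-referral algorithms under test.

#' Define a cohort composition
#'
#' @param counts Nonnegative integer vector of length 7 giving the number of
#'   images of each DR class (codes 0-6, in order).
#' @return An object of class `cohort_composition`: a named integer vector
#'   with attribute `total`.
#' @export
cohort_composition <- function(counts) {
  if (length(counts) == 0L || is.null(counts))
    stop("invalid composition: empty class counts", call. = FALSE)
  if (length(counts) != 7L)
    stop("invalid composition: exactly 7 class counts (codes 0-6) required",
         call. = FALSE)
  n <- suppressWarnings(as.integer(counts))
  if (any(is.na(n)) || any(n < 0))
    stop("invalid composition: counts must be nonnegative integers",
         call. = FALSE)
  if (sum(n) == 0L)
    stop("invalid composition: at least one class must have images",
         call. = FALSE)
  names(n) <- 0:6
  structure(n, total = sum(n), class = "cohort_composition")
}

#' Composition of the reference 6327-image DR test set
#'
#' Per-class image counts of the standardized test set used throughout the
#' package as the default study condition: 873 / 262 / 1118 / 579 / 540 /
#' 2600 / 355 images for classes 0-6, totalling 6327.
#'
#' @return A [cohort_composition()].
#' @export
testset_composition <- function() {
  cohort_composition(c(873L, 262L, 1118L, 579L, 540L, 2600L, 355L))
}

#' Summarize a composition as counts and percentages
#'
#' @param composition A [cohort_composition()].
#' @param digits Decimal places for the percentage column (default 3, the
#'   convention used in published test-set composition tables).
#' @return A data.frame with columns `class`, `n`, `percentage`, plus a
#'   total row.
#' @export
composition_summary <- function(composition, digits = 3L) {
  comp <- cohort_composition(unclass(composition))
  total <- sum(comp)
  data.frame(
    class = c(names(comp), "total"),
    n = c(as.integer(comp), total),
    percentage = c(round(100 * as.numeric(comp) / total, digits), 100),
    stringsAsFactors = FALSE
  )
}

#' Specify site and camera strata
#'
#' Strata are label-neutral by default: they diversify the manifest without
#' affecting class labels. Proportions are renormalized to sum to 1.
#'
#' @param site_props Named numeric vector of data-collection-site proportions.
#' @param camera_props Named numeric vector of camera-model proportions.
#' @return A list of class `strata_spec`.
#' @export
strata_spec <- function(site_props = stats::setNames(rep(1 / 11, 11),
                                                     sprintf("site%02d", 1:11)),
                        camera_props = stats::setNames(rep(1 / 13, 13),
                                                       sprintf("camera%02d", 1:13))) {
  for (p in list(site_props, camera_props)) {
    if (any(p < 0) || sum(p) <= 0)
      stop("strata proportions must be nonnegative and sum to a positive value",
           call. = FALSE)
    if (abs(sum(p) - 1) > 1e-6)
      stop("strata proportions must sum to 1", call. = FALSE)
  }
  structure(list(site_props = site_props / sum(site_props),
                 camera_props = camera_props / sum(camera_props)),
            class = "strata_spec")
}

#' Generate a label-level image cohort
#'
#' Produces exactly the requested number of records per class, assigns site
#' and camera strata by independent seeded multinomial draws, and shuffles
#' record order. The same `(composition, strata, seed)` always yields a
#' byte-identical manifest.
#'
#' @param composition A [cohort_composition()].
#' @param strata A [strata_spec()].
#' @param seed Integer seed.
#' @return A data.frame with columns `image_id`, `true_class`, `raw_label`
#'   (NA until [simulate_raw_labels()]), `site_id`, `camera_id`, `excluded`.
#' @export
generate_cohort <- function(composition, strata = strata_spec(), seed) {
  comp <- cohort_composition(unclass(composition))
  stopifnot(inherits(strata, "strata_spec"))
  n <- sum(comp)
  true_class <- rep(0:6, times = as.integer(comp))
  with_stream(substream_seed(seed, "cohort"), {
    ord <- sample.int(n)
    true_class <- true_class[ord]
    site_id <- sample(names(strata$site_props), n, replace = TRUE,
                      prob = strata$site_props)
    camera_id <- sample(names(strata$camera_props), n, replace = TRUE,
                        prob = strata$camera_props)
  })
  data.frame(
    image_id = sprintf("img%06d", seq_len(n)),
    true_class = true_class,
    raw_label = rep(NA_integer_, n),
    site_id = site_id,
    camera_id = camera_id,
    excluded = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

#' Simulate raw hospital labels for a cohort
#'
#' Each record's raw label is drawn independently from the confusion row of
#' its true class. The default confusion has diagonal 0.6164 (the accuracy
#' level typical of uncurated hospital labels) with adjacency-weighted
#' errors.
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param raw_confusion 7x7 row-stochastic matrix.
#' @param seed Integer seed.
#' @return The cohort with `raw_label` filled.
#' @export
simulate_raw_labels <- function(cohort,
                                raw_confusion = adjacent_confusion(0.6164, 0.7),
                                seed) {
  validate_confusion(raw_confusion)
  cohort$raw_label <- with_stream(
    substream_seed(seed, "raw_labels"),
    draw_labels(raw_confusion, validate_class(cohort$true_class))
  )
  cohort
}

#' Construct a simulated annotator profile
#'
#' The annotator is fully described by a 7x7 confusion matrix built with
#' [adjacent_confusion()]: diagonal `target_accuracy` on every row, the
#' error mass adjacency-weighted toward neighbouring severities.
#'
#' @param annotator_id Character identifier.
#' @param target_accuracy Per-class probability of a correct assignment.
#' @param adjacency_weight Fraction of error mass on adjacent severities.
#' @param seniority One of `"junior"`, `"senior"`, `"leader"`.
#' @param seed Optional integer stream seed for this reader; usually derived
#'   from the run's root seed with [substream_seed()].
#' @return An object of class `annotator_profile`.
#' @export
make_annotator <- function(annotator_id, target_accuracy,
                           adjacency_weight = 0.7,
                           seniority = c("junior", "senior", "leader"),
                           seed = NULL) {
  seniority <- match.arg(seniority)
  confusion <- adjacent_confusion(target_accuracy, adjacency_weight)
  structure(list(annotator_id = as.character(annotator_id),
                 confusion = confusion,
                 accuracy = target_accuracy,
                 seniority = seniority,
                 seed = seed),
            class = "annotator_profile")
}

#' Simulate blinded reads of cohort records by one annotator
#'
#' Labels are drawn from the confusion row of each record's true class.
#' When the profile carries a `seed` the reads come from that reader's own
#' substream (so other readers' draws are unaffected); otherwise the
#' current RNG stream is used.
#'
#' @param profile An [make_annotator()] profile.
#' @param records Cohort data.frame rows to read.
#' @return Integer vector of assigned classes, one per record.
#' @export
simulate_reads <- function(profile, records) {
  stopifnot(inherits(profile, "annotator_profile"))
  if (any(records$excluded))
    stop(sprintf("refused read: %d excluded record(s) may not be annotated",
                 sum(records$excluded)), call. = FALSE)
  truth <- validate_class(records$true_class)
  if (is.null(profile$seed)) draw_labels(profile$confusion, truth)
  else with_stream(profile$seed, draw_labels(profile$confusion, truth))
}

#' @rdname simulate_reads
#' @param record A single cohort record (one-row data.frame).
#' @export
simulate_read <- function(profile, record) {
  if (nrow(record) != 1L) stop("simulate_read expects a single record",
                               call. = FALSE)
  simulate_reads(profile, record)
}

#' Construct an algorithm-under-test capability profile
#'
#' `capability[c]` is the probability that the AUT makes the correct binary
#' referral decision on an image of class `c` (sensitivity for classes 2-4,
#' specificity for classes 0, 1, 5, 6).
#'
#' @param aut_id Character identifier.
#' @param capability Numeric vector of 7 probabilities, classes 0-6.
#' @param seed Optional integer stream seed.
#' @return An object of class `aut_profile`.
#' @export
aut_profile <- function(aut_id, capability, seed = NULL) {
  if (length(capability) != 7L || any(is.na(capability)) ||
      any(capability < 0) || any(capability > 1))
    stop("invalid AUT profile: capability must be 7 probabilities in [0, 1]",
         call. = FALSE)
  structure(list(aut_id = as.character(aut_id),
                 capability = stats::setNames(as.numeric(capability), 0:6),
                 seed = seed),
            class = "aut_profile")
}

#' Capability profiles of five benchmark DR referral algorithms
#'
#' Per-class correct-referral probabilities of five deep-learning DR
#' classifiers evaluated on the reference test set; used as the default
#' study condition of the AUT simulator.
#'
#' @return Named list of five [aut_profile()] objects.
#' @export
aut_capability_profiles <- function() {
  caps <- list(
    AUT1 = c(0.983963, 0.557252, 0.752236, 0.982729, 0.957407, 0.893846, 0.814085),
    AUT2 = c(0.989691, 0.958015, 0.645796, 0.991364, 0.974074, 0.801923, 0.442254),
    AUT3 = c(0.988545, 0.912214, 0.677102, 0.993092, 0.975926, 0.889231, 0.642254),
    AUT4 = c(0.988545, 0.885496, 0.639534, 0.984455, 0.946296, 0.761153, 0.549295),
    AUT5 = c(0.934708, 0.889313, 0.746869, 0.977547, 0.933333, 0.642308, 0.738028)
  )
  lapply(stats::setNames(names(caps), names(caps)),
         function(id) aut_profile(id, caps[[id]]))
}

#' Published overall metrics of the five benchmark algorithms
#'
#' Overall sensitivity, specificity and accuracy (referrable vs
#' nonreferrable) of the same five algorithms on the reference test set.
#' These are the values [reconstruct_overall()] reproduces from
#' [aut_capability_profiles()] and [testset_composition()].
#'
#' @return A data.frame keyed by `aut_id`.
#' @export
aut_overall_benchmarks <- function() {
  data.frame(
    aut_id = paste0("AUT", 1:5),
    sensitivity = c(0.861422, 0.814484, 0.831024, 0.802861, 0.851587),
    specificity = c(0.884597, 0.820782, 0.890465, 0.799267, 0.728851),
    accuracy    = c(0.876403, 0.818555, 0.869448, 0.800537, 0.772246),
    stringsAsFactors = FALSE
  )
}

#' Simulate binary referral outputs of an AUT on a cohort
#'
#' For an image of class `c` the simulated AUT emits the correct referral
#' decision with probability `capability[c]`, otherwise the opposite one.
#'
#' @param profile An [aut_profile()].
#' @param cohort Cohort data.frame (excluded records are refused).
#' @param seed Integer seed; the AUT draws from substream
#'   `(seed, aut_id)`. Ignored when the profile carries its own seed.
#' @return A data.frame of referral calls: `image_id`, `referrable` (logical).
#' @export
simulate_aut <- function(profile, cohort, seed = NULL) {
  stopifnot(inherits(profile, "aut_profile"))
  if (any(cohort$excluded))
    stop("excluded records may not be evaluated", call. = FALSE)
  truth <- validate_class(cohort$true_class)
  s <- profile$seed
  if (is.null(s)) {
    if (is.null(seed)) stop("simulate_aut needs a seed (argument or profile)",
                            call. = FALSE)
    s <- substream_seed(seed, paste0("aut/", profile$aut_id))
  }
  correct <- with_stream(s, stats::runif(nrow(cohort)) < profile$capability[truth + 1L])
  data.frame(image_id = cohort$image_id,
             referrable = ifelse(correct, to_referrable(truth), !to_referrable(truth)),
             stringsAsFactors = FALSE)
}
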