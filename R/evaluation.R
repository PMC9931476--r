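# Evaluation of algorithms under test against the reference standard:
# referral binarization, overall confusion counts and metrics, per-class
# decision capability, and the exact composition-weighted reconstruction
# linking per-class capability to overall metrics.

#' Referral confusion counts for one set of AUT calls
#'
#' Counts are computed against the referral binarization of the reference
#' labels; referrable reference images contribute tp/fn, nonreferrable ones
#' tn/fp.
#'
#' @param calls data.frame `image_id`, `referrable` (logical or 0/1).
#' @param reference Final-label data.frame (`image_id`, `label`).
#' @return Named list `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(calls, reference) {
  m <- match(reference$image_id, calls$image_id)
  if (any(is.na(m))) {
    missing_ids <- reference$image_id[is.na(m)]
    stop(sprintf("incomplete AUT output: no call for %d image(s): %s%s",
                 length(missing_ids),
                 paste(utils::head(missing_ids, 5L), collapse = ", "),
                 if (length(missing_ids) > 5L) ", ..." else ""),
         call. = FALSE)
  }
  truth <- to_referrable(reference$label)
  call <- as.logical(calls$referrable[m])
  list(tp = sum(truth & call), fp = sum(!truth & call),
       tn = sum(!truth & !call), fn = sum(truth & !call))
}

#' Overall sensitivity, specificity and accuracy from confusion counts
#'
#' @param counts List with `tp`, `fp`, `tn`, `fn`.
#' @return Named list `sensitivity`, `specificity`, `accuracy` at full
#'   floating precision (round only at report time).
#' @export
overall_metrics <- function(counts) {
  with(counts, {
    if (tp + fn == 0)
      stop("undefined metric: sensitivity (no referrable reference images)",
           call. = FALSE)
    if (tn + fp == 0)
      stop("undefined metric: specificity (no nonreferrable reference images)",
           call. = FALSE)
    list(sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         accuracy = (tp + tn) / (tp + fp + tn + fn))
  })
}

#' Per-class decision capability of an AUT
#'
#' For the referrable classes 2-4 the capability is the fraction of that
#' class's images called referrable (a per-class sensitivity); for classes
#' 0, 1, 5, 6 it is the fraction called nonreferrable (a per-class
#' specificity). Classes absent from the reference are reported as `NA`,
#' never as 0 or 1.
#'
#' @inheritParams confusion_counts
#' @return Named numeric vector of length 7 (classes 0-6).
#' @export
per_class_capability <- function(calls, reference) {
  m <- match(reference$image_id, calls$image_id)
  if (any(is.na(m)))
    stop("incomplete AUT output: calls do not cover the reference",
         call. = FALSE)
  cls <- validate_class(reference$label)
  call <- as.logical(calls$referrable[m])
  correct <- call == to_referrable(cls)
  vapply(stats::setNames(0:6, 0:6), function(c0) {
    idx <- cls == c0
    if (!any(idx)) NA_real_ else mean(correct[idx])
  }, numeric(1))
}

#' Reconstruct overall metrics from per-class capabilities and composition
#'
#' Overall sensitivity is the composition-weighted average of the
#' referrable-class capabilities, specificity the analogous average over
#' the nonreferrable classes, and accuracy the all-class average. With
#' `snap_counts = TRUE` (default) each per-class numerator
#' `capability * n_c` is rounded to the nearest integer before
#' aggregation: capabilities are correct-decision proportions over integer
#' denominators, so a capability quoted at finite precision is restored to
#' its exact count. For capabilities measured on the same cohort the snap
#' is a no-op and the reconstruction equals [overall_metrics()] on the
#' underlying calls to machine precision.
#'
#' @param per_class Named capability vector (classes 0-6) as returned by
#'   [per_class_capability()].
#' @param composition A [cohort_composition()].
#' @param snap_counts Round per-class correct counts to integers.
#' @return Named list `sensitivity`, `specificity`, `accuracy`.
#' @export
reconstruct_overall <- function(per_class, composition, snap_counts = TRUE) {
  comp <- cohort_composition(unclass(composition))
  n <- as.numeric(comp)
  cap <- as.numeric(per_class[as.character(0:6)])
  pop <- n > 0
  if (any(pop & is.na(cap)))
    stop("missing capability for populated class(es): ",
         paste((0:6)[pop & is.na(cap)], collapse = ", "), call. = FALSE)
  correct <- cap * n
  correct[!pop] <- 0
  if (snap_counts) correct <- round(correct)
  pos <- (0:6) %in% referrable_classes()
  P <- sum(n[pos]); N <- sum(n[!pos])
  if (P == 0) stop("undefined metric: sensitivity (no referrable images)",
                   call. = FALSE)
  if (N == 0) stop("undefined metric: specificity (no nonreferrable images)",
                   call. = FALSE)
  list(sensitivity = sum(correct[pos]) / P,
       specificity = sum(correct[!pos]) / N,
       accuracy = sum(correct) / (P + N))
}

#' Overall accuracy implied by sensitivity, specificity and composition
#'
#' `accuracy = (sens * P + spec * N) / (P + N)` where `P` and `N` are the
#' referrable and nonreferrable image totals of the composition.
#'
#' @param sensitivity,specificity Overall rates.
#' @param composition A [cohort_composition()].
#' @return Accuracy as a proportion.
#' @export
accuracy_from_rates <- function(sensitivity, specificity, composition) {
  comp <- cohort_composition(unclass(composition))
  n <- as.numeric(comp)
  pos <- (0:6) %in% referrable_classes()
  P <- sum(n[pos]); N <- sum(n[!pos])
  (sensitivity * P + specificity * N) / (P + N)
}

#' Full metrics report for one AUT
#'
#' @param aut_id Identifier of the algorithm under test.
#' @inheritParams confusion_counts
#' @return An object of class `metrics_report` with counts, overall
#'   metrics, per-class capability and a digest of the reference used.
#' @export
metrics_report <- function(aut_id, calls, reference) {
  counts <- confusion_counts(calls, reference)
  structure(
    c(list(aut_id = aut_id), counts, overall_metrics(counts),
      list(per_class_capability = per_class_capability(calls, reference),
           reference_digest = hash_string(paste(reference$image_id,
                                                reference$label,
                                                collapse = ";")))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 6L, ...) {
  cat(sprintf("AUT %s: sens %.*f  spec %.*f  acc %.*f  (tp %d fp %d tn %d fn %d)\n",
              x$aut_id, digits, x$sensitivity, digits, x$specificity,
              digits, x$accuracy, x$tp, x$fp, x$tn, x$fn))
  cat("  per-class capability:",
      paste(sprintf("%s=%.3f", 0:6, x$per_class_capability), collapse = " "),
      "\n")
  invisible(x)
}

#' Compare several AUT reports side by side
#'
#' Builds the overall-metric and per-class tables, flags the per-metric
#' argmax, and flags AUTs whose per-class capabilities are homogeneous
#' (max minus min within `homogeneity_band`).
#'
#' @param reports List of [metrics_report()] objects sharing one reference.
#' @param homogeneity_band Width of the homogeneity band (default 0.10).
#' @return List with `overall` and `per_class` data.frames, `best` (named
#'   vector of argmax AUT ids, ties comma-separated) and `homogeneous`.
#' @export
compare_auts <- function(reports, homogeneity_band = 0.10) {
  if (length(reports) < 1L) stop("need at least one report", call. = FALSE)
  digests <- vapply(reports, `[[`, integer(1), "reference_digest")
  if (length(unique(digests)) != 1L)
    stop("incomparable reports: metrics computed against different references",
         call. = FALSE)
  ids <- vapply(reports, `[[`, character(1), "aut_id")
  overall <- data.frame(
    aut_id = ids,
    sensitivity = vapply(reports, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(reports, `[[`, numeric(1), "specificity"),
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    stringsAsFactors = FALSE)
  per_class <- do.call(rbind, lapply(reports, function(r)
    data.frame(aut_id = r$aut_id, class = 0:6,
               capability = as.numeric(r$per_class_capability),
               stringsAsFactors = FALSE)))
  best <- vapply(c("sensitivity", "specificity", "accuracy"), function(mtr) {
    v <- overall[[mtr]]
    paste(ids[v == max(v)], collapse = ",")
  }, character(1))
  homogeneous <- vapply(reports, function(r) {
    cap <- r$per_class_capability[!is.na(r$per_class_capability)]
    diff(range(cap)) <= homogeneity_band
  }, logical(1))
  names(homogeneous) <- ids
  list(overall = overall, per_class = per_class, best = best,
       homogeneous = homogeneous)
}
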