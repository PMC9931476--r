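# Annotator qualification: exam construction, scoring, admission.
# Exam items are drawn by super-category (nonreferrable DR, referrable DR,
# other ocular diseases, ungradable) with largest-remainder apportionment.

exam_categories <- function() {
  list(nonreferrable_dr = 0:1, referrable_dr = 2:4,
       other_disease = 5L, ungradable = 6L)
}

exam_category_of <- function(class) {
  cls <- validate_class(class)
  out <- character(length(cls))
  for (cat in names(exam_categories()))
    out[cls %in% exam_categories()[[cat]]] <- cat
  out
}

#' Specify a qualification exam
#'
#' The default composition (18 / 45 / 32 / 6 percent for nonreferrable DR,
#' referrable DR, other ocular diseases, ungradable) sums to 101 and is
#' renormalized proportionally before use.
#'
#' @param n_items Number of exam photographs (default 100; a 120-item
#'   variant is available via `exam_spec(n_items = 120)`).
#' @param composition_pct Percentages per super-category, in the order
#'   nonreferrable DR, referrable DR, other ocular diseases, ungradable.
#' @param pass_threshold Admission threshold on exam accuracy (default 0.80).
#' @param strict If `TRUE` admission requires accuracy strictly above the
#'   threshold; the default inclusive rule admits at exactly the threshold.
#' @return An object of class `exam_spec`.
#' @export
exam_spec <- function(n_items = 100L,
                      composition_pct = c(nonreferrable_dr = 18,
                                          referrable_dr = 45,
                                          other_disease = 32,
                                          ungradable = 6),
                      pass_threshold = 0.80,
                      strict = FALSE) {
  if (length(composition_pct) != 4L || any(composition_pct < 0) ||
      sum(composition_pct) <= 0)
    stop("exam composition needs 4 nonnegative percentages", call. = FALSE)
  if (!is.numeric(pass_threshold) || pass_threshold <= 0 || pass_threshold > 1)
    stop("pass_threshold must lie in (0, 1]", call. = FALSE)
  names(composition_pct) <- names(exam_categories())
  structure(list(n_items = as.integer(n_items),
                 composition = composition_pct / sum(composition_pct),
                 pass_threshold = pass_threshold,
                 strict = isTRUE(strict)),
            class = "exam_spec")
}

# Largest-remainder apportionment of n among proportions p (sums to 1).
# Ties in the fractional remainders are broken by category order.
largest_remainder <- function(p, n) {
  quota <- p * n
  k <- floor(quota)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(quota - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  stats::setNames(as.integer(k), names(p))
}

#' Build a qualification exam from a pool of records
#'
#' Per-super-category item counts are the renormalized composition times
#' `n_items`, apportioned by largest remainder; items are sampled without
#' replacement within category and shuffled. The answer key is the true
#' class of each item.
#'
#' @param spec An [exam_spec()].
#' @param pool Cohort data.frame to draw exam items from.
#' @param seed Integer seed.
#' @return List with `items` (records in exam order), `key` (true classes)
#'   and `category_counts`.
#' @export
build_exam <- function(spec, pool, seed) {
  stopifnot(inherits(spec, "exam_spec"))
  counts <- largest_remainder(spec$composition, spec$n_items)
  pool_cat <- exam_category_of(pool$true_class)
  avail <- vapply(names(counts), function(cat) sum(pool_cat == cat), integer(1))
  short <- counts > avail
  if (any(short))
    stop(sprintf("infeasible exam: pool lacks items in %s (need %s, have %s)",
                 paste(names(counts)[short], collapse = ", "),
                 paste(counts[short], collapse = ", "),
                 paste(avail[short], collapse = ", ")), call. = FALSE)
  rows <- with_stream(substream_seed(seed, "exam"), {
    picked <- unlist(lapply(names(counts), function(cat) {
      idx <- which(pool_cat == cat)
      idx[sample.int(length(idx), counts[[cat]])]
    }), use.names = FALSE)
    sample(picked)
  })
  items <- pool[rows, , drop = FALSE]
  rownames(items) <- NULL
  list(items = items, key = validate_class(items$true_class),
       category_counts = counts)
}

#' Score an exam sheet against the answer key
#'
#' @param answers Vector of answered class codes.
#' @param key Vector of true class codes, same length.
#' @param level `"class"` for exact 7-class matching (default) or
#'   `"referral"` to score on the binary referrable mapping.
#' @return Accuracy as a proportion.
#' @export
score_exam <- function(answers, key, level = c("class", "referral")) {
  level <- match.arg(level)
  if (length(answers) != length(key) || length(key) == 0L)
    stop("answers and key must have equal, nonzero length", call. = FALSE)
  a <- validate_class(answers)
  k <- validate_class(key)
  if (level == "class") mean(a == k)
  else mean(to_referrable(a) == to_referrable(k))
}

#' Apply the admission rule to an exam accuracy
#'
#' @param accuracy Exam accuracy in `[0, 1]`.
#' @param spec An [exam_spec()]; supplies threshold and strictness.
#' @return `TRUE` if the candidate is admitted.
#' @export
admit <- function(accuracy, spec = exam_spec()) {
  stopifnot(inherits(spec, "exam_spec"))
  if (spec$strict) accuracy > spec$pass_threshold
  else accuracy >= spec$pass_threshold
}
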