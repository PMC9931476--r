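# Rater-agreement statistics: Fleiss kappa over the round-1 panel, Cohen
# kappa between two label sources, per-annotator accuracy against the
# reference standard, and intra-rater repeatability.

#' Build an items-by-categories ratings table from round-1 events
#'
#' @param events Round-1 events data.frame (`image_id`, `label`).
#' @param categories Category codes spanning the columns (default 0-6).
#' @return Integer matrix `r[i, j]` = number of raters assigning item `i`
#'   to category `j`; one row per image.
#' @export
ratings_table <- function(events, categories = dr_classes()) {
  tab <- table(events$image_id, factor(events$label, levels = categories))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), categories))
  m
}

validate_ratings <- function(table) {
  if (!is.matrix(table) || nrow(table) < 2L)
    stop("invalid ratings table: need at least 2 items", call. = FALSE)
  n_raters <- unique(rowSums(table))
  if (length(n_raters) != 1L)
    stop("invalid ratings table: unequal rater counts across items",
         call. = FALSE)
  if (n_raters < 2L)
    stop("invalid ratings table: need at least 2 raters per item",
         call. = FALSE)
  n_raters
}

#' Fleiss' kappa for multi-rater nominal agreement
#'
#' Chance-corrected agreement among a fixed number of raters:
#' `kappa = (Pbar - Pe) / (1 - Pe)` with per-item agreement
#' `P_i = sum_j r_ij (r_ij - 1) / (n (n - 1))` and expected agreement
#' `Pe = sum_j p_j^2` over the marginal category proportions. When every
#' rating falls in a single category `Pe = 1`; the conventional value 1 is
#' returned (0 with a warning if observed agreement were also imperfect,
#' which cannot occur in that degenerate case with equal rater counts).
#'
#' @param table Ratings matrix from [ratings_table()].
#' @return Kappa in `[-1, 1]`.
#' @export
fleiss_kappa <- function(table) {
  n <- validate_ratings(table)
  N <- nrow(table)
  p_j <- colSums(table) / (N * n)
  P_i <- (rowSums(table^2) - n) / (n * (n - 1))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (abs(1 - Pe) < .Machine$double.eps * 8) {
    if (Pbar >= 1 - 1e-12) return(1)
    warning("expected agreement is 1; kappa undefined, returning 0")
    return(0)
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Cohen's kappa between two label sources
#'
#' Unweighted chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`
#' with `p_e = sum_j P(A = j) P(B = j)`. If both sources are constant and
#' identical the conventional value 1 is returned; a constant pair with
#' `p_e = 1` and imperfect agreement returns 0 with a warning.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) == 0L)
    stop("label vectors must have equal, nonzero length", call. = FALSE)
  levs <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = levs)
  b <- factor(labels_b, levels = levs)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / length(a)) * (table(b) / length(b)))
  if (abs(1 - p_e) < .Machine$double.eps * 8) {
    if (p_o >= 1 - 1e-12) return(1)
    warning("expected agreement is 1; kappa undefined, returning 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Per-annotator accuracy against the reference standard
#'
#' Accuracy is the proportion of an annotator's round-1 reads that match
#' the final adjudicated label of the image read.
#'
#' @param events Round-1 events data.frame.
#' @param reference Final-label data.frame (`image_id`, `label`).
#' @return List with `per_annotator` (data.frame `annotator_id`, `n_reads`,
#'   `accuracy`) and summary fields `min`, `mean`, `max`.
#' @export
annotator_accuracy <- function(events, reference) {
  ref <- stats::setNames(reference$label, reference$image_id)
  m <- ref[events$image_id]
  if (any(is.na(names(m)) | is.na(m)))
    stop("every annotated image needs a reference label", call. = FALSE)
  ok <- events$label == m
  per <- stats::aggregate(ok, by = list(annotator_id = events$annotator_id),
                          FUN = function(z) c(n = length(z), acc = mean(z)))
  out <- data.frame(annotator_id = per$annotator_id,
                    n_reads = as.integer(per$x[, "n"]),
                    accuracy = per$x[, "acc"],
                    stringsAsFactors = FALSE)
  zero <- out$n_reads == 0L
  if (any(zero)) {
    warning(sprintf("excluding %d annotator(s) with zero reads", sum(zero)))
    out <- out[!zero, , drop = FALSE]
  }
  list(per_annotator = out, min = min(out$accuracy),
       mean = mean(out$accuracy), max = max(out$accuracy))
}

#' Intra-rater repeatability from paired repeat readings
#'
#' Default metric is exact percent agreement between the two readings of
#' each item — the honest summary for nominal labels. `method = "icc"`
#' computes the two-way random-effects single-measure intraclass
#' correlation ICC(2,1) on the integer-coded labels, for comparability with
#' reports that quote an ICC for categorical grades.
#'
#' @param first,second Equal-length label vectors: the two readings of the
#'   same items by one rater.
#' @param method `"percent"` (default) or `"icc"`.
#' @return A proportion (percent agreement) or an ICC in `[-1, 1]`.
#' @export
intra_rater <- function(first, second, method = c("percent", "icc")) {
  method <- match.arg(method)
  if (length(first) != length(second) || length(first) < 2L)
    stop("need at least 2 items with paired readings", call. = FALSE)
  if (method == "percent") return(mean(first == second))
  icc21(cbind(as.numeric(first), as.numeric(second)))
}

# ICC(2,1): two-way random effects, absolute agreement, single measure.
# x is an n-items by k-raters numeric matrix.
icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (abs(denom) < .Machine$double.eps * 8) return(1)
  (MSR - MSE) / denom
}

#' Compile an agreement report for one adjudication run
#'
#' @param round1_events Round-1 events table.
#' @param finals Final-label table.
#' @param raw_cohort Cohort with `raw_label` filled (optional; enables the
#'   raw-label accuracy and Cohen-kappa comparison).
#' @param repeats Optional data.frame `first`, `second` of one-rater repeat
#'   readings for intra-rater repeatability.
#' @return A list of class `agreement_report`.
#' @export
agreement_report <- function(round1_events, finals, raw_cohort = NULL,
                             repeats = NULL) {
  acc <- annotator_accuracy(round1_events, finals)
  out <- list(
    fleiss_kappa = fleiss_kappa(ratings_table(round1_events)),
    annotator_accuracy = acc
  )
  if (!is.null(raw_cohort)) {
    m <- match(finals$image_id, raw_cohort$image_id)
    raw <- raw_cohort$raw_label[m]
    out$raw_label_accuracy <- mean(raw == finals$label)
    out$raw_cohen_kappa <- cohen_kappa(raw, finals$label)
  }
  if (!is.null(repeats)) {
    out$intra_rater_percent <- intra_rater(repeats$first, repeats$second)
    out$intra_rater_icc <- intra_rater(repeats$first, repeats$second,
                                       method = "icc")
  }
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report\n")
  cat(sprintf("  Fleiss kappa (round 1): %.4f\n", x$fleiss_kappa))
  cat(sprintf("  Annotator accuracy: mean %.3f (min %.3f, max %.3f)\n",
              x$annotator_accuracy$mean, x$annotator_accuracy$min,
              x$annotator_accuracy$max))
  if (!is.null(x$raw_label_accuracy)) {
    cat(sprintf("  Raw-label accuracy: %.4f\n", x$raw_label_accuracy))
    cat(sprintf("  Raw-label Cohen kappa: %.4f\n", x$raw_cohen_kappa))
  }
  if (!is.null(x$intra_rater_percent)) {
    cat(sprintf("  Intra-rater agreement: %.3f (ICC(2,1) %.3f)\n",
                x$intra_rater_percent, x$intra_rater_icc))
  }
  invisible(x)
}
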