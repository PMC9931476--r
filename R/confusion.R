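# Row-stochastic 7x7 confusion matrices P(assigned = j | truth = i) are the
# whole behavioural model of a simulated reader or labelling source.

#' Validate a 7x7 row-stochastic confusion matrix
#'
#' @param m Numeric 7x7 matrix; rows index the true class (0-6), columns the
#'   assigned class. Each row must sum to 1 within `tol` and every entry must
#'   lie in `[0, 1]`.
#' @param tol Tolerance on the row sums (default `1e-9`).
#' @return The matrix, invisibly, with dimnames set to the class codes.
#' @export
validate_confusion <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !is.numeric(m) || any(dim(m) != 7L))
    stop("confusion matrix must be a numeric 7x7 matrix", call. = FALSE)
  if (any(is.na(m)) || any(m < 0) || any(m > 1))
    stop("confusion matrix entries must lie in [0, 1]", call. = FALSE)
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("confusion matrix rows must sum to 1 (max deviation %.3g)",
                 max(abs(rs - 1))), call. = FALSE)
  dimnames(m) <- list(0:6, 0:6)
  invisible(m)
}

#' Build an adjacency-weighted reader confusion matrix
#'
#' Every row has `accuracy` on the diagonal. For the ordinal severity
#' classes 0-4 the remaining mass `1 - accuracy` is split: a fraction
#' `adjacency_weight` goes (evenly) to the severity-adjacent classes within
#' 0-4, and the remainder is spread uniformly over all other classes. The
#' non-ordinal classes 5 (other fundus diseases) and 6 (ungradable) have no
#' severity neighbours, so their off-diagonal mass is uniform. This error
#' structure reflects the clinical observation that graders most often
#' confuse neighbouring severities (e.g. microaneurysms of mild NPDR with
#' the blot hemorrhages of moderate NPDR).
#'
#' @param accuracy Probability of a correct assignment, identical across
#'   classes; the confusion-matrix diagonal.
#' @param adjacency_weight Fraction of the error mass placed on
#'   severity-adjacent classes (default 0.7).
#' @return A validated 7x7 row-stochastic matrix.
#' @export
#' @examples
#' round(adjacent_confusion(0.8, 1)["3", ], 3)  # mass only on 2, 3, 4
adjacent_confusion <- function(accuracy, adjacency_weight = 0.7) {
  if (!is.numeric(accuracy) || length(accuracy) != 1L || is.na(accuracy) ||
      accuracy < 0 || accuracy > 1)
    stop("accuracy must be a probability in [0, 1]", call. = FALSE)
  if (!is.numeric(adjacency_weight) || length(adjacency_weight) != 1L ||
      is.na(adjacency_weight) || adjacency_weight < 0 || adjacency_weight > 1)
    stop("adjacency_weight must be a probability in [0, 1]", call. = FALSE)
  m <- matrix(0, 7L, 7L, dimnames = list(0:6, 0:6))
  err <- 1 - accuracy
  for (i in 0:6) {
    m[i + 1L, i + 1L] <- accuracy
    adj <- if (i <= 4L) intersect(c(i - 1L, i + 1L), 0:4) else integer(0)
    rest <- setdiff(0:6, c(i, adj))
    if (length(adj)) {
      m[i + 1L, adj + 1L] <- err * adjacency_weight / length(adj)
      m[i + 1L, rest + 1L] <- err * (1 - adjacency_weight) / length(rest)
    } else {
      m[i + 1L, rest + 1L] <- err / length(rest)
    }
  }
  validate_confusion(m)
  m
}

# Draw one assigned class per element of true_classes from the matching
# confusion row, using the current RNG stream (one uniform per draw).
draw_labels <- function(confusion, true_classes) {
  validate_confusion(confusion)
  cum <- t(apply(confusion, 1L, cumsum))
  cum[, 7L] <- 1
  u <- stats::runif(length(true_classes))
  as.integer(rowSums(u > cum[true_classes + 1L, , drop = FALSE]))
}
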