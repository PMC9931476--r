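# Seven-class DR severity scheme:
#   0 no apparent DR, 1 mild NPDR, 2 moderate NPDR, 3 severe NPDR,
#   4 PDR, 5 other fundus diseases, 6 ungradable image.

#' Admissible DR class codes
#'
#' Integer codes of the seven-class diabetic-retinopathy grading scheme:
#' 0 = no apparent DR, 1 = mild NPDR, 2 = moderate NPDR, 3 = severe NPDR,
#' 4 = PDR, 5 = other fundus diseases, 6 = ungradable image.
#'
#' @export
dr_classes <- function() 0:6

#' Human-readable labels for the seven DR classes
#' @return Named character vector keyed by class code.
#' @export
dr_class_labels <- function() {
  c(`0` = "no apparent DR", `1` = "mild NPDR", `2` = "moderate NPDR",
    `3` = "severe NPDR", `4` = "PDR", `5` = "other fundus diseases",
    `6` = "ungradable")
}

# Validate and coerce class codes; NA allowed only when `allow_na`.
validate_class <- function(x, what = "class code", allow_na = FALSE) {
  xi <- suppressWarnings(as.integer(x))
  bad_na <- is.na(xi) & !(allow_na & is.na(x))
  if (any(bad_na) || any(!is.na(xi) & !(xi %in% 0:6))) {
    bad <- unique(x[bad_na | (!is.na(xi) & !(xi %in% 0:6))])
    stop(sprintf("invalid %s: %s (admissible codes are 0-6)",
                 what, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  xi
}

#' Map a DR class to its referral decision
#'
#' Moderate NPDR, severe NPDR and PDR (classes 2-4) are referrable; no
#' apparent DR, mild NPDR, other fundus diseases and ungradable images
#' (classes 0, 1, 5, 6) are nonreferrable.
#'
#' @param class Vector of integer class codes in 0-6.
#' @return Logical vector, `TRUE` for referrable classes.
#' @export
#' @examples
#' to_referrable(0:6)
to_referrable <- function(class) {
  cls <- validate_class(class)
  cls %in% 2:4
}

#' Classes counted as referrable / nonreferrable
#' @export
referrable_classes <- function() 2:4

#' @rdname referrable_classes
#' @export
nonreferrable_classes <- function() c(0:1, 5:6)
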