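#' Ordered meiotic stage series
#'
#' The pipeline follows a synchronized meiotic time course through an ordered
#' series of stages. The default series is vegetative growth (`V`),
#' pre-meiotic (`P`), pachytene (`T0`) and six subsequent time points
#' (`T1`--`T6`) through meiotic exit. Every stage-aware computation (stage-pair
#' correlations, activation intervals, pulse windows) orients itself by the
#' ranks defined here.
#'
#' @param labels Character vector of unique stage labels in temporal order.
#'   At least two stages are required.
#'
#' @return A `stage_series` object: a character vector of labels with 0-based
#'   ranks available through [stage_rank()].
#' @examples
#' st <- stage_series()
#' stage_rank(st, c("V", "T0"))
#' @export
stage_series <- function(labels = c("V", "P", "T0", "T1", "T2", "T3", "T4", "T5", "T6")) {
  labels <- as.character(labels)
  if (length(labels) < 2) stop("a stage series needs at least 2 stages", call. = FALSE)
  if (anyDuplicated(labels)) stop("stage labels must be unique", call. = FALSE)
  if (any(is.na(labels) | labels == "")) stop("stage labels must be non-empty", call. = FALSE)
  structure(labels, class = "stage_series")
}

#' @export
print.stage_series <- function(x, ...) {
  cat("<stage_series> ", paste(unclass(x), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' 0-based rank of stage labels within a series
#'
#' @param stages A [stage_series()].
#' @param labels Stage labels to rank.
#' @return Integer vector of 0-based ranks; unknown labels raise an error.
#' @export
stage_rank <- function(stages, labels) {
  idx <- match(as.character(labels), unclass(stages))
  if (anyNA(idx)) {
    stop("unknown stage label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx - 1L
}

#' Check stage labels against a series
#' @noRd
assert_stages <- function(stages, labels, what = "stage") {
  bad <- setdiff(unique(as.character(labels)), unclass(stages))
  if (length(bad) > 0) {
    stop("unknown ", what, " label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Consecutive stage intervals of a series
#'
#' @param stages A [stage_series()].
#' @return A tibble with columns `from`, `to` (stage labels) and `interval`
#'   (label of the form `"P->T0"`), one row per consecutive pair.
#' @export
stage_intervals <- function(stages) {
  lab <- unclass(stages)
  tibble::tibble(
    from = lab[-length(lab)],
    to = lab[-1],
    interval = paste0(lab[-length(lab)], "->", lab[-1])
  )
}
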