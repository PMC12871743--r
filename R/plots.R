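#' Plot reactivity profiles of one transcript across stages
#'
#' Per-nucleotide reactivity traces, one facet per stage, with missing
#' positions left blank. Comparing an early against a late stage makes
#' one-way reactivity loss (the dsRNA signature) directly visible.
#'
#' @param reactivity Long reactivity tibble.
#' @param transcript Transcript id to plot.
#' @param stages A [stage_series()]; also fixes facet order.
#' @param which_stages Optional subset of stage labels.
#' @return A ggplot object.
#' @export
plot_reactivity_profile <- function(reactivity, transcript,
                                    stages = stage_series(),
                                    which_stages = NULL) {
  tbl <- reactivity[reactivity$transcript_id == transcript, , drop = FALSE]
  if (nrow(tbl) == 0) stop("unknown transcript: ", transcript, call. = FALSE)
  if (!is.null(which_stages)) {
    assert_stages(stages, which_stages)
    tbl <- tbl[tbl$stage %in% which_stages, , drop = FALSE]
  }
  tbl$stage <- factor(tbl$stage, levels = unclass(stages))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$position, y = .data$reactivity)) +
    ggplot2::geom_col(width = 1, fill = "steelblue", na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stage)) +
    ggplot2::labs(x = "position (nt)", y = "DMS reactivity",
                  title = transcript) +
    ggplot2::theme_minimal()
}

#' Plot antisense read-ratio trajectories
#'
#' @param ratio Tibble from [antisense_ratio()].
#' @param genes Gene ids to plot.
#' @param stages A [stage_series()].
#' @param background Optional horizontal reference at the background
#'   antisense ratio (default 0.15; `NULL` to omit).
#' @return A ggplot object.
#' @export
plot_antisense_ratio <- function(ratio, genes, stages = stage_series(),
                                 background = 0.15) {
  tbl <- ratio[ratio$gene_id %in% genes, , drop = FALSE]
  if (nrow(tbl) == 0) stop("no matching genes", call. = FALSE)
  tbl$stage <- factor(tbl$stage, levels = unclass(stages))
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$stage, y = .data$ratio,
                                         group = .data$gene_id,
                                         colour = .data$gene_id)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "stage", y = "antisense read ratio") +
    ggplot2::theme_minimal()
  if (!is.null(background)) {
    p <- p + ggplot2::geom_hline(yintercept = background, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' Autoplot a structure screen
#'
#' The cohort view of the screen: minimum stage-pair correlation against
#' maximal median reactivity difference per transcript, with the screen
#' cutoffs drawn as reference lines. Unidirectional (dsRNA-candidate)
#' transcripts separate to the upper left.
#'
#' @param object A `structure_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_screen <- function(object, ...) {
  tbl <- object$summaries[!is.na(object$summaries$min_r) &
                            !is.na(object$summaries$max_delta_median), ]
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$min_r,
                                         y = .data$max_delta_median,
                                         colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$delta_cutoff,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "minimum stage-pair r",
                  y = "max median ΔDMS (earlier - later)",
                  colour = "class") +
    ggplot2::theme_minimal()
  for (cut in object$r_cutoffs) {
    p <- p + ggplot2::geom_vline(xintercept = cut, linetype = "dotted",
                                 colour = "grey40")
  }
  p
}
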