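# Static two-panel depiction of breakpoint-spanning reads: primary
# alignments of the queried region on top, their linked partner alignments
# within the partner window below.  Forward/reverse alignments are coloured
# differently and the clipped (unaligned) extent of each record is drawn
# pale, mirroring how columns of co-terminating split reads are inspected.

#' Two-panel plot of primary and linked partner alignments
#'
#' @param split_reads Linked segment tibble ([link_split_reads()]).
#' @param region The queried region (list or string); primaries overlapping
#'   it are drawn in the upper panel.
#' @param secondary_region Optional partner region for the lower panel; when
#'   `NULL`, all partner segments of the upper-panel reads are shown.
#' @return A `ggplot` object.
#' @export
plot_breakpoint_panels <- function(split_reads, region,
                                   secondary_region = NULL) {
  if (is.character(region)) region <- parse_region(region)
  sr <- split_reads
  prim <- sr %>%
    filter(.data$role == "primary", .data$chrom == region$chrom,
           .data$ref_end > region$start, .data$ref_start < region$end) %>%
    mutate(panel = "primary alignments")
  partners <- sr %>%
    filter(.data$read_id %in% prim$read_id, .data$role != "primary")
  if (!is.null(secondary_region)) {
    if (is.character(secondary_region)) {
      secondary_region <- parse_region(secondary_region)
    }
    partners <- partners %>%
      filter(.data$chrom == secondary_region$chrom,
             .data$ref_end > secondary_region$start,
             .data$ref_start < secondary_region$end)
  }
  partners <- partners %>% mutate(panel = "linked partner alignments")
  dat <- bind_rows(prim, partners)
  if (!nrow(dat)) abort("nothing to plot", class = "splitsv_input_error")
  dat <- dat %>%
    group_by(.data$panel) %>%
    arrange(.data$ref_start) %>%
    mutate(y = as.integer(factor(.data$read_id, levels = unique(.data$read_id)))) %>%
    ungroup() %>%
    mutate(
      clip_left = .data$ref_start - .data$read_start,
      clip_right = .data$ref_end + (.data$read_len - .data$read_end),
      panel = factor(.data$panel, levels = c("primary alignments",
                                             "linked partner alignments"))
    )
  ggplot2::ggplot(dat) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$clip_left, xmax = .data$clip_right,
                   ymin = .data$y - 0.35, ymax = .data$y + 0.35,
                   fill = .data$strand),
      alpha = 0.25
    ) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$ref_start, xmax = .data$ref_end,
                   ymin = .data$y - 0.35, ymax = .data$y + 0.35,
                   fill = .data$strand)
    ) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free") +
    ggplot2::scale_fill_manual(values = c(`+` = "darkgreen", `-` = "firebrick"),
                               name = "strand") +
    ggplot2::labs(x = "reference position (bp)", y = "read") +
    ggplot2::theme_minimal()
}

#' @rdname plot_breakpoint_panels
#' @param object An `sv_columns` object.
#' @param ... Unused.
#' @export
autoplot.sv_columns <- function(object, ...) {
  cols <- object$columns
  ggplot2::ggplot(cols,
                  ggplot2::aes(x = .data$position, y = .data$support)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "reference position (bp)", y = "supporting junction ends",
                  title = "columns of co-terminating split reads") +
    ggplot2::theme_minimal()
}

#' ASCII fallback rendering of the two panels
#'
#' @param split_reads Linked segment tibble.
#' @param region Queried region.
#' @param width Character width of the rendering.
#' @return A character vector of text lines (also printed).
#' @export
render_text <- function(split_reads, region, width = 80L) {
  if (is.character(region)) region <- parse_region(region)
  span <- region$end - region$start
  scale <- function(x) {
    pmin(width, pmax(1L, 1L + as.integer((x - region$start) / span * (width - 1L))))
  }
  prim <- split_reads %>%
    filter(.data$role == "primary", .data$chrom == region$chrom,
           .data$ref_end > region$start, .data$ref_start < region$end)
  lines <- c(
    sprintf("%s:%d-%d (%d primary alignment(s))", region$chrom,
            region$start + 1, region$end, nrow(prim))
  )
  for (i in seq_len(min(nrow(prim), 40L))) {
    row <- rep(".", width)
    a <- scale(prim$ref_start[i]); b <- scale(prim$ref_end[i])
    row[a:b] <- if (prim$strand[i] == "+") ">" else "<"
    lines <- c(lines, paste(row, collapse = ""))
  }
  writeLines(lines)
  invisible(lines)
}
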