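#' Collect large CIGAR-encoded indels from a region
#'
#' Scans the primary alignments overlapping a region for insertions and
#' deletions longer than `min_len` encoded in their CIGAR strings, and
#' groups records of the same kind whose reference spans overlap (single
#' linkage), so that the same event reported by several reads lands in one
#' group.  An insertion's grouping interval extends `length` bases from its
#' position, which absorbs the per-read placement jitter of long insertions.
#'
#' @param bam_path Indexed BAM file.
#' @param region Region string or list (see [read_alignments()]).
#' @param min_len Report I/D operations strictly longer than this (bp).
#' @param min_mapq Minimum mapping quality.
#' @return A tibble of indel records with a `group_id` column; one group per
#'   putative event.
#' @export
collect_gapped <- function(bam_path, region, min_len = 10L, min_mapq = 0L) {
  segs <- read_alignments(bam_path, region, min_mapq = min_mapq)
  segs <- segs %>% filter(.data$role == "primary")
  indels <- scan_cigar_indels(segs, min_len = min_len)
  group_gapped(indels)
}

# single-linkage grouping of indel records per (chrom, kind) on interval
# overlap; exported building block so in-memory records can be grouped too
#' @rdname collect_gapped
#' @param indels An indel tibble from [scan_cigar_indels()].
#' @export
group_gapped <- function(indels) {
  if (!nrow(indels)) return(indels %>% mutate(group_id = integer()))
  indels <- indels %>%
    mutate(
      .gstart = .data$ref_start,
      .gend = pmax(.data$ref_end, .data$ref_start + .data$length)
    ) %>%
    arrange(.data$ref_chrom, .data$kind, .data$.gstart, .data$.gend)
  grouped <- indels %>%
    group_by(.data$ref_chrom, .data$kind) %>%
    mutate(
      .reach = cummax(lag(.data$.gend, default = -1L)),
      .new = .data$.gstart >= .data$.reach,
      .chain = cumsum(.data$.new)
    ) %>%
    ungroup()
  key <- paste(grouped$ref_chrom, grouped$kind, grouped$.chain)
  grouped %>%
    mutate(group_id = as.integer(factor(key, levels = unique(key)))) %>%
    select(-".gstart", -".gend", -".reach", -".new", -".chain") %>%
    arrange(.data$group_id)
}

#' Call structural indels from grouped gapped alignments
#'
#' Feeds each group of co-located same-kind indel records to
#' [annotate_gapped()].  Groups below `min_support` are not dropped: they
#' are emitted flagged `low_confidence`.
#'
#' @param groups Grouped indel tibble from [collect_gapped()].
#' @param min_support Reads required for a confident call (default 2).
#' @return An `sv_calls` tibble, one row per group (possibly empty).  Only
#'   insertions and deletions can arise from this path.
#' @export
call_gapped <- function(groups, min_support = 2L) {
  if (!nrow(groups)) return(empty_calls())
  calls <- groups %>%
    group_by(.data$group_id) %>%
    group_split() %>%
    map(function(g) {
      withCallingHandlers(
        annotate_gapped(g, min_support = min_support),
        splitsv_support_warning = function(w) invokeRestart("muffleWarning")
      )
    })
  out <- list_rbind(calls)
  class(out) <- c("sv_calls", setdiff(class(out), "sv_calls"))
  out
}
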