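#' Detect breakpoints in a region
#'
#' Runs the detection stages (alignment extraction, split-read linkage,
#' junction extraction, clustering, column building) over one region.
#'
#' @param bam_path Indexed BAM file.
#' @param region Region string or list.
#' @param config An [sv_config()].
#' @return A list: `segments`, `split_reads`, `junctions`, `clusters`,
#'   `columns` (an `sv_columns`).
#' @export
sv_detect <- function(bam_path, region, config = sv_config()) {
  segments <- read_alignments(bam_path, region, min_mapq = config$min_mapq,
                              block_limit = config$block_limit)
  split_reads <- link_split_reads(segments, overlap_tol = config$overlap_tol)
  junctions <- extract_junctions(split_reads)
  clusters <- cluster_junctions(junctions, window = config$window,
                                min_support = config$min_support)
  columns <- build_columns(clusters, junctions, window = config$window)
  list(segments = segments, split_reads = split_reads, junctions = junctions,
       clusters = clusters, columns = columns)
}

#' Call and annotate the rearrangement evidenced in a region
#'
#' The automatic pathway: detect breakpoints, compute the split-read
#' signature anchored at them, classify it against the expected pattern
#' table, and annotate with consensus coordinates.  The user-guided
#' pathways ([annotate_simple()], [annotate_complex()]) remain available
#' for selections the automatic route cannot resolve.
#'
#' @param bam_path Indexed BAM file.
#' @param region Region string or list.
#' @param config An [sv_config()].
#' @return An `sv_calls` tibble (zero rows when no supported breakpoint is
#'   found), with the signature, columns and clusters attached as
#'   attributes.
#' @export
sv_call <- function(bam_path, region, config = sv_config()) {
  det <- sv_detect(bam_path, region, config)
  if (!nrow(det$clusters)) {
    out <- empty_calls()
    attr(out, "detection") <- det
    return(out)
  }
  complexity <- assess_complexity(det$columns, window = config$window)
  sig <- compute_signature(det$split_reads, det$clusters,
                           window = config$window,
                           min_pattern_reads = config$min_pattern_reads,
                           min_pattern_prop = config$min_pattern_prop)
  cls <- classify_signature(sig, window = config$window)
  call <- call_from_classification(cls, sig)
  call$hgvs <- render_hgvs(call)
  if (call$type == "complex_insertion_deletion" &&
      is.na(call$description)) {
    call$description <- complex_description(call)
  }
  attr(call, "detection") <- det
  attr(call, "signature") <- sig
  attr(call, "complexity") <- as.character(complexity)
  attr(call, "per_read") <- sig$junctions
  call
}

#' @export
print.sv_calls <- function(x, ...) {
  cat("<sv_calls> ", nrow(x), " call(s)\n", sep = "")
  if (nrow(x)) {
    show <- x %>%
      mutate(alternatives = map_chr(.data$alternatives,
                                    function(a) paste(a, collapse = ","))) %>%
      select("type", "alternatives", "chrom_a", "pos_a", "chrom_b", "pos_b",
             "support", "hgvs")
    print(tibble::as_tibble(show), ...)
  }
  invisible(x)
}
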