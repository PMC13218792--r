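#' Run configuration
#'
#' Bundles the tunable parameters of the detection/annotation workflow.
#' Defaults follow the published workflow: junction ends within 250 nt with
#' support from at least 2 reads define a putative breakpoint, the partner
#' locus is inspected in a 50 kb half-width window, regions are screened in
#' blocks of at most 10 Mb, and gapped-alignment indels shorter than 10 bp
#' are ignored.
#'
#' @param window Clustering window in nucleotides for junction ends.
#' @param min_support Minimum number of junction ends supporting a breakpoint.
#' @param secondary_half_width Half-width of the partner-locus window (bp).
#' @param block_limit Maximum queryable region size (bp).
#' @param indel_min_len Minimum CIGAR I/D length (exclusive) reported by the
#'   gapped path.
#' @param min_mapq Minimum mapping quality for alignments; 0 keeps everything
#'   (review of the evidence replaces hard filtering).
#' @param overlap_tol Maximum tolerated overlap (bp) between the read spans of
#'   consecutive segments of a split read; larger overlaps mark the read
#'   inconsistent.
#' @param min_pattern_reads,min_pattern_prop A junction pattern must be seen in
#'   at least this many reads and this fraction of selected reads to enter
#'   classification; minority patterns are reported but not used.
#' @param read_len,step Faux-read length and tiling interval for the simulator.
#' @param seed Optional integer seed forwarded to stochastic helpers.
#' @return A list of class `sv_config`.
#' @export
#' @examples
#' cfg <- sv_config(min_mapq = 20)
#' cfg$window
sv_config <- function(window = 250L,
                      min_support = 2L,
                      secondary_half_width = 50000L,
                      block_limit = 10000000L,
                      indel_min_len = 10L,
                      min_mapq = 0L,
                      overlap_tol = 200L,
                      min_pattern_reads = 2L,
                      min_pattern_prop = 0.10,
                      read_len = 10000L,
                      step = 1000L,
                      seed = NULL) {
  cfg <- list(
    window = as.integer(window),
    min_support = as.integer(min_support),
    secondary_half_width = as.integer(secondary_half_width),
    block_limit = as.integer(block_limit),
    indel_min_len = as.integer(indel_min_len),
    min_mapq = as.integer(min_mapq),
    overlap_tol = as.integer(overlap_tol),
    min_pattern_reads = as.integer(min_pattern_reads),
    min_pattern_prop = as.numeric(min_pattern_prop),
    read_len = as.integer(read_len),
    step = as.integer(step),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  nums <- cfg[!vapply(cfg, is.null, logical(1))]
  bad <- names(nums)[vapply(nums, function(x) !is.finite(x), logical(1))]
  if (length(bad)) {
    abort(paste0("non-finite configuration value(s): ", paste(bad, collapse = ", ")),
          class = "splitsv_config_error")
  }
  positive <- c("window", "min_support", "secondary_half_width", "block_limit",
                "indel_min_len", "min_pattern_reads", "read_len", "step")
  bad <- positive[vapply(cfg[positive], function(x) x <= 0L, logical(1))]
  if (length(bad)) {
    abort(paste0("configuration value(s) must be positive: ", paste(bad, collapse = ", ")),
          class = "splitsv_config_error")
  }
  structure(cfg, class = "sv_config")
}

#' Parse a region string
#'
#' Accepts `"chrom:start-end"` with 1-based inclusive coordinates (the CLI
#' convention) and converts to the 0-based half-open interval used
#' internally. Commas in numbers are tolerated.
#'
#' @param x A region string such as `"chr7:146500000-146700000"`.
#' @return A list with `chrom`, `start`, `end` (0-based half-open).
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4L) {
    abort(paste0("cannot parse region '", x, "'; expected chrom:start-end"),
          class = "splitsv_region_error")
  }
  start1 <- as.numeric(gsub(",", "", m[3], fixed = TRUE))
  end1 <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
  if (!is.finite(start1) || !is.finite(end1) || start1 < 1 || end1 < start1) {
    abort(paste0("invalid region coordinates in '", x, "'"),
          class = "splitsv_region_error")
  }
  list(chrom = m[2], start = start1 - 1, end = end1)
}

# region constructor/validator used by the BAM layer.  0-based half-open.
region_query <- function(chrom, start, end, block_limit = 10000000L) {
  if (!(is.character(chrom) && length(chrom) == 1L)) {
    abort("region chrom must be a single string", class = "splitsv_region_error")
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end) {
    abort("region requires 0 <= start < end", class = "splitsv_region_error")
  }
  if (end - start > block_limit) {
    abort(paste0("region size ", format(end - start, big.mark = ","),
                 " exceeds the block limit of ",
                 format(block_limit, big.mark = ","), " bp"),
          class = "splitsv_region_error")
  }
  list(chrom = chrom, start = start, end = end)
}

# Lower median: the middle value, taking the smaller of the two central
# values for even n.  Used for every consensus coordinate in the package.
median_lo <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sort(x)[ceiling(length(x) / 2)]
}

flip_strand <- function(s) chartr("+-", "-+", s)

# One machine-readable log line per pipeline stage (JSON on message stream).
log_stage <- function(stage, ...) {
  fields <- list(...)
  rec <- c(list(stage = stage), fields)
  inform(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
         class = "splitsv_log")
  invisible(rec)
}
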