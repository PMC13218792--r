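# CIGAR geometry helpers.
#
# All read coordinates in this package are expressed on the original read's
# forward orientation (the strand the sequencer emitted), so that the
# segments of a split read can be ordered along the read regardless of which
# strand each local alignment used.  For a '+' alignment the read offset of
# the first aligned base is the leading clip; for a '-' alignment it is the
# trailing clip (the aligner stores the reverse complement).  Hard and soft
# clips are treated identically: supplementary records are frequently
# hard-clipped and both operations consume original-read bases.

# Per-record clip/width table: left_clip, right_clip (in CIGAR order),
# aligned query width (M/I/=/X) and implied total read length.
cigar_geometry <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  geom <- map2(ops, lens, function(op, len) {
    clip <- op %in% c("S", "H")
    n <- length(op)
    left <- 0L
    i <- 1L
    while (i <= n && clip[i]) { left <- left + len[i]; i <- i + 1L }
    right <- 0L
    j <- n
    while (j >= i && clip[j]) { right <- right + len[j]; j <- j - 1L }
    aligned <- sum(len[op %in% c("M", "I", "=", "X")])
    c(left = left, right = right, aligned = aligned)
  })
  tibble(
    left_clip = map_int(geom, function(g) as.integer(g[["left"]])),
    right_clip = map_int(geom, function(g) as.integer(g[["right"]])),
    aligned = map_int(geom, function(g) as.integer(g[["aligned"]])),
    ref_width = GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  )
}

# Read-coordinate span (original-read forward orientation), 0-based half-open.
read_span <- function(cigar, strand) {
  g <- cigar_geometry(cigar)
  lead_clip <- ifelse(strand == "+", g$left_clip, g$right_clip)
  tibble(
    read_start = as.integer(lead_clip),
    read_end = as.integer(lead_clip + g$aligned),
    read_len = as.integer(g$left_clip + g$aligned + g$right_clip),
    ref_width = as.integer(g$ref_width)
  )
}

#' Scan CIGAR strings for large insertions and deletions
#'
#' Walks each alignment's CIGAR and reports every insertion (`I`) or deletion
#' (`D`) operation strictly longer than `min_len`.  Some long-read aligners
#' encode a structural variant inside a single gapped alignment rather than
#' splitting the read, and this is the entry point of that calling path.
#'
#' @param segments A segment tibble as returned by [read_alignments()] (one
#'   row per local alignment; requires `read_id`, `chrom`, `ref_start`,
#'   `strand` and `cigar` columns).  A single CIGAR string is also accepted,
#'   in which case a minimal one-row segment is fabricated at reference
#'   position 0.
#' @param min_len Only operations with length strictly greater than this are
#'   reported (default 10 bp, the display threshold of the original tool).
#' @return A tibble with one row per qualifying indel: `read_id`, `kind`
#'   (`"insertion"`/`"deletion"`), `ref_chrom`, `ref_start`, `ref_end`
#'   (0-based half-open; equal for insertions), `length`, and the indel's
#'   coordinates on the aligned query (`query_start`, `query_end`).
#' @export
#' @examples
#' scan_cigar_indels("100M25D100M")
scan_cigar_indels <- function(segments, min_len = 10L) {
  if (is.character(segments)) {
    segments <- tibble(
      read_id = paste0("cigar", seq_along(segments)),
      chrom = "unknown", ref_start = 0L, strand = "+", cigar = segments
    )
  }
  stopifnot(all(c("read_id", "chrom", "ref_start", "strand", "cigar") %in%
                  names(segments)))
  rows <- pmap(
    list(segments$read_id, segments$chrom, segments$ref_start, segments$cigar),
    function(read_id, chrom, ref_start, cigar) {
      op <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
      len <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
      ref_consume <- op %in% c("M", "D", "N", "=", "X")
      qry_consume <- op %in% c("M", "I", "S", "=", "X")
      ref_at <- ref_start + c(0L, cumsum(len * ref_consume))[seq_along(op)]
      qry_at <- c(0L, cumsum(len * qry_consume))[seq_along(op)]
      hit <- (op %in% c("I", "D")) & len > min_len
      if (!any(hit)) return(NULL)
      tibble(
        read_id = read_id,
        kind = ifelse(op[hit] == "I", "insertion", "deletion"),
        ref_chrom = chrom,
        ref_start = as.integer(ref_at[hit]),
        ref_end = as.integer(ref_at[hit] + ifelse(op[hit] == "D", len[hit], 0L)),
        length = as.integer(len[hit]),
        query_start = as.integer(qry_at[hit]),
        query_end = as.integer(qry_at[hit] + ifelse(op[hit] == "I", len[hit], 0L))
      )
    }
  )
  out <- list_rbind(compact(rows))
  if (!nrow(out)) {
    out <- tibble(
      read_id = character(), kind = character(), ref_chrom = character(),
      ref_start = integer(), ref_end = integer(), length = integer(),
      query_start = integer(), query_end = integer()
    )
  }
  out
}
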