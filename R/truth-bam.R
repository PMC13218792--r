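# Analytically exact truth alignments.
#
# Each faux read's alignment to the ORIGINAL reference is computed by
# intersecting its source window on the rearranged contig with the
# coordinate-map pieces.  The longest chunk becomes the primary record
# (soft-clipped, with sequence); the remaining chunks become supplementary
# records (hard-clipped, SEQ "*"), all cross-referenced through SA tags.
# This replaces an external aligner for hermetic testing: on error-free
# reads a real long-read aligner produces the same geometry.

# chunk table for one read against its contig's (possibly extended) pieces
read_chunks <- function(offset, len, orientation, pieces) {
  plen <- pieces$ref_end - pieces$ref_start
  poff <- cumsum(c(0L, plen))[seq_len(nrow(pieces))]
  o2 <- offset + len
  keep <- which(poff < o2 & (poff + plen) > offset)
  if (!length(keep)) {
    abort("read window not derivable from the coordinate map",
          class = "splitsv_spec_error")
  }
  rows <- map(keep, function(i) {
    cs <- max(offset, poff[i])
    ce <- min(o2, poff[i] + plen[i])
    w <- ce - cs
    if (pieces$orientation[i] == "+") {
      rs <- pieces$ref_start[i] + (cs - poff[i])
      re <- rs + w
    } else {
      re <- pieces$ref_end[i] - (cs - poff[i])
      rs <- re - w
    }
    read_start <- if (orientation == "+") cs - offset else len - (ce - offset)
    # orientation algebra: flipping either the piece or the read flips the
    # alignment strand; flipping both restores it
    strand <- if (pieces$orientation[i] == orientation) "+" else "-"
    tibble(
      chrom = pieces$ref_chrom[i],
      ref_start = as.integer(rs), ref_end = as.integer(re),
      strand = strand,
      read_start = as.integer(read_start),
      read_end = as.integer(read_start + w)
    )
  })
  list_rbind(rows) %>% arrange(.data$read_start)
}

chunk_cigar <- function(read_start, read_end, read_len, strand, clip_op,
                        mid = NULL) {
  lead <- if (strand == "+") read_start else read_len - read_end
  trail <- read_len - (read_end - read_start) - lead
  mid <- mid %||% paste0(read_end - read_start, "M")
  paste0(
    if (lead > 0L) paste0(lead, clip_op) else "",
    mid,
    if (trail > 0L) paste0(trail, clip_op) else ""
  )
}

#' Write exact truth alignments to a sorted, indexed BAM
#'
#' @param read_set Faux reads from [make_faux_reads()] (rows from several
#'   contigs may be combined; `contig` links each read to its map pieces).
#' @param map Coordinate-map tibble from [apply_rearrangement()].
#' @param ref_lengths Named vector of ORIGINAL reference contig lengths (BAM
#'   header).
#' @param bam_prefix Output path prefix; `<prefix>.bam` and `.bam.bai` are
#'   created.
#' @param circular Named logical per contig (ring contigs wrap).
#' @param representation `"split"` (primary + supplementary records linked by
#'   SA tags) or `"gapped"` (a single record per read with the event encoded
#'   as a CIGAR `D`/`I` operation; only meaningful for deletion and clean
#'   insertion geometries).
#' @param with_seq Write read sequences into primary records (needed to
#'   export supporting reads as FASTA from the BAM; turn off for bulk runs).
#' @return The BAM path, invisibly.
#' @export
truth_alignments <- function(read_set, map, ref_lengths, bam_prefix,
                             circular = NULL,
                             representation = c("split", "gapped"),
                             with_seq = TRUE) {
  representation <- match.arg(representation)
  stopifnot(nrow(read_set) > 0L, nrow(map) > 0L)
  contigs <- split(map, map$contig)
  read_len_attr <- attr(read_set, "read_len") %||% max(read_set$length)
  pieces_of <- map(contigs, function(m) {
    m <- m %>% arrange(.data$piece)
    circ <- isTRUE((circular %||% logical())[m$contig[1]])
    if (circ) m <- bind_rows(m, m)  # wrap windows across the ring junction
    m
  })
  lines <- map(seq_len(nrow(read_set)), function(i) {
    r <- read_set[i, ]
    pieces <- pieces_of[[r$contig]]
    if (is.null(pieces)) {
      abort(paste0("read contig '", r$contig, "' absent from map"),
            class = "splitsv_spec_error")
    }
    ch <- read_chunks(r$offset, r$length, r$orientation, pieces)
    if (representation == "gapped" && nrow(ch) > 1L) {
      return(gapped_sam_line(r, ch, with_seq))
    }
    prim <- which.max(ch$read_end - ch$read_start)
    n <- nrow(ch)
    cigars <- map_chr(seq_len(n), function(k) {
      chunk_cigar(ch$read_start[k], ch$read_end[k], r$length, ch$strand[k],
                  if (k == prim) "S" else "H")
    })
    sa <- if (n > 1L) {
      map_chr(seq_len(n), function(k) {
        oth <- setdiff(seq_len(n), k)
        paste0(sprintf("%s,%d,%s,%s,60,0;", ch$chrom[oth],
                       ch$ref_start[oth] + 1L, ch$strand[oth], cigars[oth]),
               collapse = "")
      })
    } else rep(NA_character_, n)
    map_chr(seq_len(n), function(k) {
      flag <- (if (k == prim) 0L else 2048L) + (if (ch$strand[k] == "-") 16L else 0L)
      # SEQ is stored in alignment orientation
      seq_field <- if (k == prim && with_seq) {
        if (ch$strand[k] == "-") revcomp(r$seq) else r$seq
      } else "*"
      paste(
        r$read_id, flag, ch$chrom[k], ch$ref_start[k] + 1L, 60L, cigars[k],
        "*", 0L, 0L, seq_field, "*", "NM:i:0",
        if (!is.na(sa[k])) paste0("SA:Z:", sa[k]) else NULL,
        sep = "\t"
      )
    })
  })
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths))
  )
  writeLines(c(header, unlist(lines)), sam)
  bam <- Rsamtools::asBam(sam, bam_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  invisible(bam)
}

# Single gapped record per read: the chunks on the anchor chromosome/strand
# are walked in reference order (which is also ascending aligned-query
# order, for either strand); reference gaps between them become D
# operations and query gaps (bases from transposed chunks elsewhere) become
# I operations.
gapped_sam_line <- function(r, ch, with_seq) {
  widest <- which.max(ch$read_end - ch$read_start)
  anchor_chrom <- ch$chrom[widest]
  anchor_strand <- ch$strand[widest]
  anchor <- ch %>%
    filter(.data$chrom == anchor_chrom, .data$strand == anchor_strand) %>%
    arrange(.data$ref_start)
  if (nrow(anchor) < 1L) {
    abort("no anchor chunk; gapped representation impossible",
          class = "splitsv_spec_error")
  }
  # aligned-query coordinates of each chunk (alignment orientation)
  q_start <- if (anchor_strand == "+") anchor$read_start else
    r$length - anchor$read_end
  q_end <- if (anchor_strand == "+") anchor$read_end else
    r$length - anchor$read_start
  ops <- character()
  if (q_start[1] > 0L) ops <- c(ops, paste0(q_start[1], "S"))
  ops <- c(ops, paste0(q_end[1] - q_start[1], "M"))
  n <- nrow(anchor)
  if (n > 1L) {
    for (i in 2:n) {
      q_gap <- q_start[i] - q_end[i - 1L]
      ref_gap <- anchor$ref_start[i] - anchor$ref_end[i - 1L]
      if (q_gap < 0L || ref_gap < 0L) {
        abort("chunks not colinear; gapped representation impossible",
              class = "splitsv_spec_error")
      }
      if (q_gap > 0L) ops <- c(ops, paste0(q_gap, "I"))
      if (ref_gap > 0L) ops <- c(ops, paste0(ref_gap, "D"))
      ops <- c(ops, paste0(q_end[i] - q_start[i], "M"))
    }
  }
  if (r$length - q_end[n] > 0L) ops <- c(ops, paste0(r$length - q_end[n], "S"))
  cigar <- paste(ops, collapse = "")
  seq_field <- if (with_seq) {
    if (anchor_strand == "-") revcomp(r$seq) else r$seq
  } else "*"
  flag <- if (anchor_strand == "-") 16L else 0L
  paste(r$read_id, flag, anchor_chrom, anchor$ref_start[1] + 1L, 60L, cigar,
        "*", 0L, 0L, seq_field, "*", "NM:i:0", sep = "\t")
}
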