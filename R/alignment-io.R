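#' Read primary and supplementary alignments from an indexed BAM
#'
#' Extracts every primary and SA-linked supplementary record overlapping a
#' region and derives each record's span on the original read from its
#' CIGAR clips, so that the pieces of a split read can later be ordered
#' along the read.  True secondary records (flag 0x100) are excluded: with
#' the recommended aligner invocation the chimeric pieces of a split read
#' are emitted as supplementary alignments cross-referenced through the SA
#' tag, not as secondaries.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM file.
#' @param region A region: either a `"chrom:start-end"` string (1-based
#'   inclusive) or a list with `chrom`, `start`, `end` (0-based half-open).
#' @param min_mapq Minimum mapping quality (default 0: keep everything).
#' @param block_limit Maximum region size; larger queries are refused so that
#'   screening proceeds in bounded blocks.
#' @return A tibble of alignment segments with columns `read_id`, `chrom`,
#'   `ref_start`, `ref_end` (0-based half-open), `strand`, `read_start`,
#'   `read_end` (0-based on the original read's forward orientation),
#'   `read_len`, `mapq`, `role` (`"primary"`/`"supplementary"`), `cigar`,
#'   `sa` (raw SA tag or `NA`) and `synthesized` (always `FALSE` here).
#' @export
read_alignments <- function(bam_path, region, min_mapq = 0L,
                            block_limit = 10000000L) {
  if (!file.exists(bam_path)) {
    abort(paste0("BAM file not found: ", bam_path), class = "splitsv_input_error")
  }
  idx <- paste0(bam_path, ".bai")
  if (!file.exists(idx)) {
    idx2 <- sub("\\.bam$", ".bai", bam_path)
    if (file.exists(idx2)) idx <- idx2 else {
      abort(paste0("BAM index (.bai) not found for: ", bam_path),
            class = "splitsv_input_error")
    }
  }
  if (is.character(region)) region <- parse_region(region)
  region <- region_query(region$chrom, region$start, region$end, block_limit)

  targets <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (!region$chrom %in% names(targets)) {
    abort(paste0("chromosome '", region$chrom, "' absent from BAM header"),
          class = "splitsv_region_error")
  }
  chrom_len <- unname(targets[[region$chrom]])
  which <- GenomicRanges::GRanges(
    region$chrom,
    IRanges::IRanges(start = region$start + 1, end = min(region$end, chrom_len))
  )
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    tag = "SA",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    which = which
  )
  res <- Rsamtools::scanBam(Rsamtools::BamFile(bam_path, index = idx),
                            param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) return(empty_segments())
  sa <- res$tag$SA
  if (is.null(sa)) sa <- rep(NA_character_, n)
  segs <- tibble(
    read_id = res$qname,
    chrom = as.character(res$rname),
    ref_start = as.integer(res$pos - 1L),
    strand = as.character(res$strand),
    mapq = as.integer(res$mapq),
    role = ifelse(bitwAnd(res$flag, 2048L) > 0L, "supplementary", "primary"),
    cigar = res$cigar,
    sa = as.character(sa)
  )
  span <- read_span(segs$cigar, segs$strand)
  segs <- segs %>%
    mutate(
      ref_end = .data$ref_start + span$ref_width,
      read_start = span$read_start,
      read_end = span$read_end,
      read_len = span$read_len,
      synthesized = FALSE
    ) %>%
    filter(.data$mapq >= min_mapq) %>%
    select(all_of(segment_cols()))
  segs
}

segment_cols <- function() {
  c("read_id", "chrom", "ref_start", "ref_end", "strand", "read_start",
    "read_end", "read_len", "mapq", "role", "cigar", "sa", "synthesized")
}

empty_segments <- function() {
  tibble(
    read_id = character(), chrom = character(), ref_start = integer(),
    ref_end = integer(), strand = character(), read_start = integer(),
    read_end = integer(), read_len = integer(), mapq = integer(),
    role = character(), cigar = character(), sa = character(),
    synthesized = logical()
  )
}

# Parse one SA tag ("rname,pos,strand,CIGAR,mapQ,NM;...") into segment rows.
# Malformed entries are skipped with a warning rather than failing the read.
parse_sa_tag <- function(read_id, sa) {
  entries <- strsplit(sa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  rows <- map(entries, function(e) {
    f <- strsplit(e, ",", fixed = TRUE)[[1]]
    ok <- length(f) == 6L && !is.na(suppressWarnings(as.integer(f[2]))) &&
      f[3] %in% c("+", "-") &&
      grepl("^([0-9]+[MIDNSHP=X])+$", f[4])
    if (!ok) {
      warn(paste0("skipping unparsable SA entry '", e, "' on read ", read_id),
           class = "splitsv_sa_warning")
      return(NULL)
    }
    span <- read_span(f[4], f[3])
    tibble(
      read_id = read_id,
      chrom = f[1],
      ref_start = as.integer(f[2]) - 1L,
      ref_end = as.integer(f[2]) - 1L + span$ref_width,
      strand = f[3],
      read_start = span$read_start,
      read_end = span$read_end,
      read_len = span$read_len,
      mapq = suppressWarnings(as.integer(f[5])),
      role = "supplementary",
      cigar = f[4],
      sa = NA_character_,
      synthesized = TRUE
    )
  })
  list_rbind(compact(rows))
}

#' Reconstruct split reads from alignment segments
#'
#' Groups segments by read, synthesizes any segment that is referenced in an
#' SA tag but fell outside the queried region, orders each read's segments by
#' their position on the original read, and checks that consecutive read
#' spans do not overlap by more than `overlap_tol` (long-read aligners emit
#' small overlaps at split points; gross overlaps indicate an inconsistent
#' chimeric alignment, and such reads are excluded from junction
#' extraction).
#'
#' @param segments Segment tibble from [read_alignments()].
#' @param overlap_tol Maximum tolerated read-span overlap between consecutive
#'   segments (bp).
#' @return The segment tibble augmented with `seg_index` (order along the
#'   read), `n_segs`, `total_read_length` and `consistent`, sorted by read
#'   and read offset.  Exactly one segment per read carries `role ==
#'   "primary"`.
#' @export
link_split_reads <- function(segments, overlap_tol = 200L) {
  if (!nrow(segments)) {
    return(segments %>%
             mutate(seg_index = integer(), n_segs = integer(),
                    total_read_length = integer(), consistent = logical()))
  }
  groups <- segments %>% group_by(.data$read_id) %>% group_split()
  out <- map(groups, function(g) {
    rid <- g$read_id[1]
    sa_rows <- NULL
    with_sa <- g %>% filter(!is.na(.data$sa))
    if (nrow(with_sa)) {
      sa_rows <- list_rbind(compact(
        map2(with_sa$read_id, with_sa$sa, parse_sa_tag)
      ))
    }
    if (!is.null(sa_rows) && nrow(sa_rows)) {
      # keep only SA entries with no matching observed segment
      key <- paste(g$chrom, g$ref_start, g$strand)
      sa_rows <- sa_rows %>%
        filter(!paste(.data$chrom, .data$ref_start, .data$strand) %in% key) %>%
        distinct(.data$chrom, .data$ref_start, .data$strand, .keep_all = TRUE)
      g <- bind_rows(g, sa_rows)
    }
    if (!any(g$role == "primary")) {
      # the primary fell outside the query and was synthesized from SA data;
      # promote the longest-aligned segment so the invariant holds
      widest <- which.max(g$read_end - g$read_start)
      g$role[widest] <- "primary"
    } else if (sum(g$role == "primary") > 1L) {
      # defensive: keep the longest primary, demote the rest
      prim <- which(g$role == "primary")
      keep <- prim[which.max((g$read_end - g$read_start)[prim])]
      g$role[setdiff(prim, keep)] <- "supplementary"
    }
    g <- g %>% arrange(.data$read_start, .data$read_end)
    ov <- c(0L, utils::head(g$read_end, -1) - utils::tail(g$read_start, -1))
    g %>% mutate(
      seg_index = row_number() - 1L,
      n_segs = n(),
      total_read_length = max(.data$read_len),
      consistent = max(ov) <= overlap_tol
    )
  })
  list_rbind(out) %>% arrange(.data$read_id, .data$seg_index)
}
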