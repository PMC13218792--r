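# Exporters.  Cluster tables and call reports are TSV; breakpoint pairs go
# to BEDPE (0-based half-open); VCF 4.2 output uses symbolic ALT records for
# intra-chromosomal events and BND breakend pairs for translocations and
# complex events; supporting reads can be saved as FASTA.

#' Export breakpoint clusters as TSV
#'
#' Columns: chrom, position (1-based), side, support, partner chrom/position
#' and the fraction of members whose partner lies on the same strand.
#'
#' @param clusters Cluster tibble from [cluster_junctions()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  out <- clusters %>%
    mutate(position = .data$position + 1L, partner_pos = .data$partner_pos + 1L) %>%
    select("cluster_id", "chrom", "position", "side", "support",
           "partner_chrom", "partner_pos", "partner_same_strand_frac")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Export calls as TSV
#'
#' @param calls An `sv_calls` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls %>%
    mutate(alternatives = map_chr(.data$alternatives,
                                  function(a) paste(a, collapse = ",")))
  readr::write_tsv(tibble::as_tibble(out), path)
  invisible(path)
}

#' Export calls as BEDPE
#'
#' One line per breakpoint pair: both single-base breakend intervals in
#' 0-based half-open convention, the annotation string as name, support as
#' score.
#'
#' @param calls An `sv_calls` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path) {
  rows <- calls %>%
    filter(!is.na(.data$bnd_a) & !is.na(.data$bnd_b)) %>%
    mutate(
      chrom1 = .data$chrom_a, start1 = .data$bnd_a, end1 = .data$bnd_a + 1L,
      chrom2 = .data$chrom_b, start2 = .data$bnd_b, end2 = .data$bnd_b + 1L,
      name = .data$hgvs, score = .data$support,
      strand1 = "+", strand2 = "+"
    ) %>%
    select("chrom1", "start1", "end1", "chrom2", "start2", "end2",
           "name", "score", "strand1", "strand2")
  readr::write_tsv(rows, path, col_names = FALSE)
  invisible(path)
}

#' Export calls as VCF 4.2 structural-variant records
#'
#' Deletions, duplications, inversions and insertions are written as
#' symbolic ALT records with `SVTYPE`, `END` and `SVLEN`; translocations and
#' complex insertion-deletions as paired BND breakends.
#'
#' @param calls An `sv_calls` tibble.
#' @param path Output file.
#' @param ref_lengths Named contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, ref_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=splitsv",
    if (!is.null(ref_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(ref_lengths),
              as.integer(ref_lengths)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"Annotation string\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- unlist(map(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    id <- sprintf("SV%03d", i)
    info_tail <- sprintf(";SUPPORT=%d;EVENT=%s", x$support,
                         gsub("[;\t ]", "_", x$hgvs))
    if (x$type %in% c("deletion", "tandem_duplication", "inversion")) {
      alt <- switch(x$type, deletion = "<DEL>",
                    tandem_duplication = "<DUP:TANDEM>", inversion = "<INV>")
      svlen <- x$bnd_b - x$bnd_a
      if (x$type == "deletion") svlen <- -svlen
      sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d%s",
              x$chrom_a, x$bnd_a, id, alt,
              toupper(substr(sub("tandem_", "", x$type), 1, 3)),
              x$bnd_b, svlen, info_tail)
    } else if (x$type == "insertion") {
      sprintf("%s\t%d\t%s\tN\t<INS>\t.\tPASS\tSVTYPE=INS;END=%d;SVLEN=%d%s",
              x$chrom_a, x$pos_a, id, x$pos_a, x$ins_len, info_tail)
    } else if (!is.na(x$bnd_a) && !is.na(x$bnd_b)) {
      a <- sprintf("%s\t%d\t%s_1\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND;MATEID=%s_2%s",
                   x$chrom_a, max(1L, x$pos_a), id, x$chrom_b,
                   max(1L, x$pos_b), id, info_tail)
      b <- sprintf("%s\t%d\t%s_2\tN\t]%s:%d]N\t.\tPASS\tSVTYPE=BND;MATEID=%s_1%s",
                   x$chrom_b, max(1L, x$pos_b), id, x$chrom_a,
                   max(1L, x$pos_a), id, info_tail)
      c(a, b)
    } else {
      NULL
    }
  }))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Save supporting read sequences as FASTA
#'
#' @param read_set An `sv_readset` tibble (or any tibble with `read_id` and
#'   `seq`).
#' @param read_ids Which reads to export (default: all).
#' @param path Output FASTA.
#' @return `path`, invisibly.
#' @export
write_supporting_fasta <- function(read_set, path, read_ids = NULL) {
  keep <- if (is.null(read_ids)) read_set else
    read_set %>% filter(.data$read_id %in% read_ids)
  if (!nrow(keep)) abort("no reads to export", class = "splitsv_input_error")
  seqs <- Biostrings::DNAStringSet(setNames(keep$seq, keep$read_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write simulator ground truth (JSON manifest + BEDPE)
#'
#' @param truth Truth tibble rows from [apply_rearrangement()].
#' @param prefix Output prefix; `<prefix>.truth.json` and
#'   `<prefix>.truth.bedpe` are written.
#' @return The manifest path, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  json <- paste0(prefix, ".truth.json")
  jsonlite::write_json(truth, json, auto_unbox = FALSE, digits = NA,
                       na = "null")
  bedpe <- truth %>%
    filter(!is.na(.data$bnd_a) & !is.na(.data$bnd_b)) %>%
    mutate(start1 = .data$bnd_a, end1 = .data$bnd_a + 1L,
           start2 = .data$bnd_b, end2 = .data$bnd_b + 1L) %>%
    select("chrom_a", "start1", "end1", "chrom_b", "start2", "end2", "id",
           "kind")
  readr::write_tsv(bedpe, paste0(prefix, ".truth.bedpe"), col_names = FALSE)
  invisible(json)
}

#' Report gene/repeat features overlapping a call's breakpoints
#'
#' Interval files use BED conventions (0-based half-open); a breakpoint
#' boundary that merely touches an interval's half-open edge does not count
#' as an overlap.
#'
#' @param calls An `sv_calls` tibble.
#' @param intervals A BED3+ file path, a `GRanges`, or a tibble with
#'   `chrom`, `start`, `end` and optional `name`.
#' @return A tibble: one row per (call, breakend, feature) overlap.
#' @export
annotate_overlaps <- function(calls, intervals) {
  gr <- as_feature_granges(intervals)
  ends <- bind_rows(
    calls %>% filter(!is.na(.data$bnd_a)) %>%
      mutate(breakend = "a", chrom = .data$chrom_a, bnd = .data$bnd_a),
    calls %>% filter(!is.na(.data$bnd_b)) %>%
      mutate(breakend = "b", chrom = .data$chrom_b, bnd = .data$bnd_b)
  ) %>% select("type", "hgvs", "breakend", "chrom", "bnd")
  if (!nrow(ends) || !length(gr)) {
    return(tibble(type = character(), hgvs = character(),
                  breakend = character(), chrom = character(),
                  bnd = integer(), feature = character(),
                  feature_start = integer(), feature_end = integer()))
  }
  pts <- GenomicRanges::GRanges(ends$chrom,
                                IRanges::IRanges(start = ends$bnd + 1L,
                                                 width = 1L))
  hits <- GenomicRanges::findOverlaps(pts, gr)
  if (!length(hits)) {
    return(tibble(type = character(), hgvs = character(),
                  breakend = character(), chrom = character(),
                  bnd = integer(), feature = character(),
                  feature_start = integer(), feature_end = integer()))
  }
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  nm <- gr$name %||% rep(NA_character_, length(gr))
  tibble(
    type = ends$type[qi], hgvs = ends$hgvs[qi], breakend = ends$breakend[qi],
    chrom = ends$chrom[qi], bnd = ends$bnd[qi],
    feature = nm[si],
    feature_start = GenomicRanges::start(gr)[si] - 1L,
    feature_end = GenomicRanges::end(gr)[si]
  )
}

as_feature_granges <- function(intervals) {
  if (methods::is(intervals, "GRanges")) return(intervals)
  if (is.character(intervals)) {
    if (!file.exists(intervals)) {
      abort(paste0("interval file not found: ", intervals),
            class = "splitsv_input_error")
    }
    cols <- utils::read.table(intervals, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE,
                              comment.char = "#")
    if (!nrow(cols)) return(GenomicRanges::GRanges())
    intervals <- tibble(
      chrom = as.character(cols[[1]]), start = as.integer(cols[[2]]),
      end = as.integer(cols[[3]]),
      name = if (ncol(cols) >= 4) as.character(cols[[4]]) else NA_character_
    )
  }
  if (!nrow(intervals)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
  gr$name <- intervals$name %||% rep(NA_character_, nrow(intervals))
  gr
}
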