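# Rearranged-genome simulator.
#
# A rearrangement is applied to the reference by building a piece table (the
# coordinate map): an ordered list of reference intervals with orientation
# whose concatenation IS the rearranged contig.  Faux reads are tiled across
# that contig, and their alignments back to the original reference follow
# exactly from intersecting each read's window with the piece table — no
# external aligner is involved, so the expected breakpoints are known to the
# base.

#' Deterministic synthetic reference
#'
#' Seeded random nucleotide contigs with a few low-complexity patches
#' (homopolymer and short tandem repeats) per contig, standing in for the
#' genomic substrate that real rearrangements live on.  The reference is
#' substrate only: rearrangement scenarios are defined relative to it.
#'
#' @param lengths Named integer vector of contig lengths.
#' @param seed Integer seed; the same seed always yields the same reference.
#' @return A named [Biostrings::DNAStringSet].
#' @export
sim_reference <- function(lengths = c(chrS1 = 800000L, chrS2 = 400000L),
                          seed = 20260918L) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  seqs <- map_chr(as.integer(lengths), function(L) {
    x <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # low-complexity patches: ~1 per 100 kb, 300-800 bp each
    n_patch <- max(1L, L %/% 100000L)
    starts <- sort(sample.int(L - 1000L, n_patch))
    for (s in starts) {
      w <- sample(300:800, 1)
      unit <- sample(c("A", "AT", "CAG", "TTAGGG"), 1)
      patch <- strsplit(strrep(unit, ceiling(w / nchar(unit))), "")[[1]][1:w]
      x[s:(s + w - 1L)] <- patch
    }
    paste(x, collapse = "")
  })
  Biostrings::DNAStringSet(setNames(seqs, names(lengths)))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---------------------------------------------------------------------------
# rearrangement specs

#' Build a rearrangement specification
#'
#' @param id Scenario identifier.
#' @param kind One of the rearrangement types: `deletion`, `inversion`,
#'   `tandem_duplication`, `ring_chromosome`, `insertion`,
#'   `translocation_balanced`, `translocation_unbalanced`,
#'   `complex_insertion_deletion`.
#' @param chrom,start,end Primary span, 0-based half-open.  For
#'   translocations `start` is the breakpoint on `chrom`; for
#'   insertions/complex events `[start,end)` is the origin span of the
#'   transposed sequence.
#' @param chrom2,pos2 Second locus: insertion point (insertion/complex) or
#'   the partner breakpoint (translocations).
#' @param inverted Whether the transposed sequence is inserted in inverted
#'   orientation.
#' @param loss_len Length of sequence lost at the insertion site
#'   (complex events; 0 means clean insertion).
#' @return A one-row tibble.
#' @export
rearrangement_spec <- function(id, kind, chrom, start, end = NA_integer_,
                               chrom2 = NA_character_, pos2 = NA_integer_,
                               inverted = FALSE, loss_len = 0L) {
  kind <- match.arg(kind, setdiff(rearrangement_types(), "unclassified"))
  tibble(
    id = id, kind = kind, chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    chrom2 = chrom2, pos2 = as.integer(pos2),
    inverted = inverted, loss_len = as.integer(loss_len)
  )
}

validate_spec <- function(spec, ref_lengths) {
  in_bounds <- function(chrom, pos) {
    chrom %in% names(ref_lengths) && pos >= 0 && pos <= ref_lengths[[chrom]]
  }
  fail <- function(msg) abort(paste0("invalid spec '", spec$id, "': ", msg),
                              class = "splitsv_spec_error")
  if (!spec$chrom %in% names(ref_lengths)) fail("unknown chromosome")
  if (spec$kind %in% c("deletion", "inversion", "tandem_duplication",
                       "ring_chromosome", "insertion",
                       "complex_insertion_deletion")) {
    if (is.na(spec$end) || spec$end <= spec$start) fail("requires start < end")
    if (!in_bounds(spec$chrom, spec$start) || !in_bounds(spec$chrom, spec$end))
      fail("span out of bounds")
  }
  if (spec$kind %in% c("insertion", "complex_insertion_deletion",
                       "translocation_balanced", "translocation_unbalanced")) {
    if (is.na(spec$chrom2) || is.na(spec$pos2)) fail("requires chrom2/pos2")
    if (!in_bounds(spec$chrom2, spec$pos2)) fail("second locus out of bounds")
  }
  if (spec$kind == "complex_insertion_deletion") {
    if (spec$loss_len < 0L) fail("negative loss length")
    if (!in_bounds(spec$chrom2, spec$pos2 + spec$loss_len))
      fail("loss span out of bounds")
  }
  invisible(spec)
}

# merge reference-contiguous same-orientation neighbours so piece boundaries
# are true junctions, not bookkeeping seams
normalize_pieces <- function(pieces) {
  if (nrow(pieces) <= 1L) return(pieces)
  out <- pieces[1, ]
  for (i in 2:nrow(pieces)) {
    cur <- out[nrow(out), ]
    nxt <- pieces[i, ]
    mergeable <- cur$ref_chrom == nxt$ref_chrom &&
      cur$orientation == nxt$orientation &&
      ((cur$orientation == "+" && cur$ref_end == nxt$ref_start) ||
         (cur$orientation == "-" && cur$ref_start == nxt$ref_end))
    if (mergeable) {
      if (cur$orientation == "+") {
        out$ref_end[nrow(out)] <- nxt$ref_end
      } else {
        out$ref_start[nrow(out)] <- nxt$ref_start
      }
    } else {
      out <- bind_rows(out, nxt)
    }
  }
  out$piece <- seq_len(nrow(out))
  out
}

#' Apply a rearrangement to a reference
#'
#' Produces the rearranged contig(s), the coordinate map recording each
#' contig's piecewise reference provenance with orientation, and the truth
#' record carrying the breakpoint boundaries the detection pipeline is
#' expected to recover.
#'
#' @param reference Named [Biostrings::DNAStringSet].
#' @param spec A spec row from [rearrangement_spec()] / [scenario_suite()].
#' @return A list: `seqs` (named character vector of rearranged contigs),
#'   `map` (piece tibble: `contig`, `piece`, `ref_chrom`, `ref_start`,
#'   `ref_end`, `orientation`), `circular` (named logical), `truth` (one-row
#'   tibble of expected coordinates).
#' @export
apply_rearrangement <- function(reference, spec) {
  spec <- tibble::as_tibble(spec)[1, ]
  ref_lengths <- setNames(Biostrings::width(reference), names(reference))
  validate_spec(spec, ref_lengths)
  refchar <- setNames(as.character(reference), names(reference))
  L <- function(chrom) unname(ref_lengths[[chrom]])
  piece <- function(chrom, s, e, o = "+") {
    tibble(ref_chrom = chrom, ref_start = as.integer(s), ref_end = as.integer(e),
           orientation = o)
  }
  s <- spec$start; e <- spec$end
  circular <- FALSE
  expects_alt <- FALSE
  window <- 250L

  maps <- switch(
    spec$kind,
    deletion = list(der1 = bind_rows(piece(spec$chrom, 0, s),
                                     piece(spec$chrom, e, L(spec$chrom)))),
    inversion = list(der1 = bind_rows(piece(spec$chrom, 0, s),
                                      piece(spec$chrom, s, e, "-"),
                                      piece(spec$chrom, e, L(spec$chrom)))),
    tandem_duplication = {
      expects_alt <- TRUE
      list(der1 = bind_rows(piece(spec$chrom, 0, e),
                            piece(spec$chrom, s, e),
                            piece(spec$chrom, e, L(spec$chrom))))
    },
    ring_chromosome = {
      circular <- TRUE
      expects_alt <- TRUE
      list(der1 = piece(spec$chrom, s, e))
    },
    insertion = list(der1 = bind_rows(
      piece(spec$chrom2, 0, spec$pos2),
      piece(spec$chrom, s, e, if (spec$inverted) "-" else "+"),
      piece(spec$chrom2, spec$pos2, L(spec$chrom2))
    )),
    complex_insertion_deletion = {
      expects_alt <- spec$inverted && spec$chrom == spec$chrom2 &&
        spec$loss_len > window
      list(der1 = bind_rows(
        piece(spec$chrom2, 0, spec$pos2),
        piece(spec$chrom, s, e, if (spec$inverted) "-" else "+"),
        piece(spec$chrom2, spec$pos2 + spec$loss_len, L(spec$chrom2))
      ))
    },
    translocation_balanced = list(
      der1 = bind_rows(piece(spec$chrom, 0, s),
                       piece(spec$chrom2, spec$pos2, L(spec$chrom2))),
      der2 = bind_rows(piece(spec$chrom2, 0, spec$pos2),
                       piece(spec$chrom, s, L(spec$chrom)))
    ),
    translocation_unbalanced = list(
      der1 = bind_rows(piece(spec$chrom, 0, s),
                       piece(spec$chrom2, spec$pos2, L(spec$chrom2)))
    )
  )
  maps <- imap(maps, function(m, nm) {
    normalize_pieces(m) %>%
      mutate(contig = paste0(spec$id, "_", nm), .before = 1) %>%
      mutate(piece = row_number())
  })
  map_tbl <- list_rbind(maps)
  seqs <- map_chr(maps, function(m) {
    paste(pmap(list(m$ref_chrom, m$ref_start, m$ref_end, m$orientation),
               function(chrom, rs, re, o) {
                 x <- substr(refchar[[chrom]], rs + 1L, re)
                 if (o == "-") revcomp(x) else x
               }) %>% unlist(), collapse = "")
  })
  names(seqs) <- map_chr(maps, function(m) m$contig[1])
  circ <- setNames(rep(circular, length(seqs)), names(seqs))

  truth <- scenario_truth(spec, expects_alt)
  list(seqs = seqs, map = map_tbl, circular = circ, truth = truth)
}

# expected call coordinates (0-based boundaries) for a spec
scenario_truth <- function(spec, expects_alt) {
  s <- spec$start; e <- spec$end
  base <- tibble(
    id = spec$id, kind = spec$kind,
    chrom_a = NA_character_, bnd_a = NA_integer_,
    chrom_b = NA_character_, bnd_b = NA_integer_,
    origin_chrom = NA_character_, origin_x = NA_integer_,
    origin_y = NA_integer_, inverted = NA,
    loss_p = NA_integer_, loss_q = NA_integer_,
    expects_alternatives = expects_alt,
    region_chrom = NA_character_, region_start = NA_integer_,
    region_end = NA_integer_
  )
  pad <- 40000L
  if (spec$kind %in% c("deletion", "inversion", "tandem_duplication",
                       "ring_chromosome")) {
    base$chrom_a <- spec$chrom; base$bnd_a <- s
    base$chrom_b <- spec$chrom; base$bnd_b <- e
    base$region_chrom <- spec$chrom
    base$region_start <- max(0L, s - pad); base$region_end <- e + pad
  } else if (spec$kind %in% c("insertion", "complex_insertion_deletion")) {
    p <- spec$pos2; q <- spec$pos2 + spec$loss_len
    if (spec$kind == "insertion" || spec$loss_len == 0L) {
      base$kind <- "insertion"
    }
    base$chrom_a <- spec$chrom2; base$bnd_a <- p
    base$chrom_b <- spec$chrom2; base$bnd_b <- q
    base$origin_chrom <- spec$chrom; base$origin_x <- s; base$origin_y <- e
    base$inverted <- spec$inverted
    if (spec$loss_len > 0L) { base$loss_p <- p; base$loss_q <- q }
    base$region_chrom <- spec$chrom2
    base$region_start <- max(0L, p - pad); base$region_end <- q + pad
  } else {
    # translocations: breakpoint on each chromosome
    base$chrom_a <- spec$chrom; base$bnd_a <- s
    base$chrom_b <- spec$chrom2; base$bnd_b <- spec$pos2
    base$region_chrom <- spec$chrom
    base$region_start <- max(0L, s - pad); base$region_end <- s + pad
  }
  base
}

# ---------------------------------------------------------------------------
# faux reads

#' Tile deterministic faux reads across a sequence
#'
#' Reads of `read_len` bases start every `step` bases; even-numbered starts
#' are emitted forward and odd-numbered starts reverse-complemented, so both
#' orientations cross every junction.  A final window shorter than
#' `read_len` is emitted truncated rather than dropped, so coverage reaches
#' the contig end.  For circular contigs (ring chromosomes) windows wrap
#' across the junction.
#'
#' @param sequence Character scalar (or `DNAString`) of the rearranged contig.
#' @param read_len Read length in bp (default 10 kb).
#' @param step Tiling interval in bp (default 1 kb).
#' @param circular Treat the sequence as circular.
#' @param contig Contig name recorded with each read.
#' @param id_prefix Prefix for read identifiers.
#' @return A tibble (class `sv_readset`): `read_id`, `contig`, `offset`,
#'   `length`, `orientation`, `seq`.
#' @export
make_faux_reads <- function(sequence, read_len = 10000L, step = 1000L,
                            circular = FALSE, contig = "contig",
                            id_prefix = contig) {
  sequence <- as.character(sequence)
  L <- nchar(sequence)
  stopifnot(L >= 1L)
  if (circular && read_len > L) {
    abort("read_len exceeds circular contig length", class = "splitsv_spec_error")
  }
  offsets <- seq(0L, L - 1L, by = step)
  lens <- if (circular) rep(as.integer(read_len), length(offsets)) else
    pmin(as.integer(read_len), L - offsets)
  src <- if (circular) paste0(sequence, substr(sequence, 1L, read_len)) else sequence
  fwd <- substr(rep(src, length(offsets)), offsets + 1L, offsets + lens)
  orient <- ifelse(seq_along(offsets) %% 2L == 1L, "+", "-")
  seqs <- fwd
  if (any(orient == "-")) seqs[orient == "-"] <- revcomp(fwd[orient == "-"])
  out <- tibble(
    read_id = sprintf("%s_%06d", id_prefix, offsets),
    contig = contig,
    offset = as.integer(offsets),
    length = as.integer(lens),
    orientation = orient,
    seq = seqs
  )
  class(out) <- c("sv_readset", class(out))
  attr(out, "read_len") <- as.integer(read_len)
  attr(out, "step") <- as.integer(step)
  out
}

#' Add reproducible noise to faux reads
#'
#' Substitutions are sampled per base at `sub_rate`; small (1-3 bp) indels
#' at `indel_rate` per base.  Truth records are unchanged: exact truth
#' alignments remain valid under substitution noise only (indels shift read
#' coordinates).
#'
#' @param read_set An `sv_readset` tibble.
#' @param sub_rate,indel_rate Per-base event rates in `[0,1)`.
#' @param seed Integer seed (required for reproducibility).
#' @return The read set with mutated sequences.
#' @export
add_read_noise <- function(read_set, sub_rate = 0, indel_rate = 0, seed) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  if (sub_rate == 0 && indel_rate == 0) return(read_set)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  bases <- c("A", "C", "G", "T")
  read_set$seq <- map_chr(read_set$seq, function(sq) {
    n <- nchar(sq)
    v <- strsplit(sq, "", fixed = TRUE)[[1]]
    nsub <- rbinom(1L, n, sub_rate)
    if (nsub > 0L) {
      at <- sample.int(n, nsub)
      v[at] <- map_chr(v[at], function(b) sample(setdiff(bases, b), 1L))
    }
    nind <- rbinom(1L, n, indel_rate)
    if (nind > 0L) {
      for (k in seq_len(nind)) {
        at <- sample.int(length(v), 1L)
        w <- sample(1:3, 1L)
        if (runif(1) < 0.5) {
          v <- append(v, sample(bases, w, replace = TRUE), after = at)
        } else {
          v <- v[-(at:min(length(v), at + w - 1L))]
        }
      }
    }
    paste(v, collapse = "")
  })
  read_set$length <- nchar(read_set$seq)
  read_set
}
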