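# Call construction and reporting.
#
# Internal breakpoint coordinates are 0-based between-base boundaries; every
# reported coordinate is 1-based inclusive.  Conventions (fixed, documented):
# an affected span (deletion/duplication/inversion) is reported as
# [boundary_left + 1, boundary_right]; a translocation breakend is reported
# as the last retained base (left-side ends) or the first retained base
# (right-side ends).

call_columns <- function() {
  c("type", "alternatives", "chrom_a", "pos_a", "chrom_b", "pos_b",
    "bnd_a", "bnd_b", "side_a", "side_b",
    "origin_chrom", "origin_start", "origin_end", "origin_inverted",
    "loss_chrom", "loss_start", "loss_end", "ins_len",
    "support", "low_confidence", "note", "hgvs", "description")
}

new_call <- function(type, ...) {
  defaults <- list(
    type = type, alternatives = list(character()),
    chrom_a = NA_character_, pos_a = NA_integer_,
    chrom_b = NA_character_, pos_b = NA_integer_,
    bnd_a = NA_integer_, bnd_b = NA_integer_,
    side_a = NA_character_, side_b = NA_character_,
    origin_chrom = NA_character_, origin_start = NA_integer_,
    origin_end = NA_integer_, origin_inverted = NA,
    loss_chrom = NA_character_, loss_start = NA_integer_,
    loss_end = NA_integer_, ins_len = NA_integer_,
    support = NA_integer_, low_confidence = FALSE,
    note = NA_character_, hgvs = NA_character_, description = NA_character_
  )
  args <- list(...)
  if ("alternatives" %in% names(args) && !is.list(args$alternatives)) {
    args$alternatives <- list(args$alternatives)
  }
  defaults[names(args)] <- args
  out <- tibble::as_tibble(defaults[call_columns()])
  class(out) <- c("sv_calls", class(out))
  out
}

empty_calls <- function() new_call("unclassified")[0, ]

#' Per-coordinate consensus of read-level annotations
#'
#' Reduces a set of per-read coordinate tuples to one consensus tuple by
#' taking the lower median of every numeric slot; character slots (such as
#' chromosome assignments) must be constant.
#'
#' @param per_read A tibble/data.frame with one row per read and one column
#'   per coordinate slot, or a list of equal-length numeric vectors.
#' @return A one-row tibble with the same columns.
#' @export
#' @examples
#' consensus_coordinates(data.frame(p5 = c(100, 100, 101), p3 = c(900, 901, 899)))
consensus_coordinates <- function(per_read) {
  if (is.list(per_read) && !is.data.frame(per_read)) {
    lens <- lengths(per_read)
    if (length(unique(lens)) != 1L) {
      abort("coordinate tuples have differing arity", class = "splitsv_input_error")
    }
    per_read <- as.data.frame(do.call(rbind, per_read))
  }
  per_read <- tibble::as_tibble(per_read)
  if (!nrow(per_read)) {
    abort("no coordinate tuples to aggregate", class = "splitsv_input_error")
  }
  out <- map(per_read, function(col) {
    if (is.numeric(col)) return(median_lo(col))
    u <- unique(col)
    if (length(u) != 1L) {
      abort(paste0("mixed chromosome assignment in one coordinate slot: ",
                   paste(u, collapse = ", ")),
            class = "splitsv_input_error")
    }
    u
  })
  tibble::as_tibble(out)
}

# expected canonical pattern predicate per simple type, used to point at
# reads that contradict a requested annotation pathway
type_pattern_ok <- function(patterns, type) {
  switch(type,
    deletion = pattern_is_deletion_like(patterns),
    tandem_duplication = ,
    ring_chromosome = pattern_is_dup_like(patterns),
    inversion = patterns$same_chrom & patterns$strand_rel == "opposite" &
      patterns$side_1 == patterns$side_2,
    translocation_balanced = ,
    translocation_unbalanced = !patterns$same_chrom,
    insertion = rep(TRUE, nrow(patterns)),
    rep(TRUE, nrow(patterns))
  )
}

#' Annotate a simple rearrangement from selected split reads
#'
#' Annotates each selected split read in turn (its junction boundary
#' coordinates), aggregates the per-read annotations into a single generic
#' annotation by per-slot lower medians, and renders the HGVS-like string.
#' The reads must support the requested type; otherwise the offending reads
#' are named in the error rather than silently outvoted.
#'
#' @param reads Linked segment tibble ([link_split_reads()]) of the selected
#'   reads.
#' @param type One of `"deletion"`, `"inversion"`, `"tandem_duplication"`,
#'   `"ring_chromosome"`, `"insertion"`, `"translocation_balanced"`,
#'   `"translocation_unbalanced"`.
#' @param window Breakpoint agreement window (nt).
#' @return A one-row `sv_calls` tibble; the per-read annotations are attached
#'   as the `"per_read"` attribute.
#' @export
annotate_simple <- function(reads, type, window = 250L) {
  type <- match.arg(type, setdiff(rearrangement_types(),
                                  c("complex_insertion_deletion", "unclassified")))
  sig <- compute_signature(reads, NULL, window = window,
                           min_pattern_reads = 1L, min_pattern_prop = 0)
  bad <- sig$patterns %>% filter(!type_pattern_ok(sig$patterns, type))
  if (nrow(bad)) {
    bad_reads <- sig$junctions %>%
      filter(.data$pattern %in% bad$pattern) %>%
      pull("read_id") %>% unique()
    abort(paste0("read(s) inconsistent with type '", type, "': ",
                 paste(utils::head(sort(bad_reads), 10L), collapse = ", ")),
          class = "splitsv_annotation_error")
  }
  cls <- classify_signature(sig, window)
  if (cls$type != type && !(type %in% cls$alternatives)) {
    abort(paste0("selected reads classify as '", cls$type, "', not '", type, "'"),
          class = "splitsv_annotation_error")
  }
  call <- call_from_classification(cls, sig, type_override = type)
  call$hgvs <- render_hgvs(call)
  attr(call, "per_read") <- sig$junctions
  call
}

# shared builder: turns a classification geometry + signature into a call row
call_from_classification <- function(cls, sig, type_override = NULL) {
  g <- cls$geometry
  type <- type_override %||% cls$type
  support <- sig$n_reads_used
  alt <- setdiff(cls$alternatives, type)
  if (!is.null(type_override) && type_override %in% cls$alternatives) {
    alt <- unique(c(setdiff(cls$type, type), setdiff(cls$alternatives, type)))
  }
  if (type %in% c("deletion", "inversion", "tandem_duplication",
                  "ring_chromosome")) {
    return(new_call(
      type, alternatives = alt,
      chrom_a = g$chrom, chrom_b = g$chrom,
      bnd_a = g$bnd_a, bnd_b = g$bnd_b,
      pos_a = g$bnd_a + 1L, pos_b = g$bnd_b,
      side_a = "left", side_b = "right",
      support = support, note = cls$note
    ))
  }
  if (type %in% c("translocation_balanced", "translocation_unbalanced")) {
    side_a <- g$side_a %||% "left"
    side_b <- g$side_b %||% "right"
    return(new_call(
      type, alternatives = alt,
      chrom_a = g$chrom_a, chrom_b = g$chrom_b,
      bnd_a = g$bnd_a, bnd_b = g$bnd_b,
      pos_a = if (identical(side_a, "right")) g$bnd_a + 1L else g$bnd_a,
      pos_b = if (identical(side_b, "right")) g$bnd_b + 1L else g$bnd_b,
      side_a = side_a, side_b = side_b,
      support = support, note = cls$note
    ))
  }
  if (type == "insertion") {
    p <- as.integer(round(median_lo(c(g$p, g$q))))
    return(new_call(
      type, alternatives = alt,
      chrom_a = g$site_chrom, chrom_b = g$site_chrom,
      bnd_a = p, bnd_b = p,
      pos_a = p, pos_b = p + 1L,
      origin_chrom = g$origin_chrom,
      origin_start = g$x + 1L, origin_end = g$y,
      origin_inverted = g$inverted,
      ins_len = g$y - g$x,
      support = support, note = cls$note
    ))
  }
  if (type == "complex_insertion_deletion") {
    has_loss <- g$loss > 0L
    call <- new_call(
      type, alternatives = alt,
      chrom_a = g$site_chrom, chrom_b = g$site_chrom,
      bnd_a = g$p, bnd_b = g$q,
      pos_a = g$p, pos_b = g$q + 1L,
      side_a = "left", side_b = "right",
      origin_chrom = g$origin_chrom,
      origin_start = g$x + 1L, origin_end = g$y,
      origin_inverted = g$inverted,
      loss_chrom = if (has_loss) g$site_chrom else NA_character_,
      loss_start = if (has_loss) g$p + 1L else NA_integer_,
      loss_end = if (has_loss) g$q else NA_integer_,
      ins_len = g$y - g$x,
      support = support, note = cls$note
    )
    call$description <- complex_description(call)
    return(call)
  }
  new_call("unclassified", support = support, note = cls$note)
}

complex_description <- function(call) {
  loss <- if (!is.na(call$loss_chrom)) {
    sprintf("LOSS(%s:%d-%d)", call$loss_chrom, call$loss_start, call$loss_end)
  } else "LOSS(none)"
  sprintf("INS(origin=%s:%d-%d;inverted=%s);%s",
          call$origin_chrom, call$origin_start, call$origin_end,
          if (isTRUE(call$origin_inverted)) "yes" else "no", loss)
}

#' Annotate a complex insertion-deletion from two selected columns
#'
#' The two read sets must represent the two flanks of a single breakpoint at
#' which sequence has been deleted (or duplicated) secondary to the
#' insertion of a transposed sequence.  The origin of the transposed
#' sequence, its orientation, and the location and extent of sequence loss
#' at the insertion site are derived from the joint junction patterns and
#' reported descriptively.
#'
#' @param reads_a,reads_b Linked segment tibbles for the two selected
#'   columns of split reads.  Supplying only one column is refused: one
#'   column of a two-chromosome complex event is indistinguishable from a
#'   translocation.
#' @param window Breakpoint agreement window (nt).
#' @return A one-row `sv_calls` tibble of type `complex_insertion_deletion`.
#' @export
annotate_complex <- function(reads_a, reads_b = NULL, window = 250L) {
  if (is.null(reads_b) || !nrow(reads_b)) {
    abort(paste0("complex annotation requires the split reads of BOTH flank ",
                 "columns; a single column may masquerade as a simple ",
                 "rearrangement (e.g. a translocation)"),
          class = "splitsv_annotation_error")
  }
  combined <- bind_rows(reads_a, reads_b) %>%
    distinct(.data$read_id, .data$chrom, .data$ref_start, .data$strand,
             .keep_all = TRUE)
  sig <- compute_signature(combined, NULL, window = window,
                           min_pattern_reads = 1L, min_pattern_prop = 0)
  pats <- sig$patterns %>% arrange(desc(.data$n_junctions))
  if (nrow(pats) < 2L) {
    abort(paste0("the selected columns yield a single junction pattern; ",
                 "re-examine the read selection (both flanks of the ",
                 "insertion site are required)"),
          class = "splitsv_annotation_error")
  }
  geom <- solve_transposition(utils::head(pats, 2L), window)
  if (is.null(geom)) {
    abort(paste0("selected columns are not joined to a common inserted-origin ",
                 "locus; re-examine the read selection"),
          class = "splitsv_annotation_error")
  }
  alts <- character()
  note <- NA_character_
  if (geom$inverted && geom$site_chrom == geom$origin_chrom && geom$loss > window) {
    alts <- "inversion"
    note <- "offset inversion and inverted insertion-deletion cannot be distinguished from long-read alignments alone"
  }
  cls <- structure(list(type = "complex_insertion_deletion",
                        alternatives = alts, note = note, geometry = geom),
                   class = "sv_classification")
  call <- call_from_classification(cls, sig)
  call$hgvs <- render_hgvs(call)
  attr(call, "per_read") <- sig$junctions
  call
}

#' Call an insertion or deletion from grouped gapped-alignment records
#'
#' The reported location and length of a CIGAR-encoded indel vary slightly
#' between reads; the call takes the lower median of the per-read start and
#' end positions (deletions) or of the position and inserted length
#' (insertions).
#'
#' @param indels A tibble of indel records for ONE event (same kind,
#'   overlapping spans), as produced by [scan_cigar_indels()] /
#'   [collect_gapped()].
#' @param min_support Calls supported by fewer reads are flagged
#'   low-confidence (a single read also triggers a warning).
#' @return A one-row `sv_calls` tibble.
#' @export
annotate_gapped <- function(indels, min_support = 2L) {
  if (!nrow(indels)) {
    abort("no indel records to annotate", class = "splitsv_annotation_error")
  }
  kinds <- unique(indels$kind)
  if (length(kinds) != 1L) {
    abort("mixed insertion/deletion records in one group",
          class = "splitsv_annotation_error")
  }
  chroms <- unique(indels$ref_chrom)
  if (length(chroms) != 1L) {
    abort("mixed chromosomes in one indel group",
          class = "splitsv_annotation_error")
  }
  support <- dplyr::n_distinct(indels$read_id)
  if (support < 2L) {
    warn("indel call supported by a single read", class = "splitsv_support_warning")
  }
  if (kinds == "deletion") {
    bnd_a <- as.integer(median_lo(indels$ref_start))
    bnd_b <- as.integer(median_lo(indels$ref_end))
    call <- new_call(
      "deletion", chrom_a = chroms, chrom_b = chroms,
      bnd_a = bnd_a, bnd_b = bnd_b,
      pos_a = bnd_a + 1L, pos_b = bnd_b,
      side_a = "left", side_b = "right",
      support = support, low_confidence = support < min_support
    )
  } else {
    p <- as.integer(median_lo(indels$ref_start))
    len <- as.integer(median_lo(indels$length))
    call <- new_call(
      "insertion", chrom_a = chroms, chrom_b = chroms,
      bnd_a = p, bnd_b = p, pos_a = p, pos_b = p + 1L,
      ins_len = len,
      support = support, low_confidence = support < min_support
    )
  }
  call$hgvs <- render_hgvs(call)
  attr(call, "per_read") <- indels
  call
}

#' Render the HGVS-like annotation of a call
#'
#' Deterministic strings: `chr7:146534703_146611542del` (deletions, and the
#' same shape with `dup`/`inv` suffixes), `t(chr6;chr8)(g.167281716;g.113696100)`
#' for translocations, `chrB:p_p+1ins[chrA:x_y]` (with an `inv` marker for
#' inverted origins) for insertions, and the descriptive
#' `INS(origin=...);LOSS(...)` composite for complex events.
#'
#' @param call An `sv_calls` tibble (each row rendered independently).
#' @return A character vector of annotation strings.
#' @export
render_hgvs <- function(call) {
  map_chr(seq_len(nrow(call)), function(i) {
    x <- call[i, ]
    switch(
      x$type,
      deletion = sprintf("%s:%d_%ddel", x$chrom_a, x$pos_a, x$pos_b),
      tandem_duplication = sprintf("%s:%d_%ddup", x$chrom_a, x$pos_a, x$pos_b),
      inversion = sprintf("%s:%d_%dinv", x$chrom_a, x$pos_a, x$pos_b),
      ring_chromosome = sprintf("ring(%s:%d_%d)", x$chrom_a, x$pos_a, x$pos_b),
      translocation_balanced = ,
      translocation_unbalanced =
        sprintf("t(%s;%s)(g.%d;g.%d)", x$chrom_a, x$chrom_b, x$pos_a, x$pos_b),
      insertion = if (!is.na(x$origin_chrom)) {
        sprintf("%s:%d_%dins[%s%s:%d_%d]", x$chrom_a, x$pos_a, x$pos_b,
                if (isTRUE(x$origin_inverted)) "inv" else "",
                x$origin_chrom, x$origin_start, x$origin_end)
      } else {
        sprintf("%s:%d_%dins%d", x$chrom_a, x$pos_a, x$pos_b, x$ins_len)
      },
      complex_insertion_deletion = x$description %||% complex_description(x),
      sprintf("unclassified(%s)", if (is.na(x$note)) "no call" else x$note)
    )
  })
}

#' Parse an HGVS-like annotation back into a minimal call
#'
#' Supports the simple forms emitted by [render_hgvs()] (`del`, `dup`,
#' `inv`, sequence-origin `ins`, and `t(...)` breakends); used to verify
#' that rendered annotations are regenerable.
#'
#' @param x An annotation string.
#' @return A one-row `sv_calls` tibble.
#' @export
parse_hgvs <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)_([0-9]+)(del|dup|inv)$", x))[[1]]
  if (length(m) == 5L) {
    type <- switch(m[5], del = "deletion", dup = "tandem_duplication",
                   inv = "inversion")
    pos_a <- as.integer(m[3]); pos_b <- as.integer(m[4])
    return(new_call(type, chrom_a = m[2], chrom_b = m[2],
                    pos_a = pos_a, pos_b = pos_b,
                    bnd_a = pos_a - 1L, bnd_b = pos_b,
                    side_a = "left", side_b = "right",
                    alternatives = if (type == "tandem_duplication")
                      "ring_chromosome" else character()))
  }
  m <- regmatches(x, regexec(
    "^([^:]+):([0-9]+)_([0-9]+)ins\\[(inv)?([^:]+):([0-9]+)_([0-9]+)\\]$", x))[[1]]
  if (length(m) == 8L) {
    p <- as.integer(m[3])
    return(new_call("insertion", chrom_a = m[2], chrom_b = m[2],
                    pos_a = p, pos_b = as.integer(m[4]),
                    bnd_a = p, bnd_b = p,
                    origin_chrom = m[6],
                    origin_start = as.integer(m[7]),
                    origin_end = as.integer(m[8]),
                    origin_inverted = m[5] == "inv",
                    ins_len = as.integer(m[8]) - as.integer(m[7]) + 1L))
  }
  m <- regmatches(x, regexec(
    "^t\\(([^;]+);([^)]+)\\)\\(g\\.([0-9]+);g\\.([0-9]+)\\)$", x))[[1]]
  if (length(m) == 5L) {
    return(new_call("translocation_balanced", chrom_a = m[2], chrom_b = m[3],
                    pos_a = as.integer(m[4]), pos_b = as.integer(m[5])))
  }
  abort(paste0("cannot parse annotation '", x, "'"),
        class = "splitsv_parse_error")
}
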