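# Split-read signature computation and the rearrangement decision table.
#
# A junction is canonicalized so that reads sequenced in either orientation
# across the same breakpoint produce the same pattern: the two ends are
# sorted by (chrom, pos, side) and, if the first end's strand is '-', both
# strands are flipped and the read-traversal direction is inverted.  The
# invariant quantities are then the sides, the relative strand
# (same/opposite), the traversal order (concordant = the read runs from the
# lower-coordinate end to the higher one) and, within a chromosome, the
# boundary gap.

canonical_junctions <- function(junctions) {
  if (!nrow(junctions)) {
    return(tibble(
      read_id = character(), order_index = integer(),
      chrom_1 = character(), pos_1 = integer(), side_1 = character(),
      strand_1 = character(),
      chrom_2 = character(), pos_2 = integer(), side_2 = character(),
      strand_2 = character(),
      strand_rel = character(), read_order = character(),
      same_chrom = logical(), gap = integer(), gap_sign = character(),
      pattern = character()
    ))
  }
  swap <- junctions$chrom_b < junctions$chrom_a |
    (junctions$chrom_b == junctions$chrom_a &
       (junctions$pos_b < junctions$pos_a |
          (junctions$pos_b == junctions$pos_a &
             junctions$side_b < junctions$side_a)))
  pick <- function(fa, fb) ifelse(swap, junctions[[fb]], junctions[[fa]])
  out <- tibble(
    read_id = junctions$read_id,
    order_index = junctions$order_index,
    chrom_1 = pick("chrom_a", "chrom_b"),
    pos_1 = as.integer(pick("pos_a", "pos_b")),
    side_1 = pick("side_a", "side_b"),
    strand_1 = pick("strand_a", "strand_b"),
    chrom_2 = pick("chrom_b", "chrom_a"),
    pos_2 = as.integer(pick("pos_b", "pos_a")),
    side_2 = pick("side_b", "side_a"),
    strand_2 = pick("strand_b", "strand_a"),
    read_order = ifelse(swap, "reversed", "concordant")
  )
  flip <- out$strand_1 == "-"
  out$strand_1[flip] <- "+"
  out$strand_2[flip] <- flip_strand(out$strand_2[flip])
  out$read_order[flip] <- ifelse(out$read_order[flip] == "concordant",
                                 "reversed", "concordant")
  out %>% mutate(
    strand_rel = ifelse(.data$strand_1 == .data$strand_2, "same", "opposite"),
    same_chrom = .data$chrom_1 == .data$chrom_2,
    gap = ifelse(.data$same_chrom, .data$pos_2 - .data$pos_1, NA_integer_),
    gap_sign = dplyr::case_when(
      !.data$same_chrom ~ "inter",
      .data$gap > 0L ~ "positive",
      .data$gap < 0L ~ "negative",
      TRUE ~ "zero"
    )
  )
}

# Label every junction end with a positional locus (single linkage within
# `window` per chromosome and side), then key each junction by its two
# locus labels plus the orientation-invariant fields.  Without the locus
# labels, two distinct junctions with the same orientation geometry (e.g.
# the two breakpoints of a transposition within the copied sequence) would
# collapse into one pattern.
pattern_keys <- function(canon, window = 250L) {
  ends <- bind_rows(
    tibble(row = seq_len(nrow(canon)), end = 1L, chrom = canon$chrom_1,
           side = canon$side_1, pos = canon$pos_1),
    tibble(row = seq_len(nrow(canon)), end = 2L, chrom = canon$chrom_2,
           side = canon$side_2, pos = canon$pos_2)
  ) %>%
    arrange(.data$chrom, .data$side, .data$pos) %>%
    group_by(.data$chrom, .data$side) %>%
    mutate(.grp = cumsum(c(0L, diff(.data$pos)) > window)) %>%
    ungroup() %>%
    mutate(locus = paste0(.data$chrom, "/", .data$side, "/", .data$.grp))
  loc1 <- ends %>% filter(.data$end == 1L) %>% arrange(.data$row) %>% pull("locus")
  loc2 <- ends %>% filter(.data$end == 2L) %>% arrange(.data$row) %>% pull("locus")
  paste(loc1, loc2, canon$strand_rel, canon$read_order, sep = "|")
}

#' Compute the split-read signature of a selected read set
#'
#' Scans the junctions of the selected split reads, keeps those anchored at
#' the given breakpoints, and summarises them into orientation-invariant
#' junction patterns with their supporting-read proportions.  The signature
#' is the input of [classify_signature()]; identical rearrangement
#' geometries (e.g. a ring-chromosome junction and a tandem-duplication
#' junction over the same boundaries) yield identical signatures.
#'
#' @param reads Linked segment tibble ([link_split_reads()]) of the selected
#'   reads.
#' @param breakpoints Cluster tibble ([cluster_junctions()]); a junction
#'   qualifies when at least one of its ends matches a cluster's chromosome
#'   and side within `window`.  Pass `NULL` to anchor on the reads' own ends
#'   (every junction qualifies).
#' @param window Matching window in nt.
#' @param min_pattern_reads,min_pattern_prop Patterns below these support
#'   levels are retained in the signature but flagged `used = FALSE` and
#'   ignored by the decision table.
#' @return An object of class `sv_signature`.
#' @export
compute_signature <- function(reads, breakpoints, window = 250L,
                              min_pattern_reads = 2L,
                              min_pattern_prop = 0.10) {
  junctions <- extract_junctions(reads)
  if (!nrow(junctions)) {
    abort("no junctions in the selected reads", class = "splitsv_signature_error")
  }
  if (!is.null(breakpoints) && nrow(breakpoints)) {
    ends <- junction_ends(junctions)
    hit <- ends %>%
      dplyr::inner_join(
        breakpoints %>% select("chrom", "position", "side"),
        by = c("chrom", "side"), relationship = "many-to-many"
      ) %>%
      filter(abs(.data$pos - .data$position) <= window) %>%
      distinct(.data$read_id, .data$order_index)
    junctions <- junctions %>%
      dplyr::semi_join(hit, by = c("read_id", "order_index"))
    n_columns <- length(unique(column_labels(breakpoints, window)))
  } else {
    n_columns <- NA_integer_
  }
  all_reads <- unique(reads$read_id)
  used_reads <- unique(junctions$read_id)
  if (!nrow(junctions)) {
    abort("no junction in the selected reads matches the given breakpoints",
          class = "splitsv_signature_error")
  }
  canon <- canonical_junctions(junctions)
  canon$pattern <- pattern_keys(canon, window)
  n_total <- nrow(canon)
  patterns <- canon %>%
    group_by(.data$pattern) %>%
    summarise(
      chrom_1 = first(.data$chrom_1), side_1 = first(.data$side_1),
      chrom_2 = first(.data$chrom_2), side_2 = first(.data$side_2),
      strand_rel = first(.data$strand_rel),
      read_order = first(.data$read_order),
      same_chrom = first(.data$same_chrom),
      pos_1 = as.integer(median_lo(.data$pos_1)),
      pos_2 = as.integer(median_lo(.data$pos_2)),
      n_reads = dplyr::n_distinct(.data$read_id),
      n_junctions = n(),
      .groups = "drop"
    ) %>%
    mutate(
      gap = ifelse(.data$same_chrom, .data$pos_2 - .data$pos_1, NA_integer_),
      gap_sign = dplyr::case_when(
        !.data$same_chrom ~ "inter",
        .data$gap > 0L ~ "positive",
        .data$gap < 0L ~ "negative",
        TRUE ~ "zero"
      ),
      prop = .data$n_junctions / n_total,
      used = .data$n_reads >= min_pattern_reads &
        .data$prop >= min_pattern_prop
    ) %>%
    arrange(desc(.data$n_junctions), .data$pattern)
  if (!is.na(n_columns) && is.null(breakpoints)) n_columns <- NA_integer_
  structure(
    list(
      n_columns = n_columns,
      patterns = patterns,
      junctions = canon,
      n_reads_used = length(used_reads),
      n_reads_excluded = length(setdiff(all_reads, used_reads)),
      window = as.integer(window)
    ),
    class = "sv_signature"
  )
}

# positional column labels for a cluster set (same rule as build_columns)
column_labels <- function(clusters, window = 250L) {
  cl <- clusters %>% arrange(.data$chrom, .data$position)
  grp <- cl %>%
    group_by(.data$chrom) %>%
    mutate(.col = cumsum(c(0L, diff(.data$position)) > window)) %>%
    ungroup()
  paste(grp$chrom, grp$.col)
}

#' @export
print.sv_signature <- function(x, ...) {
  cat("<sv_signature> ", nrow(x$patterns), " pattern(s) from ",
      x$n_reads_used, " read(s)",
      if (x$n_reads_excluded) paste0(" (", x$n_reads_excluded, " excluded)"),
      "\n", sep = "")
  print(x$patterns %>% select(-"pattern"), ...)
  invisible(x)
}

#' Serialize a signature to JSON
#'
#' Deterministic dump used for debugging and for verifying that provably
#' ambiguous rearrangement pairs (ring chromosome vs tandem duplication;
#' offset inversion vs inverted insertion-deletion on one chromosome) are
#' byte-identical at the signature level.
#'
#' @param sig An `sv_signature`.
#' @return A JSON string.
#' @export
signature_json <- function(sig) {
  stopifnot(inherits(sig, "sv_signature"))
  jsonlite::toJSON(
    list(
      n_columns = sig$n_columns,
      patterns = sig$patterns %>%
        select("pattern", "pos_1", "pos_2", "n_reads", "n_junctions", "prop",
               "used")
    ),
    auto_unbox = TRUE, digits = NA
  )
}

# ---------------------------------------------------------------------------
# decision table

rearrangement_types <- function() {
  c("deletion", "insertion", "inversion", "tandem_duplication",
    "translocation_balanced", "translocation_unbalanced", "ring_chromosome",
    "complex_insertion_deletion", "unclassified")
}

pattern_is_deletion_like <- function(p) {
  p$same_chrom & p$strand_rel == "same" & p$read_order == "concordant" &
    p$side_1 == "left" & p$side_2 == "right" & p$gap_sign == "positive"
}

pattern_is_dup_like <- function(p) {
  p$same_chrom & p$strand_rel == "same" & p$read_order == "reversed" &
    p$side_1 == "right" & p$side_2 == "left" & p$gap_sign == "positive"
}

# Enumerate flank/origin assignments for a transposition event described by
# two junction patterns (each pattern contributes one insertion-site flank
# end and one origin end).  Valid assignments need one left + one right
# flank end on a single chromosome, and a right (start) + left (end) origin
# pair on a single chromosome delimiting a positive span.  The
# minimum-loss assignment wins; a site gain deeper than `window` is
# rejected so that the search cannot wander.
solve_transposition <- function(p, window = 250L) {
  stopifnot(nrow(p) == 2L)
  if (length(unique(p$strand_rel)) != 1L) return(NULL)
  end_of <- function(row, k) {
    list(chrom = p[[paste0("chrom_", k)]][row], pos = p[[paste0("pos_", k)]][row],
         side = p[[paste0("side_", k)]][row])
  }
  best <- NULL
  for (c1 in 1:2) {
    for (c2 in 1:2) {
      f1 <- end_of(1, c1); f2 <- end_of(2, c2)
      o1 <- end_of(1, 3 - c1); o2 <- end_of(2, 3 - c2)
      if (f1$chrom != f2$chrom) next
      sides <- c(f1$side, f2$side)
      if (!setequal(sides, c("left", "right"))) next
      pL <- if (f1$side == "left") f1$pos else f2$pos
      pR <- if (f1$side == "right") f1$pos else f2$pos
      loss <- pR - pL
      if (loss < -window) next
      if (o1$chrom != o2$chrom) next
      osides <- c(o1$side, o2$side)
      if (!setequal(osides, c("left", "right"))) next
      x <- if (o1$side == "right") o1$pos else o2$pos
      y <- if (o1$side == "left") o1$pos else o2$pos
      if (y - x < 1L) next
      cand <- list(site_chrom = f1$chrom, p = pL, q = pR, loss = loss,
                   origin_chrom = o1$chrom, x = x, y = y,
                   inverted = p$strand_rel[1] == "opposite")
      if (is.null(best) || cand$loss < best$loss ||
          (cand$loss == best$loss && (cand$y - cand$x) < (best$y - best$x))) {
        best <- cand
      }
    }
  }
  best
}

#' Classify a split-read signature
#'
#' Maps the junction-pattern set of a signature to a rearrangement type via
#' a decision table reconstructed from the expected split-read arrangements
#' of each event class, flagging the provably ambiguous outcomes.  The
#' mapping is total: any signature yields a value, with `unclassified` as
#' the fallback — never an error.
#'
#' Ambiguities carried in `alternatives`: a reversed-order same-strand
#' pattern is reported as a tandem duplication with `ring_chromosome` as the
#' alternative (the two are indistinguishable from split reads alone; copy
#' number or a karyotype is needed).  A same-chromosome inverted
#' transposition with sequence loss at the insertion site is reported as a
#' complex insertion-deletion with `inversion` (offset inversion) as the
#' alternative.
#'
#' @param sig An `sv_signature` from [compute_signature()].
#' @param window Tolerance (nt) for mirrored/reciprocal breakpoint agreement.
#' @return A list of class `sv_classification`: `type`, `alternatives`
#'   (character vector), `note`, and `geometry` (coordinates reusable by the
#'   annotators; contents depend on the type).
#' @export
classify_signature <- function(sig, window = 250L) {
  stopifnot(inherits(sig, "sv_signature"))
  p <- sig$patterns %>% filter(.data$used)
  res <- function(type, alternatives = character(), note = NA_character_,
                  geometry = NULL) {
    structure(list(type = type, alternatives = alternatives, note = note,
                   geometry = geometry),
              class = "sv_classification")
  }
  if (!nrow(p)) {
    return(res("unclassified", note = "no pattern with sufficient support"))
  }
  if (nrow(p) == 1L) {
    if (pattern_is_deletion_like(p)) {
      return(res("deletion",
                 geometry = list(chrom = p$chrom_1, bnd_a = p$pos_1,
                                 bnd_b = p$pos_2)))
    }
    if (pattern_is_dup_like(p)) {
      return(res("tandem_duplication", alternatives = "ring_chromosome",
                 note = "ring chromosome and tandem duplication share this signature",
                 geometry = list(chrom = p$chrom_1, bnd_a = p$pos_1,
                                 bnd_b = p$pos_2)))
    }
    if (!p$same_chrom) {
      return(res("translocation_unbalanced",
                 geometry = list(chrom_a = p$chrom_1, bnd_a = p$pos_1,
                                 side_a = p$side_1,
                                 chrom_b = p$chrom_2, bnd_b = p$pos_2,
                                 side_b = p$side_2)))
    }
    return(res("unclassified",
               note = "single pattern matches no simple class (one side of an inversion or complex event?)"))
  }
  if (nrow(p) == 2L) {
    opp <- all(p$strand_rel == "opposite")
    intra <- all(p$same_chrom) && length(unique(p$chrom_1)) == 1L &&
      all(p$chrom_1 == p$chrom_2)
    sides1 <- paste(p$side_1, p$side_2)
    if (opp && intra && setequal(sides1, c("left left", "right right"))) {
      ll <- p %>% filter(.data$side_1 == "left")
      rr <- p %>% filter(.data$side_1 == "right")
      mirrored <- abs(ll$pos_1 - rr$pos_1) <= window &&
        abs(ll$pos_2 - rr$pos_2) <= window
      if (mirrored) {
        return(res("inversion",
                   geometry = list(chrom = ll$chrom_1,
                                   bnd_a = as.integer(median_lo(c(ll$pos_1, rr$pos_1))),
                                   bnd_b = as.integer(median_lo(c(ll$pos_2, rr$pos_2))))))
      }
    }
    if (!any(p$same_chrom) &&
        setequal(c(p$chrom_1, p$chrom_2), unique(c(p$chrom_1, p$chrom_2))) &&
        length(unique(c(p$chrom_1, p$chrom_2))) == 2L) {
      # candidate reciprocal translocation: complementary sides and agreeing
      # positions on each chromosome
      chroms <- sort(unique(c(p$chrom_1, p$chrom_2)))
      endsA <- bind_rows(
        tibble(pos = p$pos_1, side = p$side_1, chrom = p$chrom_1),
        tibble(pos = p$pos_2, side = p$side_2, chrom = p$chrom_2)
      )
      a_ends <- endsA %>% filter(.data$chrom == chroms[1])
      b_ends <- endsA %>% filter(.data$chrom == chroms[2])
      if (nrow(a_ends) == 2L && nrow(b_ends) == 2L &&
          setequal(a_ends$side, c("left", "right")) &&
          setequal(b_ends$side, c("left", "right")) &&
          abs(diff(a_ends$pos)) <= window && abs(diff(b_ends$pos)) <= window) {
        return(res("translocation_balanced",
                   geometry = list(chrom_a = chroms[1],
                                   bnd_a = as.integer(median_lo(a_ends$pos)),
                                   chrom_b = chroms[2],
                                   bnd_b = as.integer(median_lo(b_ends$pos)))))
      }
    }
    geom <- solve_transposition(p, window)
    if (!is.null(geom)) {
      if (geom$loss <= window) {
        return(res("insertion",
                   note = if (geom$loss != 0L)
                     paste0("insertion-site offset of ", geom$loss,
                            " bp within the clustering window") else NA_character_,
                   geometry = geom))
      }
      alts <- character()
      note <- NA_character_
      if (geom$inverted && geom$site_chrom == geom$origin_chrom) {
        alts <- "inversion"
        note <- "offset inversion and inverted insertion-deletion cannot be distinguished from long-read alignments alone"
      }
      return(res("complex_insertion_deletion", alternatives = alts,
                 note = note, geometry = geom))
    }
    return(res("unclassified", note = "two patterns with no consistent joint interpretation"))
  }
  res("unclassified",
      note = paste0(nrow(p), " supported patterns: very complex event, manual review required"))
}

#' @export
print.sv_classification <- function(x, ...) {
  cat("<sv_classification> ", x$type,
      if (length(x$alternatives))
        paste0(" (alternatives: ", paste(x$alternatives, collapse = ", "), ")"),
      "\n", sep = "")
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Assess whether a column set looks simple or complex
#'
#' Simple rearrangements present two columns of split reads (insertions:
#' three, with the insertion-site column joined to both origin-end
#' columns); three or four columns otherwise indicate a complex
#' insertion-deletion, and more than four suggest several events at one
#' locus.
#'
#' @param columns An `sv_columns` object from [build_columns()].
#' @param window Agreement window used for the no-loss insertion-site test.
#' @return `"simple"` or `"complex"`, with a `note` attribute (e.g. the
#'   manual-review warning for >4 columns).
#' @export
assess_complexity <- function(columns, window = 250L) {
  stopifnot(inherits(columns, "sv_columns"))
  n <- nrow(columns$columns)
  if (n == 0L) abort("empty column set", class = "splitsv_input_error")
  note <- NA_character_
  if (n <= 2L) {
    out <- "simple"
  } else if (n == 3L) {
    # insertion topology: one column pairs with both others and holds both a
    # left- and a right-side cluster at the same position (no loss there)
    deg <- table(factor(c(columns$pairing$column_i, columns$pairing$column_j),
                        levels = columns$columns$column_id))
    hub <- as.integer(names(deg)[deg >= 2L])
    ok <- FALSE
    for (h in hub) {
      cl <- columns$clusters %>% filter(.data$column_id == h)
      if (all(c("left", "right") %in% cl$side) &&
          diff(range(cl$position)) <= window) ok <- TRUE
    }
    out <- if (ok) "simple" else "complex"
    if (!ok) note <- "three columns without an insertion-site hub"
  } else if (n == 4L) {
    out <- "complex"
  } else {
    out <- "complex"
    note <- paste0(n, " columns: very complex locus, manual review advised")
  }
  structure(out, note = note)
}
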