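#' Extract rearrangement junctions from split reads
#'
#' Each pair of consecutive segments along a read defines one junction: the
#' read leaves the reference at one segment's terminal boundary and re-enters
#' it at the next segment's entry boundary.  Boundary positions are 0-based
#' between-base coordinates; `side` records whether the retained sequence
#' lies to the left (`"left"`, boundary at the segment's `ref_end` for '+'
#' alignments) or to the right (`"right"`, boundary at `ref_start`) of the
#' break.
#'
#' @param split_reads Linked segment tibble from [link_split_reads()].
#' @return A junction tibble: one row per consecutive segment pair with both
#'   ends (`chrom_a`, `pos_a`, `side_a`, `strand_a` and the `_b`
#'   counterparts, in read order), the unaligned `read_gap` between the two
#'   segments (clamped at 0) and `order_index` (position of the junction in
#'   the read's chain).  Reads flagged inconsistent or with a single segment
#'   contribute nothing.
#' @export
extract_junctions <- function(split_reads) {
  empty <- tibble(
    read_id = character(), order_index = integer(),
    chrom_a = character(), pos_a = integer(), side_a = character(),
    strand_a = character(),
    chrom_b = character(), pos_b = integer(), side_b = character(),
    strand_b = character(),
    read_gap = integer()
  )
  if (!nrow(split_reads)) return(empty)
  sr <- split_reads %>% filter(.data$consistent, .data$n_segs >= 2L)
  if (!nrow(sr)) return(empty)
  sr <- sr %>% arrange(.data$read_id, .data$seg_index)
  jn <- sr %>%
    group_by(.data$read_id) %>%
    mutate(
      nxt_chrom = lead(.data$chrom), nxt_strand = lead(.data$strand),
      nxt_ref_start = lead(.data$ref_start), nxt_ref_end = lead(.data$ref_end),
      nxt_read_start = lead(.data$read_start)
    ) %>%
    filter(!is.na(.data$nxt_chrom)) %>%
    mutate(order_index = row_number() - 1L) %>%
    ungroup()
  tibble(
    read_id = jn$read_id,
    order_index = jn$order_index,
    chrom_a = jn$chrom,
    pos_a = as.integer(ifelse(jn$strand == "+", jn$ref_end, jn$ref_start)),
    side_a = ifelse(jn$strand == "+", "left", "right"),
    strand_a = jn$strand,
    chrom_b = jn$nxt_chrom,
    pos_b = as.integer(ifelse(jn$nxt_strand == "+", jn$nxt_ref_start,
                              jn$nxt_ref_end)),
    side_b = ifelse(jn$nxt_strand == "+", "right", "left"),
    strand_b = jn$nxt_strand,
    read_gap = pmax(0L, as.integer(jn$nxt_read_start - jn$read_end))
  )
}

# Long form: one row per junction END, carrying its partner's coordinates.
junction_ends <- function(junctions) {
  if (!nrow(junctions)) {
    return(tibble(
      read_id = character(), order_index = integer(), end = character(),
      chrom = character(), pos = integer(), side = character(),
      strand = character(), partner_chrom = character(),
      partner_pos = integer(), partner_side = character(),
      partner_strand = character()
    ))
  }
  a <- junctions %>%
    transmute_ends("a", "b")
  b <- junctions %>%
    transmute_ends("b", "a")
  bind_rows(a, b)
}

transmute_ends <- function(junctions, self, other) {
  tibble(
    read_id = junctions$read_id,
    order_index = junctions$order_index,
    end = self,
    chrom = junctions[[paste0("chrom_", self)]],
    pos = junctions[[paste0("pos_", self)]],
    side = junctions[[paste0("side_", self)]],
    strand = junctions[[paste0("strand_", self)]],
    partner_chrom = junctions[[paste0("chrom_", other)]],
    partner_pos = junctions[[paste0("pos_", other)]],
    partner_side = junctions[[paste0("side_", other)]],
    partner_strand = junctions[[paste0("strand_", other)]]
  )
}

#' Cluster junction ends into supported breakpoints
#'
#' Junction ends are partitioned per chromosome and side by single-linkage on
#' their sorted positions: consecutive ends at most `window` apart belong to
#' the same cluster.  A cluster is a putative breakpoint when it gathers at
#' least `min_support` ends.  The representative position is the lower
#' median of the member positions.
#'
#' @param junctions Junction tibble from [extract_junctions()].
#' @param window Maximum gap (nt) between consecutive member positions
#'   (default 250).
#' @param min_support Minimum number of supporting junction ends (default 2).
#' @return A cluster tibble: `cluster_id`, `chrom`, `position`, `side`,
#'   `support`, a modal partner summary (`partner_chrom`, `partner_pos`,
#'   `partner_same_strand_frac`) and a `members` list-column of per-read
#'   evidence.
#' @export
cluster_junctions <- function(junctions, window = 250L, min_support = 2L) {
  ends <- junction_ends(junctions)
  empty <- tibble(
    cluster_id = integer(), chrom = character(), position = integer(),
    side = character(), support = integer(), partner_chrom = character(),
    partner_pos = integer(), partner_same_strand_frac = double(),
    members = list()
  )
  if (!nrow(ends)) return(empty)
  ends <- ends %>% arrange(.data$chrom, .data$side, .data$pos)
  grouped <- ends %>%
    group_by(.data$chrom, .data$side) %>%
    mutate(.chain = cumsum(c(0L, diff(.data$pos)) > window)) %>%
    ungroup() %>%
    group_by(.data$chrom, .data$side, .data$.chain)
  clusters <- grouped %>%
    group_split() %>%
    map(function(g) {
      if (nrow(g) < min_support) return(NULL)
      mode_chrom <- names(sort(table(g$partner_chrom), decreasing = TRUE))[1]
      on_mode <- g$partner_pos[g$partner_chrom == mode_chrom]
      tibble(
        chrom = g$chrom[1],
        position = as.integer(median_lo(g$pos)),
        side = g$side[1],
        support = nrow(g),
        partner_chrom = mode_chrom,
        partner_pos = as.integer(median_lo(on_mode)),
        partner_same_strand_frac = mean(g$strand == g$partner_strand),
        members = list(g %>% select(
          "read_id", "order_index", "end", "pos", "strand",
          "partner_chrom", "partner_pos", "partner_strand"
        ))
      )
    })
  out <- list_rbind(compact(clusters))
  if (!nrow(out)) return(empty)
  out %>%
    arrange(.data$chrom, .data$position, .data$side) %>%
    mutate(cluster_id = row_number(), .before = 1)
}

#' Group breakpoint clusters into columns of co-terminating split reads
#'
#' A "column" is the positional unit of breakpoint evidence: all clusters on
#' the same chromosome whose representative positions fall within `window`
#' of each other (single linkage), pooling the left and right sides.  An
#' inversion breakpoint, for instance, yields one left-side and one
#' right-side cluster at the same position: one column.  Columns are then
#' paired whenever a junction connects ends in two of them through at least
#' one shared read.
#'
#' @param clusters Cluster tibble from [cluster_junctions()].
#' @param junctions The junction tibble the clusters were built from.
#' @param window Positional merging window (same default as clustering).
#' @return An object of class `sv_columns`: a list with `columns` (tibble:
#'   `column_id`, `chrom`, `position`, `support`, `sides`, `cluster_ids`),
#'   `pairing` (tibble: `column_i`, `column_j`, `n_reads`, `n_junctions`)
#'   and the input `clusters` augmented with `column_id`.
#' @export
build_columns <- function(clusters, junctions, window = 250L) {
  if (!nrow(clusters)) {
    return(structure(
      list(
        columns = tibble(column_id = integer(), chrom = character(),
                         position = integer(), support = integer(),
                         sides = character(), cluster_ids = list()),
        pairing = tibble(column_i = integer(), column_j = integer(),
                         n_reads = integer(), n_junctions = integer()),
        clusters = clusters
      ),
      class = "sv_columns"
    ))
  }
  cl <- clusters %>%
    arrange(.data$chrom, .data$position) %>%
    group_by(.data$chrom) %>%
    mutate(.col = cumsum(c(0L, diff(.data$position)) > window)) %>%
    ungroup() %>%
    group_by(.data$chrom, .data$.col) %>%
    mutate(column_id = NA_integer_) %>%
    ungroup()
  key <- paste(cl$chrom, cl$.col)
  cl$column_id <- as.integer(factor(key, levels = unique(key)))
  columns <- cl %>%
    group_by(.data$column_id) %>%
    summarise(
      chrom = first(.data$chrom),
      position = as.integer(median_lo(unlist(map(.data$members, "pos")))),
      support = sum(.data$support),
      sides = paste(sort(unique(.data$side)), collapse = "+"),
      cluster_ids = list(.data$cluster_id),
      .groups = "drop"
    )
  # map each junction end to its column (if any) to derive the pairing
  memb <- cl %>%
    select("cluster_id", "column_id", "members") %>%
    tidyr::unnest("members")
  pairing <- tibble(column_i = integer(), column_j = integer(),
                    n_reads = integer(), n_junctions = integer())
  if (nrow(junctions) && nrow(memb)) {
    ja <- memb %>% filter(.data$end == "a") %>%
      select("read_id", "order_index", col_a = "column_id")
    jb <- memb %>% filter(.data$end == "b") %>%
      select("read_id", "order_index", col_b = "column_id")
    link <- dplyr::inner_join(ja, jb, by = c("read_id", "order_index")) %>%
      mutate(column_i = pmin(.data$col_a, .data$col_b),
             column_j = pmax(.data$col_a, .data$col_b))
    if (nrow(link)) {
      pairing <- link %>%
        group_by(.data$column_i, .data$column_j) %>%
        summarise(n_reads = dplyr::n_distinct(.data$read_id),
                  n_junctions = n(), .groups = "drop")
    }
  }
  structure(
    list(columns = columns, pairing = pairing,
         clusters = cl %>% select(-".col")),
    class = "sv_columns"
  )
}

#' @export
print.sv_columns <- function(x, ...) {
  cat("<sv_columns> ", nrow(x$columns), " column(s), ",
      nrow(x$pairing), " pairing(s)\n", sep = "")
  print(x$columns, ...)
  invisible(x)
}

#' Window around a breakpoint's partner locus
#'
#' Returns the region in which the linked partner alignments of a breakpoint
#' cluster should be inspected: `half_width` either side of the modal
#' partner position (50 kb by default), clipped to the chromosome.
#'
#' @param cluster A single cluster row from [cluster_junctions()].
#' @param half_width Half-width of the window in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   clip the right edge.
#' @return A region list (`chrom`, `start`, `end`; 0-based half-open).
#' @export
secondary_window <- function(cluster, half_width = 50000L,
                             chrom_lengths = NULL) {
  if (!nrow(cluster)) {
    abort("empty cluster", class = "splitsv_input_error")
  }
  cluster <- cluster[1, ]
  if (is.na(cluster$partner_chrom) || is.na(cluster$partner_pos)) {
    abort("cluster has no partner summary", class = "splitsv_input_error")
  }
  start <- max(0, cluster$partner_pos - half_width)
  end <- cluster$partner_pos + half_width
  if (!is.null(chrom_lengths) && cluster$partner_chrom %in% names(chrom_lengths)) {
    end <- min(end, unname(chrom_lengths[[cluster$partner_chrom]]))
  }
  list(chrom = cluster$partner_chrom, start = start, end = end)
}
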