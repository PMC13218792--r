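# The validation scenario catalogue: a deterministic set of 32 simple and 36
# complex rearrangements defined against the bundled synthetic reference
# (sim_reference() defaults: chrS1 800 kb + chrS2 400 kb).  Every simple
# event kind appears in several size variants; translocation scenarios cover
# both the balanced (reciprocal derivative pair) and unbalanced (single
# derivative) presentations; three ring scenarios share their breakpoints
# with tandem duplications so the shared-signature ambiguity can be asserted
# on identical coordinates.  The complex grid crosses the origin location
# (other chromosome / same chromosome distant / nearby / within the copied
# sequence) with orientation and the extent of sequence loss at the
# insertion site.

#' The built-in rearrangement scenario catalogue
#'
#' @param reference Optional reference (defaults to [sim_reference()]
#'   geometry); only its contig lengths are consulted for validation.
#' @return A tibble of 68 rearrangement specs with bookkeeping columns:
#'   `class` (`"simple"`/`"complex"`), `expects_alternatives` (the two
#'   provably ambiguous scenario classes: ring vs tandem duplication, and
#'   same-chromosome inverted insertion-deletion vs offset inversion).
#' @export
scenario_suite <- function(reference = NULL) {
  sp <- function(...) rearrangement_spec(...)
  simple <- bind_rows(
    sp("del_040k", "deletion", "chrS1", 150000, 190000),
    sp("del_020k", "deletion", "chrS1", 300000, 320000),
    sp("del_095k", "deletion", "chrS1", 420000, 515000),
    sp("del_060k", "deletion", "chrS1", 600000, 660000),
    sp("del_030k", "deletion", "chrS2", 120000, 150000),
    sp("inv_050k", "inversion", "chrS1", 150000, 200000),
    sp("inv_025k", "inversion", "chrS1", 350000, 375000),
    sp("inv_120k", "inversion", "chrS1", 500000, 620000),
    sp("inv_080k", "inversion", "chrS2", 100000, 180000),
    sp("inv_045k", "inversion", "chrS2", 200000, 245000),
    sp("dup_040k", "tandem_duplication", "chrS1", 250000, 290000),
    sp("dup_025k", "tandem_duplication", "chrS1", 450000, 475000),
    sp("dup_080k", "tandem_duplication", "chrS2", 150000, 230000),
    sp("dup_600k", "tandem_duplication", "chrS1", 100000, 700000),
    sp("dup_250k", "tandem_duplication", "chrS2", 80000, 330000),
    sp("ring_600k", "ring_chromosome", "chrS1", 100000, 700000),
    sp("ring_250k", "ring_chromosome", "chrS2", 80000, 330000),
    sp("ring_530k", "ring_chromosome", "chrS1", 120000, 650000),
    sp("insI_030k", "insertion", "chrS1", 200000, 230000, "chrS1", 500000),
    sp("insI_050k", "insertion", "chrS1", 350000, 400000, "chrS1", 150000),
    sp("insI_025k", "insertion", "chrS2", 100000, 125000, "chrS2", 300000),
    sp("insI_040k", "insertion", "chrS1", 600000, 640000, "chrS1", 250000),
    sp("insX_030k", "insertion", "chrS2", 150000, 180000, "chrS1", 400000),
    sp("insX_080k", "insertion", "chrS1", 250000, 330000, "chrS2", 200000),
    sp("insX_040k_inv", "insertion", "chrS2", 50000, 90000, "chrS1", 650000,
       inverted = TRUE),
    sp("insX_025k_inv", "insertion", "chrS1", 500000, 525000, "chrS2", 100000,
       inverted = TRUE),
    sp("tbal_a", "translocation_balanced", "chrS1", 300000, NA, "chrS2", 200000),
    sp("tbal_b", "translocation_balanced", "chrS1", 550000, NA, "chrS2", 120000),
    sp("tbal_c", "translocation_balanced", "chrS1", 150000, NA, "chrS2", 320000),
    sp("tunb_a", "translocation_unbalanced", "chrS1", 400000, NA, "chrS2", 250000),
    sp("tunb_b", "translocation_unbalanced", "chrS1", 620000, NA, "chrS2", 90000),
    sp("tunb_c", "translocation_unbalanced", "chrS1", 220000, NA, "chrS2", 180000)
  ) %>% mutate(class = "simple")

  cplx_cfg <- tidyr::expand_grid(
    loc = c("inter", "far", "near"),
    inv = c(FALSE, TRUE),
    loss = c(2000L, 8000L)
  ) %>%
    bind_rows(
      tibble(loc = "within", inv = FALSE, loss = c(2000L, 8000L)),
      tidyr::expand_grid(loc = c("near", "within"), inv = c(FALSE, TRUE),
                         loss = 0L)
    )
  sizes <- c(25000L, 45000L)
  complex <- list_rbind(map(seq_len(nrow(cplx_cfg)), function(i) {
    cfg <- cplx_cfg[i, ]
    list_rbind(map(sizes, function(S) {
      x <- if (cfg$loc == "near" || cfg$loc == "within") 400000L else 150000L
      origin_chrom <- if (cfg$loc == "inter") "chrS2" else "chrS1"
      p <- switch(cfg$loc,
                  inter = 500000L, far = 500000L,
                  near = x + S + 5000L, within = x + S %/% 2L)
      id <- sprintf("cplx_%s_%s_l%02dk_%02dk", cfg$loc,
                    if (cfg$inv) "inv" else "fwd", cfg$loss %/% 1000L,
                    S %/% 1000L)
      rearrangement_spec(id, "complex_insertion_deletion",
                         origin_chrom, x, x + S, "chrS1", p,
                         inverted = cfg$inv, loss_len = cfg$loss)
    }))
  })) %>% mutate(class = "complex")

  suite <- bind_rows(simple, complex)
  if (!is.null(reference)) {
    ref_lengths <- setNames(Biostrings::width(reference), names(reference))
    purrr::walk(seq_len(nrow(suite)),
                function(i) validate_spec(suite[i, ], ref_lengths))
  }
  window <- 250L
  suite %>% mutate(
    expects_alternatives =
      .data$kind %in% c("tandem_duplication", "ring_chromosome") |
      (.data$kind == "complex_insertion_deletion" & .data$inverted &
         .data$chrom == .data$chrom2 & .data$loss_len > window)
  )
}

#' Materialise one scenario: rearranged contigs, faux reads and truth BAM
#'
#' @param spec One spec row.
#' @param reference Named `DNAStringSet` reference.
#' @param dir Output directory for `<id>.bam`.
#' @param read_len,step Faux-read geometry (10 kb reads every 1 kb by
#'   default).
#' @param with_seq Store read sequences in the BAM.
#' @param representation Alignment encoding passed to [truth_alignments()].
#' @param noise Optional list `(sub_rate, indel_rate, seed)` forwarded to
#'   [add_read_noise()].
#' @return A list: `bam`, `truth` (expected-coordinate tibble), `reads`,
#'   `map`, `seqs`.
#' @export
run_scenario <- function(spec, reference, dir, read_len = 10000L,
                         step = 1000L, with_seq = FALSE,
                         representation = "split", noise = NULL) {
  rr <- apply_rearrangement(reference, spec)
  reads <- list_rbind(imap(rr$seqs, function(sq, contig) {
    make_faux_reads(sq, read_len = read_len, step = step,
                    circular = isTRUE(rr$circular[[contig]]),
                    contig = contig)
  }))
  attr(reads, "read_len") <- as.integer(read_len)
  attr(reads, "step") <- as.integer(step)
  if (!is.null(noise)) {
    reads <- add_read_noise(reads, sub_rate = noise$sub_rate %||% 0,
                            indel_rate = noise$indel_rate %||% 0,
                            seed = noise$seed %||% 1L)
  }
  ref_lengths <- setNames(Biostrings::width(reference), names(reference))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bam <- truth_alignments(reads, rr$map, ref_lengths,
                          file.path(dir, spec$id),
                          circular = rr$circular,
                          representation = representation,
                          with_seq = with_seq)
  list(bam = bam, truth = rr$truth, reads = reads, map = rr$map,
       seqs = rr$seqs)
}

#' Compare a call against a scenario's truth record
#'
#' Type agreement accepts the truth type among the call's alternatives
#' (e.g. a ring-chromosome scenario called as tandem duplication with the
#' ring alternative), coordinate agreement is exact (0 bp), and the
#' ambiguity check requires alternatives exactly when the scenario belongs
#' to one of the two ambiguous classes.
#'
#' @param call A one-row `sv_calls` tibble.
#' @param truth A truth tibble row from [apply_rearrangement()].
#' @return A one-row tibble: `id`, `ok_type`, `ok_coords`, `ok_ambiguity`.
#' @export
check_scenario_call <- function(call, truth) {
  alts <- call$alternatives[[1]]
  ok_type <- call$type == truth$kind || truth$kind %in% alts
  ok_coords <- FALSE
  if (truth$kind %in% c("deletion", "inversion", "tandem_duplication",
                        "ring_chromosome")) {
    ok_coords <- isTRUE(call$chrom_a == truth$chrom_a &&
                          call$bnd_a == truth$bnd_a &&
                          call$bnd_b == truth$bnd_b)
  } else if (truth$kind %in% c("translocation_balanced",
                               "translocation_unbalanced")) {
    # chromosome assignment is name-sorted in calls
    coords <- tibble(chrom = c(call$chrom_a, call$chrom_b),
                     bnd = c(call$bnd_a, call$bnd_b))
    want <- tibble(chrom = c(truth$chrom_a, truth$chrom_b),
                   bnd = c(truth$bnd_a, truth$bnd_b))
    ok_coords <- isTRUE(all(dplyr::arrange(coords, .data$chrom, .data$bnd) ==
                              dplyr::arrange(want, .data$chrom, .data$bnd)))
  } else if (truth$kind == "insertion") {
    ok_coords <- isTRUE(call$chrom_a == truth$chrom_a &&
                          call$bnd_a == truth$bnd_a &&
                          call$origin_chrom == truth$origin_chrom &&
                          call$origin_start == truth$origin_x + 1L &&
                          call$origin_end == truth$origin_y &&
                          call$origin_inverted == truth$inverted)
  } else if (truth$kind == "complex_insertion_deletion") {
    ok_coords <- isTRUE(call$chrom_a == truth$chrom_a &&
                          call$bnd_a == truth$bnd_a &&
                          call$bnd_b == truth$bnd_b &&
                          call$origin_chrom == truth$origin_chrom &&
                          call$origin_start == truth$origin_x + 1L &&
                          call$origin_end == truth$origin_y &&
                          call$origin_inverted == truth$inverted &&
                          (is.na(truth$loss_p) ||
                             (call$loss_start == truth$loss_p + 1L &&
                                call$loss_end == truth$loss_q)))
  }
  tibble(
    id = truth$id,
    ok_type = ok_type,
    ok_coords = ok_coords,
    ok_ambiguity = (length(alts) > 0L) == truth$expects_alternatives,
    called_type = call$type,
    alternatives = paste(alts, collapse = ",")
  )
}
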