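# Consensus coordinates, annotation pathways, HGVS-like rendering.

new_call_for_test <- function(type, chrom, pos_a, pos_b) {
  splitsv:::new_call(type, chrom_a = chrom, chrom_b = chrom,
                     pos_a = pos_a, pos_b = pos_b,
                     bnd_a = pos_a - 1L, bnd_b = pos_b)
}

test_that("consensus takes the per-slot lower median", {
  expect_equal(consensus_coordinates(data.frame(p = c(100, 100, 101)))$p, 100)
  expect_equal(consensus_coordinates(data.frame(p = 42, q = 99)),
               tibble::tibble(p = 42, q = 99))
  expect_error(
    consensus_coordinates(data.frame(chrom = c("chr1", "chr2"), p = c(1, 2))),
    class = "splitsv_input_error"
  )
  expect_error(consensus_coordinates(list(c(1, 2), c(1, 2, 3))),
               class = "splitsv_input_error")
})

test_that("a majority of exact values always wins the median", {
  # brute-force property: 52 exact copies of v among 101 tuples beat up to
  # 49 corrupted values regardless of the jitter's direction
  set.seed(123)
  v <- 146534703
  for (i in 1:20) {
    n_bad <- sample(0:49, 1)
    vals <- c(rep(v, 101 - n_bad), v + sample(c(-500:-1, 1:500), n_bad,
                                              replace = TRUE))
    vals <- sample(vals)
    expect_equal(consensus_coordinates(data.frame(p = vals))$p, v)
  }
})

test_that("adding one outlier to concordant reads never moves the consensus", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:9, 1)
    base <- rep(sample.int(1e6, 1), n)
    with_outlier <- c(base, base[1] + sample(c(-1e5:-1, 1:1e5), 1))
    expect_equal(consensus_coordinates(data.frame(p = with_outlier))$p,
                 consensus_coordinates(data.frame(p = base))$p)
  }
})

test_that("error-free simulated deletions annotate to exact 1-based endpoints", {
  del <- fixture_deletion()
  det <- sv_detect(del$bam, fixture_region(del$truth))
  call <- annotate_simple(det$split_reads, "deletion")
  expect_equal(call$pos_a, del$truth$bnd_a + 1L)
  expect_equal(call$pos_b, del$truth$bnd_b)
  expect_equal(call$hgvs, sprintf("chrT1:%d_%ddel", del$truth$bnd_a + 1L,
                                  del$truth$bnd_b))
  expect_gt(call$support, 5L)
})

test_that("jittered junction ends annotate to the per-side medians", {
  jitter_a <- c(-3L, 0L, 2L, 1L, -1L)
  jitter_b <- c(2L, -2L, 0L, 3L, -3L)
  s <- 50000L; e <- 90000L
  sr <- dplyr::bind_rows(purrr::map(1:5, function(i) {
    tibble::tibble(
      read_id = paste0("j", i), chrom = "chr1",
      ref_start = c(40000L, e + jitter_b[i]),
      ref_end = c(s + jitter_a[i], 99000L),
      strand = "+", read_start = c(0L, 10000L),
      read_end = c(10000L, 19000L), read_len = 19000L, mapq = 60L,
      role = c("primary", "supplementary"), cigar = NA, sa = NA,
      synthesized = FALSE, seg_index = 0:1, n_segs = 2L,
      total_read_length = 19000L, consistent = TRUE
    )
  }))
  call <- annotate_simple(sr, "deletion")
  expect_equal(call$bnd_a, as.integer(median_lo_oracle(s + jitter_a)))
  expect_equal(call$bnd_b, as.integer(median_lo_oracle(e + jitter_b)))
})

test_that("annotation refuses reads inconsistent with the requested type", {
  del <- fixture_deletion()
  det <- sv_detect(del$bam, fixture_region(del$truth))
  err <- expect_error(annotate_simple(det$split_reads, "inversion"),
                      class = "splitsv_annotation_error")
  expect_match(conditionMessage(err), "fx_del")  # offending read ids named
})

test_that("forcing the ring pathway reports the duplication alternative", {
  dup <- fixture_scenario(
    rearrangement_spec("fx_dup2", "tandem_duplication", "chrT2", 20000, 60000)
  )
  det <- sv_detect(dup$bam, fixture_region(dup$truth))
  call <- annotate_simple(det$split_reads, "ring_chromosome")
  expect_equal(call$type, "ring_chromosome")
  expect_true("tandem_duplication" %in% call$alternatives[[1]])
  expect_equal(call$bnd_a, 20000L)
  expect_equal(call$bnd_b, 60000L)
})

test_that("complex annotation reports origin, orientation and loss", {
  cx <- fixture_complex()
  det <- sv_detect(cx$bam, fixture_region(cx$truth))
  memb <- tidyr::unnest(
    dplyr::select(det$columns$clusters, "column_id", "members"), "members"
  )
  flank_cols <- det$columns$columns$column_id[
    det$columns$columns$chrom == cx$truth$chrom_a &
      det$columns$columns$position %in% c(cx$truth$bnd_a, cx$truth$bnd_b)
  ]
  reads_of <- function(col) {
    ids <- memb$read_id[memb$column_id == col]
    det$split_reads[det$split_reads$read_id %in% ids, ]
  }
  call <- annotate_complex(reads_of(flank_cols[1]), reads_of(flank_cols[2]))
  expect_equal(call$type, "complex_insertion_deletion")
  expect_equal(call$origin_chrom, "chrT2")
  expect_equal(call$origin_start, cx$truth$origin_x + 1L)
  expect_equal(call$origin_end, cx$truth$origin_y)
  expect_false(call$origin_inverted)
  expect_equal(call$loss_start, cx$truth$loss_p + 1L)
  expect_equal(call$loss_end, cx$truth$loss_q)
  expect_equal(
    call$description,
    sprintf("INS(origin=chrT2:%d-%d;inverted=no);LOSS(chrT1:%d-%d)",
            cx$truth$origin_x + 1L, cx$truth$origin_y,
            cx$truth$loss_p + 1L, cx$truth$loss_q)
  )
  # single-column selection is refused with guidance
  expect_error(annotate_complex(reads_of(flank_cols[1])),
               class = "splitsv_annotation_error")
})

test_that("gapped groups aggregate by medians", {
  mk <- function(starts, len = 38440L) {
    tibble::tibble(
      read_id = paste0("g", seq_along(starts)), kind = "deletion",
      ref_chrom = "chr5", ref_start = as.integer(starts),
      ref_end = as.integer(starts + len), length = len,
      query_start = 0L, query_end = 0L
    )
  }
  call <- annotate_gapped(mk(c(10000, 10090, 10182)))
  expect_equal(call$bnd_a, 10090L)
  expect_equal(call$support, 3L)

  exact <- annotate_gapped(mk(rep(20000, 4)))
  expect_equal(exact$bnd_a, 20000L)
  expect_equal(exact$bnd_b, 20000L + 38440L)

  expect_warning(one <- annotate_gapped(mk(10000)),
                 class = "splitsv_support_warning")
  expect_true(one$low_confidence)

  mixed <- mk(c(1000, 1100))
  mixed$kind <- c("deletion", "insertion")
  expect_error(annotate_gapped(mixed), class = "splitsv_annotation_error")

  ins <- mk(c(5000, 5004, 5008))
  ins$kind <- "insertion"; ins$ref_end <- ins$ref_start
  ins$length <- c(38436L, 38440L, 38444L)  # lengths within 8 bp
  ic <- annotate_gapped(ins)
  expect_equal(ic$type, "insertion")
  expect_equal(ic$ins_len, 38440L)
  expect_equal(ic$bnd_a, 5004L)
})

test_that("annotation strings render deterministically and re-parse", {
  del <- new_call_for_test("deletion", "chr7", 146534703L, 146611542L)
  expect_equal(render_hgvs(del), "chr7:146534703_146611542del")
  inv <- new_call_for_test("inversion", "chr7", 27762427L, 93599530L)
  expect_equal(render_hgvs(inv), "chr7:27762427_93599530inv")

  for (x in c("chr7:146534703_146611542del", "chr12:37206133_37300424dup",
              "chr7:27762427_93599530inv",
              "chr3:1000_1001ins[invchr5:20001_30000]")) {
    expect_equal(render_hgvs(parse_hgvs(x)), x)
  }
  tr <- parse_hgvs("t(chr6;chr8)(g.167281716;g.113696100)")
  expect_equal(render_hgvs(tr), "t(chr6;chr8)(g.167281716;g.113696100)")
  expect_error(parse_hgvs("nonsense"), class = "splitsv_parse_error")
})
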