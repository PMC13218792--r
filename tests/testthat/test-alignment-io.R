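# BAM extraction, read-coordinate geometry, SA-tag linkage.

test_that("read coordinates follow from clips on either strand", {
  bam <- write_test_bam(c(
    sam_line("plain", 0L, "chr7", 1001L, "1000M"),
    sam_line("clipped_fwd", 0L, "chr7", 2001L, "500S1000M"),
    sam_line("clipped_rev", 16L, "chr7", 3001L, "1000M500S")
  ))
  segs <- read_alignments(bam, list(chrom = "chr7", start = 0, end = 10000))
  expect_equal(nrow(segs), 3L)

  plain <- segs[segs$read_id == "plain", ]
  expect_equal(plain$ref_start, 1000L)
  expect_equal(plain$ref_end, 2000L)
  expect_equal(plain$read_start, 0L)
  expect_equal(plain$read_end, 1000L)
  expect_equal(plain$role, "primary")

  fwd <- segs[segs$read_id == "clipped_fwd", ]
  expect_equal(fwd$read_start, 500L)
  expect_equal(fwd$read_end, 1500L)

  # reversing the strand together with the clip order leaves the derived
  # original-read span unchanged
  rev <- segs[segs$read_id == "clipped_rev", ]
  expect_equal(rev$read_start, 500L)
  expect_equal(rev$read_end, 1500L)
})

test_that("read span length always equals the query-consuming CIGAR width", {
  cigars <- c("1000M", "500S1000M", "300H200S700M100I40D30M20S",
              "5000M38440D5000M", "100M5I100M")
  strands <- c("+", "-", "+", "-", "+")
  span <- splitsv:::read_span(cigars, strands)
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigars, after.soft.clipping = TRUE
  )
  expect_equal(span$read_end - span$read_start, qwidth)
})

test_that("region errors are raised before any output", {
  bam <- write_test_bam(sam_line("r", 0L, "chr7", 1001L, "100M"))
  expect_error(read_alignments(bam, list(chrom = "chrZ", start = 0, end = 100)),
               class = "splitsv_region_error")
  expect_error(
    read_alignments(bam, list(chrom = "chr7", start = 0, end = 2e7)),
    regexp = "block limit"
  )
  expect_error(read_alignments("nope.bam", list(chrom = "chr7", start = 0, end = 1)),
               class = "splitsv_input_error")
  # missing index
  noidx <- tempfile(fileext = ".bam")
  file.copy(bam, noidx)
  expect_error(read_alignments(noidx, list(chrom = "chr7", start = 0, end = 1)),
               class = "splitsv_input_error")
})

test_that("secondary (flag 256) records are excluded", {
  bam <- write_test_bam(c(
    sam_line("r1", 0L, "chr7", 1001L, "1000M"),
    sam_line("r1", 256L, "chr7", 5001L, "1000M")
  ))
  segs <- read_alignments(bam, list(chrom = "chr7", start = 0, end = 10000))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$role, "primary")
})

test_that("split reads are linked and ordered by original-read offset", {
  # primary covers read bases [0,4900); supplementary '-' record covers
  # [4900,10000) after un-flipping its clips
  bam <- write_test_bam(c(
    sam_line("sr", 0L, "chr7", 101L, "4900M5100S",
             tags = "SA:Z:chr7,15001,-,5100M4900S,60,0;"),
    sam_line("sr", 2064L, "chr7", 15001L, "5100M4900H",
             tags = "SA:Z:chr7,101,+,4900M5100S,60,0;")
  ))
  segs <- read_alignments(bam, list(chrom = "chr7", start = 0, end = 30000))
  sr <- link_split_reads(segs)
  expect_equal(nrow(sr), 2L)
  expect_equal(sr$seg_index, c(0L, 1L))
  expect_equal(sr$strand, c("+", "-"))
  expect_equal(sr$read_start, c(0L, 4900L))
  expect_equal(sr$read_end, c(4900L, 10000L))
  expect_true(all(sr$consistent))
  expect_equal(sum(sr$role == "primary"), 1L)
})

test_that("a read with no SA tag yields a single-segment split read", {
  bam <- write_test_bam(sam_line("solo", 0L, "chr7", 1001L, "1000M"))
  sr <- link_split_reads(read_alignments(bam, list(chrom = "chr7", start = 0,
                                                   end = 10000)))
  expect_equal(nrow(sr), 1L)
  expect_equal(sr$n_segs, 1L)
  expect_equal(extract_junctions(sr), extract_junctions(sr[0, ]))
})

test_that("segments referenced only in the SA tag are synthesized", {
  # partner lies outside any plausible query: only the SA entry describes it
  bam <- write_test_bam(
    sam_line("sa", 0L, "chr7", 101L, "4900M5100S",
             tags = "SA:Z:chr8,90001,+,4900S5100M,60,0;")
  )
  segs <- read_alignments(bam, list(chrom = "chr7", start = 0, end = 10000))
  sr <- link_split_reads(segs)
  expect_equal(nrow(sr), 2L)
  synth <- sr[sr$synthesized, ]
  expect_equal(synth$chrom, "chr8")
  expect_equal(synth$ref_start, 90000L)
  expect_equal(synth$read_start, 4900L)
  expect_equal(synth$role, "supplementary")
})

test_that("SA-synthesized segments equal the parsed supplementary records", {
  sc <- fixture_deletion()
  region <- fixture_region(sc$truth)
  segs <- read_alignments(sc$bam, region)
  full <- link_split_reads(segs)
  # drop observed supplementary records; relink from primaries + SA only
  prim_only <- segs[segs$role == "primary", ]
  relinked <- link_split_reads(prim_only)
  shared <- intersect(
    full$read_id[full$n_segs == 2], relinked$read_id[relinked$n_segs == 2]
  )
  expect_gt(length(shared), 5)
  cols <- c("read_id", "chrom", "ref_start", "ref_end", "strand",
            "read_start", "read_end", "seg_index")
  a <- full[full$read_id %in% shared, cols]
  b <- relinked[relinked$read_id %in% shared, cols]
  expect_equal(as.data.frame(a[do.call(order, a), ]),
               as.data.frame(b[do.call(order, b), ]),
               ignore_attr = TRUE)
})

test_that("unparsable SA entries are skipped with a warning, not a crash", {
  bam <- write_test_bam(
    sam_line("bad", 0L, "chr7", 101L, "4900M5100S",
             tags = "SA:Z:chr8,notanumber,+,oops,60,0;")
  )
  segs <- read_alignments(bam, list(chrom = "chr7", start = 0, end = 10000))
  expect_warning(sr <- link_split_reads(segs), class = "splitsv_sa_warning")
  expect_equal(nrow(sr), 1L)
})

test_that("gross read-span overlaps mark the read inconsistent", {
  bam <- write_test_bam(c(
    sam_line("ov", 0L, "chr7", 101L, "6000M4000S",
             tags = "SA:Z:chr7,15001,+,5000S5000M,60,0;"),
    sam_line("ov", 2048L, "chr7", 15001L, "5000H5000M",
             tags = "SA:Z:chr7,101,+,6000M4000S,60,0;")
  ))
  sr <- link_split_reads(read_alignments(bam, list(chrom = "chr7", start = 0,
                                                   end = 30000)))
  expect_false(any(sr$consistent))  # 1000 bp overlap > 200 bp tolerance
  expect_equal(nrow(extract_junctions(sr)), 0L)
  # a small overlap within tolerance is fine
  sr2 <- link_split_reads(read_alignments(bam, list(chrom = "chr7", start = 0,
                                                    end = 30000)),
                          overlap_tol = 1500L)
  expect_true(all(sr2$consistent))
})

test_that("large CIGAR indels are reported above the length threshold only", {
  hits <- scan_cigar_indels("5000M38440D5000M")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$kind, "deletion")
  expect_equal(hits$length, 38440L)
  expect_equal(hits$ref_start, 5000L)  # offset after the first 5000 matches
  expect_equal(hits$ref_end, 43440L)

  expect_equal(nrow(scan_cigar_indels("100M5I100M", min_len = 10L)), 0L)

  d11 <- scan_cigar_indels("100M11D100M")
  expect_equal(d11$kind, "deletion")
  expect_equal(d11$length, 11L)

  i12 <- scan_cigar_indels("100M12I100M")
  expect_equal(i12$kind, "insertion")
  expect_equal(i12$ref_start, i12$ref_end)  # point of insertion
  expect_equal(i12$query_end - i12$query_start, 12L)
})
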