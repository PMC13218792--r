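# Simulator: rearrangement application, faux reads, truth alignments.

test_that("rearranged length equals the sum of the map piece lengths", {
  ref <- fixture_reference()
  set.seed(31)
  specs <- list(
    rearrangement_spec("p_del", "deletion", "chrT1", 20000, 70000),
    rearrangement_spec("p_inv", "inversion", "chrT1", 30000, 90000),
    rearrangement_spec("p_dup", "tandem_duplication", "chrT2", 10000, 45000),
    rearrangement_spec("p_ring", "ring_chromosome", "chrT1", 20000, 120000),
    rearrangement_spec("p_ins", "insertion", "chrT2", 10000, 35000,
                       "chrT1", 80000),
    rearrangement_spec("p_tb", "translocation_balanced", "chrT1", 60000, NA,
                       "chrT2", 40000),
    rearrangement_spec("p_cx", "complex_insertion_deletion", "chrT1",
                       20000, 45000, "chrT1", 100000, inverted = TRUE,
                       loss_len = 2000L)
  )
  for (spec in specs) {
    rr <- apply_rearrangement(ref, spec)
    for (ct in names(rr$seqs)) {
      m <- rr$map[rr$map$contig == ct, ]
      expect_equal(nchar(rr$seqs[[ct]]), sum(m$ref_end - m$ref_start),
                   info = spec$id)
    }
  }
  # deletion: two pieces; inversion: middle piece on the minus strand
  del_map <- apply_rearrangement(ref, specs[[1]])$map
  expect_equal(nrow(del_map), 2L)
  inv_map <- apply_rearrangement(ref, specs[[2]])$map
  expect_equal(inv_map$orientation, c("+", "-", "+"))
  ring <- apply_rearrangement(ref, specs[[4]])
  expect_equal(nrow(ring$map), 1L)
  expect_true(ring$circular[[1]])
})

test_that("invalid specs are rejected", {
  ref <- fixture_reference()
  expect_error(
    apply_rearrangement(ref, rearrangement_spec("bad1", "deletion", "chrT1",
                                                50000, 10000)),
    class = "splitsv_spec_error"
  )
  expect_error(
    apply_rearrangement(ref, rearrangement_spec("bad2", "deletion", "chrT1",
                                                50000, 9e6)),
    class = "splitsv_spec_error"
  )
  expect_error(
    apply_rearrangement(ref, rearrangement_spec(
      "bad3", "complex_insertion_deletion", "chrT1", 30000, 60000,
      "chrT1", 145000, loss_len = 10000L  # loss runs off the contig end
    )),
    class = "splitsv_spec_error"
  )
  expect_error(
    apply_rearrangement(ref, rearrangement_spec(
      "bad4", "translocation_balanced", "chrT1", 60000, NA, "chrZZ", 1000
    )),
    class = "splitsv_spec_error"
  )
})

test_that("faux reads tile with alternating orientations and exact content", {
  ref <- fixture_reference()
  sq <- substr(as.character(ref[["chrT1"]]), 1, 12000)
  rs <- make_faux_reads(sq, read_len = 10000L, step = 1000L)
  expect_equal(nrow(rs), 12L)
  expect_equal(rs$offset, seq(0L, 11000L, by = 1000L))
  expect_equal(rs$orientation, rep(c("+", "-"), 6))
  expect_equal(rs$length[1:3], rep(10000L, 3))       # full-length starts
  expect_equal(rs$length[4:12], 12000L - rs$offset[4:12])  # truncated tail

  # every read is an exact substring or reverse complement of the source
  for (i in seq_len(nrow(rs))) {
    window <- substr(sq, rs$offset[i] + 1, rs$offset[i] + rs$length[i])
    expected <- if (rs$orientation[i] == "+") window else
      splitsv:::revcomp(window)
    expect_identical(rs$seq[i], expected)
  }

  short <- make_faux_reads(substr(sq, 1, 5000), read_len = 10000L,
                           step = 1000L)
  expect_equal(short$length[1], 5000L)
  expect_equal(short$orientation[1], "+")

  # property over random windows of a rearranged contig
  rr <- apply_rearrangement(ref, rearrangement_spec(
    "fr_inv", "inversion", "chrT1", 30000, 90000))
  reads <- make_faux_reads(rr$seqs[[1]], contig = names(rr$seqs)[1])
  set.seed(21)
  for (i in sample(nrow(reads), 12)) {
    window <- substr(rr$seqs[[1]], reads$offset[i] + 1,
                     reads$offset[i] + reads$length[i])
    expected <- if (reads$orientation[i] == "+") window else
      splitsv:::revcomp(window)
    expect_identical(reads$seq[i], expected)
  }
})

test_that("the simulator is deterministic", {
  r1 <- sim_reference(c(a = 50000L), seed = 99L)
  r2 <- sim_reference(c(a = 50000L), seed = 99L)
  expect_identical(as.character(r1), as.character(r2))
  reads1 <- make_faux_reads(as.character(r1[[1]]))
  reads2 <- make_faux_reads(as.character(r2[[1]]))
  expect_identical(reads1$seq, reads2$seq)
})

test_that("truth alignments round-trip through the BAM layer field by field", {
  del <- fixture_deletion()
  segs <- read_alignments(del$bam, fixture_region(del$truth))
  sr <- link_split_reads(segs)
  # read spans reconstructed from clips must tile each read without gaps
  by_read <- split(sr, sr$read_id)
  for (g in by_read[1:20]) {
    g <- g[order(g$seg_index), ]
    expect_equal(g$read_start[1], 0L)
    expect_equal(g$read_end[nrow(g)], g$total_read_length[1])
    if (nrow(g) > 1) {
      expect_equal(g$read_start[-1], g$read_end[-nrow(g)])
    }
  }
  # split reads crossing the deletion junction span it exactly; reads in
  # either orientation traverse the same boundary pair
  jn <- extract_junctions(sr)
  expect_gt(nrow(jn), 5)
  expect_true(all(pmin(jn$pos_a, jn$pos_b) == del$truth$bnd_a))
  expect_true(all(pmax(jn$pos_a, jn$pos_b) == del$truth$bnd_b))
  left <- ifelse(jn$side_a == "left", jn$pos_a, jn$pos_b)
  right <- ifelse(jn$side_a == "left", jn$pos_b, jn$pos_a)
  expect_true(all(left == del$truth$bnd_a & right == del$truth$bnd_b))
})

test_that("reads wrap the ring junction", {
  ring <- fixture_scenario(
    rearrangement_spec("fx_ring", "ring_chromosome", "chrT1", 20000, 120000)
  )
  det <- sv_detect(ring$bam, fixture_region(ring$truth))
  jn <- det$junctions
  expect_gt(nrow(jn), 5)
  expect_setequal(unique(c(jn$pos_a, jn$pos_b)), c(20000L, 120000L))
})

test_that("substitution noise is reproducible and binomially calibrated", {
  ref <- fixture_reference()
  rs <- make_faux_reads(substr(as.character(ref[["chrT2"]]), 1, 30000))
  expect_identical(add_read_noise(rs, 0, 0, seed = 1L), rs)
  n1 <- add_read_noise(rs, 0.05, 0, seed = 7L)
  n2 <- add_read_noise(rs, 0.05, 0, seed = 7L)
  expect_identical(n1$seq, n2$seq)
  expect_false(identical(n1$seq, rs$seq))
  # per-read mismatch count within 3 sigma of Binomial(len, rate)
  mism <- purrr::map2_int(n1$seq, rs$seq, function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  })
  mu <- 0.05 * rs$length
  sigma <- sqrt(rs$length * 0.05 * 0.95)
  expect_true(all(abs(mism - mu) <= 3 * sigma))
})

test_that("the scenario catalogue matches its stated composition", {
  suite <- scenario_suite()
  expect_equal(nrow(suite), 68L)
  expect_equal(sum(suite$class == "simple"), 32L)
  expect_equal(sum(suite$class == "complex"), 36L)
  # every simple kind appears in at least two size variants
  sizes <- suite %>%
    dplyr::filter(.data$class == "simple",
                  .data$kind %in% c("deletion", "inversion",
                                    "tandem_duplication", "insertion")) %>%
    dplyr::group_by(.data$kind) %>%
    dplyr::summarise(n_sizes = dplyr::n_distinct(.data$end - .data$start))
  expect_true(all(sizes$n_sizes >= 2))
  # exactly the ring/duplication and same-chromosome inverted
  # insertion-deletion classes are tagged expected-ambiguous
  amb <- suite[suite$expects_alternatives, ]
  expect_setequal(unique(amb$kind),
                  c("tandem_duplication", "ring_chromosome",
                    "complex_insertion_deletion"))
  expect_true(all(amb$inverted[amb$kind == "complex_insertion_deletion"]))
  expect_true(all(amb$chrom[amb$kind == "complex_insertion_deletion"] ==
                    amb$chrom2[amb$kind == "complex_insertion_deletion"]))
  # rings share breakpoints with tandem duplications for the identity check
  rings <- suite[suite$kind == "ring_chromosome", c("chrom", "start", "end")]
  dups <- suite[suite$kind == "tandem_duplication", c("chrom", "start", "end")]
  expect_gt(nrow(dplyr::inner_join(rings, dups,
                                   by = c("chrom", "start", "end"))), 1L)
  # the suite validates against the bundled reference
  expect_silent(scenario_suite(sim_reference()))
})
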