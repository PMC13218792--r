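# Junction extraction and breakpoint clustering.

make_split <- function(read_id, segs) {
  # segs: list of c(chrom, start, end, strand); read offsets tiled contiguously
  rows <- purrr::imap(segs, function(s, i) {
    tibble::tibble(
      read_id = read_id, chrom = s[[1]],
      ref_start = as.integer(s[[2]]), ref_end = as.integer(s[[3]]),
      strand = s[[4]], mapq = 60L,
      role = if (i == 1) "primary" else "supplementary",
      cigar = NA_character_, sa = NA_character_, synthesized = FALSE,
      width = as.integer(s[[3]]) - as.integer(s[[2]])
    )
  })
  out <- dplyr::bind_rows(rows)
  out$read_start <- cumsum(c(0L, utils::head(out$width, -1)))
  out$read_end <- out$read_start + out$width
  out$read_len <- sum(out$width)
  out$seg_index <- seq_len(nrow(out)) - 1L
  out$n_segs <- nrow(out)
  out$total_read_length <- out$read_len
  out$consistent <- TRUE
  out$width <- NULL
  out
}

test_that("junction ends carry the correct boundary, side and strand", {
  sr <- make_split("del_read", list(
    c("chr7", 100, 5000, "+"), c("chr7", 15000, 20100, "+")
  ))
  j <- extract_junctions(sr)
  expect_equal(nrow(j), 1L)
  expect_equal(j$pos_a, 5000L); expect_equal(j$side_a, "left")
  expect_equal(j$pos_b, 15000L); expect_equal(j$side_b, "right")
  expect_equal(j$strand_a, "+"); expect_equal(j$strand_b, "+")
  expect_equal(j$read_gap, 0L)

  # the same junction read on the opposite strand gives the same boundaries
  rev <- make_split("del_read_rev", list(
    c("chr7", 15000, 20100, "-"), c("chr7", 100, 5000, "-")
  ))
  jr <- extract_junctions(rev)
  expect_setequal(c(jr$pos_a, jr$pos_b), c(5000L, 15000L))
  expect_setequal(c(jr$side_a, jr$side_b), c("left", "right"))

  # translocation-like: two chromosomes in one junction
  tl <- extract_junctions(make_split("t", list(
    c("chr6", 1000, 8000, "+"), c("chr8", 50000, 58000, "+")
  )))
  expect_equal(tl$chrom_a, "chr6")
  expect_equal(tl$chrom_b, "chr8")

  # three segments -> two junctions, order indices 0 and 1
  three <- extract_junctions(make_split("m", list(
    c("chr7", 0, 3000, "+"), c("chr7", 9000, 12000, "+"),
    c("chr7", 20000, 23000, "+")
  )))
  expect_equal(three$order_index, c(0L, 1L))
})

test_that("clustering follows the 250-nt / 2-read rule", {
  mk <- function(positions) {
    dplyr::bind_rows(purrr::imap(positions, function(p, i) {
      extract_junctions(make_split(paste0("r", i), list(
        c("chr1", 0, p, "+"), c("chr1", p + 60000, p + 70000, "+")
      )))
    }))
  }
  # two ends 200 apart merge into one supported breakpoint
  cl <- cluster_junctions(mk(c(1000, 1200)))
  left <- cl[cl$side == "left", ]
  expect_equal(nrow(left), 1L)
  expect_equal(left$support, 2L)
  expect_equal(left$position, 1000L)  # lower median of {1000, 1200}

  # a 300-nt gap does not merge and singletons are discarded
  cl2 <- cluster_junctions(mk(c(1000, 1300)))
  expect_equal(nrow(cl2[cl2$side == "left", ]), 0L)

  expect_equal(nrow(cluster_junctions(mk(integer(0)))), 0L)
})

test_that("clusters match the brute-force transitive-closure oracle", {
  set.seed(99)
  for (rep in 1:5) {
    true_bp <- c(100000L, 200000L)
    ends <- unlist(lapply(true_bp, function(b) b + sample(-50:50, 10)))
    jn <- dplyr::bind_rows(purrr::imap(as.list(ends), function(p, i) {
      extract_junctions(make_split(paste0("r", i), list(
        c("chrX", 0, p, "+"), c("chrX", 500000, 510000, "+")
      )))
    }))
    cl <- cluster_junctions(jn)
    left <- cl[cl$side == "left", ]
    oracle <- oracle_clusters(ends, window = 250L, min_support = 2L)
    expect_equal(nrow(left), length(oracle))
    expect_setequal(left$position,
                    as.integer(vapply(oracle, median_lo_oracle, 0)))
    expect_setequal(left$support, lengths(oracle))
  }
})

test_that("clustering is permutation invariant and conserves support", {
  set.seed(7)
  ends <- sample(c(5000:5200, 9000:9050, 40000), 30, replace = TRUE)
  jn <- dplyr::bind_rows(purrr::imap(as.list(ends), function(p, i) {
    extract_junctions(make_split(paste0("r", i), list(
      c("chrX", 0, p, "+"), c("chrX", 200000, 210000, "+")
    )))
  }))
  cl1 <- cluster_junctions(jn)
  cl2 <- cluster_junctions(jn[sample(nrow(jn)), ])
  expect_equal(cl1 %>% dplyr::select(-members),
               cl2 %>% dplyr::select(-members))
  # support conservation per (chrom, side): clustered + discarded = total
  left <- cl1[cl1$side == "left", ]
  oracle <- oracle_clusters(ends, min_support = 1L)
  discarded <- sum(lengths(oracle)[lengths(oracle) < 2])
  expect_equal(sum(left$support) + discarded, length(ends))
})

test_that("column building pools sides and pairs columns through reads", {
  del <- fixture_deletion()
  det <- sv_detect(del$bam, fixture_region(del$truth))
  expect_equal(nrow(det$columns$columns), 2L)
  expect_equal(nrow(det$columns$pairing), 1L)
  expect_equal(as.character(assess_complexity(det$columns)), "simple")

  ins <- fixture_insertion()
  det_ins <- sv_detect(ins$bam, fixture_region(ins$truth))
  expect_equal(nrow(det_ins$columns$columns), 3L)
  expect_equal(as.character(assess_complexity(det_ins$columns)), "simple")

  cx <- fixture_complex()
  det_cx <- sv_detect(cx$bam, fixture_region(cx$truth))
  expect_equal(nrow(det_cx$columns$columns), 4L)
  expect_equal(as.character(assess_complexity(det_cx$columns)), "complex")
})

test_that("the partner window is centred on the modal partner and clipped", {
  jn <- dplyr::bind_rows(purrr::imap(as.list(rep(15000L, 3)), function(p, i) {
    extract_junctions(make_split(paste0("r", i), list(
      c("chr7", 0, 2000, "+"), c("chr7", p, p + 9000, "+")
    )))
  }))
  cl <- cluster_junctions(jn)
  left <- cl[cl$side == "left", ]
  w <- secondary_window(left)
  expect_equal(w, list(chrom = "chr7", start = 0, end = 65000))
  w10 <- secondary_window(left, half_width = 10000L)
  expect_equal(w10$end - w10$start, 20000)
  wclip <- secondary_window(left, chrom_lengths = c(chr7 = 60000))
  expect_equal(wclip$end, 60000)
  expect_error(secondary_window(left[0, ]), class = "splitsv_input_error")
})
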