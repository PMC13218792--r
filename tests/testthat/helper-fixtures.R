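# Shared fixtures.  Everything is generated in code at test time; the small
# reference and scenario BAMs are cached per session so several test files
# can reuse them without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

fixture_reference <- function() {
  if (is.null(.fixture_env$ref)) {
    .fixture_env$ref <- sim_reference(c(chrT1 = 150000L, chrT2 = 100000L),
                                      seed = 424242L)
  }
  .fixture_env$ref
}

# materialise a scenario once per session; key by id
fixture_scenario <- function(spec, ...) {
  key <- paste0("sc_", spec$id)
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), "splitsv-fixtures")
    .fixture_env[[key]] <- run_scenario(spec, fixture_reference(), dir,
                                        with_seq = FALSE, ...)
  }
  .fixture_env[[key]]
}

fixture_deletion <- function() {
  fixture_scenario(
    rearrangement_spec("fx_del", "deletion", "chrT1", 50000, 80000)
  )
}

fixture_insertion <- function() {
  fixture_scenario(
    rearrangement_spec("fx_ins", "insertion", "chrT1", 30000, 55000,
                       "chrT1", 110000)
  )
}

fixture_complex <- function() {
  fixture_scenario(
    rearrangement_spec("fx_cplx", "complex_insertion_deletion",
                       "chrT2", 20000, 45000, "chrT1", 100000,
                       loss_len = 3000L)
  )
}

fixture_region <- function(truth, pad = 0L) {
  lens <- c(chrT1 = 150000, chrT2 = 100000)
  list(chrom = truth$region_chrom,
       start = max(0, truth$region_start - pad),
       end = min(lens[[truth$region_chrom]], truth$region_end + pad))
}

# hand-built SAM -> sorted indexed BAM, for unit tests of the BAM layer
write_test_bam <- function(lines, prefix = tempfile(),
                           ref_lengths = c(chr7 = 250000L, chr8 = 250000L)) {
  sam <- paste0(prefix, ".sam")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                      as.integer(ref_lengths)))
  writeLines(c(header, lines), sam)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

sam_line <- function(qname, flag, rname, pos1, cigar, mapq = 60L,
                     seq = "*", tags = character()) {
  paste(c(qname, flag, rname, pos1, mapq, cigar, "*", 0L, 0L, seq, "*",
          "NM:i:0", tags), collapse = "\t")
}

# brute-force single-linkage oracle: transitive closure of the pairwise
# "within window" relation, plus the support filter and lower-median
# representative -- independent of the package's sorted-gap implementation
oracle_clusters <- function(pos, window = 250L, min_support = 2L) {
  n <- length(pos)
  if (!n) return(list())
  adj <- abs(outer(pos, pos, "-")) <= window
  comp <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & comp == 0L)
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  comps <- split(pos, comp)
  keep(comps, function(x) length(x) >= min_support)
}

keep <- purrr::keep

median_lo_oracle <- function(x) sort(x)[ceiling(length(x) / 2)]
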