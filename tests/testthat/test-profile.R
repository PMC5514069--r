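test_that("insertion points follow the strand convention", {
  aln <- structure(list(
    alignments = data.frame(
      read_id = c("f", "r"), pos = c(1001L, 1001L), width = 50L,
      strand = c("+", "-"), n_hits = 1L, multimapping = FALSE),
    tallies = c(input = 2L)), class = "tradis_alignments")
  prof <- profile_from_alignments(aln, genome_length = 2000L)
  expect_equal(prof$fwd[1001], 1L)           # 5'-most base of a + read
  expect_equal(prof$rev[1050], 1L)           # 3'-most base of a - read
  expect_equal(prof$mapped_reads, 2L)
})

test_that("unique sites distinguish multiplicity, strand collapse and spacing", {
  prof <- profile_at(4000L, positions = 1001L, counts = 3L,
                     rev_positions = c(1001L, 2002L))
  us <- unique_sites(prof)
  expect_equal(us$n_sites, 2L)               # 1001 (both strands) + 2002
  expect_equal(us$sites, c(1001L, 2002L))
  expect_equal(us$mean_spacing, 2000)
  per_strand <- unique_sites(prof, collapse_strands = FALSE)
  expect_equal(per_strand$n_sites, 3L)
  expect_equal(prof$mapped_reads, 5L)        # 3 reads at one site + 2 others
})

test_that("plot tracks follow the two-column dialect and round-trip exactly", {
  prof <- insertion_profile(c(0L, 2L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L, 0L))
  f <- withr::local_tempfile()
  write_plot(prof, f)
  expect_equal(readLines(f), c("0 0", "2 0", "0 0", "0 0", "1 0"))

  set.seed(11)
  rnd <- insertion_profile(rpois(500, 0.2), rpois(500, 0.2))
  f2 <- withr::local_tempfile(); f3 <- withr::local_tempfile()
  write_plot(rnd, f2)
  back <- read_plot(f2)
  expect_identical(back$fwd, rnd$fwd)
  expect_identical(back$rev, rnd$rev)
  write_plot(back, f3)
  expect_identical(readLines(f2), readLines(f3))  # byte-identical round trip

  empty <- insertion_profile(integer(7), integer(7))
  f4 <- withr::local_tempfile()
  write_plot(empty, f4)
  expect_equal(readLines(f4), rep("0 0", 7))
})

test_that("exact-match location honours length filters and repeat exclusion", {
  ann <- toy_annotation(L = 3000L)
  gchr <- as.character(ann$sequence)
  ok42 <- substr(gchr, 501, 542)                       # unique 42-mer
  short41 <- substr(gchr, 501, 541)
  reads <- Biostrings::DNAStringSet(c(a = ok42, b = short41))
  res <- locate_reads_exact(reads, ann, trim_tn = FALSE)
  expect_equal(unname(res$tallies["too_short"]), 1L)
  expect_equal(res$alignments$read_id, "a")
  expect_equal(res$alignments$pos, 501L)
  expect_equal(res$alignments$strand, "+")

  # duplicated locus -> multimapping, excluded from the profile
  dup <- paste0(substr(gchr, 1, 100),
                substr(gchr, 901, 950),   # 50-mer planted twice
                substr(gchr, 101, 3000 - 50))
  ann2 <- tradis_annotation(dup, ann$genes)
  rd <- Biostrings::DNAStringSet(c(m = substr(dup, 101, 150)))
  res2 <- locate_reads_exact(rd, ann2, trim_tn = FALSE)
  expect_true(res2$alignments$multimapping)
  prof <- profile_from_alignments(res2, genome_length = 3000L)
  expect_equal(prof$mapped_reads, 0L)
})

test_that("exact-match location agrees with a brute-force scan oracle", {
  set.seed(21)
  gchr <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                collapse = "")
  genes <- data.frame(gene_id = "g", contig = "chr", start = 1, end = 100,
                      strand = "+", feature_type = "CDS", product = NA)
  ann <- tradis_annotation(gchr, genes)
  starts <- sample(4000, 15)
  fwd_reads <- substring(gchr, starts, starts + 44)
  rev_reads <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(fwd_reads[1:5])))
  reads <- Biostrings::DNAStringSet(c(fwd_reads, rev_reads))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  res <- locate_reads_exact(reads, ann, trim_tn = FALSE)
  for (i in seq_along(reads)) {
    oracle <- brute_force_locate(as.character(reads[[i]]), gchr)
    row <- res$alignments[res$alignments$read_id == names(reads)[i], ]
    expect_equal(nrow(row), as.integer(length(oracle) > 0))
    if (nrow(row)) {
      expect_equal(unname(row$n_hits), length(oracle))
      expect_equal(unname(row$pos), unname(oracle[[1]]["pos"]))
      expect_equal(row$strand,
                   if (oracle[[1]]["strand"] == 1L) "+" else "-")
    }
  }
})

test_that("profiles are invariant to read input order and conserve reads", {
  cfg <- small_config(seed = 2L)
  gen <- generate_genome(cfg)
  lib <- generate_library(gen$annotation, gen$truth, cfg)
  idx <- sample(length(lib$reads))
  p1 <- profile_from_alignments(locate_reads_exact(lib$reads, gen$annotation),
                                genome_length = cfg$genome_length)
  p2 <- profile_from_alignments(
    locate_reads_exact(lib$reads[idx], gen$annotation),
    genome_length = cfg$genome_length)
  expect_identical(p1$fwd, p2$fwd)
  expect_identical(p1$rev, p2$rev)
  expect_equal(p1$mapped_reads, sum(p1$fwd) + sum(p1$rev))
})

test_that("SAM flags are honoured: unmapped/secondary skipped, mapq-0 multi excluded", {
  set.seed(31)
  gchr <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(sam, gchr)
  prof <- profile_from_alignments(sam, genome_length = 100L)
  tl <- attr(prof, "tallies")
  expect_equal(unname(tl["unmapped"]), 1L)
  expect_equal(unname(tl["secondary"]), 1L)
  expect_equal(unname(tl["multimapping"]), 1L)
  expect_equal(prof$fwd[11], 1L)     # forward read junction at POS
  expect_equal(prof$rev[60], 1L)     # reverse read junction at 3' end
  expect_equal(prof$mapped_reads, 2L)
  expect_error(profile_from_alignments(sam, genome_length = 999L),
               "does not match")
})

test_that("FASTQ ingestion applies transposon trim and quality filter", {
  cfg <- small_config(seed = 9L)
  gen <- generate_genome(cfg)
  lib <- generate_library(gen$annotation, gen$truth, cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(lib, fq)
  res <- locate_reads_exact(fq, gen$annotation)
  expect_equal(unname(res$tallies["input"]), cfg$n_insertions)
  expect_gt(mean(res$alignments$n_hits == 1L), 0.99)
  prof <- profile_from_alignments(res, genome_length = cfg$genome_length)
  # junction base equals the simulated site for both strands
  us <- unique_sites(prof)
  expect_true(all(us$sites %in% lib$sites))
})
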