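#' Per-base insertion profile
#'
#' Holds, for each base of the chromosome, the number of sequenced insertion
#' events whose transposon junction maps there, split by strand.
#'
#' @param fwd,rev Non-negative integer vectors of length `genome_length`:
#'   insertion-event counts whose junction is on the forward / reverse strand.
#' @param total_reads Total reads presented to the mapper (defaults to the sum
#'   of both strand vectors).
#' @param mapped_reads Reads retained in the profile; must equal
#'   `sum(fwd) + sum(rev)`.
#' @return An object of class `insertion_profile`.
#' @export
insertion_profile <- function(fwd, rev, total_reads = NULL, mapped_reads = NULL) {
  fwd <- as.integer(fwd); rev <- as.integer(rev)
  if (length(fwd) != length(rev))
    stop("fwd and rev count vectors differ in length")
  if (any(fwd < 0L) || any(rev < 0L)) stop("negative insertion counts")
  mp <- sum(fwd) + sum(rev)
  if (is.null(mapped_reads)) mapped_reads <- mp
  if (mapped_reads != mp)
    stop("mapped_reads (", mapped_reads, ") != sum of counts (", mp, ")")
  if (is.null(total_reads)) total_reads <- mp
  if (total_reads < mapped_reads)
    stop("total_reads < mapped_reads")
  structure(
    list(fwd = fwd, rev = rev, genome_length = length(fwd),
         total_reads = as.integer(total_reads), mapped_reads = as.integer(mp)),
    class = "insertion_profile"
  )
}

#' @export
print.insertion_profile <- function(x, ...) {
  us <- unique_sites(x)
  cat(sprintf(
    "<insertion_profile> %s bp, %s mapped reads (%s total), %s unique sites (1 per %.1f bp)\n",
    format(x$genome_length, big.mark = ","),
    format(x$mapped_reads, big.mark = ","),
    format(x$total_reads, big.mark = ","),
    format(us$n_sites, big.mark = ","), us$mean_spacing))
  invisible(x)
}

#' Read-filtering policy for TraDIS libraries
#'
#' Encodes the read-processing contract applied before mapping: a 10 bp
#' transposon trim, a 42 bp minimum read length after trimming, a PHRED-30
#' base-quality threshold required over 96% of the read, exact matching only,
#' and discarding of multimapping reads (repeat exclusion).
#'
#' @param min_length_after_trim Minimum read length after the transposon trim
#'   (bp, default 42).
#' @param tn_trim Transposon prefix length removed from the 5' end (bp,
#'   default 10).
#' @param min_base_quality PHRED threshold (default 30).
#' @param quality_fraction Minimum fraction of bases meeting
#'   `min_base_quality` (default 0.96).
#' @param allow_mismatches Logical; exact matching only when `FALSE` (default).
#' @param discard_multimappers Logical; drop reads matching more than one
#'   locus (default `TRUE`).
#' @return A list of class `read_filter_policy`.
#' @export
read_filter_policy <- function(min_length_after_trim = 42L, tn_trim = 10L,
                               min_base_quality = 30L, quality_fraction = 0.96,
                               allow_mismatches = FALSE,
                               discard_multimappers = TRUE) {
  stopifnot(min_length_after_trim >= 0, tn_trim >= 0, min_base_quality >= 0,
            quality_fraction >= 0, quality_fraction <= 1)
  structure(list(min_length_after_trim = as.integer(min_length_after_trim),
                 tn_trim = as.integer(tn_trim),
                 min_base_quality = as.integer(min_base_quality),
                 quality_fraction = quality_fraction,
                 allow_mismatches = isTRUE(allow_mismatches),
                 discard_multimappers = isTRUE(discard_multimappers)),
            class = "read_filter_policy")
}

#' Locate reads on a genome by exact matching
#'
#' A minimal exact-match locator for synthetic libraries: each read (after
#' trimming the transposon prefix and applying length/quality filters) is
#' searched on both strands of the chromosome; reads matching exactly one
#' position are emitted as alignments, reads matching several are flagged
#' multimapping (and later excluded from profiles, emulating repeat
#' exclusion). Reads spanning the circular origin are not matched.
#'
#' @param reads A [Biostrings::DNAStringSet], `QualityScaledDNAStringSet`, or
#'   path to a FASTQ file.
#' @param annotation A [tradis_annotation()].
#' @param policy A [read_filter_policy()].
#' @param trim_tn Trim `policy$tn_trim` bases off the 5' end before matching
#'   (default `TRUE`; set `FALSE` for pre-trimmed reads).
#' @return A list of class `tradis_alignments`: `alignments` (data.frame with
#'   `read_id`, `pos` = leftmost reference base, `width`, `strand`, `n_hits`,
#'   `multimapping`) and `tallies` (named integer vector of filter counts).
#' @export
locate_reads_exact <- function(reads, annotation, policy = read_filter_policy(),
                               trim_tn = TRUE) {
  quals <- NULL
  if (is.character(reads) && length(reads) == 1L) {
    # FASTQ ids become names; per-read metadata beyond that is not used
    reads <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(reads))
  }
  if (methods::is(reads, "QualityScaledDNAStringSet")) {
    quals <- methods::as(Biostrings::quality(reads), "IntegerList")
    reads <- methods::as(reads, "DNAStringSet")
  }
  if (!methods::is(reads, "DNAStringSet")) stop("'reads' must be sequences or a FASTQ path")
  n_input <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_len(n_input))

  if (trim_tn && policy$tn_trim > 0L) {
    keepable <- Biostrings::width(reads) > policy$tn_trim
    reads <- reads[keepable]; ids <- ids[keepable]
    if (!is.null(quals)) quals <- quals[keepable]
    reads <- Biostrings::subseq(reads, start = policy$tn_trim + 1L)
    if (!is.null(quals))
      quals <- quals[IRanges::IntegerList(lapply(
        lengths(quals), function(n) seq.int(policy$tn_trim + 1L, n)))]
  }

  short <- Biostrings::width(reads) < policy$min_length_after_trim
  n_short <- sum(short) + (n_input - length(reads))
  reads <- reads[!short]; ids <- ids[!short]
  if (!is.null(quals)) quals <- quals[!short]

  n_lowq <- 0L
  if (!is.null(quals) && length(reads)) {
    frac_ok <- vapply(quals, function(q) mean(q >= policy$min_base_quality), 0)
    lowq <- frac_ok < policy$quality_fraction
    n_lowq <- sum(lowq)
    reads <- reads[!lowq]; ids <- ids[!lowq]
  }

  L <- annotation$genome_length
  hits_f <- exact_hits(reads, annotation$sequence)
  hits_r <- exact_hits(reads, Biostrings::reverseComplement(annotation$sequence))
  w <- Biostrings::width(reads)
  n_hits <- hits_f$n + hits_r$n

  matched <- n_hits > 0L
  on_fwd <- hits_f$n[matched] > 0L
  # a hit in the reverse-complement maps back to reference leftmost base
  pos <- ifelse(on_fwd, hits_f$first[matched],
                L - (hits_r$first[matched] + w[matched] - 1L) + 1L)
  aln <- data.frame(read_id = ids[matched], pos = as.integer(pos),
                    width = w[matched],
                    strand = ifelse(on_fwd, "+", "-"),
                    n_hits = n_hits[matched],
                    multimapping = n_hits[matched] > 1L,
                    stringsAsFactors = FALSE)
  tallies <- c(input = n_input, too_short = n_short, low_quality = n_lowq,
               unmatched = sum(!matched), unique_match = sum(aln$n_hits == 1L),
               multimapping = sum(aln$multimapping))
  structure(list(alignments = aln, tallies = tallies), class = "tradis_alignments")
}

# exact-match hit count and first start position per read, one genome strand
exact_hits <- function(reads, genome) {
  n_reads <- length(reads)
  n <- integer(n_reads); first <- rep(NA_integer_, n_reads)
  if (!n_reads) return(list(n = n, first = first))
  widths <- Biostrings::width(reads)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(reads[idx])
    m <- Biostrings::matchPDict(pd, genome)
    cnt <- S4Vectors::elementNROWS(m)
    n[idx] <- cnt
    starts <- unlist(Biostrings::startIndex(m), use.names = FALSE)
    if (length(starts)) {
      owner <- rep(idx, cnt)
      # reversed assignment keeps the earliest hit per read
      first[rev(owner)] <- rev(starts)
    }
  }
  list(n = n, first = first)
}

#' Build an insertion profile from read alignments
#'
#' Each retained alignment contributes one insertion event at its transposon
#' junction: the 5'-most reference base for forward-strand alignments, the
#' 3'-most for reverse-strand ones. Unmapped, secondary, supplementary and
#' (optionally) multimapping records are skipped and tallied.
#'
#' @param alignments A `tradis_alignments` object from [locate_reads_exact()],
#'   or a path to a SAM/BAM file (single contig). In SAM/BAM input, records
#'   with mapping quality 0 are treated as multimapping.
#' @param policy A [read_filter_policy()]; only `discard_multimappers` is
#'   consulted here.
#' @param genome_length Expected contig length; mismatch with the SAM/BAM
#'   header is an error.
#' @return An [insertion_profile()] with a `tallies` attribute.
#' @export
profile_from_alignments <- function(alignments, policy = read_filter_policy(),
                                    genome_length) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_sam_alignments(alignments, genome_length)
  }
  if (!methods::is(alignments, "tradis_alignments"))
    stop("'alignments' must be a tradis_alignments object or a SAM/BAM path")
  aln <- alignments$alignments
  n_multi <- sum(aln$multimapping)
  if (policy$discard_multimappers) aln <- aln[!aln$multimapping, , drop = FALSE]

  fwd <- integer(genome_length); rev <- integer(genome_length)
  if (nrow(aln)) {
    ins <- ifelse(aln$strand == "+", aln$pos, aln$pos + aln$width - 1L)
    if (any(ins < 1L | ins > genome_length))
      stop("alignment outside contig of length ", genome_length)
    tf <- tabulate(ins[aln$strand == "+"], nbins = genome_length)
    tr <- tabulate(ins[aln$strand == "-"], nbins = genome_length)
    fwd <- as.integer(tf); rev <- as.integer(tr)
  }
  total <- unname(alignments$tallies["input"])
  if (is.na(total)) total <- nrow(alignments$alignments)
  prof <- insertion_profile(fwd, rev, total_reads = max(total, sum(fwd) + sum(rev)))
  attr(prof, "tallies") <- c(alignments$tallies, discarded_multimapping = n_multi)
  prof
}

# SAM/BAM -> tradis_alignments; honours flags 0x4/0x100/0x800, mapq 0 = multi
read_sam_alignments <- function(path, genome_length) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (length(hdr) != 1L)
    stop("expected a single reference contig, found ", length(hdr))
  if (!missing(genome_length) && hdr[[1L]] != genome_length)
    stop("contig length in alignment header (", hdr[[1L]],
         ") does not match annotation (", genome_length, ")")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "qwidth", "strand", "mapq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n_input <- length(b$flag)
  unmapped <- bitwAnd(b$flag, 0x4L) != 0L
  secondary <- bitwAnd(b$flag, 0x100L) != 0L
  suppl <- bitwAnd(b$flag, 0x800L) != 0L
  keep <- !(unmapped | secondary | suppl)
  multi <- !is.na(b$mapq) & b$mapq == 0L & keep
  aln <- data.frame(read_id = b$qname[keep], pos = b$pos[keep],
                    width = b$qwidth[keep],
                    strand = as.character(b$strand[keep]),
                    n_hits = ifelse(multi[keep], 2L, 1L),
                    multimapping = multi[keep], stringsAsFactors = FALSE)
  tallies <- c(input = n_input, unmapped = sum(unmapped),
               secondary = sum(secondary), supplementary = sum(suppl),
               unique_match = sum(keep & !multi), multimapping = sum(multi))
  structure(list(alignments = aln, tallies = tallies), class = "tradis_alignments")
}

#' Read / write per-base insertion "plot" tracks
#'
#' The plot-track dialect stores one line per genome base with two
#' whitespace-separated integers: the forward- then reverse-strand insertion
#' count. `write_plot()` followed by `read_plot()` is the identity.
#'
#' @param path Plot-track file path.
#' @param profile An [insertion_profile()].
#' @param total_reads Total-read count to record on the profile returned by
#'   `read_plot()` (the format itself does not carry it).
#' @return `read_plot()` returns an `insertion_profile`; `write_plot()`
#'   returns `path` invisibly.
#' @export
read_plot <- function(path, total_reads = NULL) {
  m <- as.matrix(utils::read.table(path, colClasses = "integer",
                                   col.names = c("fwd", "rev")))
  insertion_profile(m[, 1L], m[, 2L], total_reads = total_reads)
}

#' @rdname read_plot
#' @export
write_plot <- function(profile, path) {
  utils::write.table(cbind(profile$fwd, profile$rev), path, sep = " ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Unique insertion sites of a profile
#'
#' @param profile An [insertion_profile()].
#' @param collapse_strands Count a base hit on both strands as one site
#'   (default `TRUE`, the conservative reading for a target-site-duplicating
#'   transposon); `FALSE` counts per (base, strand).
#' @return A list: `n_sites`, `sites` (positions, or a data.frame with
#'   `pos`/`strand` in per-strand mode) and `mean_spacing` =
#'   `genome_length / n_sites`.
#' @export
unique_sites <- function(profile, collapse_strands = TRUE) {
  if (collapse_strands) {
    sites <- which(profile$fwd + profile$rev > 0L)
    n <- length(sites)
  } else {
    f <- which(profile$fwd > 0L); r <- which(profile$rev > 0L)
    sites <- data.frame(pos = c(f, r),
                        strand = rep(c("+", "-"), c(length(f), length(r))),
                        stringsAsFactors = FALSE)
    sites <- sites[order(sites$pos, sites$strand), , drop = FALSE]
    rownames(sites) <- NULL
    n <- nrow(sites)
  }
  list(n_sites = n, sites = sites,
       mean_spacing = if (n > 0) profile$genome_length / n else Inf)
}
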