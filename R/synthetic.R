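#' Configuration for the synthetic TraDIS library simulator
#'
#' Defaults emulate the statistical structure of a saturated Tn5 library in a
#' bifidobacterial-sized genome: a 2.42 Mbp circular chromosome carrying 1,985
#' genes of mean length 1,099 bp; 58,000 insertion mutants (colonies) yielding
#' about 46,000 unique insertion sites (one per ~52 bp) when sequenced to a
#' depth of 2 million reads; 22.8% of genes essential (no insertions in their
#' 5' 90%); an ori-to-ter insertion gradient with endpoint ratio 2.5 (about 30
#' vs 12 insertions per gene); and insertion weights elevated 1.46-fold in
#' top-quartile A+T-rich windows (densities up to ~46% higher).
#'
#' @param genome_length Chromosome length in bp.
#' @param n_genes Total gene count (includes `n_trna` + `n_rrna`).
#' @param mean_gene_length Target mean gene length in bp.
#' @param n_trna,n_rrna Number of tRNA (77 bp) and rRNA (~1.5-3 kb) genes.
#' @param essential_fraction Fraction of genes in the essential set.
#' @param n_insertions Number of insertion mutants (colonies).
#' @param seq_depth Sequenced reads used for read-level draws (rarefaction).
#' @param target_unique_sites Expected distinct insertion sites; the
#'   candidate-site pool is calibrated to this yield.
#' @param ori_ter_ratio Insertion-weight ratio at ori vs ter (linear decline
#'   with distance from ori).
#' @param at_factor Weight multiplier inside top-quartile-AT windows.
#' @param at_window_bp Window size used for the AT classification.
#' @param read_length Genomic portion of each read in bp; reads carry an
#'   additional `tn_prefix` at the 5' end.
#' @param tn_prefix Transposon prefix sequence (10 bp).
#' @param seed Integer seed; all generators are fully deterministic given the
#'   configuration.
#' @return A list of class `library_sim_config`.
#' @export
library_sim_config <- function(genome_length = 2420000L, n_genes = 1985L,
                               mean_gene_length = 1099L, n_trna = 54L,
                               n_rrna = 6L, essential_fraction = 0.228,
                               n_insertions = 58000L, seq_depth = 2000000L,
                               target_unique_sites = 46000L,
                               ori_ter_ratio = 2.5, at_factor = 1.46,
                               at_window_bp = 1000L, read_length = 50L,
                               tn_prefix = "ACTTATCAGC", seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              mean_gene_length = as.integer(mean_gene_length),
              n_trna = as.integer(n_trna), n_rrna = as.integer(n_rrna),
              essential_fraction = essential_fraction,
              n_insertions = as.integer(n_insertions),
              seq_depth = as.integer(seq_depth),
              target_unique_sites = as.integer(target_unique_sites),
              ori_ter_ratio = ori_ter_ratio, at_factor = at_factor,
              at_window_bp = as.integer(at_window_bp),
              read_length = as.integer(read_length),
              tn_prefix = toupper(tn_prefix), seed = as.integer(seed))
  stopifnot(cfg$genome_length > 0, cfg$n_genes > 0, cfg$mean_gene_length > 0,
            cfg$essential_fraction >= 0, cfg$essential_fraction < 1,
            cfg$n_insertions > 0, cfg$ori_ter_ratio > 0, cfg$at_factor > 0)
  structure(cfg, class = "library_sim_config")
}

#' Generate a synthetic annotated genome with known essential set
#'
#' Builds a circular chromosome with patchwise base composition (creating
#' genuinely A+T-rich windows), places non-overlapping genes (CDS lengths
#' gamma-distributed and rescaled so the overall mean matches the target;
#' fixed-length tRNAs and long rRNAs), and samples the essential subset
#' uniformly over all genes.
#'
#' @param config A [library_sim_config()].
#' @return A list: `annotation` (a [tradis_annotation()]) and `truth` (list
#'   with `essential_gene_ids` and the `config`).
#' @export
generate_genome <- function(config = library_sim_config()) {
  set.seed(config$seed)
  L <- config$genome_length
  # patchwise AT composition at the AT-window scale
  n_patch <- ceiling(L / config$at_window_bp)
  patch_at <- pmin(pmax(stats::rnorm(n_patch, 0.41, 0.08), 0.15), 0.70)
  p_at <- rep(patch_at, each = config$at_window_bp)[seq_len(L)]
  is_at <- stats::runif(L) < p_at
  base <- character(L)
  base[is_at] <- sample(c("A", "T"), sum(is_at), replace = TRUE)
  base[!is_at] <- sample(c("G", "C"), sum(!is_at), replace = TRUE)
  sequence <- Biostrings::DNAString(paste(base, collapse = ""))

  n_cds <- config$n_genes - config$n_trna - config$n_rrna
  stopifnot(n_cds > 0)
  len_trna <- rep(77L, config$n_trna)
  len_rrna <- if (config$n_rrna > 0)
    as.integer(round(stats::runif(config$n_rrna, 1500, 3000))) else integer()
  target_total <- config$n_genes * config$mean_gene_length
  cds_raw <- stats::rgamma(n_cds, shape = 2.5, rate = 2.5 / 1000)
  cds_len <- pmax(90L, as.integer(round(
    cds_raw * (target_total - sum(len_trna) - sum(len_rrna)) / sum(cds_raw))))
  lengths <- c(cds_len, len_trna, len_rrna)
  types <- c(rep("CDS", n_cds), rep("tRNA", config$n_trna),
             rep("rRNA", config$n_rrna))
  ord <- sample.int(config$n_genes)
  lengths <- lengths[ord]; types <- types[ord]
  total_gap <- L - sum(lengths)
  if (total_gap < config$n_genes)
    stop("genes do not fit: total gene length ", sum(lengths), " vs genome ", L)
  gaps <- as.vector(stats::rmultinom(1L, total_gap - config$n_genes,
                                     rep(1, config$n_genes))) + 1L
  # layout: gap_1, gene_1, gap_2, gene_2, ...
  starts <- as.integer(cumsum(gaps) + cumsum(c(0L, lengths[-config$n_genes])) + 1L)
  ends <- as.integer(starts + lengths - 1L)
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
    contig = "chr", start = starts, end = ends,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    feature_type = types, product = NA_character_,
    stringsAsFactors = FALSE)
  ann <- tradis_annotation(sequence, genes, is_circular = TRUE, ori_position = 1L)
  n_ess <- round(config$essential_fraction * config$n_genes)
  essential <- if (n_ess > 0) sort(sample(genes$gene_id, n_ess)) else character()
  list(annotation = ann,
       truth = list(essential_gene_ids = essential, config = config,
                    seed = config$seed))
}

#' Generate a biased synthetic insertion library
#'
#' Per-base insertion weights combine three factors: a linear ori-to-ter
#' gradient (from `ori_ter_ratio` at the origin down to 1 at the terminus),
#' an `at_factor` multiplier inside top-quartile-AT windows, and zero weight
#' across the 5' 90% of every essential gene (essentiality modelled as
#' inability to recover insertion mutants). Tn5 target-site preference is
#' modelled by restricting insertions to a candidate-site subset whose size
#' is calibrated, from the weight vector alone, so the expected distinct-site
#' count under weighted multinomial sampling of `n_insertions` colonies
#' equals `target_unique_sites`. One sequencing read per colony is emitted
#' (5'-tagged with the transposon prefix); read-level site draws at
#' `seq_depth` support rarefaction.
#'
#' @param annotation,truth Output of [generate_genome()].
#' @param config A [library_sim_config()] (defaults to the one in `truth`).
#' @return A list of class `synthetic_library`: `reads` (named
#'   [Biostrings::DNAStringSet]), `sites` (per-colony insertion positions),
#'   `strands`, `site_draws` (length `seq_depth`), `weights` (per-base),
#'   `n_candidates`, `expected_unique_sites`, `truth`.
#' @export
generate_library <- function(annotation, truth, config = truth$config) {
  set.seed(config$seed + 1L)
  L <- annotation$genome_length
  rl <- config$read_length

  # ori->ter linear gradient on circular distance. ori_ter_ratio is the
  # ratio of mean insertions around ori vs around ter (octant means); under a
  # linear gradient with endpoint ratio Re, the octant-mean ratio is
  # (15*Re + 1) / (Re + 15), inverted here to find Re.
  Ro <- config$ori_ter_ratio
  Re <- (15 * Ro - 1) / (15 - Ro)
  d <- ori_distance(seq_len(L), annotation$ori_position, L)
  w <- Re - (Re - 1) * d / (L / 2)

  # AT elevation in top-quartile-AT windows (same windowing as at_bias)
  starts <- seq.int(1L, L, by = config$at_window_bp)
  ends <- pmin(starts + config$at_window_bp - 1L, L)
  atv <- window_at_fractions(annotation$sequence, starts, ends)
  top <- atv >= stats::quantile(atv, 0.75, na.rm = TRUE)
  for (i in which(top)) w[starts[i]:ends[i]] <- w[starts[i]:ends[i]] * config$at_factor

  # essential genes: no recoverable insertions in the 5' 90%
  g <- annotation$genes
  ess <- g[g$gene_id %in% truth$essential_gene_ids, , drop = FALSE]
  for (i in seq_len(nrow(ess))) {
    len <- ess$length[i]; keep <- len - floor(0.10 * len)
    span <- if (ess$strand[i] == "+")
      seq.int(ess$start[i], length.out = keep)
    else seq.int(ess$end[i] - keep + 1L, length.out = keep)
    w[circ_pos(span, L)] <- 0
  }
  # keep reads clear of the sequence ends (the locator does not wrap)
  w[c(seq_len(rl), seq.int(L - rl + 1L, L))] <- 0

  # calibrate candidate-site count to the target unique-site yield
  eligible <- which(w > 0)
  perm <- eligible[sample.int(length(eligible))]
  n_cand <- calibrate_candidates(w, perm, config$n_insertions,
                                 config$target_unique_sites)
  cand <- perm[seq_len(n_cand)]
  pw <- w[cand] / sum(w[cand])
  expected_unique <- sum(1 - (1 - pw)^config$n_insertions)

  sites <- cand[sample.int(n_cand, config$n_insertions, replace = TRUE, prob = pw)]
  strands <- sample(c("+", "-"), config$n_insertions, replace = TRUE)

  seq_chr <- as.character(annotation$sequence)
  fwd <- strands == "+"
  reads_chr <- character(config$n_insertions)
  reads_chr[fwd] <- substring(seq_chr, sites[fwd], sites[fwd] + rl - 1L)
  rev_part <- substring(seq_chr, sites[!fwd] - rl + 1L, sites[!fwd])
  reads_chr[!fwd] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rev_part)))
  reads <- Biostrings::DNAStringSet(paste0(config$tn_prefix, reads_chr))
  names(reads) <- sprintf("ins_%06d", seq_len(config$n_insertions))

  site_draws <- sites[sample.int(config$n_insertions, config$seq_depth,
                                 replace = TRUE)]
  structure(list(reads = reads, sites = sites, strands = strands,
                 site_draws = site_draws, weights = w,
                 n_candidates = n_cand,
                 expected_unique_sites = expected_unique, truth = truth),
            class = "synthetic_library")
}

# smallest candidate count whose expected distinct-site yield under weighted
# multinomial sampling reaches the target (bisection on a fixed permutation)
calibrate_candidates <- function(w, perm, n_draws, target) {
  expected <- function(n_cand) {
    p <- w[perm[seq_len(n_cand)]]
    p <- p / sum(p)
    sum(1 - (1 - p)^n_draws)
  }
  hi <- length(perm)
  if (expected(hi) <= target) return(hi)
  lo <- min(target, hi)
  while (lo > 1L && expected(lo) > target) lo <- lo %/% 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (expected(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat(sprintf(
    "<synthetic_library> %s insertions over %s candidate sites (expect %.0f unique); %s read draws\n",
    format(length(x$sites), big.mark = ","),
    format(x$n_candidates, big.mark = ","), x$expected_unique_sites,
    format(length(x$site_draws), big.mark = ",")))
  invisible(x)
}

#' Write synthetic outputs to standard formats
#'
#' @param library_ A `synthetic_library`.
#' @param annotation A `tradis_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(library_, path) {
  quals <- Biostrings::PhredQuality(
    vapply(Biostrings::width(library_$reads),
           function(w) paste(rep("I", w), collapse = ""), ""))
  reads <- Biostrings::QualityScaledDNAStringSet(library_$reads, quals)
  Biostrings::writeXStringSet(methods::as(reads, "DNAStringSet"), path,
                              format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_genome_fasta <- function(annotation, path) {
  s <- Biostrings::DNAStringSet(annotation$sequence)
  names(s) <- "chr"
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  biotype <- ifelse(g$feature_type %in% c("tRNA", "rRNA"),
                    g$feature_type, "protein_coding")
  attrs <- sprintf("ID=%s;gene_biotype=%s%s", g$gene_id, biotype,
                   ifelse(is.na(g$product), "",
                          paste0(";product=", g$product)))
  lines <- c("##gff-version 3",
             sprintf("chr\ttradisr\tgene\t%d\t%d\t.\t%s\t.\t%s",
                     g$start, g$end, g$strand, attrs))
  writeLines(lines, path)
  invisible(path)
}

#' Generate synthetic proteome panels with known family structure
#'
#' Family ancestors are random proteins; members are point-mutated copies at
#' the stated divergence. With probability `core_fraction` a family is core
#' (present in every genome); otherwise it is present in each genome
#' independently with probability `presence_prob`. Paralogues (second,
#' independently mutated copies) are added per genome at `paralogue_rate`.
#'
#' @param n_genomes,n_families Panel dimensions.
#' @param core_fraction Probability a family is core.
#' @param presence_prob Per-genome presence probability of non-core families.
#' @param paralogue_rate Per-(family, genome) probability of a duplicate.
#' @param divergence Per-site substitution probability applied to each member.
#' @param mean_length Mean ancestor length (aa).
#' @param seed Integer seed.
#' @return A list: `proteins` (named [Biostrings::AAStringSet], ids
#'   `genome|family_copy`), `genome_map` (protein id -> genome id), `truth`
#'   (list with `family_of` protein -> family, `core_families`).
#' @export
generate_proteomes <- function(n_genomes = 8L, n_families = 40L,
                               core_fraction = 0.75, presence_prob = 0.5,
                               paralogue_rate = 0.05, divergence = 0.05,
                               mean_length = 250L, seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  genomes <- sprintf("g%02d", seq_len(n_genomes))
  fams <- sprintf("F%03d", seq_len(n_families))
  anc <- lapply(fams, function(f) {
    len <- max(50L, stats::rpois(1L, mean_length))
    sample(aa, len, replace = TRUE)
  })
  names(anc) <- fams
  is_core <- stats::runif(n_families) < core_fraction

  mutate <- function(s) {
    hit <- stats::runif(length(s)) < divergence
    if (any(hit)) s[hit] <- sample(aa, sum(hit), replace = TRUE)
    paste(s, collapse = "")
  }
  seqs <- character(); ids <- character(); gmap <- character(); fam_of <- character()
  for (fi in seq_len(n_families)) {
    for (gi in seq_len(n_genomes)) {
      present <- is_core[fi] || stats::runif(1L) < presence_prob
      if (!present) next
      n_copies <- 1L + (stats::runif(1L) < paralogue_rate)
      for (cp in seq_len(n_copies)) {
        id <- sprintf("%s|%s_%d", genomes[gi], fams[fi], cp)
        ids <- c(ids, id)
        seqs <- c(seqs, mutate(anc[[fi]]))
        gmap <- c(gmap, genomes[gi])
        fam_of <- c(fam_of, fams[fi])
      }
    }
  }
  proteins <- Biostrings::AAStringSet(seqs)
  names(proteins) <- ids
  names(gmap) <- ids; names(fam_of) <- ids
  list(proteins = proteins, genome_map = gmap,
       truth = list(family_of = fam_of, core_families = fams[is_core],
                    seed = seed))
}
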