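# Fixtures and independent oracles used across the suite.

# deterministic toy chromosome with a handful of genes
toy_annotation <- function(L = 3000L, seed = 99L) {
  set.seed(seed)
  seq_chr <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    contig = "chr",
    start = c(1L, 1201L, 1801L, 2401L),
    end = c(1000L, 1700L, 2300L, 2900L),
    strand = c("+", "-", "+", "-"),
    feature_type = c("CDS", "CDS", "CDS", "tRNA"),
    product = c("alpha", "beta", NA, NA),
    stringsAsFactors = FALSE)
  tradis_annotation(seq_chr, genes)
}

# profile with unique sites at given positions (forward strand, count 1 each
# unless counts given)
profile_at <- function(L, positions, counts = 1L, rev_positions = integer()) {
  fwd <- integer(L); rev <- integer(L)
  fwd[positions] <- counts
  rev[rev_positions] <- 1L
  insertion_profile(fwd, rev)
}

# small simulator configuration for fast unit tests
small_config <- function(seed = 7L, ...) {
  library_sim_config(genome_length = 200000L, n_genes = 160L, n_trna = 5L,
                     n_rrna = 1L, n_insertions = 5000L, seq_depth = 50000L,
                     target_unique_sites = 3800L, seed = seed, ...)
}

# brute-force exact-match oracle: scan every genome position on both strands
brute_force_locate <- function(read, genome_chr) {
  L <- nchar(genome_chr); w <- nchar(read)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  hits <- list()
  for (p in seq_len(L - w + 1L)) {
    win <- substr(genome_chr, p, p + w - 1L)
    if (win == read) hits[[length(hits) + 1L]] <- c(pos = p, strand = 1L)
    if (win == rc) hits[[length(hits) + 1L]] <- c(pos = p, strand = -1L)
  }
  hits
}

# independent minimal MCL: dense, no pruning, explicit loops, DFS components
mcl_oracle <- function(adj, inflation = 2, max_iter = 300L) {
  n <- nrow(adj)
  M <- adj
  for (i in seq_len(n)) M[i, i] <- max(adj[, i], max(adj[adj > 0], 1))
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    E <- M %*% M
    E <- E^inflation
    for (j in seq_len(n)) E[, j] <- E[, j] / sum(E[, j])
    if (max(abs(E - M)) < 1e-10) { M <- E; break }
    M <- E
  }
  S <- (M > 1e-9) | t(M > 1e-9)
  comp <- rep(NA_integer_, n); cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(S[v, ] & is.na(comp)))
    }
  }
  comp
}

# independent Gotoh local-alignment score (affine gaps) for short proteins
sw_score_oracle <- function(a, b, gap_open = 10, gap_extend = 0.5,
                            mat = NULL) {
  if (is.null(mat)) {
    mat <- get(data("BLOSUM62", package = "Biostrings", envir = environment()))
  }
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1L, m + 1L); E <- matrix(-Inf, n + 1L, m + 1L)
  FF <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(E[i + 1L, j] - gap_extend,
                               H[i + 1L, j] - gap_open - gap_extend)
      FF[i + 1L, j + 1L] <- max(FF[i, j + 1L] - gap_extend,
                                H[i, j + 1L] - gap_open - gap_extend)
      H[i + 1L, j + 1L] <- max(0,
                               H[i, j] + mat[a[i], b[j]],
                               E[i + 1L, j + 1L], FF[i + 1L, j + 1L])
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# canonical form of a family partition for exact comparison
canonical_families <- function(fams) {
  unname(sort(vapply(fams, function(m) paste(sort(m), collapse = ","), "")))
}

# family-exact agreement fraction between clustering and truth
family_agreement <- function(families, family_of) {
  truth <- split(names(family_of), family_of)
  got <- canonical_families(families)
  want <- canonical_families(truth)
  mean(want %in% got)
}

# hand-built 5-record SAM fixture over a 100 bp contig
write_sam_fixture <- function(path, genome_chr) {
  r1 <- substr(genome_chr, 11, 30)                       # forward @ 11
  r2seq <- substr(genome_chr, 41, 60)                    # reverse @ 41..60
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r2seq)))
  q <- paste(rep("I", 20), collapse = "")
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr\tLN:100",
    sprintf("r1\t0\tchr\t11\t60\t20M\t*\t0\t0\t%s\t%s", r1, q),
    sprintf("r2\t16\tchr\t41\t60\t20M\t*\t0\t0\t%s\t%s", substr(genome_chr, 41, 60), q),
    sprintf("r3\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", r1, q),        # unmapped
    sprintf("r4\t256\tchr\t11\t60\t20M\t*\t0\t0\t%s\t%s", r1, q), # secondary
    sprintf("r5\t0\tchr\t71\t0\t20M\t*\t0\t0\t%s\t%s",            # mapq 0 multi
            substr(genome_chr, 71, 90), q))
  writeLines(lines, path)
  path
}

# minimal GenBank flat file with 3 features
write_genbank_fixture <- function(path, seq_chr) {
  n <- nchar(seq_chr)
  chunks <- substring(seq_chr, seq(1, n, 60), pmin(seq(1, n, 60) + 59, n))
  origin <- vapply(seq_along(chunks), function(i) {
    inner <- gsub("(.{10})", "\\1 ", tolower(chunks[i]))
    sprintf("%9d %s", (i - 1L) * 60L + 1L, trimws(inner))
  }, "")
  lines <- c(
    sprintf("LOCUS       testchr        %d bp    DNA     circular BCT 01-JAN-2020", n),
    "DEFINITION  synthetic test chromosome.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    "     CDS             10..39",
    '                     /locus_tag="g1"',
    '                     /product="protein one"',
    "     CDS             complement(50..79)",
    '                     /locus_tag="g2"',
    "     tRNA            90..110",
    '                     /locus_tag="t1"',
    "ORIGIN",
    origin,
    "//")
  writeLines(lines, path)
  path
}
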