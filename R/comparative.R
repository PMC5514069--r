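#' Local protein alignment similarity
#'
#' Smith-Waterman local alignment of two proteins under a standard
#' substitution matrix with affine gaps; reports percent identity over
#' alignment columns and per-sequence coverage (aligned span / sequence
#' length). A self-contained surrogate for BLASTP in desk-scale analyses;
#' externally computed tabular hits are the faithful replication path (see
#' [read_blast_tab()]).
#'
#' @param a,b Protein sequences ([Biostrings::AAString] or character) with
#'   names used as ids (fallback: `"query"`/`"subject"`).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 / 0.5).
#' @return A one-row data.frame: `query_id`, `subject_id`,
#'   `percent_identity`, `coverage_query`, `coverage_subject`, `score`.
#' @export
pairwise_similarity <- function(a, b, matrix = "BLOSUM62",
                                gap_open = 10, gap_extend = 0.5) {
  qa <- if (is.character(a)) a else as.character(a)
  qb <- if (is.character(b)) b else as.character(b)
  if (!nzchar(qa) || !nzchar(qb)) stop("empty protein sequence")
  qid <- if (!is.null(names(a))) names(a)[1L] else "query"
  sid <- if (!is.null(names(b))) names(b)[1L] else "subject"
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qa), Biostrings::AAString(qb), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open, gapExtension = gap_extend)
  ncol_aln <- Biostrings::nchar(al)
  ident <- if (ncol_aln > 0) 100 * Biostrings::nmatch(al) / ncol_aln else 0
  span_q <- Biostrings::width(al@pattern@range)
  span_s <- Biostrings::width(al@subject@range)
  data.frame(query_id = qid, subject_id = sid,
             percent_identity = ident,
             coverage_query = span_q / nchar(qa),
             coverage_subject = span_s / nchar(qb),
             score = Biostrings::score(al),
             stringsAsFactors = FALSE)
}

#' All-against-all similarity hits for a protein panel
#'
#' Runs [pairwise_similarity()] for every unordered pair and emits both
#' directions (local alignment is symmetric; coverages are swapped).
#'
#' @param proteins A named [Biostrings::AAStringSet] (or named character
#'   vector).
#' @param min_score Minimum alignment score for a hit to be reported
#'   (default 0 keeps everything).
#' @inheritParams pairwise_similarity
#' @return A data.frame of similarity hits in both directions.
#' @export
all_vs_all_similarity <- function(proteins, matrix = "BLOSUM62",
                                  gap_open = 10, gap_extend = 0.5,
                                  min_score = 0) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  ids <- names(proteins)
  if (is.null(ids)) stop("proteins must be named")
  n <- length(proteins)
  rows <- vector("list", n)
  # one vectorised alignment call per subject: patterns i < j vs subject j
  for (j in seq.int(2L, n)) {
    pat <- proteins[seq_len(j - 1L)]
    al <- Biostrings::pairwiseAlignment(
      pat, proteins[[j]], type = "local", substitutionMatrix = matrix,
      gapOpening = gap_open, gapExtension = gap_extend)
    ncol_aln <- Biostrings::nchar(al)
    ident <- ifelse(ncol_aln > 0, 100 * Biostrings::nmatch(al) / ncol_aln, 0)
    cov_q <- Biostrings::width(al@pattern@range) / Biostrings::width(pat)
    cov_s <- Biostrings::width(al@subject@range) / Biostrings::width(proteins)[j]
    sc <- Biostrings::score(al)
    keep <- sc >= min_score
    if (!any(keep)) next
    h <- data.frame(query_id = ids[seq_len(j - 1L)][keep], subject_id = ids[j],
                    percent_identity = ident[keep],
                    coverage_query = cov_q[keep], coverage_subject = cov_s[keep],
                    score = sc[keep], stringsAsFactors = FALSE)
    rows[[j]] <- rbind(h, data.frame(
      query_id = h$subject_id, subject_id = h$query_id,
      percent_identity = h$percent_identity,
      coverage_query = h$coverage_subject, coverage_subject = h$coverage_query,
      score = h$score, stringsAsFactors = FALSE))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), coverage_query = numeric(),
                      coverage_subject = numeric(), score = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read 12-column tabular similarity hits
#'
#' Parses the standard 12-column blast tabular dialect (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) into
#' similarity hits, filtering on E-value. Coverages are computed from the
#' aligned spans and the supplied sequence lengths.
#'
#' @param path Tabular hits file.
#' @param seq_lengths Named integer vector: sequence id -> length (aa).
#' @param max_evalue E-value cutoff (default 1e-4).
#' @return A data.frame of similarity hits (same columns as
#'   [pairwise_similarity()], with `score` = bitscore).
#' @export
read_blast_tab <- function(path, seq_lengths, max_evalue = 1e-4) {
  cols <- c("query_id", "subject_id", "percent_identity", "aln_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  h <- utils::read.delim(path, header = FALSE, col.names = cols,
                         stringsAsFactors = FALSE)
  h <- h[h$evalue <= max_evalue, , drop = FALSE]
  missing_ids <- setdiff(unique(c(h$query_id, h$subject_id)), names(seq_lengths))
  if (length(missing_ids))
    stop("seq_lengths lacks: ", paste(utils::head(missing_ids, 5), collapse = ", "))
  data.frame(query_id = h$query_id, subject_id = h$subject_id,
             percent_identity = h$percent_identity,
             coverage_query = (abs(h$qend - h$qstart) + 1) / seq_lengths[h$query_id],
             coverage_subject = (abs(h$send - h$sstart) + 1) / seq_lengths[h$subject_id],
             score = h$bitscore, stringsAsFactors = FALSE)
}

#' Build a similarity graph from hits
#'
#' Keeps an undirected edge between two proteins when the hit passes the
#' identity and coverage thresholds -- "coverage of either sequence" is read
#' as `max(coverage_query, coverage_subject)` -- in both directions when
#' `reciprocal = TRUE`. At species/genus level the study thresholds are 50%
#' identity / 50% coverage; the cross-phylum mode lowers identity to 20%.
#'
#' @param hits Similarity-hit data.frame ([all_vs_all_similarity()] or
#'   [read_blast_tab()]).
#' @param min_identity Percent-identity cutoff (default 50; use 20 for
#'   cross-phylum comparisons).
#' @param min_coverage Coverage cutoff as a fraction (default 0.5).
#' @param reciprocal Require the thresholds to hold in both directions
#'   (default `TRUE`).
#' @param nodes Optional character vector of all proteins; proteins without
#'   passing edges become singleton families downstream.
#' @return A list of class `similarity_graph`: `nodes`, `edges` (data.frame
#'   `from`, `to`, `weight` = mean score of the two directions).
#' @export
build_graph <- function(hits, min_identity = 50, min_coverage = 0.5,
                        reciprocal = TRUE, nodes = NULL) {
  ok <- hits$percent_identity >= min_identity &
        pmax(hits$coverage_query, hits$coverage_subject) >= min_coverage &
        hits$query_id != hits$subject_id
  h <- hits[ok, , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (nrow(h)) {
    k <- key(h$query_id, h$subject_id)
    spl <- split(seq_len(nrow(h)), k)
    dirs <- vapply(spl, function(ix) length(unique(h$query_id[ix])), 0L)
    keep_keys <- names(spl)[if (reciprocal) dirs >= 2L else rep(TRUE, length(spl))]
    edges <- do.call(rbind, lapply(keep_keys, function(kk) {
      ix <- spl[[kk]]
      parts <- strsplit(kk, "\r", fixed = TRUE)[[1L]]
      data.frame(from = parts[1L], to = parts[2L],
                 weight = mean(h$score[ix]), stringsAsFactors = FALSE)
    }))
    if (is.null(edges))
      edges <- data.frame(from = character(), to = character(), weight = numeric())
  } else {
    edges <- data.frame(from = character(), to = character(), weight = numeric())
  }
  all_nodes <- sort(unique(c(nodes, hits$query_id, hits$subject_id)))
  structure(list(nodes = all_nodes, edges = edges), class = "similarity_graph")
}

#' Markov clustering of a similarity graph
#'
#' The Markov Cluster Algorithm: random walks on the similarity graph are
#' simulated by alternating expansion (matrix squaring) and inflation
#' (entrywise power followed by column renormalisation and pruning) of a
#' column-stochastic transition matrix with self-loops, until the matrix is
#' (numerically) idempotent; clusters are read off as the connected
#' components of the limiting matrix's support.
#'
#' @param graph A `similarity_graph` from [build_graph()].
#' @param inflation Inflation exponent (default 2.0).
#' @param prune Entries below this are zeroed each iteration (default 1e-5).
#' @param max_iter Maximum iterations (default 100); non-convergence is an
#'   error reporting the residual.
#' @return A list of class `ortholog_families`: `families` (list of character
#'   vectors of protein ids, largest first), `params`, `n_iter`.
#' @export
mcl_cluster <- function(graph, inflation = 2.0, prune = 1e-5, max_iter = 100L) {
  stopifnot(inherits(graph, "similarity_graph"), inflation > 1)
  nodes <- graph$nodes
  n <- length(nodes)
  if (!n) stop("empty graph")
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e)) {
    i <- match(e$from, nodes); j <- match(e$to, nodes)
    M[cbind(i, j)] <- e$weight
    M[cbind(j, i)] <- e$weight
  }
  diag(M) <- pmax(apply(M, 2, max), if (nrow(e)) min(e$weight[e$weight > 0]) else 1)
  normalize <- function(A) sweep(A, 2, pmax(colSums(A), .Machine$double.eps), "/")
  M <- normalize(M)
  converged <- FALSE; res <- NA_real_
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                 # expansion
    M2 <- M2^inflation            # inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    res <- max(abs(M2 - M))
    M <- M2
    if (res < 1e-8) { converged <- TRUE; break }
  }
  if (!converged)
    stop("MCL did not converge in ", max_iter, " iterations (residual ",
         signif(res, 3), ")")
  comp <- support_components(M > 1e-9)
  fams <- split(nodes, comp)
  fams <- fams[order(-lengths(fams), vapply(fams, `[`, "", 1L))]
  names(fams) <- sprintf("fam_%04d", seq_along(fams))
  structure(list(families = fams,
                 params = list(inflation = inflation, prune = prune),
                 n_iter = it),
            class = "ortholog_families")
}

# connected components of a symmetric-ised boolean support matrix (union-find)
support_components <- function(S) {
  n <- nrow(S)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  idx <- which(S | t(S), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    ra <- find(idx[r, 1L]); rb <- find(idx[r, 2L])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, 0L)
}

#' @export
print.ortholog_families <- function(x, ...) {
  cat(sprintf("<ortholog_families> %d families over %d proteins (inflation %.2g, %d iterations)\n",
              length(x$families), sum(lengths(x$families)),
              x$params$inflation, x$n_iter))
  invisible(x)
}

#' Core-genome sets from ortholog families
#'
#' Builds the family-by-genome presence matrix and derives the core (families
#' present in all genomes), the extended core (present in at least
#' `presence_fraction` of genomes; 0.8 is used at genus level where draft
#' genomes may be incomplete), and the single-copy core (core families with
#' exactly one member per genome, the orthologue/paralogue filter).
#'
#' @param families An `ortholog_families` object (or a list of character
#'   vectors of protein ids).
#' @param genome_map Named character vector: protein id -> genome id.
#' @param genomes Genomes to consider (default: all in `genome_map`).
#' @param presence_fraction Fraction of genomes a family must occupy to be in
#'   the extended core (default 1.0 = species-level strict core).
#' @return A list of class `core_sets`: `presence` (member-count matrix),
#'   `core`, `extended_core`, `single_copy_core` (family names),
#'   `presence_fraction`.
#' @export
core_sets <- function(families, genome_map, genomes = NULL,
                      presence_fraction = 1.0) {
  fams <- if (inherits(families, "ortholog_families")) families$families else families
  if (is.null(names(fams))) names(fams) <- sprintf("fam_%04d", seq_along(fams))
  if (is.null(genomes)) genomes <- sort(unique(genome_map))
  presence <- t(vapply(fams, function(members) {
    gm <- genome_map[members]
    if (anyNA(gm)) stop("genome_map lacks protein(s): ",
                        paste(utils::head(members[is.na(gm)], 3), collapse = ", "))
    tabulate(factor(gm, genomes), nbins = length(genomes))
  }, integer(length(genomes))))
  colnames(presence) <- genomes
  n_present <- rowSums(presence > 0)
  core <- rownames(presence)[n_present == length(genomes)]
  extended <- rownames(presence)[n_present >= presence_fraction * length(genomes)]
  single <- core[apply(presence[core, , drop = FALSE] == 1L, 1L, all)]
  structure(list(presence = presence, core = core, extended_core = extended,
                 single_copy_core = single,
                 presence_fraction = presence_fraction),
            class = "core_sets")
}

#' @export
print.core_sets <- function(x, ...) {
  cat(sprintf(
    "<core_sets> %d families x %d genomes: core %d, extended core (>=%.0f%%) %d, single-copy core %d\n",
    nrow(x$presence), ncol(x$presence), length(x$core),
    100 * x$presence_fraction, length(x$extended_core),
    length(x$single_copy_core)))
  invisible(x)
}

#' Overlap report between gene sets
#'
#' Pairwise intersections and Venn-region counts for named gene-id sets (for
#' example the TraDIS essential set against species/genus cores, or essential
#' sets of several taxa). Percentages are `100 * |A intersect B| / |A|`,
#' rounded to the nearest integer as in prose-style reporting.
#'
#' @param sets A named list of character vectors.
#' @return A list of class `overlap_report`: `sizes`, `pairwise` (data.frame
#'   `set_a`, `set_b`, `n_overlap`, `pct_of_a`), and `venn_regions`
#'   (exclusive-region counts keyed by membership pattern).
#' @export
overlap_report <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(sets) >= 2L)
  sets <- lapply(sets, unique)
  nm <- names(sets)
  pair_rows <- list()
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i == j) next
    ov <- length(intersect(sets[[i]], sets[[j]]))
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      set_a = nm[i], set_b = nm[j], n_overlap = ov,
      pct_of_a = round(100 * ov / length(sets[[i]])),
      stringsAsFactors = FALSE)
  }
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, nm))
  pattern <- apply(membership, 1L, function(r) paste(nm[r], collapse = "&"))
  venn <- table(pattern)
  structure(list(sizes = lengths(sets),
                 pairwise = do.call(rbind, pair_rows),
                 venn_regions = venn),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> set sizes:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  pw <- x$pairwise
  for (r in seq_len(nrow(pw)))
    cat(sprintf("  |%s & %s| = %d (%d%% of %s)\n", pw$set_a[r], pw$set_b[r],
                pw$n_overlap[r], pw$pct_of_a[r], pw$set_a[r]))
  invisible(x)
}

#' Functional-category frequency table
#'
#' Counts genes per functional category (COG/KEGG style) over a gene set,
#' with genes absent from the assignment table tallied in an explicit
#' `"Unassigned function"` category. Percentages are reported to one decimal
#' place and sum to 100 up to rounding.
#'
#' @param gene_ids Character vector of gene ids (e.g. protein-coding
#'   essential genes).
#' @param assignment Two-column data.frame (`gene_id`, `category`) or a path
#'   to a two-column TSV.
#' @param unassigned_label Label for genes without an assignment.
#' @return A data.frame: `category`, `genes`, `pct`, sorted by count
#'   (unassigned last).
#' @export
cog_frequency <- function(gene_ids, assignment,
                          unassigned_label = "Unassigned function") {
  if (is.character(assignment) && length(assignment) == 1L)
    assignment <- utils::read.delim(assignment, header = FALSE,
                                    col.names = c("gene_id", "category"),
                                    stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "category") %in% names(assignment)))
  gene_ids <- unique(gene_ids)
  cat_of <- assignment$category[match(gene_ids, assignment$gene_id)]
  cat_of[is.na(cat_of)] <- unassigned_label
  tab <- sort(table(cat_of), decreasing = TRUE)
  df <- data.frame(category = names(tab), genes = as.integer(tab),
                   pct = pct(as.integer(tab), length(gene_ids)),
                   stringsAsFactors = FALSE)
  ua <- df$category == unassigned_label
  rbind(df[!ua, , drop = FALSE], df[ua, , drop = FALSE])
}

#' Write family membership and presence/absence tables
#'
#' @param families An `ortholog_families` object.
#' @param cs A `core_sets` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(families, path) {
  df <- data.frame(
    family = rep(names(families$families), lengths(families$families)),
    protein_id = unlist(families$families, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_family_table
#' @export
write_presence_matrix <- function(cs, path) {
  utils::write.table(data.frame(family = rownames(cs$presence), cs$presence),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
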