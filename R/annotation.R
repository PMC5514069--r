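#' Genome annotation container
#'
#' Bundles a (typically circular) chromosome sequence with its ordered gene
#' models and the replication-origin coordinate used by positional analyses
#' such as [octant_density()].
#'
#' @param sequence A [Biostrings::DNAString], `DNAStringSet` of length 1, or a
#'   character scalar over `A,C,G,T,N`.
#' @param genes A data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `feature_type` (`CDS`, `tRNA`, `rRNA` or `other`)
#'   and `product`. Coordinates are 1-based inclusive. A gene wrapping the
#'   circular origin is encoded with `start > end`.
#' @param is_circular Logical; is the chromosome circular?
#' @param ori_position 1-based coordinate of the replication origin. Defaults
#'   to 1 (annotation convention for closed bacterial chromosomes).
#'
#' @return An object of class `tradis_annotation`: a list with elements
#'   `sequence`, `genome_length`, `is_circular`, `ori_position` and `genes`
#'   (genes sorted by `start`, with a `length` column that accounts for
#'   origin-wrapping).
#' @export
tradis_annotation <- function(sequence, genes, is_circular = TRUE, ori_position = 1L) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (methods::is(sequence, "DNAStringSet")) {
    if (length(sequence) != 1L)
      stop("annotation expects a single contig; got ", length(sequence))
    sequence <- sequence[[1L]]
  }
  if (!methods::is(sequence, "DNAString")) stop("'sequence' must be DNA")
  L <- length(sequence)
  if (L < 1L) stop("empty genome sequence")

  required <- c("gene_id", "contig", "start", "end", "strand", "feature_type", "product")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)

  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  bad <- genes$start < 1L | genes$start > L | genes$end < 1L | genes$end > L
  if (any(bad))
    stop("gene coordinates outside [1, ", L, "]: ",
         paste(genes$gene_id[bad], collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  wraps <- genes$end < genes$start
  if (any(wraps) && !is_circular)
    stop("origin-wrapping gene on a linear chromosome: ",
         paste(genes$gene_id[wraps], collapse = ", "))
  genes$length <- ifelse(wraps,
                         L - genes$start + 1L + genes$end,
                         genes$end - genes$start + 1L)
  genes <- genes[order(genes$start, genes$end, genes$gene_id),
                 c("gene_id", "contig", "start", "end", "strand",
                   "feature_type", "product", "length"), drop = FALSE]
  rownames(genes) <- NULL

  ori_position <- as.integer(ori_position)
  if (ori_position < 1L || ori_position > L)
    stop("ori_position outside genome")

  structure(
    list(sequence = sequence, genome_length = L, is_circular = is_circular,
         ori_position = ori_position, genes = genes),
    class = "tradis_annotation"
  )
}

#' @export
print.tradis_annotation <- function(x, ...) {
  cat(sprintf("<tradis_annotation> %s chromosome, %s bp, %d genes (ori at %d)\n",
              if (x$is_circular) "circular" else "linear",
              format(x$genome_length, big.mark = ","),
              nrow(x$genes), x$ori_position))
  tab <- table(x$genes$feature_type)
  cat("  feature types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Load a genome annotation from GenBank or GFF3 (+ FASTA)
#'
#' Reads CDS, tRNA and rRNA features into a [tradis_annotation()]. GenBank
#' flat files carry their own sequence; GFF3 files require a companion FASTA.
#'
#' @param path Path to a GenBank flat file (`.gb`, `.gbk`, `.gbff`) or a GFF3
#'   file. Format is sniffed from the first line when the extension is
#'   ambiguous.
#' @param fasta_path FASTA with the chromosome sequence (GFF3 input only).
#' @param ori_position Replication-origin coordinate; defaults to 1 unless the
#'   GenBank file contains a `rep_origin` feature.
#' @param is_circular Logical, default `TRUE`.
#' @return A `tradis_annotation`.
#' @export
read_annotation <- function(path, fasta_path = NULL, ori_position = NULL,
                            is_circular = TRUE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^LOCUS", first)) {
    parsed <- parse_genbank(path)
    if (is.null(ori_position)) ori_position <- if (is.na(parsed$ori)) 1L else parsed$ori
    ann <- tradis_annotation(parsed$sequence, parsed$genes,
                             is_circular = is_circular, ori_position = ori_position)
  } else {
    if (is.null(fasta_path))
      stop("GFF3 input requires 'fasta_path' with the chromosome sequence")
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    gff <- rtracklayer::import(path)
    keep <- gff$type %in% c("CDS", "tRNA", "rRNA", "gene")
    gff <- gff[keep]
    # prefer explicit gene features; fall back to CDS/tRNA/rRNA records
    if (any(gff$type == "gene")) {
      feats <- gff[gff$type == "gene"]
      ftype <- if (!is.null(feats$gene_biotype)) {
        ifelse(feats$gene_biotype %in% c("tRNA", "rRNA"),
               as.character(feats$gene_biotype), "CDS")
      } else rep("CDS", length(feats))
    } else {
      feats <- gff
      ftype <- as.character(feats$type)
    }
    ids <- feats$ID
    if (is.null(ids) || anyNA(ids)) ids <- feats$locus_tag
    if (is.null(ids) || anyNA(ids))
      ids <- sprintf("gene_%05d", seq_along(feats))
    prod <- feats$product
    if (is.null(prod)) prod <- rep(NA_character_, length(feats))
    genes <- data.frame(
      gene_id = as.character(ids),
      contig = as.character(GenomicRanges::seqnames(feats)),
      start = GenomicRanges::start(feats),
      end = GenomicRanges::end(feats),
      strand = ifelse(as.character(GenomicRanges::strand(feats)) == "-", "-", "+"),
      feature_type = ftype,
      product = as.character(prod),
      stringsAsFactors = FALSE
    )
    if (!nrow(genes)) stop("no CDS/tRNA/rRNA features in ", path)
    ann <- tradis_annotation(seqs, genes, is_circular = is_circular,
                             ori_position = if (is.null(ori_position)) 1L else ori_position)
  }
  if (!any(ann$genes$feature_type == "CDS"))
    stop("annotation contains no CDS feature")
  ann
}

# Minimal GenBank flat-file parser: LOCUS, FEATURES (CDS/tRNA/rRNA/rep_origin
# with plain or complement() spans and locus_tag/gene/product qualifiers) and
# ORIGIN sequence block. Joins beyond a single span are not supported.
parse_genbank <- function(path) {
  lines <- readLines(path)
  fstart <- grep("^FEATURES", lines)[1L]
  ostart <- grep("^ORIGIN", lines)[1L]
  if (is.na(fstart) || is.na(ostart))
    stop("GenBank file lacks FEATURES or ORIGIN block: ", path)

  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq_chr <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
  if (!nchar(seq_chr)) stop("GenBank file has an empty ORIGIN sequence: ", path)

  feat_lines <- lines[(fstart + 1L):(ostart - 1L)]
  is_key <- grepl("^ {5}\\S", feat_lines)
  keys <- trimws(substr(feat_lines[is_key], 1, 20))
  locs <- trimws(substr(feat_lines[is_key], 21, nchar(feat_lines[is_key])))
  idx <- which(is_key)
  bounds <- c(idx, length(feat_lines) + 1L)

  recs <- list(); ori <- NA_integer_
  for (i in seq_along(idx)) {
    key <- keys[i]
    body <- feat_lines[idx[i]:(bounds[i + 1L] - 1L)]
    loc <- locs[i]
    if (key == "rep_origin") {
      m <- regmatches(loc, regexpr("[0-9]+", loc))
      if (length(m)) ori <- as.integer(m)
      next
    }
    if (!key %in% c("CDS", "tRNA", "rRNA")) next
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]
    if (length(nums) < 1L) stop("malformed location '", loc, "' in ", path)
    start <- as.integer(nums[1L])
    end <- as.integer(nums[length(nums)])
    qual <- function(name) {
      hit <- grep(sprintf('/%s="?', name), body, value = TRUE)
      if (!length(hit)) return(NA_character_)
      gsub(sprintf('.*/%s="?([^"]*)"?.*', name), "\\1", hit[1L])
    }
    id <- qual("locus_tag")
    if (is.na(id)) id <- qual("gene")
    recs[[length(recs) + 1L]] <- data.frame(
      gene_id = id, contig = "chr", start = start, end = end, strand = strand,
      feature_type = key, product = qual("product"), stringsAsFactors = FALSE)
  }
  if (!length(recs)) stop("no CDS/tRNA/rRNA features found in ", path)
  genes <- do.call(rbind, recs)
  noid <- is.na(genes$gene_id)
  if (any(noid)) genes$gene_id[noid] <- sprintf("feature_%05d", which(noid))
  list(sequence = seq_chr, genes = genes, ori = ori)
}

#' Write / read the internal TSV gene table
#'
#' The gene table is the package's plain-text interchange format for gene
#' models: one row per gene with columns `gene_id`, `contig`, `start`, `end`,
#' `strand`, `feature_type`, `length`, `product`.
#'
#' @param annotation A `tradis_annotation`.
#' @param path Output (or input) TSV path.
#' @return `write_gene_table()` returns `path` invisibly; `read_gene_table()`
#'   returns the gene data.frame (as accepted by [tradis_annotation()]).
#' @export
write_gene_table <- function(annotation, path) {
  g <- annotation$genes
  utils::write.table(
    g[, c("gene_id", "contig", "start", "end", "strand", "feature_type",
          "length", "product")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(gene_id = "character", product = "character"))
  g$product[is.na(g$product) | g$product == ""] <- NA_character_
  g
}

#' A+T fraction of a genomic window
#'
#' Fraction of A or T bases in `[start, end]`; `N` bases are excluded from both
#' numerator and denominator.
#'
#' @param annotation A `tradis_annotation`.
#' @param start,end 1-based inclusive window bounds.
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when the window
#'   contains only `N`.
#' @export
at_fraction <- function(annotation, start, end) {
  L <- annotation$genome_length
  if (start < 1L || end > L || start > end)
    stop("window [", start, ", ", end, "] outside genome [1, ", L, "]")
  win <- Biostrings::subseq(annotation$sequence, start, end)
  freq <- Biostrings::letterFrequency(win, c("A", "T", "G", "C"))
  denom <- sum(freq)
  if (denom == 0) {
    warning("window contains no A/C/G/T bases; A+T fraction undefined")
    return(NA_real_)
  }
  unname((freq[["A"]] + freq[["T"]]) / denom)
}

# circular distance from ori, in bp, for 1-based positions
ori_distance <- function(pos, ori, L) {
  d <- abs(pos - ori)
  pmin(d, L - d)
}
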