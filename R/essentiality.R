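#' Per-gene insertion statistics
#'
#' Computes, for every gene, the number of unique insertion sites in its full
#' span (`raw_sites`), the number in its 5' portion after excluding the 3'
#' `trim3_fraction` of the gene (`trimmed_sites`; 3'-end insertions do not
#' necessarily inactivate the product), the total read count, and the
#' insertion index `trimmed_sites / gene_length`.
#'
#' @param annotation A [tradis_annotation()].
#' @param profile An [insertion_profile()] over the same chromosome.
#' @param trim3_fraction Fraction of the gene's 3' end excluded from the
#'   numerator (default 0.10).
#' @return A data.frame with one row per gene: `gene_id`, `feature_type`,
#'   `strand`, `gene_length`, `raw_sites`, `trimmed_sites`, `read_count`,
#'   `insertion_index`.
#' @export
gene_stats <- function(annotation, profile, trim3_fraction = 0.10) {
  if (annotation$genome_length != profile$genome_length)
    stop("annotation (", annotation$genome_length, " bp) and profile (",
         profile$genome_length, " bp) lengths differ")
  stopifnot(trim3_fraction >= 0, trim3_fraction < 1)
  L <- annotation$genome_length
  site <- as.integer(profile$fwd + profile$rev > 0L)
  cs_site <- cumsum(site)
  cs_count <- cumsum(as.numeric(profile$fwd + profile$rev))

  g <- annotation$genes
  n <- nrow(g)
  raw <- integer(n); trimmed <- integer(n); rc <- numeric(n)
  for (i in seq_len(n)) {
    s <- g$start[i]; e <- g$end[i]; len <- g$length[i]
    keep <- len - floor(trim3_fraction * len)   # 5'-side bases retained
    if (g$strand[i] == "+") {
      ta <- s; tb <- circ_pos(s + keep - 1L, L)
    } else {
      ta <- circ_pos(e - keep + 1L, L); tb <- e
    }
    raw[i] <- circ_sum(cs_site, s, e, L)
    trimmed[i] <- circ_sum(cs_site, ta, tb, L)
    rc[i] <- circ_sum(cs_count, s, e, L)
  }
  data.frame(gene_id = g$gene_id, feature_type = g$feature_type,
             strand = g$strand, gene_length = g$length,
             raw_sites = raw, trimmed_sites = trimmed, read_count = rc,
             insertion_index = trimmed / g$length,
             stringsAsFactors = FALSE)
}

# wrap a possibly out-of-range 1-based position onto the circle
circ_pos <- function(p, L) ((p - 1L) %% L) + 1L

# sum of a cumulative vector over circular interval [a, b] (a > b wraps)
circ_sum <- function(cs, a, b, L) {
  if (a <= b) {
    cs[b] - if (a > 1L) cs[a - 1L] else 0
  } else {
    (cs[L] - if (a > 1L) cs[a - 1L] else 0) + cs[b]
  }
}

#' Fit the bimodal gamma insertion-index model
#'
#' The distribution of per-gene insertion indices in a saturated transposon
#' library is bimodal: a mode at (or near) zero formed by essential genes, and
#' a broad non-essential mode. This fits a two-component gamma model: a kernel
#' density estimate locates the anti-mode (valley) between the two largest
#' modes, a gamma is fitted by maximum likelihood to each side (zero indices
#' are replaced by `epsilon` for fitting only, since the gamma excludes 0),
#' and the index values at which the log2 likelihood ratio crosses the
#' essential/non-essential thresholds are derived as dataset-specific
#' cutoffs.
#'
#' @param x A numeric vector of insertion indices, or a data.frame from
#'   [gene_stats()] (its `insertion_index` column is used).
#' @param llr_essential_max LLR below which a gene is called essential
#'   (default -2).
#' @param llr_nonessential_min LLR above which a gene is called non-essential
#'   (default +2).
#' @param epsilon Replacement for zero indices during fitting; defaults to
#'   `1 / (2 * genome_length)` when `genome_length` is given, else one tenth
#'   of the smallest positive index.
#' @param genome_length Optional chromosome length used for the default
#'   `epsilon`.
#' @return An object of class `tradis_fit` with components `essential` and
#'   `nonessential` (named `shape`/`rate` vectors), mixture `weights`,
#'   `valley_index`, `derived_ess_cutoff`, `derived_noness_cutoff`, the LLR
#'   thresholds, `epsilon` and the data. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `simulate`, `logLik`.
#' @seealso [llr()], [classify()]
#' @export
fit_insertion_model <- function(x, llr_essential_max = -2,
                                llr_nonessential_min = 2,
                                epsilon = NULL, genome_length = NULL) {
  if (is.data.frame(x)) x <- x$insertion_index
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 0)) stop("insertion indices must be non-negative")
  if (length(x) < 100L)
    stop("need at least 100 genes to fit the bimodal model; got ", length(x))
  if (is.null(epsilon)) {
    epsilon <- if (!is.null(genome_length)) 1 / (2 * genome_length)
               else min(x[x > 0]) / 10
  }

  dens <- stats::density(x, bw = "nrd0")   # Gaussian kernel, Silverman bw
  y <- dens$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1L] > y[2L]) is_max <- c(1L, is_max)
  if (y[length(y)] > y[length(y) - 1L]) is_max <- c(is_max, length(y))
  # noise floor: a genuine mode must reach 5% of the tallest mode's height
  is_max <- is_max[y[is_max] >= 0.05 * max(y[is_max])]
  if (length(is_max) < 2L)
    stop("insertion-index distribution is unimodal; the library is likely ",
         "unsaturated and the essential/non-essential modes cannot be separated")
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  between <- seq(top2[1L], top2[2L])
  # tie between equal minima broken toward the smaller index
  valley <- dens$x[between[which.min(y[between])]]
  valley <- max(valley, epsilon * 2)

  xe <- x[x < valley]; xn <- x[x >= valley]
  if (!length(xe) || !length(xn))
    stop("valley at ", signif(valley, 4), " leaves an empty component")
  xe[xe <= 0] <- epsilon
  ess <- fit_gamma(xe)
  non <- fit_gamma(xn)
  w <- c(essential = length(xe), nonessential = length(xn)) / length(x)

  fit <- structure(
    list(essential = ess, nonessential = non, weights = w,
         valley_index = valley,
         llr_essential_max = llr_essential_max,
         llr_nonessential_min = llr_nonessential_min,
         epsilon = epsilon, data = x, n = length(x)),
    class = "tradis_fit")
  cuts <- derive_cutoffs(fit)
  fit$derived_ess_cutoff <- cuts[1L]
  fit$derived_noness_cutoff <- cuts[2L]
  fit
}

#' @rdname fit_insertion_model
#' @export
fit_bimodal_gamma <- fit_insertion_model

# gamma MLE; scale-normalised so fitdistrplus works on tiny indices
# (shape is scale-invariant, the rate is rescaled back)
fit_gamma <- function(x) {
  if (length(x) < 2L || stats::sd(x) == 0) {
    # degenerate (near-)constant component: exponential with the observed mean
    return(c(shape = 1, rate = 1 / mean(x)))
  }
  s <- 1 / mean(x)
  f <- suppressWarnings(
    fitdistrplus::fitdist(x * s, "gamma", method = "mle"))
  est <- f$estimate
  c(shape = unname(est["shape"]), rate = unname(est["rate"]) * s)
}

#' Log2 likelihood ratio of the two fitted components
#'
#' `llr(index) = log2( density_nonessential(index) / density_essential(index) )`,
#' so strongly negative values are evidence for essentiality. An index of 0 is
#' `-Inf` by convention: a gene with no insertions is maximal evidence of
#' essentiality.
#'
#' @param index Numeric vector of insertion indices.
#' @param fit A `tradis_fit`.
#' @return Numeric vector of LLR values (may be `-Inf`/`Inf`).
#' @export
llr <- function(index, fit) {
  stopifnot(inherits(fit, "tradis_fit"))
  ln <- stats::dgamma(index, fit$nonessential["shape"], fit$nonessential["rate"], log = TRUE)
  le <- stats::dgamma(index, fit$essential["shape"], fit$essential["rate"], log = TRUE)
  out <- (ln - le) / log(2)
  out[index <= 0] <- -Inf
  unname(out)
}

# index values where the LLR crosses the two thresholds, scanned on a fine
# grid from epsilon to the non-essential mode and refined by uniroot
derive_cutoffs <- function(fit) {
  sh <- fit$nonessential["shape"]; ra <- fit$nonessential["rate"]
  mode_n <- if (sh > 1) (sh - 1) / ra else fit$valley_index * 2
  hi <- max(mode_n, fit$valley_index)
  grid <- seq(fit$epsilon, hi, length.out = 4000L)
  lv <- llr(grid, fit)
  cross <- function(threshold) {
    above <- which(lv >= threshold)
    if (!length(above)) return(hi)
    i <- above[1L]
    if (i == 1L) return(grid[1L])
    stats::uniroot(function(z) llr(z, fit) - threshold,
                   c(grid[i - 1L], grid[i]), tol = 1e-12)$root
  }
  ess <- cross(fit$llr_essential_max)
  non <- cross(fit$llr_nonessential_min)
  c(min(ess, non), max(ess, non))
}

#' @export
print.tradis_fit <- function(x, ...) {
  cat("Bimodal gamma insertion-index model\n")
  cat(sprintf("  genes: %d   valley index: %.5g\n", x$n, x$valley_index))
  cat(sprintf("  essential component:     Gamma(shape %.3g, rate %.4g)  weight %.2f\n",
              x$essential["shape"], x$essential["rate"], x$weights[1L]))
  cat(sprintf("  non-essential component: Gamma(shape %.3g, rate %.4g)  weight %.2f\n",
              x$nonessential["shape"], x$nonessential["rate"], x$weights[2L]))
  cat(sprintf("  LLR thresholds %g / %g -> index cutoffs %.4g (essential) / %.4g (non-essential)\n",
              x$llr_essential_max, x$llr_nonessential_min,
              x$derived_ess_cutoff, x$derived_noness_cutoff))
  invisible(x)
}

#' @export
coef.tradis_fit <- function(object, ...) {
  c(ess_shape = unname(object$essential["shape"]),
    ess_rate = unname(object$essential["rate"]),
    noness_shape = unname(object$nonessential["shape"]),
    noness_rate = unname(object$nonessential["rate"]))
}

#' @export
logLik.tradis_fit <- function(object, ...) {
  x <- object$data
  x[x <= 0] <- object$epsilon
  d <- object$weights[1L] * stats::dgamma(x, object$essential["shape"], object$essential["rate"]) +
       object$weights[2L] * stats::dgamma(x, object$nonessential["shape"], object$nonessential["rate"])
  structure(sum(log(d)), df = 5L, nobs = object$n, class = "logLik")
}

#' Predict essentiality classes for insertion indices
#'
#' @param object A `tradis_fit`.
#' @param newdata Numeric vector of insertion indices; defaults to the fitted
#'   data.
#' @param ... Unused.
#' @return A data.frame with `insertion_index`, `llr` and `class`
#'   (`essential`, `ambiguous`, `non_essential`).
#' @export
predict.tradis_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data else as.numeric(newdata)
  lv <- llr(x, object)
  cls <- ifelse(lv < object$llr_essential_max, "essential",
         ifelse(lv > object$llr_nonessential_min, "non_essential", "ambiguous"))
  data.frame(insertion_index = x, llr = lv, class = cls, stringsAsFactors = FALSE)
}

#' @export
summary.tradis_fit <- function(object, ...) {
  pr <- predict(object)
  tab <- table(factor(pr$class, c("essential", "ambiguous", "non_essential")))
  out <- list(fit = object, class_counts = tab,
              class_pct = round(100 * as.numeric(tab) / object$n, 1))
  class(out) <- "summary.tradis_fit"
  out
}

#' @export
print.summary.tradis_fit <- function(x, ...) {
  print(x$fit)
  tab <- x$class_counts
  for (i in seq_along(tab))
    cat(sprintf("  %-14s %5d  (%.1f%%)\n", names(tab)[i], tab[i], x$class_pct[i]))
  invisible(x)
}

#' @export
plot.tradis_fit <- function(x, breaks = 60, ...) {
  h <- graphics::hist(x$data, breaks = breaks, freq = FALSE,
                      main = "Insertion-index distribution",
                      xlab = "insertion index (sites / bp)", border = "grey40", ...)
  grid <- seq(max(min(x$data), x$epsilon), max(x$data), length.out = 500)
  graphics::lines(grid, x$weights[1L] * stats::dgamma(grid, x$essential["shape"], x$essential["rate"]),
                  col = "firebrick", lwd = 2)
  graphics::lines(grid, x$weights[2L] * stats::dgamma(grid, x$nonessential["shape"], x$nonessential["rate"]),
                  col = "steelblue", lwd = 2)
  graphics::abline(v = c(x$derived_ess_cutoff, x$derived_noness_cutoff),
                   lty = 2, col = "grey30")
  invisible(h)
}

#' @importFrom stats simulate
#' @export
simulate.tradis_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n * nsim
  comp <- stats::rbinom(n, 1L, object$weights[2L])
  out <- numeric(n)
  out[comp == 0L] <- stats::rgamma(sum(comp == 0L), object$essential["shape"],
                                   object$essential["rate"])
  out[comp == 1L] <- stats::rgamma(sum(comp == 1L), object$nonessential["shape"],
                                   object$nonessential["rate"])
  matrix(out, ncol = nsim)
}

#' Classify genes as essential, ambiguous or non-essential
#'
#' Applies the LLR thresholds of a fitted model to per-gene statistics:
#' essential iff `llr < llr_essential_max`, non-essential iff
#' `llr > llr_nonessential_min`, ambiguous otherwise. Curation flags annotate
#' but never silently change the class.
#'
#' @param stats A data.frame from [gene_stats()].
#' @param fit A `tradis_fit`.
#' @param uneven_flags Optional logical vector (e.g. from
#'   [unevenness_flag()]), aligned with `stats`.
#' @param repeat_gene_ids Optional character vector of genes in repeat /
#'   multi-copy regions, marked `excluded_repeat` (reported but flagged for
#'   exclusion from final essential lists as presumptive false positives).
#' @return A data.frame of calls: `gene_id`, `feature_type`, `gene_length`,
#'   `raw_sites`, `trimmed_sites`, `read_count`, `insertion_index`, `llr`,
#'   `class`, `uneven_flag`, `excluded_repeat`.
#' @export
classify <- function(stats, fit, uneven_flags = NULL, repeat_gene_ids = NULL) {
  stopifnot(inherits(fit, "tradis_fit"))
  pr <- predict(fit, stats$insertion_index)
  if (is.null(uneven_flags)) uneven_flags <- rep(FALSE, nrow(stats))
  stopifnot(length(uneven_flags) == nrow(stats))
  data.frame(stats[, c("gene_id", "feature_type", "gene_length", "raw_sites",
                       "trimmed_sites", "read_count", "insertion_index")],
             llr = pr$llr, class = pr$class,
             uneven_flag = uneven_flags,
             excluded_repeat = stats$gene_id %in% repeat_gene_ids,
             stringsAsFactors = FALSE)
}

#' Flag genes with insertions confined to one gene end
#'
#' Automated surrogate for manual curation of unevenly disrupted genes: a gene
#' is flagged when all of its insertion sites fall within one terminal bin
#' covering at most 20% of the gene, the remaining length is insertion-free,
#' and the library's global site density predicts at least `min_expected`
#' sites for a gene of that length (so the emptiness is surprising).
#'
#' @param annotation A [tradis_annotation()].
#' @param profile An [insertion_profile()].
#' @param n_bins Number of equal bins per gene (default 5; terminal bins then
#'   cover 20% of the gene).
#' @param min_expected Minimum expected site count for the flag to fire
#'   (default 3).
#' @return Logical vector aligned with the annotation's gene table.
#' @export
unevenness_flag <- function(annotation, profile, n_bins = 5L, min_expected = 3) {
  L <- annotation$genome_length
  site <- as.integer(profile$fwd + profile$rev > 0L)
  cs <- cumsum(site)
  density_global <- cs[L] / L
  g <- annotation$genes
  out <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    len <- g$length[i]
    if (density_global * len < min_expected) next
    # gene positions in 5'->3' order, circular-safe
    pos <- circ_pos(seq.int(g$start[i], length.out = len), L)
    bins <- cut(seq_len(len), n_bins, labels = FALSE)
    hits <- vapply(split(pos, bins), function(p) sum(site[p]), 0)
    total <- sum(hits)
    if (total == 0) next
    terminal <- c(1L, n_bins)
    out[i] <- any(hits[terminal] == total) && (1 / n_bins) <= 0.2
  }
  out
}

#' Summarise essentiality calls
#'
#' Counts and percentages (one decimal place) of genes with at least one
#' insertion and of each essentiality class, overall and by feature type.
#'
#' @param calls A data.frame from [classify()].
#' @return A list of class `tradis_summary`: `n_genes`, `with_insertion`
#'   (count + pct), per-class counts/pcts, and a `by_feature_type` table.
#' @export
summarize_essentiality <- function(calls) {
  n <- nrow(calls)
  wi <- sum(calls$raw_sites > 0)
  classes <- c("essential", "ambiguous", "non_essential")
  cls <- factor(calls$class, classes)
  tab <- table(cls)
  by_ft <- as.data.frame.matrix(table(calls$feature_type, cls))
  out <- list(
    n_genes = n,
    with_insertion = c(count = wi, pct = pct(wi, n)),
    class_counts = as.integer(tab),
    class_pct = pct(as.integer(tab), n),
    classes = classes,
    by_feature_type = by_ft)
  class(out) <- "tradis_summary"
  out
}

#' @export
print.tradis_summary <- function(x, ...) {
  cat(sprintf("%d genes; %d (%.1f%%) with >=1 insertion\n",
              x$n_genes, x$with_insertion["count"], x$with_insertion["pct"]))
  for (i in seq_along(x$classes))
    cat(sprintf("  %-14s %5d  (%.1f%%)\n", x$classes[i], x$class_counts[i],
                x$class_pct[i]))
  cat("by feature type:\n")
  print(x$by_feature_type)
  invisible(x)
}

#' Percentage of a count, to one decimal place
#'
#' @param count,total Numerators and denominator.
#' @param digits Decimal places (default 1; use 0 for prose-style integers).
#' @return `round(100 * count / total, digits)`.
#' @export
pct <- function(count, total, digits = 1) round(100 * count / total, digits)

#' Documented full-data replication benchmarks
#'
#' Benchmark targets for full-scale analysis of the deposited *B. breve*
#' UCC2003 TraDIS sequencing runs, which require downloading the runs and
#' mapping with an external aligner. Recorded here as documentation; they are
#' not computed at desk scale.
#'
#' @return A list: ENA run accessions, reference accession, expected essential
#'   gene count and expected three-taxon essential core size.
#' @export
replication_benchmarks <- function() {
  list(
    ena_runs = c("ERR877647", "ERR877656"),
    reference = "CP000303.1",
    expected_essential_genes = 453L,
    expected_three_taxon_essential_core = 106L,
    note = paste("Full-data replication: map the deposited runs to the",
                 "reference with an external aligner (exact matching, PHRED>=30,",
                 "42 bp post-trim cutoff), then run the essentiality and",
                 "comparative stages; not a desk-scale test.")
  )
}
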