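#' Rarefaction (saturation) analysis
#'
#' Subsamples the library's read-level site draws without replacement at a
#' ladder of depths and averages the number of distinct insertion sites
#' recovered, estimating how close the library is to saturation. The
#' saturation statistic compares the slope over the final 10% of the curve
#' with the initial slope.
#'
#' @param site_draws Integer vector of site positions, one entry per sequenced
#'   read (draws with multiplicity).
#' @param depths Read depths at which to subsample; defaults to 15 levels
#'   spaced evenly up to `length(site_draws)`.
#' @param replicates Subsampling replicates per depth (default 3).
#' @param seed Integer seed; the curve is exactly reproducible for a fixed
#'   seed.
#' @return A list of class `rarefaction_curve`: `depths`,
#'   `mean_unique_sites`, `replicates`, `seed`, `initial_slope`,
#'   `terminal_slope` and `saturation_ratio` = terminal / initial slope.
#' @export
rarefaction <- function(site_draws, depths = NULL, replicates = 3L, seed = 1L) {
  n <- length(site_draws)
  if (!n) stop("empty read set")
  if (is.null(depths)) depths <- unique(round(seq(n / 15, n, length.out = 15)))
  depths <- sort(unique(pmin(as.integer(depths), n)))
  if (any(depths < 1L)) stop("depths must be >= 1")
  set.seed(seed)
  mean_unique <- vapply(depths, function(d) {
    mean(vapply(seq_len(replicates), function(r) {
      if (d == n) length(unique(site_draws))
      else length(unique(site_draws[sample.int(n, d)]))
    }, 0))
  }, 0)

  slope <- function(i, j) (mean_unique[j] - mean_unique[i]) / (depths[j] - depths[i])
  initial <- mean_unique[1L] / depths[1L]          # from the origin (0 reads, 0 sites)
  tail_from <- which(depths >= 0.9 * max(depths))[1L]
  terminal <- if (tail_from < length(depths)) slope(tail_from, length(depths))
              else slope(length(depths) - 1L, length(depths))
  structure(list(depths = depths, mean_unique_sites = mean_unique,
                 replicates = replicates, seed = seed,
                 initial_slope = initial, terminal_slope = terminal,
                 saturation_ratio = terminal / initial),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf(
    "<rarefaction_curve> %d depths to %s reads; %.0f sites at full depth\n",
    length(x$depths), format(max(x$depths), big.mark = ","),
    x$mean_unique_sites[length(x$depths)]))
  cat(sprintf("  terminal/initial slope = %.3g (saturated when << 1)\n",
              x$saturation_ratio))
  invisible(x)
}

#' @export
plot.rarefaction_curve <- function(x, ...) {
  graphics::plot(x$depths, x$mean_unique_sites, type = "b", pch = 16,
                 xlab = "reads sampled", ylab = "mean unique insertion sites",
                 main = "Rarefaction", ...)
  invisible(x)
}

#' Insertion density by chromosome octant
#'
#' Splits the chromosome into 8 equal arcs, with octant 1 centred on the
#' replication origin (and octant 5 on the terminus, the point opposite), and
#' reports the mean number of insertion events per gene in each octant. Genes
#' are assigned to octants by midpoint. In exponentially growing cells,
#' ori-proximal genes are present in more copies and collect more insertions,
#' so the octant means decline from octant 1 towards octant 5.
#'
#' @param annotation A [tradis_annotation()].
#' @param profile An [insertion_profile()].
#' @return A data.frame with `octant_id` (1-8), `genes`, and
#'   `mean_insertions_per_gene` (read multiplicities, not unique sites).
#' @export
octant_density <- function(annotation, profile) {
  L <- annotation$genome_length
  cs <- cumsum(as.numeric(profile$fwd + profile$rev))
  g <- annotation$genes
  counts <- vapply(seq_len(nrow(g)), function(i)
    circ_sum(cs, g$start[i], g$end[i], L), 0)
  mid <- ifelse(g$end >= g$start,
                (g$start + g$end) %/% 2L,
                circ_pos(g$start + g$length %/% 2L, L))
  # octant 1 centred on ori: offset so arcs start at ori - L/16
  arc <- L / 8
  rel <- (mid - annotation$ori_position + arc / 2) %% L
  oct <- pmin(floor(rel / arc) + 1L, 8L)
  agg <- tapply(counts, factor(oct, 1:8), mean)
  n_g <- tapply(counts, factor(oct, 1:8), length)
  data.frame(octant_id = 1:8,
             genes = as.integer(ifelse(is.na(n_g), 0L, n_g)),
             mean_insertions_per_gene = as.numeric(ifelse(is.na(agg), 0, agg)))
}

#' A+T-richness insertion bias
#'
#' Splits the chromosome into fixed-size windows, ranks them by A+T fraction,
#' and compares the mean insertion density (events per bp) of the
#' top-quartile-AT windows against the remaining windows. The report value is
#' the relative elevation in percent:
#' `100 * (density_topAT / density_rest - 1)`.
#'
#' @param annotation A [tradis_annotation()].
#' @param profile An [insertion_profile()].
#' @param window_bp Window size in bp (default 1000).
#' @return A list of class `at_bias_report`: `bias_pct` (`NA` with a warning
#'   for an insertion-free profile), `window_bp`, `n_windows`, and the
#'   per-window table (`start`, `end`, `at_fraction`, `density`, `top_at`).
#' @export
at_bias <- function(annotation, profile, window_bp = 1000L) {
  L <- annotation$genome_length
  starts <- seq.int(1L, L, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, L)
  # drop a trailing fragment shorter than half a window
  if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)] + 1L) < window_bp / 2) {
    starts <- starts[-length(starts)]; ends <- ends[-length(ends)]
  }
  atv <- window_at_fractions(annotation$sequence, starts, ends)
  cs <- cumsum(as.numeric(profile$fwd + profile$rev))
  counts <- vapply(seq_along(starts), function(i)
    circ_sum(cs, starts[i], ends[i], L), 0)
  dens <- counts / (ends - starts + 1L)
  top <- atv >= stats::quantile(atv, 0.75, na.rm = TRUE)
  tab <- data.frame(start = starts, end = ends, at_fraction = atv,
                    density = dens, top_at = top)
  if (sum(counts) == 0) {
    warning("insertion-free profile: A+T bias undefined")
    bias <- NA_real_
  } else {
    bias <- 100 * (mean(dens[top]) / mean(dens[!top]) - 1)
  }
  structure(list(bias_pct = bias, window_bp = as.integer(window_bp),
                 n_windows = length(starts), windows = tab),
            class = "at_bias_report")
}

#' @export
print.at_bias_report <- function(x, ...) {
  cat(sprintf("<at_bias_report> %d windows of %d bp; top-quartile-AT elevation: %s\n",
              x$n_windows, x$window_bp,
              if (is.na(x$bias_pct)) "undefined (no insertions)"
              else sprintf("%+.1f%%", x$bias_pct)))
  invisible(x)
}

# vectorised per-window A+T fractions (N excluded from both terms)
window_at_fractions <- function(sequence, starts, ends) {
  v <- Biostrings::Views(sequence, start = starts, end = ends)
  freq <- Biostrings::letterFrequency(v, c("A", "T", "G", "C"))
  denom <- rowSums(freq)
  ifelse(denom == 0, NA_real_, (freq[, "A"] + freq[, "T"]) / denom)
}

#' Export binned insertion density as a plot-style track
#'
#' Writes mean insertion density per fixed-size bin (one line per bin:
#' `start end density`) for use by circular-plot tools.
#'
#' @param profile An [insertion_profile()].
#' @param path Output TSV path.
#' @param bin_bp Bin size (default 10000).
#' @return `path`, invisibly.
#' @export
write_density_track <- function(profile, path, bin_bp = 10000L) {
  L <- profile$genome_length
  starts <- seq.int(1L, L, by = bin_bp)
  ends <- pmin(starts + bin_bp - 1L, L)
  cs <- cumsum(as.numeric(profile$fwd + profile$rev))
  dens <- vapply(seq_along(starts), function(i)
    circ_sum(cs, starts[i], ends[i], L), 0) / (ends - starts + 1L)
  utils::write.table(data.frame(starts, ends, signif(dens, 6)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("start", "end", "density"))
  invisible(path)
}
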