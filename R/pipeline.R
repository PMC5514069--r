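#' Run configuration for an end-to-end analysis
#'
#' Bundles the simulator configuration (or input paths for pre-computed
#' data), the read-filter policy, essentiality thresholds and QC parameters.
#' Configurations round-trip through YAML so a run can be reproduced from its
#' serialized configuration alone.
#'
#' @param sim A [library_sim_config()] for synthetic runs, or `NULL` when
#'   `annotation_path`/`plot_path` are given.
#' @param annotation_path,fasta_path,plot_path Input files for runs on
#'   pre-computed data (annotation + per-base plot track).
#' @param policy A [read_filter_policy()].
#' @param trim3_fraction 3'-end exclusion fraction (default 0.10).
#' @param llr_essential_max,llr_nonessential_min LLR thresholds (-2 / +2).
#' @param at_window_bp AT-bias window size (default 1000).
#' @param rarefaction_replicates Subsampling replicates (default 3).
#' @param seed Run seed (routed to every stochastic stage).
#' @return A list of class `tradis_config`.
#' @export
tradis_config <- function(sim = library_sim_config(), annotation_path = NULL,
                          fasta_path = NULL, plot_path = NULL,
                          policy = read_filter_policy(),
                          trim3_fraction = 0.10,
                          llr_essential_max = -2, llr_nonessential_min = 2,
                          at_window_bp = 1000L,
                          rarefaction_replicates = 3L, seed = 1L) {
  if (is.null(sim) && (is.null(annotation_path) || is.null(plot_path)))
    stop("config needs either a simulator block or annotation + plot paths")
  structure(list(sim = sim, annotation_path = annotation_path,
                 fasta_path = fasta_path, plot_path = plot_path,
                 policy = policy, trim3_fraction = trim3_fraction,
                 llr_essential_max = llr_essential_max,
                 llr_nonessential_min = llr_nonessential_min,
                 at_window_bp = as.integer(at_window_bp),
                 rarefaction_replicates = as.integer(rarefaction_replicates),
                 seed = as.integer(seed)),
            class = "tradis_config")
}

#' Serialize / load a run configuration (YAML)
#'
#' @param config A [tradis_config()].
#' @param path YAML file path.
#' @return `read_config()` returns a `tradis_config` identical to the one
#'   written.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$sim)) do.call(library_sim_config, raw$sim) else NULL
  policy <- if (!is.null(raw$policy)) do.call(read_filter_policy, raw$policy)
            else read_filter_policy()
  tradis_config(sim = sim, annotation_path = raw$annotation_path,
                fasta_path = raw$fasta_path, plot_path = raw$plot_path,
                policy = policy, trim3_fraction = raw$trim3_fraction,
                llr_essential_max = raw$llr_essential_max,
                llr_nonessential_min = raw$llr_nonessential_min,
                at_window_bp = raw$at_window_bp,
                rarefaction_replicates = raw$rarefaction_replicates,
                seed = raw$seed)
}

#' Run the full analysis end to end
#'
#' Orchestrates simulate (synthetic mode) or load (plot-track mode) ->
#' profile -> per-gene statistics -> bimodal gamma fit -> classification ->
#' QC (rarefaction, octant gradient, AT bias) -> summary. Deterministic for a
#' fixed configuration; with `outdir` set, per-stage TSVs, a JSON summary and
#' the serialized configuration are written alongside a timing log.
#'
#' @param config A [tradis_config()].
#' @param outdir Optional output directory.
#' @return A list of class `tradis_run`: `annotation`, `profile`, `stats`,
#'   `fit`, `calls`, `summary`, `qc` (rarefaction / octants / at_bias),
#'   `performance` (sensitivity/specificity vs truth, synthetic mode only)
#'   and `log` (stage timings).
#' @export
run_tradis <- function(config = tradis_config(), outdir = NULL) {
  stopifnot(inherits(config, "tradis_config"))
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log[[name]] <<- round(tic() - t0, 3)
    out
  }

  truth <- NULL; site_draws <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    gen <- stage("simulate_genome", generate_genome(sim))
    annotation <- gen$annotation; truth <- gen$truth
    lib <- stage("simulate_library", generate_library(annotation, truth, sim))
    aln <- stage("map_reads",
                 locate_reads_exact(lib$reads, annotation, config$policy))
    profile <- stage("profile", profile_from_alignments(
      aln, config$policy, annotation$genome_length))
    site_draws <- lib$site_draws
  } else {
    annotation <- stage("load_annotation",
                        read_annotation(config$annotation_path,
                                        fasta_path = config$fasta_path))
    profile <- stage("load_profile", read_plot(config$plot_path))
    if (profile$genome_length != annotation$genome_length)
      stop("plot track length (", profile$genome_length,
           ") does not match annotation (", annotation$genome_length, ")")
    us <- unique_sites(profile)
    site_draws <- rep(us$sites, profile$fwd[us$sites] + profile$rev[us$sites])
  }

  stats <- stage("gene_stats",
                 gene_stats(annotation, profile, config$trim3_fraction))
  fit <- stage("fit", fit_insertion_model(
    stats, llr_essential_max = config$llr_essential_max,
    llr_nonessential_min = config$llr_nonessential_min,
    genome_length = annotation$genome_length))
  uneven <- stage("unevenness", unevenness_flag(annotation, profile))
  calls <- stage("classify", classify(stats, fit, uneven_flags = uneven))
  summ <- stage("summarize", summarize_essentiality(calls))
  qc <- list(
    rarefaction = stage("rarefaction",
                        rarefaction(site_draws,
                                    replicates = config$rarefaction_replicates,
                                    seed = config$seed)),
    octants = stage("octants", octant_density(annotation, profile)),
    at_bias = stage("at_bias",
                    at_bias(annotation, profile, config$at_window_bp)))

  performance <- NULL
  if (!is.null(truth))
    performance <- call_performance(calls, truth$essential_gene_ids)

  run <- structure(list(annotation = annotation, profile = profile,
                        stats = stats, fit = fit, calls = calls,
                        summary = summ, qc = qc, performance = performance,
                        truth = truth, config = config, log = unlist(log)),
                   class = "tradis_run")
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

#' Sensitivity and specificity of essential calls against a known truth
#'
#' @param calls A data.frame from [classify()].
#' @param essential_gene_ids Character vector of truly essential genes.
#' @return Named numeric vector: `sensitivity`, `specificity`,
#'   `true_positives`, `false_positives`, `false_negatives`,
#'   `true_negatives`.
#' @export
call_performance <- function(calls, essential_gene_ids) {
  called <- calls$class == "essential"
  truly <- calls$gene_id %in% essential_gene_ids
  tp <- sum(called & truly); fp <- sum(called & !truly)
  fn <- sum(!called & truly); tn <- sum(!called & !truly)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    true_positives = tp, false_positives = fp,
    false_negatives = fn, true_negatives = tn)
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outdir, f)
  utils::write.table(run$calls, fp("calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(run$qc$octants, fp("octants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rc <- run$qc$rarefaction
  utils::write.table(
    data.frame(depth = rc$depths, mean_unique_sites = rc$mean_unique_sites),
    fp("rarefaction.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_table(run$annotation, fp("genes.tsv"))
  write_config(run$config, fp("config.yaml"))
  s <- run$summary
  json <- list(
    n_genes = s$n_genes,
    genes_with_insertion = unname(s$with_insertion["count"]),
    pct_genes_with_insertion = unname(s$with_insertion["pct"]),
    class_counts = stats::setNames(as.list(s$class_counts), s$classes),
    class_pct = stats::setNames(as.list(s$class_pct), s$classes),
    derived_ess_cutoff = run$fit$derived_ess_cutoff,
    derived_noness_cutoff = run$fit$derived_noness_cutoff,
    at_bias_pct = run$qc$at_bias$bias_pct,
    saturation_ratio = rc$saturation_ratio,
    stage_seconds = as.list(run$log))
  if (!is.null(run$performance))
    json$performance <- as.list(run$performance)
  jsonlite::write_json(json, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.tradis_run <- function(x, ...) {
  cat("<tradis_run>\n")
  print(x$summary)
  if (!is.null(x$performance))
    cat(sprintf("essential-call sensitivity %.3f, specificity %.3f\n",
                x$performance["sensitivity"], x$performance["specificity"]))
  invisible(x)
}
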