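test_that("gene statistics apply the 3'-end exclusion on both strands", {
  genes <- data.frame(
    gene_id = c("plus", "minus"), contig = "chr",
    start = c(1L, 1501L), end = c(1000L, 2500L),
    strand = c("+", "-"), feature_type = "CDS", product = NA)
  set.seed(1)
  ann <- tradis_annotation(paste(sample(c("A", "C", "G", "T"), 2600, TRUE),
                                 collapse = ""), genes)
  # plus gene: sites at 10/500/850 all in 5' 90% (1..900); 950 is excluded
  p1 <- profile_at(2600L, c(10L, 500L, 850L))
  s1 <- gene_stats(ann, p1)
  expect_equal(s1$trimmed_sites[s1$gene_id == "plus"], 3L)
  expect_equal(s1$insertion_index[s1$gene_id == "plus"], 0.003)

  p2 <- profile_at(2600L, 950L)
  s2 <- gene_stats(ann, p2)
  expect_equal(s2$raw_sites[s2$gene_id == "plus"], 1L)
  expect_equal(s2$trimmed_sites[s2$gene_id == "plus"], 0L)
  expect_equal(s2$insertion_index[s2$gene_id == "plus"], 0)

  # minus gene 1501..2500: its 3' end is the low-coordinate end
  p3 <- profile_at(2600L, 1550L)   # within first 10% -> excluded
  s3 <- gene_stats(ann, p3)
  expect_equal(s3$raw_sites[s3$gene_id == "minus"], 1L)
  expect_equal(s3$trimmed_sites[s3$gene_id == "minus"], 0L)
})

test_that("genes wrapping the circular origin are measured as one span", {
  genes <- data.frame(
    gene_id = c("wrap", "plain"), contig = "chr",
    start = c(1900L, 500L), end = c(100L, 900L),
    strand = c("+", "+"), feature_type = "CDS", product = NA)
  set.seed(2)
  ann <- tradis_annotation(paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                                 collapse = ""), genes)
  expect_equal(ann$genes$length[ann$genes$gene_id == "wrap"], 201L)
  prof <- profile_at(2000L, c(1950L, 50L))
  st <- gene_stats(ann, prof)
  expect_equal(st$raw_sites[st$gene_id == "wrap"], 2L)
  # 5' 90% of the 201 bp wrap gene covers 1900..2000 and 1..80
  expect_equal(st$trimmed_sites[st$gene_id == "wrap"], 2L)
})

test_that("the gamma mixture recovers generating parameters and ordered cutoffs", {
  set.seed(20240915)
  x <- c(rgamma(500, shape = 0.2, scale = 0.002),
         rgamma(1500, shape = 8, scale = 0.002))
  fit <- fit_insertion_model(x)
  expect_lt(abs(coef(fit)["ess_shape"] - 0.2) / 0.2, 0.25)
  expect_lt(abs(coef(fit)["noness_shape"] - 8) / 8, 0.25)
  expect_lte(fit$derived_ess_cutoff, fit$derived_noness_cutoff)
  mode_n <- (coef(fit)["noness_shape"] - 1) / coef(fit)["noness_rate"]
  expect_gt(fit$derived_ess_cutoff, 0)
  expect_lt(fit$derived_noness_cutoff, mode_n)

  # cutoffs agree with a brute-force scan for LLR sign changes on a fine grid
  grid <- seq(fit$epsilon, mode_n, length.out = 50000)
  lv <- llr(grid, fit)
  brute_ess <- grid[max(which(lv < fit$llr_essential_max))]
  brute_non <- grid[min(which(lv > fit$llr_nonessential_min))]
  expect_lt(abs(brute_ess - fit$derived_ess_cutoff), diff(grid[1:2]) * 2)
  expect_lt(abs(brute_non - fit$derived_noness_cutoff), diff(grid[1:2]) * 2)
})

test_that("LLR is oriented and monotone between the modes", {
  set.seed(33)
  x <- c(rep(0, 400), rgamma(1600, shape = 7, scale = 0.003))
  fit <- fit_insertion_model(x, genome_length = 2e6)
  mode_n <- (coef(fit)["noness_shape"] - 1) / coef(fit)["noness_rate"]
  expect_identical(llr(0, fit), -Inf)
  expect_lt(llr(fit$epsilon, fit), -10)          # essential mode dominance
  expect_gt(llr(mode_n, fit), 10)                # non-essential mode dominance
  grid <- seq(fit$epsilon, mode_n, length.out = 400)
  expect_true(all(diff(llr(grid, fit)) >= -1e-9))
  # zero-insertion genes are always classified essential
  expect_equal(predict(fit, 0)$class, "essential")
})

test_that("classification partitions genes and honours curation flags", {
  set.seed(44)
  x <- c(rep(0, 50), rgamma(150, shape = 7, scale = 0.003))
  fit <- fit_insertion_model(x, genome_length = 2e6)
  stats <- data.frame(
    gene_id = sprintf("g%03d", seq_along(x)),
    feature_type = "CDS", gene_length = 1000L,
    raw_sites = as.integer(x > 0), trimmed_sites = as.integer(x > 0),
    read_count = as.integer(x > 0), insertion_index = x)
  calls <- classify(stats, fit, repeat_gene_ids = "g001")
  expect_true(all(calls$class %in% c("essential", "ambiguous", "non_essential")))
  expect_equal(nrow(calls), length(x))
  expect_true(calls$excluded_repeat[calls$gene_id == "g001"])
  # the flag annotates: the class is still determined by the LLR alone
  expect_equal(calls$class[calls$gene_id == "g001"], "essential")
  expect_true(all(calls$class[calls$insertion_index == 0] == "essential"))
})

test_that("classification is equivariant to a common index rescaling", {
  set.seed(55)
  x <- c(rep(0, 300), rgamma(900, shape = 8, scale = 0.002))
  f1 <- fit_insertion_model(x)
  f2 <- fit_insertion_model(x / 4)   # double lengths, halve counts
  expect_identical(predict(f1, x)$class, predict(f2, x / 4)$class)
})

test_that("unimodal index distributions are rejected with advice", {
  set.seed(66)
  expect_error(fit_insertion_model(rgamma(500, shape = 6, scale = 0.003)),
               "unsaturated")
})

test_that("unevenness flag fires only for terminal-bin-confined insertions", {
  genes <- data.frame(
    gene_id = c("tail", "spread", "empty"), contig = "chr",
    start = c(1L, 1101L, 2201L), end = c(1000L, 2100L, 3200L),
    strand = "+", feature_type = "CDS", product = NA)
  set.seed(3)
  ann <- tradis_annotation(paste(sample(c("A", "C", "G", "T"), 3300, TRUE),
                                 collapse = ""), genes)
  prof <- profile_at(3300L,
                     c(910L, 930L, 950L, 970L, 990L,       # tail: last 100 bp
                       1150L, 1450L, 1700L, 1950L,         # spread: 4 of 5 bins
                       3250L, 3260L, 3270L))               # intergenic background
  flags <- unevenness_flag(ann, prof)
  names(flags) <- ann$genes$gene_id
  expect_true(flags["tail"])
  expect_false(flags["spread"])
  expect_false(flags["empty"])    # nothing to assess
})

test_that("summaries report class percentages to one decimal place", {
  calls <- data.frame(
    gene_id = sprintf("g%d", 1:200), feature_type = "CDS",
    gene_length = 1000L, raw_sites = c(rep(0L, 40), rep(2L, 160)),
    trimmed_sites = 0L, read_count = 0L, insertion_index = 0,
    llr = -5, class = c(rep("essential", 40), rep("non_essential", 160)),
    uneven_flag = FALSE, excluded_repeat = FALSE)
  s <- summarize_essentiality(calls)
  expect_equal(unname(s$with_insertion["pct"]), 80.0)
  expect_equal(s$class_pct, c(20.0, 0.0, 80.0))
  calls$class <- "non_essential"
  expect_equal(summarize_essentiality(calls)$class_pct[1], 0.0)
})
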