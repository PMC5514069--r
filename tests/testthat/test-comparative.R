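test_that("pairwise similarity handles identity, containment and random pairs", {
  set.seed(12)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p <- paste(sample(aa, 100, replace = TRUE), collapse = "")
  h <- pairwise_similarity(c(x = p), c(y = p))
  expect_equal(h$percent_identity, 100)
  expect_equal(h$coverage_query, 1.0)
  expect_equal(h$coverage_subject, 1.0)

  half <- substr(p, 1, 50)
  h2 <- pairwise_similarity(c(x = p), c(y = half))
  expect_equal(h2$coverage_subject, 1.0)
  expect_lt(abs(h2$coverage_query - 0.5), 0.02)

  q <- paste(sample(aa, 100, replace = TRUE), collapse = "")
  h3 <- pairwise_similarity(c(x = p), c(y = q))
  expect_false(h3$percent_identity >= 50 &&
               max(h3$coverage_query, h3$coverage_subject) >= 0.5)
  expect_error(pairwise_similarity(c(x = ""), c(y = p)), "empty")
})

test_that("alignment scores agree with an independent Gotoh oracle", {
  set.seed(13)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    a <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    b <- if (i <= 2) {
      # related pair: mutate a at 20%
      v <- strsplit(a, "")[[1]]
      hit <- runif(40) < 0.2
      v[hit] <- sample(aa, sum(hit), replace = TRUE)
      paste(v, collapse = "")
    } else paste(sample(aa, 45, replace = TRUE), collapse = "")
    got <- pairwise_similarity(c(x = a), c(y = b))$score
    expect_equal(got, sw_score_oracle(a, b), tolerance = 1e-8)
  }
})

test_that("graph edges respect identity, coverage and reciprocity rules", {
  hit <- function(q, s, id, cq, cs) data.frame(
    query_id = q, subject_id = s, percent_identity = id,
    coverage_query = cq, coverage_subject = cs, score = 100)
  # 49% identity: below the default threshold
  g <- build_graph(rbind(hit("a", "b", 49, 1, 1), hit("b", "a", 49, 1, 1)))
  expect_equal(nrow(g$edges), 0L)
  # 20% identity passes in cross-phylum mode
  g2 <- build_graph(rbind(hit("a", "b", 20, 1, 1), hit("b", "a", 20, 1, 1)),
                    min_identity = 20)
  expect_equal(nrow(g2$edges), 1L)
  # one direction missing with reciprocal = TRUE
  g3 <- build_graph(hit("a", "b", 90, 1, 1))
  expect_equal(nrow(g3$edges), 0L)
  g4 <- build_graph(hit("a", "b", 90, 1, 1), reciprocal = FALSE)
  expect_equal(nrow(g4$edges), 1L)
  # "either sequence" coverage = max of the two
  g5 <- build_graph(rbind(hit("a", "b", 90, 0.2, 0.6), hit("b", "a", 90, 0.6, 0.2)))
  expect_equal(nrow(g5$edges), 1L)
  g6 <- build_graph(rbind(hit("a", "b", 90, 0.2, 0.3), hit("b", "a", 90, 0.3, 0.2)))
  expect_equal(nrow(g6$edges), 0L)
})

test_that("MCL equals connected components on disconnected graphs", {
  tri <- function(a, b, c) data.frame(from = c(a, b, a), to = c(b, c, c),
                                      weight = 1)
  graph <- structure(list(nodes = letters[1:6],
                          edges = rbind(tri("a", "b", "c"), tri("d", "e", "f"))),
                     class = "similarity_graph")
  for (infl in c(1.3, 2, 4)) {
    fam <- mcl_cluster(graph, inflation = infl)
    expect_equal(canonical_families(fam$families), c("a,b,c", "d,e,f"))
  }
})

test_that("MCL splits weakly-bridged cliques and matches the reference oracle", {
  clique <- function(nodes, w) {
    cmb <- t(combn(nodes, 2))
    data.frame(from = cmb[, 1], to = cmb[, 2], weight = w)
  }
  edges <- rbind(clique(paste0("a", 1:5), 100),
                 clique(paste0("b", 1:5), 100),
                 data.frame(from = "a1", to = "b1", weight = 1))
  nodes <- sort(unique(c(edges$from, edges$to)))
  graph <- structure(list(nodes = nodes, edges = edges),
                     class = "similarity_graph")
  fam <- mcl_cluster(graph, inflation = 2.0)
  expect_equal(canonical_families(fam$families),
               c("a1,a2,a3,a4,a5", "b1,b2,b3,b4,b5"))

  # reference: independent dense MCL on the same adjacency matrix
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  A[cbind(edges$from, edges$to)] <- edges$weight
  A[cbind(edges$to, edges$from)] <- edges$weight
  comp <- mcl_oracle(A, inflation = 2.0)
  oracle_fams <- split(nodes, comp)
  expect_equal(canonical_families(fam$families),
               canonical_families(oracle_fams))

  # node-order permutation leaves families unchanged
  perm <- sample(length(nodes))
  graph_p <- structure(list(nodes = nodes[perm], edges = edges),
                       class = "similarity_graph")
  expect_equal(canonical_families(mcl_cluster(graph_p)$families),
               canonical_families(fam$families))
})

test_that("core sets follow the presence and paralogue rules, nested", {
  fams <- list(
    all8 = sprintf("g%d|p1", 1:8),                 # single copy in all
    of4 = sprintf("g%d|p2", 1:4),                  # 4 of 5 genomes below
    para = c(sprintf("g%d|p3", 1:8), "g1|p3b"))    # duplicated in g1
  gmap <- setNames(sub("\\|.*", "", unlist(fams)), unlist(fams))
  cs <- core_sets(fams, gmap, genomes = sprintf("g%d", 1:8))
  expect_true("all8" %in% cs$single_copy_core)
  expect_true("para" %in% cs$core)
  expect_false("para" %in% cs$single_copy_core)
  expect_false("of4" %in% cs$core)

  cs5 <- core_sets(fams["of4"], gmap[fams$of4], genomes = sprintf("g%d", 1:5),
                   presence_fraction = 0.8)
  expect_true("of4" %in% cs5$extended_core)
  expect_false("of4" %in% cs5$core)
  # nesting invariant
  expect_true(all(cs$single_copy_core %in% cs$core))
  expect_true(all(cs$core %in% cs$extended_core))
})

test_that("overlap reports match printed-ratio arithmetic and symmetry", {
  ess <- sprintf("e%03d", 1:400)
  core <- c(ess[1:377], sprintf("c%03d", 1:500))
  ov <- overlap_report(list(essential = ess, species_core = core))
  pw <- ov$pairwise
  expect_equal(pw$n_overlap[pw$set_a == "essential"], 377L)
  expect_equal(pw$pct_of_a[pw$set_a == "essential"], 94)
  # symmetric counts agree from either side
  expect_equal(pw$n_overlap[1], pw$n_overlap[2])

  dis <- overlap_report(list(a = c("x", "y"), b = c("z")))
  expect_true(all(dis$pairwise$n_overlap == 0))
  sub <- overlap_report(list(a = c("x", "y"), b = c("x", "y", "z")))
  expect_equal(sub$pairwise$pct_of_a[sub$pairwise$set_a == "a"], 100)
})

test_that("functional-category frequencies tally unassigned genes explicitly", {
  genes <- sprintf("g%03d", 1:400)
  assign <- data.frame(gene_id = genes[1:344],
                       category = c(rep("Ribosome", 52),
                                    rep("Translation", 292)))
  tab <- cog_frequency(genes, assign)
  expect_equal(tab$pct[tab$category == "Ribosome"], 13.0)
  expect_equal(tab$genes[tab$category == "Unassigned function"], 56L)
  expect_equal(tab$pct[tab$category == "Unassigned function"], 14.0)
  expect_equal(sum(tab$pct), 100, tolerance = 0.11)
  empty <- cog_frequency(genes, assign[0, ])
  expect_equal(empty$pct, 100)
})

test_that("synthetic proteome panels re-cluster to the known families", {
  agree <- numeric(3)
  for (s in 1:3) {
    pan <- generate_proteomes(n_genomes = 4L, n_families = 12L,
                              core_fraction = 0.75, divergence = 0.05,
                              paralogue_rate = 0.1, seed = 200L + s)
    hits <- all_vs_all_similarity(pan$proteins)
    fam <- mcl_cluster(build_graph(hits, nodes = names(pan$proteins)))
    agree[s] <- family_agreement(fam$families, pan$truth$family_of)
  }
  expect_true(all(agree >= 0.95))
})

test_that("tabular hits are filtered on E-value and given correct coverage", {
  f <- withr::local_tempfile()
  writeLines(c("q1\ts1\t80.0\t50\t10\t0\t1\t50\t1\t50\t1e-20\t200",
               "q1\ts2\t90.0\t30\t3\t0\t1\t30\t1\t30\t0.5\t80"), f)
  hits <- read_blast_tab(f, seq_lengths = c(q1 = 100L, s1 = 50L, s2 = 60L))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$coverage_query, 0.5)
  expect_equal(hits$coverage_subject, 1.0)
})
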