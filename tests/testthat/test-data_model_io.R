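test_that("gene lists normalize, deduplicate, and reject bad input", {
  f <- withr::local_tempfile(lines = c("apoe", "APOE", "APP"))
  gs <- read_gene_list(f)
  expect_s3_class(gs, "gene_set")
  expect_equal(gs$genes, c("APOE", "APP"))

  f3 <- withr::local_tempfile(lines = c("a", "b", "c"))
  expect_length(read_gene_list(f3), 3L)

  empty <- withr::local_tempfile(lines = character(0))
  expect_error(read_gene_list(empty), "empty gene list")

  multi <- withr::local_tempfile(lines = c("APOE", "APP PSEN1"))
  expect_error(read_gene_list(multi), "line 2")

  hdr <- withr::local_tempfile(lines = c("symbol", "APOE"))
  expect_equal(read_gene_list(hdr, header = TRUE)$genes, "APOE")

  expect_error(gene_set(c("A", "")), "non-empty")
  expect_error(gene_set("A", name = ""), "non-empty")
})

test_that("GMT parsing collapses duplicates and flags malformed input", {
  f <- withr::local_tempfile(lines = c("P1\tdesc\tA\tB\tC",
                                       "P2\tdesc\tA\tA\tB"))
  db <- read_gmt(f)
  expect_length(db, 2L)
  expect_length(db[[1]]$members$genes, 3L)
  expect_equal(db[[2]]$members$genes, c("A", "B"))

  short <- withr::local_tempfile(lines = c("P1\tdesc\tA", "P2\tonlydesc"))
  expect_error(read_gmt(short), "line 2")

  dup <- withr::local_tempfile(lines = c("P1\td\tA\tB", "P1\td\tC\tD"))
  expect_error(read_gmt(dup), "duplicate")
})

test_that("edge lists canonicalize: self-loops dropped, unordered pairs collapsed", {
  f <- withr::local_tempfile(lines = c("A B", "B A", "A A"))
  g <- read_edge_list(f)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::vcount(g), 2L)

  empty <- withr::local_tempfile(lines = character(0))
  g0 <- read_edge_list(empty)
  expect_equal(igraph::vcount(g0), 0L)

  bad <- withr::local_tempfile(lines = c("A\tB", "C"))
  expect_error(read_edge_list(bad), "line 2")

  sif <- withr::local_tempfile(lines = c("A pp B C", "# comment", "B pp A"))
  gs <- read_edge_list(sif, dialect = "sif")
  expect_equal(igraph::ecount(gs), 2L)  # A-B (deduped) and A-C
  expect_setequal(igraph::V(gs)$name, c("A", "B", "C"))
})

test_that("read_edge_list is invariant under row permutation and endpoint swap", {
  set.seed(11)
  syms <- sprintf("G%03d", 1:30)
  a <- sample(syms, 60, replace = TRUE)
  b <- sample(syms, 60, replace = TRUE)
  f1 <- withr::local_tempfile(lines = paste(a, b, sep = "\t"))
  perm <- sample(60)
  swap <- runif(60) < 0.5
  a2 <- ifelse(swap, b, a)[perm]
  b2 <- ifelse(swap, a, b)[perm]
  f2 <- withr::local_tempfile(lines = paste(a2, b2, sep = "\t"))
  g1 <- read_edge_list(f1)
  g2 <- read_edge_list(f2)
  expect_identical(igraph::as_edgelist(g1, names = TRUE),
                   igraph::as_edgelist(g2, names = TRUE))
  expect_identical(igraph::V(g1)$name, igraph::V(g2)$name)
})

test_that("gene list, GMT, and edge list survive write/read round trips", {
  gs <- gene_set(c("TP53", "APOE", "APP"), name = "rt")
  f <- withr::local_tempfile()
  write_gene_list(gs, f)
  expect_equal(read_gene_list(f)$genes, gs$genes)

  db <- list(pathway_record("P1", c("A", "B", "C"), display_name = "one"),
             pathway_record("P2", c("B", "D"), display_name = "two"))
  fg <- withr::local_tempfile()
  write_gmt(db, fg)
  back <- read_gmt(fg)
  expect_equal(vapply(back, `[[`, "", "pathway_id"), c("P1", "P2"))
  expect_equal(back[[2]]$members$genes, c("B", "D"))

  set.seed(7)
  g <- random_connected_graph(12, extra = 8L)
  fe <- withr::local_tempfile()
  write_edge_list(g, fe)
  g2 <- read_edge_list(fe)
  expect_identical(igraph::as_edgelist(g, names = TRUE),
                   igraph::as_edgelist(g2, names = TRUE))
})

test_that("packaged pathway table loads with valid integrity invariants", {
  tab <- load_alzgset_pathways()
  expect_true(all(tab$p_raw <= tab$p_bh))
  expect_true(all(tab$p_bh < 0.05))
  expect_true(all(lengths(tab$genes) >= 1L))
  expect_false(anyDuplicated(tab$pathway) > 0L)
  # spot checks against the printed candidate lists
  cyt <- tab$genes[[match("cytokine network", tab$pathway)]]
  expect_setequal(cyt, c("CXCL8", "IL10", "IL12A", "IL12B", "IL18",
                         "IL1A", "IL4", "IL6", "TNF"))
  cat2 <- tab$n_genes[grepl("^Catecholamine biosynthesis", tab$pathway)]
  expect_equal(cat2, 2L)
  expect_equal(
    tab$n_genes[match("Cytokines and inflammatory response", tab$pathway)],
    11L)
})

test_that("a corrupted pathway table is rejected", {
  tab <- utils::read.delim(system.file("extdata", "alzgset_pathways.tsv",
                                       package = "netpathad"))
  tab$p_bh[3] <- 0.2
  f <- withr::local_tempfile()
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_alzgset_pathways(f), "integrity")
})
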