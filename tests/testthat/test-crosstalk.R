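test_that("jaccard and overlap coefficients on elementary set configurations", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0.0)
  expect_equal(overlap_coef(c("A", "B"), c("A", "B", "C")), 1.0)  # subset
  expect_equal(overlap_coef(c("A", "B"), c("C", "D")), 0.0)
  expect_error(jaccard(character(0), character(0)), "empty")
  expect_error(overlap_coef(c("A"), character(0)), "non-empty")
})

test_that("the curated cytokine pathway pair reproduces the printed coefficients", {
  tab <- load_alzgset_pathways()
  a <- tab$genes[[match("Cytokines and inflammatory response", tab$pathway)]]
  b <- tab$genes[[match("cytokine network", tab$pathway)]]
  expect_equal(jaccard(a, b), 8 / 12)
  expect_equal(overlap_coef(a, b), 8 / 9)
})

test_that("jaccard never exceeds the overlap coefficient", {
  set.seed(17)
  pool <- sprintf("G%03d", 1:40)
  for (rep in 1:200) {
    a <- sample(pool, sample(1:20, 1))
    b <- sample(pool, sample(1:20, 1))
    expect_lte(jaccard(a, b), overlap_coef(a, b))
  }
})

test_that("crosstalk filter cascade and scores are consistent", {
  sets <- list(
    big1 = sprintf("A%02d", 1:8),
    big2 = c(sprintf("A%02d", 1:3), sprintf("B%02d", 1:5)),  # shares 3 with big1
    big3 = sprintf("C%02d", 1:7),                            # isolated
    small = c("A01", "A02", "B01")                           # < 6 genes
  )
  net <- build_crosstalk(sets, min_genes = 6, min_shared = 2)
  expect_equal(net$n_input, 4L)
  expect_equal(net$n_size_filtered, 3L)
  expect_setequal(net$nodes, c("big1", "big2"))   # big3 isolated, not a node
  expect_equal(nrow(net$edges), 1L)
  e <- net$edges
  expect_equal(e$n_shared, 3L)
  expect_equal(e$jc, 3 / 13)
  expect_equal(e$oc, 3 / 8)
  expect_equal(e$score, (e$jc + e$oc) / 2)
  expect_error(build_crosstalk(sets, min_genes = 0), ">= 1")
})

test_that("empty input yields an empty network", {
  net <- build_crosstalk(list(a = c("X1", "X2")), min_genes = 6)
  expect_length(net$nodes, 0L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("crosstalk construction is invariant under input order and matches brute force", {
  set.seed(23)
  for (rep in 1:10) {
    m <- sample(5:12, 1)
    pool <- sprintf("G%03d", 1:60)
    sets <- lapply(seq_len(m), function(i) sample(pool, sample(3:15, 1)))
    names(sets) <- sprintf("PW%02d", seq_len(m))
    net <- build_crosstalk(sets, min_genes = 4, min_shared = 2)
    perm <- sample(m)
    net2 <- build_crosstalk(sets[perm], min_genes = 4, min_shared = 2)
    expect_identical(net$edges, net2$edges)
    expect_identical(net$nodes, net2$nodes)

    # brute-force pair count over the size-filtered survivors
    keep <- sets[lengths(lapply(sets, unique)) >= 4]
    cnt <- 0L
    if (length(keep) >= 2) {
      for (i in seq_len(length(keep) - 1)) {
        for (j in seq.int(i + 1, length(keep))) {
          if (length(intersect(keep[[i]], keep[[j]])) >= 2) cnt <- cnt + 1L
        }
      }
    }
    expect_equal(nrow(net$edges), cnt)
  }
})

test_that("module detection respects connected components and is deterministic", {
  tri1 <- list(t1 = c("A", "B", "C"), t2 = c("A", "B", "D"), t3 = c("A", "C", "D"))
  tri2 <- list(s1 = c("X", "Y", "Z"), s2 = c("X", "Y", "W"), s3 = c("X", "Z", "W"))
  net <- build_crosstalk(c(tri1, tri2), min_genes = 3, min_shared = 2)
  mods <- detect_modules(net)
  expect_equal(length(unique(mods[c("t1", "t2", "t3")])), 1L)
  expect_equal(length(unique(mods[c("s1", "s2", "s3")])), 1L)
  expect_false(mods[["t1"]] == mods[["s1"]])
  expect_identical(mods, detect_modules(net))

  single <- build_crosstalk(list(a = c("A", "B"), b = c("A", "B", "C")),
                            min_genes = 2, min_shared = 2)
  expect_equal(length(unique(detect_modules(single))), 1L)
})

test_that("the curated table yields a reportable module partition", {
  net <- build_crosstalk(load_alzgset_pathways())
  mods <- detect_modules(net)
  expect_length(mods, 37L)
  expect_gte(length(unique(mods)), 2L)  # qualitative: several modules emerge
})
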