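test_that("every suffix of every sequence is represented exactly once", {
  # single one-base sequence: suffixes "A$" and "$"
  g1 <- build_gst(c(s = "A"))
  expect_equal(gst_stats(g1)$n_annotations, 2)

  # two sequences: all 5 + 4 suffixed positions retrievable by path-spelling
  seqs <- c(x = "ACGT", y = "CGT")
  g <- build_gst(seqs)
  ann <- lwords:::gst_annotations(g)
  expect_equal(nrow(ann), 9)
  for (r in seq_len(nrow(ann))) {
    s <- unclass(seqs)[[ann$seq[r]]]
    expect_identical(ann$path[r],
                     paste0(substring(s, ann$pos[r], nchar(s)), "$"))
  }
})

test_that("random sequence sets satisfy all structural invariants", {
  set.seed(1)
  seqs <- random_sequences(50, 200, seed = 1)
  g <- build_gst(seqs)
  st <- gst_stats(g)

  # leaf-annotation conservation
  expect_equal(st$n_annotations, sum(nchar(seqs) + 1))
  # path compression / distinct child symbols / annotation placement
  chk <- lwords:::gst_validate(g)
  expect_true(chk$ok)
  # node count stays linear in total (sentinel-terminated) input length
  expect_lte(st$n_nodes, 2 * st$text_length)

  # path-spelling reproduces each suffix + sentinel
  ann <- lwords:::gst_annotations(g)
  idx <- sample(nrow(ann), 200)
  for (r in idx) {
    s <- unclass(seqs)[[ann$seq[r]]]
    expect_identical(ann$path[r],
                     paste0(substring(s, ann$pos[r], nchar(s)), "$"))
  }
})

test_that("count_word matches the sliding-window brute force", {
  g <- build_gst(c(s = "AAAA"))
  expect_equal(unname(count_word(g, "AA")), 3L)

  g2 <- build_gst(c(a = "ACGTACGT", b = "TTTT"))
  expect_equal(unname(count_word(g2, "CG")), c(2L, 0L))
  expect_equal(unname(count_word(g2, "GGGG")), c(0L, 0L))

  # property: 100 random (sequence set, word) instances
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(1:4, 1)
    seqs <- stats::setNames(
      vapply(1:n, function(i) random_dna(sample(20:300, 1)), character(1)),
      paste0("s", 1:n))
    g <- build_gst(seqs)
    w <- random_dna(sample(1:8, 1))
    expect_equal(unname(count_word(g, w)),
                 vapply(unname(seqs), brute_count, integer(1), w = w, USE.NAMES = FALSE),
                 info = paste("seed-42 rep", rep, "word", w))
  }
})

test_that("count_word validates its input", {
  g <- build_gst(c(s = "ACGT"))
  expect_error(count_word(g, "ACN"), "\\{A,C,G,T\\}")
  expect_error(count_word(g, ""), "non-empty")
  gt <- build_gst(c(s = "ACGTACGT"), max_depth = 3)
  expect_error(count_word(gt, "ACGT"), "truncation depth")
})

test_that("bulk depth-L collection equals per-word queries", {
  g <- build_gst(c(s = "ACGTACGT"))
  res <- count_all_words_at_depth(g, 2)
  expect_identical(names(res), c("AC", "CG", "GT", "TA"))
  expect_equal(unname(unlist(res)), c(2L, 2L, 2L, 1L), ignore_attr = TRUE)

  g1 <- build_gst(c(s = "AAAA"))
  expect_equal(count_all_words_at_depth(g1, 1), list(A = c(s = 4L)))

  # self-consistency on a random 3-sequence set: identical to 64 count_word calls
  seqs <- random_sequences(3, 120, seed = 7)
  g3 <- build_gst(seqs)
  bulk <- count_all_words_at_depth(g3, 3)
  for (w in enumerate_words(3)) {
    expected <- count_word(g3, w)
    got <- if (w %in% names(bulk)) bulk[[w]]
           else stats::setNames(integer(3), names(seqs))
    expect_equal(got, expected, info = w)
  }
})

test_that("ambiguity codes live in the tree but are never counted", {
  g <- build_gst(c(s = "ACNGT"))
  expect_equal(gst_stats(g)$n_annotations, 6)  # N is an ordinary tree symbol
  res <- count_all_words_at_depth(g, 2)
  expect_identical(names(res), c("AC", "GT"))  # CN and NG windows skipped
  expect_equal(unname(count_word(g, "AC")), 1L)
})

test_that("depth-truncated trees answer word queries identically", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    seqs <- stats::setNames(
      vapply(1:n, function(i) random_dna(sample(50:200, 1)), character(1)),
      paste0("s", 1:n))
    L <- sample(1:5, 1)
    k <- L + sample(0:3, 1)
    full <- build_gst(seqs)
    trunc <- build_gst(seqs, max_depth = k)
    expect_equal(count_all_words_at_depth(trunc, L),
                 count_all_words_at_depth(full, L))
    # conservation and structure hold for the truncated form too
    expect_equal(gst_stats(trunc)$n_annotations, sum(nchar(seqs) + 1))
    expect_true(lwords:::gst_validate(trunc)$ok)
  }
})

test_that("degenerate input is rejected", {
  expect_error(build_gst(c(a = "")), "empty")
  expect_error(build_gst(c(a = "ACGT"), max_depth = 0), "max_depth")
})

test_that("construction scales linearly in total input length", {
  # node growth per base stays roughly constant as input doubles
  lens <- c(2000, 4000, 8000)
  ratio <- vapply(lens, function(len) {
    g <- build_gst(random_sequences(2, len, seed = len))
    gst_stats(g)$n_nodes / (2 * (len + 1))
  }, numeric(1))
  expect_lt(max(ratio), 2)           # <= 2 nodes per text symbol
  expect_lt(diff(range(ratio)), 0.2) # no superlinear drift
})
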