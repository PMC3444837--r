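test_that("word length is the smallest L with 4^L >= max sequence length", {
  sel <- select_word_length(c(a = strrep("A", 16)))
  expect_equal(sel$m, 16)
  expect_equal(sel$L, 2)      # exact power of 4: ceiling(log4(16)) = 2, not 3
  expect_equal(sel$t, 16)

  expect_equal(select_word_length(c(a = strrep("C", 100)))$L, 4)
  expect_equal(select_word_length(c(a = "A"))$L, 1)

  # monotone non-decreasing in m
  Ls <- vapply(c(3, 5, 17, 64, 65, 300, 1024, 5e4, 2e6),
               function(m) select_word_length(c(x = strrep("A", m)))$L,
               numeric(1))
  expect_true(all(diff(Ls) >= 0))
})

test_that("word enumeration is lexicographic over A < C < G < T", {
  expect_identical(enumerate_words(1), c("A", "C", "G", "T"))
  expect_identical(enumerate_words(2),
                   c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
                     "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT"))
  w3 <- enumerate_words(3)
  expect_length(w3, 64)
  expect_identical(w3[1], "AAA")
  expect_identical(w3[64], "TTT")
  expect_false(is.unsorted(w3))
  expect_error(enumerate_words(13), "guard")
})

test_that("occurrence matrix densifies suffix-tree counts over all 4^L words", {
  seqs <- c(s = "ACGTACGT")
  g <- build_gst(seqs)
  O <- occurrence_matrix(g, seqs, 2)
  expect_identical(colnames(O), enumerate_words(2))
  expect_equal(unname(O[1, ]),
               c(0L, 2L, 0L, 0L, 0L, 0L, 2L, 0L, 0L, 0L, 0L, 2L,
                 1L, 0L, 0L, 0L))
  expect_equal(sum(O), 8 - 2 + 1)

  s2 <- c(s = "AAAA")
  O2 <- occurrence_matrix(build_gst(s2), s2, 2)
  expect_equal(unname(O2[1, "AA"]), 3L)
  expect_equal(sum(O2), 3)

  # duplicated sequences give identical rows
  s3 <- c(a = "AAAA", b = "AAAA")
  O3 <- occurrence_matrix(build_gst(s3), s3, 2)
  expect_equal(unname(O3[1, ]), unname(O3[2, ]))

  # sequence shorter than L is rejected by name
  s4 <- c(longer = "ACGTACGT", shorty = "AC")
  expect_error(occurrence_matrix(build_gst(s4), s4, 3), "shorty")
})

test_that("occurrence rows equal the sliding-window oracle on random sets", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(1:4, 1)
    seqs <- stats::setNames(
      vapply(1:n, function(i) random_dna(sample(10:250, 1)), character(1)),
      paste0("s", 1:n))
    L <- sample(1:4, 1)
    if (min(nchar(seqs)) < L) next
    O <- occurrence_matrix(build_gst(seqs), seqs, L)
    for (i in 1:n) {
      expect_equal(O[i, ], oracle_counts(unclass(seqs)[[i]], L),
                   info = paste("rep", rep, "seq", i))
      # conservation of windows for pure-ACGT sequences
      expect_equal(sum(O[i, ]), nchar(seqs)[[i]] - L + 1)
    }
  }
})

test_that("frequency matrix divides rows by their sums", {
  O <- matrix(c(2L, 2L, 2L, 1L, rep(0L, 12)), nrow = 1,
              dimnames = list("s", enumerate_words(2)))
  Fm <- frequency_matrix(O)
  expect_equal(unname(Fm[1, 1:4]), c(2, 2, 2, 1) / 7)
  expect_equal(sum(Fm), 1)

  # a single nonzero entry normalizes to a unit vector
  O1 <- matrix(c(0L, 5L, 0L, 0L), 1, dimnames = list("s", enumerate_words(1)))
  expect_equal(unname(frequency_matrix(O1)[1, ]), c(0, 1, 0, 0))

  # all-zero row is an error naming the sequence
  O0 <- matrix(0L, 2, 4, dimnames = list(c("ok", "allN"), enumerate_words(1)))
  O0[1, ] <- 1L
  expect_error(frequency_matrix(O0), "allN")

  # every row sums to 1 within 1e-12 on random input
  set.seed(6)
  Or <- matrix(rpois(5 * 16, 3), 5, 16,
               dimnames = list(paste0("s", 1:5), enumerate_words(2)))
  Or[, 1] <- Or[, 1] + 1L
  expect_lt(max(abs(rowSums(frequency_matrix(Or)) - 1)), 1e-12)

  # invariant under duplication of a sequence
  seqs <- random_sequences(2, 90, seed = 8)
  dup <- sequence_set(c(unclass(seqs), dup1 = unclass(seqs)[[1]]))
  Fd <- frequency_matrix(occurrence_matrix(build_gst(dup), dup, 3))
  expect_equal(unname(Fd["dup1", ]), unname(Fd[1, ]))
})

test_that("sliding-window oracle skips ambiguous windows and handles bounds", {
  oc <- oracle_counts("ACNGT", 2)
  expect_equal(unname(oc[c("AC", "GT")]), c(1L, 1L))
  expect_equal(sum(oc), 2)  # CN and NG skipped

  oc2 <- oracle_counts("ACGT", 4)   # m = L: exactly one window
  expect_equal(sum(oc2), 1)
  expect_equal(unname(oc2["ACGT"]), 1L)

  expect_equal(sum(oracle_counts("ACG", 4)), 0)  # m < L: all zeros
})
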