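test_that("miRNA standardization anchors at the 5' end and pads with N", {
  long <- "UGAGGUAGUAGGUUGUAUAGUU"            # 22 nt
  expect_identical(standardize_mirna(long)$seq, substr(long, 1, 20))
  exact <- substr(long, 1, 20)
  expect_identical(standardize_mirna(exact)$seq, exact)
  short <- substr(long, 1, 18)
  expect_identical(standardize_mirna(short)$seq, paste0(short, "NN"))
  # case folding and T -> U
  expect_identical(standardize_mirna("tgaggtagtaggttgtatag")$seq,
                   "UGAGGUAGUAGGUUGUAUAG")
})

test_that("miRNA standardization rejects short and illegal input", {
  expect_error(standardize_mirna("ACGUA"), "seed")
  expect_error(standardize_mirna("ACGUXACGUA"), "position\\(s\\) 5: X")
  expect_error(standardize_mirna(""), "nonempty")
})

test_that("target windowing recenters to [c-25, c+25) with N padding", {
  g <- c(chr1 = paste(rep("ACGT", 100), collapse = ""))
  # length-50 interval centered at c maps onto itself
  w <- window_target(list(chrom = "chr1", start = 85, end = 135), g)
  expect_identical(w$seq, chartr("T", "U", substr(g[["chr1"]], 86, 135)))
  # [100, 120): c = 110, window [85, 135)
  w2 <- window_target(list(chrom = "chr1", start = 100, end = 120), g)
  expect_identical(w2$seq, w$seq)
  expect_equal(nchar(w2$seq), 50)
})

test_that("windows truncated at sequence boundaries are N-padded", {
  g <- c(s = paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                   collapse = ""))
  # interval [10, 20): c = 15, window [-10, 40): 10 left pads, 0 right...
  w <- window_target(list(chrom = "s", start = 10, end = 20), g)
  expect_equal(nchar(w$seq), 50)
  # direct index arithmetic: genome covers [0, 40); window is [-10, 40)
  expect_identical(substr(w$seq, 1, 10), strrep("N", 10))
  expect_identical(substr(w$seq, 11, 50),
                   chartr("T", "U", toupper(g[["s"]])))
  expect_error(window_target(list(chrom = "s", start = 100, end = 120), g),
               "off sequence")
})

test_that("minus-strand windows are reverse-complemented", {
  g <- c(s = strrep("A", 200))
  w <- window_target(list(chrom = "s", start = 100, end = 120, strand = "-"), g)
  expect_identical(w$seq, strrep("U", 50))
})

test_that("encode_pair marks exactly the Watson-Crick contacts", {
  aaa <- strrep("A", 20)
  expect_equal(sum(encode_pair(aaa, strrep("A", 50))), 0)
  expect_equal(sum(encode_pair(aaa, strrep("U", 50))), 1000)
  m <- encode_pair(aaa, strrep("U", 50))
  expect_equal(dim(m), c(20L, 50L))
  expect_true(all(m %in% 0:1))
  # alphabet-exhaustive: all 25 symbol pairs (incl N) at one position
  for (a in c("A", "C", "G", "U", "N"))
    for (b in c("A", "C", "G", "U", "N")) {
      mi <- paste0(a, strrep("N", 19))
      tg <- paste0(b, strrep("N", 49))
      expect_equal(encode_pair(mi, tg)[1, 1],
                   as.integer(paste0(a, b) %in% WC_PAIRS),
                   info = paste(a, b))
    }
  expect_error(encode_pair(strrep("A", 19), strrep("U", 50)), "20")
  expect_error(encode_pair(aaa, strrep("U", 49)), "50")
})

test_that("encode_pair agrees with the brute-force double loop", {
  set.seed(101)
  for (i in 1:200) {
    mi <- random_rna(1, 20)
    tg <- random_rna(1, 50)
    expect_equal(unclass(unname(encode_pair(mi, tg))), oracle_encode(mi, tg))
  }
})

test_that("row i depends only on miRNA[i]; column j only on target[j]", {
  set.seed(7)
  mi <- random_rna(1, 20)
  tg <- random_rna(1, 50)
  base <- unname(unclass(encode_pair(mi, tg)))
  for (i in c(1, 7, 20)) {
    mut <- mi
    old <- substr(mut, i, i)
    substr(mut, i, i) <- setdiff(c("A", "C", "G", "U"), old)[1]
    m2 <- unname(unclass(encode_pair(mut, tg)))
    expect_equal(m2[-i, ], base[-i, ])      # only row i may change
  }
  for (j in c(1, 25, 50)) {
    mut <- tg
    old <- substr(mut, j, j)
    substr(mut, j, j) <- setdiff(c("A", "C", "G", "U"), old)[1]
    m2 <- unname(unclass(encode_pair(mi, mut)))
    expect_equal(m2[, -j], base[, -j])      # only column j may change
  }
  # total 1s equals independently counted complementary pairs
  expect_equal(sum(base), sum(oracle_encode(mi, tg)))
})

test_that("encode_batch is order-preserving and matches encode_pair", {
  expect_equal(dim(encode_batch(make_pairs(character(0), character(0)))),
               c(20L, 50L, 0L))
  set.seed(11)
  pairs <- make_pairs(random_rna(30, 20), random_rna(30, 50))
  x <- encode_batch(pairs)
  for (k in seq_len(30))
    expect_equal(x[, , k],
                 unname(unclass(encode_pair(pairs$mirna_seq[k],
                                            pairs$target_seq[k]))))
  perm <- sample(30)
  xp <- encode_batch(pairs[perm, ])
  expect_equal(xp, x[, , perm])
  bad <- pairs
  bad$target_seq[17] <- strrep("U", 49)
  expect_error(encode_batch(bad), "pair 17")
})
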