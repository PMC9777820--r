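write_pair_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("load_pairs standardizes, validates and reports duplicates", {
  set.seed(21)
  df <- make_pairs(random_rna(3, 22), random_rna(3, 50))
  p <- load_pairs(write_pair_tsv(df))
  expect_equal(nrow(p), 3)
  expect_true(all(nchar(p$mirna_seq) == 20))
  expect_equal(attr(p, "duplicates"), 0)

  bad <- df
  bad$target_seq[2] <- strrep("A", 19)
  expect_error(load_pairs(write_pair_tsv(bad)), "line 3.*19")

  dup <- rbind(df, df[1, ])
  expect_message(p2 <- load_pairs(write_pair_tsv(dup)), "1 duplicated")
  expect_equal(nrow(p2), 4)
  expect_equal(attr(p2, "duplicates"), 1)
})

test_that("make_negatives meets quota and never emits a positive pair", {
  set.seed(33)
  pos <- make_pairs(random_rna(100, 20), random_rna(100, 50))
  neg <- make_negatives(pos, k = 10, rng_seed = 4)
  expect_equal(nrow(neg), 1000)
  expect_true(all(neg$label == 0))
  expect_true(all(neg$origin == "shuffled"))
  pos_ids <- paste(pos$mirna_seq, pos$target_seq)
  expect_false(any(paste(neg$mirna_seq, neg$target_seq) %in% pos_ids))
  # every negative target is a positive target; miRNAs come from the pool
  expect_true(all(neg$target_seq %in% pos$target_seq))
  expect_true(all(neg$mirna_seq %in% pos$mirna_seq))
})

test_that("negative generation is reproducible and seed-sensitive", {
  set.seed(5)
  pos <- make_pairs(random_rna(40, 20), random_rna(40, 50))
  a <- make_negatives(pos, k = 3, rng_seed = 9)
  b <- make_negatives(pos, k = 3, rng_seed = 9)
  expect_identical(a, b)
  c <- make_negatives(pos, k = 3, rng_seed = 10)
  expect_false(identical(a, c))
  expect_equal(nrow(c), nrow(a))              # same ratio statistics
  expect_equal(table(c$label), table(a$label))
})

test_that("a single-miRNA pool is rejected", {
  pos <- make_pairs(rep(strrep("A", 20), 3), random_rna(3, 50))
  expect_error(make_negatives(pos, k = 1), "2 distinct")
})

test_that("assemble_ratio yields exact prevalence and deterministic shuffle", {
  set.seed(8)
  pos <- make_pairs(random_rna(30, 20), random_rna(30, 50))
  neg <- make_negatives(pos, k = 20, rng_seed = 2)
  for (k in c(1, 10, 20)) {
    ds <- assemble_ratio(pos, neg, k = k, split_tag = "train", rng_seed = 3)
    expect_equal(nrow(ds), 30 * (k + 1))
    expect_equal(sum(ds$label == 1) / nrow(ds), 1 / (1 + k))
    expect_equal(sum(ds$label == 0), k * 30)
  }
  d1 <- assemble_ratio(pos, neg, k = 5, rng_seed = 7)
  d2 <- assemble_ratio(pos, neg, k = 5, rng_seed = 7)
  expect_identical(d1, d2)
  expect_error(assemble_ratio(pos, neg[1:10, ], k = 1), "insufficient|only")
})

test_that("split_pairs partitions exhaustively and deterministically", {
  set.seed(13)
  pairs <- make_pairs(random_rna(100, 20), random_rna(100, 50))
  sp <- split_pairs(pairs, c(0.8, 0.1, 0.1), rng_seed = 1)
  expect_equal(vapply(sp, nrow, numeric(1)),
               c(train = 80, validation = 10, test = 10))
  back <- rbind(sp$train, sp$validation, sp$test)
  expect_setequal(paste(back$mirna_seq, back$target_seq),
                  paste(pairs$mirna_seq, pairs$target_seq))
  sp2 <- split_pairs(pairs, c(0.8, 0.1, 0.1), rng_seed = 1)
  expect_identical(sp, sp2)
  expect_error(split_pairs(pairs[0, ], c(0.8, 0.1, 0.1)), "empty")
  expect_error(split_pairs(pairs, c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("dedup_across_splits keeps identical sequence pairs together", {
  set.seed(17)
  base <- make_pairs(random_rna(20, 20), random_rna(20, 50))
  pairs <- rbind(base, base, base)             # every pair in triplicate
  sp <- split_pairs(pairs, c(0.6, 0.2, 0.2), rng_seed = 2,
                    dedup_across_splits = TRUE)
  key <- function(d) unique(paste(d$mirna_seq, d$target_seq))
  expect_length(intersect(key(sp$train), key(sp$validation)), 0)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_length(intersect(key(sp$validation), key(sp$test)), 0)
})

test_that("pair tables round-trip through TSV with manifests", {
  set.seed(19)
  pos <- make_pairs(random_rna(10, 20), random_rna(10, 50))
  neg <- make_negatives(pos, k = 1, rng_seed = 1)
  ds <- assemble_ratio(pos, neg, k = 1, rng_seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_pairs(ds, path)
  expect_true(file.exists(paste0(path, ".manifest")))
  back <- load_pairs(path)
  expect_equal(back$mirna_seq, ds$mirna_seq)
  expect_equal(back$label, ds$label)
})
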