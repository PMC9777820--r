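# Committee members in these tests are plain scoring functions; the
# wiring to trained networks is exercised in the acceptance suite.

const_scorer <- function(v) function(pairs) rep(v, nrow(pairs))

test_that("instance hardness is the committee-mean misclassification rate", {
  set.seed(31)
  neg <- make_pairs(random_rna(4, 20), random_rna(4, 50), labels = 0)
  ih <- estimate_instance_hardness(neg, list(const_scorer(0)))
  expect_equal(ih$ih, rep(0, 4))
  ih <- estimate_instance_hardness(neg, list(const_scorer(1)))
  expect_equal(ih$ih, rep(1, 4))
  ih <- estimate_instance_hardness(neg, list(const_scorer(0.2),
                                             const_scorer(0.4),
                                             const_scorer(0.6)))
  expect_equal(ih$ih, rep(0.4, 4))
  expect_equal(ih$committee_size, rep(3L, 4))
  # a positive's hardness is 1 - mean predicted probability
  pos <- make_pairs(random_rna(2, 20), random_rna(2, 50), labels = 1)
  ih <- estimate_instance_hardness(pos, list(const_scorer(0.9)))
  expect_equal(ih$ih, rep(0.1, 2), tolerance = 1e-12)
})

test_that("scorers emitting values outside [0, 1] are rejected", {
  neg <- make_pairs(random_rna(2, 20), random_rna(2, 50), labels = 0)
  expect_error(estimate_instance_hardness(neg, list(const_scorer(1.2))),
               "outside")
  expect_error(estimate_instance_hardness(neg, list()), "nonempty")
})

test_that("smoothing policy enforces range, endpoints and monotonicity", {
  pol <- smoothing_policy()
  expect_equal(pol$map(0), 0)
  expect_equal(pol$map(1), 0.5)
  expect_equal(pol$map(0.6), 0.3)
  expect_error(smoothing_policy(map = function(ih) ih), "0.5")
  expect_error(smoothing_policy(map = function(ih) 0.5 - ih / 2), "0 to 0")
  expect_error(smoothing_policy(map = function(ih) abs(ih - 0.5) ),
               "non-decreasing|0 to 0")
})

test_that("smooth_labels maps negative labels through IH, never flipping", {
  set.seed(37)
  pairs <- make_pairs(random_rna(6, 20), random_rna(6, 50),
                      labels = c(1, 1, 0, 0, 0, 0))
  ihv <- c(0.2, 0.9, 0, 0.6, 1, 0.31)
  ih <- structure(data.frame(pair_id = paste(pairs$mirna_seq,
                                             pairs$target_seq, sep = ":"),
                             ih = ihv, committee_size = 1L),
                  class = c("ih_table", "data.frame"))
  sm <- smooth_labels(pairs, ih)
  expect_equal(sm$label[1:2], c(1, 1))          # positives untouched
  expect_equal(sm$label[3:6], c(0, 0.3, 0.5, 0.155))
  expect_true(all(sm$label[3:6] <= 0.5))
  # monotonicity: higher IH never yields a lower smoothed label
  ord <- order(ihv[3:6])
  expect_true(all(diff(sm$label[3:6][ord]) >= 0))
})

test_that("select_hard_negatives keeps positives plus the hardest negatives", {
  set.seed(41)
  pos <- make_pairs(random_rna(10, 20), random_rna(10, 50), labels = 1)
  neg <- make_pairs(random_rna(1000, 20), random_rna(1000, 50), labels = 0)
  all_pairs <- rbind(pos, neg)
  ihv <- c(rep(0, 10), stats::runif(1000))
  ih <- structure(data.frame(pair_id = paste(all_pairs$mirna_seq,
                                             all_pairs$target_seq, sep = ":"),
                             ih = ihv, committee_size = 1L),
                  class = c("ih_table", "data.frame"))
  out <- select_hard_negatives(all_pairs, ih, target_ratio = 20)
  expect_equal(sum(out$label == 1), 10)
  expect_equal(sum(out$label == 0), 200)
  kept <- ih$ih[match(paste(out$mirna_seq[out$label == 0],
                            out$target_seq[out$label == 0], sep = ":"),
                      ih$pair_id)]
  expect_equal(sort(kept, decreasing = TRUE),
               sort(ihv[-(1:10)], decreasing = TRUE)[1:200])

  ident <- select_hard_negatives(all_pairs, ih, keep_fraction = 1)
  expect_equal(sum(ident$label == 0), 1000)
  expect_error(select_hard_negatives(all_pairs, ih, target_ratio = 200),
               "only 1000")
})

test_that("ties at the selection cutoff break deterministically", {
  set.seed(43)
  pos <- make_pairs(random_rna(2, 20), random_rna(2, 50), labels = 1)
  neg <- make_pairs(random_rna(30, 20), random_rna(30, 50), labels = 0)
  all_pairs <- rbind(pos, neg)
  ih <- structure(data.frame(pair_id = paste(all_pairs$mirna_seq,
                                             all_pairs$target_seq, sep = ":"),
                             ih = c(0, 0, rep(0.5, 30)),   # all negatives tied
                             committee_size = 1L),
                  class = c("ih_table", "data.frame"))
  a <- select_hard_negatives(all_pairs, ih, target_ratio = 5)
  b <- select_hard_negatives(all_pairs[sample(32), ], ih, target_ratio = 5)
  key <- function(d) paste(d$mirna_seq, d$target_seq)[d$label == 0]
  expect_identical(sort(key(a)), sort(key(b)))
  # tie-break is by ascending pair id
  ids <- sort(ih$pair_id[3:32])[1:10]
  expect_setequal(paste(a$mirna_seq, a$target_seq, sep = ":")[a$label == 0],
                  ids)
})

test_that("IH tables round-trip through TSV", {
  neg <- make_pairs(random_rna(3, 20), random_rna(3, 50), labels = 0)
  ih <- estimate_instance_hardness(neg, list(const_scorer(0.25)))
  path <- tempfile(fileext = ".tsv")
  write_ih_table(ih, path)
  back <- read_ih_table(path)
  expect_equal(back$ih, ih$ih)
  expect_equal(back$pair_id, ih$pair_id)
})

test_that("out-of-fold hardness is defined, bounded and reproducible", {
  set.seed(47)
  ds <- gen_dataset(synth_spec(n_pos = 30, rng_seed = 12), k = 3)
  tiny <- function() build_cnn(cnn_config("desk", conv_blocks = 2,
                                          filters = c(4, 4), kernel = c(3, 3),
                                          pool_blocks = 1:2, dense_units = 8))
  ih <- estimate_instance_hardness_oof(ds, committee_size = 3,
                                       scorer_factory = tiny, seed = 2,
                                       epochs = 1, batch_size = 32)
  expect_equal(nrow(ih), nrow(ds))
  expect_true(all(ih$ih >= 0 & ih$ih <= 1))
  expect_length(attr(ih, "committee"), 3)
  expect_length(attr(ih, "fold"), nrow(ds))
  ih2 <- estimate_instance_hardness_oof(ds, committee_size = 3,
                                        scorer_factory = tiny, seed = 2,
                                        epochs = 1, batch_size = 32)
  expect_equal(ih$ih, ih2$ih)
})
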