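# Labeled pair tables, shuffled negatives, ratio-controlled datasets, splits.
#
# A pair collection is a plain data.frame with columns
#   mirna_id, mirna_seq (20 nt), target_id, target_seq (50 nt),
#   label (in [0,0.5] u {1}), origin ("experimental"|"shuffled"|"synthetic")
# and optionally `mechanism` (synthetic provenance).  A ratio dataset is the
# same data.frame with class "ratio_dataset" and attributes `ratio`,
# `rng_seed`, `split_tag`.

PAIR_COLUMNS <- c("mirna_id", "mirna_seq", "target_id", "target_seq",
                  "label", "origin")

new_ratio_dataset <- function(pairs, ratio, rng_seed, split_tag) {
  structure(pairs, ratio = ratio, rng_seed = rng_seed, split_tag = split_tag,
            class = c("ratio_dataset", "data.frame"))
}

#' Load a labeled miRNA:target pair table from TSV
#'
#' Expects a tab-separated file with a header containing at least
#' `mirna_seq` and `target_seq` (plus optional `mirna_id`, `target_id`,
#' `label`, `origin`). Every miRNA is standardized to 20 nt via
#' [standardize_mirna()]; targets must already be 50-nt windows (rows that
#' are not are rejected, with their line numbers). Duplicate
#' (miRNA, target) records are retained but counted in the
#' `duplicates` attribute and reported via a message.
#'
#' @param path TSV file path.
#' @return data.frame of labeled pairs (see module header for columns),
#'   with attribute `duplicates` = number of extra copies observed.
#' @export
load_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("mirna_seq", "target_seq") %in% names(tab)))
    stop("pair table must have 'mirna_seq' and 'target_seq' columns",
         call. = FALSE)
  n <- nrow(tab)
  mirna_id <- if ("mirna_id" %in% names(tab)) tab$mirna_id else
    sprintf("mir_%d", seq_len(n))
  target_id <- if ("target_id" %in% names(tab)) tab$target_id else
    sprintf("site_%d", seq_len(n))
  label <- if ("label" %in% names(tab)) as.numeric(tab$label) else rep(1, n)
  origin <- if ("origin" %in% names(tab)) tab$origin else
    rep("experimental", n)

  bad <- character(0)
  mirna_seq <- character(n)
  target_seq <- character(n)
  for (k in seq_len(n)) {
    line <- k + 1L                     # header is line 1
    m <- tryCatch(standardize_mirna(tab$mirna_seq[k])$seq, error = identity)
    if (inherits(m, "condition")) {
      bad <- c(bad, sprintf("line %d: %s", line, conditionMessage(m)))
      next
    }
    t <- tryCatch(normalize_rna(tab$target_seq[k], "target"), error = identity)
    if (inherits(t, "condition")) {
      bad <- c(bad, sprintf("line %d: %s", line, conditionMessage(t)))
      next
    }
    if (nchar(t) != 50L) {
      bad <- c(bad, sprintf("line %d: target is %d nt, expected 50",
                            line, nchar(t)))
      next
    }
    mirna_seq[k] <- m
    target_seq[k] <- t
  }
  if (length(bad))
    stop(paste(c("malformed pair table rows:", bad), collapse = "\n  "),
         call. = FALSE)
  if (any(!(label %in% 1 | (label >= 0 & label <= 0.5))))
    stop("labels must lie in [0, 0.5] or equal 1", call. = FALSE)

  out <- data.frame(mirna_id = mirna_id, mirna_seq = mirna_seq,
                    target_id = target_id, target_seq = target_seq,
                    label = label, origin = origin,
                    stringsAsFactors = FALSE)
  dup <- sum(duplicated(pair_id(out)))
  if (dup > 0)
    message(sprintf("load_pairs: %d duplicated (miRNA, target) record(s) retained",
                    dup))
  attr(out, "duplicates") <- dup
  out
}

#' Write a pair table (or ratio dataset) to TSV
#'
#' @param pairs labeled pair data.frame.
#' @param path output TSV path.
#' @param manifest optionally also write `<path>.manifest` recording ratio,
#'   seed, class counts and an md5 checksum of the TSV.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, manifest = inherits(pairs, "ratio_dataset")) {
  keep <- intersect(c(PAIR_COLUMNS, "mechanism"), names(pairs))
  utils::write.table(as.data.frame(pairs)[, keep], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (manifest) {
    lab <- pairs$label
    write_manifest(list(
      ratio = if (is.null(attr(pairs, "ratio"))) NA else attr(pairs, "ratio"),
      rng_seed = if (is.null(attr(pairs, "rng_seed"))) NA else attr(pairs, "rng_seed"),
      split_tag = if (is.null(attr(pairs, "split_tag"))) NA else attr(pairs, "split_tag"),
      n_total = nrow(pairs),
      n_positive = sum(lab == 1),
      n_negative = sum(lab != 1),
      md5 = unname(tools::md5sum(path))
    ), paste0(path, ".manifest"))
  }
  invisible(path)
}

#' Generate shuffled negatives for a set of positive pairs
#'
#' Negatives are built the way CLASH-style studies randomize their
#' positives: each positive target sequence is re-paired with `k` miRNAs
#' drawn from the pool of distinct miRNAs occurring in the positive set,
#' excluding any miRNA that forms a positive pair with that target. Per
#' target, miRNAs are drawn without replacement until the admissible pool is
#' exhausted, then with replacement. The emitted set never contains a
#' (miRNA, target) sequence pair present in the positives.
#'
#' @param positives positive pair data.frame (labels all 1).
#' @param k negatives per positive (>= 1).
#' @param rng_seed integer seed; the construction is fully reproducible.
#' @return data.frame of `k * nrow(positives)` negative pairs
#'   (label 0, origin "shuffled").
#' @export
make_negatives <- function(positives, k, rng_seed = 1L) {
  stopifnot(nrow(positives) > 0, k >= 1)
  k <- as.integer(k)
  pool <- unique(positives$mirna_seq)
  if (length(pool) < 2L)
    stop("need at least 2 distinct miRNAs to form non-positive pairings",
         call. = FALSE)
  pos_ids <- unique(pair_id(positives))
  mirna_name <- positives$mirna_id[!duplicated(positives$mirna_seq)]
  names(mirna_name) <- positives$mirna_seq[!duplicated(positives$mirna_seq)]

  with_seed(rng_seed, {
    res <- vector("list", nrow(positives))
    for (i in seq_len(nrow(positives))) {
      tgt <- positives$target_seq[i]
      banned <- positives$mirna_seq[positives$target_seq == tgt]
      allowed <- setdiff(pool, banned)
      if (length(allowed) == 0L)
        stop(sprintf(
          "target '%s' pairs positively with every miRNA in the pool; attainable negatives for it: 0",
          positives$target_id[i]), call. = FALSE)
      if (k <= length(allowed)) {
        draw <- sample(allowed, k)
      } else {
        draw <- c(sample(allowed, length(allowed)),
                  sample(allowed, k - length(allowed), replace = TRUE))
      }
      res[[i]] <- data.frame(
        mirna_id = unname(mirna_name[draw]),
        mirna_seq = draw,
        target_id = positives$target_id[i],
        target_seq = tgt,
        label = 0, origin = "shuffled", stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    if ("mechanism" %in% names(positives)) out$mechanism <- "none"
    rownames(out) <- NULL
    stopifnot(!any(pair_id(out) %in% pos_ids))
    out
  })
}

#' Assemble a ratio-controlled dataset
#'
#' Combines positives with exactly `k` negatives per positive and shuffles
#' the records deterministically. The positive-class prevalence of the
#' result is exactly `1 / (1 + k)`.
#'
#' @param positives,negatives pair data.frames.
#' @param k declared positives:negatives ratio 1:k.
#' @param split_tag one of "train", "validation", "test".
#' @param rng_seed seed controlling negative subsampling and the shuffle.
#' @return a `ratio_dataset`.
#' @export
assemble_ratio <- function(positives, negatives, k,
                           split_tag = c("train", "validation", "test"),
                           rng_seed = 1L) {
  split_tag <- match.arg(split_tag)
  k <- as.integer(k)
  need <- k * nrow(positives)
  if (nrow(negatives) < need)
    stop(sprintf("need %d negatives for ratio 1:%d but only %d supplied",
                 need, k, nrow(negatives)), call. = FALSE)
  cols <- intersect(c(PAIR_COLUMNS, "mechanism"), names(positives))
  cols <- intersect(cols, names(negatives))
  with_seed(rng_seed, {
    keep <- if (nrow(negatives) == need) seq_len(need) else
      sample(nrow(negatives), need)
    out <- rbind(as.data.frame(positives)[, cols],
                 as.data.frame(negatives)[keep, cols])
    out <- out[sample(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    new_ratio_dataset(out, ratio = k, rng_seed = rng_seed,
                      split_tag = split_tag)
  })
}

#' Split pairs into train/validation/test partitions
#'
#' Deterministic disjoint, exhaustive partition under `rng_seed`. Splitting
#' is by record; with `dedup_across_splits = TRUE`, identical
#' (miRNA, target) sequence pairs are kept within a single partition. With
#' `group_by`, whole groups (e.g. all sites of one miRNA) stay together.
#'
#' @param pairs pair data.frame.
#' @param fractions length-3 numeric summing to 1 (train, validation, test).
#' @param rng_seed integer seed.
#' @param dedup_across_splits keep duplicate sequence pairs in one split.
#' @param group_by optional column name to split by group instead of by row.
#' @return named list of data.frames `train`, `validation`, `test`.
#' @export
split_pairs <- function(pairs, fractions = c(0.8, 0.1, 0.1), rng_seed = 1L,
                        dedup_across_splits = FALSE, group_by = NULL) {
  if (nrow(pairs) == 0L) stop("cannot split an empty pair set", call. = FALSE)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must be 3 values summing to 1", call. = FALSE)

  key <- if (!is.null(group_by)) pairs[[group_by]]
         else if (dedup_across_splits) pair_id(pairs)
         else seq_len(nrow(pairs))
  groups <- unique(key)
  ng <- length(groups)
  n_train <- floor(fractions[1] * ng)
  n_val <- floor(fractions[2] * ng)
  # remainder goes to test, then rebalanced so rounding never empties test
  with_seed(rng_seed, {
    ord <- sample(groups)
    assignment <- rep("test", ng)
    assignment[seq_len(n_train)] <- "train"
    if (n_val > 0) assignment[n_train + seq_len(n_val)] <- "validation"
    names(assignment) <- ord
    tag <- assignment[as.character(key)]
    if (is.null(group_by) && !dedup_across_splits)
      tag <- assignment[as.character(seq_len(nrow(pairs)))]
    out <- list(train = pairs[tag == "train", , drop = FALSE],
                validation = pairs[tag == "validation", , drop = FALSE],
                test = pairs[tag == "test", , drop = FALSE])
    lapply(out, function(d) { rownames(d) <- NULL; d })
  })
}

#' @export
print.ratio_dataset <- function(x, ...) {
  lab <- x$label
  cat(sprintf("ratio dataset (%s): %d pairs, 1:%s positives:negatives, seed %s\n",
              attr(x, "split_tag"), nrow(x), attr(x, "ratio"),
              attr(x, "rng_seed")))
  cat(sprintf("  positives: %d  negatives: %d (of which %d soft-labeled)\n",
              sum(lab == 1), sum(lab != 1), sum(lab > 0 & lab != 1)))
  invisible(x)
}
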