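# Instance-hardness estimation and label smoothing for the negative class.
#
# Instance hardness (IH) is the estimated probability that a model — here a
# committee of scorers — misclassifies a sample.  Hard negatives (samples a
# scorer keeps calling positive) get soft labels in (0, 0.5] instead of a
# hard 0, so the model is forced to be unsure on them rather than taught a
# flipped label; easy negatives can additionally be discarded to rebalance
# a skewed ratio.

#' Estimate instance hardness from a committee of scorers
#'
#' For a negative sample, IH is the mean predicted positive-class
#' probability over the committee (how strongly it is mistaken for a
#' positive); for a positive sample, the mean of one minus that
#' probability. Committee members may be `trained_scorer` objects or plain
#' functions mapping a pair data.frame to scores in [0, 1]; any member
#' emitting a score outside [0, 1] is rejected.
#'
#' @param samples labeled pair data.frame.
#' @param committee nonempty list of scorers.
#' @return data.frame of class `ih_table`: `pair_id`, `ih`,
#'   `committee_size`, aligned with `samples` rows.
#' @export
estimate_instance_hardness <- function(samples, committee) {
  if (!length(committee)) stop("committee must be nonempty", call. = FALSE)
  if (!is.list(committee)) committee <- list(committee)
  scores <- vapply(committee, function(m) scorer_predict(m, samples),
                   numeric(nrow(samples)))
  scores <- matrix(scores, nrow = nrow(samples))
  mean_pos <- rowMeans(scores)
  is_pos <- samples$label == 1
  ih <- ifelse(is_pos, 1 - mean_pos, mean_pos)
  structure(data.frame(pair_id = pair_id(samples), ih = ih,
                       committee_size = length(committee),
                       stringsAsFactors = FALSE),
            class = c("ih_table", "data.frame"))
}

#' Out-of-fold instance hardness for a training pool
#'
#' Trains a committee of balanced (1:1) CNN scorers and scores every sample
#' only with members that never saw it, avoiding optimistic hardness
#' estimates. Samples are partitioned into `committee_size` folds; member
#' `m` is trained on a balanced draw (all positives plus an equal number of
#' negatives) from every fold except folds `m` and `m + 1` (cyclically), so
#' each sample is held out from exactly two members, whose predictions are
#' averaged into its IH.
#'
#' @param samples labeled pair data.frame (hard labels).
#' @param committee_size number of committee members / folds (default 5).
#' @param scorer_factory function() returning an untrained scorer; default
#'   a desk-profile CNN.
#' @param seed integer seed for fold assignment and member training.
#' @param epochs,batch_size training schedule per member; the defaults
#'   (15 epochs, batch 32) suit the small balanced member sets.
#' @return an `ih_table` aligned with `samples`, plus attribute
#'   `committee` (the trained members) and `fold` (fold assignment).
#' @export
estimate_instance_hardness_oof <- function(samples, committee_size = 5L,
                                           scorer_factory = NULL,
                                           seed = 1L, epochs = 15L,
                                           batch_size = 32L) {
  stopifnot(committee_size >= 3L)
  if (is.null(scorer_factory))
    scorer_factory <- function() build_cnn(cnn_config("desk"))
  n <- nrow(samples)
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(committee_size), n))
    member_seeds <- sample.int(.Machine$integer.max, committee_size)
    excluded <- lapply(seq_len(committee_size), function(m)
      c(m, m %% committee_size + 1L))
    members <- vector("list", committee_size)
    for (m in seq_len(committee_size)) {
      sub <- samples[!(fold %in% excluded[[m]]), , drop = FALSE]
      pos <- sub[sub$label == 1, , drop = FALSE]
      neg <- sub[sub$label != 1, , drop = FALSE]
      if (nrow(pos) == 0L || nrow(neg) == 0L)
        stop(sprintf("training folds for member %d lack one of the classes", m),
             call. = FALSE)
      take <- min(nrow(pos), nrow(neg))
      train <- rbind(pos[sample(nrow(pos), take), , drop = FALSE],
                     neg[sample(nrow(neg), take), , drop = FALSE])
      train$label <- as.numeric(train$label == 1)
      members[[m]] <- train_scorer(scorer_factory(), train,
                                   seed = member_seeds[m], epochs = epochs,
                                   batch_size = batch_size)
    }
    # member m never saw folds m and m+1: score each sample with the two
    # members blind to its fold
    voters <- lapply(seq_len(committee_size), function(f)
      which(vapply(excluded, function(e) f %in% e, logical(1))))
    preds <- vapply(members, function(mm) predict(mm, samples), numeric(n))
    preds <- matrix(preds, nrow = n)
    mean_pos <- vapply(seq_len(n), function(i)
      mean(preds[i, voters[[fold[i]]]]), numeric(1))
    ih <- ifelse(samples$label == 1, 1 - mean_pos, mean_pos)
    out <- structure(data.frame(pair_id = pair_id(samples), ih = ih,
                                committee_size = committee_size,
                                stringsAsFactors = FALSE),
                     class = c("ih_table", "data.frame"))
    attr(out, "committee") <- members
    attr(out, "fold") <- fold
    out
  })
}

#' Label-smoothing policy
#'
#' A monotone map from instance hardness in [0, 1] to soft labels in
#' [0, 0.5]: `map(0) = 0`, `map(1) = 0.5`, never exceeding 0.5, so smoothed
#' labels are never flipped — the hardest samples become maximally
#' uncertain, not positive. The default map is linear, `ih / 2`. By default
#' the policy applies to negatives only (the majority class the smoothing
#' is meant to tame).
#'
#' @param map monotone function [0,1] -> [0,0.5] (default `ih / 2`).
#' @param applies_to `"negatives"` or `"both"`.
#' @return list of class `smoothing_policy`.
#' @export
smoothing_policy <- function(map = function(ih) ih / 2,
                             applies_to = c("negatives", "both")) {
  applies_to <- match.arg(applies_to)
  grid <- seq(0, 1, by = 1 / 64)
  v <- vapply(grid, map, numeric(1))
  if (abs(v[1]) > 1e-12 || abs(v[length(v)] - 0.5) > 1e-12)
    stop("smoothing map must send 0 to 0 and 1 to 0.5", call. = FALSE)
  if (any(diff(v) < -1e-12)) stop("smoothing map must be non-decreasing",
                                  call. = FALSE)
  if (any(v < -1e-12 | v > 0.5 + 1e-12))
    stop("smoothing map must stay within [0, 0.5]", call. = FALSE)
  structure(list(map = map, applies_to = applies_to),
            class = "smoothing_policy")
}

#' Smooth labels by instance hardness
#'
#' Replaces the hard 0 label of each selected negative with
#' `policy$map(IH)`; positives (and unselected samples) are unchanged
#' unless `applies_to = "both"`, in which case positives are mapped to
#' `1 - map(IH)` (still never crossing 0.5).
#'
#' @param samples labeled pair data.frame.
#' @param ih_table `ih_table` covering every selected sample (matched by
#'   pair id).
#' @param policy a [smoothing_policy()].
#' @return `samples` with updated `label` column.
#' @export
smooth_labels <- function(samples, ih_table, policy = smoothing_policy()) {
  ids <- pair_id(samples)
  idx <- match(ids, ih_table$pair_id)
  sel_neg <- samples$label != 1
  need <- if (policy$applies_to == "both") seq_len(nrow(samples)) else which(sel_neg)
  if (anyNA(idx[need]))
    stop("instance hardness undefined for some selected sample(s)",
         call. = FALSE)
  ih <- ih_table$ih[idx]
  if (any(!is.na(ih) & (ih < 0 | ih > 1)))
    stop("IH values must lie in [0, 1]", call. = FALSE)
  out <- samples
  sm <- vapply(ih[sel_neg], policy$map, numeric(1))
  out$label[sel_neg] <- pmin(sm, 0.5)
  if (policy$applies_to == "both") {
    pos <- which(samples$label == 1)
    out$label[pos] <- 1 - pmin(vapply(ih[pos], policy$map, numeric(1)), 0.5)
  }
  out
}

#' Keep the hardest negatives to rebalance a skewed ratio
#'
#' Retains all positives and the negatives with the highest instance
#' hardness — the discriminative, false-positive-prone samples — until the
#' requested ratio (or fraction of negatives) is met. Ties at the cutoff
#' are broken deterministically by (IH descending, pair id ascending).
#'
#' @param samples labeled pair data.frame.
#' @param ih_table `ih_table` covering all negatives.
#' @param target_ratio keep `target_ratio` negatives per positive
#'   (mutually exclusive with `keep_fraction`).
#' @param keep_fraction fraction of negatives to keep.
#' @return filtered pair data.frame (positives first, then kept negatives
#'   in hardness order).
#' @export
select_hard_negatives <- function(samples, ih_table, target_ratio = NULL,
                                  keep_fraction = NULL) {
  if (is.null(target_ratio) == is.null(keep_fraction))
    stop("give exactly one of target_ratio or keep_fraction", call. = FALSE)
  pos <- samples[samples$label == 1, , drop = FALSE]
  neg <- samples[samples$label != 1, , drop = FALSE]
  n_keep <- if (!is.null(target_ratio)) {
    as.integer(round(target_ratio * nrow(pos)))
  } else {
    as.integer(round(keep_fraction * nrow(neg)))
  }
  if (n_keep > nrow(neg))
    stop(sprintf("requested %d negatives but only %d available",
                 n_keep, nrow(neg)), call. = FALSE)
  ids <- pair_id(neg)
  idx <- match(ids, ih_table$pair_id)
  if (anyNA(idx))
    stop("instance hardness undefined for some negative(s)", call. = FALSE)
  ih <- ih_table$ih[idx]
  ord <- order(-ih, ids)
  out <- rbind(pos, neg[ord[seq_len(n_keep)], , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write / read IH tables as TSV
#'
#' @param ih_table an `ih_table`.
#' @param path TSV path.
#' @return the path (write) or the table (read).
#' @export
write_ih_table <- function(ih_table, path) {
  utils::write.table(as.data.frame(ih_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ih_table
#' @export
read_ih_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(tab, class = c("ih_table", "data.frame"))
}
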