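# Seed-match heuristic and free-energy score normalization baselines.

#' Canonical seed match (miRNA positions 2-7)
#'
#' The classic heuristic for canonical miRNA target sites: does the reverse
#' complement of the miRNA's 2-7 hexamer (1-based, 5'-anchored) occur as a
#' contiguous substring of the target? The call is strictly binary — no
#' score — but all (possibly overlapping) match offsets are reported.
#' Complementarity is Watson-Crick only, consistent with [encode_pair()].
#'
#' @param mirna a `mirna_seq` or >= 7-nt RNA string.
#' @param target a `target_seq` or RNA string.
#' @return list of class `seed_call`: `match` (logical),
#'   `match_offsets` (0-based target offsets, integer vector), and
#'   `undefined` (TRUE when the seed region contains `N`, in which case
#'   `match` is FALSE and a warning is raised).
#' @examples
#' sc <- seed_match("AGAGGUAG", strrep("C", 20))
#' sc$match
#' @export
seed_match <- function(mirna, target) {
  ms <- if (inherits(mirna, "mirna_seq")) mirna$seq else
    normalize_rna(as.character(mirna), "miRNA")
  ts <- if (inherits(target, "target_seq")) target$seq else
    normalize_rna(as.character(target), "target")
  if (nchar(ms) < 7L) stop("miRNA shorter than 7 nt has no 2-7 seed",
                           call. = FALSE)
  seed <- substr(ms, 2L, 7L)
  if (grepl("N", seed, fixed = TRUE)) {
    warning("seed region contains N; seed call undefined (reported as no match)")
    return(structure(list(match = FALSE, match_offsets = integer(0),
                          undefined = TRUE), class = "seed_call"))
  }
  probe <- rna_revcomp(seed)
  hits <- gregexpr(paste0("(?=", probe, ")"), ts, perl = TRUE)[[1]]
  offsets <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  structure(list(match = length(offsets) > 0L, match_offsets = offsets,
                 undefined = FALSE), class = "seed_call")
}

#' Seed-heuristic scores for a table of pairs
#'
#' Vectorized wrapper over [seed_match()]: returns 1 for pairs with a
#' canonical 2-7 seed complement in the target, 0 otherwise.
#'
#' @param pairs pair data.frame with `mirna_seq` and `target_seq`.
#' @return numeric vector of 0/1 scores, one per row.
#' @export
seed_classifier <- function(pairs) {
  if (nrow(pairs) == 0L) return(numeric(0))
  vapply(seq_len(nrow(pairs)), function(k) {
    as.numeric(seed_match(pairs$mirna_seq[k], pairs$target_seq[k])$match)
  }, numeric(1))
}

#' Min-max normalize free-energy scores to [0, 1]
#'
#' Minimum-free-energy values (kcal/mol, more negative = more stable) are
#' mapped linearly so the most favorable (lowest) energy scores 1 and the
#' least favorable scores 0: `score = (max - raw) / (max - min)`. If all
#' raw values are identical the range is degenerate; every score is then
#' defined as 0.5 and a warning is raised.
#'
#' @param raw numeric vector of finite free-energy values.
#' @return data.frame with columns `raw` and `score`, class
#'   `normalized_scores`.
#' @examples
#' normalize_energies(c(-10, -7.5, -5))$score # 1.0 0.5 0.0
#' @export
normalize_energies <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop("energies must be finite numbers", call. = FALSE)
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("degenerate energy range: all raw values identical; scores set to 0.5")
    score <- rep(0.5, length(raw))
  } else {
    score <- (rng[2] - raw) / (rng[2] - rng[1])
  }
  structure(data.frame(raw = raw, score = score),
            class = c("normalized_scores", "data.frame"))
}

#' Import scores produced by an external tool
#'
#' Adapter for precomputed score tables from hybridization/co-folding tools
#' (e.g. RNAhybrid, RNAcofold) or p-value-based tools (e.g. RNA22). The tool
#' output is a TSV with columns `mirna_id`, `target_id`, `value`; a missing
#' value marker (empty, `NA` or `.`) means the tool reported no interaction
#' for that pair, which receives the worst score (0 after normalization).
#' `type = "energy"` treats values as free energies (lower = better);
#' `type = "pvalue"` first converts each p-value to `1 - p` (so small
#' p-values score high) and then min-max normalizes.
#'
#' @param path tool-output TSV.
#' @param pairs pair data.frame the scores must cover; output rows align
#'   with `pairs` rows via (`mirna_id`, `target_id`).
#' @param type `"energy"` or `"pvalue"`.
#' @return data.frame `mirna_id`, `target_id`, `raw`, `score` aligned with
#'   `pairs` (order preserved).
#' @export
import_external_scores <- function(path, pairs, type = c("energy", "pvalue")) {
  type <- match.arg(type)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("mirna_id", "target_id", "value")
  if (!all(need %in% names(tab)))
    stop("external score table needs columns mirna_id, target_id, value",
         call. = FALSE)
  v <- trimws(tab$value)
  missing_mark <- is.na(v) | v == "" | v == "." | toupper(v) == "NA"
  v[is.na(v)] <- ""
  num <- suppressWarnings(as.numeric(v))
  bad <- which(!missing_mark & is.na(num))
  if (length(bad))
    stop(sprintf("unparseable score value(s) at line(s) %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)

  key <- paste(tab$mirna_id, tab$target_id, sep = "\r")
  want <- paste(pairs$mirna_id, pairs$target_id, sep = "\r")
  idx <- match(want, key)
  if (anyNA(idx))
    stop(sprintf("%d pair(s) absent from the score table (first: %s/%s)",
                 sum(is.na(idx)), pairs$mirna_id[which(is.na(idx))[1]],
                 pairs$target_id[which(is.na(idx))[1]]), call. = FALSE)
  raw <- num[idx]
  absent <- missing_mark[idx]

  present <- !absent
  score <- numeric(length(raw))
  if (!any(present)) {
    warning("no pair has a reported score; all scores 0")
  } else {
    x <- raw[present]
    x <- if (type == "pvalue") 1 - x else -x   # higher x = stronger binding
    rng <- range(x)
    score[present] <- if (diff(rng) == 0) {
      warning("degenerate score range: all reported values identical; scores set to 0.5")
      0.5
    } else (x - rng[1]) / (rng[2] - rng[1])
  }
  score[absent] <- 0
  data.frame(mirna_id = pairs$mirna_id, target_id = pairs$target_id,
             raw = raw, score = score, stringsAsFactors = FALSE)
}
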