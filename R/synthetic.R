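# Synthetic miRNA:target pairs with planted binding mechanisms.
#
# The generator emulates the composition reported for unbiased chimeric
# (CLASH-style) interaction data: roughly 40% of positives carry a
# canonical 2-7 seed match, 18% bind only through the miRNA 3' end, and
# the remainder are non-canonical partial duplexes.  Negatives are random
# miRNA:target re-pairings.  Planted mechanisms are recorded per pair so
# per-mechanism recall is computable for any scorer.

#' Specification of a synthetic dataset
#'
#' @param n_pos number of positive pairs.
#' @param canonical_fraction fraction of positives with a perfect seed
#'   complement (default 0.40, the canonical share seen in chimeric data).
#' @param three_prime_fraction fraction binding only via the miRNA 3' end
#'   (default 0.18); the remainder are non-canonical partial duplexes.
#' @param mutation_rate per-site probability of mutating a planted duplex
#'   position, in [0, 1).
#' @param gc_content G+C fraction of random sequence (default 0.5).
#' @param rng_seed integer seed recorded in provenance.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_pos = 1000L, canonical_fraction = 0.40,
                       three_prime_fraction = 0.18, mutation_rate = 0,
                       gc_content = 0.5, rng_seed = 1L) {
  if (canonical_fraction < 0 || three_prime_fraction < 0)
    stop("mechanism fractions must be non-negative", call. = FALSE)
  if (canonical_fraction + three_prime_fraction > 1)
    stop("canonical_fraction + three_prime_fraction must not exceed 1",
         call. = FALSE)
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must lie in [0, 1)", call. = FALSE)
  if (gc_content <= 0 || gc_content >= 1)
    stop("gc_content must lie in (0, 1)", call. = FALSE)
  structure(list(n_pos = as.integer(n_pos),
                 canonical_fraction = canonical_fraction,
                 three_prime_fraction = three_prime_fraction,
                 mutation_rate = mutation_rate, gc_content = gc_content,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_spec")
}

rand_rna <- function(n, length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = ""),
    character(1))
}

#' Generate random miRNA sequences
#'
#' @param n number of sequences.
#' @param length sequence length (default 20).
#' @param seed integer seed.
#' @param gc_content G+C fraction.
#' @return data.frame `mirna_id`, `mirna_seq`.
#' @export
gen_mirnas <- function(n, length = 20L, seed = 1L, gc_content = 0.5) {
  stopifnot(n >= 1)
  with_seed(seed, {
    data.frame(mirna_id = sprintf("synmir_%05d", seq_len(n)),
               mirna_seq = rand_rna(n, length, gc_content),
               stringsAsFactors = FALSE)
  })
}

# Mutate planted-element positions independently at `rate` to a random
# different base.
mutate_element <- function(element, rate) {
  if (rate <= 0) return(element)
  ch <- strsplit(element, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "U"), b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

#' Plant a binding site for a miRNA into a random 50-nt target
#'
#' Mechanisms:
#' * `canonical` — the reverse complement of the miRNA 2-7 seed hexamer is
#'   embedded, so [seed_match()] is true by construction (at
#'   `mutation_rate` 0).
#' * `three_prime` — the reverse complement of miRNA positions 13-20 is
#'   embedded and the target is rejection-sampled to contain no canonical
#'   seed complement anywhere ([seed_match()] false by construction).
#' * `noncanonical` — the reverse complement of miRNA positions 3-9 with
#'   one forced internal mismatch; also guaranteed free of a canonical
#'   seed complement.
#'
#' The element lands at a uniform random offset; flanks are random
#' sequence and are regenerated if they create an accidental seed match
#' for the seed-free mechanisms.
#'
#' @param mirna a `mirna_seq` or 20-nt string.
#' @param mechanism `"canonical"`, `"three_prime"` or `"noncanonical"`.
#' @param mutation_rate per-site mutation probability of the planted
#'   element.
#' @param seed optional integer seed (omit to use the current RNG stream).
#' @param gc_content G+C fraction of flanking sequence.
#' @return a 50-character target string.
#' @export
plant_site <- function(mirna, mechanism = c("canonical", "three_prime",
                                            "noncanonical"),
                       mutation_rate = 0, seed = NULL, gc_content = 0.5) {
  mechanism <- match.arg(mechanism)
  ms <- if (inherits(mirna, "mirna_seq")) mirna$seq else
    normalize_rna(as.character(mirna), "miRNA")
  if (nchar(ms) != 20L) stop("miRNA must be 20 nt", call. = FALSE)
  body <- function() {
    seed_probe <- rna_revcomp(substr(ms, 2L, 7L))
    element <- switch(mechanism,
      canonical = rna_revcomp(substr(ms, 2L, 7L)),
      three_prime = rna_revcomp(substr(ms, 13L, 20L)),
      noncanonical = {
        el <- rna_revcomp(substr(ms, 3L, 9L))
        pos <- sample(2:6, 1L)                       # internal mismatch
        ch <- strsplit(el, "", fixed = TRUE)[[1]]
        ch[pos] <- sample(setdiff(c("A", "C", "G", "U"), ch[pos]), 1L)
        paste(ch, collapse = "")
      })
    element <- mutate_element(element, mutation_rate)
    if (mechanism != "canonical" && grepl(seed_probe, element, fixed = TRUE))
      stop(sprintf(
        "planted %s element of this miRNA itself contains its seed complement; draw another miRNA",
        mechanism), call. = FALSE)
    L <- nchar(element)
    for (try in seq_len(200L)) {
      off <- sample.int(50L - L + 1L, 1L) - 1L       # 0-based
      flank_l <- rand_rna(1L, off, gc_content)
      flank_r <- rand_rna(1L, 50L - L - off, gc_content)
      tgt <- paste0(flank_l, element, flank_r)
      if (mechanism == "canonical") return(tgt)
      if (!grepl(seed_probe, tgt, fixed = TRUE)) return(tgt)
    }
    stop("could not place a seed-free element after 200 attempts",
         call. = FALSE)
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' Generate a synthetic ratio dataset with planted mechanisms
#'
#' Positives follow the mechanism mixture of the spec (counts are the
#' floored fractions, remainder assigned to the non-canonical class);
#' negatives are produced with [make_negatives()] and rejection-sampled so
#' no negative pair carries an accidental canonical seed complement for
#' its miRNA. The returned `ratio_dataset` has a `mechanism` column
#' (`canonical` / `three_prime` / `noncanonical` / `none`) and a `manifest`
#' attribute recording the spec.
#'
#' @param spec a [synth_spec()].
#' @param k negatives per positive.
#' @param split_tag dataset role tag.
#' @return a `ratio_dataset`.
#' @export
gen_dataset <- function(spec, k = 1L, split_tag = "train") {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_pos
  n_can <- floor(spec$canonical_fraction * n)
  n_3p <- floor(spec$three_prime_fraction * n)
  n_non <- n - n_can - n_3p
  mech <- c(rep("canonical", n_can), rep("three_prime", n_3p),
            rep("noncanonical", n_non))

  with_seed(spec$rng_seed, {
    mirnas <- data.frame(
      mirna_id = sprintf("synmir_%05d", seq_len(n)),
      mirna_seq = rand_rna(n, 20L, spec$gc_content),
      stringsAsFactors = FALSE)
    targets <- character(n)
    for (i in seq_len(n)) {
      for (try in seq_len(50L)) {
        res <- tryCatch(plant_site(mirnas$mirna_seq[i], mech[i],
                                   mutation_rate = spec$mutation_rate,
                                   gc_content = spec$gc_content),
                        error = identity)
        if (!inherits(res, "condition")) break
        # pathological miRNA for this mechanism: replace it and retry
        mirnas$mirna_seq[i] <- rand_rna(1L, 20L, spec$gc_content)
        res <- NULL
      }
      if (is.null(res)) stop("failed to plant a site after 50 miRNA redraws",
                             call. = FALSE)
      targets[i] <- res
    }
    positives <- data.frame(
      mirna_id = mirnas$mirna_id, mirna_seq = mirnas$mirna_seq,
      target_id = sprintf("synsite_%05d", seq_len(n)),
      target_seq = targets, label = 1, origin = "synthetic",
      mechanism = mech, stringsAsFactors = FALSE)

    neg_seed <- child_seed()
    negatives <- make_negatives(positives, k = k, rng_seed = neg_seed)
    # rejection: no negative pair may carry its miRNA's seed complement
    pool <- unique(positives$mirna_seq)
    for (round in seq_len(100L)) {
      bad <- which(seed_classifier(negatives) == 1)
      if (!length(bad)) break
      for (j in bad) {
        allowed <- setdiff(pool, positives$mirna_seq[
          positives$target_seq == negatives$target_seq[j]])
        negatives$mirna_seq[j] <- sample(allowed, 1L)
        negatives$mirna_id[j] <- positives$mirna_id[
          match(negatives$mirna_seq[j], positives$mirna_seq)]
      }
    }
    if (length(which(seed_classifier(negatives) == 1)))
      warning("some negatives retain an accidental seed complement after 100 rounds")

    ds <- assemble_ratio(positives, negatives, k = k, split_tag = split_tag,
                         rng_seed = child_seed())
    attr(ds, "manifest") <- c(unclass(spec), list(k = k, n_neg = k * n))
    ds
  })
}

#' Per-mechanism recall of a score vector on a synthetic dataset
#'
#' @param dataset a synthetic `ratio_dataset` (with `mechanism` column).
#' @param scores numeric scores aligned with rows.
#' @param threshold decision threshold (default 0.5).
#' @return named numeric vector of recalls, one per planted mechanism.
#' @export
mechanism_recall <- function(dataset, scores, threshold = 0.5) {
  stopifnot("mechanism" %in% names(dataset),
            length(scores) == nrow(dataset))
  mechs <- setdiff(unique(dataset$mechanism), "none")
  out <- vapply(mechs, function(m) {
    sel <- dataset$mechanism == m & dataset$label == 1
    mean(scores[sel] >= threshold)
  }, numeric(1))
  names(out) <- mechs
  out
}

#' Export pairs as FASTA files
#'
#' Writes `<stem>_mirna.fa` and `<stem>_target.fa` (via Biostrings) for
#' interoperability with external folding/hybridization tools.
#'
#' @param pairs pair data.frame.
#' @param stem output path stem.
#' @return character vector of the two paths, invisibly.
#' @export
export_fasta <- function(pairs, stem) {
  ids <- sprintf("%s|%s", pairs$mirna_id, pairs$target_id)
  m <- Biostrings::RNAStringSet(pairs$mirna_seq)
  names(m) <- ids
  t <- Biostrings::RNAStringSet(chartr("N", "N", pairs$target_seq))
  names(t) <- ids
  paths <- paste0(stem, c("_mirna.fa", "_target.fa"))
  Biostrings::writeXStringSet(m, paths[1])
  Biostrings::writeXStringSet(t, paths[2])
  invisible(paths)
}
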