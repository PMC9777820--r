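#' Standardize a miRNA sequence to 20 nt
#'
#' miRNAs vary in length (roughly 17-25 nt); for matrix encoding they are
#' standardized to exactly 20 nt anchored at the 5' end: sequences longer
#' than 20 nt are truncated to their first 20 nt, shorter ones are padded at
#' the 3' end with `N` (which never base-pairs). Input is case-folded and
#' DNA-style `T` is mapped to `U`, since target and miRNA sequences often
#' come from DNA references.
#'
#' @param raw a single RNA/DNA string over `{A,C,G,U,T,N}`, any case,
#'   length >= 6 (anything shorter has no seed region and is rejected).
#' @param id optional identifier carried along with the sequence.
#' @return an object of class `mirna_seq`: a list with `id` and `seq`
#'   (20-character RNA string).
#' @examples
#' standardize_mirna("UGAGGUAGUAGGUUGUAUAGUU")$seq  # first 20 nt
#' standardize_mirna("ugagguaguagguuguau")$seq      # 18 nt + "NN"
#' @export
standardize_mirna <- function(raw, id = NA_character_) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("`raw` must be a single nonempty sequence string", call. = FALSE)
  s <- normalize_rna(raw, what = "miRNA")
  if (nchar(s) < 6L)
    stop(sprintf("miRNA of length %d has no 2-7 seed region (need >= 6 nt)",
                 nchar(s)), call. = FALSE)
  if (nchar(s) >= 20L) {
    s <- substr(s, 1L, 20L)
  } else {
    s <- paste0(s, strrep("N", 20L - nchar(s)))
  }
  structure(list(id = id, seq = s), class = "mirna_seq")
}

#' Extract a 50-nt target window around a genomic interval
#'
#' Target-site coordinates are re-centered and resized to a fixed 50-nt
#' window: with a 0-based half-open interval `[start, end)` the center is
#' `c = floor((start + end) / 2)` and the window is `[c - 25, c + 25)`.
#' Minus-strand intervals are reverse-complemented so the returned sequence
#' reads 5'->3' on the transcribed strand. Windows truncated by a sequence
#' boundary are padded with `N` on the truncated side(s).
#'
#' @param interval a list or one-row data.frame with fields `chrom`,
#'   `start`, `end` (0-based half-open) and optionally `strand`
#'   (`"+"`/`"-"`, default `"+"`) and `name`.
#' @param genome a named character vector, named list of strings, or a
#'   `Biostrings::XStringSet` keyed by chromosome/sequence name.
#' @return an object of class `target_seq`: list with `id`, `seq` (50-nt RNA
#'   string) and `interval` (the source coordinates).
#' @examples
#' g <- c(chr1 = strrep("ACGT", 100))
#' window_target(list(chrom = "chr1", start = 100, end = 120), g)
#' @export
window_target <- function(interval, genome) {
  iv <- as.list(interval)
  for (f in c("chrom", "start", "end")) {
    if (is.null(iv[[f]])) stop(sprintf("interval lacks field '%s'", f),
                               call. = FALSE)
  }
  strand <- if (is.null(iv$strand) || is.na(iv$strand)) "+" else as.character(iv$strand)
  if (!strand %in% c("+", "-")) strand <- "+"
  chrom <- as.character(iv$chrom)
  start <- as.integer(iv$start)
  end <- as.integer(iv$end)
  if (end <= start) stop("interval has end <= start", call. = FALSE)

  seqs <- genome
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.list(seqs)) seqs <- unlist(seqs)
  if (!chrom %in% names(seqs))
    stop(sprintf("sequence '%s' not found in genome", chrom), call. = FALSE)
  chromseq <- toupper(seqs[[chrom]])
  L <- nchar(chromseq)
  if (start >= L || end <= 0L)
    stop(sprintf("interval [%d, %d) lies entirely off sequence '%s' (length %d)",
                 start, end, chrom, L), call. = FALSE)

  cen <- (start + end) %/% 2L
  w0 <- cen - 25L
  w1 <- cen + 25L                      # 0-based half-open [w0, w1)
  lo <- max(w0, 0L)
  hi <- min(w1, L)
  core <- substr(chromseq, lo + 1L, hi)      # 1-based substr
  s <- paste0(strrep("N", lo - w0), core, strrep("N", w1 - hi))
  s <- normalize_rna(s, what = sprintf("window on '%s'", chrom))
  if (strand == "-") s <- rna_revcomp(s)
  structure(list(id = if (is.null(iv$name)) sprintf("%s:%d-%d(%s)", chrom,
                                                    start, end, strand)
                 else as.character(iv$name),
                 seq = s,
                 interval = list(chrom = chrom, start = start, end = end,
                                 strand = strand)),
            class = "target_seq")
}

#' Read genomic intervals from a BED file
#'
#' Thin wrapper over [rtracklayer::import()] returning the fields
#' `window_target()` consumes (0-based half-open coordinates, strand-aware).
#'
#' @param path path to a BED file (3-6 columns).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_intervals <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED files requires the 'rtracklayer' package", call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,   # back to 0-based
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Encode one miRNA:target pair as a binary binding matrix
#'
#' The pair is represented as a 20 x 50 grid of Watson-Crick
#' complementarity indicators: entry `(i, j)` is 1 exactly when miRNA
#' position `i` and target position `j` form an A:U or G:C pair, and 0
#' otherwise. Both sequences are read 5'->3'; rows index the miRNA,
#' columns the target. G:U wobble pairs and any position involving `N`
#' score 0. No sequence content beyond pairing survives the encoding.
#'
#' @param mirna a `mirna_seq` (or 20-nt string, standardized implicitly).
#' @param target a `target_seq` (or 50-nt string).
#' @return 20 x 50 integer matrix of 0/1, class `binding_matrix`.
#' @examples
#' m <- standardize_mirna(strrep("A", 20))
#' t1 <- strrep("U", 50)
#' sum(encode_pair(m, t1)) # 1000: every A:U position pairs
#' @export
encode_pair <- function(mirna, target) {
  ms <- if (inherits(mirna, "mirna_seq")) mirna$seq else {
    s <- normalize_rna(as.character(mirna), "miRNA")
    if (nchar(s) != 20L)
      stop(sprintf("miRNA must be standardized to 20 nt (got %d); see standardize_mirna()",
                   nchar(s)), call. = FALSE)
    s
  }
  ts <- if (inherits(target, "target_seq")) target$seq else {
    s <- normalize_rna(as.character(target), "target")
    s
  }
  if (nchar(ms) != 20L)
    stop(sprintf("miRNA must be 20 nt (got %d)", nchar(ms)), call. = FALSE)
  if (nchar(ts) != 50L)
    stop(sprintf("target must be 50 nt (got %d)", nchar(ts)), call. = FALSE)
  mi <- strsplit(ms, "", fixed = TRUE)[[1]]
  tg <- strsplit(ts, "", fixed = TRUE)[[1]]
  comp <- WC_COMPLEMENT[mi]            # NA for N
  m <- outer(comp, tg, `==`)
  m[is.na(m)] <- FALSE
  m <- matrix(as.integer(m), nrow = 20L, ncol = 50L)
  dimnames(m) <- list(mirna = mi, target = tg)
  class(m) <- c("binding_matrix", class(m))
  m
}

#' Encode a batch of pairs into a 20 x 50 x n array
#'
#' Order-preserving: slab `k` of the result equals
#' `encode_pair(pairs$mirna_seq[k], pairs$target_seq[k])`.
#'
#' @param pairs data.frame with columns `mirna_seq` (20 nt) and
#'   `target_seq` (50 nt), e.g. from [load_pairs()].
#' @return numeric array with dim `c(20, 50, nrow(pairs))`.
#' @export
encode_batch <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) return(array(0, dim = c(20L, 50L, 0L)))
  ms <- toupper(chartr("T", "U", pairs$mirna_seq))
  ts <- toupper(chartr("T", "U", pairs$target_seq))
  bad <- which(nchar(ms) != 20L | nchar(ts) != 50L |
                 grepl("[^ACGUN]", ms) | grepl("[^ACGUN]", ts))
  if (length(bad))
    stop(sprintf("pair %d cannot be encoded: %s",
                 bad[1],
                 tryCatch({ encode_pair(pairs$mirna_seq[bad[1]],
                                        pairs$target_seq[bad[1]]); "" },
                          error = conditionMessage)),
         call. = FALSE)
  cpp_encode_batch(ms, ts, 20L, 50L)
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat(sprintf("binding matrix: %d x %d, %d Watson-Crick contact(s)\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' @export
print.mirna_seq <- function(x, ...) {
  cat(sprintf("miRNA %s: %s\n", if (is.na(x$id)) "<unnamed>" else x$id, x$seq))
  invisible(x)
}

#' @export
print.target_seq <- function(x, ...) {
  cat(sprintf("target %s: %s\n", if (is.na(x$id)) "<unnamed>" else x$id, x$seq))
  invisible(x)
}
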