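# Internal helpers shared across modules.

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

# Watson-Crick complement lookup; N has no complement.
WC_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", N = NA_character_)

#' Reverse complement of an RNA string
#'
#' Watson-Crick complement (A<->U, C<->G) read 3'->5', i.e. the sequence a
#' perfectly complementary strand would have written 5'->3'. `N` stays `N`.
#'
#' @param x character vector of RNA strings over `{A,C,G,U,N}`.
#' @return character vector of the same length.
#' @examples
#' rna_revcomp("GAGGUA") # "UACCUC"
#' @export
rna_revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Normalize a raw sequence: upper case, T -> U.  Errors (with offending
# positions) on characters outside {A,C,G,U,T,N}.
normalize_rna <- function(raw, what = "sequence") {
  s <- toupper(raw)
  s <- chartr("T", "U", s)
  bad <- gregexpr("[^ACGUN]", s)[[1]]
  if (bad[1] != -1L) {
    stop(sprintf("illegal character(s) in %s at position(s) %s: %s",
                 what, paste(bad, collapse = ", "),
                 paste(unique(substring(s, bad, bad)), collapse = ", ")),
         call. = FALSE)
  }
  s
}

# Draw a deterministic child seed (< 2^31) from the current RNG stream.
child_seed <- function() {
  sample.int(.Machine$integer.max, 1L)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls do not perturb user-level streams.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stable pair identifier used for IH tables and tie-breaking.
pair_id <- function(pairs) {
  paste(pairs$mirna_seq, pairs$target_seq, sep = ":")
}

# Write a flat key = value manifest file.
write_manifest <- function(values, path) {
  stopifnot(is.list(values) || is.character(values))
  lines <- vapply(names(values), function(k) {
    paste0(k, " = ", paste(format(values[[k]], trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  out <- lapply(kv, function(x) paste(x[-1], collapse = " = "))
  names(out) <- vapply(kv, `[[`, character(1), 1L)
  out
}
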