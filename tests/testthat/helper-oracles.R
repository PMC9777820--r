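# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own vectorized/compiled code paths.

WC_PAIRS <- c("AU", "UA", "GC", "CG")

# Double loop over every (i, j) testing Watson-Crick membership.
oracle_encode <- function(mirna, target) {
  mi <- strsplit(mirna, "")[[1]]
  tg <- strsplit(target, "")[[1]]
  m <- matrix(0L, length(mi), length(tg))
  for (i in seq_along(mi))
    for (j in seq_along(tg))
      if (paste0(mi[i], tg[j]) %in% WC_PAIRS) m[i, j] <- 1L
  m
}

# Scan all 45 length-6 windows of a 50-nt target for perfect
# complementarity (reversed orientation) to the miRNA 2-7 seed.
oracle_seed_scan <- function(mirna, target) {
  seed <- substr(mirna, 2, 7)
  sc <- strsplit(seed, "")[[1]]
  hits <- integer(0)
  for (off in 0:(nchar(target) - 6)) {
    win <- strsplit(substr(target, off + 1, off + 6), "")[[1]]
    # seed position p pairs with window position 7 - p (antiparallel)
    ok <- all(vapply(1:6, function(p)
      paste0(sc[p], win[7 - p]) %in% WC_PAIRS, logical(1)))
    if (ok) hits <- c(hits, off)
  }
  hits
}

oracle_confusion <- function(scores, labels, thr) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(scores)) {
    pred <- scores[i] >= thr
    if (pred && labels[i] == 1) tp <- tp + 1L
    if (pred && labels[i] == 0) fp <- fp + 1L
    if (!pred && labels[i] == 0) tn <- tn + 1L
    if (!pred && labels[i] == 1) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Non-interpolated AP and trapezoidal AUROC by exhaustive enumeration over
# every distinct score threshold.
oracle_areas <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  rec <- prec <- tpr <- fpr <- numeric(length(ths))
  for (i in seq_along(ths)) {
    cc <- oracle_confusion(scores, labels, ths[i])
    rec[i] <- cc$TP / P
    prec[i] <- cc$TP / max(1L, cc$TP + cc$FP)
    tpr[i] <- cc$TP / P
    fpr[i] <- cc$FP / N
  }
  ap <- sum(diff(c(0, rec)) * prec)
  xs <- c(0, fpr, 1)
  ys <- c(0, tpr, 1)
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  list(auprc = ap, auroc = auc)
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Small labeled pair table (positives only unless labels given).
make_pairs <- function(mirnas, targets, labels = 1,
                       origin = "experimental") {
  data.frame(mirna_id = sprintf("m%03d", seq_along(mirnas)),
             mirna_seq = mirnas,
             target_id = sprintf("t%03d", seq_along(targets)),
             target_seq = targets,
             label = rep_len(labels, length(mirnas)),
             origin = rep_len(origin, length(mirnas)),
             stringsAsFactors = FALSE)
}

# A miRNA whose 2-7 seed is complemented inside `target_with_site`.
planted_pair <- function() {
  mirna <- "UGAGGUAGUAGGUUGUAUAGUU"      # classic let-7-like sequence
  std <- standardize_mirna(mirna)$seq
  probe <- rna_revcomp(substr(std, 2, 7))
  left <- strrep("C", 20)
  right <- strrep("C", 50 - 20 - nchar(probe))
  list(mirna = std, target = paste0(left, probe, right), offset = 20L)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
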