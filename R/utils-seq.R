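# Low-level sequence helpers shared across modules. Internal alphabet is DNA
# (A,C,G,T,N); RNA inputs are converted on read (see read_fasta).

#' Reverse-complement DNA sequences
#'
#' Vectorized reverse complement over the DNA alphabet (A,C,G,T,N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Integer encoding of a sequence for fast mismatch counting.
seq_ints <- function(s) utf8ToInt(s)

# Count mismatches between tag and every full-length window of ref.
# Returns integer vector over 0-based window starts 0..(nchar(ref)-L).
# O(L) vectorized passes over the reference; N never matches.
window_mismatches <- function(tag, ref) {
  ti <- seq_ints(tag)
  ri <- seq_ints(ref)
  L <- length(ti)
  M <- length(ri)
  if (M < L) return(integer(0))
  nwin <- M - L + 1L
  mm <- integer(nwin)
  for (k in seq_len(L)) {
    mm <- mm + (ri[k:(k + nwin - 1L)] != ti[k])
  }
  mm
}

# All 0-based start positions where tag matches ref with <= max_mm
# substitutions (ungapped, full tag length).
scan_substitution_hits <- function(tag, ref, max_mm = 1L) {
  mm <- window_mismatches(tag, ref)
  which(mm <= max_mm) - 1L
}

# One-hot encode equal-length sequences into an n x 4L 0/1 matrix
# (A,C,G,T stacked per position; N matches nothing).
onehot_matrix <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  do.call(cbind, lapply(c("A", "C", "G", "T"), function(b) (ch == b) * 1L))
}

# Batch ungapped scan: all (tag, window) pairs with <= max_mm substitutions.
# `tags` must share one length L. Returns data.frame(tag_idx, start (0-based),
# mm). Uses a one-hot matrix product so the cost is one BLAS call.
batch_substitution_hits <- function(tags, ref, max_mm = 1L) {
  L <- nchar(tags[1])
  M <- nchar(ref)
  empty <- data.frame(tag_idx = integer(0), start = integer(0),
                      mm = integer(0))
  if (M < L) return(empty)
  nwin <- M - L + 1L
  starts <- seq_len(nwin)
  windows <- substring(ref, starts, starts + L - 1L)
  T1 <- onehot_matrix(tags)
  W1 <- onehot_matrix(windows)
  matches <- T1 %*% t(W1)                      # n_tags x n_windows
  hit <- which(matches >= L - max_mm, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  data.frame(tag_idx = hit[, 1], start = hit[, 2] - 1L,
             mm = L - matches[hit])
}

# All 0-based start positions of exact occurrences of pattern in subject.
exact_hits <- function(pattern, subject) {
  out <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (out[1] == -1L) return(integer(0))
  as.integer(out) - 1L
}

# Per-base counts for a character vector of sequences; returns a matrix with
# one row per sequence and columns A,C,G,T,N.
base_counts <- function(x) {
  bases <- c("A", "C", "G", "T", "N")
  out <- vapply(bases, function(b) {
    nchar(x) - nchar(gsub(b, "", x, fixed = TRUE))
  }, integer(length(x)))
  if (length(x) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, bases))
  out
}

# Deterministic child seed derived from a base seed and a stream label;
# stays below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 65521L)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
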