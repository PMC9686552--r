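# Independent oracles used to check the implementation from a second route.
# These deliberately use different algorithms (naive scans, recursion,
# closed-form combinatorics, stats::t.test / lm) than the code under test.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# naive per-position substring scan (both strands) for exact genome hits
oracle_genome_scan <- function(tag, genome_seq) {
  L <- nchar(tag)
  rc <- revcomp(tag)
  out <- list()
  for (s in seq_len(nchar(genome_seq) - L + 1L)) {
    w <- substr(genome_seq, s, s + L - 1L)
    if (w == tag) out[[length(out) + 1L]] <- c(s - 1L, 1L)
    if (w == rc) out[[length(out) + 1L]] <- c(s - 1L, -1L)
  }
  out
}

# character-by-character mismatch count of tag against every ref window
oracle_window_mm <- function(tag, ref) {
  L <- nchar(tag)
  M <- nchar(ref)
  if (M < L) return(integer(0))
  vapply(seq_len(M - L + 1L), function(s) {
    a <- strsplit(substr(ref, s, s + L - 1L), "")[[1]]
    b <- strsplit(tag, "")[[1]]
    sum(a != b)
  }, integer(1))
}

# maximum number of non-crossing base pairs (min hairpin loop 3, G.U
# allowed), by plain recursion over "pair position i with some k or leave
# it unpaired" with memoisation
oracle_max_pairs <- function(seq) {
  ch <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(ch)
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i >= j) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + 1L):j) {
      if (k - i > 3L && pairable(ch[i], ch[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, n)
}

# exact upper-tail hypergeometric by summing binomial coefficients
oracle_hyper_upper <- function(N, K, n, k) {
  sum(vapply(k:min(n, K), function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, numeric(1))) / choose(N, n)
}

# Benjamini-Hochberg step-up written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m >= 2) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force seed-site scan: search the reverse complement of miRNA
# positions 2-7 at every UTR offset and classify by direct character checks
oracle_scan_sites <- function(mirna, utr) {
  core <- revcomp(substr(mirna, 2, 7))
  m8 <- revcomp(substr(mirna, 8, 8))
  hits <- list()
  for (s in seq_len(nchar(utr) - 5L)) {
    if (substr(utr, s, s + 5L) != core) next
    up <- if (s > 1) substr(utr, s - 1L, s - 1L) else ""
    dn <- substr(utr, s + 6L, s + 6L)
    type <- if (up == m8 && dn == "A") "8mer"
            else if (up == m8) "7mer-m8"
            else if (dn == "A") "7mer-A1"
            else "6mer"
    hits[[length(hits) + 1L]] <- list(position = s - 1L, site_type = type)
  }
  hits
}

# --- hairpin fixture builder ------------------------------------------------
# Build a dot-bracket structure + sequence from an outer-to-inner stem
# description. Segments: p(n) = n stacked pairs, b5(n)/b3(n) = one-sided
# bulge of n nt on the 5'/3' side, il(l, r) = two-sided interior loop.
# Loop bases are A, pairs are G (5') / C (3').
seg_p <- function(n) list(type = "p", n = n)
seg_b5 <- function(n) list(type = "b5", n = n)
seg_b3 <- function(n) list(type = "b3", n = n)
seg_il <- function(l, r) list(type = "il", l = l, r = r)

build_hairpin_fixture <- function(segments, loop_len = 8L, flank5 = 10L,
                                  flank3 = 10L, energy = -30) {
  left_seq <- character(0); left_db <- character(0)
  right_seq <- character(0); right_db <- character(0)  # outer-to-inner
  for (sg in segments) {
    if (sg$type == "p") {
      left_seq <- c(left_seq, strrep("G", sg$n))
      left_db <- c(left_db, strrep("(", sg$n))
      right_seq <- c(right_seq, strrep("C", sg$n))
      right_db <- c(right_db, strrep(")", sg$n))
    } else if (sg$type == "b5") {
      left_seq <- c(left_seq, strrep("A", sg$n))
      left_db <- c(left_db, strrep(".", sg$n))
    } else if (sg$type == "b3") {
      right_seq <- c(right_seq, strrep("A", sg$n))
      right_db <- c(right_db, strrep(".", sg$n))
    } else {
      left_seq <- c(left_seq, strrep("A", sg$l))
      left_db <- c(left_db, strrep(".", sg$l))
      right_seq <- c(right_seq, strrep("A", sg$r))
      right_db <- c(right_db, strrep(".", sg$r))
    }
  }
  L <- paste(left_seq, collapse = "")
  R <- paste(rev(right_seq), collapse = "")
  Ldb <- paste(left_db, collapse = "")
  Rdb <- paste(rev(right_db), collapse = "")
  sequence <- paste0(strrep("T", flank5), L, strrep("A", loop_len), R,
                     strrep("T", flank3))
  structure <- paste0(strrep(".", flank5), Ldb, strrep(".", loop_len), Rdb,
                      strrep(".", flank3))
  list(sequence = sequence, structure = structure, energy = energy,
       flank5 = flank5, left_len = nchar(L))
}

fold_fixture <- function(fx) {
  fold(fx$sequence, "file", structure = fx$structure, energy = fx$energy)
}

eval_fixture <- function(fx, mature_start, mature_end) {
  st <- fold_fixture(fx)
  evaluate_criteria(st, decompose(st), mature_start, mature_end)
}

# The acceptance fixture suite: for each criterion 1..11, one structure
# passing all criteria and one failing exactly that criterion. Mature
# intervals are 0-based half-open in window coordinates.
criteria_fixture_suite <- function() {
  fxs <- list()
  add <- function(id, expect_fail, fx, mstart, mend) {
    fxs[[length(fxs) + 1L]] <<- list(id = id, expect_fail = expect_fail,
                                     fx = fx, mstart = mstart, mend = mend)
  }
  # passing variants: perfect stems of varying geometry, mature on 5' arm
  arms <- c(25L, 22L, 27L, 24L, 26L, 23L, 25L, 22L, 27L, 24L, 26L)
  loops <- c(8L, 6L, 4L, 8L, 6L, 7L, 5L, 8L, 4L, 6L, 8L)
  for (i in 1:11) {
    fx <- build_hairpin_fixture(list(seg_p(arms[i])), loop_len = loops[i])
    add(i, NA_integer_, fx, 10L, 10L + 22L)
  }
  # 1: one interior loop totalling 13 nt, outside the mature region
  fx <- build_hairpin_fixture(list(seg_p(5), seg_il(7, 6), seg_p(20)))
  add(1, 1L, fx, 10L + 12L, 10L + 12L + 20L)     # mature = inner 20 pairs
  # 2: only 15 stem pairs (span kept >= 50 via a 20-nt terminal loop)
  fx <- build_hairpin_fixture(list(seg_p(15)), loop_len = 20L)
  add(2, 2L, fx, 10L, 25L)
  # 3: perfect stem, weak energy
  fx <- build_hairpin_fixture(list(seg_p(25)), energy = -10)
  add(3, 3L, fx, 10L, 32L)
  # 4: 48-nt hairpin
  fx <- build_hairpin_fixture(list(seg_p(22)), loop_len = 4L)
  add(4, 4L, fx, 10L, 32L)
  # 5: 22-nt terminal loop
  fx <- build_hairpin_fixture(list(seg_p(25)), loop_len = 22L)
  add(5, 5L, fx, 10L, 32L)
  # 6: 9-nt one-sided bulge inside the mature
  fx <- build_hairpin_fixture(list(seg_p(8), seg_b5(9), seg_p(12)))
  add(6, 6L, fx, 10L, 10L + 29L)
  # 7: (6,1) interior loop inside the mature (asymmetry 5)
  fx <- build_hairpin_fixture(list(seg_p(8), seg_il(6, 1), seg_p(12)))
  add(7, 7L, fx, 10L, 10L + 26L)
  # 8: three 1-nt bulges inside the mature
  fx <- build_hairpin_fixture(list(seg_p(5), seg_b5(1), seg_p(5), seg_b5(1),
                                   seg_p(5), seg_b5(1), seg_p(10)))
  add(8, 8L, fx, 10L, 10L + 28L)
  # 9: eight 1x1 mismatch loops inside the mature
  segs <- list(seg_p(4))
  for (k in 1:8) segs <- c(segs, list(seg_il(1, 1), seg_p(2)))
  fx <- build_hairpin_fixture(segs)
  add(9, 9L, fx, 10L, 10L + 28L)
  # 10: mature covers only 11 pairs
  fx <- build_hairpin_fixture(list(seg_p(25)))
  add(10, 10L, fx, 10L, 21L)
  # 11: mature hangs 5 nt outside the hairpin span
  fx <- build_hairpin_fixture(list(seg_p(25)))
  add(11, 11L, fx, 5L, 27L)
  fxs
}

# lazily simulated shared fixture for the acceptance tests
.mirexo_acceptance_env <- new.env(parent = emptyenv())
acceptance_sim <- function() {
  if (is.null(.mirexo_acceptance_env$sim)) {
    dir <- file.path(tempdir(), "mirexo-acceptance")
    ref <- generate_reference(file.path(dir, "reference"), seed = 20260912L)
    design <- read_sim_design(n_reads = 10000L, seed = 20260912L)
    reads <- generate_reads(design, ref, file.path(dir, "reads"))
    .mirexo_acceptance_env$sim <- list(dir = dir, ref = ref, design = design,
                                       reads = reads)
  }
  .mirexo_acceptance_env$sim
}
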