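# Raw FASTQ -> "valid data": adapter-trimmed, junk-filtered,
# contaminant-filtered unique tags with per-sample copy numbers.

#' Default 3' adapter (TruSeq small RNA kit)
#' @export
TRUSEQ_SMALL_RNA_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Trim the 3' adapter from a read sequence
#'
#' Removes the suffix starting at the leftmost position where a prefix of
#' the adapter (length >= `min_overlap`) aligns with at most one mismatch.
#' A match at position 0 (empty insert) is an adapter dimer and is rejected;
#' reads with no adapter match are returned whole.
#'
#' @param sequence read sequence (DNA, upper case).
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length to call a match (>= 4).
#' @return list with `insert` (trimmed sequence, or NA for a dimer) and
#'   `status`: one of "trimmed", "untrimmed", "adapter_dimer".
#' @export
trim_adapter <- function(sequence, adapter = TRUSEQ_SMALL_RNA_ADAPTER,
                         min_overlap = 8L) {
  res <- trim_adapter_batch(sequence, adapter, min_overlap)
  list(insert = res$insert[1], status = res$status[1])
}

#' Trim the 3' adapter from many reads at once
#'
#' Vectorized form of [trim_adapter()]; same matching contract.
#'
#' @param sequences character vector of read sequences.
#' @inheritParams trim_adapter
#' @return data.frame with columns `insert` (NA for dimers) and `status`.
#' @export
trim_adapter_batch <- function(sequences, adapter = TRUSEQ_SMALL_RNA_ADAPTER,
                               min_overlap = 8L) {
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 4L) stop("min_overlap must be >= 4", call. = FALSE)
  if (nchar(adapter) < min_overlap) {
    stop("adapter shorter than min_overlap", call. = FALSE)
  }
  n <- length(sequences)
  lens <- nchar(sequences)
  maxlen <- if (n > 0) max(lens) else 0L
  ai <- seq_ints(adapter)
  # char matrix: one row per read, padded with 0 beyond the read end
  mat <- matrix(0L, nrow = n, ncol = maxlen)
  for (i in seq_len(n)) {
    v <- seq_ints(sequences[i])
    if (length(v)) mat[i, seq_along(v)] <- v
  }
  best <- rep(NA_integer_, n)  # leftmost 1-based match start, NA = none
  for (s in seq_len(max(0L, maxlen - min_overlap + 1L))) {
    undecided <- is.na(best) & (lens - s + 1L >= min_overlap)
    if (!any(undecided)) next
    L <- pmin(nchar(adapter), lens - s + 1L)
    # mismatches over the matched region for each undecided read
    idx <- which(undecided)
    mm <- integer(length(idx))
    for (k in seq_len(max(L[idx]))) {
      active <- L[idx] >= k
      col <- s + k - 1L
      mm[active] <- mm[active] + (mat[idx[active], col] != ai[k])
    }
    hit <- mm <= 1L
    best[idx[hit]] <- s
  }
  status <- ifelse(is.na(best), "untrimmed",
                   ifelse(best == 1L, "adapter_dimer", "trimmed"))
  insert <- ifelse(is.na(best), sequences,
                   ifelse(best == 1L, NA_character_,
                          substr(sequences, 1L, ifelse(is.na(best), 0L, best - 1L))))
  data.frame(insert = insert, status = status, stringsAsFactors = FALSE)
}

# ordered rule ids, reported by first match
JUNK_RULES <- c("too_short", "base80", "n3", "ac_only", "gt_only",
                "dimer_repeat", "trimer_repeat")

is_periodic <- function(x, period) {
  # perfect k-periodic repeat covering the whole sequence (trailing partial
  # unit allowed); requires at least two full units
  n <- nchar(x)
  ok <- n >= 2L * period
  unit <- substr(x, 1L, period)
  reps <- strrep(unit, ceiling(n / period))
  ok & substr(reps, 1L, n) == x
}

#' Junk-read filter
#'
#' Applies the low-complexity rules to post-trim insert sequences, in fixed
#' precedence order: (a) length < 18; (b) any single base >= 80 percent of the
#' length; (c) three or more N; (d) only A/C; (e) only G/T; (f) perfect
#' dinucleotide repeat; (g) perfect trinucleotide repeat.
#'
#' @param sequences character vector of post-trim sequences.
#' @return character vector: "keep" or the id of the first firing rule
#'   (one of `JUNK_RULES`).
#' @export
junk_filter <- function(sequences) {
  n <- length(sequences)
  out <- rep(NA_character_, n)
  len <- nchar(sequences)
  assign_rule <- function(out, cond, rule) {
    ifelse(is.na(out) & cond, rule, out)
  }
  out <- assign_rule(out, len < 18L, "too_short")
  bc <- base_counts(sequences)
  frac_max <- apply(bc[, c("A", "C", "G", "T"), drop = FALSE], 1, max) / len
  out <- assign_rule(out, frac_max >= 0.8, "base80")
  out <- assign_rule(out, bc[, "N"] >= 3L, "n3")
  out <- assign_rule(out, bc[, "G"] + bc[, "T"] + bc[, "N"] == 0L, "ac_only")
  out <- assign_rule(out, bc[, "A"] + bc[, "C"] + bc[, "N"] == 0L, "gt_only")
  out <- assign_rule(out, is_periodic(sequences, 2L), "dimer_repeat")
  out <- assign_rule(out, is_periodic(sequences, 3L), "trimer_repeat")
  out[is.na(out)] <- "keep"
  unname(out)
}

#' Collapse surviving reads into unique tags with per-sample copy numbers
#'
#' @param reads data.frame with columns `sequence` and `sample` (one row per
#'   surviving read).
#' @return data.frame with column `sequence` plus one integer copy-number
#'   column per sample, ordered by decreasing total copies then sequence.
#' @export
collapse_reads <- function(reads) {
  samples <- sort(unique(reads$sample))
  if (nrow(reads) == 0) {
    return(data.frame(sequence = character(0), stringsAsFactors = FALSE))
  }
  tab <- table(reads$sequence, factor(reads$sample, levels = samples))
  out <- data.frame(sequence = rownames(tab), stringsAsFactors = FALSE)
  for (s in samples) out[[s]] <- as.integer(tab[, s])
  tot <- rowSums(as.matrix(out[, samples, drop = FALSE]))
  out <- out[order(-tot, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# class priority when a tag matches contaminants of several classes
CONTAMINANT_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat", "mRNA")

#' Filter tags against a contaminant reference
#'
#' A tag is removed iff it matches some contaminant record as an ungapped
#' full-length alignment with at most one substitution, on either strand.
#' When several classes match, the reported class follows the fixed priority
#' rRNA > tRNA > snRNA > snoRNA > repeat > mRNA (record order never matters).
#'
#' @param tags data.frame from [collapse_reads()].
#' @param contaminants data.frame as [read_fasta()]; each record's
#'   `description` must start with its class label (e.g. "rRNA").
#' @return list with `kept` (tags data.frame), `removed` (tags data.frame with
#'   extra `class` column).
#' @export
contaminant_filter <- function(tags, contaminants) {
  classes <- sub("\\s.*$", "", contaminants$description)
  unknown <- setdiff(unique(classes), CONTAMINANT_CLASSES)
  if (length(unknown)) {
    stop("unknown contaminant class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  refs <- contaminants$sequence
  refs_rc <- revcomp(refs)
  hit_class <- rep(NA_character_, nrow(tags))
  rank <- match(classes, CONTAMINANT_CLASSES)
  ord <- order(rank)  # scan classes by priority so the first hit wins
  lens <- nchar(tags$sequence)
  for (j in ord) {
    todo <- which(is.na(hit_class))
    if (!length(todo)) break
    for (L in unique(lens[todo])) {
      sel <- todo[lens[todo] == L]
      hits_f <- batch_substitution_hits(tags$sequence[sel], refs[j], 1L)
      hits_r <- batch_substitution_hits(tags$sequence[sel], refs_rc[j], 1L)
      hit_idx <- unique(c(hits_f$tag_idx, hits_r$tag_idx))
      if (length(hit_idx)) hit_class[sel[hit_idx]] <- classes[j]
    }
  }
  removed <- tags[!is.na(hit_class), , drop = FALSE]
  if (nrow(removed)) removed$class <- hit_class[!is.na(hit_class)]
  else removed$class <- character(0)
  kept <- tags[is.na(hit_class), , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Preprocess raw FASTQ reads into valid unique tags
#'
#' Runs adapter trimming, junk filtering, collapsing and contaminant
#' filtering for a set of samples, and accounts for every read: per sample,
#' raw = valid + sum(removed categories).
#'
#' @param fastq_paths named character vector: sample name -> FASTQ path.
#' @param adapter 3' adapter sequence.
#' @param contaminants contaminant reference (data.frame as [read_fasta()]),
#'   or NULL to skip contaminant filtering.
#' @param min_overlap minimum adapter overlap.
#' @return list with `tags` (valid 18-26 nt tags, copy columns per sample),
#'   `long_tags` (tags > 26 nt, excluded from identification), `stats`
#'   (per-sample FilterStats data.frame), `removed_contaminants`.
#' @export
preprocess_samples <- function(fastq_paths, adapter = TRUSEQ_SMALL_RNA_ADAPTER,
                               contaminants = NULL, min_overlap = 8L) {
  samples <- names(fastq_paths)
  if (is.null(samples) || any(!nzchar(samples))) {
    stop("fastq_paths must be a named vector (sample -> path)", call. = FALSE)
  }
  all_survivors <- list()
  stats_rows <- list()
  for (s in samples) {
    reads <- read_fastq(fastq_paths[[s]])
    raw <- nrow(reads)
    tr <- trim_adapter_batch(reads$sequence, adapter, min_overlap)
    n_dimer <- sum(tr$status == "adapter_dimer")
    inserts <- tr$insert[tr$status != "adapter_dimer"]
    verdict <- junk_filter(inserts)
    junk_counts <- vapply(JUNK_RULES, function(r) sum(verdict == r), integer(1))
    keep <- inserts[verdict == "keep"]
    stats_rows[[s]] <- data.frame(
      sample = s, raw = raw, adapter_trimmed = sum(tr$status == "trimmed"),
      adapter_dimer = n_dimer,
      as.list(stats::setNames(junk_counts, paste0("junk_", JUNK_RULES))),
      stringsAsFactors = FALSE)
    if (length(keep)) {
      all_survivors[[s]] <- data.frame(sequence = keep, sample = s,
                                       stringsAsFactors = FALSE)
    }
  }
  survivors <- if (length(all_survivors)) do.call(rbind, all_survivors)
               else data.frame(sequence = character(0), sample = character(0))
  tags <- collapse_reads(survivors)
  # contaminant filtering on unique tags
  removed_cont <- tags[0, , drop = FALSE]
  if (!is.null(contaminants) && nrow(tags) > 0) {
    cf <- contaminant_filter(tags, contaminants)
    tags <- cf$kept
    removed_cont <- cf$removed
  } else if (nrow(tags) > 0) {
    removed_cont$class <- character(0)
  }
  lens <- nchar(tags$sequence)
  long_tags <- tags[lens > 26L, , drop = FALSE]
  tags <- tags[lens >= 18L & lens <= 26L, , drop = FALSE]
  rownames(tags) <- rownames(long_tags) <- NULL
  stats <- do.call(rbind, stats_rows)
  copy_cols <- function(df, s) if (s %in% names(df)) sum(df[[s]]) else 0L
  for (s in samples) {
    cls_counts <- vapply(CONTAMINANT_CLASSES, function(cl) {
      sub <- removed_cont[removed_cont$class == cl, , drop = FALSE]
      as.integer(copy_cols(sub, s))
    }, integer(1))
    stats[stats$sample == s, paste0("contaminant_", CONTAMINANT_CLASSES)] <-
      as.list(cls_counts)
    stats[stats$sample == s, "long_tag"] <- copy_cols(long_tags, s)
    stats[stats$sample == s, "valid"] <- copy_cols(tags, s)
  }
  rownames(stats) <- NULL
  list(tags = tags, long_tags = long_tags, stats = stats,
       removed_contaminants = removed_cont)
}
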