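# Readers/writers for the external formats the pipeline touches: FASTA,
# FASTQ (Phred+33), TSV with header, Vienna-style dot-bracket files, and a
# DCF key-value config. Internal coordinates are 0-based half-open; exported
# TSV tables that carry coordinates say so in a header comment.

fmt_error <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

#' Read a FASTA file
#'
#' Sequences are upper-cased and U is converted to T (the internal alphabet
#' is DNA); records that contained U are flagged so writers can restore the
#' original alphabet.
#'
#' @param path path to an (optionally gzipped) FASTA file.
#' @return data.frame with columns `id`, `description`, `sequence`,
#'   `rna` (logical: original record used the RNA alphabet).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) | seq_along(lines) < length(lines)
  ids <- character(0); desc <- character(0); seqs <- character(0)
  cur <- NULL; buf <- character(0); cur_line <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    s <- paste(buf, collapse = "")
    if (!nzchar(s)) fmt_error(path, cur_line, sprintf("empty sequence for record '%s'", cur[1]))
    ids <<- c(ids, cur[1]); desc <<- c(desc, cur[2]); seqs <<- c(seqs, s)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^>", ln)) {
      flush()
      hdr <- sub("^>\\s*", "", ln)
      if (!nzchar(hdr)) fmt_error(path, i, "malformed header: empty id")
      id <- sub("\\s.*$", "", hdr)
      d <- if (grepl("\\s", hdr)) sub("^\\S+\\s+", "", hdr) else ""
      cur <- c(id, d); buf <- character(0); cur_line <- i
    } else if (grepl("^\\s*$", ln)) {
      next
    } else {
      if (is.null(cur)) fmt_error(path, i, "sequence data before first header")
      up <- toupper(gsub("\\s", "", ln))
      bad <- regmatches(up, regexpr("[^ACGTUN]", up))
      if (length(bad) > 0 && nzchar(bad)) {
        fmt_error(path, i, sprintf("illegal character '%s' in sequence", bad))
      }
      buf <- c(buf, up)
    }
  }
  flush()
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("%s: duplicate record id '%s'", path, dup), call. = FALSE)
  }
  rna <- grepl("U", seqs, fixed = TRUE)
  seqs <- chartr("U", "T", seqs)
  data.frame(id = ids, description = desc, sequence = seqs, rna = rna,
             stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' Records flagged `rna` are written back in the RNA alphabet (T restored
#' to U), inverting the normalization applied by [read_fasta()].
#'
#' @param records data.frame as returned by [read_fasta()] (the `rna` and
#'   `description` columns are optional).
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "wb")
  on.exit(close(con))
  rna <- if ("rna" %in% names(records)) records$rna else rep(FALSE, nrow(records))
  desc <- if ("description" %in% names(records)) records$description else rep("", nrow(records))
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    if (isTRUE(rna[i])) s <- chartr("T", "U", s)
    hdr <- if (nzchar(desc[i])) paste0(">", records$id[i], " ", desc[i]) else paste0(">", records$id[i])
    starts <- seq(1L, nchar(s), by = width)
    body <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    writeLines(c(hdr, body), con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to an (optionally gzipped) 4-line-record FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) %% 4 != 0) {
    fmt_error(path, length(lines), "FASTQ record count not a multiple of 4 lines")
  }
  n <- length(lines) %/% 4
  if (n == 0) return(data.frame(id = character(0), sequence = character(0),
                                quality = character(0), stringsAsFactors = FALSE))
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seqs <- toupper(lines[seq(2, by = 4, length.out = n)])
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad_hdr <- which(!grepl("^@", hdr))
  if (length(bad_hdr)) fmt_error(path, (bad_hdr[1] - 1L) * 4L + 1L, "expected '@' header")
  bad_plus <- which(!grepl("^\\+", plus))
  if (length(bad_plus)) fmt_error(path, (bad_plus[1] - 1L) * 4L + 3L, "expected '+' separator")
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len)) {
    fmt_error(path, (bad_len[1] - 1L) * 4L + 4L,
              "quality length differs from sequence length")
  }
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  data.frame(id = ids, sequence = seqs, quality = qual, stringsAsFactors = FALSE)
}

#' Write a FASTQ file (Phred+33)
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    out <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality)
    writeLines(as.vector(out), con, sep = "\n")
  }
  invisible(path)
}

#' Read a miRBase-dialect reference bundle
#'
#' Loads hairpin (precursor) and mature FASTA plus a coordinates TSV mapping
#' each mature id to (precursor_id, start, end, arm) with 0-based half-open
#' coordinates. Every mature sequence must equal the precursor substring at
#' its coordinates (after U to T normalization). Matures absent from the
#' coordinates table are placed by unique exact substring search and get arm
#' "unknown"; an ambiguous or failed search is an error.
#'
#' @param hairpin_path precursor FASTA.
#' @param mature_path mature FASTA.
#' @param coords_path TSV with columns mature_id, precursor_id, start, end, arm.
#' @return list with `precursors` (data.frame as [read_fasta()]) and
#'   `annotations` (data.frame: precursor_id, mature_id, arm, start, end,
#'   mature_sequence).
#' @export
read_mirbase_dialect <- function(hairpin_path, mature_path, coords_path) {
  pre <- read_fasta(hairpin_path)
  mat <- read_fasta(mature_path)
  coords <- utils::read.delim(coords_path, stringsAsFactors = FALSE,
                              comment.char = "#")
  need <- c("mature_id", "precursor_id", "start", "end", "arm")
  if (!all(need %in% names(coords))) {
    stop("coords TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pre_seq <- stats::setNames(pre$sequence, pre$id)
  ann <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    mid <- mat$id[i]
    mseq <- mat$sequence[i]
    row <- coords[coords$mature_id == mid, , drop = FALSE]
    if (nrow(row) >= 1) {
      row <- row[1, ]
      pid <- row$precursor_id
      if (!pid %in% names(pre_seq)) {
        stop(sprintf("coords for mature '%s' name unknown precursor '%s'", mid, pid),
             call. = FALSE)
      }
      sub <- substr(pre_seq[[pid]], row$start + 1L, row$end)
      if (!identical(sub, mseq)) {
        stop(sprintf(
          "mature '%s' does not match precursor '%s' at [%d,%d): got '%s', mature is '%s'",
          mid, pid, row$start, row$end, sub, mseq), call. = FALSE)
      }
      ann[[i]] <- data.frame(precursor_id = pid, mature_id = mid,
                             arm = as.character(row$arm),
                             start = as.integer(row$start), end = as.integer(row$end),
                             mature_sequence = mseq, stringsAsFactors = FALSE)
    } else {
      # fallback: unique exact substring search across all precursors
      hits <- list()
      for (pid in names(pre_seq)) {
        pos <- exact_hits(mseq, pre_seq[[pid]])
        for (p in pos) hits[[length(hits) + 1L]] <- c(pid, p)
      }
      if (length(hits) != 1) {
        stop(sprintf(
          "mature '%s' has no coords row and %d exact precursor matches (need exactly 1)",
          mid, length(hits)), call. = FALSE)
      }
      pid <- hits[[1]][1]; p <- as.integer(hits[[1]][2])
      ann[[i]] <- data.frame(precursor_id = pid, mature_id = mid, arm = "unknown",
                             start = p, end = p + nchar(mseq),
                             mature_sequence = mseq, stringsAsFactors = FALSE)
    }
  }
  annotations <- do.call(rbind, ann)
  if (is.null(annotations)) {
    annotations <- data.frame(precursor_id = character(0), mature_id = character(0),
                              arm = character(0), start = integer(0), end = integer(0),
                              mature_sequence = character(0), stringsAsFactors = FALSE)
  }
  bad <- annotations$start < 0 | annotations$start >= annotations$end
  if (any(bad)) {
    stop("invalid mature coordinates for: ",
         paste(annotations$mature_id[bad], collapse = ", "), call. = FALSE)
  }
  list(precursors = pre, annotations = annotations)
}

#' Write a TSV table with a fixed schema
#'
#' Tab-separated with a header line; floating-point columns are rendered
#' with 6 significant digits and NaN/NA p-values render as "NA". Output is
#' byte-stable for identical inputs.
#'
#' @param rows data.frame conforming to `schema`.
#' @param path output path.
#' @param schema character vector of required column names (defaults to
#'   `names(rows)`).
#' @param comment optional comment lines (written as `# ...` before header).
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(rows, path, schema = names(rows), comment = NULL) {
  missing <- setdiff(schema, names(rows))
  if (length(missing)) {
    stop("rows missing schema column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- rows[, schema, drop = FALSE]
  fmt_col <- function(x) {
    if (is.double(x)) {
      out <- vapply(x, function(v) {
        if (is.na(v) || is.nan(v)) "NA" else format(v, digits = 6, scientific = FALSE,
                                                    trim = TRUE)
      }, character(1))
      out
    } else {
      out <- as.character(x)
      out[is.na(out)] <- "NA"
      out
    }
  }
  cells <- vapply(rows, fmt_col, character(nrow(rows)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con, sep = "\n")
  writeLines(paste(schema, collapse = "\t"), con, sep = "\n")
  if (nrow(rows) > 0) {
    if (nrow(rows) == 1L) cells <- matrix(cells, nrow = 1)
    writeLines(apply(cells, 1, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a TSV table written by [write_tsv_table()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}

#' Read a Vienna-style dot-bracket structure file
#'
#' Records are triples of lines: `>id`, sequence, then
#' `structure (energy)`; e.g. `"((((....)))) (-12.30)"`.
#'
#' @param path input path.
#' @return data.frame with columns `id`, `sequence`, `structure`, `energy`.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) %% 3 != 0) {
    stop(path, ": dot-bracket file must contain id/sequence/structure triples",
         call. = FALSE)
  }
  n <- length(lines) %/% 3
  ids <- sub("^>\\s*", "", lines[seq(1, by = 3, length.out = n)])
  seqs <- toupper(chartr("U", "T", lines[seq(2, by = 3, length.out = n)]))
  sl <- lines[seq(3, by = 3, length.out = n)]
  m <- regmatches(sl, regexec("^([().]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", sl))
  bad <- which(vapply(m, length, integer(1)) != 3)
  if (length(bad)) {
    stop(sprintf("%s: malformed structure line for record '%s'", path, ids[bad[1]]),
         call. = FALSE)
  }
  structure_str <- vapply(m, `[`, character(1), 2)
  energy <- as.numeric(vapply(m, `[`, character(1), 3))
  if (any(nchar(structure_str) != nchar(seqs))) {
    stop(path, ": structure length differs from sequence length", call. = FALSE)
  }
  data.frame(id = ids, sequence = seqs, structure = structure_str,
             energy = energy, stringsAsFactors = FALSE)
}

#' Write a Vienna-style dot-bracket structure file
#'
#' @param records data.frame with columns `id`, `sequence`, `structure`, `energy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(records, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(c(paste0(">", records$id[i]), records$sequence[i],
                 sprintf("%s (%.2f)", records$structure[i], records$energy[i])),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a key-value pipeline config (DCF format)
#'
#' @param path path to a `Key: value` DCF file.
#' @param allowed character vector of allowed keys; unknown keys are an error.
#' @return named list of character values.
#' @export
read_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  m <- read.dcf(path)
  out <- as.list(stats::setNames(as.character(m[1, ]), colnames(m)))
  if (!is.null(allowed)) {
    unknown <- setdiff(names(out), allowed)
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  out
}
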