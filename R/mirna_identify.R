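# Classify valid 18-26 nt tags: known mature miRNA, novel arm product
# (opposite arm of a known hairpin), other-species-derived known miRNA, or
# candidate novel locus to be screened by the hairpin criteria.

# Assign the arm of a tag interval within a precursor given the annotated
# mature. A tag on the opposite arm must not overlap the mature and must have
# >= 80% of its positions on the other side of the precursor midpoint.
opposite_arm_category <- function(tag_start, tag_end, mat_start, mat_end, pre_len) {
  overlap <- max(0L, min(tag_end, mat_end) - max(tag_start, mat_start))
  if (overlap > 0L) return(NA_character_)
  mid <- pre_len / 2
  mature_is_5p <- (mat_start + mat_end) / 2 < mid
  pos <- seq(tag_start, tag_end - 1L) + 0.5
  frac_other <- if (mature_is_5p) mean(pos > mid) else mean(pos < mid)
  if (frac_other >= 0.8) {
    if (mature_is_5p) "novel_arm_3p" else "novel_arm_5p"
  } else NA_character_
}

#' Map tags to miRNA precursors
#'
#' A hit is an ungapped alignment of the whole tag within a precursor with at
#' most one substitution. A tag overlapping an annotated mature with both end
#' shifts within `max_end_shift` is `known_mature`; a tag wholly on the arm
#' opposite the annotated mature is `novel_arm_5p`/`novel_arm_3p`. Tags
#' hitting a precursor without any mature annotation are flagged
#' `unannotated_precursor`. Tags with no hit are returned for the next stage.
#'
#' @param tags character vector of 18-26 nt tag sequences.
#' @param reference list from [read_mirbase_dialect()] (`precursors`,
#'   `annotations`).
#' @param max_end_shift maximum absolute 5'/3' end shift (nt) for a
#'   known-mature call.
#' @return list with `hits` (data.frame: tag, precursor_id, offset,
#'   mismatches, category, mature_id, end_shift_5p, end_shift_3p,
#'   multi_mapping) and `unmapped` (character vector).
#' @export
map_to_precursors <- function(tags, reference, max_end_shift = 4L) {
  pre <- reference$precursors
  ann <- reference$annotations
  rows <- list()
  mapped <- logical(length(tags))
  lens <- nchar(tags)
  # batch scan every (tag, precursor) pair, then annotate the sparse hits
  hitlist <- vector("list", length(tags))
  for (pi in seq_len(nrow(pre))) {
    pseq <- pre$sequence[pi]
    for (L in unique(lens)) {
      sel <- which(lens == L)
      bh <- batch_substitution_hits(tags[sel], pseq, 1L)
      for (r in seq_len(nrow(bh))) {
        ti <- sel[bh$tag_idx[r]]
        hitlist[[ti]] <- rbind(hitlist[[ti]],
                               data.frame(pi = pi, start = bh$start[r],
                                          mm = bh$mm[r]))
      }
    }
  }
  for (ti in seq_along(tags)) {
    tg <- tags[ti]
    tag_rows <- list()
    th <- hitlist[[ti]]
    for (hi in seq_len(if (is.null(th)) 0L else nrow(th))) {
      pi <- th$pi[hi]
      pid <- pre$id[pi]
      pseq <- pre$sequence[pi]
      pann <- ann[ann$precursor_id == pid, , drop = FALSE]
      {
        st <- th$start[hi]
        en <- st + nchar(tg)
        mm <- th$mm[hi]
        cat <- NA_character_; mat_id <- NA_character_
        s5 <- NA_integer_; s3 <- NA_integer_
        if (nrow(pann) == 0) {
          cat <- "unannotated_precursor"
        } else {
          # known_mature against any overlapping mature within shift bounds
          for (ai in seq_len(nrow(pann))) {
            shift5 <- st - pann$start[ai]
            shift3 <- en - pann$end[ai]
            overlap <- min(en, pann$end[ai]) - max(st, pann$start[ai])
            if (overlap > 0 && abs(shift5) <= max_end_shift &&
                abs(shift3) <= max_end_shift) {
              cat <- "known_mature"; mat_id <- pann$mature_id[ai]
              s5 <- shift5; s3 <- shift3
              break
            }
          }
          if (is.na(cat) && nrow(pann) == 1) {
            cat <- opposite_arm_category(st, en, pann$start[1], pann$end[1],
                                         nchar(pseq))
          }
        }
        if (!is.na(cat)) {
          tag_rows[[length(tag_rows) + 1L]] <- data.frame(
            tag = tg, precursor_id = pid, offset = st, mismatches = mm,
            category = cat, mature_id = mat_id, end_shift_5p = s5,
            end_shift_3p = s3, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(tag_rows)) {
      df <- do.call(rbind, tag_rows)
      df$multi_mapping <- nrow(df) > 1L
      rows[[length(rows) + 1L]] <- df
      mapped[ti] <- TRUE
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tag = character(0), precursor_id = character(0),
               offset = integer(0), mismatches = integer(0),
               category = character(0), mature_id = character(0),
               end_shift_5p = integer(0), end_shift_3p = integer(0),
               multi_mapping = logical(0), stringsAsFactors = FALSE)
  list(hits = hits, unmapped = tags[!mapped])
}

#' Map leftover tags to other-species precursors with genome confirmation
#'
#' Same alignment contract as [map_to_precursors()]; a hit is retained only
#' if its precursor also occurs exactly (either strand) in the
#' specific-species genome. Retained hits are known miRNAs of other-species
#' origin.
#'
#' @param tags character vector (unmapped from the previous stage).
#' @param other_reference reference bundle for other species, or NULL (stage
#'   is then the identity on the unmapped set).
#' @param genome data.frame as [read_fasta()] for the specific species.
#' @param max_end_shift see [map_to_precursors()].
#' @return list with `hits` (category "known_other_species") and `unmapped`.
#' @export
map_to_other_species <- function(tags, other_reference, genome,
                                 max_end_shift = 4L) {
  empty <- data.frame(tag = character(0), precursor_id = character(0),
                      offset = integer(0), mismatches = integer(0),
                      category = character(0), stringsAsFactors = FALSE)
  if (is.null(other_reference) || length(tags) == 0) {
    return(list(hits = empty, unmapped = tags))
  }
  res <- map_to_precursors(tags, other_reference, max_end_shift)
  hits <- res$hits
  if (nrow(hits) == 0) return(list(hits = empty, unmapped = tags))
  # precursor must occur exactly in the specific genome (either strand)
  pre <- other_reference$precursors
  confirmed <- vapply(unique(hits$precursor_id), function(pid) {
    pseq <- pre$sequence[pre$id == pid]
    any(vapply(seq_len(nrow(genome)), function(ci) {
      g <- genome$sequence[ci]
      length(exact_hits(pseq, g)) > 0 || length(exact_hits(revcomp(pseq), g)) > 0
    }, logical(1)))
  }, logical(1))
  ok_pre <- names(confirmed)[confirmed]
  hits <- hits[hits$precursor_id %in% ok_pre, , drop = FALSE]
  if (nrow(hits)) hits$category <- "known_other_species"
  retained_tags <- unique(hits$tag)
  list(hits = hits, unmapped = setdiff(tags, retained_tags))
}

#' Exact genome scan for tags
#'
#' Reports all exact occurrences of each tag on both strands; coordinates are
#' 0-based half-open on the forward strand (minus-strand hits report the
#' interval of the reverse-complement match).
#'
#' @param tags character vector of tag sequences.
#' @param genome data.frame as [read_fasta()].
#' @return data.frame with columns tag, contig, start, end, strand.
#' @export
genome_scan <- function(tags, genome) {
  rows <- list()
  for (ci in seq_len(nrow(genome))) {
    contig <- genome$id[ci]
    g <- genome$sequence[ci]
    for (tg in tags) {
      for (st in exact_hits(tg, g)) {
        rows[[length(rows) + 1L]] <- data.frame(
          tag = tg, contig = contig, start = st, end = st + nchar(tg),
          strand = "+", stringsAsFactors = FALSE)
      }
      rc <- revcomp(tg)
      for (st in exact_hits(rc, g)) {
        rows[[length(rows) + 1L]] <- data.frame(
          tag = tg, contig = contig, start = st, end = st + nchar(tg),
          strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(tag = character(0), contig = character(0), start = integer(0),
               end = integer(0), strand = character(0), stringsAsFactors = FALSE)
}

#' Extract candidate hairpin windows around a genome hit
#'
#' Window A spans `[start - flank, end)`, window B `[start, end + flank)`,
#' clipped at contig bounds; each carries the tag's mature-region
#' coordinates within the window. Minus-strand hits are returned in
#' transcript orientation (reverse complement of the forward interval).
#'
#' @param hit one row of the [genome_scan()] result.
#' @param genome data.frame as [read_fasta()].
#' @param flank flanking length in nt (default 80).
#' @return data.frame with columns window ("A"/"B"), sequence, mature_start,
#'   mature_end (0-based half-open within the window), contig_start,
#'   contig_end, strand.
#' @export
extract_hairpin_windows <- function(hit, genome, flank = 80L) {
  g <- genome$sequence[genome$id == hit$contig]
  if (length(g) != 1) stop("unknown contig: ", hit$contig, call. = FALSE)
  glen <- nchar(g)
  iv <- list(A = c(max(0L, hit$start - flank), hit$end),
             B = c(hit$start, min(glen, hit$end + flank)))
  rows <- lapply(names(iv), function(w) {
    a <- iv[[w]][1]; b <- iv[[w]][2]
    s <- substr(g, a + 1L, b)
    if (hit$strand == "+") {
      ms <- hit$start - a; me <- hit$end - a
    } else {
      s <- revcomp(s)
      ms <- b - hit$end; me <- b - hit$start
    }
    data.frame(window = w, sequence = s, mature_start = ms, mature_end = me,
               contig_start = a, contig_end = b, strand = hit$strand,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify valid tags into the identification categories
#'
#' Runs the sequential identification: specific-species precursors, then
#' other-species precursors with genome confirmation, then an exact genome
#' scan for novel-candidate loci. Category priority for multi-hit tags is
#' known_mature > novel_arm > known_other_species > novel_candidate.
#'
#' @param tags character vector of valid tags.
#' @param reference specific-species bundle from [read_mirbase_dialect()].
#' @param genome genome data.frame as [read_fasta()].
#' @param other_reference optional other-species bundle.
#' @param max_end_shift maximum end shift for known-mature calls.
#' @return list with `hits`, `categories` (data.frame tag -> primary
#'   category, mature_id), `genome_hits` (for novel candidates), `unplaced`.
#' @export
identify_tags <- function(tags, reference, genome, other_reference = NULL,
                          max_end_shift = 4L) {
  st1 <- map_to_precursors(tags, reference, max_end_shift)
  st2 <- map_to_other_species(st1$unmapped, other_reference, genome,
                              max_end_shift)
  gh <- genome_scan(st2$unmapped, genome)
  novel_tags <- unique(gh$tag)
  prio <- c(known_mature = 1, novel_arm_5p = 2, novel_arm_3p = 2,
            known_other_species = 3, unannotated_precursor = 4)
  primary <- function(df) {
    if (nrow(df) == 0) return(NULL)
    sp <- split(df, df$tag)
    do.call(rbind, lapply(sp, function(d) {
      d <- d[order(prio[d$category], d$mismatches), , drop = FALSE]
      d[1, c("tag", "category", if ("mature_id" %in% names(d)) "mature_id"),
        drop = FALSE]
    }))
  }
  cats <- list()
  p1 <- primary(st1$hits)
  if (!is.null(p1)) cats[[length(cats) + 1L]] <- p1
  p2 <- primary(st2$hits)
  if (!is.null(p2)) { p2$mature_id <- NA_character_; cats[[length(cats) + 1L]] <- p2 }
  if (length(novel_tags)) {
    cats[[length(cats) + 1L]] <- data.frame(
      tag = novel_tags, category = "novel_candidate", mature_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  categories <- if (length(cats)) do.call(rbind, cats) else
    data.frame(tag = character(0), category = character(0),
               mature_id = character(0), stringsAsFactors = FALSE)
  rownames(categories) <- NULL
  unplaced <- setdiff(tags, categories$tag)
  list(hits = rbind(st1$hits[, c("tag", "precursor_id", "offset", "mismatches",
                                 "category")],
                    st2$hits[, c("tag", "precursor_id", "offset", "mismatches",
                                 "category")]),
       categories = categories, genome_hits = gh, unplaced = unplaced)
}
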