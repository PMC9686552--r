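# Seed-match target prediction with a transparent two-channel scorer and
# the dual-threshold intersection filter (context-like score >= 50 AND
# duplex energy < -10), plus hypergeometric GO/KEGG enrichment with BH
# correction. The scorer deliberately replaces external context/alignment
# scorers with a documented 0-100 linear combination so the intersection
# semantics can be exercised and tested.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Scan a 3'-UTR for miRNA seed-match sites
#'
#' Finds every occurrence of the reverse complement of miRNA positions 2-7
#' (the 6mer core) and classifies each site: 8mer (2-8 match plus 'A'
#' opposite position 1), 7mer-m8 (2-8 match), 7mer-A1 (2-7 match plus 'A'),
#' else 6mer. Site position is the 0-based UTR start of the core match.
#'
#' @param mirna mature miRNA sequence (>= 8 nt, DNA alphabet).
#' @param utr 3'-UTR sequence (>= 8 nt).
#' @return data.frame: position (0-based), site_type.
#' @export
scan_sites <- function(mirna, utr) {
  mirna <- toupper(chartr("U", "T", mirna))
  utr <- toupper(chartr("U", "T", utr))
  if (nchar(mirna) < 8 || nchar(utr) < 8) {
    stop("miRNA and UTR must each be >= 8 nt", call. = FALSE)
  }
  core <- revcomp(substr(mirna, 2, 7))      # matches miRNA 2-7
  m8 <- revcomp(substr(mirna, 8, 8))        # UTR base opposite miRNA pos 8
  starts <- exact_hits(core, utr)
  if (!length(starts)) {
    return(data.frame(position = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE))
  }
  classify <- vapply(starts, function(p) {
    # p is 0-based; UTR base opposite position 8 sits 5' of the core match,
    # the base opposite position 1 sits immediately 3' of it
    up <- if (p >= 1) substr(utr, p, p) else ""
    dn <- if (p + 7 <= nchar(utr) - 1 + 1) substr(utr, p + 7, p + 7) else ""
    has_m8 <- identical(up, m8)
    has_a1 <- identical(dn, "A")
    if (has_m8 && has_a1) "8mer"
    else if (has_m8) "7mer-m8"
    else if (has_a1) "7mer-A1"
    else "6mer"
  }, character(1))
  data.frame(position = starts, site_type = classify, stringsAsFactors = FALSE)
}

# supplementary pairing: contiguous Watson-Crick matches of miRNA positions
# 13-17 against the UTR region just 5' of the seed site
supplementary_pairs <- function(mirna, utr, position) {
  region_end <- position - 2               # 0-based, leave a 2-nt gap
  sup <- revcomp(substr(mirna, 13, 17))
  if (region_end - nchar(sup) + 1 < 0) return(0L)
  window <- substr(utr, max(0, region_end - 6) + 1, region_end + 1)
  if (nchar(window) < nchar(sup)) return(0L)
  hits <- exact_hits(sup, window)
  if (length(hits)) 5L else {
    # longest suffix/prefix partial match
    best <- 0L
    for (k in 4:2) {
      if (length(exact_hits(substr(sup, 1, k), window))) { best <- k; break }
    }
    best
  }
}

#' Score a predicted site on both scorer channels
#'
#' The context-like score (0-100) is a documented linear combination:
#' site-type points (8mer 45, 7mer-m8 35, 7mer-A1 25, 6mer 15) + 40 x AU
#' fraction of the 30-nt flanks + 3 x supplementary pairing count (miRNA
#' positions 13-17), capped at 100. The duplex energy sums crude per-pair
#' stacking estimates (GC -3, AT -2, GU -1 kcal/mol) over the seed duplex
#' and supplementary pairs; 0 pairs give 0.
#'
#' @param mirna mature miRNA sequence.
#' @param utr 3'-UTR sequence.
#' @param position 0-based site position from [scan_sites()].
#' @param site_type site class from [scan_sites()].
#' @return list: context_like_score, duplex_energy.
#' @export
score_site <- function(mirna, utr, position, site_type) {
  mirna <- toupper(chartr("U", "T", mirna))
  utr <- toupper(chartr("U", "T", utr))
  type_points <- c("8mer" = 45, "7mer-m8" = 35, "7mer-A1" = 25, "6mer" = 15)
  flank_l <- substr(utr, max(1, position - 30 + 1), position)
  flank_r <- substr(utr, position + 7, min(nchar(utr), position + 6 + 30))
  fl <- paste0(flank_l, flank_r)
  au <- if (nchar(fl)) {
    bc <- base_counts(fl)
    (bc[1, "A"] + bc[1, "T"]) / nchar(fl)
  } else 0
  sup <- supplementary_pairs(mirna, utr, position)
  score <- min(100, unname(type_points[site_type]) + 40 * au + 3 * sup)
  # seed duplex: miRNA positions 2-7 always pair; position 8 pairs for
  # 8mer/7mer-m8
  seed_pos <- 2:7
  if (site_type %in% c("8mer", "7mer-m8")) seed_pos <- 2:8
  bases <- strsplit(substr(mirna, min(seed_pos), max(seed_pos)), "")[[1]]
  energy <- sum(ifelse(bases %in% c("G", "C"), -3, -2))
  if (sup > 0) {
    sup_bases <- strsplit(substr(mirna, 13, 12 + sup), "")[[1]]
    energy <- energy + sum(ifelse(sup_bases %in% c("G", "C"), -3, -2)) / 2
  }
  list(context_like_score = score, duplex_energy = energy)
}

#' Predict targets of a set of miRNAs over a UTR set
#'
#' Scans and scores every site; overlapping calls at the same position keep
#' the strongest class (already guaranteed by the classifier).
#'
#' @param mirnas named character vector: miRNA id -> sequence.
#' @param utrs named character vector: transcript id -> 3'-UTR sequence.
#' @return data.frame: mirna, transcript, position, site_type,
#'   context_like_score, duplex_energy, passes.
#' @export
predict_targets <- function(mirnas, utrs) {
  rows <- list()
  for (mi in names(mirnas)) {
    for (tx in names(utrs)) {
      sites <- scan_sites(mirnas[[mi]], utrs[[tx]])
      for (k in seq_len(nrow(sites))) {
        sc <- score_site(mirnas[[mi]], utrs[[tx]], sites$position[k],
                         sites$site_type[k])
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mi, transcript = tx, position = sites$position[k],
          site_type = sites$site_type[k],
          context_like_score = sc$context_like_score,
          duplex_energy = sc$duplex_energy, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0), transcript = character(0),
               position = integer(0), site_type = character(0),
               context_like_score = numeric(0), duplex_energy = numeric(0),
               stringsAsFactors = FALSE)
  out$passes <- out$context_like_score >= 50 & out$duplex_energy < -10
  out
}

#' Dual-threshold intersection filter
#'
#' Keeps predictions passing both scorer channels: context-like score >= 50
#' (inclusive) AND duplex energy < -10 (strict), the intersection semantics
#' of taking only targets called by both scorers.
#'
#' @param predictions data.frame from [predict_targets()].
#' @param score_threshold context-like score minimum (default 50).
#' @param energy_threshold duplex-energy maximum, exclusive (default -10).
#' @return the passing subset of `predictions`.
#' @export
intersect_filter <- function(predictions, score_threshold = 50,
                             energy_threshold = -10) {
  keep <- predictions$context_like_score >= score_threshold &
          predictions$duplex_energy < energy_threshold
  out <- predictions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric enrichment over an annotation table
#'
#' Per term, p = P(X >= k) for X hypergeometric with population N, K
#' annotated, n drawn; BH adjustment within each namespace; terms with
#' k = 0 are omitted.
#'
#' @param study character vector of study gene ids (must be a subset of the
#'   population).
#' @param population character vector of background gene ids (defaults to
#'   all genes in `annotations`).
#' @param annotations data.frame: gene_id, term_id, term_name, namespace
#'   (one of GO:BP, GO:MF, GO:CC, KEGG). Duplicated rows are ignored.
#' @return data.frame: term_id, term_name, namespace, k, K, n, N, p_value,
#'   bh_fdr; sorted by p then term_id.
#' @export
hypergeom_enrich <- function(study, population = NULL, annotations) {
  annotations <- unique(annotations[, c("gene_id", "term_id", "term_name",
                                        "namespace")])
  if (is.null(population)) population <- unique(annotations$gene_id)
  population <- unique(population)
  study <- unique(study)
  missing <- setdiff(study, population)
  if (length(missing)) {
    stop("study gene(s) absent from population: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  annotations <- annotations[annotations$gene_id %in% population, , drop = FALSE]
  N <- length(population)
  n <- length(study)
  terms <- unique(annotations[, c("term_id", "term_name", "namespace")])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tid <- terms$term_id[i]
    genes <- annotations$gene_id[annotations$term_id == tid]
    K <- length(unique(genes))
    k <- length(intersect(study, genes))
    if (k == 0) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, term_name = terms$term_name[i],
               namespace = terms$namespace[i], k = k, K = K, n = n, N = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      namespace = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      bh_fdr = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$bh_fdr <- NA_real_
  for (ns in unique(out$namespace)) {
    sel <- out$namespace == ns
    out$bh_fdr[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top enriched terms report
#'
#' @param enrichment data.frame from [hypergeom_enrich()].
#' @param top number of terms per namespace (default 20).
#' @return the top rows per namespace, ties broken by term_id.
#' @export
top_terms <- function(enrichment, top = 20) {
  do.call(rbind, lapply(split(enrichment, enrichment$namespace), function(d) {
    d <- d[order(d$p_value, d$term_id), , drop = FALSE]
    utils::head(d, top)
  }))
}
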