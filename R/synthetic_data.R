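# Deterministic, seeded generators for every input the pipeline needs, with
# machine-readable truth tables: a toy reference bundle (hairpin/mature
# FASTA + coordinates, contaminants, genome with planted novel hairpin
# loci), per-sample FASTQ reads with per-read origin labels, two-group count
# matrices with planted fold changes, and UTR/annotation sets for the
# target-prediction and enrichment stages.
#
# The stated world: 1 x 50 bp single-end reads (inserts shorter than 50
# carry 3' adapter), n = 3 animals per group, mature miRNAs ~22 nt on
# 25-bp-stem hairpins, planted differential expression of at least 4-fold.

ARM_LEN <- 25L
LOOP_LEN <- 8L
MATURE_LEN <- 22L

# verify a mature and all its end-shift variants are clean: never junk,
# composition leaves margin so a single substitution cannot create a junk
# call, and no window is within `min_mm` substitutions of the adapter prefix
mature_region_clean <- function(pre_seq, m_start, m_end, end_var, adapter,
                                min_mm = 3L) {
  L <- nchar(pre_seq)
  variants <- character(0)
  for (s5 in -end_var:end_var) for (s3 in -end_var:end_var) {
    a <- m_start + s5; b <- m_end + s3
    if (a < 0 || b > L || b - a < 18L || b - a > 26L) next
    variants <- c(variants, substr(pre_seq, a + 1L, b))
  }
  if (!length(variants)) return(FALSE)
  if (any(junk_filter(variants) != "keep")) return(FALSE)
  bc <- base_counts(variants)
  if (any(apply(bc[, 1:4, drop = FALSE], 1, max) / nchar(variants) > 0.7)) {
    return(FALSE)
  }
  if (any(bc[, "A"] + bc[, "C"] < 2L) || any(bc[, "G"] + bc[, "T"] < 2L)) {
    return(FALSE)
  }
  ap <- substr(adapter, 1L, 8L)
  mm <- window_mismatches(ap, pre_seq)
  if (length(mm) && min(mm) < min_mm) return(FALSE)
  TRUE
}

# Build a stem-loop with two planted asymmetries in the 3' arm (inside the
# region pairing with the mature) so the mature's reverse complement does
# NOT reoccur verbatim on the opposite arm; returns the sequence and its
# intended dot-bracket structure.
make_hairpin <- function(adapter, end_var = 4L) {
  bases <- c("A", "C", "G", "T")
  repeat {
    arm <- random_dna(1, ARM_LEN)
    loop <- random_dna(1, LOOP_LEN)
    rc_arm <- strsplit(revcomp(arm), "", fixed = TRUE)[[1]]
    arm_ch <- strsplit(arm, "", fixed = TRUE)[[1]]
    asym <- sort(sample(3:22, 2L))          # arm positions, inside the mature
    for (i in asym) {
      j <- ARM_LEN + 1L - i                 # pairing position in rc_arm
      ok_bases <- bases[!can_pair(rep(arm_ch[i], 4), bases)]
      rc_arm[j] <- sample(ok_bases, 1)
    }
    pre <- paste0(arm, loop, paste(rc_arm, collapse = ""))
    arm_db <- rep("(", ARM_LEN); arm_db[asym] <- "."
    rc_db <- rep(")", ARM_LEN); rc_db[ARM_LEN + 1L - asym] <- "."
    db <- paste0(paste(arm_db, collapse = ""), strrep(".", LOOP_LEN),
                 paste(rc_db, collapse = ""))
    ok5 <- mature_region_clean(pre, 1L, 1L + MATURE_LEN, end_var, adapter)
    ok3 <- mature_region_clean(pre, ARM_LEN + LOOP_LEN + 1L,
                               ARM_LEN + LOOP_LEN + 1L + MATURE_LEN,
                               end_var, adapter)
    if (ok5 && ok3) return(list(sequence = pre, structure = db))
  }
}

# ideal dot-bracket of the planted stem-loop inside a longer window
planted_structure <- function(window, hairpin_seq, hairpin_db) {
  p <- exact_hits(hairpin_seq, window)
  if (!length(p)) stop("hairpin not found in window", call. = FALSE)
  p <- p[1]
  paste0(strrep(".", p), hairpin_db,
         strrep(".", nchar(window) - p - nchar(hairpin_seq)))
}

#' Generate a synthetic reference bundle
#'
#' Builds stem-loop precursors (25-bp perfect stem, 8-nt loop) with annotated
#' ~22-nt matures alternating between arms, class-labeled contaminant
#' records, and a toy genome carrying planted novel hairpin loci with at
#' least 80-nt flanks. All outputs are reproducible bit-for-bit from the
#' seed. Sequences are vetted at construction so that mature-derived reads
#' are never junk, never contaminant-like, and never clipped early by
#' adapter trimming.
#'
#' @param out_dir output directory (created if needed).
#' @param n_precursors number of known precursors (>= 1).
#' @param n_contaminants number of contaminant records.
#' @param genome_length toy genome length in nt (>= 500).
#' @param n_novel number of planted novel hairpin loci.
#' @param seed integer seed.
#' @param adapter 3' adapter the read generator will use (sequences are
#'   vetted against its prefix).
#' @return list with file paths (hairpin_fasta, mature_fasta, coords_tsv,
#'   contaminant_fasta, genome_fasta, novel_tsv) and in-memory objects
#'   (`reference`, `contaminants`, `genome`, `novel`).
#' @export
generate_reference <- function(out_dir, n_precursors = 30L,
                               n_contaminants = 12L, genome_length = 10000L,
                               n_novel = 3L, seed = 1L,
                               adapter = TRUSEQ_SMALL_RNA_ADAPTER) {
  stopifnot(n_precursors >= 1, genome_length >= 500)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(seed, "reference"))
  # --- precursors + matures ------------------------------------------------
  pre_ids <- sprintf("syn-mir-%02d", seq_len(n_precursors))
  pre_seqs <- character(n_precursors)
  pre_structs <- character(n_precursors)
  ann <- vector("list", n_precursors)
  for (i in seq_len(n_precursors)) {
    hp_i <- make_hairpin(adapter)
    pre_seqs[i] <- hp_i$sequence
    pre_structs[i] <- hp_i$structure
    arm <- if (i %% 2 == 1) "5p" else "3p"
    if (arm == "5p") { a <- 1L; b <- 1L + MATURE_LEN }
    else { a <- ARM_LEN + LOOP_LEN + 1L; b <- a + MATURE_LEN }
    ann[[i]] <- data.frame(
      mature_id = paste0(pre_ids[i], "-", arm), precursor_id = pre_ids[i],
      start = a, end = b, arm = arm, stringsAsFactors = FALSE)
  }
  coords <- do.call(rbind, ann)
  matures <- data.frame(
    id = coords$mature_id, description = "",
    sequence = substr(pre_seqs[match(coords$precursor_id, pre_ids)],
                      coords$start + 1L, coords$end),
    stringsAsFactors = FALSE)
  # distinct matures so tag -> truth is unambiguous
  stopifnot(!anyDuplicated(matures$sequence))
  # --- contaminants --------------------------------------------------------
  cls <- rep(CONTAMINANT_CLASSES, length.out = n_contaminants)
  cont_seqs <- character(n_contaminants)
  ap <- substr(adapter, 1L, 8L)
  for (i in seq_len(n_contaminants)) {
    repeat {
      s <- random_dna(1, 300L)
      mm <- window_mismatches(ap, s)
      near_mature <- any(vapply(matures$sequence, function(m) {
        length(scan_substitution_hits(m, s, 1L)) > 0 ||
          length(scan_substitution_hits(m, revcomp(s), 1L)) > 0
      }, logical(1)))
      if (min(mm) >= 3L && !near_mature) { cont_seqs[i] <- s; break }
    }
  }
  contaminants <- data.frame(
    id = sprintf("contam-%02d", seq_len(n_contaminants)),
    description = cls, sequence = cont_seqs, rna = FALSE,
    stringsAsFactors = FALSE)
  # --- genome with planted novel loci -------------------------------------
  flank <- 80L
  hp_len <- 2L * ARM_LEN + LOOP_LEN
  need <- n_novel * (hp_len + 2L * flank)
  if (genome_length < need + 100L) {
    stop("genome_length too short for ", n_novel, " planted loci (need >= ",
         need + 100L, ")", call. = FALSE)
  }
  novel_rows <- vector("list", n_novel)
  repeat {
    genome_seq <- random_dna(1, genome_length)
    slot <- genome_length %/% n_novel
    ok <- TRUE
    for (i in seq_len(n_novel)) {
      hp_obj <- make_hairpin(adapter)
      hp <- hp_obj$sequence
      # mature at hairpin offset 0 so the downstream 80-nt window contains
      # the whole stem-loop
      mat <- substr(hp, 1L, MATURE_LEN)
      # planted mature must not look like a known miRNA or contaminant
      near_known <- any(vapply(pre_seqs, function(p) {
        length(scan_substitution_hits(mat, p, 1L)) > 0
      }, logical(1)))
      if (near_known) { ok <- FALSE; break }
      pos <- (i - 1L) * slot + flank + sample.int(slot - hp_len - 2L * flank, 1)
      genome_seq <- paste0(substr(genome_seq, 1L, pos),
                           hp,
                           substr(genome_seq, pos + hp_len + 1L, genome_length))
      novel_rows[[i]] <- data.frame(
        locus_id = sprintf("novel-%02d", i), contig = "chr_syn",
        start = pos, end = pos + hp_len, strand = "+",
        mature_start = pos, mature_end = pos + MATURE_LEN,
        mature_sequence = mat, hairpin_sequence = hp,
        hairpin_structure = hp_obj$structure, stringsAsFactors = FALSE)
    }
    if (!ok) next
    # each planted mature must occur exactly once in the genome
    counts <- vapply(novel_rows, function(r) {
      length(exact_hits(r$mature_sequence, genome_seq)) +
        length(exact_hits(revcomp(r$mature_sequence), genome_seq))
    }, integer(1))
    # and known matures must not occur in the genome (keeps categories clean)
    known_in_genome <- any(vapply(matures$sequence, function(m) {
      length(exact_hits(m, genome_seq)) > 0 ||
        length(exact_hits(revcomp(m), genome_seq)) > 0
    }, logical(1)))
    if (all(counts == 1L) && !known_in_genome) break
  }
  novel <- do.call(rbind, novel_rows)
  genome <- data.frame(id = "chr_syn", description = "synthetic toy genome",
                       sequence = genome_seq, rna = FALSE,
                       stringsAsFactors = FALSE)
  # --- write files ---------------------------------------------------------
  paths <- list(
    hairpin_fasta = file.path(out_dir, "hairpin.fa"),
    mature_fasta = file.path(out_dir, "mature.fa"),
    coords_tsv = file.path(out_dir, "mature_coords.tsv"),
    contaminant_fasta = file.path(out_dir, "contaminants.fa"),
    genome_fasta = file.path(out_dir, "genome.fa"),
    novel_tsv = file.path(out_dir, "novel_loci.tsv"))
  write_fasta(data.frame(id = pre_ids, description = "", sequence = pre_seqs,
                         rna = FALSE, stringsAsFactors = FALSE),
              paths$hairpin_fasta)
  write_fasta(matures, paths$mature_fasta)
  write_tsv_table(coords[, c("mature_id", "precursor_id", "start", "end", "arm")],
                  paths$coords_tsv,
                  comment = "0-based half-open coordinates within precursor")
  write_fasta(contaminants, paths$contaminant_fasta)
  write_fasta(genome, paths$genome_fasta)
  write_tsv_table(novel, paths$novel_tsv,
                  comment = "0-based half-open genome coordinates")
  reference <- list(
    precursors = data.frame(id = pre_ids, description = "",
                            sequence = pre_seqs, rna = FALSE,
                            stringsAsFactors = FALSE),
    annotations = data.frame(precursor_id = coords$precursor_id,
                             mature_id = coords$mature_id, arm = coords$arm,
                             start = coords$start, end = coords$end,
                             mature_sequence = matures$sequence,
                             stringsAsFactors = FALSE))
  c(paths, list(reference = reference, contaminants = contaminants,
                genome = genome, novel = novel, adapter = adapter,
                precursor_structures = stats::setNames(pre_structs, pre_ids)))
}

#' Default read-simulation design
#'
#' Six samples, two groups of three, 50-nt single-end reads.
#'
#' @param n_reads reads per sample.
#' @param seed integer seed.
#' @return list of design parameters (see [generate_reads()]).
#' @export
read_sim_design <- function(n_reads = 10000L, seed = 1L) {
  list(
    samples = stats::setNames(rep(c("A", "B"), each = 3),
                              c("A1", "A2", "A3", "B1", "B2", "B3")),
    n_reads = n_reads,
    fractions = c(known = 0.70, novel = 0.05, contaminant = 0.10,
                  junk = 0.10, adapter_dimer = 0.05),
    end_var = 2L, mismatch_rate = 0.10,
    # planted expression structure over the known matures: lognormal
    # baseline abundances plus a DEM subset with a 4-fold between-group
    # ratio (half up, half down)
    n_dem_matures = 10L, dem_fold = 4, weight_sd_log2 = 1,
    adapter = TRUSEQ_SMALL_RNA_ADAPTER, read_length = 50L, seed = seed)
}

validate_read_design <- function(design) {
  fr <- design$fractions
  need <- c("known", "novel", "contaminant", "junk", "adapter_dimer")
  stopifnot(all(need %in% names(fr)))
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("composition fractions must be in [0,1] and sum to 1", call. = FALSE)
  }
  if (design$n_reads <= 0) stop("read count must be > 0", call. = FALSE)
  if (nchar(design$adapter) < 6) stop("adapter shorter than 6 nt", call. = FALSE)
  invisible(design)
}

make_junk_insert <- function() {
  kind <- sample(c("poly", "dimer", "trimer", "nrich", "short"), 1)
  switch(kind,
    poly = strrep(sample(c("A", "C", "G", "T"), 1), 20L),
    dimer = {
      u <- paste(sample(c("A", "C", "G", "T"), 2), collapse = "")
      substr(strrep(u, 11L), 1L, 20L)
    },
    trimer = {
      u <- paste(sample(c("A", "C", "G", "T"), 3), collapse = "")
      substr(strrep(u, 8L), 1L, 21L)
    },
    nrich = {
      s <- strsplit(random_dna(1, 20L), "")[[1]]
      s[sample(20L, 3L)] <- "N"
      paste(s, collapse = "")
    },
    short = random_dna(1, sample(5:17, 1)))
}

#' Generate per-sample FASTQ reads with a truth table
#'
#' Known-miRNA reads are mature sequences with uniform end shifts (kept
#' within the 18-26 nt window) and Bernoulli single substitutions; novel
#' reads are the matures of planted novel loci; contaminant reads are exact
#' windows of contaminant records; junk reads satisfy one junk rule by
#' construction; adapter-dimer reads start with the adapter. Inserts shorter
#' than the read length carry the 3' adapter and an A-tail pad.
#'
#' @param design list from [read_sim_design()].
#' @param reference bundle from [generate_reference()].
#' @param out_dir directory for FASTQ files and the truth TSV.
#' @return list: fastq (named paths), truth_tsv, truth (data.frame: read_id,
#'   sample, category, source_id, shift5, shift3, mismatches, insert).
#' @export
generate_reads <- function(design, reference, out_dir) {
  validate_read_design(design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(design$seed, "reads"))
  ann <- reference$reference$annotations
  pre_seq <- stats::setNames(reference$reference$precursors$sequence,
                             reference$reference$precursors$id)
  cont <- reference$contaminants
  novel <- reference$novel
  cats <- names(design$fractions)
  # planted expression structure over the known matures
  n_mat <- nrow(ann)
  n_dem <- min(design$n_dem_matures %||% 0L, n_mat)
  w_base <- 2^stats::rnorm(n_mat, 0, design$weight_sd_log2 %||% 0)
  dem_idx <- if (n_dem > 0) sort(sample.int(n_mat, n_dem)) else integer(0)
  dem_dir <- rep(c("up", "down"), length.out = n_dem)
  lfc <- rep(0, n_mat)
  if (n_dem > 0) {
    lfc[dem_idx] <- ifelse(dem_dir == "up", log2(design$dem_fold),
                           -log2(design$dem_fold))
  }
  w_A <- w_base * 2^(lfc / 2)
  w_B <- w_base * 2^(-lfc / 2)
  dem_truth <- data.frame(mature_id = ann$mature_id[dem_idx],
                          direction = dem_dir,
                          fold = rep(design$dem_fold %||% NA_real_,
                                     length(dem_idx)),
                          stringsAsFactors = FALSE)
  fastq_paths <- character(0)
  truth_all <- list()
  for (s in names(design$samples)) {
    n <- design$n_reads
    w <- if (design$samples[[s]] == "A") w_A else w_B
    category <- sample(cats, n, replace = TRUE, prob = design$fractions)
    seqs <- character(n); src <- character(n)
    sh5 <- integer(n); sh3 <- integer(n); mm <- integer(n)
    for (r in seq_len(n)) {
      cat_r <- category[r]
      if (cat_r == "known") {
        ai <- sample.int(n_mat, 1, prob = w)
        ps <- pre_seq[[ann$precursor_id[ai]]]
        repeat {
          a <- ann$start[ai] + sample(-design$end_var:design$end_var, 1)
          b <- ann$end[ai] + sample(-design$end_var:design$end_var, 1)
          if (a >= 0 && b <= nchar(ps) && b - a >= 18L && b - a <= 26L) break
        }
        insert <- substr(ps, a + 1L, b)
        nmm <- 0L
        if (stats::runif(1) < design$mismatch_rate) {
          pos <- sample(2:(nchar(insert) - 1L), 1)
          old <- substr(insert, pos, pos)
          substr(insert, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
          nmm <- 1L
        }
        seqs[r] <- insert; src[r] <- ann$mature_id[ai]
        sh5[r] <- a - ann$start[ai]; sh3[r] <- b - ann$end[ai]; mm[r] <- nmm
      } else if (cat_r == "novel") {
        ni <- sample.int(nrow(novel), 1)
        seqs[r] <- novel$mature_sequence[ni]; src[r] <- novel$locus_id[ni]
      } else if (cat_r == "contaminant") {
        ci <- sample.int(nrow(cont), 1)
        wlen <- sample(20:24, 1)
        p <- sample.int(nchar(cont$sequence[ci]) - wlen, 1)
        seqs[r] <- substr(cont$sequence[ci], p, p + wlen - 1L)
        src[r] <- cont$id[ci]
      } else if (cat_r == "junk") {
        seqs[r] <- make_junk_insert(); src[r] <- "junk"
      } else {
        seqs[r] <- ""; src[r] <- "adapter_dimer"
      }
    }
    read_seq <- paste0(seqs, design$adapter)
    short <- nchar(read_seq) < design$read_length
    pad <- strrep("A", design$read_length)
    read_seq <- substr(paste0(read_seq, pad), 1L, design$read_length)
    ids <- sprintf("%s_r%06d", s, seq_len(n))
    fq <- data.frame(id = ids, sequence = read_seq,
                     quality = strrep("I", nchar(read_seq)),
                     stringsAsFactors = FALSE)
    path <- file.path(out_dir, paste0(s, ".fastq"))
    write_fastq(fq, path)
    fastq_paths[s] <- path
    truth_all[[s]] <- data.frame(
      read_id = ids, sample = s, category = category, source_id = src,
      shift5 = sh5, shift3 = sh3, mismatches = mm, insert = seqs,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_all)
  rownames(truth) <- NULL
  truth_tsv <- file.path(out_dir, "read_truth.tsv")
  write_tsv_table(truth, truth_tsv)
  dem_truth_tsv <- file.path(out_dir, "dem_truth.tsv")
  write_tsv_table(dem_truth, dem_truth_tsv)
  list(fastq = fastq_paths, truth_tsv = truth_tsv, truth = truth,
       dem_truth = dem_truth, dem_truth_tsv = dem_truth_tsv,
       groups = design$samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default count-simulation design
#'
#' Two groups of three replicates; per-miRNA baselines drawn lognormal
#' (log2 mean 8, log2 sd 2); planted fold changes of 4 (at least 2 by
#' contract); lognormal replicate noise with log2-scale sd 0.2.
#'
#' @param n_mirnas number of miRNAs.
#' @param n_dem number of planted DEMs.
#' @param fold planted fold change (>= 2).
#' @param noise_sd lognormal replicate noise, sd on the log2 scale.
#' @param n_rep replicates per group.
#' @param seed integer seed.
#' @return design list for [generate_counts()].
#' @export
count_sim_design <- function(n_mirnas = 2000L, n_dem = 100L, fold = 4,
                             noise_sd = 0.2, n_rep = 3L, seed = 1L) {
  list(n_mirnas = n_mirnas, n_dem = n_dem, fold = fold, noise_sd = noise_sd,
       n_rep = n_rep, base_mean_log2 = 8, base_sd_log2 = 2, seed = seed)
}

#' Generate a two-group count matrix with planted fold changes
#'
#' Non-DEM miRNAs share group means; planted DEMs differ by the design fold
#' change (half up in A, half down), with lognormal replicate noise. Values
#' emulate normalized copy numbers ("norm values").
#'
#' @param design list from [count_sim_design()].
#' @param out_dir optional directory; when given, writes matrix and truth TSV.
#' @return list: counts (matrix, miRNA x sample), truth (data.frame: mirna,
#'   direction, fold; empty when no DEMs planted), groups (named vector),
#'   plus file paths when `out_dir` is given.
#' @export
generate_counts <- function(design, out_dir = NULL) {
  stopifnot(design$fold >= 2, design$n_rep >= 2,
            design$n_dem <= design$n_mirnas)
  set.seed(derive_seed(design$seed, "counts"))
  n <- design$n_mirnas
  ids <- sprintf("mir-%05d", seq_len(n))
  base <- stats::rnorm(n, design$base_mean_log2, design$base_sd_log2)
  dem_idx <- if (design$n_dem > 0) sort(sample.int(n, design$n_dem)) else integer(0)
  dirs <- rep(c("up", "down"), length.out = length(dem_idx))
  lfc <- rep(0, n)
  lfc[dem_idx] <- ifelse(dirs == "up", log2(design$fold), -log2(design$fold))
  mu_a <- base + lfc / 2
  mu_b <- base - lfc / 2
  samples <- c(paste0("A", seq_len(design$n_rep)),
               paste0("B", seq_len(design$n_rep)))
  groups <- stats::setNames(rep(c("A", "B"), each = design$n_rep), samples)
  counts <- matrix(0, nrow = n, ncol = length(samples),
                   dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    mu <- if (groups[j] == "A") mu_a else mu_b
    counts[, j] <- 2^(stats::rnorm(n, mu, design$noise_sd))
  }
  truth <- data.frame(mirna = ids[dem_idx], direction = dirs,
                      fold = rep(design$fold, length(dem_idx)),
                      stringsAsFactors = FALSE)
  out <- list(counts = counts, truth = truth, groups = groups)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    mat <- data.frame(mirna = ids, counts, stringsAsFactors = FALSE,
                      check.names = FALSE)
    out$counts_tsv <- write_tsv_table(mat, file.path(out_dir, "counts.tsv"))
    out$truth_tsv <- write_tsv_table(truth, file.path(out_dir, "dem_truth.tsv"))
  }
  out
}

#' Generate 3'-UTR sequences with planted seed sites
#'
#' Each synthetic gene gets an AT-biased random UTR; a subset of genes gets
#' an 8mer site for one miRNA planted in an AU-rich context.
#'
#' @param mirnas named character vector: miRNA id -> mature sequence.
#' @param n_genes number of genes.
#' @param target_fraction fraction of genes receiving a planted site.
#' @param utr_length UTR length in nt.
#' @param seed integer seed.
#' @return list: utrs (named vector gene -> sequence), truth (data.frame:
#'   gene_id, mirna, position).
#' @export
generate_utrs <- function(mirnas, n_genes = 60L, target_fraction = 0.5,
                          utr_length = 300L, seed = 1L) {
  set.seed(derive_seed(seed, "utrs"))
  genes <- sprintf("gene-%03d", seq_len(n_genes))
  utrs <- vapply(seq_len(n_genes), function(i) {
    paste(sample(c("A", "T", "C", "G"), utr_length, replace = TRUE,
                 prob = c(0.32, 0.32, 0.18, 0.18)), collapse = "")
  }, character(1))
  names(utrs) <- genes
  n_target <- round(target_fraction * n_genes)
  rows <- list()
  if (n_target > 0 && length(mirnas) > 0) {
    targets <- sample(genes, n_target)
    for (g in targets) {
      mi <- sample(names(mirnas), 1)
      site <- paste0(revcomp(substr(mirnas[[mi]], 2, 8)), "A")  # 8mer
      pos <- sample(seq(40L, utr_length - 40L), 1)
      u <- utrs[[g]]
      utrs[[g]] <- paste0(substr(u, 1, pos), site,
                          substr(u, pos + nchar(site) + 1L, utr_length))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, mirna = mi, position = pos + 1L, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), mirna = character(0),
               position = integer(0), stringsAsFactors = FALSE)
  list(utrs = utrs, truth = truth)
}

#' Generate a GO/KEGG-style annotation table
#'
#' @param gene_ids character vector of gene ids.
#' @param n_terms_per_ns terms per namespace.
#' @param seed integer seed.
#' @return data.frame: gene_id, term_id, term_name, namespace.
#' @export
generate_annotations <- function(gene_ids, n_terms_per_ns = 5L, seed = 1L) {
  set.seed(derive_seed(seed, "annotations"))
  namespaces <- c("GO:BP", "GO:MF", "GO:CC", "KEGG")
  rows <- list()
  for (ns in namespaces) {
    for (t in seq_len(n_terms_per_ns)) {
      tid <- sprintf("%s:%04d", sub("GO:", "GO", ns), t)
      size <- sample(3:max(4, length(gene_ids) %/% 3), 1)
      genes <- sample(gene_ids, min(size, length(gene_ids)))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes, term_id = tid,
        term_name = paste0("synthetic term ", tid), namespace = ns,
        stringsAsFactors = FALSE)
    }
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
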