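# End-to-end orchestration: simulate a fixture, then run
# preprocess -> identify -> hairpin -> normalize -> diffexp -> targets ->
# enrich, each stage writing TSVs plus a manifest with input hashes and
# parameters. Reruns with identical inputs are byte-identical; stages whose
# manifests match are skipped.

PIPELINE_KEYS <- c(
  "sample_manifest", "hairpin_fasta", "mature_fasta", "coords_tsv",
  "contaminant_fasta", "genome_fasta", "utr_fasta", "annotation_tsv",
  "out_dir", "adapter", "min_overlap", "max_end_shift", "flank", "backend",
  "structure_file", "min_common_copy", "delta", "eps", "fc_threshold",
  "p_threshold", "score_threshold", "energy_threshold", "top_terms",
  "contrast", "seed")

#' Default pipeline parameters
#'
#' Thresholds default to the values the method prescribes: 18-26 nt tags,
#' one mismatch, 80-nt folding flanks, |delta log2| < 2 regression subset,
#' DEM gate |log2FC| >= 1 and p < 0.05, target intersection score >= 50 and
#' energy < -10.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(adapter = TRUSEQ_SMALL_RNA_ADAPTER, min_overlap = 8L,
       max_end_shift = 4L, flank = 80L, backend = "builtin",
       structure_file = "", min_common_copy = 1, delta = 2, eps = 1,
       fc_threshold = 1, p_threshold = 0.05, score_threshold = 50,
       energy_threshold = -10, top_terms = 20L, contrast = "A_vs_B",
       seed = 1L)
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config, allowed = PIPELINE_KEYS)
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  num_keys <- c("min_overlap", "max_end_shift", "flank", "min_common_copy",
                "delta", "eps", "fc_threshold", "p_threshold",
                "score_threshold", "energy_threshold", "top_terms", "seed")
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  required <- c("sample_manifest", "hairpin_fasta", "mature_fasta",
                "coords_tsv", "contaminant_fasta", "genome_fasta", "out_dir")
  for (k in required) {
    if (is.null(cfg[[k]])) stop("missing config key: ", k, call. = FALSE)
  }
  for (k in setdiff(required, "out_dir")) {
    if (!file.exists(cfg[[k]])) {
      stop("config key '", k, "' points to missing file: ", cfg[[k]],
           call. = FALSE)
    }
  }
  cfg
}

stage_manifest <- function(dir, stage, inputs, params) {
  hashes <- vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  df <- data.frame(
    key = c(paste0("input:", basename(inputs)), paste0("param:", names(params))),
    value = c(unname(hashes), vapply(params, function(x)
      paste(format(x, digits = 15), collapse = ","), character(1))),
    stringsAsFactors = FALSE)
  df[order(df$key), , drop = FALSE]
}

stage_up_to_date <- function(dir, stage, manifest, outputs) {
  mf <- file.path(dir, paste0(stage, ".manifest.tsv"))
  if (!file.exists(mf) || !all(file.exists(outputs))) return(FALSE)
  old <- tryCatch(read_tsv_table(mf), error = function(e) NULL)
  !is.null(old) && isTRUE(all.equal(old$key, manifest$key)) &&
    isTRUE(all.equal(old$value, manifest$value))
}

write_stage_manifest <- function(dir, stage, manifest) {
  write_tsv_table(manifest, file.path(dir, paste0(stage, ".manifest.tsv")))
}

log_stage <- function(...) message("[mirexo] ", ...)

#' Run the full pipeline
#'
#' @param config path to a DCF config file or a named list; see
#'   [pipeline_defaults()] and the package vignette for keys. Required keys:
#'   sample_manifest (TSV: sample, group, fastq), hairpin_fasta,
#'   mature_fasta, coords_tsv, contaminant_fasta, genome_fasta, out_dir;
#'   optional utr_fasta + annotation_tsv enable the target/enrichment
#'   stages.
#' @return invisibly, a list of stage output paths.
#' @export
pipeline_run <- function(config) {
  cfg <- load_pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- read_tsv_table(cfg$sample_manifest)
  need <- c("sample", "group", "fastq")
  if (!all(need %in% names(manifest))) {
    stop("sample manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  # resolve fastq paths relative to the manifest location
  rel <- !file.exists(manifest$fastq)
  manifest$fastq[rel] <- file.path(dirname(cfg$sample_manifest),
                                   manifest$fastq[rel])
  if (!all(file.exists(manifest$fastq))) {
    stop("missing FASTQ file(s): ",
         paste(manifest$fastq[!file.exists(manifest$fastq)], collapse = ", "),
         call. = FALSE)
  }
  paths <- list()

  # --- stage: preprocess ---------------------------------------------------
  tags_tsv <- file.path(out, "tags.tsv")
  stats_tsv <- file.path(out, "filter_stats.tsv")
  mfst <- stage_manifest(out, "preprocess",
                         c(cfg$sample_manifest, manifest$fastq,
                           cfg$contaminant_fasta),
                         cfg[c("adapter", "min_overlap")])
  if (!stage_up_to_date(out, "preprocess", mfst, c(tags_tsv, stats_tsv))) {
    log_stage("preprocess: ", nrow(manifest), " samples")
    contaminants <- read_fasta(cfg$contaminant_fasta)
    pp <- preprocess_samples(stats::setNames(manifest$fastq, manifest$sample),
                             adapter = cfg$adapter,
                             contaminants = contaminants,
                             min_overlap = cfg$min_overlap)
    write_tsv_table(pp$tags, tags_tsv)
    write_tsv_table(pp$stats, stats_tsv)
    write_stage_manifest(out, "preprocess", mfst)
  } else log_stage("preprocess: up to date, skipped")
  paths$tags <- tags_tsv; paths$filter_stats <- stats_tsv

  # --- stage: identify -----------------------------------------------------
  cat_tsv <- file.path(out, "tag_categories.tsv")
  counts_tsv <- file.path(out, "mirna_counts.tsv")
  ghits_tsv <- file.path(out, "novel_genome_hits.tsv")
  mfst <- stage_manifest(out, "identify",
                         c(tags_tsv, cfg$hairpin_fasta, cfg$mature_fasta,
                           cfg$coords_tsv, cfg$genome_fasta),
                         cfg["max_end_shift"])
  if (!stage_up_to_date(out, "identify", mfst,
                        c(cat_tsv, counts_tsv, ghits_tsv))) {
    reference <- read_mirbase_dialect(cfg$hairpin_fasta, cfg$mature_fasta,
                                      cfg$coords_tsv)
    genome <- read_fasta(cfg$genome_fasta)
    tags <- read_tsv_table(tags_tsv)
    log_stage("identify: ", nrow(tags), " tags")
    idr <- identify_tags(tags$sequence, reference, genome,
                         max_end_shift = cfg$max_end_shift)
    write_tsv_table(idr$categories, cat_tsv)
    write_tsv_table(idr$genome_hits, ghits_tsv)
    # aggregate known-mature tag copies into a miRNA x sample matrix
    known <- idr$categories[idr$categories$category == "known_mature", ]
    sample_cols <- setdiff(names(tags), "sequence")
    merged <- merge(known[, c("tag", "mature_id")], tags,
                    by.x = "tag", by.y = "sequence")
    agg <- stats::aggregate(merged[, sample_cols, drop = FALSE],
                            by = list(mirna = merged$mature_id), FUN = sum)
    agg <- agg[order(agg$mirna), , drop = FALSE]
    write_tsv_table(agg, counts_tsv)
    write_stage_manifest(out, "identify", mfst)
  } else log_stage("identify: up to date, skipped")
  paths$categories <- cat_tsv; paths$counts <- counts_tsv

  # --- stage: hairpin (novel candidates) -----------------------------------
  novel_tsv <- file.path(out, "novel_accepted.tsv")
  crit_tsv <- file.path(out, "novel_criteria.tsv")
  mfst <- stage_manifest(out, "hairpin",
                         c(ghits_tsv, cfg$genome_fasta,
                           if (nzchar(cfg$structure_file)) cfg$structure_file),
                         cfg[c("flank", "backend")])
  if (!stage_up_to_date(out, "hairpin", mfst, c(novel_tsv, crit_tsv))) {
    gh <- read_tsv_table(ghits_tsv)
    log_stage("hairpin: ", nrow(gh), " genome hits")
    genome <- read_fasta(cfg$genome_fasta)
    winlist <- lapply(seq_len(nrow(gh)), function(i) {
      w <- extract_hairpin_windows(gh[i, ], genome, flank = cfg$flank)
      w$tag <- gh$tag[i]
      w
    })
    windows <- if (length(winlist)) do.call(rbind, winlist) else
      data.frame(tag = character(0), window = character(0),
                 sequence = character(0), mature_start = integer(0),
                 mature_end = integer(0), stringsAsFactors = FALSE)
    structures <- if (nzchar(cfg$structure_file))
      read_dotbracket(cfg$structure_file) else NULL
    sc <- screen_candidates(windows,
                            backend = if (is.null(structures)) "builtin" else "file",
                            structures = structures)
    write_tsv_table(sc$accepted, novel_tsv)
    crit_rows <- lapply(names(sc$reports), function(k) {
      r <- sc$reports[[k]]
      if (is.data.frame(r)) {
        data.frame(candidate = k, criterion = r$criterion, name = r$name,
                   observed = r$observed, threshold = r$threshold,
                   pass = r$pass, stringsAsFactors = FALSE)
      } else {
        data.frame(candidate = k, criterion = NA_integer_, name = "rejected",
                   observed = NA_real_, threshold = NA_real_, pass = FALSE,
                   stringsAsFactors = FALSE)
      }
    })
    crit <- if (length(crit_rows)) do.call(rbind, crit_rows) else
      data.frame(candidate = character(0), criterion = integer(0),
                 name = character(0), observed = numeric(0),
                 threshold = numeric(0), pass = logical(0),
                 stringsAsFactors = FALSE)
    crit <- crit[order(crit$candidate, crit$criterion), , drop = FALSE]
    write_tsv_table(crit, crit_tsv)
    write_stage_manifest(out, "hairpin", mfst)
  } else log_stage("hairpin: up to date, skipped")
  paths$novel <- novel_tsv; paths$criteria <- crit_tsv

  # --- stage: normalize ----------------------------------------------------
  norm_tsv <- file.path(out, "norm_values.tsv")
  model_tsv <- file.path(out, "norm_model.tsv")
  mfst <- stage_manifest(out, "normalize", counts_tsv,
                         cfg[c("min_common_copy", "delta")])
  if (!stage_up_to_date(out, "normalize", mfst, c(norm_tsv, model_tsv))) {
    cm <- read_tsv_table(counts_tsv)
    counts <- as.matrix(cm[, -1, drop = FALSE])
    rownames(counts) <- cm$mirna
    log_stage("normalize: ", nrow(counts), " miRNAs x ", ncol(counts),
              " samples")
    model <- fit_normalization(counts, min_copy = cfg$min_common_copy,
                               delta = cfg$delta)
    normalized <- apply_normalization(counts, model)
    nm <- data.frame(mirna = rownames(normalized), normalized,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_table(nm, norm_tsv)
    md <- do.call(rbind, lapply(names(model$fits), function(s) {
      f <- model$fits[[s]]
      data.frame(sample = s, a = f$a, b = f$b, x_mid = f$x_mid,
                 delta_y = f$delta_y, f = f$f, subset_size = length(f$subset),
                 stringsAsFactors = FALSE)
    }))
    write_tsv_table(md, model_tsv)
    write_stage_manifest(out, "normalize", mfst)
  } else log_stage("normalize: up to date, skipped")
  paths$norm <- norm_tsv; paths$norm_model <- model_tsv

  # --- stage: diffexp ------------------------------------------------------
  de_tsv <- file.path(out, "de_results.tsv")
  sum_tsv <- file.path(out, "de_summary.tsv")
  volc_tsv <- file.path(out, "volcano.tsv")
  heat_tsv <- file.path(out, "heatmap.tsv")
  mfst <- stage_manifest(out, "diffexp", c(norm_tsv, cfg$sample_manifest),
                         cfg[c("eps", "fc_threshold", "p_threshold",
                               "contrast")])
  if (!stage_up_to_date(out, "diffexp",
                        mfst, c(de_tsv, sum_tsv, volc_tsv, heat_tsv))) {
    nm <- read_tsv_table(norm_tsv)
    normalized <- as.matrix(nm[, -1, drop = FALSE])
    rownames(normalized) <- nm$mirna
    groups <- stats::setNames(manifest$group, manifest$sample)
    log_stage("diffexp: contrast ", cfg$contrast)
    res <- de_test(normalized, groups, eps = cfg$eps)
    called <- call_dems(res, contrast = cfg$contrast,
                        fc_threshold = cfg$fc_threshold,
                        p_threshold = cfg$p_threshold)
    write_tsv_table(called$results, de_tsv)
    write_tsv_table(called$summary, sum_tsv)
    export_volcano(called$results, volc_tsv)
    export_heatmap_matrix(normalized,
                          called$results$mirna[called$results$is_dem],
                          heat_tsv, eps = cfg$eps)
    write_stage_manifest(out, "diffexp", mfst)
  } else log_stage("diffexp: up to date, skipped")
  paths$de <- de_tsv; paths$de_summary <- sum_tsv

  # --- stages: targets + enrich (optional) ---------------------------------
  if (!is.null(cfg$utr_fasta) && nzchar(cfg$utr_fasta %||% "")) {
    pred_tsv <- file.path(out, "target_predictions.tsv")
    enr_tsv <- file.path(out, "enrichment.tsv")
    top_tsv <- file.path(out, "enrichment_top.tsv")
    mfst <- stage_manifest(out, "targets",
                           c(de_tsv, cfg$utr_fasta, cfg$annotation_tsv,
                             cfg$mature_fasta, cfg$coords_tsv),
                           cfg[c("score_threshold", "energy_threshold",
                                 "top_terms")])
    if (!stage_up_to_date(out, "targets", mfst,
                          c(pred_tsv, enr_tsv, top_tsv))) {
      de <- read_tsv_table(de_tsv)
      dem_ids <- de$mirna[de$is_dem]
      mat <- read_fasta(cfg$mature_fasta)
      mirnas <- stats::setNames(mat$sequence, mat$id)[dem_ids]
      mirnas <- mirnas[!is.na(mirnas)]
      utr_fa <- read_fasta(cfg$utr_fasta)
      utrs <- stats::setNames(utr_fa$sequence, utr_fa$id)
      log_stage("targets: ", length(mirnas), " DEMs x ", length(utrs),
                " UTRs")
      pred <- predict_targets(mirnas, utrs)
      pred <- pred[order(pred$mirna, pred$transcript, pred$position), ]
      write_tsv_table(pred, pred_tsv)
      passing <- intersect_filter(pred, cfg$score_threshold,
                                  cfg$energy_threshold)
      ann <- read_tsv_table(cfg$annotation_tsv)
      study <- sort(unique(passing$transcript))
      enr <- hypergeom_enrich(study, population = sort(names(utrs)),
                              annotations = ann)
      write_tsv_table(enr, enr_tsv)
      write_tsv_table(top_terms(enr, cfg$top_terms), top_tsv)
      write_stage_manifest(out, "targets", mfst)
    } else log_stage("targets: up to date, skipped")
    paths$predictions <- pred_tsv; paths$enrichment <- enr_tsv
  }
  invisible(paths)
}

#' Simulate a complete pipeline fixture
#'
#' Wraps the synthetic-data generators: reference bundle, per-sample FASTQ
#' with truth tables, UTRs and annotations, a sample manifest, and a ready
#' pipeline config file.
#'
#' @param out_dir fixture directory.
#' @param seed integer seed.
#' @param n_reads reads per sample.
#' @param n_precursors known precursors in the reference.
#' @return list: config (path), plus everything the generators return.
#' @export
pipeline_simulate <- function(out_dir, seed = 1L, n_reads = 10000L,
                              n_precursors = 30L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(file.path(out_dir, "reference"),
                            n_precursors = n_precursors, seed = seed)
  design <- read_sim_design(n_reads = n_reads, seed = seed)
  reads <- generate_reads(design, ref, file.path(out_dir, "reads"))
  manifest <- data.frame(sample = names(design$samples),
                         group = unname(design$samples),
                         fastq = unname(reads$fastq), stringsAsFactors = FALSE)
  manifest_tsv <- file.path(out_dir, "samples.tsv")
  write_tsv_table(manifest, manifest_tsv)
  mat <- stats::setNames(ref$reference$annotations$mature_sequence,
                         ref$reference$annotations$mature_id)
  utrs <- generate_utrs(mat, seed = seed)
  utr_fasta <- file.path(out_dir, "utrs.fa")
  write_fasta(data.frame(id = names(utrs$utrs), description = "",
                         sequence = unname(utrs$utrs), rna = FALSE,
                         stringsAsFactors = FALSE), utr_fasta)
  ann <- generate_annotations(names(utrs$utrs), seed = seed)
  annotation_tsv <- file.path(out_dir, "annotations.tsv")
  write_tsv_table(ann, annotation_tsv)
  cfg <- c(list(sample_manifest = manifest_tsv,
                hairpin_fasta = ref$hairpin_fasta,
                mature_fasta = ref$mature_fasta, coords_tsv = ref$coords_tsv,
                contaminant_fasta = ref$contaminant_fasta,
                genome_fasta = ref$genome_fasta, utr_fasta = utr_fasta,
                annotation_tsv = annotation_tsv,
                out_dir = file.path(out_dir, "results")),
           pipeline_defaults())
  cfg$seed <- seed
  config_path <- file.path(out_dir, "pipeline.dcf")
  m <- matrix(vapply(cfg, function(x) paste(as.character(x), collapse = ","),
                     character(1)), nrow = 1,
              dimnames = list(NULL, names(cfg)))
  write.dcf(m, config_path)
  list(config = config_path, reference = ref, reads = reads, utrs = utrs,
       annotations = ann, manifest = manifest_tsv, design = design)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --out DIR [--seed N] [--reads N]`,
#' `run-all --config FILE`, `milkstats --in TSV --out TSV
#' [--variant student|welch]`. Results go to files; logs go to standard
#' error.
#'
#' @param args character vector (defaults to `commandArgs(trailingOnly=TRUE)`).
#' @return exit status, invisibly (0 = success, 2 = usage/config error).
#' @export
mirexo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  status <- tryCatch({
    if (!length(args)) stop("usage: mirexo <simulate|run-all|milkstats> ...",
                            call. = FALSE)
    cmd <- args[1]
    if (cmd == "simulate") {
      out <- opt("--out")
      if (is.null(out)) stop("simulate needs --out DIR", call. = FALSE)
      pipeline_simulate(out, seed = as.integer(opt("--seed", "1")),
                        n_reads = as.integer(opt("--reads", "10000")))
    } else if (cmd == "run-all") {
      cfgp <- opt("--config")
      if (is.null(cfgp)) stop("run-all needs --config FILE", call. = FALSE)
      pipeline_run(cfgp)
    } else if (cmd == "milkstats") {
      inp <- opt("--in"); outp <- opt("--out")
      if (is.null(inp) || is.null(outp)) {
        stop("milkstats needs --in TSV --out TSV", call. = FALSE)
      }
      tab <- read_tsv_table(inp)
      write_tsv_table(compare_table(tab, opt("--variant", "student")), outp)
    } else stop("unknown subcommand: ", cmd, call. = FALSE)
    0L
  }, error = function(e) {
    message("[mirexo] error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
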