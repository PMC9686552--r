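test_that("generate_reference is deterministic and self-consistent", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- generate_reference(d1, n_precursors = 6, n_contaminants = 6, seed = 5)
  r2 <- generate_reference(d2, n_precursors = 6, n_contaminants = 6, seed = 5)
  for (k in c("hairpin_fasta", "mature_fasta", "coords_tsv",
              "contaminant_fasta", "genome_fasta", "novel_tsv")) {
    expect_equal(readLines(r1[[k]]), readLines(r2[[k]]), info = k)
  }
  # distinct seed changes the genome
  r3 <- generate_reference(withr::local_tempdir(), n_precursors = 6,
                           n_contaminants = 6, seed = 6)
  expect_false(identical(readLines(r1$genome_fasta),
                         readLines(r3$genome_fasta)))
  # the emitted files satisfy the io_formats substring contract
  ref <- read_mirbase_dialect(r1$hairpin_fasta, r1$mature_fasta, r1$coords_tsv)
  expect_equal(nrow(ref$annotations), 6L)
  expect_equal(ref$annotations$mature_sequence,
               r1$reference$annotations$mature_sequence)
  # sizing error
  expect_error(generate_reference(withr::local_tempdir(), genome_length = 600,
                                  n_novel = 3, seed = 1), "genome_length")
})

test_that("planted novel loci occur exactly once (naive full-scan oracle)", {
  dir <- withr::local_tempdir()
  ref <- generate_reference(dir, n_precursors = 4, n_contaminants = 4,
                            genome_length = 6000, n_novel = 2, seed = 9)
  g <- ref$genome$sequence
  for (i in seq_len(nrow(ref$novel))) {
    hits <- oracle_genome_scan(ref$novel$mature_sequence[i], g)
    expect_length(hits, 1L)
    expect_equal(hits[[1]][1], ref$novel$mature_start[i])
    # the planted hairpin itself occurs exactly once, with >= 80 nt flanks
    expect_length(oracle_genome_scan(ref$novel$hairpin_sequence[i], g), 1L)
    expect_gte(ref$novel$start[i], 80L)
    expect_lte(ref$novel$end[i] + 80L, nchar(g))
  }
})

test_that("generate_reads plants the designed composition", {
  dir <- withr::local_tempdir()
  ref <- generate_reference(file.path(dir, "ref"), n_precursors = 6,
                            n_contaminants = 6, seed = 4)
  # junk fraction 1.0: preprocessing retains nothing
  design <- read_sim_design(n_reads = 150, seed = 4)
  design$samples <- c(s1 = "A", s2 = "B")
  design$fractions <- c(known = 0, novel = 0, contaminant = 0, junk = 1,
                        adapter_dimer = 0)
  reads <- generate_reads(design, ref, file.path(dir, "junk"))
  pp <- preprocess_samples(reads$fastq,
                           contaminants = read_fasta(ref$contaminant_fasta))
  expect_equal(nrow(pp$tags), 0L)
  # known fraction 1.0, no end variation, no mismatches: every tag maps
  # as a known mature with zero mismatches
  design$fractions <- c(known = 1, novel = 0, contaminant = 0, junk = 0,
                        adapter_dimer = 0)
  design$end_var <- 0L; design$mismatch_rate <- 0
  reads <- generate_reads(design, ref, file.path(dir, "known"))
  pp <- preprocess_samples(reads$fastq,
                           contaminants = read_fasta(ref$contaminant_fasta))
  mp <- map_to_precursors(pp$tags$sequence, ref$reference)
  expect_length(mp$unmapped, 0L)
  expect_true(all(mp$hits$category == "known_mature"))
  expect_true(all(mp$hits$mismatches == 0L))
  # every generated read has exactly one truth row
  expect_equal(nrow(reads$truth), 2L * design$n_reads)
  expect_false(anyDuplicated(reads$truth$read_id) > 0)
})

test_that("realized category fractions sit within 3 binomial SEs", {
  dir <- withr::local_tempdir()
  ref <- generate_reference(file.path(dir, "ref"), n_precursors = 6,
                            n_contaminants = 6, seed = 8)
  design <- read_sim_design(n_reads = 10000, seed = 8)
  design$samples <- c(s1 = "A")
  reads <- generate_reads(design, ref, file.path(dir, "reads"))
  tab <- table(reads$truth$category)
  n <- design$n_reads
  for (cat in names(design$fractions)) {
    p <- design$fractions[[cat]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(tab[[cat]] / n - p), 3 * se + 1e-12,
              label = paste("fraction of", cat))
  }
})

test_that("generate_counts plants fold changes reproducibly", {
  d <- count_sim_design(n_mirnas = 100, n_dem = 0, seed = 2)
  g <- generate_counts(d)
  expect_equal(nrow(g$truth), 0L)
  g2 <- generate_counts(d)
  expect_identical(g$counts, g2$counts)
  # noise-free limit: planted 4-fold DEM has mean ratio exactly 4
  d <- count_sim_design(n_mirnas = 50, n_dem = 10, fold = 4, noise_sd = 0,
                        seed = 2)
  g <- generate_counts(d)
  up <- g$truth$mirna[g$truth$direction == "up"]
  ratio <- rowMeans(g$counts[up, 1:3, drop = FALSE]) /
           rowMeans(g$counts[up, 4:6, drop = FALSE])
  expect_equal(unname(ratio), rep(4, length(up)), tolerance = 1e-9)
  expect_error(generate_counts(count_sim_design(n_dem = 10, fold = 1.5)),
               "fold")
})

test_that("generate_utrs plants recoverable 8mer sites", {
  mirnas <- c(m1 = "TGAGGTAGTAGGTTGTATAGTT", m2 = "ACCGTTAGCATCGGATTACCGT")
  u <- generate_utrs(mirnas, n_genes = 20, target_fraction = 0.5, seed = 3)
  expect_equal(nrow(u$truth), 10L)
  for (i in seq_len(nrow(u$truth))) {
    sites <- scan_sites(mirnas[[u$truth$mirna[i]]],
                        u$utrs[[u$truth$gene_id[i]]])
    expect_true("8mer" %in% sites$site_type,
                info = paste("gene", u$truth$gene_id[i]))
  }
  # annotations have unique (gene, term) pairs
  ann <- generate_annotations(names(u$utrs), seed = 3)
  expect_false(any(duplicated(ann[, c("gene_id", "term_id")])))
  expect_setequal(unique(ann$namespace), c("GO:BP", "GO:MF", "GO:CC", "KEGG"))
})
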