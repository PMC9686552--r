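# a hand-built precursor: 24-nt 5' arm, 8-nt loop, complementary 3' arm;
# annotated mature on the 5' arm
arm <- "TGAGGTAGTAGGTTGTATAGTTGC"
hairpin <- paste0(arm, "ATTTCCAA", revcomp(arm))
mature <- substr(arm, 1, 22)
toy_ref <- list(
  precursors = data.frame(id = "pre1", description = "", sequence = hairpin,
                          rna = FALSE, stringsAsFactors = FALSE),
  annotations = data.frame(precursor_id = "pre1", mature_id = "mat1",
                           arm = "5p", start = 0L, end = 22L,
                           mature_sequence = mature, stringsAsFactors = FALSE))

test_that("map_to_precursors classifies known matures and isomiRs", {
  r <- map_to_precursors(mature, toy_ref)
  expect_equal(r$hits$category, "known_mature")
  expect_equal(r$hits$mismatches, 0L)
  expect_equal(r$hits$end_shift_5p, 0L)
  expect_equal(r$hits$end_shift_3p, 0L)
  # one internal substitution
  m1 <- mature
  substr(m1, 10, 10) <- "C"
  r <- map_to_precursors(m1, toy_ref)
  expect_equal(r$hits$category, "known_mature")
  expect_equal(r$hits$mismatches, 1L)
  # 5' shift of +2 within the allowance
  shifted <- substr(hairpin, 3, 24)
  r <- map_to_precursors(shifted, toy_ref, max_end_shift = 4)
  expect_equal(r$hits$category, "known_mature")
  expect_equal(r$hits$end_shift_5p, 2L)
  # shift beyond the allowance is not a known mature
  far <- substr(hairpin, 8, 29)
  r <- map_to_precursors(far, toy_ref, max_end_shift = 4)
  expect_false(any(r$hits$category == "known_mature"))
})

test_that("opposite-arm tags become novel arm candidates", {
  tag3p <- substr(hairpin, 35, 56)   # wholly on the 3' arm
  r <- map_to_precursors(tag3p, toy_ref)
  expect_equal(r$hits$category, "novel_arm_3p")
  # precursor without annotation: flagged, not a mature call
  unann <- list(precursors = toy_ref$precursors,
                annotations = toy_ref$annotations[0, ])
  r <- map_to_precursors(mature, unann)
  expect_equal(r$hits$category, "unannotated_precursor")
})

test_that("two substitutions leave a tag unmapped (window-scan oracle)", {
  m2 <- mature
  substr(m2, 5, 5) <- "C"; substr(m2, 15, 15) <- "A"
  r <- map_to_precursors(m2, toy_ref)
  expect_equal(r$unmapped, m2)
  expect_equal(min(oracle_window_mm(m2, hairpin)), 2L)
  # agreement with the exhaustive oracle for random tags at the threshold
  set.seed(11)
  for (i in 1:25) {
    tg <- rand_dna(20)
    mapped <- length(map_to_precursors(tg, toy_ref)$unmapped) == 0
    expect_equal(mapped, min(oracle_window_mm(tg, hairpin)) <= 1,
                 info = paste("tag", tg))
  }
})

test_that("other-species mapping requires genome confirmation", {
  genome_with <- data.frame(id = "c1", description = "",
                            sequence = paste0(rand_dna(50), hairpin,
                                              rand_dna(50)),
                            rna = FALSE, stringsAsFactors = FALSE)
  genome_without <- data.frame(id = "c1", description = "",
                               sequence = rand_dna(200), rna = FALSE,
                               stringsAsFactors = FALSE)
  r <- map_to_other_species(mature, toy_ref, genome_with)
  expect_equal(r$hits$category, "known_other_species")
  expect_length(r$unmapped, 0L)
  r <- map_to_other_species(mature, toy_ref, genome_without)
  expect_equal(nrow(r$hits), 0L)
  expect_equal(r$unmapped, mature)
  # no other-species reference: identity on the unmapped set
  r <- map_to_other_species(mature, NULL, genome_with)
  expect_equal(r$unmapped, mature)
})

test_that("genome_scan equals the brute-force oracle", {
  set.seed(13)
  g <- rand_dna(2000)
  tag_f <- substr(g, 101, 120)
  tag_r <- revcomp(substr(g, 501, 522))
  tag_none <- paste0(strrep("T", 10), strrep("G", 12))
  genome <- data.frame(id = "chr1", description = "", sequence = g,
                       rna = FALSE, stringsAsFactors = FALSE)
  hits <- genome_scan(c(tag_f, tag_r, tag_none), genome)
  hf <- hits[hits$tag == tag_f, ]
  expect_true(any(hf$start == 100 & hf$end == 120 & hf$strand == "+"))
  hr <- hits[hits$tag == tag_r, ]
  expect_true(any(hr$start == 500 & hr$end == 522 & hr$strand == "-"))
  expect_equal(nrow(hits[hits$tag == tag_none, ]), 0L)
  # full agreement with the naive oracle
  for (tg in c(tag_f, tag_r, substr(g, 1500, 1519))) {
    ours <- hits <- genome_scan(tg, genome)
    orac <- oracle_genome_scan(tg, g)
    expect_equal(nrow(ours), length(orac), info = tg)
    if (length(orac)) {
      expect_setequal(ours$start, vapply(orac, `[`, integer(1), 1))
    }
  }
})

test_that("extract_hairpin_windows gets the flank arithmetic right", {
  g <- data.frame(id = "chr1", description = "",
                  sequence = rand_dna(10000), rna = FALSE,
                  stringsAsFactors = FALSE)
  hit <- data.frame(tag = "x", contig = "chr1", start = 100L, end = 120L,
                    strand = "+", stringsAsFactors = FALSE)
  w <- extract_hairpin_windows(hit, g, flank = 80)
  expect_equal(w$contig_start, c(20L, 100L))
  expect_equal(w$contig_end, c(120L, 200L))
  expect_equal(w$mature_start, c(80L, 0L))
  expect_equal(w$mature_end, c(100L, 20L))
  expect_equal(w$sequence[1], substr(g$sequence, 21, 120))
  # clipping at the contig start
  hit$start <- 10L; hit$end <- 30L
  w <- extract_hairpin_windows(hit, g, flank = 80)
  expect_equal(w$contig_start[1], 0L)
  expect_equal(w$mature_start[1], 10L)
  # minus-strand: transcript orientation is the reverse complement
  hit$strand <- "-"
  w <- extract_hairpin_windows(hit, g, flank = 80)
  expect_equal(w$sequence[1], revcomp(substr(g$sequence, 1, 30)))
  expect_equal(w$mature_end[2] - w$mature_start[2], 20L)
})

test_that("identify_tags yields one primary category per tag", {
  tags <- c(mature, substr(hairpin, 35, 56))
  genome <- data.frame(id = "c1", description = "", sequence = rand_dna(500),
                       rna = FALSE, stringsAsFactors = FALSE)
  r <- identify_tags(tags, toy_ref, genome)
  expect_equal(nrow(r$categories), 2L)
  expect_equal(sort(r$categories$category),
               c("known_mature", "novel_arm_3p"))
  expect_false(anyDuplicated(r$categories$tag) > 0)
})
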