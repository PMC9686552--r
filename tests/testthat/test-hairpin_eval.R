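test_that("fold backends honour their contracts", {
  # pass-through returns the supplied structure verbatim
  st <- fold("GGGGAAAACCCC", "file", structure = "((((....))))",
             energy = -12.3)
  expect_equal(st$dot_bracket, "((((....))))")
  expect_equal(st$energy, -12.3)
  expect_false(st$energy_approximate)
  expect_error(fold("GGGG", "file", structure = "((((", energy = -1),
               "unbalanced")
  expect_error(fold("GGGGA", "file", structure = "....", energy = -1),
               "length")
  # builtin pairs the GC run of GGGGGAAAAACCCCC
  st <- fold("GGGGGAAAAACCCCC", "builtin")
  expect_gte(sum(!is.na(st$pair_table)) / 2, 4)
  expect_true(st$energy_approximate)
})

test_that("builtin fold never pairs i,j closer than the minimum loop", {
  set.seed(21)
  for (i in 1:30) {
    st <- fold(rand_dna(sample(10:40, 1)), "builtin")
    pt <- st$pair_table
    paired <- which(!is.na(pt) & seq_along(pt) < pt)
    if (length(paired)) expect_true(all(pt[paired] - paired >= 4))
    # pair table is an involution consistent with the dot-bracket
    expect_equal(pair_table(st$dot_bracket), pt)
    idx <- which(!is.na(pt))
    expect_equal(pt[pt[idx]], idx)
  }
})

test_that("builtin fold equals exhaustive maximum pairing for short seqs", {
  set.seed(22)
  for (i in 1:60) {
    s <- rand_dna(sample(8:18, 1))
    st <- fold(s, "builtin")
    expect_equal(sum(!is.na(st$pair_table)) / 2, oracle_max_pairs(s),
                 info = s)
  }
})

test_that("decompose reads hairpin anatomy from the dot-bracket", {
  st <- fold("GGGGAAAACCCC", "file", structure = "((((....))))", energy = -10)
  d <- decompose(st)
  expect_true(d$ok)
  expect_equal(d$n_pairs, 4)
  expect_equal(d$terminal_loop, c(5L, 8L))
  expect_length(d$loops, 0L)
  # interior loop with sides (2,2)
  st <- fold("GGGAAGGAAAACCAACCC", "file",
             structure = "(((..((....))..)))", energy = -10)
  d <- decompose(st)
  expect_length(d$loops, 1L)
  expect_equal(d$loops[[1]]$left_count, 2L)
  expect_equal(d$loops[[1]]$right_count, 2L)
  # multi-hairpin structures are rejected
  st <- fold("GGAAACCGGAAACC", "file", structure = "((...))((...))",
             energy = -10)
  expect_false(decompose(st)$ok)
  expect_match(decompose(st)$reason, "single hairpin")
  st <- fold("AAAA", "file", structure = "....", energy = 0)
  expect_match(decompose(st)$reason, "no hairpin")
})

test_that("the criteria fixture suite classifies with zero errors", {
  suite <- criteria_fixture_suite()
  expect_gte(length(suite), 22L)
  for (cs in suite) {
    rep <- eval_fixture(cs$fx, cs$mstart, cs$mend)
    if (is.na(cs$expect_fail)) {
      expect_true(attr(rep, "accept"),
                  info = paste("passing fixture for criterion", cs$id))
    } else {
      expect_equal(rep$criterion[!rep$pass], cs$expect_fail,
                   info = paste("failing fixture for criterion", cs$id))
    }
  }
})

test_that("criteria respond monotonically to structure changes", {
  # enlarging the terminal loop flips only criterion 5
  base <- build_hairpin_fixture(list(seg_p(25)), loop_len = 8)
  big <- build_hairpin_fixture(list(seg_p(25)), loop_len = 22)
  rb <- eval_fixture(base, 10, 32); rg <- eval_fixture(big, 10, 32)
  expect_true(rb$pass[5]); expect_false(rg$pass[5])
  expect_equal(rb$pass[-5], rg$pass[-5])
  # removing base pairs flips criteria 2 and 10
  thin <- build_hairpin_fixture(list(seg_p(15)), loop_len = 20)
  rt <- eval_fixture(thin, 10, 21)   # mature over 11 of the 15 pairs
  expect_false(rt$pass[2]); expect_false(rt$pass[10])
  # overall accept is the AND of the per-criterion flags
  for (cs in criteria_fixture_suite()[c(1, 13, 17, 22)]) {
    rep <- eval_fixture(cs$fx, cs$mstart, cs$mend)
    expect_equal(attr(rep, "accept"), all(rep$pass))
  }
  expect_error(eval_fixture(base, 10, 500), "mature interval")
})

test_that("screen_candidates accepts planted loci and rejects shuffles", {
  dir <- withr::local_tempdir()
  ref <- generate_reference(dir, n_precursors = 4, n_contaminants = 4,
                            genome_length = 6000, n_novel = 2, seed = 31)
  tag <- ref$novel$mature_sequence[1]
  gh <- genome_scan(tag, ref$genome)
  win <- extract_hairpin_windows(gh[gh$strand == "+", ][1, ], ref$genome)
  win$tag <- tag
  structures <- data.frame(
    id = c("A", "B"),
    sequence = win$sequence,
    structure = vapply(win$sequence, function(s) {
      tryCatch(mirexo:::planted_structure(s, ref$novel$hairpin_sequence[1],
                                          ref$novel$hairpin_structure[1]),
               error = function(e) strrep(".", nchar(s)))
    }, character(1), USE.NAMES = FALSE),
    energy = -40, stringsAsFactors = FALSE)
  res <- screen_candidates(win, "file", structures)
  expect_equal(res$accepted$tag, tag)
  # two all-dot windows: nothing accepted, reports retained
  bad <- win
  badstr <- data.frame(id = c("A", "B"), sequence = win$sequence,
                       structure = strrep(".", nchar(win$sequence)),
                       energy = 0, stringsAsFactors = FALSE)
  res <- screen_candidates(bad, "file", badstr)
  expect_equal(nrow(res$accepted), 0L)
  expect_length(res$reports, 2L)
  # dinucleotide shuffles of the accepted window almost never pass
  set.seed(31)
  window <- win$sequence[which(win$window == "B")]
  rejected <- 0L
  n_shuffle <- 40L
  for (i in seq_len(n_shuffle)) {
    sh <- dinucleotide_shuffle(window)
    w1 <- data.frame(tag = "sh", window = "B", sequence = sh,
                     mature_start = win$mature_start[win$window == "B"],
                     mature_end = win$mature_end[win$window == "B"],
                     stringsAsFactors = FALSE)
    r <- screen_candidates(w1, "builtin")
    if (nrow(r$accepted) == 0L) rejected <- rejected + 1L
  }
  expect_gte(rejected / n_shuffle, 0.95)
})

test_that("dinucleotide_shuffle preserves dinucleotide counts", {
  set.seed(5)
  s <- rand_dna(80)
  sh <- dinucleotide_shuffle(s)
  dinucs <- function(x) {
    table(substring(x, 1:(nchar(x) - 1), 2:nchar(x)))
  }
  expect_equal(as.list(dinucs(sh)), as.list(dinucs(s)))
  expect_equal(nchar(sh), nchar(s))
})
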