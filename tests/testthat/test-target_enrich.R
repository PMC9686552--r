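let7 <- "TGAGGTAGTAGGTTGTATAGTT"

test_that("scan_sites classifies canonical seed matches", {
  # 8mer: reverse complement of positions 2-8 plus A opposite position 1
  utr <- paste0(strrep("G", 20), "CTACCTCA", strrep("G", 20))
  s <- scan_sites(let7, utr)
  expect_equal(nrow(s), 1L)
  expect_equal(s$site_type, "8mer")
  expect_equal(s$position, 21L)
  # 7mer-m8: 2-8 match, no A1
  utr <- paste0(strrep("G", 20), "CTACCTCG", strrep("G", 20))
  expect_equal(scan_sites(let7, utr)$site_type, "7mer-m8")
  # 7mer-A1: 2-7 match plus A, mismatched m8 position
  utr <- paste0(strrep("G", 20), "GTACCTCA", strrep("G", 20))
  expect_equal(scan_sites(let7, utr)$site_type, "7mer-A1")
  # bare 6mer
  utr <- paste0(strrep("G", 20), "GTACCTCG", strrep("G", 20))
  expect_equal(scan_sites(let7, utr)$site_type, "6mer")
  # no complement of the core: empty
  expect_equal(nrow(scan_sites(let7, strrep("G", 40))), 0L)
  expect_error(scan_sites("ACGTACG", strrep("G", 40)), ">= 8 nt")
})

test_that("scan_sites agrees with the brute-force oracle", {
  set.seed(51)
  for (i in 1:40) {
    mirna <- rand_dna(22)
    utr <- rand_dna(200)
    ours <- scan_sites(mirna, utr)
    orac <- oracle_scan_sites(mirna, utr)
    expect_equal(nrow(ours), length(orac))
    if (length(orac)) {
      expect_equal(ours$position, vapply(orac, `[[`, integer(1), "position"))
      expect_equal(ours$site_type,
                   vapply(orac, `[[`, character(1), "site_type"))
    }
  }
})

test_that("score_site ranks site types and AU context as designed", {
  au_utr <- paste0(strrep("AT", 15), "CTACCTCA", strrep("TA", 15))
  gc_utr <- paste0(strrep("GC", 15), "CTACCTCA", strrep("CG", 15))
  s_au <- scan_sites(let7, au_utr); s_gc <- scan_sites(let7, gc_utr)
  sc_au <- score_site(let7, au_utr, s_au$position, s_au$site_type)
  sc_gc <- score_site(let7, gc_utr, s_gc$position, s_gc$site_type)
  expect_gt(sc_au$context_like_score, sc_gc$context_like_score)
  # type ranking with identical context
  base <- strrep("G", 30)
  mk <- function(site) paste0(base, site, base)
  types <- c("CTACCTCA", "CTACCTCG", "GTACCTCA", "GTACCTCG")
  scores <- vapply(types, function(st) {
    u <- mk(st)
    s <- scan_sites(let7, u)
    score_site(let7, u, s$position, s$site_type)$context_like_score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))   # 8mer > 7mer-m8 > 7mer-A1 > 6mer
  # seed duplex energy is negative; scores are within [0, 100]
  expect_lt(sc_au$duplex_energy, -10)
  expect_true(all(scores >= 0 & scores <= 100))
})

test_that("intersect_filter keeps the printed threshold semantics", {
  pred <- data.frame(
    mirna = "m", transcript = "t", position = 0L, site_type = "8mer",
    context_like_score = c(55, 45, 80, 50), duplex_energy = c(-12, -20, -10, -10.5),
    passes = NA, stringsAsFactors = FALSE)
  kept <- intersect_filter(pred)
  expect_equal(kept$context_like_score, c(55, 50))
  # score 50 inclusive, energy -10 exclusive
  expect_true(50 %in% kept$context_like_score)
  expect_false(any(kept$duplex_energy == -10))
  # monotone: raising either threshold never adds predictions
  for (st in c(50, 60, 70)) for (et in c(-10, -11, -15)) {
    sub <- intersect_filter(pred, st, et)
    expect_true(all(sub$context_like_score %in% kept$context_like_score))
  }
})

test_that("hypergeometric p equals exhaustive enumeration", {
  # the worked example: N=20, K=5, n=5, k=3
  genes <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene_id = genes[1:5], term_id = "T1", term_name = "term",
                    namespace = "GO:BP", stringsAsFactors = FALSE)
  study <- c(genes[1:3], genes[19:20])   # k = 3 of K = 5
  r <- hypergeom_enrich(study, genes, ann)
  expect_equal(r$k, 3L)
  expect_equal(r$p_value, 1126 / 15504, tolerance = 1e-12)
  expect_equal(r$p_value, oracle_hyper_upper(20, 5, 5, 3), tolerance = 1e-12)
  # k = K = n = N: the certain event
  annall <- data.frame(gene_id = genes[1:4], term_id = "T", term_name = "t",
                       namespace = "KEGG", stringsAsFactors = FALSE)
  r <- hypergeom_enrich(genes[1:4], genes[1:4], annall)
  expect_equal(r$p_value, 1)
  # randomized agreement for N <= 25
  set.seed(52)
  for (i in 1:30) {
    N <- sample(8:25, 1); K <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    pop <- sprintf("x%02d", 1:N)
    ann <- data.frame(gene_id = pop[1:K], term_id = "T", term_name = "t",
                      namespace = "KEGG", stringsAsFactors = FALSE)
    study <- sample(pop, n)
    k <- sum(study %in% pop[1:K])
    r <- hypergeom_enrich(study, pop, ann)
    if (k == 0) expect_equal(nrow(r), 0L)
    else expect_equal(r$p_value, oracle_hyper_upper(N, K, n, k),
                      tolerance = 1e-12)
  }
  expect_error(hypergeom_enrich("zz", genes, ann), "absent from population")
})

test_that("BH adjustment matches the step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(oracle_bh(p), rep(0.04, 4))
  set.seed(53)
  for (i in 1:20) {
    p <- stats::runif(sample(3:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # BH is computed within namespace and is monotone in rank
  genes <- sprintf("g%02d", 1:20)
  ann <- rbind(
    data.frame(gene_id = genes[1:5], term_id = "T1", term_name = "t1",
               namespace = "GO:BP", stringsAsFactors = FALSE),
    data.frame(gene_id = genes[3:10], term_id = "T2", term_name = "t2",
               namespace = "GO:BP", stringsAsFactors = FALSE),
    data.frame(gene_id = genes[2:4], term_id = "P1", term_name = "p1",
               namespace = "KEGG", stringsAsFactors = FALSE))
  r <- hypergeom_enrich(genes[1:5], genes, ann)
  for (ns in unique(r$namespace)) {
    sub <- r[r$namespace == ns, ]
    expect_equal(sub$bh_fdr, oracle_bh(sub$p_value), tolerance = 1e-12)
    expect_true(all(diff(sub$bh_fdr[order(sub$p_value)]) >= -1e-12))
  }
  # duplicated annotation rows and gene order do not change p-values
  r2 <- hypergeom_enrich(rev(genes[1:5]), rev(genes), rbind(ann, ann[1, ]))
  expect_equal(r2$p_value, r$p_value)
})
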