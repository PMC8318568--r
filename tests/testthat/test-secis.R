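test_that("a perfect planted stem is found with the expected score", {
  set.seed(71)
  for (i in 1:10) {
    w <- make_hairpin_window(stem_len = 12, loop = 6)
    h <- find_hairpin(w$seq, min_stem = 7)
    expect_equal(h$start, w$start)
    expect_equal(h$stem_bp, 12L)
    expect_equal(h$mismatches, 0L)
    expect_equal(h$score, 24L)  # 2 per Watson-Crick pair, no wobble
  }
})

test_that("homopolymers and over-long windows are rejected", {
  expect_null(find_hairpin(strrep("A", 80)))
  expect_error(find_hairpin(strrep("A", 201)), "200")
  expect_error(find_hairpin("ACGTB"), "outside")
})

test_that("the mismatch budget is enforced exactly", {
  # C10 stem with one internal A corruption against a G10 arm: the window
  # holds no T, so no alternative 10-bp placement can pair without the
  # corrupted column
  seq_mm <- paste0("CCCCACCCCC", "AAAAAA", "GGGGGGGGGG")
  h1 <- find_hairpin(seq_mm, min_stem = 10, max_mismatch = 1)
  expect_equal(h1$mismatches, 1L)
  expect_equal(h1$stem_bp, 10L)
  expect_equal(h1$start, 1L)
  expect_equal(h1$score, 2L * 9L - 2L)
  h0 <- find_hairpin(seq_mm, min_stem = 10, max_mismatch = 0)
  expect_null(h0)
})

test_that("score grows by exactly 2 per extra Watson-Crick pair", {
  set.seed(73)
  for (len in 8:12) {
    w <- make_hairpin_window(stem_len = len, loop = 6)
    expect_equal(find_hairpin(w$seq)$score, 2L * len)
  }
})

test_that("find_hairpin matches the exhaustive placement oracle", {
  set.seed(74)
  for (i in 1:25) {
    n <- sample(50:120, 1)
    s <- rand_dna(n, gc = runif(1, .3, .6))
    got <- find_hairpin(s, min_stem = 5, loop_range = c(3, 10),
                        max_mismatch = 1)
    want <- oracle_hairpin_best(s, min_stem = 5, loop_lo = 3, loop_hi = 10,
                                max_mm = 1)
    if (is.null(want)) expect_null(got) else {
      expect_equal(got$score, want$score, info = paste("window", i))
    }
  }
})

make_sel_bench <- function(seed, n_sel = 3L, n_decoy = 0L) {
  generate(plant_spec(genome_length = 30000L, n_selenoproteins = n_sel,
                      n_pyl = 0L, n_decoy_uga = n_decoy, n_decoy_gbmt = 0L,
                      n_sec_trna = 0L, n_pyl_trna = 0L, n_std_trna = 0L,
                      machinery = FALSE, seed = seed))
}

test_that("planted selenoprotein genes yield exactly one SECIS hit each", {
  b <- make_sel_bench(81)
  genes <- find_orfs(b$genome, translation_table("opal"))
  truth <- b$truth[b$truth$class == "selenoprotein", ]
  for (k in seq_len(nrow(truth))) {
    gk <- genes[genes$start == truth$start[k] & genes$end == truth$end[k], ]
    expect_equal(nrow(gk), 1L)
    hits <- scan_secis(gk, b$genome)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$uga_protein_pos, truth$u_pos[k])
    expect_equal(hits$offset_nt, truth$secis_offset[k])
    expect_equal(hits$mismatches, 0L)
  }
})

test_that("a smaller planted stem is recovered at an explicit threshold", {
  # offset mechanics with the 9-bp stem geometry; scored below the default
  # threshold, so the scan threshold is passed explicitly
  b <- generate(plant_spec(genome_length = 20000L, n_selenoproteins = 2L,
                           n_pyl = 0L, n_decoy_uga = 0L, n_decoy_gbmt = 0L,
                           n_sec_trna = 0L, n_pyl_trna = 0L,
                           n_std_trna = 0L, machinery = FALSE,
                           secis_stem = 9L, secis_loop = 6L, seed = 82L))
  genes <- find_orfs(b$genome, translation_table("opal"))
  truth <- b$truth[b$truth$class == "selenoprotein", ]
  pars <- secis_defaults()
  pars$threshold <- 18L
  for (k in seq_len(nrow(truth))) {
    gk <- genes[genes$start == truth$start[k] & genes$end == truth$end[k], ]
    hits <- scan_secis(gk, b$genome, params = pars)
    expect_gte(nrow(hits), 1L)
    expect_equal(hits$offset_nt[1], 18L)
    expect_equal(hits$stem_bp[1], 9L)
  }
})

test_that("genes whose only UGA is the terminal stop are never scanned", {
  # under the standard table a TGA-terminated gene has no readthrough
  # event, so its terminal UGA is never searched for a hairpin
  g <- c(ctg = paste0("ATG", strrep("GCT", 70), "TGA"))
  genes <- find_orfs(g, translation_table(), min_len_codons = 60)
  expect_equal(nrow(genes), 1L)
  expect_equal(genes$n_events, 0L)
  expect_equal(nrow(scan_secis(genes, g)), 0L)
})

test_that("decoy UGA genes almost never produce a SECIS hit", {
  hits <- 0L
  total <- 0L
  for (sd in 1:30) {
    b <- make_sel_bench(1000L + sd, n_sel = 0L, n_decoy = 2L)
    genes <- find_orfs(b$genome, translation_table("opal"))
    truth <- b$truth[b$truth$class == "decoy_uga", ]
    for (k in seq_len(nrow(truth))) {
      gk <- genes[genes$start == truth$start[k] &
                    genes$end == truth$end[k], ]
      if (nrow(gk) != 1L) next
      total <- total + 1L
      if (nrow(scan_secis(gk, b$genome)) > 0) hits <- hits + 1L
    }
  }
  expect_gte(total, 50L)
  expect_lte(hits / total, 0.05)
})

test_that("hits are identical on a reverse-complemented contig", {
  b <- make_sel_bench(83, n_sel = 2L)
  genes <- find_orfs(b$genome, translation_table("opal"))
  rc <- setNames(reverse_complement(b$genome[[1]]), names(b$genome))
  genes_rc <- find_orfs(rc, translation_table("opal"))
  truth <- b$truth[b$truth$class == "selenoprotein", ]
  L <- nchar(b$genome[[1]])
  for (k in seq_len(nrow(truth))) {
    g1 <- genes[genes$start == truth$start[k] & genes$end == truth$end[k], ]
    s2 <- L - truth$end[k] + 1L
    e2 <- L - truth$start[k] + 1L
    g2 <- genes_rc[genes_rc$start == s2 & genes_rc$end == e2, ]
    h1 <- scan_secis(g1, b$genome)
    h2 <- scan_secis(g2, rc)
    expect_equal(h1[, -1], h2[, -1])  # all fields but the gene id
  }
})

test_that("identical inputs yield identical hit lists", {
  b <- make_sel_bench(84, n_sel = 2L)
  genes <- find_orfs(b$genome, translation_table("opal"))
  h1 <- scan_secis_all(genes, b$genome)
  h2 <- scan_secis_all(genes, b$genome)
  expect_identical(h1, h2)
})
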