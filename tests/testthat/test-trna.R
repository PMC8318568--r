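std_layout <- list(acceptor_stem = 9L, acc_d_spacer = 2L, d_stem = 4L,
                   d_loop = 8L, ac_stem = 6L, var_region = 4L, t_stem = 5L,
                   t_loop = 7L)

test_that("a constructed cloverleaf refolds to its generating layout", {
  set.seed(61)
  for (i in 1:15) {
    s <- make_trna_seq(std_layout, anticodon = "CAU")
    f <- fold_cloverleaf(s)
    expect_false(is.null(f))
    # round-trip: refolded score at least the generating layout's score
    expect_gte(f$pair_score, 2 * (9 + 4 + 6 + 5))
    expect_equal(f$pair_score, 48L)
  }
})

test_that("wobble pairs are accepted in stems and counted", {
  set.seed(62)
  ok <- FALSE
  for (i in 1:20) {
    s <- make_trna_seq(std_layout, anticodon = "CAU", gu_acceptor = 2L)
    f <- fold_cloverleaf(s)
    if (is.null(f)) next
    if (f$pair_score == 48L && f$gu_pairs >= 2L) { ok <- TRUE; break }
  }
  expect_true(ok)
})

test_that("unfoldable sequences yield no layout", {
  expect_null(fold_cloverleaf(strrep("A", 80)))
  expect_error(fold_cloverleaf(strrep("A", 30)), "60-120")
  expect_error(fold_cloverleaf(paste0(strrep("A", 70), "Z")), "outside")
})

test_that("classification follows the anticodon plus structural hallmark", {
  pyl <- list(anticodon = "CUA", ac_stem = 6L, acc_d_spacer = 2L,
              var_region = 4L, var_arm = FALSE, var_stem = 0L)
  expect_equal(classify_trna(pyl), "pyl")
  pyl2 <- modifyList(pyl, list(ac_stem = 5L, acc_d_spacer = 1L))
  expect_equal(classify_trna(pyl2), "pyl")
  amb <- modifyList(pyl, list(ac_stem = 5L, acc_d_spacer = 2L))
  expect_equal(classify_trna(amb), "ambiguous")
  sec <- list(anticodon = "UCA", ac_stem = 6L, acc_d_spacer = 2L,
              var_region = 16L, var_arm = TRUE, var_stem = 5L)
  expect_equal(classify_trna(sec), "sec")
  sec_noarm <- modifyList(sec, list(var_arm = FALSE, var_region = 4L,
                                    var_stem = 0L))
  expect_equal(classify_trna(sec_noarm), "ambiguous")
  std <- modifyList(pyl, list(anticodon = "CAU"))
  expect_equal(classify_trna(std), "standard")
})

test_that("classification is a pure function of anticodon and layout", {
  set.seed(63)
  s <- make_trna_seq(modifyList(std_layout, list(acc_d_spacer = 1L)),
                     anticodon = "CUA")
  f <- fold_cloverleaf(s)
  expect_equal(classify_trna(f), "pyl")
  # planting the same gene in different flanking contexts never changes
  # the reported class at the planted locus
  for (i in 1:5) {
    g <- setNames(paste0(rand_dna(3000, .41), s, rand_dna(3000, .41)), "c")
    hits <- scan_genome_trnas(g)
    at <- hits[hits$start <= 3001 + 5 & hits$end >= 3000 + nchar(s) - 5, ]
    expect_equal(nrow(at), 1L)
    expect_equal(at$class, "pyl")
  }
})

test_that("planted sec and pyl tRNAs are recovered from a 20-kb genome", {
  set.seed(64)
  b <- generate(plant_spec(genome_length = 20000L, n_selenoproteins = 0L,
                           n_pyl = 0L, n_decoy_uga = 0L, n_decoy_gbmt = 0L,
                           n_sec_trna = 1L, n_pyl_trna = 1L,
                           n_std_trna = 0L, machinery = FALSE, seed = 64L))
  hits <- scan_genome_trnas(b$genome)
  truth <- b$truth
  for (cls in c("sec", "pyl")) {
    tr <- truth[truth$trna_class == cls & !is.na(truth$trna_class), ]
    ov <- hits[hits$class == cls, ]
    expect_equal(nrow(ov), 1L, info = cls)
    # recovered at the planted locus (>=90% span overlap), right strand
    inter <- min(ov$end, tr$end) - max(ov$start, tr$start) + 1
    expect_gte(inter / (tr$end - tr$start + 1), 0.9)
    expect_equal(ov$strand, tr$strand)
  }
})

test_that("planted standard tRNAs are never classified pyl or sec", {
  set.seed(65)
  b <- generate(plant_spec(genome_length = 20000L, n_selenoproteins = 0L,
                           n_pyl = 0L, n_decoy_uga = 0L, n_decoy_gbmt = 0L,
                           n_sec_trna = 0L, n_pyl_trna = 0L,
                           n_std_trna = 3L, machinery = FALSE, seed = 65L))
  hits <- scan_genome_trnas(b$genome)
  expect_gte(nrow(hits), 3L)
  expect_true(all(hits$class %in% c("standard", "ambiguous")))
})

test_that("random sequence almost never yields a tRNA call", {
  set.seed(66)
  n_nonempty <- 0L
  for (i in 1:100) {
    g <- setNames(rand_dna(3000, gc = 0.41), "r")
    if (nrow(scan_genome_trnas(g)) > 0) n_nonempty <- n_nonempty + 1L
  }
  expect_lte(n_nonempty, 5L)
})

test_that("reported candidates never overlap on the same strand", {
  set.seed(67)
  b <- generate(plant_spec(genome_length = 30000L, n_selenoproteins = 0L,
                           n_pyl = 0L, n_decoy_uga = 0L, n_decoy_gbmt = 0L,
                           n_sec_trna = 2L, n_pyl_trna = 2L,
                           n_std_trna = 3L, machinery = FALSE, seed = 67L))
  hits <- scan_genome_trnas(b$genome)
  for (st in c("+", "-")) {
    h <- hits[hits$strand == st, ]
    if (nrow(h) < 2) next
    h <- h[order(h$start), ]
    expect_true(all(h$start[-1] > h$end[-nrow(h)]))
  }
})
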