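test_that("alignment of trivial cases follows the identity definition", {
  a <- global_align("MKV", "MKV")
  expect_equal(a$percent_identity, 100)
  expect_equal(a$aligned_a, "MKV")
  b <- global_align("MKKV", "MKV")
  expect_equal(nchar(b$aligned_a), 4L)
  expect_equal(sum(strsplit(b$aligned_b, "")[[1]] == "-"), 1L)
  # identity over residue-residue columns: 3 matches of 3
  expect_equal(b$percent_identity, 100)
  expect_error(global_align("", "MKV"), "non-empty")
  expect_error(global_align("MKB", "MKV"), "illegal")
})

test_that("gap removal recovers the inputs", {
  set.seed(91)
  for (i in 1:25) {
    a <- rand_protein(sample(5:60, 1))
    b <- rand_protein(sample(5:60, 1))
    al <- global_align(a, b)
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
    expect_gte(al$percent_identity, 0)
    expect_lte(al$percent_identity, 100)
  }
})

test_that("alignment scores equal the dynamic-programming oracle", {
  set.seed(92)
  sub <- gce_substitution_matrix()
  for (i in 1:200) {
    a <- rand_protein(sample(5:60, 1))
    b <- rand_protein(sample(5:60, 1))
    got <- global_align(a, b)$score
    want <- oracle_align_score(a, b, sub)
    expect_equal(got, want, info = paste("pair", i))
  }
})

test_that("the O/U-extended substitution scheme scores as documented", {
  m <- gce_substitution_matrix()
  expect_equal(m["O", "O"], m["U", "U"])
  expect_equal(m["O", "K"], m["O", "O"] / 2)
  expect_equal(m["U", "C"], m["U", "U"] / 2)
  expect_true(all(m["X", ] == 0))
  expect_equal(unname(m["O", "G"]), -4)
})

test_that("pyl site verification reports positions and conservation", {
  set.seed(93)
  ref <- paste0(rand_protein(333), "O", rand_protein(149))
  r0 <- verify_pyl_site(ref, ref)
  expect_true(r0$site_aligned)
  expect_equal(r0$downstream_window_identity, 100)
  expect_equal(r0$candidate_pyl_pos, 334L)
  expect_equal(r0$reference_length, 483L)
  # single insertion before the site still aligns the two O columns
  cand <- paste0(substr(ref, 1, 100), "A", substr(ref, 101, nchar(ref)))
  r1 <- verify_pyl_site(cand, ref)
  expect_true(r1$site_aligned)
  expect_equal(r1$candidate_pyl_pos, 335L)
  expect_equal(r1$downstream_window_identity, 100)
  expect_error(verify_pyl_site(rand_protein(50), ref), "candidate")
  expect_error(verify_pyl_site(paste0("O", rand_protein(49)),
                               rand_protein(50)), "reference")
})

test_that("selenoprotein calls require both a U event and a SECIS hit", {
  b <- generate(plant_spec(genome_length = 30000L, n_selenoproteins = 2L,
                           n_pyl = 0L, n_decoy_uga = 2L, n_decoy_gbmt = 0L,
                           n_sec_trna = 0L, n_pyl_trna = 0L,
                           n_std_trna = 0L, machinery = FALSE, seed = 94L))
  genes <- find_orfs(b$genome, translation_table("opal"))
  hits <- scan_secis_all(genes, b$genome)
  truth <- b$truth[b$truth$class == "selenoprotein", ]
  # no references: all calls are novel
  calls0 <- call_selenoproteins(genes, hits)
  expect_equal(nrow(calls0), 2L)
  expect_true(all(calls0$group == "novel"))
  # labeled references at high identity: known_family with that label
  refs <- setNames(b$proteins[truth$feature_id],
                   paste0("fam_", seq_len(nrow(truth))))
  calls1 <- call_selenoproteins(genes, hits, refs)
  expect_true(all(calls1$group == "known_family"))
  expect_gte(min(calls1$best_reference_identity), 96)
  # genes with U events but no SECIS hit are absent
  called_genes <- genes[match(calls1$gene_id, genes$gene_id), ]
  expect_true(all(called_genes$start %in% truth$start))
})

test_that("pyl calls verify the active site and reject decoys", {
  b <- generate(plant_spec(genome_length = 40000L, n_selenoproteins = 0L,
                           n_pyl = 3L, n_decoy_uga = 0L, n_decoy_gbmt = 3L,
                           n_sec_trna = 0L, n_pyl_trna = 0L,
                           n_std_trna = 0L, machinery = FALSE, seed = 95L))
  genes <- find_orfs(b$genome, translation_table("amber"))
  res <- call_pyl_proteins(genes, b$references["archaeal_mttB_ref"])
  expect_equal(nrow(res$calls), 3L)
  expect_true(all(res$calls$site_aligned))
  expect_true(all(res$calls$pyl_protein_pos == 327L))
  expect_true(all(res$calls$protein_length == 485L))
  truth_gb <- b$truth[b$truth$class == "decoy_gbmt", ]
  called <- genes[match(res$calls$gene_id, genes$gene_id), ]
  expect_equal(sum(called$start %in% truth_gb$start), 0L)
})

test_that("consensus follows the strict-majority rule", {
  expect_equal(consensus_sequence(c("MKV", "MKV", "MRV"), 0.5), "MKV")
  expect_equal(consensus_sequence(c("MA", "MG"), 0.5), "MX")
  expect_equal(consensus_sequence(c("M-", "M-"), 0.5), "M-")
  expect_error(consensus_sequence(c("MK", "MKV"), 0.5), "unequal")
  set.seed(96)
  for (i in 1:20) {
    rows <- vapply(1:10, function(j) rand_protein(15), character(1))
    th <- sample(c(0.3, 0.5, 0.75), 1)
    expect_equal(consensus_sequence(rows, th), oracle_consensus(rows, th))
  }
  # identical rows return the row itself for any threshold < 1
  row <- rand_protein(30)
  for (th in c(0.2, 0.5, 0.9))
    expect_equal(consensus_sequence(rep(row, 4), th), row)
})

test_that("conserved columns use a strict threshold", {
  rows <- c("MKVA", "MKVA", "MRVA", "MRCA")
  # col1 4/4, col2 2/4, col3 3/4, col4 4/4
  expect_equal(conserved_columns(rows, 0.75), c(1L, 4L))
  expect_equal(conserved_columns(rows, 0.5), c(1L, 3L, 4L))
  expect_equal(conserved_columns(rep("AAAA", 4), 0.99), 1:4)
  set.seed(97)
  for (i in 1:10) {
    r <- vapply(1:6, function(j) rand_protein(12), character(1))
    got <- conserved_columns(r, 0.75)
    cons <- oracle_consensus(r, 0.75)
    want <- which(strsplit(cons, "")[[1]] != "X")
    expect_equal(got, want)
  }
})

test_that("dereplication clusters greedily at the identity threshold", {
  s <- rand_protein(100)
  two <- c(a = s, b = s)
  d <- dereplicate(two, 0.9)
  expect_length(d$representatives, 1L)
  expect_equal(unname(d$membership), c("a", "a"))
  # sequences all below 90% pairwise identity are all retained
  set.seed(98)
  far <- setNames(vapply(1:4, function(i) rand_protein(80), character(1)),
                  paste0("s", 1:4))
  pid <- combn(4, 2, function(ij)
    global_align(far[[ij[1]]], far[[ij[2]]])$percent_identity)
  expect_true(all(pid < 90))
  d2 <- dereplicate(far, 0.9)
  expect_length(d2$representatives, 4L)
  # cluster count invariant under input permutation (distinct lengths)
  set.seed(99)
  base <- vapply(c(120, 100, 80, 60), function(n) rand_protein(n),
                 character(1))
  fam <- setNames(c(base, vapply(base, function(s)
    .mutate_near(s, 0.05), character(1))), paste0("q", 1:8))
  n0 <- length(dereplicate(fam, 0.9)$representatives)
  for (i in 1:5) {
    perm <- sample(names(fam))
    expect_equal(length(dereplicate(fam[perm], 0.9)$representatives), n0)
  }
})
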