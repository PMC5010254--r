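test_that("percent identity counts matched columns with gaps as mismatches", {
  set.seed(81)
  s <- random_dna(40)
  expect_equal(percent_identity(align_global(s, s)), 100)
  expect_equal(percent_identity(align_global(strrep("A", 4), strrep("T", 4))),
               0)
  # 437 matching amino-acid positions of 512
  aa <- paste(sample(c("M", "F", "L", "S", "W"), 512, replace = TRUE),
              collapse = "")
  bb <- strsplit(aa, "")[[1]]
  bb[sample(512, 75)] <- "X"
  aln <- pairwise_alignment(aa, paste(bb, collapse = ""))
  expect_equal(percent_identity(aln, mode = "aa"), 85)
  expect_error(percent_identity(pairwise_alignment("", "")), "empty")
})

test_that("identical blocks are maximal runs with coordinates on both inputs", {
  set.seed(82)
  s <- random_dna(50)
  b <- find_identical_blocks(align_global(s, s), min_len = 10)
  expect_equal(nrow(b), 1L)
  expect_equal(b$length, 50L)
  expect_equal(c(b$a_start, b$a_end), c(0L, 50L))
  # single difference at position 25 (1-based) splits into 24 + 25 runs
  t <- strsplit(s, "")[[1]]
  t[25] <- setdiff(c("A", "C", "G", "T"), t[25])[1]
  b2 <- find_identical_blocks(align_global(s, paste(t, collapse = "")),
                              min_len = 10)
  expect_equal(b2$length, c(25L, 24L))
  expect_equal(b2$a_start, c(25L, 0L))
})

test_that("a planted identical block is recovered from low-identity noise", {
  set.seed(83)
  motif <- random_dna(19)
  noise <- function(x, p) {
    v <- strsplit(x, "")[[1]]
    hit <- which(stats::runif(length(v)) < p)
    for (j in hit) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
    paste(v, collapse = "")
  }
  a <- paste0(random_dna(60), motif, random_dna(60))
  left <- noise(substr(a, 1, 60), 0.45)
  right <- noise(substr(a, 80, 139), 0.45)
  # force mismatches at the motif flanks so the planted block is exact
  substr(left, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                  c(substr(a, 60, 60),
                                    substr(left, 60, 60)))[1]
  substr(right, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                 c(substr(a, 80, 80),
                                   substr(right, 1, 1)))[1]
  b <- paste0(left, motif, right)
  aln <- align_global(a, b, align_params_noncoding())
  blocks <- find_identical_blocks(aln, min_len = 10)
  expect_gte(nrow(blocks), 1L)
  expect_equal(blocks$length[1], 19L)
  expect_equal(blocks$a_start[1], 60L)
})

test_that("block discovery is symmetric in its two inputs", {
  set.seed(84)
  g <- generate_minicircle_pair(sim_config(seed = 84, n_clones = 4))
  cmp_ab <- compare_species(g$a$circle, g$b$circle)
  cmp_ba <- compare_species(g$b$circle, g$a$circle)
  expect_equal(cmp_ab$gene_blocks$length, cmp_ba$gene_blocks$length)
  expect_equal(cmp_ab$gene_blocks$a_start, cmp_ba$gene_blocks$b_start)
  expect_equal(cmp_ab$gene_nt_identity, cmp_ba$gene_nt_identity)
})

test_that("simulated species pairs show the expected identities and blocks", {
  cfg <- sim_config(seed = 85, n_clones = 6)
  pair <- generate_minicircle_pair(cfg)
  cmp <- compare_species(pair$a$circle, pair$b$circle)
  # divergence presets target roughly 76% gene identity
  expect_gt(cmp$gene_nt_identity, 68)
  expect_lt(cmp$gene_nt_identity, 84)
  # the planted 23-bp gene block is recovered with exact coordinates
  gb <- cmp$gene_blocks
  hit23 <- gb[gb$a_start == pair$truth$gene_block[1], ]
  expect_equal(nrow(hit23), 1L)
  expect_equal(hit23$length, 23L)
  # planted noncoding motifs (19 and 11 bp) recovered at their coordinates
  nc <- cmp$noncoding_blocks
  expect_equal(nc$length[nc$a_start == pair$truth$motif1[1]], 19L)
  expect_equal(nc$length[nc$a_start == pair$truth$motif2[1]], 11L)
})

test_that("universality is checked against both species' clone matrices", {
  cfg <- sim_config(seed = 86, n_clones = 5, n_frameshift = 0L)
  pair <- generate_minicircle_pair(cfg)
  cl_a <- generate_clones(pair$a, cfg)
  cfg_b <- sim_config(seed = 87, n_clones = 5, n_frameshift = 0L)
  cl_b <- generate_clones(pair$b, cfg_b)
  cm_a <- map_clones(pair$a$circle, cl_a$clones, arc = cl_a$arc)
  cm_b <- map_clones(pair$b$circle, cl_b$clones, arc = cl_b$arc)
  cmp <- compare_species(pair$a$circle, pair$b$circle)
  ub <- universal_blocks(cmp$noncoding_blocks, cm_a, cm_b,
                         pair$a$circle, pair$b$circle)
  m1 <- which(ub$a_start == pair$truth$motif1[1] & ub$length == 19L)
  m2 <- which(ub$a_start == pair$truth$motif2[1] & ub$length == 11L)
  expect_length(m1, 1L)
  expect_length(m2, 1L)
  expect_true(ub$universal[m1])
  expect_true(ub$universal[m2])
  # a block holding a heteroplasmic column is not universal
  sub1 <- cl_a$truth$substitutions
  if (nrow(sub1)) {
    bad <- data.frame(length = 5L, a_start = sub1$pos[1],
                      a_end = sub1$pos[1] + 5L, b_start = sub1$pos[1],
                      b_end = sub1$pos[1] + 5L)
    ub2 <- universal_blocks(bad, cm_a, cm_b, pair$a$circle, pair$b$circle)
    expect_false(isTRUE(ub2$universal))
  }
  # blocks outside the cloned arc are undetermined
  out <- data.frame(length = 5L, a_start = 700L, a_end = 705L,
                    b_start = 700L, b_end = 705L)
  expect_true(is.na(universal_blocks(out, cm_a, cm_b, pair$a$circle,
                                     pair$b$circle)$universal))
})
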