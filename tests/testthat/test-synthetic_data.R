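test_that("configuration validates its length arithmetic", {
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$circle_len, 1914L)
  expect_equal(cfg$gene_nt + cfg$trna_len - cfg$trna_overlap +
                 cfg$noncoding_len, cfg$circle_len)
  cfg_t <- sim_config_tminor(seed = 1)
  expect_equal(cfg_t$circle_len, 1905L)
  expect_error(sim_config(noncoding_len = 50L), "too short")
  expect_error(sim_config(coding_flank = c(1000L, 1000L)), "flanks")
})

test_that("the generator is deterministic and honors its layout", {
  cfg <- sim_config(seed = 101)
  g1 <- generate_minicircle(cfg)
  g2 <- generate_minicircle(cfg)
  expect_identical(g1$circle$seq$residues, g2$circle$seq$residues)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g1$circle$seq, f1)
  write_fasta(g2$circle$seq, f2)
  expect_identical(readLines(f1), readLines(f2))
  # planted arms are exact reverse complements at the recorded coordinates
  tr <- g1$truth
  arm1 <- subseq_circular(g1$circle$seq,
                          interval(tr$ir_arm1[1], tr$ir_arm1[2]))
  arm2 <- subseq_circular(g1$circle$seq,
                          interval(tr$ir_arm2[1], tr$ir_arm2[2]))
  expect_equal(arm2$residues, reverse_complement(arm1$residues))
  # the gene is stop-free apart from its terminal stop
  gene <- subseq_circular(g1$circle$seq, interval(0, cfg$gene_nt))
  expect_equal(internal_stop_scan(gene), cfg$gene_codons - 1L)
})

test_that("start types control gene length and classification", {
  g_atg <- generate_minicircle(sim_config(seed = 102))
  expect_equal(classify_start(subseq_circular(g_atg$circle$seq,
                                              interval(0, 1536)))$category,
               "standard_ATG")
  cfg_t <- sim_config(seed = 102, start_type = "ATGT")
  expect_equal(cfg_t$gene_nt, 1537L)
  g_t <- generate_minicircle(cfg_t)
  expect_equal(substr(g_t$circle$seq$residues, 1, 4), "ATGT")
  # the TGT (cysteine) reading is the same DNA
  cfg_c <- sim_config(seed = 102, start_type = "TGT")
  expect_identical(generate_minicircle(cfg_c)$circle$seq$residues,
                   g_t$circle$seq$residues)
})

test_that("zero mutation rates give identical clones", {
  cfg <- sim_config(seed = 103, n_clones = 5, p_coding = 0, p_noncoding = 0,
                    p_trna = 0, indel_rate = 0, n_frameshift = 0L)
  g <- generate_minicircle(cfg)
  cl <- generate_clones(g, cfg)
  ref <- subseq_circular(g$circle$seq, cl$arc)$residues
  expect_true(all(vapply(cl$clones, `[[`, character(1), "residues") == ref))
  expect_equal(unique_clone_count(cl$clones), 1L)
  expect_equal(nrow(cl$truth$substitutions), 0L)
  expect_equal(nrow(cl$truth$indels), 0L)
})

test_that("a single planted substitution is reported as one site", {
  cfg <- sim_config(seed = 104, n_clones = 5, p_coding = 0, p_noncoding = 0,
                    p_trna = 0, indel_rate = 0, n_frameshift = 0L)
  g <- generate_minicircle(cfg)
  cl <- generate_clones(g, cfg)
  r <- cl$clones[[3]]$residues
  old <- substr(r, 100, 100)
  substr(r, 100, 100) <- setdiff(c("A", "C", "G", "T"), old)[1]
  cl$clones[[3]] <- nuc_seq(r, id = cl$clones[[3]]$id)
  cm <- map_clones(g$circle, cl$clones, arc = cl$arc)
  sites <- call_sites(cm, g$circle)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$col, 100L)
})

test_that("ground-truth substitutions match the emitted clone sequences", {
  cfg <- sim_config(seed = 105, n_clones = 6, indel_rate = 0,
                    n_frameshift = 0L, p_noncoding = 0.02)
  g <- generate_minicircle(cfg)
  cl <- generate_clones(g, cfg)
  ref <- strsplit(subseq_circular(g$circle$seq, cl$arc)$residues, "")[[1]]
  for (i in seq_along(cl$clones)) {
    cv <- strsplit(cl$clones[[i]]$residues, "")[[1]]
    diffs <- which(cv != ref)
    tru <- cl$truth$substitutions
    tru <- tru[tru$clone == cl$clones[[i]]$id, ]
    expect_equal(sort(diffs), sort(tru$arc_col))
  }
})

test_that("region-specific rates surface in the called site tallies", {
  # noncoding variation should clearly exceed coding variation
  cfg <- sim_config(seed = 106, n_clones = 20, p_noncoding = 0.01,
                    p_coding = 0.0017, indel_rate = 0, n_frameshift = 0L)
  g <- generate_minicircle(cfg)
  cl <- generate_clones(g, cfg)
  cm <- map_clones(g$circle, cl$clones, arc = cl$arc)
  rep <- heteroplasmy_report(cm, g$circle, clones = cl$clones)
  rate_nc <- rep$site_counts$noncoding / rep$surveyed_bp$noncoding
  rate_c <- rep$site_counts$coding / rep$surveyed_bp$coding
  expect_gt(rate_nc, rate_c)
})
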