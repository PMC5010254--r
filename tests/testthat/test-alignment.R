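test_that("global alignment handles identity and forced gaps", {
  aln <- align_global("ACGT", "ACGT")
  expect_equal(aln$aligned_a, "ACGT")
  expect_equal(aln$aligned_b, "ACGT")
  expect_equal(aln$score, 8)
  aln2 <- align_global("ACGT", "ACT")
  expect_equal(sum(strsplit(aln2$aligned_b, "")[[1]] == "-"), 1L)
  expect_equal(aln2$score, 3 * 2 - 5)
  expect_error(align_global("", "ACGT"), "empty")
})

test_that("alignment score equals the brute-force matching-enumeration oracle", {
  set.seed(41)
  mers <- replicate(5, random_dna(8))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      dp <- align_global(mers[i], mers[j])$score
      expect_equal(dp, oracle_global_score(mers[i], mers[j]),
                   info = paste(mers[i], mers[j]))
    }
  }
  # unequal lengths exercise the gap machinery harder
  for (r in 1:6) {
    a <- random_dna(sample(4:8, 1))
    b <- random_dna(sample(4:8, 1))
    expect_equal(align_global(a, b)$score, oracle_global_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment invariants hold: gap removal, no gap/gap columns, symmetry", {
  set.seed(42)
  for (r in 1:10) {
    a <- random_dna(sample(10:30, 1))
    b <- random_dna(sample(10:30, 1))
    aln <- align_global(a, b)
    expect_equal(gsub("-", "", aln$aligned_a), a)
    expect_equal(gsub("-", "", aln$aligned_b), b)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
    expect_equal(align_global(b, a)$score, aln$score)
  }
})

test_that("alignment scores agree with an established aligner", {
  # cross-check the compiled kernel against Biostrings on longer pairs
  set.seed(43)
  for (r in 1:5) {
    a <- random_dna(80)
    b <- random_dna(70)
    ours <- align_global(a, b)$score
    # Biostrings: gapOpening is charged in addition to the first extension
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -1, baseOnly = TRUE),
      gapOpening = 4, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("clone mapping builds reference-coordinate columns", {
  mc <- small_circle()
  arc <- interval(0, 90)
  ref <- subseq_circular(mc$seq, arc)$residues
  clones <- list(nuc_seq(ref, id = "c1"), nuc_seq(ref, id = "c2"))
  cm <- map_clones(mc, clones, arc = arc)
  expect_equal(ncol(cm$columns), 90L)
  expect_equal(nrow(cm$insertions), 0L)
  expect_true(all(cm$columns[1, ] == cm$columns[2, ]))
  # single substitution appears in exactly its column
  mut <- ref
  substr(mut, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                 substr(ref, 11, 11))[1]
  cm2 <- map_clones(mc, list(nuc_seq(ref, id = "c1"),
                             nuc_seq(mut, id = "c2")), arc = arc)
  diffcols <- which(cm2$columns[1, ] != cm2$columns[2, ])
  expect_equal(diffcols, 11L)
})

test_that("planted indels are recovered as insertion/deletion records", {
  mc <- small_circle(52)
  arc <- interval(0, 90)
  ref <- subseq_circular(mc$seq, arc)$residues
  # deletion of columns 50-53 and an insertion after column 70
  del <- paste0(substr(ref, 1, 49), substr(ref, 54, 90))
  ins <- paste0(substr(ref, 1, 70), "CTAGG", substr(ref, 71, 90))
  cm <- map_clones(mc, list(nuc_seq(del, id = "del"),
                            nuc_seq(ins, id = "ins")), arc = arc)
  ev <- indel_events(cm)
  evd <- ev[ev$clone == "del", ]
  expect_equal(nrow(evd), 1L)
  expect_equal(evd$len, 4L)
  expect_equal(evd$type, "deletion")
  evi <- ev[ev$clone == "ins", ]
  expect_equal(nrow(evi), 1L)
  expect_equal(evi$len, 5L)
  expect_equal(evi$type, "insertion")
  expect_equal(cm$insertions$seq, "CTAGG")
})

test_that("clone order does not change columns or downstream tallies", {
  g <- generate_minicircle(sim_config(seed = 53, n_clones = 6))
  cl <- generate_clones(g, sim_config(seed = 53, n_clones = 6))
  cm1 <- map_clones(g$circle, cl$clones, arc = cl$arc)
  perm <- rev(seq_along(cl$clones))
  cm2 <- map_clones(g$circle, cl$clones[perm], arc = cl$arc)
  expect_equal(ncol(cm1$columns), ncol(cm2$columns))
  expect_equal(cm1$columns[cm2$clone_ids, ], cm2$columns)
  s1 <- call_sites(cm1, g$circle)
  s2 <- call_sites(cm2, g$circle)
  expect_equal(s1, s2)
})

test_that("clones below the identity floor are excluded with a warning", {
  mc <- small_circle(54)
  arc <- interval(0, 90)
  ref <- subseq_circular(mc$seq, arc)$residues
  set.seed(54)
  junk <- nuc_seq(random_dna(90), id = "junk")
  expect_warning(
    cm <- map_clones(mc, list(nuc_seq(ref, id = "ok"), junk), arc = arc),
    "identity floor")
  expect_equal(cm$clone_ids, "ok")
  expect_equal(cm$excluded, "junk")
})
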