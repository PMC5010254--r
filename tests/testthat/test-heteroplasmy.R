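# helpers building tiny clone matrices through the real mapping path
het_fixture <- function(seed = 61, n_clones = 4) {
  mc <- small_circle(seed)
  arc <- interval(0, 90)
  ref <- subseq_circular(mc$seq, arc)$residues
  list(mc = mc, arc = arc, ref = ref,
       clones = lapply(seq_len(n_clones), function(i) {
         nuc_seq(ref, id = sprintf("c%02d", i))
       }))
}

mutate_at <- function(seqs, idx, pos1, base) {
  r <- seqs[[idx]]$residues
  substr(r, pos1, pos1) <- base
  seqs[[idx]] <- nuc_seq(r, id = seqs[[idx]]$id)
  seqs
}

test_that("uniform matrices yield no heteroplasmic sites", {
  fx <- het_fixture()
  cm <- map_clones(fx$mc, fx$clones, arc = fx$arc)
  expect_equal(nrow(call_sites(cm, fx$mc)), 0L)
})

test_that("a single variant clone creates one site with correct classification", {
  fx <- het_fixture()
  # substitution at gene position 0 (arc column 1): codon position 1
  alt <- setdiff(c("A", "C", "G", "T"), substr(fx$ref, 1, 1))[1]
  clones <- mutate_at(fx$clones, 2L, 1L, alt)
  cm <- map_clones(fx$mc, clones, arc = fx$arc)
  sites <- call_sites(cm, fx$mc)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos, 0L)
  expect_equal(sites$region, "overlap")  # gene start overlaps the tRNA here
  expect_equal(sites$codon_position, 1L)
  expect_equal(sites$n_alleles, 2L)
  # gaps and ambiguity codes neither create nor join sites
  clones2 <- mutate_at(fx$clones, 2L, 20L, "N")
  cm2 <- map_clones(fx$mc, clones2, arc = fx$arc)
  expect_equal(nrow(call_sites(cm2, fx$mc)), 0L)
})

test_that("codon positions cycle with gene coordinates", {
  fx <- het_fixture()
  clones <- fx$clones
  for (pos1 in c(10L, 11L, 12L)) {
    alt <- setdiff(c("A", "C", "G", "T"), substr(fx$ref, pos1, pos1))[1]
    clones <- mutate_at(clones, 2L, pos1, alt)
  }
  cm <- map_clones(fx$mc, clones, arc = fx$arc)
  sites <- call_sites(cm, fx$mc)
  expect_equal(sites$codon_position, c(1L, 2L, 3L))
  expect_equal(sites$region, rep("coding", 3))
})

test_that("rate and per-clone statistics round half-up as reported", {
  expect_identical(het_rate(26, 26, 591), 0.0017)
  expect_identical(het_rate(8, 7, 591), 0.0019)
  expect_identical(het_rate(10, 12, 591), 0.0014)
  expect_identical(het_rate(17, 7, 1572), 0.0015)
  expect_identical(het_rate(0, 10, 500), 0)
  expect_error(het_rate(5, 0, 591), "positive")
  expect_identical(sites_per_clone(17, 7), 2.4)
  expect_identical(sites_per_clone(0, 7), 0)
  expect_identical(sites_per_clone(26, 26), 1)
  expect_identical(taq_error_expectation(1.1e-4, 1000), 0.1)
  expect_identical(taq_error_expectation(0, 5000), 0)
  expect_identical(taq_error_expectation(1e-3, 500), 0.5)
})

test_that("rate is linear in sites and inverse-linear in clones and bp", {
  for (s in c(1, 5, 20)) {
    for (n in c(5, 10)) {
      for (bp in c(100, 500)) {
        expect_equal(s / (n * bp),
                     het_rate(s, n, bp, digits = 10L), tolerance = 1e-9)
      }
    }
  }
})

test_that("distinct clone sequences are counted exactly", {
  set.seed(62)
  base <- random_dna(50)
  clones <- c(replicate(25, random_dna(50)), base, base)
  expect_equal(unique_clone_count(clones), 26L)
  expect_equal(unique_clone_count(rep(base, 7)), 1L)
  expect_equal(unique_clone_count(lapply(1:3, function(i)
    nuc_seq(random_dna(30)))), 3L)
})

test_that("frameshifts are flagged by net indel length mod 3", {
  fx <- het_fixture(63, n_clones = 4)
  ref <- fx$ref
  # 1-bp deletion in gene, 3-bp deletion in gene, 22-bp deletion spanning
  # gene interior, and an unchanged clone
  del1 <- paste0(substr(ref, 1, 9), substr(ref, 11, 90))
  del3 <- paste0(substr(ref, 1, 9), substr(ref, 13, 90))
  del22 <- paste0(substr(ref, 1, 9), substr(ref, 32, 90))
  clones <- list(nuc_seq(del1, id = "del1"), nuc_seq(del3, id = "del3"),
                 nuc_seq(del22, id = "del22"), nuc_seq(ref, id = "wt"))
  cm <- map_clones(fx$mc, clones, arc = fx$arc)
  fs <- detect_frameshifts(cm, fx$mc)
  expect_equal(fs$frameshift[match(c("del1", "del3", "del22", "wt"),
                                   fs$clone)],
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(fs$net_indel[match("del22", fs$clone)], -22L)
})

test_that("replacement substitutions are translated and uniqueness-flagged", {
  fx <- het_fixture(64, n_clones = 4)
  ref <- fx$ref
  # codon 1 ATG -> ACG codes threonine in clone 1
  acg <- ref
  substr(acg, 2, 2) <- "C"
  # a shared synonymous change: codon 4 third base; table 5 family boxes
  clones <- list(nuc_seq(acg, id = "thr"), nuc_seq(ref, id = "wt1"),
                 nuc_seq(ref, id = "wt2"), nuc_seq(ref, id = "wt3"))
  cm <- map_clones(fx$mc, clones, arc = fx$arc)
  rs <- replacement_substitutions(cm, fx$mc)
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$clone, "thr")
  expect_equal(rs$aa_pos, 1L)
  expect_equal(rs$ref_aa, "M")
  expect_equal(rs$clone_aa, "T")
  expect_true(rs$unique)
  # identical clones produce no replacement records
  cmw <- map_clones(fx$mc, clones[2:4], arc = fx$arc)
  expect_equal(nrow(replacement_substitutions(cmw, fx$mc)), 0L)
})

test_that("the heteroplasmy report assembles consistent tallies", {
  cfg <- sim_config(seed = 65, n_clones = 10)
  g <- generate_minicircle(cfg)
  cl <- generate_clones(g, cfg)
  cm <- map_clones(g$circle, cl$clones, arc = cl$arc)
  rep <- heteroplasmy_report(cm, g$circle, clones = cl$clones)
  expect_equal(rep$n_clones, 10L)
  expect_equal(rep$surveyed_bp$coding, 591L)
  expect_equal(rep$site_counts$coding,
               sum(rep$codon_position_counts$p1,
                   rep$codon_position_counts$p2,
                   rep$codon_position_counts$p3))
  expect_equal(rep$rate,
               het_rate(rep$site_counts$coding, 10, rep$surveyed_bp$coding))
  expect_lte(rep$unique_clone_count, rep$n_clones)
  expect_equal(sum(rep$frameshifts$frameshift), cfg$n_frameshift)
})
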