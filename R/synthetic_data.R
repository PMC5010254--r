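# Seeded simulator of minicircles and heteroplasmic clone sets. The
# generator's defaults mirror the organization the analysis is built for:
# a ~1.9-kb circle with a 512-codon protein gene at the origin, a tRNA
# overlapping the gene start, and a noncoding region carrying a planted
# inverted repeat and two conserved motifs. Clone sets carry region-specific
# substitution heteroplasmy, noncoding indels, and coding frameshifts, with
# every planted event recorded as ground truth.

#' Simulator configuration
#'
#' Defaults reproduce the Geomydoecus aurei organization: 1,536 bp gene +
#' 68 bp tRNA - 6 bp overlap + 316 bp noncoding = 1,914 bp circle, with
#' conserved motifs of 19 bp and 11 bp placed 19 bp after the stop codon
#' and 15 bp apart, and an inverted repeat centered in the noncoding
#' region. The per-site coding substitution probability defaults to the
#' observed per-bp-per-clone heteroplasmy rate of 0.0017; noncoding
#' variation is set an order of magnitude higher, and tRNA variation
#' matches the observed 2-sites-in-68-bp tally.
#'
#' @param seed Integer seed; the generator is deterministic under it.
#' @param gene_codons Gene length in codons (default 512).
#' @param start_type `"ATG"` (standard), `"ATGT"` (tetranucleotide start;
#'   gene is `3 * gene_codons + 1` nt), or `"TGT"` (cysteine reading of the
#'   same ATGT DNA).
#' @param stop_codon Terminal stop (default `"TAG"`).
#' @param trna_len,trna_overlap tRNA length and its overlap with the gene
#'   start (defaults 68 and 6; the overlap grows by 1 for ATGT/TGT starts).
#' @param noncoding_len Noncoding length (default 316).
#' @param ir_arm,ir_spacer Planted inverted-repeat arm and spacer lengths.
#' @param ir_offset Offset of arm 1 within the noncoding region; `NULL`
#'   centers the repeat.
#' @param motif_lens Planted conserved motif lengths (default 19 and 11).
#' @param motif_gap_after_stop Gap between the stop codon and motif 1.
#' @param motif_spacing Gap between motif 1 and motif 2.
#' @param n_clones Number of clones (default 26).
#' @param p_coding,p_noncoding,p_trna Per-site per-clone substitution
#'   probabilities by region.
#' @param indel_rate Per-bp probability that a noncoding position initiates
#'   an indel in a clone.
#' @param indel_max Maximum indel length (lengths uniform on 1..indel_max).
#' @param n_frameshift Number of clones receiving a 1-bp coding indel.
#' @param coding_flank Coding bp covered by the cloned arc at the gene 3'
#'   and 5' ends (defaults sum to the 591 bp surveyed in all clones).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, gene_codons = 512L,
                       start_type = c("ATG", "ATGT", "TGT"),
                       stop_codon = "TAG",
                       trna_len = 68L, trna_overlap = 6L,
                       noncoding_len = 316L,
                       ir_arm = 10L, ir_spacer = 71L, ir_offset = NULL,
                       motif_lens = c(19L, 11L),
                       motif_gap_after_stop = 19L, motif_spacing = 15L,
                       n_clones = 26L,
                       p_coding = 0.0017, p_noncoding = 0.01,
                       p_trna = 0.0012,
                       indel_rate = 0.004, indel_max = 8L,
                       n_frameshift = 2L,
                       coding_flank = c(296L, 295L)) {
  start_type <- match.arg(start_type)
  stopifnot(seed == as.integer(seed), gene_codons >= 3L,
            stop_codon %in% c("TAG", "TAA"),
            trna_overlap >= 0L, trna_len > trna_overlap,
            all(c(p_coding, p_noncoding, p_trna) >= 0),
            all(c(p_coding, p_noncoding, p_trna) <= 1),
            indel_rate >= 0, indel_rate <= 1, indel_max >= 1L,
            n_frameshift <= n_clones, length(coding_flank) == 2L)
  gene_nt <- 3L * gene_codons + if (start_type == "ATG") 0L else 1L
  overlap <- trna_overlap + if (start_type == "ATG") 0L else 1L
  L <- gene_nt + trna_len - overlap + noncoding_len
  ir_region <- 2L * ir_arm + ir_spacer
  if (is.null(ir_offset)) {
    ir_offset <- (noncoding_len - ir_region) %/% 2L
  }
  motif_end <- motif_gap_after_stop + motif_lens[1L] + motif_spacing +
    motif_lens[2L]
  if (motif_end > ir_offset || ir_offset + ir_region > noncoding_len)
    stop("noncoding region too short for planted motifs and inverted repeat")
  if (sum(coding_flank) > gene_nt) stop("coding flanks exceed gene length")
  structure(list(
    seed = as.integer(seed), gene_codons = gene_codons,
    start_type = start_type, stop_codon = stop_codon,
    gene_nt = gene_nt, trna_len = trna_len, trna_overlap = overlap,
    noncoding_len = noncoding_len, circle_len = L,
    ir_arm = ir_arm, ir_spacer = ir_spacer, ir_offset = ir_offset,
    motif_lens = motif_lens, motif_gap_after_stop = motif_gap_after_stop,
    motif_spacing = motif_spacing,
    n_clones = n_clones, p_coding = p_coding, p_noncoding = p_noncoding,
    p_trna = p_trna, indel_rate = indel_rate, indel_max = indel_max,
    n_frameshift = n_frameshift, coding_flank = as.integer(coding_flank)),
    class = "sim_config")
}

#' Configuration preset for the T. minor-like organization
#'
#' 1,537 bp gene with a tetranucleotide ATGT start, 65 bp tRNA with a 4 bp
#' overlap, 307 bp noncoding: a 1,905 bp circle.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_tminor <- function(seed = 1L, ...) {
  args <- list(seed = seed, start_type = "ATGT", stop_codon = "TAA",
               trna_len = 65L, trna_overlap = 3L, noncoding_len = 307L,
               ir_arm = 9L, ir_spacer = 20L, n_clones = 12L,
               n_frameshift = 0L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

rand_bases <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# random stop-free coding body of n codons under table 5 (stops TAA/TAG)
rand_codons <- function(n_codons, code) {
  nonstop <- names(code$map)[code$map != "*"]
  paste(sample(nonstop, n_codons, replace = TRUE), collapse = "")
}

#' Generate a synthetic minicircle
#'
#' Deterministic under the configured seed. The gene sits at the origin
#' with a stop-free body and the configured start; the noncoding region
#' carries the planted inverted repeat (arms exact reverse complements)
#' and conserved motifs; the tRNA occupies the arc crossing the origin,
#' overlapping the gene start.
#'
#' @param cfg A `sim_config`.
#' @return List with `circle` (an annotated `minicircle`) and `truth`
#'   (planted feature coordinates, in 0-based circle coordinates).
#' @export
generate_minicircle <- function(cfg) {
  set.seed(cfg$seed)
  code <- genetic_code(5L)
  body <- rand_codons(cfg$gene_codons - 2L, code)
  gene <- if (cfg$start_type == "ATG") {
    paste0("ATG", body, cfg$stop_codon)
  } else {
    paste0("ATGT", body, cfg$stop_codon)
  }
  stopifnot(nchar(gene) == cfg$gene_nt)
  # noncoding layout (offsets relative to noncoding start = gene end)
  m1_off <- cfg$motif_gap_after_stop
  m2_off <- m1_off + cfg$motif_lens[1L] + cfg$motif_spacing
  arm1 <- rand_bases(cfg$ir_arm)
  nc <- strsplit(rand_bases(cfg$noncoding_len), "")[[1L]]
  ir1 <- cfg$ir_offset
  ir2 <- ir1 + cfg$ir_arm + cfg$ir_spacer
  nc[(ir1 + 1L):(ir1 + cfg$ir_arm)] <- strsplit(arm1, "")[[1L]]
  nc[(ir2 + 1L):(ir2 + cfg$ir_arm)] <-
    strsplit(reverse_complement(arm1), "")[[1L]]
  # buffer the planted arms with non-pairable bases so neither chance
  # complementarity nor short gap-bridged extensions can blur the planted
  # boundaries: A/A outside, C/C inside (A-A, C-C and A-C never pair)
  outer_l <- max(ir1 - 3L, 0L)
  if (ir1 >= 1L) nc[(outer_l + 1L):ir1] <- "A"
  outer_r <- min(ir2 + cfg$ir_arm + 3L, length(nc))
  if (ir2 + cfg$ir_arm < length(nc))
    nc[(ir2 + cfg$ir_arm + 1L):outer_r] <- "A"
  if (cfg$ir_spacer >= 6L) {
    nc[(ir1 + cfg$ir_arm + 1L):(ir1 + cfg$ir_arm + 3L)] <- "C"
    nc[(ir2 - 2L):ir2] <- "C"
  } else if (cfg$ir_spacer >= 2L) {
    nc[ir2] <- nc[ir1 + cfg$ir_arm + 1L]
  }
  noncoding <- paste(nc, collapse = "")
  trna_tail <- rand_bases(cfg$trna_len - cfg$trna_overlap)
  residues <- paste0(gene, noncoding, trna_tail)
  L <- nchar(residues)
  stopifnot(L == cfg$circle_len)
  circ <- nuc_seq(residues, id = sprintf("sim_circle_seed%d", cfg$seed),
                  topology = "circular")
  mc <- minicircle(circ)
  mc <- add_feature(mc, "gene", interval(0L, cfg$gene_nt), label = "cox1-like")
  trna_start <- L - (cfg$trna_len - cfg$trna_overlap)
  mc <- add_feature(mc, "tRNA",
                    interval(trna_start, cfg$trna_overlap, wraps = TRUE),
                    label = "trnI-like")
  nc0 <- cfg$gene_nt
  truth <- list(
    seed = cfg$seed,
    gene = c(0L, cfg$gene_nt),
    trna = c(trna_start, cfg$trna_overlap),
    noncoding = c(nc0, nc0 + cfg$noncoding_len),
    ir_arm1 = c(nc0 + ir1, nc0 + ir1 + cfg$ir_arm),
    ir_arm2 = c(nc0 + ir2, nc0 + ir2 + cfg$ir_arm),
    motif1 = c(nc0 + m1_off, nc0 + m1_off + cfg$motif_lens[1L]),
    motif2 = c(nc0 + m2_off, nc0 + m2_off + cfg$motif_lens[2L]))
  list(circle = mc, truth = truth)
}

# positions (0-based circle coords) protected from mutation: planted
# motifs and inverted-repeat arms must stay recoverable
protected_positions <- function(truth) {
  unlist(lapply(truth[c("ir_arm1", "ir_arm2", "motif1", "motif2")],
                function(x) x[1L]:(x[2L] - 1L)))
}

#' The cloned arc of a simulated circle
#'
#' The arc an outward-facing amplicon covers: the gene 3' flank, the
#' noncoding region, the tRNA, and the gene 5' flank, wrapping the origin.
#'
#' @param cfg A `sim_config`.
#' @return An `interval`.
#' @export
cloned_arc <- function(cfg) {
  interval(cfg$gene_nt - cfg$coding_flank[1L], cfg$coding_flank[2L],
           wraps = TRUE)
}

#' Generate a heteroplasmic clone set from a simulated circle
#'
#' Each clone covers the cloned arc. Substitutions are drawn independently
#' per site per clone at region-specific probabilities; noncoding positions
#' initiate insertions or deletions (uniform lengths) at the configured
#' rate; the first `n_frameshift` clones additionally receive a 1-bp coding
#' indel (alternating deletion/insertion). Planted motifs and repeat arms
#' are excluded from mutation. Every event is recorded in the ground truth.
#'
#' @param sim Output of [generate_minicircle()].
#' @param cfg The same `sim_config`.
#' @return List with `clones` (list of `nuc_seq`), `truth` (data frames
#'   `substitutions` and `indels`), and `arc` (the cloned `interval`).
#' @export
generate_clones <- function(sim, cfg) {
  set.seed(cfg$seed + 1L)
  mc <- sim$circle
  L <- seq_length(mc$seq)
  arc <- cloned_arc(cfg)
  arc_pos <- interval_positions(arc, L)
  ref <- strsplit(subseq_circular(mc$seq, arc)$residues, "")[[1L]]
  n <- length(ref)
  gene <- get_feature(mc, "gene")
  trna <- get_feature(mc, "tRNA")
  gpos <- interval_positions(gene, L)
  tpos <- interval_positions(trna, L)
  prot <- protected_positions(sim$truth)
  region <- ifelse(arc_pos %in% tpos, "trna",
                   ifelse(arc_pos %in% gpos, "coding", "noncoding"))
  psub <- c(coding = cfg$p_coding, trna = cfg$p_trna,
            noncoding = cfg$p_noncoding)[region]
  psub[arc_pos %in% prot] <- 0
  # indels initiate only in the noncoding interior, a margin away from the
  # region boundaries, so alignment cannot slide a gap into another region
  margin <- cfg$indel_max
  nc_cols <- which(region == "noncoding")
  interior <- nc_cols[vapply(nc_cols, function(j) {
    all(region[max(1L, j - margin):min(n, j + margin)] == "noncoding")
  }, logical(1))]
  pind <- rep(0, n)
  pind[setdiff(interior, which(arc_pos %in% prot))] <- cfg$indel_rate
  subs <- list()
  inds <- list()
  clones <- vector("list", cfg$n_clones)
  for (ci in seq_len(cfg$n_clones)) {
    id <- sprintf("clone_%02d", ci)
    bases <- ref
    hit <- which(stats::runif(n) < psub)
    for (j in hit) {
      alt <- sample(setdiff(BASES, bases[j]), 1L)
      subs[[length(subs) + 1L]] <- data.frame(
        clone = id, pos = arc_pos[j], arc_col = j, ref = bases[j],
        alt = alt, region = region[j], stringsAsFactors = FALSE)
      bases[j] <- alt
    }
    # indels: collect events on the unmutated coordinate system, then
    # apply right-to-left so arc columns stay valid
    ev <- list()
    istart <- which(stats::runif(n) < pind)
    for (j in istart) {
      len <- sample.int(cfg$indel_max, 1L)
      type <- if (stats::runif(1) < 0.5) "deletion" else "insertion"
      if (type == "deletion") {
        jj <- j:(j + len - 1L)
        if (max(jj) > n || any(region[jj] != "noncoding") ||
            any(arc_pos[jj] %in% prot)) next
      }
      ev[[length(ev) + 1L]] <- list(col = j, len = len, type = type,
                                    seq = if (type == "insertion")
                                      rand_bases(len) else "")
    }
    if (ci <= cfg$n_frameshift) {
      # keep the frameshift indel off the terminal arc columns, where a
      # cloned read cannot distinguish an indel from a shorter insert
      fscols <- setdiff(which(region == "coding"), c(1L, n))
      j <- sample(fscols, 1L)
      type <- if (ci %% 2L == 1L) "deletion" else "insertion"
      ev[[length(ev) + 1L]] <- list(col = j, len = 1L, type = type,
                                    seq = if (type == "insertion")
                                      rand_bases(1L) else "")
    }
    if (length(ev)) {
      ord <- order(-vapply(ev, `[[`, integer(1), "col"))
      for (e in ev[ord]) {
        if (e$type == "deletion") {
          bases <- bases[-(e$col:(e$col + e$len - 1L))]
        } else {
          bases <- append(bases, strsplit(e$seq, "")[[1L]], after = e$col)
        }
      }
      for (e in ev) {
        inds[[length(inds) + 1L]] <- data.frame(
          clone = id, pos = arc_pos[e$col], arc_col = e$col, len = e$len,
          type = e$type, seq = e$seq,
          region = region[e$col], stringsAsFactors = FALSE)
      }
    }
    clones[[ci]] <- nuc_seq(paste(bases, collapse = ""), id = id)
  }
  empty_sub <- data.frame(clone = character(0), pos = integer(0),
                          arc_col = integer(0), ref = character(0),
                          alt = character(0), region = character(0),
                          stringsAsFactors = FALSE)
  empty_ind <- data.frame(clone = character(0), pos = integer(0),
                          arc_col = integer(0), len = integer(0),
                          type = character(0), seq = character(0),
                          region = character(0), stringsAsFactors = FALSE)
  list(clones = clones,
       truth = list(
         substitutions = if (length(subs)) do.call(rbind, subs) else empty_sub,
         indels = if (length(inds)) do.call(rbind, inds) else empty_ind),
       arc = arc)
}

#' Generate a pair of related circles for cross-species comparison
#'
#' Species B derives from species A by independent per-site substitution at
#' region-specific divergences (defaults give roughly the observed ~76%
#' gene and ~55% noncoding cross-species identities), except that the
#' planted conserved motifs and one gene block of `gene_block_len` bp kept
#' identical between the species.
#'
#' @param cfg A `sim_config` (species A).
#' @param gene_divergence,noncoding_divergence Per-site substitution
#'   probabilities applied to species B.
#' @param gene_block_len Length of the identical gene block (default 23).
#' @param gene_block_offset Gene coordinate of the identical block.
#' @return List with `a`, `b` (each as from [generate_minicircle()]) and
#'   `truth` for the planted cross-species blocks.
#' @export
generate_minicircle_pair <- function(cfg, gene_divergence = 0.24,
                                     noncoding_divergence = 0.45,
                                     gene_block_len = 23L,
                                     gene_block_offset = 700L) {
  sim_a <- generate_minicircle(cfg)
  set.seed(cfg$seed + 2L)
  a <- sim_a$circle
  L <- seq_length(a$seq)
  bases <- strsplit(a$seq$residues, "")[[1L]]
  gene <- get_feature(a, "gene")
  keep <- c(protected_positions(sim_a$truth),
            gene_block_offset:(gene_block_offset + gene_block_len - 1L))
  gpos <- interval_positions(gene, L)
  p <- rep(noncoding_divergence, L)
  p[gpos + 1L] <- gene_divergence
  p[keep + 1L] <- 0
  hit <- which(stats::runif(L) < p)
  for (j in hit) bases[j] <- sample(setdiff(BASES, bases[j]), 1L)
  # pin a mismatch at both flanks of each deliberately conserved block so
  # the planted block boundaries are exact in the cross-species alignment
  av <- strsplit(a$seq$residues, "")[[1L]]
  gb <- c(gene_block_offset, gene_block_offset + gene_block_len)
  for (blk in list(sim_a$truth$motif1, sim_a$truth$motif2, gb)) {
    for (pos in c(blk[1L] - 1L, blk[2L])) {
      j <- (pos %% L) + 1L
      if (j %in% (keep + 1L)) next
      bases[j] <- setdiff(BASES, c(bases[j], av[j]))[1L]
    }
  }
  b_seq <- nuc_seq(paste(bases, collapse = ""),
                   id = sprintf("sim_circle_b_seed%d", cfg$seed),
                   topology = "circular")
  b <- minicircle(b_seq)
  b <- add_feature(b, "gene", interval(gene$start, gene$end), "cox1-like")
  trna <- get_feature(a, "tRNA")
  b <- add_feature(b, "tRNA",
                   interval(trna$start, trna$end, wraps = trna$wraps),
                   "trnI-like")
  truth <- sim_a$truth
  truth$gene_block <- c(gene_block_offset,
                        gene_block_offset + gene_block_len)
  list(a = sim_a, b = list(circle = b, truth = truth), truth = truth)
}
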