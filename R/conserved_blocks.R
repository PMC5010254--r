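# Cross-species comparison: percent identity of aligned regions and
# discovery of identical conserved blocks, with a universality check
# against the clone matrices of both species.

#' Percent identity of a pairwise alignment
#'
#' `100 * matched columns / total columns`; gap columns count as
#' mismatches. Reported rounded half-up to integer, matching how such
#' values are usually printed.
#'
#' @param aln A `pairwise_alignment`.
#' @param mode `"nt"` or `"aa"` (recorded only; the column arithmetic is
#'   identical).
#' @param digits Rounding digits (default 0).
#' @return Percent identity.
#' @export
percent_identity <- function(aln, mode = c("nt", "aa"), digits = 0L) {
  mode <- match.arg(mode)
  n <- nchar(aln$aligned_a)
  if (n == 0L) stop("empty alignment")
  round_half_up(100 * alignment_identity(aln), digits)
}

# map alignment column index to 0-based ungapped coordinate on each input
alignment_coords <- function(aln) {
  a <- strsplit(aln$aligned_a, "")[[1L]]
  b <- strsplit(aln$aligned_b, "")[[1L]]
  list(a = cumsum(a != "-") - 1L, b = cumsum(b != "-") - 1L,
       chars_a = a, chars_b = b)
}

#' Maximal identical blocks in a pairwise alignment
#'
#' Finds maximal runs of gap-free identical columns of length at least
#' `min_len`, reporting coordinates on both input sequences (0-based,
#' half-open). Blocks are sorted by length (descending) then position.
#'
#' @param aln A `pairwise_alignment`.
#' @param min_len Minimum block length in bp (default 10).
#' @return Data frame `length`, `a_start`, `a_end`, `b_start`, `b_end`.
#' @export
find_identical_blocks <- function(aln, min_len = 10L) {
  co <- alignment_coords(aln)
  same <- co$chars_a == co$chars_b & co$chars_a != "-"
  r <- rle(same)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  out <- data.frame(
    length = r$lengths[keep],
    a_start = co$a[starts[keep]],
    a_end = co$a[ends[keep]] + 1L,
    b_start = co$b[starts[keep]],
    b_end = co$b[ends[keep]] + 1L)
  out[order(-out$length, out$a_start), , drop = FALSE]
}

# uniformity of a clone matrix over a circle-coordinate interval:
# TRUE if every covered column is identical across clones and equal to the
# reference; NA if any position lies outside the cloned arc
matrix_uniform_over <- function(cm, mc, start, end) {
  pos <- start:(end - 1L)
  cols <- match(pos, cm$arc_positions)
  if (anyNA(cols)) return(NA)
  ref <- strsplit(subseq_circular(mc$seq, cm$arc)$residues, "")[[1L]]
  all(vapply(cols, function(j) {
    all(cm$columns[, j] == ref[j])
  }, logical(1)))
}

#' Flag conserved blocks identical across all clones of both species
#'
#' A block is universal when every clone column within it is uniform and
#' equal to the reference in both species' clone matrices. Blocks falling
#' outside a cloned region are flagged undetermined (NA).
#'
#' @param blocks Block table from [find_identical_blocks()], with `a_start`
#'   / `b_start` in the circle coordinates of the two references.
#' @param cm_a,cm_b `clone_matrix` objects for the two species.
#' @param mc_a,mc_b The two reference `minicircle`s.
#' @return The block table with a logical `universal` column.
#' @export
universal_blocks <- function(blocks, cm_a, cm_b, mc_a, mc_b) {
  blocks$universal <- vapply(seq_len(nrow(blocks)), function(i) {
    ua <- matrix_uniform_over(cm_a, mc_a, blocks$a_start[i], blocks$a_end[i])
    ub <- matrix_uniform_over(cm_b, mc_b, blocks$b_start[i], blocks$b_end[i])
    if (is.na(ua) || is.na(ub)) NA else ua && ub
  }, logical(1))
  blocks
}

#' Cross-species comparison of two annotated circles
#'
#' Aligns gene to gene (nucleotide and translated) and noncoding to
#' noncoding (with the relaxed exploratory preset), reporting percent
#' identities and identical blocks of the full-circle gene alignment.
#'
#' @param mc_a,mc_b Two annotated `minicircle`s.
#' @param code A `genetic_code`.
#' @param min_len Minimum conserved-block length.
#' @return List with `gene_nt_identity`, `gene_aa_identity`,
#'   `noncoding_identity`, `gene_blocks`, `noncoding_blocks`.
#' @export
compare_species <- function(mc_a, mc_b, code = genetic_code(5L),
                            min_len = 10L) {
  ga <- subseq_circular(mc_a$seq, get_feature(mc_a, "gene"))
  gb <- subseq_circular(mc_b$seq, get_feature(mc_b, "gene"))
  aln_nt <- align_global(ga, gb)
  aa_a <- translate_nuc(ga, code, if (substr(ga$residues, 1, 4) == "ATGT") 1L else 0L)
  aa_b <- translate_nuc(gb, code, if (substr(gb$residues, 1, 4) == "ATGT") 1L else 0L)
  naa <- min(nchar(aa_a), nchar(aa_b))
  aln_aa <- new_pairwise_alignment(substr(aa_a, 1L, naa),
                                   substr(aa_b, 1L, naa), NA_real_,
                                   align_params())
  nc_iv_a <- noncoding_interval(mc_a)
  nc_iv_b <- noncoding_interval(mc_b)
  aln_nc <- align_global(subseq_circular(mc_a$seq, nc_iv_a),
                         subseq_circular(mc_b$seq, nc_iv_b),
                         align_params_noncoding())
  shift_blocks <- function(b, off_a, off_b) {
    # to circle coordinates (gene and noncoding intervals do not wrap here)
    b$a_start <- b$a_start + off_a; b$a_end <- b$a_end + off_a
    b$b_start <- b$b_start + off_b; b$b_end <- b$b_end + off_b
    b
  }
  gene_blocks <- shift_blocks(find_identical_blocks(aln_nt, min_len),
                              get_feature(mc_a, "gene")$start,
                              get_feature(mc_b, "gene")$start)
  nc_blocks <- shift_blocks(find_identical_blocks(aln_nc, min_len),
                            nc_iv_a$start, nc_iv_b$start)
  list(gene_nt_identity = percent_identity(aln_nt),
       gene_aa_identity = percent_identity(aln_aa, mode = "aa"),
       noncoding_identity = percent_identity(aln_nc),
       gene_alignment = aln_nt,
       noncoding_alignment = aln_nc,
       gene_blocks = gene_blocks,
       noncoding_blocks = nc_blocks)
}

# the contiguous noncoding interval between gene end and tRNA start
noncoding_interval <- function(mc) {
  L <- seq_length(mc$seq)
  gene <- get_feature(mc, "gene")
  trna <- get_feature(mc, "tRNA", required = FALSE)
  start <- gene$end %% L
  end <- if (is.null(trna)) gene$start else trna$start
  interval(start, end, wraps = start >= end)
}

#' Write a conserved-block table as TSV
#' @param blocks Block table.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_block_table <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
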