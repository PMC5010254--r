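# Deterministic pairwise global alignment (Gotoh affine-gap dynamic
# programming, compiled) and reference-coordinate column-matrix construction
# for clone sets.

#' Affine-gap alignment scoring parameters
#'
#' A gap run of length L costs `gap_open + L * gap_extend`.
#'
#' @param match Match score (default +2).
#' @param mismatch Mismatch score (default -1).
#' @param gap_open Gap opening penalty (default -4).
#' @param gap_extend Per-position gap extension penalty (default -1).
#' @return List of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -1, gap_open = -4,
                         gap_extend = -1) {
  stopifnot(match > 0, mismatch < match, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

#' Relaxed preset for exploratory noncoding cross-species alignment
#' @return An `align_params` with match +1, mismatch -1, open -2, extend -1.
#' @export
align_params_noncoding <- function() {
  align_params(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
}

new_pairwise_alignment <- function(aligned_a, aligned_b, score, params) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned strings must have equal length")
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score, params = params),
            class = "pairwise_alignment")
}

#' Construct a pairwise alignment from pre-aligned strings
#'
#' For alignments produced elsewhere (e.g. gap-free comparisons of
#' equal-length sequences) that downstream operations should consume.
#'
#' @param aligned_a,aligned_b Equal-length gapped strings.
#' @param params Scoring parameters used (for the record).
#' @return A `pairwise_alignment`.
#' @export
pairwise_alignment <- function(aligned_a, aligned_b,
                               params = align_params()) {
  sc <- alignment_score(aligned_a, aligned_b, params)
  new_pairwise_alignment(aligned_a, aligned_b, sc, params)
}

# score of a given gapped alignment under affine parameters
alignment_score <- function(aligned_a, aligned_b, params) {
  a <- strsplit(aligned_a, "")[[1L]]
  b <- strsplit(aligned_b, "")[[1L]]
  if (any(a == "-" & b == "-")) stop("gap/gap column in alignment")
  sub <- sum(ifelse(a[a != "-" & b != "-"] == b[a != "-" & b != "-"],
                    params$match, params$mismatch))
  gap_runs <- function(isgap) {
    r <- rle(isgap)
    r$lengths[r$values]
  }
  runs <- c(gap_runs(a == "-"), gap_runs(b == "-"))
  sub + sum(params$gap_open + runs * params$gap_extend)
}

#' Optimal global alignment of two nucleotide sequences
#'
#' Needleman-Wunsch / Gotoh dynamic programming with affine gaps and a
#' deterministic traceback (ties resolved diagonal, then vertical, then
#' horizontal).
#'
#' @param a,b Linear `nuc_seq` objects (or character scalars).
#' @param params An `align_params`.
#' @return A `pairwise_alignment` with fields `aligned_a`, `aligned_b`,
#'   `score`, `params`.
#' @examples
#' aln <- align_global(nuc_seq("ACGT"), nuc_seq("ACT"))
#' aln$aligned_b  # one gap column
#' @export
align_global <- function(a, b, params = align_params()) {
  ra <- if (inherits(a, "nuc_seq")) a$residues else nuc_seq(a)$residues
  rb <- if (inherits(b, "nuc_seq")) b$residues else nuc_seq(b)$residues
  res <- .gotoh_align(ra, rb, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  new_pairwise_alignment(res$aligned_a, res$aligned_b, res$score, params)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f over %d columns\n",
              x$score, nchar(x$aligned_a)))
  invisible(x)
}

#' Fraction of identical columns in an alignment
#' @param aln A `pairwise_alignment`.
#' @return Matches / total columns (gap columns count as non-matches).
#' @export
alignment_identity <- function(aln) {
  a <- strsplit(aln$aligned_a, "")[[1L]]
  b <- strsplit(aln$aligned_b, "")[[1L]]
  sum(a == b & a != "-") / length(a)
}

#' Map clone sequences onto a reference arc of a minicircle
#'
#' Each clone is globally aligned to the reference sequence of the arc it
#' covers. The result is a reference-coordinate column matrix: one column
#' per reference arc position holding each clone's base (or `-` for a
#' deletion); insertions relative to the reference are stored as separate
#' insertion records, not columns. Clones aligning below the identity floor
#' are excluded with a warning.
#'
#' @param mc Reference `minicircle`.
#' @param clones List of linear `nuc_seq` clones.
#' @param arc `interval` on the circle that the clones cover; defaults to
#'   the whole circle starting at the gene start.
#' @param params Alignment parameters.
#' @param min_identity Identity floor below which a clone is flagged
#'   unmappable (default 0.6).
#' @return Object of class `clone_matrix`: `ref_id`, `arc`, `circle_length`,
#'   `columns` (clones x positions character matrix), `clone_ids`,
#'   `insertions` (data.frame `col`, `pos`, `clone`, `seq`), `excluded`.
#' @export
map_clones <- function(mc, clones, arc = NULL, params = align_params(),
                       min_identity = 0.6) {
  L <- seq_length(mc$seq)
  if (is.null(arc)) {
    gene <- get_feature(mc, "gene")
    arc <- interval(gene$start,
                    if (gene$start == 0L) L else gene$start,
                    wraps = gene$start != 0L)
  }
  ref <- subseq_circular(mc$seq, arc)
  arc_len <- seq_length(ref)
  ids <- vapply(clones, `[[`, character(1), "id")
  cols <- matrix("-", nrow = length(clones), ncol = arc_len,
                 dimnames = list(ids, NULL))
  ins <- data.frame(col = integer(0), pos = integer(0),
                    clone = character(0), seq = character(0),
                    stringsAsFactors = FALSE)
  excluded <- character(0)
  arc_pos <- interval_positions(arc, L)
  for (ci in seq_along(clones)) {
    aln <- align_global(ref, clones[[ci]], params)
    if (alignment_identity(aln) < min_identity) {
      warning("clone ", ids[ci], " aligns below identity floor; excluded")
      excluded <- c(excluded, ids[ci])
      next
    }
    ra <- strsplit(aln$aligned_a, "")[[1L]]
    rb <- strsplit(aln$aligned_b, "")[[1L]]
    refcol <- cumsum(ra != "-")      # reference arc column of each aln column
    base_cols <- ra != "-"
    cols[ci, refcol[base_cols]] <- rb[base_cols]
    if (any(ra == "-")) {
      r <- rle(ra == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        after_col <- refcol[starts[k]]  # inserted after this arc column (0 = before first)
        ins <- rbind(ins, data.frame(
          col = after_col,
          pos = if (after_col == 0L) arc_pos[1L] else arc_pos[after_col],
          clone = ids[ci],
          seq = paste(rb[starts[k]:ends[k]], collapse = ""),
          stringsAsFactors = FALSE))
      }
    }
  }
  keep <- !(ids %in% excluded)
  structure(list(ref_id = mc$seq$id, arc = arc, circle_length = L,
                 columns = cols[keep, , drop = FALSE],
                 clone_ids = ids[keep], insertions = ins,
                 excluded = excluded, arc_positions = arc_pos),
            class = "clone_matrix")
}

#' @export
print.clone_matrix <- function(x, ...) {
  cat(sprintf("<clone_matrix> %d clones x %d reference columns (%d insertions)\n",
              nrow(x$columns), ncol(x$columns), nrow(x$insertions)))
  invisible(x)
}

#' Export the reference-coordinate matrix as aligned FASTA
#'
#' Insertions relative to the reference are not represented (they are not
#' columns of the matrix).
#'
#' @param cm A `clone_matrix`.
#' @param mc The reference `minicircle`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_alignment_fasta <- function(cm, mc, path) {
  ref <- subseq_circular(mc$seq, cm$arc)
  rows <- c(stats::setNames(ref$residues, cm$ref_id),
            stats::setNames(apply(cm$columns, 1L, paste, collapse = ""),
                            cm$clone_ids))
  ss <- Biostrings::BStringSet(rows)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
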