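# Minicircle container and reconstruction of a full circle from an internal
# gene sequence plus an outward-facing amplicon spanning the gene-external
# arc. Circularity is declared only when both junction overlaps are found.

#' Minicircle: a circular sequence plus typed features
#'
#' @param seq A circular `nuc_seq`.
#' @param features Data frame with columns `type` (one of `gene`, `tRNA`,
#'   `inverted_repeat`, `conserved_block`, `noncoding`), `start`, `end`,
#'   `wraps`, `strand`, `label`, in 0-based half-open circle coordinates.
#' @return Object of class `minicircle`.
#' @export
minicircle <- function(seq, features = empty_features()) {
  stopifnot(inherits(seq, "nuc_seq"))
  if (seq$topology != "circular") stop("minicircle sequence must be circular")
  L <- seq_length(seq)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  for (i in seq_len(nrow(features))) {
    validate_interval(feature_interval(features[i, ]), L)
  }
  if (sum(features$type == "gene") > 1L)
    stop("minicircle must carry at most one gene feature")
  structure(list(seq = seq, features = features), class = "minicircle")
}

#' @export
print.minicircle <- function(x, ...) {
  cat(sprintf("<minicircle> %s: %d bp, %d features\n",
              x$seq$id, seq_length(x$seq), nrow(x$features)))
  if (nrow(x$features)) print(x$features, row.names = FALSE)
  invisible(x)
}

#' @rdname minicircle
#' @export
empty_features <- function() {
  data.frame(type = character(0), start = integer(0), end = integer(0),
             wraps = logical(0), strand = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

feature_interval <- function(row) {
  interval(row$start, row$end, wraps = row$wraps, strand = row$strand)
}

#' Add a feature to a minicircle
#' @param mc A `minicircle`.
#' @param type Feature type.
#' @param iv An `interval`.
#' @param label Feature label.
#' @return The updated `minicircle`.
#' @export
add_feature <- function(mc, type, iv, label = type) {
  validate_interval(iv, seq_length(mc$seq))
  mc$features <- rbind(mc$features, data.frame(
    type = type, start = iv$start, end = iv$end, wraps = iv$wraps,
    strand = iv$strand, label = label, stringsAsFactors = FALSE))
  mc
}

get_feature <- function(mc, type, required = TRUE) {
  idx <- which(mc$features$type == type)
  if (!length(idx)) {
    if (required) stop("minicircle has no '", type, "' feature")
    return(NULL)
  }
  feature_interval(mc$features[idx[1L], ])
}

# all occurrence start positions (1-based) of pattern in subject, exact
find_occurrences <- function(subject, pattern) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Reconstruct a circle from a gene and an outward-facing amplicon
#'
#' An outward-facing primer pair amplifies the gene-external arc of a
#' circular template; the resulting amplicon begins inside the gene near its
#' 3' end and ends inside the gene near its 5' end. This function anchors
#' both amplicon ends in the gene and merges the sequences into a circle,
#' rotated so the gene starts at position 0. The reconstructed length is
#' `len(gene) + len(amplicon) - left_overlap - right_overlap`.
#'
#' @param gene_seq Linear `nuc_seq` of the gene.
#' @param amplicon Linear `nuc_seq` of the outward-facing amplicon.
#' @param min_overlap Minimum junction overlap in bp (default 20).
#' @param max_mismatch Maximum mismatches tolerated per junction (default 0).
#' @return A `minicircle` with the gene annotated at the origin. The
#'   `overlap_join` attribute records both junction overlap lengths.
#' @export
merge_amplicon <- function(gene_seq, amplicon, min_overlap = 20L,
                           max_mismatch = 0L) {
  if (gene_seq$topology != "linear" || amplicon$topology != "linear")
    stop("merge_amplicon expects linear inputs")
  g <- gene_seq$residues
  a <- amplicon$residues
  G <- nchar(g); A <- nchar(a)
  if (min_overlap > min(G, A)) stop("min_overlap exceeds input length")
  n_mismatch <- function(x, y) {
    sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
  }
  # Left junction: amplicon prefix anchors in the gene (the anchor probe is
  # exact) and the overlap extends to the gene's 3' end with at most
  # max_mismatch mismatches; overlap length = G - anchor + 1.
  probe_l <- substr(a, 1L, min_overlap)
  occ_l <- find_occurrences(g, probe_l)
  cand_l <- occ_l[vapply(occ_l, function(p) {
    k <- G - p + 1L
    ok <- k <= A && n_mismatch(substr(g, p, G), substr(a, 1L, k)) <= max_mismatch
    ok
  }, logical(1))]
  # Right junction: amplicon suffix matches a gene prefix.
  probe_r <- substr(a, A - min_overlap + 1L, A)
  occ_r <- find_occurrences(g, probe_r)
  cand_r <- occ_r[vapply(occ_r, function(p) {
    k <- p + min_overlap - 1L  # overlap = gene prefix length
    k <= A &&
      n_mismatch(substr(g, 1L, k), substr(a, A - k + 1L, A)) <= max_mismatch
  }, logical(1))]
  if (!length(cand_l) || !length(cand_r))
    stop("no circularity evidence: amplicon ends do not overlap the gene ",
         "ends by at least ", min_overlap, " bp")
  if (length(cand_l) > 1L || length(cand_r) > 1L)
    stop("ambiguous amplicon placement; candidate anchors at gene positions ",
         paste(c(cand_l, cand_r), collapse = ", "))
  lo <- G - cand_l + 1L
  ro <- cand_r + min_overlap - 1L
  if (lo + ro > A)
    stop("junction overlaps exceed amplicon length; inputs inconsistent")
  external <- if (lo + ro == A) "" else substr(a, lo + 1L, A - ro)
  circ <- nuc_seq(paste0(g, external),
                  id = paste0(gene_seq$id, "_circle"), topology = "circular")
  mc <- minicircle(circ)
  mc <- add_feature(mc, "gene", interval(0L, G), label = gene_seq$id)
  attr(mc, "overlap_join") <- list(
    left_overlap_len = lo, right_overlap_len = ro,
    mismatches = c(n_mismatch(substr(g, cand_l, G), substr(a, 1L, lo)),
                   n_mismatch(substr(g, 1L, ro), substr(a, A - ro + 1L, A))))
  mc
}

#' Component-length bookkeeping for an annotated circle
#'
#' Computes `gene + tRNA - overlap + noncoding` from the circle's features
#' and checks that it equals the circle length. When the circle carries
#' explicit `noncoding` features their spans are used (and checked);
#' otherwise the noncoding length is derived as the complement of the gene
#' and tRNA spans.
#'
#' @param mc A `minicircle` annotated with gene and tRNA features.
#' @return List with fields `gene_len`, `trna_len`, `overlap_len`,
#'   `noncoding_len`, `total`.
#' @export
length_bookkeeping <- function(mc) {
  L <- seq_length(mc$seq)
  gene <- get_feature(mc, "gene")
  trna <- get_feature(mc, "tRNA", required = FALSE)
  gene_len <- interval_span(gene, L)
  trna_len <- if (is.null(trna)) 0L else interval_span(trna, L)
  gpos <- interval_positions(gene, L)
  tpos <- if (is.null(trna)) integer(0) else interval_positions(trna, L)
  overlap_len <- length(intersect(gpos, tpos))
  nc_rows <- which(mc$features$type == "noncoding")
  noncoding_len <- if (length(nc_rows)) {
    sum(vapply(nc_rows, function(i) {
      interval_span(feature_interval(mc$features[i, ]), L)
    }, integer(1)))
  } else {
    L - length(union(gpos, tpos))
  }
  total <- gene_len + trna_len - overlap_len + noncoding_len
  if (total != L)
    stop("length bookkeeping mismatch: components sum to ", total,
         " but circle is ", L, " bp")
  list(gene_len = gene_len, trna_len = trna_len, overlap_len = overlap_len,
       noncoding_len = noncoding_len, total = total)
}

#' Noncoding span of an annotated circle
#' @param mc A `minicircle`.
#' @return Integer bp not covered by gene or tRNA features.
#' @export
noncoding_span <- function(mc) {
  length_bookkeeping(mc)$noncoding_len
}
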