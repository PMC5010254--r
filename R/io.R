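# FASTA and GFF3 interchange. Circular topology is carried in the FASTA
# description ("topology=circular"); GFF3 features that cross the circle
# origin use the standard circular-genome convention of end > seqlength.

#' Read a multi-record FASTA file
#'
#' Records whose description contains `topology=circular` are returned as
#' circular sequences.
#'
#' @param path FASTA file path.
#' @return List of `nuc_seq` objects.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    hdr <- names(ss)[i]
    id <- strsplit(hdr, "\\s+")[[1]][1]
    topo <- if (grepl("topology=circular", hdr)) "circular" else "linear"
    nuc_seq(as.character(ss[[i]]), id = id, topology = topo)
  })
}

#' Write sequences to FASTA (wrapped at 70 columns)
#'
#' @param seqs A `nuc_seq` or list of them.
#' @param path Output path.
#' @param desc Optional extra description strings, recycled.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path, desc = NULL) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  hdr <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    extra <- c(if (s$topology == "circular") "topology=circular",
               if (!is.null(desc)) desc[[((i - 1L) %% length(desc)) + 1L]])
    paste(c(s$id, extra), collapse = " ")
  }, character(1))
  ss <- Biostrings::DNAStringSet(vapply(seqs, `[[`, character(1), "residues"))
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# features data.frame <-> GRanges (1-based; wrap encoded as end > L)
features_to_granges <- function(mc) {
  ft <- mc$features
  L <- seq_length(mc$seq)
  start1 <- ft$start + 1L
  end1 <- ifelse(ft$wraps, L + ft$end, ft$end)
  gr <- GenomicRanges::GRanges(
    seqnames = mc$seq$id,
    ranges = IRanges::IRanges(start = start1, end = end1),
    strand = ft$strand)
  gr$type <- ft$type
  gr$ID <- ft$label
  GenomeInfoDb::isCircular(gr) <- TRUE
  suppressWarnings(GenomeInfoDb::seqlengths(gr) <- stats::setNames(L, mc$seq$id))
  gr
}

#' Write minicircle annotations as GFF3
#'
#' Coordinates are converted to 1-based inclusive; features crossing the
#' origin are written with end beyond the circle length, the GFF3 convention
#' for circular genomes.
#'
#' @param mc A `minicircle`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gff3 <- function(mc, path) {
  rtracklayer::export.gff3(features_to_granges(mc), path)
  invisible(path)
}

#' Read feature annotations from GFF3
#'
#' @param path GFF3 path.
#' @param circle_length Circle length, used to decode origin-crossing
#'   features written with end > length.
#' @return Feature data.frame (`type`, `start`, `end`, `wraps`, `strand`,
#'   `label`) in 0-based half-open coordinates.
#' @export
read_gff3 <- function(path, circle_length) {
  gr <- rtracklayer::import(path)
  st <- GenomicRanges::start(gr) - 1L
  en <- GenomicRanges::end(gr)
  wraps <- en > circle_length
  en <- ifelse(wraps, en - circle_length, en)
  lab <- if (!is.null(gr$ID)) as.character(gr$ID) else
    as.character(gr$type)
  data.frame(type = as.character(gr$type), start = st, end = as.integer(en),
             wraps = wraps,
             strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                             "-", "+"),
             label = lab, stringsAsFactors = FALSE)
}
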