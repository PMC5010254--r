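# Core sequence types: nucleotide sequences with linear or circular
# topology, wrap-aware intervals, invertebrate-mitochondrial translation,
# and start/stop codon analysis.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Nucleotide sequence with topology
#'
#' Construct a nucleotide sequence object. Input is normalized: lowercase is
#' uppercased and U is mapped to T. IUPAC ambiguity codes are preserved.
#'
#' @param residues Character scalar over the IUPAC nucleotide alphabet.
#' @param id Text label.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `nuc_seq` with fields `id`, `residues`,
#'   `topology`.
#' @examples
#' s <- nuc_seq("acguT", id = "x")
#' s$residues  # "ACGTT"
#' @export
nuc_seq <- function(residues, id = "seq", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("residues must be a single character string")
  r <- chartr("u", "T", toupper(residues))
  r <- gsub("U", "T", r, fixed = TRUE)
  if (nchar(r) == 0L) stop("empty sequence rejected")
  bad <- setdiff(unique(strsplit(r, "")[[1]]), IUPAC_CHARS)
  if (length(bad))
    stop("invalid residue characters: ", paste(bad, collapse = ", "))
  structure(list(id = as.character(id), residues = r, topology = topology),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq> %s (%s, %d bp)\n", x$id, x$topology, seq_length(x)))
  invisible(x)
}

#' Sequence length in residues
#' @param seq A `nuc_seq`.
#' @return Integer number of residues.
#' @export
seq_length <- function(seq) nchar(seq$residues)

#' Reverse complement of a nucleotide string or `nuc_seq`
#'
#' IUPAC ambiguity codes are complemented according to their definitions.
#'
#' @param x A character scalar or a `nuc_seq`.
#' @return Same type as the input.
#' @export
reverse_complement <- function(x) {
  if (inherits(x, "nuc_seq")) {
    out <- x
    out$residues <- reverse_complement(x$residues)
    return(out)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Wrap-aware interval on a sequence
#'
#' Coordinates are 0-based, half-open. A wrapping interval crosses the circle
#' origin: its `end` is numerically smaller than its `start` and its span is
#' `(L - start) + end` on a circle of length `L`.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param wraps Does the interval cross the origin?
#' @param strand `"+"` or `"-"`.
#' @return An object of class `interval`.
#' @export
interval <- function(start, end, wraps = FALSE, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  structure(list(start = start, end = end, wraps = isTRUE(wraps),
                 strand = strand), class = "interval")
}

#' Span length of an interval on a sequence of length `L`
#' @param iv An `interval`.
#' @param L Sequence length (required for wrapping intervals).
#' @return Integer span in bp.
#' @export
interval_span <- function(iv, L = NULL) {
  if (iv$wraps) {
    if (is.null(L)) stop("circle length required for wrapping interval")
    (L - iv$start) + iv$end
  } else {
    iv$end - iv$start
  }
}

validate_interval <- function(iv, L) {
  if (iv$wraps) {
    # end == start denotes the full circle read from `start`
    if (!(iv$end <= iv$start))
      stop("wrapping interval must have end <= start")
    if (iv$start < 0L || iv$start >= L || iv$end < 0L || iv$end > L)
      stop("wrapping interval out of range")
  } else {
    if (!(0L <= iv$start && iv$start < iv$end && iv$end <= L))
      stop("interval [", iv$start, ",", iv$end, ") invalid for length ", L)
  }
  if (interval_span(iv, L) <= 0L) stop("interval span must be positive")
  invisible(iv)
}

#' Positions covered by an interval (0-based circle coordinates)
#' @param iv An `interval`.
#' @param L Sequence length.
#' @return Integer vector of covered positions in walk order.
#' @export
interval_positions <- function(iv, L) {
  if (iv$wraps) c(iv$start:(L - 1L), if (iv$end > 0L) 0:(iv$end - 1L))
  else iv$start:(iv$end - 1L)
}

#' Extract an interval from a (possibly circular) sequence
#'
#' Returns the residues of the interval in order, reverse-complemented when
#' the strand is `-`. Wrapping intervals require circular topology.
#'
#' @param seq A `nuc_seq`.
#' @param iv An `interval`.
#' @return A linear `nuc_seq` of length equal to the interval span.
#' @examples
#' s <- nuc_seq("AACCGGTT", topology = "circular")
#' subseq_circular(s, interval(6, 2, wraps = TRUE))$residues  # "TTAA"
#' @export
subseq_circular <- function(seq, iv) {
  L <- seq_length(seq)
  if (iv$wraps && seq$topology != "circular")
    stop("wrapping interval requested on a linear sequence")
  validate_interval(iv, L)
  r <- if (iv$wraps) {
    paste0(substr(seq$residues, iv$start + 1L, L),
           substr(seq$residues, 1L, iv$end))
  } else {
    substr(seq$residues, iv$start + 1L, iv$end)
  }
  if (iv$strand == "-") r <- reverse_complement(r)
  nuc_seq(r, id = sprintf("%s:%d-%d%s%s", seq$id, iv$start, iv$end,
                          if (iv$wraps) "w" else "", iv$strand))
}

#' Genetic code table
#'
#' Codon-to-amino-acid map with start-codon set. The default is NCBI
#' translation table 5 (invertebrate mitochondrial): ATA codes M, TGA codes
#' W, and AGA/AGG code S; stops are TAA and TAG.
#'
#' @param table_id NCBI genetic-code table number.
#' @return Object of class `genetic_code` with fields `id`, `map` (named
#'   character vector over 64 codons, stops as `"*"`), and `starts`.
#' @export
genetic_code <- function(table_id = 5L) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  att <- attr(map, "alt_init_codons")
  starts <- unique(c(names(map)[map == "M"], att))
  structure(list(id = as.integer(table_id), map = map[1:64], starts = starts),
            class = "genetic_code")
}

codons_of <- function(residues, frame = 0L) {
  n <- nchar(residues)
  ncod <- (n - frame) %/% 3L
  if (ncod <= 0L) return(character(0))
  starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
  substring(residues, starts, starts + 2L)
}

#' Translate a nucleotide sequence
#'
#' The trailing incomplete codon is dropped; codons containing ambiguity
#' codes translate to `X`; stop codons are emitted as `*`.
#'
#' @param seq A `nuc_seq` (or character scalar).
#' @param code A `genetic_code`.
#' @param frame Frame offset 0, 1 or 2.
#' @return Amino-acid string of length `floor((len - frame) / 3)`.
#' @examples
#' translate_nuc(nuc_seq("ATATGAAGA"))  # "MWS" under table 5
#' @export
translate_nuc <- function(seq, code = genetic_code(5L), frame = 0L) {
  res <- if (inherits(seq, "nuc_seq")) seq$residues else nuc_seq(seq)$residues
  stopifnot(frame %in% 0:2)
  if (nchar(res) - frame < 3L) stop("sequence too short to translate")
  cod <- codons_of(res, frame)
  aa <- unname(code$map[cod])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Codon indices of stop codons
#'
#' Scans a reading frame and returns the 0-based codon indices whose codon
#' is a stop. A clean gene yields exactly one stop, at the final codon.
#'
#' @inheritParams translate_nuc
#' @return Integer vector of 0-based stop codon indices.
#' @export
internal_stop_scan <- function(seq, code = genetic_code(5L), frame = 0L) {
  aa <- strsplit(translate_nuc(seq, code, frame), "")[[1]]
  which(aa == "*") - 1L
}

# TRUE when the frame has no stop codon before the final codon
frame_stop_free <- function(res, code, frame) {
  ncod <- (nchar(res) - frame) %/% 3L
  if (ncod < 1L) return(FALSE)
  stops <- internal_stop_scan(nuc_seq(res), code, frame)
  length(setdiff(stops, ncod - 1L)) == 0L
}

#' Classify the start codon of a protein gene
#'
#' Recognizes a standard ATG/ATA start (frame 0 free of internal stops), a
#' tetranucleotide ATGT start (frame at offset 1 stop-free while frame 0 is
#' not, as expected if the fourth base is removed by mRNA editing), and a
#' cysteine TGT start read from residues 2-4. The ATGT and TGT readings use
#' the same offset-1 frame and differ only in interpretation, so an ATGT
#' classification always lists the cysteine reading as an alternative.
#'
#' @param gene_seq A `nuc_seq` of length >= 4.
#' @param code A `genetic_code`.
#' @return List of class `start_classification` with fields `category`
#'   (`standard_ATG`, `tetranucleotide_ATGT`, `cysteine_TGT`, or `other`),
#'   `offset` (frame offset of the stop-free reading), and `alternative`.
#' @export
classify_start <- function(gene_seq, code = genetic_code(5L)) {
  res <- gene_seq$residues
  if (nchar(res) < 4L) stop("gene sequence shorter than 4 residues")
  first3 <- substr(res, 1L, 3L)
  first4 <- substr(res, 1L, 4L)
  res2_4 <- substr(res, 2L, 4L)
  sf0 <- frame_stop_free(res, code, 0L)
  sf1 <- frame_stop_free(res, code, 1L)
  cl <- function(category, offset, alternative = NA_character_) {
    structure(list(category = category, offset = offset,
                   alternative = alternative),
              class = "start_classification")
  }
  if (first3 %in% c("ATG", "ATA") && sf0) return(cl("standard_ATG", 0L))
  if (first4 == "ATGT" && sf1 && !sf0)
    return(cl("tetranucleotide_ATGT", 1L, alternative = "cysteine_TGT"))
  if (res2_4 == "TGT" && sf1) return(cl("cysteine_TGT", 1L))
  cl("other", NA_integer_)
}

# half-up decimal rounding (base round() is round-half-even)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
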