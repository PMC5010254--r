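# Inverted-repeat discovery: local dynamic-programming alignment of a
# sequence against its own reverse complement (einverted-style scoring),
# constrained so the two arms are disjoint and ordered.

#' Inverted-repeat scoring parameters
#'
#' Defaults follow the einverted-style scheme: match +3, mismatch -4, a
#' linear gap penalty of 5 per gap position, and a minimum reported score
#' of 15 (so a perfect palindromic arm is reported iff its length is >= 5).
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_penalty Penalty per gap position (> 0, subtracted).
#' @param min_score Minimum reported hit score (> 0).
#' @param min_arm Minimum arm length in bp (default 3).
#' @param max_spacer Maximum spacer between arms (default unlimited).
#' @return List of class `ir_params`.
#' @export
ir_params <- function(match = 3, mismatch = -4, gap_penalty = 5,
                      min_score = 15, min_arm = 3L, max_spacer = Inf) {
  stopifnot(match > 0, mismatch < 0, gap_penalty > 0, min_score > 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_penalty = gap_penalty, min_score = min_score,
                 min_arm = as.integer(min_arm), max_spacer = max_spacer),
            class = "ir_params")
}

#' Find inverted repeats in a sequence
#'
#' Runs a Smith-Waterman-style dynamic program of the sequence against its
#' own reverse complement, restricted so that the two aligned segments (the
#' repeat arms) do not overlap and arm 1 precedes arm 2. Hits scoring at
#' least `min_score` are selected greedily by descending score with overlap
#' suppression (a hit whose region span overlaps an already selected hit is
#' dropped); ties break by ascending arm-1 start, then ascending region
#' span. Circular sequences are scanned on a doubled linearization with
#' duplicate hits (arm-1 start beyond the original length) discarded.
#'
#' @param seq A `nuc_seq`.
#' @param params An `ir_params`.
#' @param suppress_overlaps Apply the greedy arm-overlap suppression
#'   (default). With `FALSE` every above-threshold hit is returned,
#'   including overlapping variants of the same repeat.
#' @return Data frame of hits: `arm1_start`, `arm1_end`, `arm2_start`,
#'   `arm2_end` (0-based half-open), `arm1_len`, `arm2_len`, `spacer_len`,
#'   `score`, `region_span`.
#' @export
find_inverted_repeats <- function(seq, params = ir_params(),
                                  suppress_overlaps = TRUE) {
  n0 <- seq_length(seq)
  empty <- data.frame(arm1_start = integer(0), arm1_end = integer(0),
                      arm2_start = integer(0), arm2_end = integer(0),
                      arm1_len = integer(0), arm2_len = integer(0),
                      spacer_len = integer(0), score = numeric(0),
                      region_span = integer(0))
  if (n0 < 2L * params$min_arm) {
    warning("sequence shorter than twice the minimum arm length")
    return(empty)
  }
  circular <- seq$topology == "circular"
  s <- if (circular) paste0(seq$residues, seq$residues) else seq$residues
  cand <- .ir_scan(s, params$match, params$mismatch, params$gap_penalty,
                   params$min_score)
  if (nrow(cand) == 0L) return(empty)
  cand <- as.data.frame(cand)
  cand$arm1_len <- cand$arm1_end - cand$arm1_start
  cand$arm2_len <- cand$arm2_end - cand$arm2_start
  cand$spacer_len <- cand$arm2_start - cand$arm1_end
  cand$region_span <- cand$arm2_end - cand$arm1_start
  keep <- cand$arm1_len >= params$min_arm & cand$arm2_len >= params$min_arm &
    cand$spacer_len <= params$max_spacer & cand$spacer_len >= 0L
  if (circular) {
    keep <- keep & cand$arm1_start < n0 & cand$region_span <= n0
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$score, cand$arm1_start, cand$region_span), ,
               drop = FALSE]
  # greedy selection: a candidate is dropped when either of its arms
  # overlaps an arm of an already selected hit (overlapping variants of
  # one repeat collapse to the best-scoring one; nested repeats survive)
  if (!suppress_overlaps) {
    hits <- cand[, c("arm1_start", "arm1_end", "arm2_start", "arm2_end",
                     "arm1_len", "arm2_len", "spacer_len", "score",
                     "region_span"), drop = FALSE]
    rownames(hits) <- NULL
    return(hits)
  }
  sel <- integer(0)
  arms_s <- numeric(0)
  arms_e <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    clash <- any(cand$arm1_start[i] < arms_e & arms_s < cand$arm1_end[i]) ||
      any(cand$arm2_start[i] < arms_e & arms_s < cand$arm2_end[i])
    if (!clash) {
      sel <- c(sel, i)
      arms_s <- c(arms_s, cand$arm1_start[i], cand$arm2_start[i])
      arms_e <- c(arms_e, cand$arm1_end[i], cand$arm2_end[i])
    }
  }
  hits <- cand[sel, c("arm1_start", "arm1_end", "arm2_start", "arm2_end",
                      "arm1_len", "arm2_len", "spacer_len", "score",
                      "region_span"), drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Annotate a minicircle with its inverted repeats
#'
#' Runs [find_inverted_repeats()] on the circle and adds an
#' `inverted_repeat` feature per arm of each hit.
#'
#' @param mc A `minicircle`.
#' @param params An `ir_params`.
#' @return The annotated `minicircle`; the hit table is attached as the
#'   `ir_hits` attribute.
#' @export
annotate_inverted_repeats <- function(mc, params = ir_params()) {
  L <- seq_length(mc$seq)
  hits <- find_inverted_repeats(mc$seq, params)
  for (i in seq_len(nrow(hits))) {
    for (arm in 1:2) {
      st0 <- hits[[paste0("arm", arm, "_start")]][i]
      span <- hits[[paste0("arm", arm, "_len")]][i]
      st <- st0 %% L
      mc <- add_feature(mc, "inverted_repeat",
                        if (st + span <= L) interval(st, st + span)
                        else interval(st, st + span - L, wraps = TRUE),
                        label = sprintf("IR%d_arm%d", i, arm))
    }
  }
  attr(mc, "ir_hits") <- hits
  mc
}

#' Write inverted-repeat hits as a BED-like TSV
#' @param hits Hit table from [find_inverted_repeats()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ir_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
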