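# Heteroplasmic site calling from a reference-coordinate clone matrix,
# region/codon-position classification, rate statistics, frameshift and
# replacement-substitution detection.

BASES <- c("A", "C", "G", "T")

# per-position region lookup for the arc of a clone matrix:
# "coding", "tRNA", "overlap" (gene and tRNA), or "noncoding"
region_of_positions <- function(cm, mc) {
  L <- cm$circle_length
  gene <- get_feature(mc, "gene")
  trna <- get_feature(mc, "tRNA", required = FALSE)
  gpos <- interval_positions(gene, L)
  tpos <- if (is.null(trna)) integer(0) else interval_positions(trna, L)
  p <- cm$arc_positions
  ifelse(p %in% gpos & p %in% tpos, "overlap",
         ifelse(p %in% gpos, "coding",
                ifelse(p %in% tpos, "tRNA", "noncoding")))
}

# coverage: a clone covers the columns between its first and last aligned
# base; internal gaps (deletions) count as covered
coverage_matrix <- function(cm) {
  t(apply(cm$columns, 1L, function(row) {
    nb <- which(row != "-")
    cov <- logical(length(row))
    if (length(nb)) cov[nb[1L]:nb[length(nb)]] <- TRUE
    cov
  }))
}

#' Call heteroplasmic sites from a clone matrix
#'
#' A heteroplasmic site is any reference column where at least two distinct
#' unambiguous bases (A/C/G/T) occur among the clones. Gaps and IUPAC
#' ambiguity codes neither create nor join sites. Each site is classified
#' by region; the codon position of coding/overlap sites is
#' `((pos - gene_start) mod 3) + 1` on the coding strand.
#'
#' @param cm A `clone_matrix`.
#' @param mc The annotated reference `minicircle` (gene and tRNA features).
#' @return Data frame with one row per site: `pos` (0-based circle
#'   coordinate), `col` (arc column), `region`, `codon_position` (NA outside
#'   coding/overlap), `alleles` (e.g. `"A:25,G:1"`), `n_alleles`.
#' @export
call_sites <- function(cm, mc) {
  if (is.null(get_feature(mc, "gene", required = FALSE)))
    stop("reference circle lacks gene annotation")
  region <- region_of_positions(cm, mc)
  gene <- get_feature(mc, "gene")
  L <- cm$circle_length
  out <- lapply(seq_len(ncol(cm$columns)), function(j) {
    tab <- table(cm$columns[, j])
    tab <- tab[names(tab) %in% BASES]
    if (length(tab) < 2L) return(NULL)
    pos <- cm$arc_positions[j]
    reg <- region[j]
    cp <- if (reg %in% c("coding", "overlap")) {
      ((pos - gene$start) %% L) %% 3L + 1L
    } else NA_integer_
    tab <- sort(tab, decreasing = TRUE)
    data.frame(pos = pos, col = j, region = reg, codon_position = cp,
               alleles = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                               collapse = ","),
               n_alleles = length(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(pos = integer(0), col = integer(0),
                      region = character(0), codon_position = integer(0),
                      alleles = character(0), n_alleles = integer(0),
                      stringsAsFactors = FALSE)
  out
}

#' Heteroplasmy rate in sites per bp per clone
#'
#' @param sites Number of heteroplasmic sites.
#' @param n_clones Number of clones surveyed.
#' @param surveyed_bp Reference bp covered by all clones.
#' @param digits Reporting precision (half-up rounding; default 4).
#' @return `sites / (n_clones * surveyed_bp)`, rounded half-up.
#' @examples
#' het_rate(26, 26, 591)  # 0.0017
#' @export
het_rate <- function(sites, n_clones, surveyed_bp, digits = 4L) {
  if (n_clones <= 0 || surveyed_bp <= 0)
    stop("n_clones and surveyed_bp must be positive")
  if (sites < 0) stop("negative site count")
  round_half_up(sites / (n_clones * surveyed_bp), digits)
}

#' Heteroplasmic sites per clone
#' @param sites Number of sites.
#' @param n_clones Number of clones (> 0).
#' @return `sites / n_clones`, rounded half-up to 1 decimal.
#' @examples
#' sites_per_clone(17, 7)  # 2.4
#' @export
sites_per_clone <- function(sites, n_clones) {
  if (n_clones <= 0) stop("n_clones must be positive")
  round_half_up(sites / n_clones, 1L)
}

#' Expected polymerase errors over a stretch of sequence
#' @param error_rate Errors per bp (>= 0).
#' @param bp Sequence length.
#' @return `error_rate * bp`, rounded half-up to 1 decimal.
#' @examples
#' taq_error_expectation(1.1e-4, 1000)  # 0.1
#' @export
taq_error_expectation <- function(error_rate, bp) {
  if (error_rate < 0) stop("error rate must be nonnegative")
  round_half_up(error_rate * bp, 1L)
}

#' Number of distinct clone sequences
#' @param clones List of `nuc_seq` (or character vector).
#' @return Count of unique residue strings after normalization.
#' @export
unique_clone_count <- function(clones) {
  if (!length(clones)) stop("at least one clone required")
  res <- if (is.character(clones)) {
    vapply(clones, function(x) nuc_seq(x)$residues, character(1))
  } else {
    vapply(clones, `[[`, character(1), "residues")
  }
  length(unique(res))
}

# deletion runs per clone within a column subset, as (clone, col, len)
deletion_events <- function(cm) {
  cov <- coverage_matrix(cm)
  out <- list()
  for (ci in seq_len(nrow(cm$columns))) {
    isdel <- cm$columns[ci, ] == "-" & cov[ci, ]
    r <- rle(isdel)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        clone = cm$clone_ids[ci], col = starts[k],
        pos = cm$arc_positions[starts[k]], len = r$lengths[k],
        type = "deletion", stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(clone = character(0), col = integer(0), pos = integer(0),
               len = integer(0), type = character(0), stringsAsFactors = FALSE)
}

#' All insertion/deletion events in a clone matrix
#' @param cm A `clone_matrix`.
#' @return Data frame `clone`, `col`, `pos`, `len`, `type`.
#' @export
indel_events <- function(cm) {
  dels <- deletion_events(cm)
  ins <- cm$insertions
  if (nrow(ins)) {
    ins <- data.frame(clone = ins$clone, col = ins$col, pos = ins$pos,
                      len = nchar(ins$seq), type = "insertion",
                      stringsAsFactors = FALSE)
  } else {
    ins <- dels[0, ]
  }
  out <- rbind(dels, ins)
  out[order(out$clone, out$col), , drop = FALSE]
}

# reconstruct a clone's sequence over the contiguous covered gene region
# that begins at the gene start (gene coordinate 0), splicing insertions
clone_gene_prefix <- function(cm, mc, ci) {
  L <- cm$circle_length
  gene <- get_feature(mc, "gene")
  gcoord <- (cm$arc_positions - gene$start) %% L
  in_gene <- gcoord < interval_span(gene, L)
  ord <- order(gcoord)
  cols <- ord[in_gene[ord]]
  if (!length(cols) || gcoord[cols[1L]] != 0L) return(NULL)
  run <- cols[seq_len(max(which(gcoord[cols] == seq_along(cols) - 1L)))]
  pieces <- character(0)
  ins <- cm$insertions
  pre <- ins[ins$clone == cm$clone_ids[ci] & ins$col == 0L, , drop = FALSE]
  row <- cm$columns[ci, ]
  for (j in run) {
    insj <- ins[ins$clone == cm$clone_ids[ci] & ins$col == j, , drop = FALSE]
    pieces <- c(pieces, if (row[j] != "-") row[j], insj$seq)
  }
  paste(c(pre$seq, pieces), collapse = "")
}

#' Detect frameshift indels within the gene region
#'
#' For each clone, sums insertion and deletion lengths falling inside the
#' gene; a frameshift is flagged when the net indel length is not divisible
#' by 3. For frameshifted clones the truncated-protein length is the number
#' of codons preceding the first stop in the shifted frame, evaluated over
#' the covered gene sequence (NA when no stop occurs within coverage).
#'
#' @param cm A `clone_matrix`.
#' @param mc The annotated reference `minicircle`.
#' @param code A `genetic_code`.
#' @return Data frame `clone`, `net_indel`, `frameshift`, `truncated_aa`.
#' @export
detect_frameshifts <- function(cm, mc, code = genetic_code(5L)) {
  L <- cm$circle_length
  gene <- get_feature(mc, "gene")
  gpos <- interval_positions(gene, L)
  ev <- indel_events(cm)
  in_gene <- ev$pos %in% gpos
  out <- lapply(seq_along(cm$clone_ids), function(ci) {
    id <- cm$clone_ids[ci]
    evc <- ev[ev$clone == id & in_gene, , drop = FALSE]
    net <- sum(evc$len[evc$type == "insertion"]) -
      sum(evc$len[evc$type == "deletion"])
    fs <- net %% 3L != 0L
    trunc_aa <- NA_integer_
    if (fs) {
      gseq <- clone_gene_prefix(cm, mc, ci)
      if (!is.null(gseq) && nchar(gseq) >= 3L) {
        stops <- internal_stop_scan(nuc_seq(gseq), code, 0L)
        if (length(stops)) trunc_aa <- stops[1L]
      }
    }
    data.frame(clone = id, net_indel = net, frameshift = fs,
               truncated_aa = trunc_aa, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Amino-acid replacement substitutions per clone
#'
#' Translates each non-frameshifted clone codon-by-codon against the
#' reference over fully covered, gap-free codons and lists the amino-acid
#' differences. A substitution is unique when its (position, amino acid)
#' pair occurs in exactly one clone.
#'
#' @param cm A `clone_matrix`.
#' @param mc The annotated reference `minicircle`.
#' @param code A `genetic_code`.
#' @return Data frame `clone`, `aa_pos` (1-based), `ref_aa`, `clone_aa`,
#'   `unique`.
#' @export
replacement_substitutions <- function(cm, mc, code = genetic_code(5L)) {
  L <- cm$circle_length
  gene <- get_feature(mc, "gene")
  glen <- interval_span(gene, L)
  gcoord <- (cm$arc_positions - gene$start) %% L
  in_gene <- gcoord < glen
  ref <- subseq_circular(mc$seq, cm$arc)$residues
  refchars <- strsplit(ref, "")[[1L]]
  cov <- coverage_matrix(cm)
  fs <- detect_frameshifts(cm, mc, code)
  # arc column for each gene coordinate (NA when not covered by the arc)
  col_of <- rep(NA_integer_, glen)
  col_of[gcoord[in_gene] + 1L] <- which(in_gene)
  ncodon <- glen %/% 3L
  out <- list()
  for (ci in seq_along(cm$clone_ids)) {
    if (fs$frameshift[ci]) next
    id <- cm$clone_ids[ci]
    for (k in seq_len(ncodon)) {
      cols <- col_of[(3L * (k - 1L) + 1L):(3L * k)]
      if (anyNA(cols)) next
      if (!all(cov[ci, cols])) next
      cb <- cm$columns[ci, cols]
      rb <- refchars[cols]
      if (any(cb == "-") || !all(cb %in% BASES) || !all(rb %in% BASES)) next
      if (all(cb == rb)) next
      raa <- unname(code$map[paste(rb, collapse = "")])
      caa <- unname(code$map[paste(cb, collapse = "")])
      if (!identical(raa, caa)) {
        out[[length(out) + 1L]] <- data.frame(
          clone = id, aa_pos = k, ref_aa = raa, clone_aa = caa,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(clone = character(0), aa_pos = integer(0),
               ref_aa = character(0), clone_aa = character(0),
               stringsAsFactors = FALSE)
  key <- paste(res$aa_pos, res$clone_aa)
  res$unique <- key %in% names(which(table(key) == 1L))
  res
}

#' Full heteroplasmy report for a clone set
#'
#' Assembles per-region surveyed lengths, site tallies (with codon-position
#' breakdown), indel events, frameshift calls, the per-bp-per-clone rate
#' statistic, the number of distinct clone sequences, and the clone
#' noncoding length range. Sites in the gene/tRNA overlap contribute to
#' both the coding and tRNA tallies; the double counting is flagged.
#'
#' @param cm A `clone_matrix`.
#' @param mc The annotated reference `minicircle`.
#' @param code A `genetic_code`.
#' @param clones Optional list of the original clone `nuc_seq` objects, used
#'   for the distinct-sequence count; defaults to matrix rows plus insertions.
#' @return Object of class `heteroplasmy_report`.
#' @export
heteroplasmy_report <- function(cm, mc, code = genetic_code(5L),
                                clones = NULL) {
  region <- region_of_positions(cm, mc)
  cov <- coverage_matrix(cm)
  surveyed <- colSums(!cov) == 0L
  surveyed_bp <- list(
    coding = sum(surveyed & region %in% c("coding", "overlap")),
    trna = sum(surveyed & region %in% c("tRNA", "overlap")),
    noncoding = sum(surveyed & region == "noncoding"))
  sites <- call_sites(cm, mc)
  sites_surv <- sites[surveyed[sites$col], , drop = FALSE]
  coding_sites <- sites_surv[sites_surv$region %in% c("coding", "overlap"), ,
                             drop = FALSE]
  trna_sites <- sites_surv[sites_surv$region %in% c("tRNA", "overlap"), ,
                           drop = FALSE]
  nc_sites <- sites_surv[sites_surv$region == "noncoding", , drop = FALSE]
  codon_tally <- vapply(1:3, function(p) {
    sum(coding_sites$codon_position == p)
  }, integer(1))
  n_clones <- length(cm$clone_ids)
  rate <- if (nrow(coding_sites) == 0L && surveyed_bp$coding == 0L) NA_real_
          else het_rate(nrow(coding_sites), n_clones, surveyed_bp$coding)
  ev <- indel_events(cm)
  fs <- detect_frameshifts(cm, mc, code)
  ucc <- if (!is.null(clones)) unique_clone_count(clones) else {
    sig <- vapply(seq_len(n_clones), function(ci) {
      insc <- cm$insertions[cm$insertions$clone == cm$clone_ids[ci], ,
                            drop = FALSE]
      paste(paste(cm$columns[ci, ], collapse = ""),
            paste(insc$col, insc$seq, collapse = ";"))
    }, character(1))
    length(unique(sig))
  }
  nc_cols <- which(region == "noncoding")
  nc_len <- vapply(seq_len(n_clones), function(ci) {
    insc <- cm$insertions[cm$insertions$clone == cm$clone_ids[ci] &
                            cm$insertions$col %in% nc_cols, , drop = FALSE]
    sum(cm$columns[ci, nc_cols] %in% c(BASES, setdiff(IUPAC_CHARS, BASES))) +
      sum(nchar(insc$seq))
  }, integer(1))
  structure(list(
    n_clones = n_clones,
    surveyed_bp = surveyed_bp,
    site_counts = list(coding = nrow(coding_sites), trna = nrow(trna_sites),
                       noncoding = nrow(nc_sites),
                       overlap = sum(sites_surv$region == "overlap"),
                       total = nrow(sites_surv)),
    codon_position_counts = stats::setNames(as.list(codon_tally),
                                            c("p1", "p2", "p3")),
    overlap_double_counted = sum(sites_surv$region == "overlap") > 0L,
    sites = sites,
    indel_events = ev,
    frameshifts = fs,
    replacement_substitutions = replacement_substitutions(cm, mc, code),
    unique_clone_count = ucc,
    rate = rate,
    rate_raw = if (surveyed_bp$coding > 0L)
      nrow(coding_sites) / (n_clones * surveyed_bp$coding) else NA_real_,
    noncoding_length_range = if (length(nc_len))
      c(min = min(nc_len), max = max(nc_len)) else c(min = NA, max = NA)),
    class = "heteroplasmy_report")
}

#' @export
print.heteroplasmy_report <- function(x, ...) {
  cat(sprintf("<heteroplasmy_report> %d clones (%d unique)\n",
              x$n_clones, x$unique_clone_count))
  cat(sprintf("  surveyed bp: coding %d, tRNA %d, noncoding %d\n",
              x$surveyed_bp$coding, x$surveyed_bp$trna,
              x$surveyed_bp$noncoding))
  cat(sprintf("  sites: coding %d (codon pos %d/%d/%d), tRNA %d, noncoding %d\n",
              x$site_counts$coding, x$codon_position_counts$p1,
              x$codon_position_counts$p2, x$codon_position_counts$p3,
              x$site_counts$trna, x$site_counts$noncoding))
  cat(sprintf("  rate: %.4f heteroplasmic sites per bp per clone\n", x$rate))
  cat(sprintf("  frameshifted clones: %d; noncoding length range %d-%d bp\n",
              sum(x$frameshifts$frameshift),
              x$noncoding_length_range[["min"]],
              x$noncoding_length_range[["max"]]))
  invisible(x)
}

#' Write the site table as TSV
#' @param report A `heteroplasmy_report`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_site_table <- function(report, path) {
  utils::write.table(report$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
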