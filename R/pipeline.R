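# End-to-end orchestration: assemble (or simulate) -> annotate -> map ->
# heteroplasmy -> inverted repeats -> clone tree, with a uniform output
# bundle and a JSON summary. Deterministic for fixed inputs and seed.

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

report_to_list <- function(rep) {
  list(
    n_clones = rep$n_clones,
    unique_clone_count = rep$unique_clone_count,
    surveyed_bp = rep$surveyed_bp,
    site_counts = rep$site_counts,
    codon_position_counts = rep$codon_position_counts,
    overlap_double_counted = rep$overlap_double_counted,
    rate = rep$rate,
    rate_raw = rep$rate_raw,
    n_indel_events = nrow(rep$indel_events),
    n_frameshift_clones = sum(rep$frameshifts$frameshift),
    n_replacement_substitutions = nrow(rep$replacement_substitutions),
    noncoding_length_range = as.list(rep$noncoding_length_range))
}

#' Run the full minicircle analysis pipeline
#'
#' Either reconstructs a circle from `gene` + `amplicon` FASTA files (with
#' `gff` supplying tRNA annotation) or simulates one under `sim`; maps the
#' clones, and writes the output bundle: circle FASTA + GFF3, heteroplasmy
#' site TSV + report JSON, inverted-repeat TSV, Newick clone tree, and a
#' run manifest.
#'
#' @param out_dir Output directory (created if missing).
#' @param gene,amplicon,clones,gff Input file paths (FASTA / GFF3), or
#'   `NULL` when simulating.
#' @param sim A `sim_config` to simulate inputs instead of reading files.
#' @param arc Cloned-arc `interval`; defaults to the simulator's arc or the
#'   whole circle.
#' @param ir An `ir_params`.
#' @param align An `align_params`.
#' @return Invisibly, a list with the circle, clone matrix, report, IR
#'   hits, tree, and output paths.
#' @export
run_pipeline <- function(out_dir, gene = NULL, amplicon = NULL,
                         clones = NULL, gff = NULL, sim = NULL,
                         arc = NULL, ir = ir_params(),
                         align = align_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  code <- genetic_code(5L)
  if (!is.null(sim)) {
    log_stage("simulate", "seed %d, %d clones", sim$seed, sim$n_clones)
    gen <- generate_minicircle(sim)
    mc <- gen$circle
    cl <- generate_clones(gen, sim)
    clone_seqs <- cl$clones
    if (is.null(arc)) arc <- cl$arc
  } else {
    for (p in c(gene, amplicon, clones)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
    log_stage("assemble", "gene %s + amplicon %s", gene, amplicon)
    gseq <- read_fasta(gene)[[1L]]
    aseq <- read_fasta(amplicon)[[1L]]
    mc <- merge_amplicon(gseq, aseq)
    if (!is.null(gff)) {
      ft <- read_gff3(gff, seq_length(mc$seq))
      ft <- ft[ft$type != "gene", , drop = FALSE]  # gene comes from assembly
      for (i in seq_len(nrow(ft))) {
        mc <- add_feature(mc, ft$type[i], feature_interval(ft[i, ]),
                          ft$label[i])
      }
    }
    clone_seqs <- read_fasta(clones)
  }
  log_stage("annotate", "circle %d bp; start codon: %s",
            seq_length(mc$seq),
            classify_start(subseq_circular(mc$seq,
                                           get_feature(mc, "gene")))$category)
  log_stage("ir", "scanning inverted repeats")
  mc <- annotate_inverted_repeats(mc, ir)
  ir_hits <- attr(mc, "ir_hits")
  log_stage("map", "aligning %d clones", length(clone_seqs))
  cm <- map_clones(mc, clone_seqs, arc = arc, params = align)
  log_stage("het", "calling heteroplasmic sites")
  rep <- heteroplasmy_report(cm, mc, code, clones = clone_seqs)
  log_stage("tree", "neighbor-joining %d leaves", length(cm$clone_ids) + 1L)
  tr <- clone_tree(cm, mc)
  paths <- list(
    circle_fasta = file.path(out_dir, "circle.fasta"),
    circle_gff = file.path(out_dir, "circle.gff3"),
    clones_fasta = file.path(out_dir, "clones.fasta"),
    sites_tsv = file.path(out_dir, "sites.tsv"),
    ir_tsv = file.path(out_dir, "inverted_repeats.tsv"),
    tree_newick = file.path(out_dir, "clones.nwk"),
    summary_json = file.path(out_dir, "summary.json"))
  write_fasta(mc$seq, paths$circle_fasta,
              desc = if (!is.null(sim)) sprintf("seed=%d", sim$seed))
  write_gff3(mc, paths$circle_gff)
  write_fasta(clone_seqs, paths$clones_fasta,
              desc = if (!is.null(sim)) sprintf("seed=%d", sim$seed))
  write_site_table(rep, paths$sites_tsv)
  write_ir_table(ir_hits, paths$ir_tsv)
  ape::write.tree(tr, paths$tree_newick)
  summary <- list(
    run = list(seed = if (!is.null(sim)) sim$seed else NA,
               circle_length = seq_length(mc$seq),
               start_classification =
                 classify_start(subseq_circular(mc$seq,
                                                get_feature(mc, "gene")))$category,
               bookkeeping = length_bookkeeping(mc)),
    heteroplasmy = report_to_list(rep),
    inverted_repeats = list(n_hits = nrow(ir_hits),
                            top_score = if (nrow(ir_hits)) ir_hits$score[1L]
                                        else NA))
  jsonlite::write_json(summary, paths$summary_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("done", "outputs in %s", out_dir)
  invisible(list(circle = mc, matrix = cm, report = rep, ir_hits = ir_hits,
                 tree = tr, paths = paths))
}
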