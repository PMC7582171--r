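#' Run the full census pipeline on a synthetic genome
#'
#' Stages in dependency order: genome simulation, domain scan +
#' classification, census, exon-intron structure, gene density, motif
#' discovery (within the groups carrying planted motifs), reciprocal-
#' best-hit orthology against the reference panel combined with the
#' joint full-length tree, expression responsiveness, and the assay
#' statistics.  Deterministic for a fixed configuration; every number
#' in the report is re-derivable from the stage tables.
#'
#' @param config a [syn_config()]
#' @param outdir optional directory: stage tables are written as TSV
#'   after each stage completes
#' @param motif_widths candidate widths for the motif stage (kept
#'   narrow here; [discover_motifs()] defaults to the full 6-50 range)
#' @return report list with per-stage results
#' @export
run_census_pipeline <- function(config = syn_config(), outdir = NULL,
                                motif_widths = c(6L, 8L, 10L)) {
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(outdir))
      write.table(df, file.path(outdir, paste0(name, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  syn <- generate_genome(config)
  emit(syn$truth, "truth")
  refs <- make_reference_set()

  cls <- classify_proteins(syn$proteins, refs)
  emit(cls$assignments, "assignments")
  cen <- census(cls$assignments)

  struct <- structure_table(syn$models, cls$assignments)
  emit(struct$per_gene, "structure_per_gene")
  genome_mb <- sum(nchar(syn$genome)) / 1e6
  density <- gene_density(cen$total, genome_mb)

  # motif discovery inside the groups that carry planted motifs
  motif_res <- list()
  for (grp in names(config$motif_plants)) {
    ids <- cls$assignments$protein_id[
      !is.na(cls$assignments$group) & cls$assignments$group == grp]
    if (length(ids) >= 2L) {
      found <- discover_motifs(syn$proteins[ids], n_motifs = 1L,
                               widths = motif_widths)
      for (k in seq_along(found))
        found[[k]]$name <- sprintf("%s_%s", grp, found[[k]]$name)
      motif_res[[grp]] <- found
    }
  }
  presence <- if (length(motif_res) > 0)
    presence_matrix(unlist(motif_res, recursive = FALSE),
                    cls$assignments) else NULL

  # orthology against the reference panel, tree-validated
  ref_prot <- setNames(refs$full_seq, refs$id)
  calls <- rbh(syn$proteins, ref_prot)
  full_aln <- progressive_align(c(syn$proteins, ref_prot))
  full_tree <- nj_tree(alignment_distances(full_aln, "p"))
  ortho <- combine_with_tree(calls, full_tree,
                             names(syn$proteins), names(ref_prot))
  emit(ortho, "orthologs")

  design <- default_design()
  counts <- generate_counts(syn$truth, design, config)
  emit(data.frame(gene_id = rownames(counts), counts), "counts")
  lens <- vapply(syn$models, `[[`, 0L, "cds_length")
  fp <- fpkm(counts, lens)
  resp <- responsiveness(fp, design)
  emit(resp$calls, "responsiveness")
  clust <- hcluster(resp$log2fc)

  # qPCR validation of the first induced gene, luciferase for one TF
  ind <- syn$truth[syn$truth$induced, ]
  qpcr_res <- luc_res <- NULL
  if (nrow(ind) > 0) {
    fold <- matrix(c(1, ind$induction_fold[1], ind$induction_fold[1], 1),
                   1, 4, dimnames = list(ind$gene_id[1], c(0, 1, 4, 24)))
    qpcr_res <- ddct(generate_qpcr(fold, n_reps = 3L, config))
    emit(qpcr_res, "qpcr")
  }
  luc_res <- luc_relative(generate_luc(c(TF = 2.5), n_reps = 3L, config))
  emit(luc_res, "luc")

  truth_fam <- table(factor(syn$truth$family,
                            levels = c("AP2", "DREB", "ERF", "RAV",
                                       "Soloist")))
  report <- list(
    config = config,
    truth_family_counts = setNames(as.integer(truth_fam),
                                   names(truth_fam)),
    census = cen,
    structure_overall = struct$overall,
    structure_per_family = struct$per_family,
    genome_size_mb = genome_mb,
    gene_density = density,
    upregulated = resp$calls$gene_id[resp$calls$upregulated],
    cluster_order = clust$order,
    ortho_final_set = table(ortho$final_set),
    motif_presence = presence,
    qpcr = qpcr_res,
    luc = luc_res,
    assignments = cls$assignments,
    truth = syn$truth)
  if (!is.null(outdir))
    emit(data.frame(family = names(report$truth_family_counts),
                    truth = as.integer(truth_fam),
                    census = report$census$family[
                      names(report$truth_family_counts)]),
         "census_vs_truth")
  report
}
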