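#' Exon-intron structure statistics
#'
#' Per-gene intron counts plus per-family and per-group aggregation.
#' Percentages are rounded half-up to 1 decimal, matching how census
#' tables are conventionally printed.  Genes without an assignment are
#' aggregated under `"unassigned"`.
#'
#' @param models list of [gene_model()]
#' @param assignments optional data.frame with `protein_id`, `family`,
#'   `group`
#' @return list with `per_gene`, `per_family`, `per_group` data.frames
#'   and `overall` (n_genes, n_with_introns, pct_intronless)
#' @export
structure_table <- function(models, assignments = NULL) {
  per_gene <- do.call(rbind, lapply(models, function(m) {
    stopifnot(nrow(m$exons) >= 1L)
    data.frame(gene_id = m$gene_id, n_exons = nrow(m$exons),
               n_introns = nrow(m$exons) - 1L,
               intronless = nrow(m$exons) == 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  if (!is.null(assignments)) {
    m <- match(per_gene$gene_id, assignments$protein_id)
    per_gene$family <- ifelse(is.na(m), "unassigned", assignments$family[m])
    per_gene$group <- assignments$group[m]
  } else {
    per_gene$family <- "unassigned"
    per_gene$group <- NA_character_
  }

  summarize <- function(key) {
    keys <- unique(key[!is.na(key)])
    if (length(keys) == 0L)
      return(data.frame(category = character(0), n_genes = integer(0),
                        n_with_introns = integer(0),
                        pct_intronless = numeric(0)))
    out <- lapply(keys, function(k) {
      sub <- per_gene[!is.na(key) & key == k, ]
      category_stats(k, sub$intronless)
    })
    df <- do.call(rbind, out)
    df[order(df$category), , drop = FALSE]
  }
  list(per_gene = per_gene,
       per_family = summarize(per_gene$family),
       per_group = summarize(per_gene$group),
       overall = category_stats("all", per_gene$intronless))
}

category_stats <- function(name, intronless) {
  data.frame(category = name, n_genes = length(intronless),
             n_with_introns = sum(!intronless),
             pct_intronless = round_half_up(
               100 * mean(intronless), 1),
             stringsAsFactors = FALSE)
}

#' Gene density per megabase
#'
#' @param total_genes number of family members found in the genome
#' @param genome_size_mb assembly size in megabases (> 0)
#' @return density rounded half-up to 3 decimals
#' @export
gene_density <- function(total_genes, genome_size_mb) {
  if (!is.numeric(genome_size_mb) || genome_size_mb <= 0)
    stop("genome size must be > 0")
  round_half_up(total_genes / genome_size_mb, 3)
}
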