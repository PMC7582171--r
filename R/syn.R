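#' Configuration for the synthetic-data generators
#'
#' One seed governs every generator; each stage draws from its own
#' substream derived by a fixed offset, so outputs are byte-identical
#' under an identical configuration.
#'
#' Default family counts mirror a genome-wide AP2/ERF census of a
#' mid-size plant genome (20 AP2, 5 RAV, 47 DREB, 60 ERF, 2 Soloist);
#' DREB genes cycle through groups I-IV and ERF genes through groups
#' V-X and VI-L (group Xb-L is legal but receives no genes, so a
#' downstream census prints 0 for it).
#'
#' @param seed integer RNG seed
#' @param n_genes_per_family named counts for AP2, RAV, DREB, ERF, Soloist
#' @param domain_divergence per-site substitution probability applied to
#'   planted domains outside their diagnostic columns, in `[0, 1)`;
#'   values `>= 0.5` warn that truth may be unrecoverable
#' @param intron_rules named list mapping a group (or family for AP2,
#'   RAV, Soloist) to the vector of intron counts sampled uniformly
#' @param nb_dispersion relative extra-Poisson variance of simulated
#'   counts: `var = mu * (1 + nb_dispersion)`; 0 gives Poisson noise
#' @param base_expression_mean baseline mean count per gene
#' @param ct_sd standard deviation of qPCR Ct replicate noise (cycles)
#' @param luc_cv coefficient of variation of luciferase ratios
#' @param induced_groups groups whose genes are MeJA-induced
#' @param induction_fold expression fold applied to induced genes in
#'   MeJA samples at times > 0
#' @param ap2_single_domain_frac fraction of AP2-family genes planted
#'   with a single AP2 domain (recovered downstream by tree rescue)
#' @param motif_plants named list group -> protein motif word inserted
#'   into the C-terminal flank of that group's proteins
#' @return object of class `syn_config`
#' @export
syn_config <- function(seed = 1L,
                       n_genes_per_family = c(AP2 = 20L, RAV = 5L,
                                              DREB = 47L, ERF = 60L,
                                              Soloist = 2L),
                       domain_divergence = 0.05,
                       intron_rules = default_intron_rules(),
                       nb_dispersion = 0.05,
                       base_expression_mean = 500,
                       ct_sd = 0.2,
                       luc_cv = 0.05,
                       induced_groups = c("IX", "X", "III"),
                       induction_fold = 8,
                       ap2_single_domain_frac = 0.25,
                       motif_plants = list("IX" = "DSVWRGKH",
                                           "VIII" = "FDLNLAP")) {
  if (any(n_genes_per_family < 0)) stop("gene counts must be >= 0")
  stopifnot_scalar_number(domain_divergence, "domain_divergence", 0)
  if (domain_divergence >= 1) stop("domain_divergence must be < 1")
  if (domain_divergence >= 0.5)
    warning("domain_divergence >= 0.5: truth may be unrecoverable")
  stopifnot_scalar_number(nb_dispersion, "nb_dispersion", 0)
  stopifnot_scalar_number(base_expression_mean, "base_expression_mean", 0)
  stopifnot_scalar_number(ct_sd, "ct_sd", 0)
  stopifnot_scalar_number(luc_cv, "luc_cv", 0)
  structure(list(seed = as.integer(seed),
                 n_genes_per_family = n_genes_per_family,
                 domain_divergence = domain_divergence,
                 intron_rules = intron_rules,
                 nb_dispersion = nb_dispersion,
                 base_expression_mean = base_expression_mean,
                 ct_sd = ct_sd, luc_cv = luc_cv,
                 induced_groups = induced_groups,
                 induction_fold = induction_fold,
                 ap2_single_domain_frac = ap2_single_domain_frac,
                 motif_plants = motif_plants),
            class = "syn_config")
}

#' Default intron-count rules per family/group
#'
#' Groups III, VI, VI-L and IX are always intronless and every group
#' VII gene carries at least one intron; AP2-family genes carry 1-9
#' introns and Soloists 4-5, matching the structural regularities a
#' census of this superfamily reports.
#'
#' @return named list of integer vectors
#' @export
default_intron_rules <- function() {
  list(AP2 = 1:9, RAV = 0L, Soloist = 4:5,
       I = c(0L, 0L, 0L, 1L), II = c(0L, 0L, 0L, 1L), III = 0L,
       IV = c(0L, 0L, 0L, 1L), V = c(0L, 0L, 0L, 1L), VI = 0L,
       VII = 1:3, VIII = c(0L, 0L, 0L, 0L, 1L), IX = 0L,
       X = c(0L, 1L), "VI-L" = 0L, "Xb-L" = 0L)
}

resample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# mutate each non-fixed position with probability p to a different residue
apply_divergence <- function(seq, fixed, p) {
  if (p <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  free <- setdiff(seq_along(s), fixed)
  hit <- free[runif(length(free)) < p]
  for (i in hit) s[i] <- resample1(setdiff(AA_ALPHABET20, s[i]))
  paste(s, collapse = "")
}

# deterministic reverse translation: uniform draw among synonymous codons
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  codons_of <- split(names(gc), gc)
  aa <- strsplit(protein, "")[[1]]
  paste0(paste(vapply(aa, function(a) resample1(codons_of[[a]]), ""),
               collapse = ""), "TAA")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Generate a synthetic genome with planted AP2/ERF gene families
#'
#' Every gene carries the domain architecture of its family (AP2: two
#' AP2 domains; RAV: one AP2 + one B3; DREB/ERF: one AP2 with four
#' fixed group-diagnostic columns; Soloist: a divergent AP2 variant with
#' conserved flanks), an exon-intron structure drawn from the group's
#' intron rule (introns at codon boundaries with canonical GT..AG ends),
#' and a complete CDS ending in a stop codon.
#'
#' @param config a [syn_config()]
#' @return object of class `syn_genome`: named list with `genome`
#'   (named scaffold sequences), `models` (list of [gene_model()]),
#'   `proteins` (named character), `truth` (data.frame of truth labels),
#'   and serialized `genome_fasta`, `protein_fasta`, `gff3` text lines
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  n <- config$n_genes_per_family
  if (sum(n) == 0L) stop("configuration generates zero genes")

  erf_cycle <- c("V", "VI", "VII", "VIII", "IX", "X", "VI-L")
  plan <- list()
  for (fam in names(n)) {
    cnt <- n[[fam]]
    if (cnt == 0L) next
    groups <- switch(fam,
      DREB = rep(DREB_GROUPS, length.out = cnt),
      ERF = rep(erf_cycle, length.out = cnt),
      rep(NA_character_, cnt))
    single <- rep(FALSE, cnt)
    if (fam == "AP2" && config$ap2_single_domain_frac > 0) {
      k <- round(config$ap2_single_domain_frac * cnt)
      if (k > 0) single[seq(cnt - k + 1L, cnt)] <- TRUE
    }
    for (i in seq_len(cnt))
      plan[[length(plan) + 1L]] <- list(family = fam, group = groups[i],
                                        single_domain = single[i])
  }

  b3_cons <- consensus_sequence(domain_seed_alignment("B3"))
  genome <- character(0); models <- list(); proteins <- character(0)
  truth <- list()

  with_substream(config$seed, 1L, {
    for (gi in seq_along(plan)) {
      p <- plan[[gi]]
      gid <- sprintf("SYN%03d", gi)
      v <- domain_variant(p$family, p$group)
      dom <- function() apply_divergence(v$seq, v$fixed,
                                         config$domain_divergence)
      motif <- if (!is.na(p$group %||% NA))
        config$motif_plants[[p$group]] else NULL
      nfl <- if (p$family == "Soloist") SOLOIST_NFLANK
             else random_protein(sample(20:40, 1L))
      cfl <- if (p$family == "Soloist") SOLOIST_CFLANK
             else random_protein(sample(20:40, 1L))
      if (!is.null(motif) && !is.na(p$group))
        cfl <- paste0(substr(cfl, 1, 5), motif,
                      substr(cfl, 6, nchar(cfl)))
      core <- switch(p$family,
        AP2 = if (p$single_domain) dom()
              else paste0(dom(), random_protein(25L), dom()),
        RAV = paste0(dom(), random_protein(20L),
                     apply_divergence(b3_cons, integer(0),
                                      config$domain_divergence)),
        dom())
      protein <- paste0("M", nfl, core, cfl)
      cds <- reverse_translate(protein)

      grp <- p$group
      key <- if (is.na(grp %||% NA)) p$family else grp
      rule <- config$intron_rules[[key]] %||% 0L
      n_int <- resample1(rule)

      # split the CDS at distinct codon boundaries and insert introns
      n_cod <- nchar(cds) / 3L
      cuts <- if (n_int > 0) sort(sample(seq_len(n_cod - 1L), n_int)) * 3L
              else integer(0)
      starts <- c(0L, cuts); ends <- c(cuts, nchar(cds))
      exon_seqs <- substring(cds, starts + 1L, ends)
      intron_seqs <- if (n_int > 0)
        vapply(seq_len(n_int), function(i)
          paste0("GT", random_dna(sample(56:196, 1L)), "AG"), "")
        else character(0)

      gene_seq <- exon_seqs[1]
      for (i in seq_len(n_int))
        gene_seq <- paste0(gene_seq, intron_seqs[i], exon_seqs[i + 1L])
      strand <- sample(c("+", "-"), 1L)
      flankL <- random_dna(100L); flankR <- random_dna(100L)
      gl <- nchar(gene_seq)
      scaffold_seq <- paste0(flankL,
        if (strand == "+") gene_seq else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(gene_seq))),
        flankR)
      scf <- sprintf("scf_%s", gid)

      # exon offsets within the transcribed gene sequence
      off <- 100L
      ex_starts <- integer(0); pos <- 0L
      ivs <- matrix(integer(0), ncol = 2)
      for (i in seq_len(n_int + 1L)) {
        len <- nchar(exon_seqs[i])
        ivs <- rbind(ivs, c(pos, pos + len))
        pos <- pos + len + if (i <= n_int) nchar(intron_seqs[i]) else 0L
      }
      g_ivs <- if (strand == "+") ivs + off
               else cbind(off + gl - ivs[, 2], off + gl - ivs[, 1])

      model <- gene_model(gid, scf, strand, g_ivs, g_ivs)
      genome[scf] <- scaffold_seq
      model <- extract_protein(model, setNames(scaffold_seq, scf))
      stopifnot(model$protein == protein)
      models[[gid]] <- model
      proteins[gid] <- protein
      truth[[gid]] <- data.frame(
        gene_id = gid, family = p$family,
        group = if (is.na(grp %||% NA)) NA_character_ else grp,
        n_introns = n_int,
        induced = !is.na(grp %||% NA) && grp %in% config$induced_groups,
        induction_fold = if (!is.na(grp %||% NA) &&
                             grp %in% config$induced_groups)
                           config$induction_fold else 1,
        planted_motifs = if (!is.null(motif)) motif else "",
        stringsAsFactors = FALSE)
    }
  })

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(genome = genome, models = models, proteins = proteins,
                 truth = truth,
                 genome_fasta = write_fasta(genome),
                 protein_fasta = write_fasta(proteins),
                 gff3 = write_gff3(models)),
            class = "syn_genome")
}

#' @export
print.syn_genome <- function(x, ...) {
  cat(sprintf("<syn_genome: %d genes on %d scaffolds>\n",
              nrow(x$truth), length(x$genome)))
  invisible(x)
}

#' Default MeJA/mock time-course sample design
#'
#' Paired mock samples at every time point, one replicate each (the
#' profiling design this pipeline targets has no sequencing replicates).
#'
#' @param times time points in hours
#' @param n_reps replicates per treatment x time
#' @return data.frame with sample_id, treatment, time_h, replicate
#' @export
default_design <- function(times = c(0, 0.5, 1, 3, 6, 12), n_reps = 1L) {
  g <- expand.grid(replicate = seq_len(n_reps), time_h = times,
                   treatment = c("mock", "MeJA"),
                   stringsAsFactors = FALSE)
  g <- g[, c("treatment", "time_h", "replicate")]
  g$sample_id <- sprintf("%s_%sh_r%d", g$treatment,
                         format(g$time_h, trim = TRUE), g$replicate)
  g[, c("sample_id", "treatment", "time_h", "replicate")]
}

#' Simulate a read-count matrix for the MeJA/mock time course
#'
#' Counts are negative binomial with `var = mu * (1 + nb_dispersion)`
#' (`nb_dispersion = 0` gives Poisson noise).  Induced genes have their
#' mean multiplied by `induction_fold` in MeJA samples at times > 0;
#' all other gene/sample means are shared across treatments.
#'
#' The returned matrix carries a `total_fragments` attribute: the
#' per-sample total mapped fragments, i.e. the census genes' counts
#' plus `background_fragments` for the rest of the transcriptome.
#' FPKM denominators should use these totals; using the column sums of
#' a matrix restricted to one gene family would introduce a strong
#' composition bias whenever many family members are induced.
#'
#' @param truth truth-label data.frame from [generate_genome()]
#' @param design sample design data.frame (see [default_design()])
#' @param config a [syn_config()]
#' @param background_fragments mapped fragments outside the census
#'   genes, per sample
#' @return integer matrix, genes x samples, with attribute
#'   `total_fragments`
#' @export
generate_counts <- function(truth, design = default_design(), config,
                            background_fragments = 1e6) {
  stopifnot(inherits(config, "syn_config"))
  if (!any(design$treatment == "mock" & design$time_h == 0))
    stop("design lacks a mock 0 h sample: baseline undefined")
  ng <- nrow(truth)
  with_substream(config$seed, 2L, {
    base_mu <- config$base_expression_mean * 2^rnorm(ng, 0, 1)
    counts <- matrix(0L, ng, nrow(design),
                     dimnames = list(truth$gene_id, design$sample_id))
    for (s in seq_len(nrow(design))) {
      mu <- base_mu
      if (design$treatment[s] == "MeJA" && design$time_h[s] > 0)
        mu <- ifelse(truth$induced, mu * truth$induction_fold, mu)
      counts[, s] <- if (config$nb_dispersion == 0) rpois(ng, mu)
                     else rnbinom(ng, mu = mu,
                                  size = mu / config$nb_dispersion)
    }
    attr(counts, "total_fragments") <-
      colSums(counts) + background_fragments
    counts
  })
}

#' Simulate qPCR Ct tables with known true fold changes
#'
#' Ct_target = Ct_reference + dCt_baseline - log2(fold) + N(0, ct_sd);
#' the reference-gene Ct is fixed, emulating a stable internal control.
#' Mock samples at every time point have fold 1.
#'
#' @param fold_matrix genes x times numeric matrix of true MeJA fold
#'   changes relative to mock 0 h (dimnames required)
#' @param n_reps biological replicates per group (>= 2)
#' @param config a [syn_config()]
#' @param ct_reference reference-gene Ct (cycles)
#' @param dct_baseline true target-minus-reference dCt at mock 0 h
#' @return data.frame: gene, treatment, time_h, replicate, ct_target,
#'   ct_reference
#' @export
generate_qpcr <- function(fold_matrix, n_reps = 3L, config,
                          ct_reference = 18, dct_baseline = 5) {
  stopifnot(inherits(config, "syn_config"))
  if (n_reps < 2L) stop("need n_reps >= 2")
  genes <- rownames(fold_matrix); times <- as.numeric(colnames(fold_matrix))
  if (any(ct_reference + dct_baseline - log2(fold_matrix) < 0))
    stop("requested fold changes imply negative Ct values")
  rows <- list()
  with_substream(config$seed, 3L, {
    for (g in seq_along(genes)) for (ti in seq_along(times))
      for (trt in c("mock", "MeJA")) for (r in seq_len(n_reps)) {
        fold <- if (trt == "MeJA") fold_matrix[g, ti] else 1
        ct <- ct_reference + dct_baseline - log2(fold) +
          rnorm(1, 0, config$ct_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes[g], treatment = trt, time_h = times[ti],
          replicate = r, ct_target = ct, ct_reference = ct_reference,
          stringsAsFactors = FALSE)
      }
  })
  do.call(rbind, rows)
}

#' Simulate dual-luciferase luminescence tables
#'
#' Firefly/renilla ratios have coefficient of variation `luc_cv` around
#' the true transactivation activity; the vector control (VC) defines
#' activity 1 and is always included.
#'
#' @param activities named numeric vector of true effector activities
#'   relative to VC
#' @param n_reps biological transfections per construct (>= 2)
#' @param config a [syn_config()]
#' @return data.frame: effector, replicate, firefly, renilla
#' @export
generate_luc <- function(activities, n_reps = 3L, config) {
  stopifnot(inherits(config, "syn_config"))
  if (n_reps < 2L) stop("need n_reps >= 2")
  if (!("VC" %in% names(activities)))
    activities <- c(VC = 1, activities)
  renilla <- 1e4; base_ratio <- 0.5
  rows <- list()
  with_substream(config$seed, 4L, {
    for (e in names(activities)) for (r in seq_len(n_reps)) {
      ratio <- base_ratio * activities[[e]] *
        (1 + rnorm(1, 0, config$luc_cv))
      rows[[length(rows) + 1L]] <- data.frame(
        effector = e, replicate = r, firefly = ratio * renilla,
        renilla = renilla, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
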