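small_cfg <- function(seed = 7, ...)
  syn_config(seed = seed,
             n_genes_per_family = c(AP2 = 2L, RAV = 1L, DREB = 4L,
                                    ERF = 7L, Soloist = 1L), ...)

test_that("genome generation is deterministic and structurally truthful", {
  g1 <- generate_genome(small_cfg())
  g2 <- generate_genome(small_cfg())
  expect_identical(g1$genome_fasta, g2$genome_fasta)
  expect_identical(g1$gff3, g2$gff3)
  expect_identical(g1$truth, g2$truth)
  expect_equal(nrow(g1$truth), 15L)

  # exon count - 1 = truth introns; protein length = cds/3 - 1
  for (gid in g1$truth$gene_id) {
    m <- g1$models[[gid]]
    expect_equal(nrow(m$exons) - 1L,
                 g1$truth$n_introns[g1$truth$gene_id == gid])
    expect_equal(nchar(m$protein), m$cds_length / 3 - 1)
  }
  # canonical intron ends on the coding strand
  m <- g1$models[[which(g1$truth$n_introns > 0)[1]]]
  scf <- g1$genome[[m$scaffold]]
  ex <- m$exons
  intr <- cbind(ex[-nrow(ex), 2], ex[-1, 1])
  for (i in seq_len(nrow(intr))) {
    s <- substr(scf, intr[i, 1] + 1, intr[i, 2])
    if (m$strand == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    expect_equal(substr(s, 1, 2), "GT")
    expect_equal(substr(s, nchar(s) - 1, nchar(s)), "AG")
  }
})

test_that("intron rules and divergence guards behave as configured", {
  cfg <- syn_config(seed = 3, n_genes_per_family = c(ERF = 14L),
                    intron_rules = within_rules <- modifyList(
                      default_intron_rules(), list(IX = 0L)))
  g <- generate_genome(cfg)
  ix <- g$truth[g$truth$group %in% c("IX", "III", "VI", "VI-L"), ]
  expect_true(all(ix$n_introns == 0))
  vii <- g$truth[g$truth$group == "VII", ]
  expect_true(all(vii$n_introns >= 1))

  expect_warning(syn_config(domain_divergence = 0.6), "unrecoverable")
  expect_error(generate_genome(
    syn_config(n_genes_per_family = c(AP2 = 0L))), "zero genes")
})

test_that("zero divergence plants exact consensus domains with maximal score", {
  cfg <- syn_config(seed = 5, domain_divergence = 0,
                    n_genes_per_family = c(ERF = 2L))
  g <- generate_genome(cfg)
  v <- domain_variant("ERF", g$truth$group[1])
  expect_true(grepl(v$seq, g$proteins[[1]], fixed = TRUE))

  # the seed-alignment consensus attains the PSSM's maximal score
  p <- get_pssms()$AP2
  cons <- consensus_sequence(domain_seed_alignment("AP2"))
  idx <- match(strsplit(cons, "")[[1]], AA20)
  sc <- sum(p$log_odds[cbind(seq_len(p$width), idx)])
  expect_equal(sc, sum(apply(p$log_odds, 1, max)))
  hits <- scan_pssm(g$proteins[[1]], p)
  expect_true(any(hits$complete))
})

test_that("count simulation honours the null, the fold and the baseline", {
  d <- default_design()
  cfg <- syn_config(seed = 2, n_genes_per_family = c(DREB = 8L, ERF = 7L),
                    induced_groups = character(0), nb_dispersion = 0.05)
  g <- generate_genome(cfg)
  cts <- generate_counts(g$truth, d, cfg)
  expect_true(all(colSums(cts) > 0))
  expect_identical(cts, generate_counts(g$truth, d, cfg))
  # null: MeJA/mock log2 ratios hover near 0
  meja <- rowMeans(cts[, d$treatment == "MeJA"])
  mock <- rowMeans(cts[, d$treatment == "mock"])
  expect_lt(max(abs(log2(meja / mock))), 0.5)

  cfg8 <- syn_config(seed = 2, n_genes_per_family = c(ERF = 7L),
                     induced_groups = "IX", induction_fold = 8,
                     nb_dispersion = 0)
  g8 <- generate_genome(cfg8)
  c8 <- generate_counts(g8$truth, d, cfg8)
  ind <- g8$truth$induced
  fc <- log2(rowMeans(c8[ind, d$treatment == "MeJA" & d$time_h > 0,
                         drop = FALSE]) /
             rowMeans(c8[ind, d$treatment == "mock", drop = FALSE]))
  expect_equal(unname(fc), rep(3, sum(ind)), tolerance = 0.1)

  bad <- d[!(d$treatment == "mock" & d$time_h == 0), ]
  expect_error(generate_counts(g8$truth, bad, cfg8), "mock 0 h")
})

test_that("qPCR and luciferase generators recover their planted truth", {
  cfg0 <- syn_config(seed = 1, ct_sd = 0, luc_cv = 0)
  fold <- matrix(c(1, 70, 8, 1), 1, 4,
                 dimnames = list("G1", c(0, 1, 4, 24)))
  q <- generate_qpcr(fold, n_reps = 3, cfg0)
  res <- suppressWarnings(ddct(q))
  expect_equal(res$mean_rq[res$treatment == "MeJA" & res$time_h == 1], 70)
  expect_equal(res$mean_rq[res$treatment == "MeJA" & res$time_h == 4], 8)
  expect_true(all(res$mean_rq[res$treatment == "mock"] == 1))

  luc <- generate_luc(c(TF = 2.5), n_reps = 3, cfg0)
  rel <- suppressWarnings(luc_relative(luc))
  expect_equal(rel$mean_relative[rel$effector == "TF"], 2.5)
  expect_equal(rel$mean_relative[rel$effector == "VC"], 1)

  expect_error(generate_qpcr(matrix(2^40, 1, 1,
                                    dimnames = list("G1", "1")),
                             n_reps = 2, cfg0), "negative Ct")
  expect_error(generate_qpcr(fold, n_reps = 1, cfg0), "n_reps")
})
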