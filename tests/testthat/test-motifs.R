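plant_word <- function(n_seqs, word, len = 50, in_frac = 1) {
  has <- seq_len(n_seqs) <= round(in_frac * n_seqs)
  offs <- integer(n_seqs)
  seqs <- vapply(seq_len(n_seqs), function(i) {
    s <- rand_prot(len)
    if (!has[i]) return(s)
    off <- sample(seq_len(len - nchar(word)), 1)
    offs[i] <<- off
    paste0(substr(s, 1, off), word, substr(s, off + 1, len))
  }, "")
  names(seqs) <- sprintf("s%02d", seq_len(n_seqs))
  list(seqs = seqs, offsets = offs, has = has)
}

overlap_ok <- function(site_off, w, planted_off, planted_w) {
  !is.na(site_off) &&
    min(site_off + w, planted_off + planted_w) -
      max(site_off, planted_off) >= planted_w / 2
}

test_that("a planted motif is recovered in every carrier sequence", {
  set.seed(4)
  p <- plant_word(10, "DSVWRGKH")
  mo <- discover_motifs(p$seqs, n_motifs = 1, widths = seq(6, 12, 2))
  expect_length(mo, 1)
  m <- mo[[1]]
  sites <- m$sites
  expect_equal(sum(!is.na(sites$offset0)), 10)
  for (i in 1:10)
    expect_true(overlap_ok(sites$offset0[i], m$width,
                           p$offsets[i], 8))
  # site p-values feed the capped display height
  expect_true(all(sites$height <= 10))
  expect_true(all(sites$height[!is.na(sites$height)] > 0))
})

test_that("ZOOPS finds sites only in carrier sequences", {
  set.seed(8)
  p <- plant_word(10, "WWHHKKQQEE", in_frac = 0.5)
  mo <- discover_motifs(p$seqs, n_motifs = 1, widths = seq(6, 12, 2))
  sites <- mo[[1]]$sites
  found <- !is.na(sites$offset0)
  expect_equal(sum(found & p$has), 5)
  expect_equal(sum(found & !p$has), 0)
})

test_that("uniform noise yields lower motif LLR than a planted signal", {
  set.seed(15)
  noise <- setNames(vapply(1:10, function(i) rand_prot(50), ""),
                    paste0("n", 1:10))
  m_noise <- discover_motifs(noise, n_motifs = 1, widths = c(8))
  p <- plant_word(10, "DSVWRGKH")
  m_plant <- discover_motifs(p$seqs, n_motifs = 1, widths = c(8))
  expect_lt(m_noise[[1]]$llr, m_plant[[1]]$llr)
})

test_that("motif sites never overlap across successive motifs", {
  set.seed(22)
  p1 <- plant_word(8, "DSVWRGKH", len = 60)
  # add a second, disjoint planted word
  seqs <- vapply(seq_along(p1$seqs), function(i)
    paste0(p1$seqs[[i]], "GG", "FDLNLAPW", rand_prot(5)), "")
  names(seqs) <- names(p1$seqs)
  mo <- discover_motifs(seqs, n_motifs = 2, widths = c(8))
  expect_gte(length(mo), 2)
  for (sid in names(seqs)) {
    ivs <- lapply(mo, function(m) {
      r <- m$sites[m$sites$seq_id == sid, ]
      if (is.na(r$offset0)) NULL else c(r$offset0, r$offset0 + m$width)
    })
    ivs <- Filter(Negate(is.null), ivs)
    if (length(ivs) == 2)
      expect_lte(min(ivs[[1]][2], ivs[[2]][2]),
                 max(ivs[[1]][1], ivs[[2]][1]))
  }
})

test_that("presence matrix localizes group-specific motifs", {
  g <- generate_genome(syn_config(
    seed = 19, n_genes_per_family = c(ERF = 14L),
    motif_plants = list(IX = "DSVWRGKH")))
  asn <- data.frame(protein_id = g$truth$gene_id, family = g$truth$family,
                    group = g$truth$group, stringsAsFactors = FALSE)
  ix <- g$truth$gene_id[g$truth$group == "IX"]
  mo <- discover_motifs(g$proteins[ix], n_motifs = 1,
                        widths = seq(6, 10, 2))
  pm <- presence_matrix(mo, asn)
  expect_gt(pm["IX", 1], 0)
  expect_true(all(pm[setdiff(rownames(pm), "IX"), 1] == 0))

  expect_equal(dim(presence_matrix(list(), asn)), c(0, 0))
})
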