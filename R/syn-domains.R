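# Domain consensus fixtures and family/group sequence variants.
#
# The packaged AP2 (60 columns) and B3 (40 columns) seed alignments are
# small hand-built synthetic stand-ins for curated domain models; their
# consensus sequences seed both the PSSMs and the planted domains of the
# synthetic genomes.  Each DREB/ERF group variant fixes 4 diagnostic
# columns of the AP2 consensus so that phylogenetic group recovery is
# possible at desk scale.

DREB_GROUPS <- c("I", "II", "III", "IV")
ERF_GROUPS  <- c("V", "VI", "VII", "VIII", "IX", "X", "VI-L", "Xb-L")
ALL_GROUPS  <- c(DREB_GROUPS, ERF_GROUPS)

#' Load a packaged domain seed alignment
#'
#' @param model `"AP2"` or `"B3"`
#' @return named character vector of aligned sequences
#' @export
domain_seed_alignment <- function(model = c("AP2", "B3")) {
  model <- match.arg(model)
  f <- system.file("extdata",
                   if (model == "AP2") "ap2_seed_alignment_synthetic.fasta"
                   else "b3_seed_alignment_synthetic.fasta",
                   package = "tfcensus", mustWork = TRUE)
  read_fasta(f, type = "AA")
}

#' Majority-rule consensus of an ungapped alignment
#'
#' Ties broken by alphabet order (deterministic).
#'
#' @param alignment named character vector of equal-length sequences
#' @return consensus string
#' @export
consensus_sequence <- function(alignment) {
  m <- do.call(rbind, strsplit(unname(alignment), ""))
  paste(apply(m, 2, function(col) {
    col <- col[col != "-"]
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  }), collapse = "")
}

# shift a residue k steps along the fixed 20-letter alphabet
shift_residue <- function(ch, k) {
  i <- match(ch, AA_ALPHABET20)
  AA_ALPHABET20[(i - 1L + k) %% 20L + 1L]
}

substitute_at <- function(seq, positions, shift) {
  s <- strsplit(seq, "")[[1]]
  s[positions] <- vapply(s[positions], shift_residue, "", k = shift)
  paste(s, collapse = "")
}

# Diagnostic columns: group k (1..12) owns AP2-consensus columns
# 4(k-1)+1 .. 4k; the AP2 family variant owns columns 49-60, the RAV
# AP2-domain variant columns 49-56, the Soloist variant every odd column.
group_marker_columns <- function(group) {
  k <- match(group, ALL_GROUPS)
  if (is.na(k)) stop("unknown DREB/ERF group: ", group)
  (4L * (k - 1L) + 1L):(4L * k)
}

#' AP2-domain sequence variant for a family or DREB/ERF group
#'
#' Returns the planted domain sequence together with the diagnostic
#' column positions that the genome generator never mutates, so truth
#' stays recoverable under divergence.
#'
#' @param family one of `AP2`, `RAV`, `DREB`, `ERF`, `Soloist`
#' @param group DREB/ERF group label (required for those families)
#' @return list with `seq` and `fixed` (integer positions)
#' @export
domain_variant <- function(family, group = NA) {
  cons <- consensus_sequence(domain_seed_alignment("AP2"))
  switch(family,
    AP2 = {
      pos <- 49:60
      list(seq = substitute_at(cons, pos, 3L), fixed = pos)
    },
    RAV = {
      pos <- 49:56
      list(seq = substitute_at(cons, pos, 5L), fixed = pos)
    },
    Soloist = {
      pos <- seq(1L, 59L, by = 2L)
      list(seq = substitute_at(cons, pos, 11L), fixed = pos)
    },
    DREB = ,
    ERF = {
      pos <- group_marker_columns(group)
      list(seq = substitute_at(cons, pos, 7L), fixed = pos)
    },
    stop("unknown family: ", family))
}

# Conserved Soloist flanking regions: the Soloist family is recognized by
# full-length homology, so its proteins share characteristic flanks.
SOLOIST_NFLANK <- "MSDQLKTPEWIAQHRGNVLSTEAPF"
SOLOIST_CFLANK <- "GWESKVTDHLRAMPQNEYFSICKDL"

#' Build the labelled reference protein set
#'
#' Emulates a panel of curated family/group anchors: two slightly
#' perturbed references per DREB/ERF group (including Xb-L, which may
#' legitimately collect zero census members), two AP2, one RAV and two
#' Soloist anchors.  Perturbations avoid diagnostic columns.
#'
#' @param seed integer seed for the reference flanks
#' @return data.frame with id, family, group, domain_seq, full_seq
#' @export
make_reference_set <- function(seed = 101L) {
  rows <- list()
  add <- function(id, family, group, domain_seq, full_seq)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, family = family, group = group,
      domain_seq = domain_seq, full_seq = full_seq,
      stringsAsFactors = FALSE)

  with_substream(seed, 0L, {
    for (g in ALL_GROUPS) {
      v <- domain_variant(if (g %in% DREB_GROUPS) "DREB" else "ERF", g)
      free <- setdiff(seq_len(nchar(v$seq)), v$fixed)
      for (r in 1:2) {
        dseq <- substitute_at(v$seq, sample(free, 2L), if (r == 1) 1L else 2L)
        flankN <- random_protein(15L)
        flankC <- random_protein(15L)
        fam <- if (g %in% DREB_GROUPS) "DREB" else "ERF"
        add(sprintf("REF_%s_%s_%d", fam, g, r), fam, g, dseq,
            paste0(flankN, dseq, flankC))
      }
    }
    for (r in 1:2) {
      v <- domain_variant("AP2")
      free <- setdiff(seq_len(nchar(v$seq)), v$fixed)
      d1 <- substitute_at(v$seq, sample(free, 2L), r)
      d2 <- substitute_at(v$seq, sample(free, 2L), r + 1L)
      add(sprintf("REF_AP2_%d", r), "AP2", NA,
          d1, paste0(random_protein(15L), d1, random_protein(25L), d2,
                     random_protein(15L)))
    }
    vr <- domain_variant("RAV")
    b3 <- consensus_sequence(domain_seed_alignment("B3"))
    add("REF_RAV_1", "RAV", NA, vr$seq,
        paste0(random_protein(15L), vr$seq, random_protein(20L), b3,
               random_protein(10L)))
    for (r in 1:2) {
      vs <- domain_variant("Soloist")
      free <- setdiff(seq_len(nchar(vs$seq)), vs$fixed)
      d <- substitute_at(vs$seq, sample(free, r), 1L)
      add(sprintf("REF_Soloist_%d", r), "Soloist", NA, d,
          paste0(SOLOIST_NFLANK, d, SOLOIST_CFLANK))
    }
  })
  do.call(rbind, rows)
}

random_protein <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}
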