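#' Gene model: exon/CDS structure of one gene on a scaffold
#'
#' Internal coordinates are 0-based half-open throughout the package;
#' serialized GFF3 is 1-based inclusive.  The CDS includes the terminal
#' stop codon, so a complete CDS of `L` bp encodes `L/3 - 1` amino acids.
#'
#' @param gene_id gene identifier
#' @param scaffold scaffold/sequence name
#' @param strand `"+"` or `"-"`
#' @param exons integer matrix with columns `start`, `end` (0-based
#'   half-open), one row per exon, sorted by start
#' @param cds_intervals same convention, subset of the exons
#' @param protein translated protein sequence (may be `NA` before
#'   translation)
#' @return an object of class `gene_model`
#' @export
gene_model <- function(gene_id, scaffold, strand, exons, cds_intervals,
                       protein = NA_character_) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  cds_intervals <- matrix(as.integer(cds_intervals), ncol = 2,
                          dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds_intervals <- cds_intervals[order(cds_intervals[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stop("empty exon in gene ", gene_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in gene ", gene_id)
  structure(list(gene_id = gene_id, scaffold = scaffold, strand = strand,
                 exons = exons, cds_intervals = cds_intervals,
                 cds_length = sum(cds_intervals[, 2] - cds_intervals[, 1]),
                 protein = protein),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s %s:%s %d exon(s), CDS %d bp>\n",
              x$gene_id, x$scaffold, x$strand, nrow(x$exons), x$cds_length))
  invisible(x)
}

n_introns <- function(model) nrow(model$exons) - 1L

#' Translate a coding sequence to protein
#'
#' Standard genetic code.  A terminal stop codon is dropped, so a CDS of
#' 339 bp with its stop encodes a 112-aa protein.  A CDS lacking a
#' terminal stop is accepted (with a message) and translates to `L/3`
#' residues; an internal stop is an error naming the offending codon.
#'
#' @param cds nucleotide string, length divisible by 3
#' @return amino-acid string
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) == 0L) stop("empty CDS")
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length ", nchar(cds), " not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  n <- nchar(aa)
  stops <- which(strsplit(aa, "")[[1]] == "*")
  internal <- stops[stops < n]
  if (length(internal) > 0L)
    stop("internal stop codon at codon offset ", internal[1] - 1L)
  if (n > 0L && substr(aa, n, n) == "*") {
    aa <- substr(aa, 1L, n - 1L)
  } else {
    message("CDS has no terminal stop codon; translating all ", n, " codons")
  }
  aa
}

#' Extract and translate the CDS of a gene model from its genome
#'
#' Minus-strand CDS intervals are concatenated in genomic order and
#' reverse-complemented, i.e. translated in transcription order.
#'
#' @param model a [gene_model()]
#' @param genome named `DNAStringSet` (or named character vector)
#' @return the model with `protein` filled in
#' @export
extract_protein <- function(model, genome) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  seq <- genome[[model$scaffold]]
  parts <- apply(model$cds_intervals, 1, function(iv)
    as.character(Biostrings::subseq(seq, iv[1] + 1L, iv[2])))
  cds <- paste(parts, collapse = "")
  if (model$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds)))
  model$protein <- tryCatch(translate_cds(cds),
    error = function(e) stop("gene ", model$gene_id, ": ",
                             conditionMessage(e), call. = FALSE))
  model
}

#' Read gene models from GFF3
#'
#' Expects `gene`/`mRNA`/`exon`/`CDS` features with `ID=`/`Parent=`
#' attributes (one mRNA per gene).  Features whose `Parent` is missing are
#' skipped with a warning.  If `genome` is supplied, proteins are
#' translated; a CDS whose length is not divisible by 3 raises an error
#' naming the gene.
#'
#' @param gff path to a GFF3 file, or GFF3 text (detected by newlines)
#' @param genome optional named `DNAStringSet` / character vector
#' @return named list of [gene_model()] objects, sorted by gene id
#' @export
read_gff3 <- function(gff, genome = NULL) {
  path <- gff
  if (length(gff) > 1L || grepl("\n", gff[1])) {
    path <- tempfile(fileext = ".gff3")
    writeLines(gff, path)
    on.exit(unlink(path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ == "mRNA"]
  mrna_parent <- vapply(mrna$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  gene_of_mrna <- setNames(mrna_parent, mrna$ID)

  models <- list()
  for (feat in c("exon", "CDS")) {
    sub <- gr[typ == feat]
    par <- vapply(sub$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    if (anyNA(par)) {
      warning(sum(is.na(par)), " ", feat,
              " feature(s) without Parent skipped")
      sub <- sub[!is.na(par)]
      par <- par[!is.na(par)]
    }
    for (k in seq_along(sub)) {
      gid <- gene_of_mrna[[par[k]]] %||% par[k]
      if (is.na(gid)) gid <- par[k]
      m <- models[[gid]] %||% list(exons = NULL, cds = NULL,
                                   scaffold = NA, strand = NA)
      iv <- c(GenomicRanges::start(sub[k]) - 1L, GenomicRanges::end(sub[k]))
      slot <- if (feat == "exon") "exons" else "cds"
      m[[slot]] <- rbind(m[[slot]], iv)
      m$scaffold <- as.character(GenomicRanges::seqnames(sub[k]))
      m$strand <- as.character(BiocGenerics::strand(sub[k]))
      models[[gid]] <- m
    }
  }

  out <- lapply(sort(names(models)), function(gid) {
    m <- models[[gid]]
    gm <- gene_model(gid, m$scaffold, m$strand, m$exons, m$cds)
    if (gm$cds_length %% 3L != 0L)
      stop("gene ", gid, ": CDS length ", gm$cds_length,
           " not divisible by 3", call. = FALSE)
    if (!is.null(genome)) gm <- extract_protein(gm, genome)
    gm
  })
  setNames(out, sort(names(models)))
}

#' Serialize gene models to GFF3 text
#'
#' 1-based inclusive coordinates, `gene`/`mRNA`/`exon`/`CDS` rows with
#' `ID=`/`Parent=` attributes, records sorted by gene id.
#'
#' @param models list of [gene_model()]
#' @return character vector of GFF3 lines
#' @export
write_gff3 <- function(models) {
  models <- models[order(vapply(models, `[[`, "", "gene_id"))]
  lines <- "##gff-version 3"
  for (m in models) {
    g1 <- min(m$exons[, 1]) + 1L; g2 <- max(m$exons[, 2])
    row <- function(type, s, e, attrs)
      sprintf("%s\ttfcensus\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              m$scaffold, type, s, e, m$strand,
              if (type == "CDS") "0" else ".", attrs)
    lines <- c(lines,
      row("gene", g1, g2, sprintf("ID=%s", m$gene_id)),
      row("mRNA", g1, g2, sprintf("ID=%s.t1;Parent=%s", m$gene_id,
                                  m$gene_id)))
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, row("exon", m$exons[i, 1] + 1L, m$exons[i, 2],
                            sprintf("ID=%s.exon%d;Parent=%s.t1",
                                    m$gene_id, i, m$gene_id)))
    for (i in seq_len(nrow(m$cds_intervals)))
      lines <- c(lines, row("CDS", m$cds_intervals[i, 1] + 1L,
                            m$cds_intervals[i, 2],
                            sprintf("ID=%s.cds%d;Parent=%s.t1",
                                    m$gene_id, i, m$gene_id)))
  }
  lines
}

#' Write sequences as FASTA text (60-column wrap, records sorted by id)
#'
#' @param seqs named character vector of sequences
#' @return character vector of FASTA lines
#' @export
write_fasta <- function(seqs) {
  seqs <- seqs[order(names(seqs))]
  unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = 60L)
    c(paste0(">", id), substring(s, starts, pmin(starts + 59L, nchar(s))))
  }))
}

#' Read FASTA text or file into a named character vector
#'
#' @param fasta path or FASTA text (detected by a leading `>`)
#' @param type `"AA"` or `"DNA"` (validation alphabet only)
#' @return named character vector
#' @export
read_fasta <- function(fasta, type = c("AA", "DNA")) {
  type <- match.arg(type)
  path <- fasta
  if (length(fasta) > 1L || startsWith(fasta[1], ">")) {
    path <- tempfile(fileext = ".fasta")
    writeLines(fasta, path)
    on.exit(unlink(path))
  }
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  setNames(as.character(set), sub("\\s.*$", "", names(set)))
}
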