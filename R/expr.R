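#' FPKM normalization
#'
#' `FPKM = counts * 1e9 / (total_fragments * exon_length_bp)`.
#'
#' @param counts genes x samples count matrix
#' @param gene_lengths_bp named summed exon lengths (> 0)
#' @param totals per-sample total mapped fragments (> 0); defaults to
#'   the matrix's `total_fragments` attribute (set by
#'   [generate_counts()]) or, failing that, its column sums
#' @return FPKM matrix with the same dimnames
#' @export
fpkm <- function(counts, gene_lengths_bp, totals = NULL) {
  if (is.null(totals))
    totals <- attr(counts, "total_fragments") %||% colSums(counts)
  counts <- as.matrix(counts)
  gene_lengths_bp <- gene_lengths_bp[rownames(counts)]
  if (any(is.na(gene_lengths_bp)) || any(gene_lengths_bp <= 0))
    stop("gene lengths must be > 0 for every gene in the matrix")
  if (any(totals <= 0)) stop("per-sample totals must be > 0")
  sweep(sweep(counts, 2, totals, "/"), 1, gene_lengths_bp, "/") * 1e9
}

#' MeJA-responsiveness calls from an FPKM matrix
#'
#' Per-sample `log2 FC = log2(FPKM + pc) - log2(mean baseline FPKM +
#' pc)`, the baseline being the mock 0 h replicate mean.  A gene is
#' upregulated when its maximum log2 FC over MeJA samples strictly
#' exceeds `threshold` (so a change of exactly 1 is not called), and
#' downregulated symmetrically.
#'
#' @param fpkm_mat genes x samples FPKM matrix
#' @param design sample design (see [default_design()])
#' @param pseudocount offset inside the log
#' @param threshold log2 fold-change call threshold
#' @return list with `log2fc` (genes x samples) and `calls`
#'   (gene_id, max_log2fc, time_of_max, upregulated, downregulated)
#' @export
responsiveness <- function(fpkm_mat, design, pseudocount = 1,
                           threshold = 1) {
  base_cols <- design$sample_id[design$treatment == "mock" &
                                  design$time_h == 0]
  if (length(base_cols) == 0L) stop("design lacks a mock 0 h baseline")
  baseline <- rowMeans(fpkm_mat[, base_cols, drop = FALSE])
  log2fc <- log2(fpkm_mat + pseudocount) -
    log2(baseline + pseudocount)
  meja <- design$sample_id[design$treatment == "MeJA"]
  fc_meja <- log2fc[, meja, drop = FALSE]
  imax <- max.col(fc_meja, ties.method = "first")
  calls <- data.frame(
    gene_id = rownames(fpkm_mat),
    max_log2fc = fc_meja[cbind(seq_len(nrow(fc_meja)), imax)],
    time_of_max = design$time_h[match(meja[imax], design$sample_id)],
    stringsAsFactors = FALSE)
  calls$upregulated <- calls$max_log2fc > threshold
  calls$downregulated <- apply(fc_meja, 1, min) < -threshold
  rownames(calls) <- NULL
  list(log2fc = log2fc, calls = calls)
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Distance is `1 - Pearson correlation` between rows; a zero-variance
#' row has undefined correlation and its distances are set to the
#' maximum (1), with a warning.
#'
#' @param mat numeric matrix (>= 2 rows), e.g. log2 fold changes
#' @return list with `order` (row names in leaf order) and `tree`
#'   (an `hclust` object)
#' @export
hcluster <- function(mat) {
  if (nrow(mat) < 2L) stop("need at least 2 rows")
  v <- apply(mat, 1, stats::var)
  cc <- suppressWarnings(cor(t(mat)))
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance row(s): correlation undefined, ",
            "distance set to 1")
    cc[v == 0, ] <- 0; cc[, v == 0] <- 0
    diag(cc) <- 1
  }
  hc <- hclust(as.dist(1 - cc), method = "average")
  list(order = rownames(mat)[hc$order], tree = hc)
}
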