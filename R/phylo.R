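# cached BLOSUM62 (from Biostrings), subset to the 20-letter alphabet
.blosum_env <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$m <- e$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
  }
  .blosum_env$m
}

# k-mer count distance used only for the guide tree
kmer_distance <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- counts[[i]]; b <- counts[[j]]
    shared <- sum(pmin(a[names(b)[names(b) %in% names(a)]],
                       b[names(b) %in% names(a)]))
    denom <- min(sum(a), sum(b))
    d[i, j] <- d[j, i] <- if (denom == 0) 1 else 1 - shared / denom
  }
  d
}

profile_freqs <- function(rows) {
  # rows: character matrix (sequences x columns); returns 20 x L freqs
  L <- ncol(rows)
  f <- matrix(0, 20L, L)
  for (j in seq_len(L)) {
    cnt <- table(factor(rows[, j], levels = AA_ALPHABET20))
    f[, j] <- as.numeric(cnt) / nrow(rows)
  }
  f
}

align_profiles <- function(A, B, gap_open, gap_ext) {
  fa <- profile_freqs(A); fb <- profile_freqs(B)
  S <- t(fa) %*% blosum62() %*% fb
  res <- .affine_align_cpp(S, gap_open, gap_ext, FALSE)
  na <- nrow(A); nb <- nrow(B)
  out <- matrix("-", na + nb, length(res$a_idx))
  for (c_ in seq_along(res$a_idx)) {
    if (res$a_idx[c_] > 0) out[1:na, c_] <- A[, res$a_idx[c_]]
    if (res$b_idx[c_] > 0) out[(na + 1):(na + nb), c_] <- B[, res$b_idx[c_]]
  }
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

#' Progressive multiple alignment
#'
#' Pairwise global alignment with BLOSUM62 scores and affine gaps
#' (a gap of length L costs `gap_open + L * gap_ext`), merged as
#' profile-profile alignments along a UPGMA guide tree built on 3-mer
#' count distances.  Deterministic for fixed inputs.
#'
#' @param seqs named character vector of protein sequences
#' @param gap_open,gap_ext affine gap parameters (positive costs)
#' @return named character vector of equal-length gapped sequences, in
#'   input order
#' @export
progressive_align <- function(seqs, gap_open = 10, gap_ext = 1) {
  if (length(seqs) == 0L) stop("no sequences")
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  if (length(seqs) == 1L) return(seqs)

  profiles <- lapply(names(seqs), function(id) {
    m <- matrix(strsplit(seqs[[id]], "")[[1]], nrow = 1)
    rownames(m) <- id
    m
  })
  if (length(seqs) == 2L) {
    merged <- align_profiles(profiles[[1]], profiles[[2]],
                             gap_open, gap_ext)
  } else {
    guide <- hclust(as.dist(kmer_distance(seqs)), method = "average")
    nodes <- vector("list", nrow(guide$merge))
    for (s in seq_len(nrow(guide$merge))) {
      pick <- function(x) if (x < 0) profiles[[-x]] else nodes[[x]]
      nodes[[s]] <- align_profiles(pick(guide$merge[s, 1]),
                                   pick(guide$merge[s, 2]),
                                   gap_open, gap_ext)
    }
    merged <- nodes[[length(nodes)]]
  }
  out <- apply(merged, 1, paste, collapse = "")
  out[names(seqs)]
}

#' Pairwise distances from an alignment
#'
#' Gap-containing sites are deleted pairwise (per sequence pair).
#' `p` is the proportion of mismatched compared sites; `poisson` is the
#' Poisson-corrected distance `-ln(1 - p)`.  A saturated pair
#' (`p = 1`) has no finite Poisson distance and is replaced by twice
#' the maximum observed finite distance, with a warning.
#'
#' @param alignment named character vector of equal-length rows
#' @param model `"p"` or `"poisson"`
#' @return symmetric distance matrix with zero diagonal
#' @export
alignment_distances <- function(alignment, model = c("poisson", "p")) {
  model <- match.arg(model)
  rows <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(rows) <- names(alignment)
  n <- nrow(rows)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- rows[i, ] != "-" & rows[j, ] != "-"
    if (!any(ok)) stop("no comparable sites between ",
                       names(alignment)[i], " and ", names(alignment)[j])
    p <- mean(rows[i, ok] != rows[j, ok])
    d[i, j] <- d[j, i] <- if (model == "p") p else -log(1 - p)
  }
  if (any(!is.finite(d))) {
    mx <- max(d[is.finite(d)])
    warning("saturated pairs (p = 1): replacing infinite distances with ",
            "2 * max finite distance")
    d[!is.finite(d)] <- 2 * mx
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch
#' lengths from the standard two-point formula (negative lengths
#' clamped to 0).  Equal-Q ties are broken by the lexicographically
#' smallest id pair, so the result is fully deterministic.  Exact on
#' additive distance matrices.
#'
#' @param d symmetric distance matrix with ids as dimnames
#' @return unrooted `phylo` tree (ape)
#' @export
nj_tree <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 taxa")
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  rep_ <- setNames(ids, ids)  # newick fragment per active cluster

  if (n == 2L) {
    tx <- sprintf("(%s:%s,%s:%s);", ids[1], fmt(d[1, 2] / 2),
                  ids[2], fmt(d[1, 2] / 2))
    return(ape::read.tree(text = tx))
  }

  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(rownames(D)[ij])
      paste(p, collapse = "\r")
    })
    best <- cand[order(key)[1], ]
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_rep <- sprintf("(%s:%s,%s:%s)", rep_[[rownames(D)[i]]], fmt(li),
                       rep_[[rownames(D)[j]]], fmt(lj))
    new_id <- min(rownames(D)[c(i, j)])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nm <- c(rownames(D)[keep], new_id)
    dimnames(D2) <- list(nm, nm)
    rep_ <- c(rep_[rownames(D)[keep]], setNames(new_rep, new_id))
    D <- D2
  }

  a <- rownames(D)
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  tx <- sprintf("(%s:%s,%s:%s,%s:%s);",
                rep_[[a[1]]], fmt(l1), rep_[[a[2]]], fmt(l2),
                rep_[[a[3]]], fmt(l3))
  ape::read.tree(text = tx)
}

#' Neighbour-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement; the support of each
#' internal edge of the reference tree is 100 times the fraction of
#' replicate trees containing the same leaf bipartition.  All values
#' are recorded, including those below 50.
#'
#' @param alignment named character vector of equal-length gapped rows
#' @param n_reps bootstrap replicates (0 leaves supports blank)
#' @param seed RNG seed for resampling
#' @param model distance model passed to [alignment_distances()]
#' @return `phylo` tree with `node.label` holding supports
#' @export
bootstrap_nj <- function(alignment, n_reps = 1000L, seed = 1L,
                         model = "poisson") {
  rows <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(rows) <- names(alignment)
  L <- ncol(rows)
  if (L < 1L) stop("empty alignment")
  ref <- nj_tree(alignment_distances(alignment, model))
  if (n_reps == 0L) {
    ref$node.label <- rep("", ref$Nnode)
    return(ref)
  }
  reps <- with_substream(seed, 0L, {
    lapply(seq_len(n_reps), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      aln <- apply(rows[, cols, drop = FALSE], 1, paste, collapse = "")
      nj_tree(alignment_distances(aln, model))
    })
  })
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- round(100 * counts / n_reps)
  # the basal trichotomy node is not a bipartition; leave it blank
  lab <- as.character(supp)
  lab[1] <- ""
  ref$node.label <- lab
  ref
}

#' Patristic (tree-path) distances between all leaves
#'
#' @param tree a `phylo` tree
#' @return symmetric matrix of path lengths
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}
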