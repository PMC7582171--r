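#' Build a position-specific scoring matrix from a seed alignment
#'
#' Columns with more than 50% gaps are dropped; foreground column
#' frequencies are pseudocount-smoothed (adding `pseudocount * bg`)
#' so they sum to 1, then converted to log2 odds against the
#' background.  The default background is the training-set residue
#' frequency (add-one smoothed), so log-odds are finite everywhere.
#'
#' Scores are also discretized to bins of width `eps` bits; the exact
#' p-value machinery operates on the binned matrix.
#'
#' @param alignment character vector of aligned sequences (gaps `-`)
#' @param pseudocount positive smoothing weight
#' @param background optional named vector of 20 frequencies summing to 1
#' @param name model name (e.g. `"AP2"`, `"B3"`)
#' @param eps score discretization bin width in bits
#' @return object of class `pssm`
#' @export
build_pssm <- function(alignment, pseudocount = 1, background = NULL,
                       name = "model", eps = 0.01) {
  if (length(alignment) == 0L) stop("empty alignment")
  if (eps <= 0) stop("eps must be > 0")
  rows <- do.call(rbind, strsplit(unname(alignment), ""))
  gap_frac <- colMeans(rows == "-")
  rows <- rows[, gap_frac <= 0.5, drop = FALSE]
  w <- ncol(rows)
  if (w < 1L) stop("no ungapped-majority columns")

  if (is.null(background)) {
    all_res <- rows[rows != "-"]
    cnt <- table(factor(all_res, levels = AA_ALPHABET20))
    background <- as.numeric(cnt + 1) / (sum(cnt) + 20)
  }
  names(background) <- AA_ALPHABET20
  stopifnot(all(background > 0), abs(sum(background) - 1) < 1e-6)

  log_odds <- matrix(0, nrow = w, ncol = 20,
                     dimnames = list(NULL, AA_ALPHABET20))
  for (j in seq_len(w)) {
    col <- rows[, j]; col <- col[col != "-"]
    cnt <- table(factor(col, levels = AA_ALPHABET20))
    fg <- (as.numeric(cnt) + pseudocount * background) /
      (length(col) + pseudocount)
    log_odds[j, ] <- log2(fg / background)
  }
  structure(list(name = name, width = w, log_odds = log_odds,
                 background = background, eps = eps,
                 binned = matrix(as.integer(round(log_odds / eps)),
                                 nrow = w, dimnames = dimnames(log_odds)),
                 cache = new.env(parent = emptyenv())),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm %s: %d columns, eps = %g bits>\n",
              x$name, x$width, x$eps))
  invisible(x)
}

# Distribution of the binned window score over model columns under the
# background, by position-wise convolution.  One cumulative pass yields
# the upper-tail function for every prefix of `columns`:
# P(S_k >= b) = tails[[k]]$tail[b - tails[[k]]$offset + 1].
score_tail_distributions <- function(pssm, columns = seq_len(pssm$width)) {
  probs <- 1; offset <- 0L
  bg <- pssm$background
  tails <- vector("list", length(columns))
  for (idx in seq_along(columns)) {
    s <- pssm$binned[columns[idx], ]
    lo <- min(s); hi <- max(s)
    newp <- numeric(length(probs) + hi - lo)
    for (l in seq_len(20L)) {
      sh <- s[l] - lo
      ix <- (sh + 1L):(sh + length(probs))
      newp[ix] <- newp[ix] + bg[l] * probs
    }
    probs <- newp; offset <- offset + lo
    tails[[idx]] <- list(offset = offset, tail = rev(cumsum(rev(probs))))
  }
  tails
}

# memoized prefix/suffix/full tail distributions
pssm_tail <- function(pssm, type = c("full", "prefix", "suffix"), k = NULL) {
  type <- match.arg(type)
  if (type == "full") { type <- "prefix"; k <- pssm$width }
  if (is.null(pssm$cache[[type]]))
    pssm$cache[[type]] <- score_tail_distributions(
      pssm,
      if (type == "prefix") seq_len(pssm$width) else rev(seq_len(pssm$width)))
  pssm$cache[[type]][[k]]
}

tail_pvalue <- function(tl, bin) {
  idx <- bin - tl$offset + 1L
  if (idx <= 1L) return(1)
  # above the maximal achievable score: no random word reaches it
  if (idx > length(tl$tail)) return(.Machine$double.xmin)
  max(tl$tail[idx], .Machine$double.xmin)
}

#' Exact p-value of a PSSM window score
#'
#' `P(random window score >= score)` under the model background,
#' computed by position-wise convolution of the discretized per-column
#' score distribution.  Discretization error is at most
#' `width * eps` bits of score.
#'
#' @param pssm a [build_pssm()] model
#' @param score window score in bits
#' @return p-value in (0, 1]
#' @export
exact_score_pvalue <- function(pssm, score) {
  tail_pvalue(pssm_tail(pssm, "full"),
              as.integer(round(score / pssm$eps)))
}

protein_to_idx <- function(protein) {
  match(strsplit(toupper(protein), "")[[1]], AA_ALPHABET20)
}

#' Scan a protein with a PSSM
#'
#' Scores every full window, plus end-truncated alignments (the model
#' hanging off either protein end by at least 6 retained columns, or the
#' model's prefix/suffix when the protein is shorter than the model).
#' Hits with `pvalue <= p_threshold` are reduced to local maxima by
#' greedy best-first selection suppressing overlaps of more than 50% of
#' the shorter hit, and returned sorted by start.  `coverage` is the
#' fraction of model columns aligned; a hit is `complete` when coverage
#' is at least `completeness` (default 0.9).
#'
#' Unknown residues (not in the 20-letter alphabet) score 0 bits.
#'
#' @param protein protein sequence (single string)
#' @param pssm a [build_pssm()] model
#' @param p_threshold per-window p-value threshold
#' @param completeness coverage threshold for a complete domain
#' @param protein_id identifier used in the output
#' @return data.frame of hits: protein_id, model, start, end (0-based
#'   half-open), score_bits, pvalue, coverage, complete
#' @export
scan_pssm <- function(protein, pssm, p_threshold = 1e-5,
                      completeness = 0.9, protein_id = "protein") {
  ai <- protein_to_idx(protein)
  L <- length(ai)
  if (L < 1L) stop("empty protein")
  w <- pssm$width
  bin <- pssm$binned
  cand <- list()
  add <- function(start, end, binscore, tl, coverage)
    cand[[length(cand) + 1L]] <<- data.frame(
      protein_id = protein_id, model = pssm$name,
      start = start, end = end,
      score_bits = binscore * pssm$eps,
      pvalue = tail_pvalue(tl, binscore),
      coverage = coverage, stringsAsFactors = FALSE)

  if (L >= w) {
    n_win <- L - w + 1L
    sc <- integer(n_win)
    for (j in seq_len(w)) {
      v <- bin[j, ][ai[j:(j + n_win - 1L)]]
      v[is.na(v)] <- 0L
      sc <- sc + v
    }
    tl <- pssm_tail(pssm, "full")
    for (p in seq_len(n_win))
      add(p - 1L, p - 1L + w, sc[p], tl, 1)
    # end-truncated candidates: model overhanging either protein end
    for (k in seq_len(w - 1L)[-seq_len(min(5L, w - 1L))]) {
      cols <- (w - k + 1L):w          # model suffix at protein start
      v <- bin[cbind(cols, ai[1:k])]; v[is.na(v)] <- 0L
      add(0L, k, sum(v), pssm_tail(pssm, "suffix", k), k / w)
      cols <- seq_len(k)              # model prefix at protein end
      v <- bin[cbind(cols, ai[(L - k + 1L):L])]; v[is.na(v)] <- 0L
      add(L - k, L, sum(v), pssm_tail(pssm, "prefix", k), k / w)
    }
  } else {
    v <- bin[cbind(seq_len(L), ai)]; v[is.na(v)] <- 0L
    add(0L, L, sum(v), pssm_tail(pssm, "prefix", L), L / w)
    v <- bin[cbind((w - L + 1L):w, ai)]; v[is.na(v)] <- 0L
    add(0L, L, sum(v), pssm_tail(pssm, "suffix", L), L / w)
  }

  hits <- do.call(rbind, cand)
  hits <- hits[hits$pvalue <= p_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) {
    hits$complete <- logical(0)
    return(hits)
  }
  # greedy best-first local-maximum reduction
  hits <- hits[order(-hits$score_bits, hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      shorter <- min(hits$end[i] - hits$start[i],
                     hits$end[j] - hits$start[j])
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  hits$complete <- hits$coverage >= completeness
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a set of proteins with one or more PSSMs
#'
#' @param proteins named character vector
#' @param pssms list of [build_pssm()] models
#' @param ... passed to [scan_pssm()]
#' @return combined hit data.frame
#' @export
scan_proteins <- function(proteins, pssms, ...) {
  out <- list()
  for (id in names(proteins))
    for (m in pssms)
      out[[length(out) + 1L]] <- scan_pssm(proteins[[id]], m,
                                           protein_id = id, ...)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the packaged AP2 and B3 domain PSSMs
#'
#' @param eps discretization bin width in bits
#' @return named list of two `pssm` objects
#' @export
default_pssms <- function(eps = 0.01) {
  list(AP2 = build_pssm(domain_seed_alignment("AP2"), name = "AP2",
                        eps = eps),
       B3 = build_pssm(domain_seed_alignment("B3"), name = "B3",
                       eps = eps))
}
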