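AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_prot <- function(n) paste(sample(AA20, n, replace = TRUE),
                               collapse = "")

# share the packaged PSSMs across tests: their exact p-value tables are
# computed once per object and memoized
.shared <- new.env()
get_pssms <- function() {
  if (is.null(.shared$pssms)) .shared$pssms <- default_pssms()
  .shared$pssms
}

blosum <- function() {
  if (is.null(.shared$blos)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .shared$blos <- e$BLOSUM62[AA20, AA20]
  }
  .shared$blos
}

# Brute-force optimal local alignment score by exhaustive enumeration of
# index subsequences (independent of the DP implementation).  A gap of
# length L costs open + L * ext in each sequence; terminal overhangs are
# free (local alignment).
sw_enumerate <- function(a, b, open = 11, ext = 1) {
  B <- blosum()
  ia <- match(strsplit(a, "")[[1]], AA20)
  ib <- match(strsplit(b, "")[[1]], AA20)
  la <- length(ia); lb <- length(ib)
  gapcost <- function(idx) {
    g <- diff(idx) - 1L
    sum(ifelse(g > 0, open + g * ext, 0))
  }
  best <- 0
  for (k in seq_len(min(la, lb))) {
    ca <- utils::combn(la, k); cb <- utils::combn(lb, k)
    for (i in seq_len(ncol(ca))) for (j in seq_len(ncol(cb))) {
      s <- sum(B[cbind(ia[ca[, i]], ib[cb[, j]])]) -
        gapcost(ca[, i]) - gapcost(cb[, j])
      if (s > best) best <- s
    }
  }
  best
}

# Enumeration oracle for PSSM window-score tail probabilities: brute
# force over all 20^w words, on the same eps-discretized score scale the
# scanner and the DP use (binning is part of the p-value definition).
enumerate_pvalue <- function(pssm, score) {
  w <- pssm$width
  grid <- as.matrix(expand.grid(rep(list(1:20), w)))
  sc <- integer(nrow(grid))
  pr <- rep(1, nrow(grid))
  for (c_ in seq_len(w)) {
    sc <- sc + pssm$binned[c_, grid[, c_]]
    pr <- pr * pssm$background[grid[, c_]]
  }
  sum(pr[sc >= round(score / pssm$eps)])
}
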