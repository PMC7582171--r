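# ZOOPS (zero-or-one occurrence per sequence) EM motif discovery,
# MEME-style: deterministic subword seedings, best width chosen by
# penalized log-likelihood ratio, discovered sites masked before the
# next motif is sought.

seq_windows <- function(idx_list, w) {
  # all windows of width w across sequences; windows touching masked
  # (NA) positions are invalid
  W <- NULL; seq_of <- integer(0); pos_of <- integer(0)
  for (i in seq_along(idx_list)) {
    s <- idx_list[[i]]
    mi <- length(s) - w + 1L
    if (mi < 1L) next
    win <- vapply(seq_len(w), function(c_) s[(0:(mi - 1L)) + c_],
                  integer(mi))
    if (mi == 1L) win <- matrix(win, nrow = 1L)
    W <- rbind(W, win)
    seq_of <- c(seq_of, rep(i, mi))
    pos_of <- c(pos_of, seq_len(mi))
  }
  valid <- if (is.null(W)) logical(0) else !apply(is.na(W), 1, any)
  list(W = W, seq_of = seq_of, pos_of = pos_of, valid = valid)
}

zoops_em <- function(win, n_seqs, w, background, theta, gamma = 0.5,
                     pseudocount = 0.1, max_iter = 200L, tol = 1e-6) {
  lb <- log(background)
  llr_path <- numeric(0)
  prev <- -Inf
  nwin_per_seq <- tabulate(win$seq_of[win$valid], nbins = n_seqs)
  for (it in seq_len(max_iter)) {
    # E-step: log likelihood-ratio of each valid window
    lt <- log(theta)
    sc <- numeric(sum(win$valid))
    Wv <- win$W[win$valid, , drop = FALSE]
    for (c_ in seq_len(w))
      sc <- sc + lt[c_, Wv[, c_]] - lb[Wv[, c_]]
    so <- win$seq_of[win$valid]
    z <- numeric(length(sc))
    llr <- 0
    for (i in seq_len(n_seqs)) {
      rows <- which(so == i)
      mi <- length(rows)
      if (mi == 0L) next
      lg <- c(log1p(-gamma), log(gamma / mi) + sc[rows])
      mx <- max(lg)
      li <- mx + log(sum(exp(lg - mx)))
      llr <- llr + li
      z[rows] <- exp(lg[-1] - li)
    }
    # EM monotonicity is a structural guarantee; assert it
    stopifnot(llr >= prev - 1e-8 * max(1, abs(prev)))
    llr_path <- c(llr_path, llr)
    if (is.finite(prev) && llr - prev < tol) { prev <- llr; break }
    prev <- llr
    # M-step
    counts <- matrix(0, w, 20L)
    for (c_ in seq_len(w)) {
      cs <- rowsum(z, Wv[, c_])
      counts[c_, as.integer(rownames(cs))] <- cs[, 1]
    }
    theta <- (counts + pseudocount * rep(background, each = w)) /
      (rowSums(counts) + pseudocount)
    gamma <- min(max(sum(z) / n_seqs, 1e-6), 1 - 1e-6)
  }
  list(theta = theta, gamma = gamma, llr = prev, z = z,
       llr_path = llr_path, sc = sc)
}

#' De novo ZOOPS-EM motif discovery
#'
#' For each motif, every candidate width is seeded deterministically
#' from the subwords of the first `k_seed` unmasked sequences (one EM
#' iteration per seed), the best seeding is run to convergence
#' (delta LLR < `tol` or `max_iter` iterations), and the width
#' maximizing the penalized LLR (`LLR - 0.5 * 19 * w * ln(N)`, `N` the
#' total residue count) is kept.  Sites (posterior > 0.5) are masked
#' before the next motif.  Site p-values reuse the exact PSSM p-value
#' machinery; display heights are `min(-log10(p), 10)`.
#'
#' @param sequences named character vector of protein sequences
#' @param n_motifs maximum number of motifs
#' @param widths candidate motif widths (default 6 to 50 in steps of 2)
#' @param k_seed number of sequences whose subwords seed EM
#' @param max_iter,tol EM convergence controls
#' @param min_llr stop early when a motif's LLR falls below this
#' @return list of motif models: name, width, pfm (width x 20), llr,
#'   gamma, sites (data.frame seq_id, offset0, site, pvalue, height)
#' @export
discover_motifs <- function(sequences, n_motifs = 12L,
                            widths = seq(6L, 50L, by = 2L),
                            k_seed = 3L, max_iter = 200L, tol = 1e-6,
                            min_llr = 1e-3) {
  if (length(sequences) < 2L) stop("need >= 2 sequences")
  idx <- lapply(sequences, protein_to_idx)
  if (max(lengths(idx)) < min(widths)) return(list())
  all_res <- unlist(idx); all_res <- all_res[!is.na(all_res)]
  background <- (tabulate(all_res, 20L) + 1) / (length(all_res) + 20)
  N <- length(all_res)

  motifs <- list()
  for (mnum in seq_len(n_motifs)) {
    best <- NULL
    for (w in widths[widths <= max(lengths(idx))]) {
      win <- seq_windows(idx, w)
      if (sum(win$valid) < 2L) next
      # deterministic seedings: subwords of the first k_seed sequences
      seed_rows <- which(win$valid & win$seq_of <= k_seed)
      if (length(seed_rows) == 0L) seed_rows <- which(win$valid)[1]
      if (length(seed_rows) > 60L)
        seed_rows <- seed_rows[unique(as.integer(
          seq(1L, length(seed_rows), length.out = 60L)))]
      seed_fit <- NULL
      for (r in seed_rows) {
        theta0 <- matrix(rep(background, each = w), w, 20L)
        theta0 <- 0.25 * theta0
        theta0[cbind(seq_len(w), win$W[r, ])] <-
          theta0[cbind(seq_len(w), win$W[r, ])] + 0.75
        fit1 <- zoops_em(win, length(idx), w, background, theta0,
                         max_iter = 1L)
        if (is.null(seed_fit) || fit1$llr > seed_fit$llr) {
          seed_fit <- fit1; seed_fit$theta0 <- theta0
        }
      }
      fit <- zoops_em(win, length(idx), w, background, seed_fit$theta0,
                      max_iter = max_iter, tol = tol)
      fit$w <- w; fit$win <- win
      fit$pen_llr <- fit$llr - 0.5 * 19 * w * log(N)
      if (is.null(best) || fit$pen_llr > best$pen_llr) best <- fit
    }
    if (is.null(best) || best$llr < min_llr) break

    # ZOOPS site assignment: best window per sequence if posterior > 0.5
    w <- best$w; win <- best$win
    so <- win$seq_of[win$valid]; po <- win$pos_of[win$valid]
    site_pssm <- pfm_to_pssm(best$theta, background,
                             name = sprintf("M%d", mnum))
    sites <- lapply(seq_along(idx), function(i) {
      rows <- which(so == i)
      if (length(rows) == 0L)
        return(data.frame(seq_id = names(sequences)[i],
                          offset0 = NA_integer_, site = NA_character_,
                          pvalue = NA_real_, height = NA_real_))
      r <- rows[which.max(best$z[rows])]
      if (best$z[r] <= 0.5)
        return(data.frame(seq_id = names(sequences)[i],
                          offset0 = NA_integer_, site = NA_character_,
                          pvalue = NA_real_, height = NA_real_))
      off <- po[r] - 1L
      word <- substr(sequences[[i]], off + 1L, off + w)
      p <- exact_score_pvalue(site_pssm,
                              sum(site_pssm$log_odds[
                                cbind(seq_len(w), protein_to_idx(word))]))
      data.frame(seq_id = names(sequences)[i], offset0 = off,
                 site = word, pvalue = p,
                 height = min(-log10(p), 10), stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, sites)

    motifs[[length(motifs) + 1L]] <- list(
      name = sprintf("M%d", mnum), width = w, pfm = best$theta,
      llr = best$llr, gamma = best$gamma, sites = sites)

    # mask discovered sites
    for (k in which(!is.na(sites$offset0))) {
      i <- match(sites$seq_id[k], names(sequences))
      idx[[i]][(sites$offset0[k] + 1L):(sites$offset0[k] + w)] <- NA
    }
    if (all(vapply(idx, function(s) all(is.na(s)), TRUE))) break
  }
  motifs
}

# wrap a position frequency matrix as a pssm object so the exact
# p-value machinery applies to motif sites
pfm_to_pssm <- function(pfm, background, name = "motif", eps = 0.01) {
  lo <- log2(sweep(pfm, 2, background, "/"))
  colnames(lo) <- AA_ALPHABET20
  structure(list(name = name, width = nrow(pfm), log_odds = lo,
                 background = setNames(background, AA_ALPHABET20),
                 eps = eps,
                 binned = matrix(as.integer(round(lo / eps)),
                                 nrow = nrow(pfm), dimnames = dimnames(lo)),
                 cache = new.env(parent = emptyenv())),
            class = "pssm")
}

#' Group-by-motif presence matrix
#'
#' @param motifs list from [discover_motifs()]
#' @param assignments data.frame with protein_id, family, group
#' @return integer matrix: rows = family/group categories, columns =
#'   motif names; entries count member sequences carrying a site
#' @export
presence_matrix <- function(motifs, assignments) {
  if (length(motifs) == 0L)
    return(matrix(integer(0), 0, 0))
  cat_of <- ifelse(is.na(assignments$group), assignments$family,
                   assignments$group)
  names(cat_of) <- assignments$protein_id
  cats <- sort(unique(cat_of))
  out <- matrix(0L, length(cats), length(motifs),
                dimnames = list(cats,
                                vapply(motifs, `[[`, "", "name")))
  for (m in motifs) {
    hit_ids <- m$sites$seq_id[!is.na(m$sites$offset0)]
    tab <- table(cat_of[intersect(hit_ids, names(cat_of))])
    out[names(tab), m$name] <- as.integer(tab)
  }
  out
}

#' Serialize motifs in MEME-minimal text format
#'
#' @param motifs list from [discover_motifs()]
#' @param background background frequencies (for the header)
#' @return character vector of lines
#' @export
write_meme <- function(motifs, background = rep(0.05, 20)) {
  lines <- c("MEME version 4", "",
             "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", AA_ALPHABET20, background),
                   collapse = " "), "")
  for (m in motifs) {
    n_sites <- sum(!is.na(m$sites$offset0))
    lines <- c(lines, sprintf("MOTIF %s", m$name),
               sprintf(
                 "letter-probability matrix: alength= 20 w= %d nsites= %d",
                 m$width, n_sites),
               apply(m$pfm, 1, function(r)
                 paste(sprintf("%.6f", r), collapse = " ")),
               "")
  }
  lines
}
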