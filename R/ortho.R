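# Karlin-Altschul parameters for gapped BLOSUM62 with gap open 11 /
# extend 1 (standard first-order values).
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Optimal local alignment of two proteins (Smith-Waterman)
#'
#' BLOSUM62 scores with affine gaps (defaults are the conventional
#' gapped-BLOSUM62 parameters: open 11, extend 1, a gap of length L
#' costing `11 + L`).  Traceback ties prefer diagonal over vertical
#' over horizontal moves, so results are deterministic.
#'
#' Reported statistics: bit score `S' = (lambda * S - ln K) / ln 2`;
#' `e_value = m * n * 2^-S'` for search-space sizes `m`, `n`;
#' `similarity_pct` = positives (BLOSUM62 > 0) per aligned column
#' (gap columns counted); `coverage_pct` = aligned query span over
#' query length.
#'
#' @param a,b query and subject protein sequences
#' @param gap_open,gap_ext affine gap costs
#' @param m,n search-space sizes for the e-value (default: sequence
#'   lengths)
#' @return one-row data.frame: score, bit_score, e_value,
#'   similarity_pct, coverage_pct, align_length, q_start, q_end,
#'   s_start, s_end (1-based inclusive)
#' @export
local_align <- function(a, b, gap_open = 11, gap_ext = 1,
                        m = nchar(a), n = nchar(b)) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  ia <- protein_to_idx(a); ib <- protein_to_idx(b)
  B <- blosum62()
  S <- matrix(0, length(ia), length(ib))
  ok_a <- which(!is.na(ia)); ok_b <- which(!is.na(ib))
  S[ok_a, ok_b] <- B[ia[ok_a], ib[ok_b], drop = FALSE]
  res <- .affine_align_cpp(S, gap_open, gap_ext, TRUE)

  if (length(res$a_idx) == 0L)
    return(data.frame(score = 0, bit_score = 0, e_value = Inf,
                      similarity_pct = 0, coverage_pct = 0,
                      align_length = 0L, q_start = NA_integer_,
                      q_end = NA_integer_, s_start = NA_integer_,
                      s_end = NA_integer_))
  pos <- 0L
  for (k in seq_along(res$a_idx)) {
    i <- res$a_idx[k]; j <- res$b_idx[k]
    if (i > 0 && j > 0 && !is.na(ia[i]) && !is.na(ib[j]) &&
        B[ia[i], ib[j]] > 0) pos <- pos + 1L
  }
  qa <- res$a_idx[res$a_idx > 0]; sb <- res$b_idx[res$b_idx > 0]
  bit <- (KA_LAMBDA * res$score - log(KA_K)) / log(2)
  data.frame(score = res$score, bit_score = bit,
             e_value = m * n * 2^-bit,
             similarity_pct = 100 * pos / length(res$a_idx),
             coverage_pct = 100 * (max(qa) - min(qa) + 1) / nchar(a),
             align_length = length(res$a_idx),
             q_start = min(qa), q_end = max(qa),
             s_start = min(sb), s_end = max(sb))
}

best_hits <- function(queries, subjects, n_space) {
  # one best subject per query, by bit score; ties -> lexicographically
  # smallest subject id
  out <- list()
  for (q in names(queries)) {
    hits <- lapply(sort(names(subjects)), function(s)
      cbind(query = q, subject = s,
            local_align(queries[[q]], subjects[[s]],
                        m = nchar(queries[[q]]), n = n_space)))
    hits <- do.call(rbind, hits)
    out[[q]] <- hits[which.max(hits$bit_score), ]
  }
  do.call(rbind, out)
}

#' Reciprocal-best-hit orthology between two proteomes
#'
#' Best hits are selected per query by bit score *before* thresholds
#' are applied; a reciprocal pair is called when both directions pass
#' all three gates (similarity >= `min_similarity`, query coverage >
#' `min_coverage` in each direction, e-value <= `max_e`).
#'
#' @param proteome_a,proteome_b named character vectors
#' @param min_similarity positives percentage threshold
#' @param min_coverage query-coverage percentage threshold (strict >)
#' @param max_e e-value threshold
#' @return data.frame of calls: a, b, plus forward-direction alignment
#'   statistics and an `rbh` flag (always TRUE here)
#' @export
rbh <- function(proteome_a, proteome_b, min_similarity = 45,
                min_coverage = 50, max_e = 1e-20) {
  if (length(proteome_a) == 0L || length(proteome_b) == 0L)
    stop("empty proteome")
  n_a <- sum(nchar(proteome_a)); n_b <- sum(nchar(proteome_b))
  ab <- best_hits(proteome_a, proteome_b, n_b)
  ba <- best_hits(proteome_b, proteome_a, n_a)
  calls <- list()
  for (k in seq_len(nrow(ab))) {
    q <- ab$query[k]; s <- ab$subject[k]
    back <- ba[ba$query == s, ]
    if (nrow(back) == 0L || back$subject != q) next
    fwd_ok <- ab$similarity_pct[k] >= min_similarity &&
      ab$coverage_pct[k] > min_coverage && ab$e_value[k] <= max_e
    rev_ok <- back$similarity_pct >= min_similarity &&
      back$coverage_pct > min_coverage && back$e_value <= max_e
    if (fwd_ok && rev_ok)
      calls[[length(calls) + 1L]] <-
        cbind(a = q, b = s, ab[k, setdiff(names(ab),
                                          c("query", "subject"))],
              rbh = TRUE)
  }
  res <- do.call(rbind, calls)
  if (is.null(res))
    res <- data.frame(a = character(0), b = character(0), rbh = logical(0))
  rownames(res) <- NULL
  res
}

#' Intersect RBH calls with tree-sister evidence
#'
#' A pair is tree-supported when the two proteins are sisters in the
#' joint full-length tree, or when `b` is `a`'s nearest cross-proteome
#' leaf by patristic distance.  Tree-supported nearest pairs that were
#' not called by RBH are added with `final_set = "tree_only"`.
#'
#' @param calls RBH call data.frame from [rbh()]
#' @param tree joint `phylo` tree covering both proteomes
#' @param ids_a,ids_b leaf ids of the two proteomes
#' @return data.frame: a, b, rbh, tree_supported, final_set
#' @export
combine_with_tree <- function(calls, tree, ids_a, ids_b) {
  pd <- patristic_distances(tree)
  missing <- setdiff(c(ids_a, ids_b), rownames(pd))
  if (length(missing) > 0)
    warning("absent from tree, tree support undefined: ",
            paste(missing, collapse = ", "))
  ids_a <- intersect(ids_a, rownames(pd))
  ids_b <- intersect(ids_b, rownames(pd))

  sisters <- function(x, y) {
    ei <- match(x, tree$tip.label); ej <- match(y, tree$tip.label)
    pi_ <- tree$edge[tree$edge[, 2] == ei, 1]
    pj <- tree$edge[tree$edge[, 2] == ej, 1]
    length(pi_) == 1 && length(pj) == 1 && pi_ == pj
  }
  nearest_b <- vapply(ids_a, function(x)
    ids_b[which.min(pd[x, ids_b])], "")

  supported <- function(x, y)
    (x %in% ids_a && y %in% ids_b) &&
      (identical(nearest_b[[x]], y) || sisters(x, y))

  out <- list()
  seen <- character(0)
  for (k in seq_len(nrow(calls))) {
    x <- calls$a[k]; y <- calls$b[k]
    ts <- supported(x, y)
    out[[length(out) + 1L]] <- data.frame(
      a = x, b = y, rbh = TRUE, tree_supported = ts,
      final_set = if (ts) "both" else "rbh_only",
      stringsAsFactors = FALSE)
    seen <- c(seen, x)
  }
  # pairs added on tree evidence alone must be genuine sisters
  for (x in setdiff(ids_a, seen)) {
    y <- nearest_b[[x]]
    if (sisters(x, y))
      out[[length(out) + 1L]] <- data.frame(
        a = x, b = y, rbh = FALSE, tree_supported = TRUE,
        final_set = "tree_only", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
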