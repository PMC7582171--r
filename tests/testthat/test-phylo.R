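test_that("progressive alignment handles identity, gaps and scores", {
  a <- progressive_align(c(x = "MKLV", y = "MKLV"))
  expect_equal(unname(a), c("MKLV", "MKLV"))

  # one gap column; affine score 4 + 9 + 5 - (10 + 1) = 7 by hand
  a2 <- progressive_align(c(x = "ACDE", y = "ACE"))
  expect_equal(nchar(a2[["x"]]), 4)
  expect_equal(sum(strsplit(a2[["y"]], "")[[1]] == "-"), 1)
  B <- blosum()
  cols <- cbind(strsplit(a2[["x"]], "")[[1]], strsplit(a2[["y"]], "")[[1]])
  sc <- 0; gap_len <- 0
  for (k in seq_len(nrow(cols))) {
    if (any(cols[k, ] == "-")) gap_len <- gap_len + 1
    else sc <- sc + B[cols[k, 1], cols[k, 2]]
  }
  expect_equal(sc - (10 + gap_len), 7)

  # group-diagnostic marker columns stay in register across groups
  doms <- c(ix = domain_variant("ERF", "IX")$seq,
            vii = domain_variant("ERF", "VII")$seq,
            ii = domain_variant("DREB", "II")$seq)
  a3 <- progressive_align(doms)
  expect_true(all(nchar(a3) == 60))  # equal-length inputs: no gaps
})

test_that("distance models follow their closed forms", {
  aln <- c(a = paste(rep("A", 10), collapse = ""),
           b = paste(c(rep("A", 8), "C", "C"), collapse = ""))
  expect_equal(alignment_distances(aln, "p")["a", "b"], 0.2)
  expect_equal(alignment_distances(aln, "poisson")["a", "b"], -log(0.8))
  d <- alignment_distances(c(aln, c = "AAAAAAAAAA"), "p")
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  # saturation under the Poisson correction is replaced, with warning
  expect_warning(
    alignment_distances(c(a = "AAAA", b = "CCCC", c = "AACC"), "poisson"),
    "saturated")
})

test_that("NJ is exact on additive matrices and deterministic on ties", {
  set.seed(20)
  tr <- ape::rtree(4)
  D <- stats::cophenetic(tr)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  t2 <- nj_tree(D)
  expect_lt(max(abs(stats::cophenetic(t2)[rownames(D), colnames(D)] - D)),
            1e-9)

  # star matrix: all internal branches zero
  ids <- c("a", "b", "c", "d")
  S <- matrix(2, 4, 4, dimnames = list(ids, ids)); diag(S) <- 0
  ts <- nj_tree(S)
  internal <- ts$edge[, 2] > length(ts$tip.label)
  expect_true(all(ts$edge.length[internal] < 1e-12))
  expect_identical(ape::write.tree(nj_tree(S)), ape::write.tree(ts))

  t_2 <- nj_tree(S[1:2, 1:2])
  expect_equal(sum(t_2$edge.length), 2)
})

test_that("NJ topology matches the brute-force least-squares oracle", {
  # all 15 unrooted 5-leaf topologies, least-squares fitted
  ls_best_topology <- function(D) {
    tips <- rownames(D)
    # enumerate the 15 unrooted binary topologies: two disjoint cherries
    # plus the remaining leaf on the central edge
    trees <- list()
    for (p1 in utils::combn(5, 2, simplify = FALSE))
      for (p2 in utils::combn(setdiff(1:5, p1), 2, simplify = FALSE)) {
        if (min(p1) > min(p2)) next
        e <- setdiff(1:5, c(p1, p2))
        nwk <- sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1,%s:1);",
                       tips[p1[1]], tips[p1[2]],
                       tips[p2[1]], tips[p2[2]], tips[e])
        trees[[length(trees) + 1L]] <- ape::read.tree(text = nwk)
      }
    stopifnot(length(trees) == 15L)
    pair_idx <- t(utils::combn(5, 2))
    rss <- vapply(trees, function(tp) {
      tp <- ape::unroot(tp)
      A <- vapply(seq_along(tp$edge.length), function(e) {
        tp$edge.length <- rep(0, length(tp$edge.length))
        tp$edge.length[e] <- 1
        pd <- stats::cophenetic(tp)[tips, tips]
        pd[pair_idx]
      }, numeric(nrow(pair_idx)))
      y <- D[pair_idx]
      fit <- stats::lm.fit(A, y)
      sum(fit$residuals^2)
    }, 0)
    ape::unroot(trees[[which.min(rss)]])
  }
  set.seed(33)
  for (rep in 1:3) {
    tr <- ape::rtree(5)
    tr$edge.length <- tr$edge.length + 0.2
    D <- stats::cophenetic(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    mine <- nj_tree(D)
    oracle <- ls_best_topology(D)
    expect_equal(ape::dist.topo(ape::unroot(mine), oracle), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports reflect column signal and fixed seeds", {
  aln <- c(a = "AAAAAAAAKKKKQ", b = "AAAAAAAAKKKRQ",
           c = "CCCCCCCCKKKKQ", d = "CCCCCCCCKKKSQ",
           e = "GGGGGGGGKKKKQ")
  t1 <- suppressWarnings(bootstrap_nj(aln, n_reps = 100, seed = 9))
  t2 <- suppressWarnings(bootstrap_nj(aln, n_reps = 100, seed = 9))
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # the {a,b} block is diagnosed by 8 perfectly clade-diagnostic columns
  supp <- as.numeric(t1$node.label[t1$node.label != ""])
  expect_true(any(supp == 100))

  t0 <- suppressWarnings(bootstrap_nj(aln, n_reps = 0))
  expect_true(all(t0$node.label == ""))

  # newick round-trip preserves topology, lengths and supports
  txt <- ape::write.tree(t1)
  t3 <- ape::read.tree(text = txt)
  expect_identical(t3$node.label, t1$node.label)
  expect_equal(stats::cophenetic(t3)[rownames(stats::cophenetic(t1)),
                                     colnames(stats::cophenetic(t1))],
               stats::cophenetic(t1), tolerance = 1e-9)
})
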