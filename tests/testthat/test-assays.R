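mk_qpcr <- function(dct_by_group, ct_ref = 18, n_reps = 3) {
  rows <- lapply(names(dct_by_group), function(k) {
    parts <- strsplit(k, "_")[[1]]
    data.frame(gene = "G", treatment = parts[1],
               time_h = as.numeric(parts[2]),
               replicate = seq_len(n_reps),
               ct_target = ct_ref + dct_by_group[[k]],
               ct_reference = ct_ref, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("2^-ddCt closed forms hold", {
  m <- mk_qpcr(list(mock_0 = 4, mock_1 = 4, MeJA_1 = 1))
  res <- suppressWarnings(ddct(m))
  # calibrator group itself: mean RQ = 1 by construction
  expect_equal(res$mean_rq[res$treatment == "mock" & res$time_h == 0], 1)
  # ddCt = 1 - 4 = -3  =>  RQ = 8
  expect_equal(res$mean_rq[res$treatment == "MeJA"], 8)

  # adding a constant to every Ct (target and reference) leaves RQ fixed
  m2 <- m; m2$ct_target <- m2$ct_target + 3.7
  m2$ct_reference <- m2$ct_reference + 3.7
  res2 <- suppressWarnings(ddct(m2))
  expect_equal(res2$mean_rq, res$mean_rq)

  # missing reference wells drop the replicate with a warning
  m3 <- m; m3$ct_reference[1] <- NA
  w <- testthat::capture_warnings(ddct(m3))
  expect_true(any(grepl("dropped", w)))
})

test_that("the equal-variance t-test matches the textbook formula", {
  x <- c(4.1, 3.9, 4.3); y <- c(3.2, 3.4, 3.0)
  # hand-computed pooled-variance two-sample t
  sp2 <- (2 * stats::var(x) + 2 * stats::var(y)) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * stats::pt(-abs(tstat), df = 4)

  m <- rbind(
    data.frame(gene = "G", treatment = "mock", time_h = 0,
               replicate = 1:3, ct_target = 18 + 4, ct_reference = 18),
    data.frame(gene = "G", treatment = "mock", time_h = 1,
               replicate = 1:3, ct_target = 18 + y, ct_reference = 18),
    data.frame(gene = "G", treatment = "MeJA", time_h = 1,
               replicate = 1:3, ct_target = 18 + x, ct_reference = 18))
  res <- suppressWarnings(ddct(m))
  p_pkg <- res$p_value[res$treatment == "MeJA" & res$time_h == 1]
  # same test on the RQ scale
  rq_x <- 2^-(x - 4); rq_y <- 2^-(y - 4)
  sp2r <- (2 * stats::var(rq_x) + 2 * stats::var(rq_y)) / 4
  tr <- (mean(rq_x) - mean(rq_y)) / sqrt(sp2r * (2 / 3))
  expect_equal(p_pkg, 2 * stats::pt(-abs(tr), df = 4), tolerance = 1e-10)
  expect_true(p_hand > 0 && p_hand < 1)  # sanity on the hand formula
})

test_that("parameter recovery: RQ bias stays small at ct_sd = 0.2", {
  cfg <- syn_config(seed = 1, ct_sd = 0.2)
  fold <- matrix(c(1, 4), 1, 2, dimnames = list("G1", c(0, 1)))
  means <- vapply(1:200, function(i) {
    cfg_i <- syn_config(seed = i, ct_sd = 0.2)
    q <- generate_qpcr(fold, n_reps = 3, cfg_i)
    r <- suppressWarnings(ddct(q))
    r$mean_rq[r$treatment == "MeJA" & r$time_h == 1]
  }, 0)
  expect_lt(abs(mean(means) - 4) / 4, 0.05)
})

test_that("luciferase relative activity is VC-standardized and tested", {
  base <- data.frame(effector = rep(c("VC", "TF"), each = 3),
                     replicate = rep(1:3, 2),
                     firefly = c(100, 110, 90, 210, 200, 220),
                     renilla = rep(100, 6))
  res <- luc_relative(base)
  expect_equal(res$mean_relative[res$effector == "VC"], 1)
  expect_gt(res$mean_relative[res$effector == "TF"], 1.9)
  expect_true(res$p_value[res$effector == "TF"] < 0.01)
  expect_equal(res$stars[res$effector == "TF"], "**")

  # exact doubling with zero variance: degenerate test, p = 0 + warning
  con <- data.frame(effector = rep(c("VC", "TF"), each = 2),
                    replicate = rep(1:2, 2),
                    firefly = c(100, 100, 200, 200),
                    renilla = rep(100, 4))
  expect_warning(r2 <- luc_relative(con), "degenerate")
  expect_equal(r2$mean_relative[r2$effector == "TF"], 2)
  expect_equal(r2$p_value[r2$effector == "TF"], 0)

  bad <- base; bad$renilla[4] <- 0
  expect_warning(luc_relative(bad), "renilla")

  # simulation recovery: activity 2.5 at cv 0.05, n = 3
  rec <- vapply(1:50, function(i)
    luc_relative(generate_luc(c(TF = 2.5), 3,
                              syn_config(seed = i, luc_cv = 0.05)))$
      mean_relative[2], 0)
  se <- 2.5 * 0.05 / sqrt(3)
  expect_lt(abs(mean(rec) - 2.5), 3 * se)
})
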