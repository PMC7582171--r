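star_codes <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# Equal-variance two-sided Student's t-test; a degenerate comparison
# (both groups constant) is reported as p = 0 with a warning.
student_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(NA_real_)
    warning("zero-variance groups: t-test degenerate, p reported as 0")
    return(0)
  }
  t.test(x, y, var.equal = TRUE)$p.value
}

#' Relative expression by the comparative 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; `ddCt = dCt -
#' mean(dCt)` of the calibrator group (mock 0 h by default); `RQ =
#' 2^-ddCt`.  Replicates with a missing reference well are dropped
#' with a warning.  Each MeJA group is compared to its matched mock at
#' the same time point by a two-sided equal-variance Student's t-test
#' on replicate RQs; stars mark p < 0.05 (`*`) and p < 0.01 (`**`).
#'
#' @param measurements data.frame: gene, treatment, time_h, replicate,
#'   ct_target, ct_reference
#' @param calibrator list naming the calibrator group (treatment,
#'   time_h)
#' @return data.frame per gene x treatment x time: mean_rq, sd_rq, n,
#'   p_value (MeJA vs matched mock), stars
#' @export
ddct <- function(measurements,
                 calibrator = list(treatment = "mock", time_h = 0)) {
  m <- measurements
  bad <- is.na(m$ct_reference) | is.na(m$ct_target)
  if (any(bad)) {
    warning(sum(bad), " replicate(s) without a reference well dropped")
    m <- m[!bad, ]
  }
  if (any(m$ct_target <= 0 | m$ct_reference <= 0))
    stop("Ct values must be finite and > 0")
  m$dct <- m$ct_target - m$ct_reference

  out <- list()
  for (g in unique(m$gene)) {
    sub <- m[m$gene == g, ]
    cal <- sub$dct[sub$treatment == calibrator$treatment &
                     sub$time_h == calibrator$time_h]
    if (length(cal) == 0L) stop("calibrator group absent for gene ", g)
    sub$rq <- 2^-(sub$dct - mean(cal))
    for (trt in unique(sub$treatment)) for (tt in unique(sub$time_h)) {
      rq <- sub$rq[sub$treatment == trt & sub$time_h == tt]
      if (length(rq) == 0L) next
      p <- NA_real_
      if (trt != "mock") {
        mock <- sub$rq[sub$treatment == "mock" & sub$time_h == tt]
        if (length(mock) > 0) p <- student_p(rq, mock)
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = g, treatment = trt, time_h = tt,
        mean_rq = mean(rq), sd_rq = stats::sd(rq), n = length(rq),
        p_value = p, stars = star_codes(p), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative transactivation activity from a dual-luciferase assay
#'
#' Per replicate, the firefly/renilla ratio is normalized by the mean
#' vector-control (VC) ratio, so VC has relative activity 1.  Each
#' effector is compared to VC by a two-sided equal-variance Student's
#' t-test.  Replicates with renilla <= 0 are invalid and dropped with
#' a warning.
#'
#' @param measurements data.frame: effector, replicate, firefly,
#'   renilla; must include a `VC` group with >= 2 replicates
#' @return data.frame per effector: mean_relative, sd_relative, n,
#'   p_value, stars
#' @export
luc_relative <- function(measurements) {
  m <- measurements
  bad <- !(m$renilla > 0)
  if (any(bad)) {
    warning(sum(bad), " replicate(s) with renilla <= 0 dropped")
    m <- m[!bad, ]
  }
  if (sum(m$effector == "VC") < 2L)
    stop("need a VC group with >= 2 replicates")
  m$ratio <- m$firefly / m$renilla
  vc_mean <- mean(m$ratio[m$effector == "VC"])
  m$relative <- m$ratio / vc_mean
  vc_rel <- m$relative[m$effector == "VC"]
  out <- lapply(unique(m$effector), function(e) {
    rel <- m$relative[m$effector == e]
    p <- if (e == "VC") NA_real_ else student_p(rel, vc_rel)
    data.frame(effector = e, mean_relative = mean(rel),
               sd_relative = stats::sd(rel), n = length(rel),
               p_value = p, stars = star_codes(p),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
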