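#' @useDynLib tfcensus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnbinom rnorm rpois runif t.test cor hclust as.dist
#'   setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

# 20-letter amino-acid alphabet, fixed ordering used by all matrices
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Round half away from zero at a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; printed tables in this field
#' conventionally round half up, so census percentages and densities use
#' this rule.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-stage RNG substreams: one user seed governs every
# generator; each stage derives its own stream by a fixed offset so adding
# a stage never perturbs the draws of another.
with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower)
    stop(sprintf("'%s' must be a single number >= %s", name, lower),
         call. = FALSE)
  invisible(x)
}
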