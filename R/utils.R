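#' @useDynLib pathgwas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor integrate median pchisq phyper pnorm prcomp
#'   qchisq qnorm rbeta rbinom rnorm runif sd var binomial glm coef
#'   model.matrix
#' @importFrom utils read.table write.table head modifyList
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Each pipeline stage draws its randomness from its own substream so stages
#' can be re-run in isolation. The substream seed is a fixed affine hash of
#' the global seed and the stage name, kept below `.Machine$integer.max`.
#'
#' @param seed global integer seed.
#' @param stage stage name (character).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  idx <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + idx) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
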