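# Internal helpers shared across modules.

#' @useDynLib famvarsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm qnorm rnorm runif rpois rbinom plogis pchisq rmultinom
#' @importFrom utils read.table write.table
NULL

vs_log <- function(...) message("[famvarsim] ", ...)

#' Derive a reproducible sub-stream seed from a master seed
#'
#' One master seed drives every stage of a pipeline; each stage draws its own
#' seed from the master so stages can be re-run independently without
#' perturbing each other's random streams. The derived seed is always a
#' non-negative integer below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param tag character label of the stage.
#' @return an integer seed.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(master) %% 65011 + 1) * 32713 + h * 97) %% 2147483629L
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
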