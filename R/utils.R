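#' @importFrom stats optim rpois rmultinom quantile cor kmeans prcomp sd setNames
#' @importFrom utils head tail
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library code never leaks RNG
#' state into the caller's session. All randomness in the package flows
#' through named `seed` arguments via this helper.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## md5 of an arbitrary R object, via its serialization written to a temp file.
## Used for config and feature-registry fingerprints.
.object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

.assert_nucleotides <- function(x, what = "sequence") {
  if (length(x) && !all(x %in% c("A", "C", "G", "T"))) {
    stop(sprintf("%s must contain only A/C/G/T", what))
  }
  invisible(x)
}
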