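#' @useDynLib vdomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cmdscale cor dist plogis qnorm rbinom rlnorm rmultinom
#'   rnorm runif sd setNames aggregate quantile
#' @importFrom utils read.delim write.table
NULL

# INFO-level audit trail for every filtering operation: counts before/after.
# Silenced unless options(vdomics.verbose = TRUE).
vdom_log <- function(fmt, ...) {
  if (isTRUE(getOption("vdomics.verbose", FALSE))) {
    message(sprintf(paste0("[vdomics] ", fmt), ...))
  }
  invisible(NULL)
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
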