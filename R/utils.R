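#' @keywords internal
"_PACKAGE"

#' @importFrom stats integrate runif setNames dnorm pnorm var
#' @importFrom utils read.delim write.table head tail
NULL

# numeric tolerance used across constructors/validators
.tol <- 1e-9

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate fn with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
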