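#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats rnorm rbinom runif cor t.test plogis setNames
#' @importFrom utils read.delim write.table read.csv packageVersion
NULL

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
# All randomness in the package flows through this; no global state leaks.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_fmt <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "rwrscreen_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
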