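#' @keywords internal
"_PACKAGE"

#' @importFrom stats approxfun coef cor lm mad median nls.control pnorm
#'   quantile rbinom rexp rnorm rpois runif sd setNames var
#' @importFrom utils head read.csv write.csv tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# Derive a reproducible sub-seed for a named random substream from the master
# seed, so that e.g. the photophysics draws do not perturb the binding draws.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483587
  as.integer((abs(seed) + h * 7919) %% 2147483587 + 1)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

# polynomial rolling hash of a canonical text rendering; used for run
# manifests (collision resistance needs are modest: change detection only)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop2(name, " must be a single positive finite number")
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop2(name, " must be a single non-negative finite number")
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop2(name, " must lie in [0, 1]")
  invisible(x)
}
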