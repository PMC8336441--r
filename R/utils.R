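#' @useDynLib pathcnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor median pchisq prcomp rbinom rexp rnorm runif sd wilcox.test predict
#' @importFrom utils head read.delim write.table
#' @importFrom rlang abort warn .data
NULL

# Deterministic seed derivation: every randomised stage draws from its own
# substream so inserting a stage never shifts another stage's draws.
derive_seed <- function(master, ...) {
  key <- paste(c(format(master), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647L
  as.integer((h + as.numeric(master)) %% 2147483647)
}

# Run code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) abort(msg)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)

is_fraction <- function(x, lo = 0, hi = 1, open_hi = TRUE) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= lo &&
    (if (open_hi) x < hi else x <= hi)
}
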