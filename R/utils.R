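# Shared low-level helpers: base alphabet, seed derivation, validation.

BASES <- c("A", "C", "G", "T")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Derive a reproducible sub-seed from a master seed
#'
#' Random streams in the simulator are separated by purpose and by sample so
#' that re-running one stage does not perturb another. Each stream seeds a
#' fresh RNG with a value derived deterministically from the master seed and
#' a set of string/integer tags. The derivation is a simple polynomial hash
#' kept strictly below 2^31 so it is a valid R integer seed.
#'
#' @param seed master integer seed
#' @param ... character or integer tags identifying the stream
#' @return an integer in `[0, 2^31 - 1)`
#' @export
derive_seed <- function(seed, ...) {
  tags <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(seed %% 2147483647)
  for (tag in tags) {
    for (cp in utf8ToInt(tag)) {
      h <- (h * 131 + cp) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `expr` with a temporary RNG state seeded from `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stopf(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

reverse_complement <- function(s) {
  vapply(strsplit(s, ""), function(ch) {
    paste(rev(unname(BASE_COMPLEMENT[ch])), collapse = "")
  }, character(1))
}
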