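# Shared internal helpers.

#' @keywords internal
"_PACKAGE"

#' Inverse logit
#' @param x numeric vector on the logit scale.
#' @return numeric vector in (0, 1).
#' @keywords internal
invlogit <- function(x) 1 / (1 + exp(-x))

#' Logit
#' @param p numeric vector in (0, 1).
#' @return numeric vector on the logit scale.
#' @keywords internal
logit <- function(p) log(p / (1 - p))

# Derive a reproducible child seed from a parent seed and a stage label.
# Keeps results below 2^31 so they remain valid R integers.
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483399) + 1L
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consistent stop() with sprintf formatting.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
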