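# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package internals never disturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a user seed, kept < 2^31.
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483629
}

stop_if_na <- function(x, what) {
  if (anyNA(x)) {
    stop(sprintf("%s contains missing values; inputs must be complete", what),
         call. = FALSE)
  }
  invisible(x)
}

check_unique_ids <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate %s: %s", what,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

check_aligned <- function(a, b, what) {
  if (length(a) != length(b) || !all(a == b)) {
    stop(sprintf("%s are not aligned", what), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
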