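# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (if (allow_zero) x < 0 else x <= 0)) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (allow_zero) "non-negative" else "positive"), call. = FALSE)
  }
  invisible(x)
}

# Collapse timestamps that coincide at 1 ms resolution and return them sorted.
dedup_times <- function(t, resolution = 1e-3) {
  if (length(t) == 0L) return(numeric(0))
  t <- sort(t)
  t[!duplicated(round(t / resolution))]
}

# Derive a reproducible child seed from a base seed and a stream label,
# staying inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  x <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + x) %% 2147483587) + 1L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
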