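# internal numeric / RNG helpers

# log(sum(exp(x))) without overflow; tolerates -Inf entries
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.  seed = NULL uses the current stream.
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# One master seed spawns per-run integer seeds deterministically.
draw_run_seeds <- function(n) sample.int(2147483646L, n)

# memory keys for order-n transitions at (1-based) positions t, t > n;
# key lists the previous tokens most-recent first, "" for n = 0
memory_keys <- function(x, n, t) {
  if (n == 0L) return(rep("", length(t)))
  cols <- lapply(seq_len(n), function(k) x[t - k])
  do.call(paste, c(cols, list(sep = ",")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
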