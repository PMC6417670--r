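# internal helpers shared across modules

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed means "use the current RNG stream"
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# derive a reproducible child seed below 2^31 from a parent seed and index
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + i * 1009) %% 2147483647
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

stop_domain <- function(msg, class) {
  rlang::abort(msg, class = c(class, "diffclone_error"))
}
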