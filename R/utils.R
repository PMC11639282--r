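# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# log-spaced time grid
log_times <- function(n, t_min, t_max) {
  stopifnot(n >= 2, t_min > 0, t_max > t_min)
  10^seq(log10(t_min), log10(t_max), length.out = n)
}
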