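# Run `code` under a temporary RNG stream seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL leaves the global stream untouched
# (draws then consume it, as base R generators do).
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
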